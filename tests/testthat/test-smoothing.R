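test_that("interval construction covers the path in R-length pieces", {
  tr <- straight_traj(n = 401, spacing = 2.5)  # 1000 cm
  iv <- build_intervals(tr, 100)
  expect_equal(nrow(iv), 10)
  expect_equal(iv$arc_start, seq(0, 900, by = 100))
  expect_equal(iv$arc_end - iv$arc_start, rep(100, 10))

  tr2 <- straight_traj(n = 101, spacing = 2.5)  # 250 cm
  iv2 <- build_intervals(tr2, 100)
  expect_equal(iv2$arc_end - iv2$arc_start, c(100, 100, 50))

  tr3 <- straight_traj(n = 21, spacing = 2.5)  # 50 cm, shorter than R
  expect_equal(nrow(build_intervals(tr3, 100)), 1)
})

test_that("class weights clip shares before inversion and renormalise", {
  expect_equal(class_weights(c(A = 0.5, B = 0.5)), c(A = 0.5, B = 0.5))

  w <- class_weights(c(A = 0.8, B = 0.2))
  expect_equal(unname(w), c(2 / 7, 5 / 7), tolerance = 1e-12)

  # a sub-1% share is clipped up to 1% before inversion: capped advantage
  w2 <- class_weights(c(A = 0.995, B = 0.005))
  expect_equal(unname(w2), c(1 / 51, 50 / 51), tolerance = 1e-12)

  expect_equal(sum(class_weights(c(A = 0.3, B = 0.3, C = 0.4))), 1)
  expect_named(class_weights(c(A = 0.7, B = 0.3, C = 0)), c("A", "B"))
  expect_error(class_weights(c(A = 0, B = 0)), "zero")
})

test_that("the Gaussian vote kernel admits segments up to twice sigma", {
  s <- 100
  k <- exp(-(2 * s)^2 / (2 * s^2))
  expect_equal(k, exp(-2))
  expect_equal(sprintf("%.2f", k), "0.14")
  cfg <- smoothing_config(sigma = s)
  expect_true(k >= cfg$kernel_cutoff - 1e-12)  # d = 2*sigma still votes
  expect_lt(exp(-(2.01 * s)^2 / (2 * s^2)), cfg$kernel_cutoff)
})

test_that("interval classification equals the brute-force triple loop", {
  cfg <- smoothing_config(sigma = 100)
  w <- c(TT = 0.5, IC = 0.3, SC = 0.2)
  for (seed in 1:5) {
    fx <- random_smoothing_fixture(seed)
    iv <- build_intervals(fx$tr, 100)
    got <- classify_intervals(iv, fx$st, cfg, w)
    ref <- brute_classify(iv, fx$st, cfg, w)
    expect_equal(got$class, ref$class)
    expect_equal(unname(as.matrix(got[, paste0("vote_", names(w))])),
                 unname(ref$votes), tolerance = 1e-12)
  }
})

test_that("a single overlapping classified segment wins its interval", {
  tr <- straight_traj(n = 101, spacing = 2.5)
  iv <- build_intervals(tr, 100)
  st <- segment_trajectory(tr, segmentation_config(250, 0))
  st$class <- "TT"
  got <- classify_intervals(iv, st, smoothing_config(100),
                            c(TT = 0.6, IC = 0.4))
  expect_true(all(got$class == "TT"))
})

test_that("raising sigma with one contributing class never changes the winner", {
  fx <- random_smoothing_fixture(3)
  fx$st$class <- "TT"
  iv <- build_intervals(fx$tr, 100)
  base <- classify_intervals(iv, fx$st, smoothing_config(100), c(TT = 1))
  for (s in c(150, 300, 1000)) {
    alt <- classify_intervals(iv, fx$st, smoothing_config(s), c(TT = 1))
    changed <- base$class != UNDEFINED & alt$class != base$class
    expect_false(any(changed))
  }
})

test_that("transition counting removes undefined intervals first", {
  expect_equal(count_transitions(c("TT", "TT", "IC", "IC", "TT")), 2)
  expect_equal(count_transitions(rep("SC", 6)), 0)
  expect_equal(count_transitions(c("TT", UNDEFINED, "TT")), 0)
  expect_equal(count_transitions(c("TT", UNDEFINED, "IC")), 1)
  expect_equal(count_transitions(character()), 0)
})

test_that("short trajectories map to direct finding unless labelled", {
  a <- fixture_arena()
  short <- straight_traj(n = 31, spacing = 2.5, animal = "s1")
  long <- random_traj(n = 400, seed = 2, step = 5)
  trajs <- list(s1_d1_t1 = short, rw_d1_t1 = long)
  sc <- segment_cohort(trajs, segmentation_config(250, 0.7))
  segtab <- sc$segments
  segtab$class <- "TT"
  iv <- smooth_cohort(trajs, segtab, a,
                      short_trajectories = sc$short_trajectories)
  expect_true(all(iv$class[iv$traj_id == "s1_d1_t1"] == "DF"))

  iv2 <- smooth_cohort(trajs, segtab, a,
                       short_trajectories = sc$short_trajectories,
                       whole_path_labels = c(s1_d1_t1 = "SC"))
  expect_true(all(iv2$class[iv2$traj_id == "s1_d1_t1"] == "SC"))
})

test_that("strategy profiles normalise per trial and count transitions", {
  d <- data.frame(
    traj_id = rep(c("a_d1_t1", "b_d1_t1"), each = 4),
    animal = rep(c("a", "b"), each = 4),
    group = rep(c("g1", "g2"), each = 4),
    day = 1, trial = 1, ordinal = rep(1:4, 2),
    arc_start = 0, arc_end = 100,
    class = c("TT", "TT", "TT", "TT",
              "TT", "IC", UNDEFINED, "IC"),
    stringsAsFactors = FALSE)
  prof <- strategy_profile(d)
  p1 <- prof$percentages[prof$percentages$group == "g1", ]
  expect_equal(p1$pct[p1$class == "TT"], 100)
  byg <- tapply(prof$percentages$pct, prof$percentages$group, sum)
  expect_equal(as.numeric(byg), c(100, 100))
  expect_equal(prof$undefined$pct_undefined[prof$undefined$group == "g2"],
               25)
  tr2 <- prof$transitions[prof$transitions$group == "g2", ]
  expect_equal(tr2$transitions, 1)  # TT -> IC with the undefined bridged
})
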