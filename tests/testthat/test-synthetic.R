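test_that("strategy paths are seed-deterministic and arena-bounded", {
  a <- fixture_arena()
  for (strat in strategy_codes()) {
    t1 <- generate_strategy_path(strat, a, seed = 7)
    t2 <- generate_strategy_path(strat, a, seed = 7)
    expect_identical(t1$points, t2$points)
    r <- sqrt(t1$points$x^2 + t1$points$y^2)
    expect_true(all(r <= a$radius + 1e-9))
  }
  expect_error(generate_strategy_path("ZZ", a), "unknown strategy")
})

test_that("stereotyped paths express their defining geometry", {
  a <- fixture_arena()
  # thigmotaxis hugs the wall
  for (s in 1:3) {
    tt <- generate_strategy_path("TT", a, seed = s)
    r <- sqrt(tt$points$x^2 + tt$points$y^2)
    expect_gte(mean(r > 0.8 * a$radius), 0.9)
  }
  # direct finding is near-straight and ends on the platform
  for (s in 1:3) {
    df <- generate_strategy_path("DF", a, seed = s)
    p <- df$points
    pm <- path_metrics(df)
    disp <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
    expect_gt(disp / pm$path_length, 0.9)
    dend <- sqrt((p$x[nrow(p)] - a$platform_centre[1])^2 +
                 (p$y[nrow(p)] - a$platform_centre[2])^2)
    expect_lte(dend, a$platform_radius + 1e-9)
  }
  # chaining response circles at the platform's distance from the centre
  cr <- generate_strategy_path("CR", a, seed = 2)
  r <- sqrt(cr$points$x^2 + cr$points$y^2)
  rc <- sqrt(sum(a$platform_centre^2))
  expect_lt(abs(median(r) - rc), 0.15 * a$radius)
})

test_that("cohorts contain one trajectory per animal-trial with bout truth", {
  a <- fixture_arena()
  spec <- cohort_spec(group_sizes = c(g1 = 3, g2 = 2),
                      mixtures = setNames(default_mixtures(), c("g1", "g2")),
                      trials = 4, trials_per_day = 2, seed = 21)
  cohort <- generate_cohort(spec, a)
  expect_length(cohort$trajectories, 5 * 4)
  days <- vapply(cohort$trajectories, `[[`, integer(1), "day")
  expect_setequal(unique(days), 1:2)

  tt <- cohort$truth
  expect_true(all(tt$class %in% strategy_codes()))
  # bout arcs tile each trajectory's path without gaps
  for (id in names(cohort$trajectories)[1:5]) {
    bt <- tt[tt$traj_id == id, ]
    expect_equal(bt$arc_start[1], 0)
    if (nrow(bt) > 1) {
      expect_equal(bt$arc_start[-1], bt$arc_end[-nrow(bt)])
    }
    L <- max(cumulative_arc_length(cohort$trajectories[[id]]))
    expect_equal(bt$arc_end[nrow(bt)], L, tolerance = 1e-9)
  }

  # determinism under the master seed
  cohort2 <- generate_cohort(spec, a)
  expect_identical(cohort$truth, cohort2$truth)
  expect_identical(cohort$trajectories[[1]]$points,
                   cohort2$trajectories[[1]]$points)
})

test_that("a pure direct-finding mixture produces only DF bouts", {
  a <- fixture_arena()
  mix <- list(g = c(TT = 0, IC = 0, SC = 0, FS = 0, CR = 0, SO = 0,
                    SS = 0, ST = 0, DF = 1))
  spec <- cohort_spec(group_sizes = c(g = 3), mixtures = mix, trials = 3,
                      seed = 4)
  cohort <- generate_cohort(spec, a)
  expect_true(all(cohort$truth$class == "DF"))
})

test_that("ground-truth class shares track the mixture weights", {
  a <- fixture_arena()
  spec <- cohort_spec(group_sizes = c(g = 8), trials = 8, seed = 31,
                      mixtures = list(g = c(TT = 0.5, SC = 0.3, DF = 0.0,
                                            IC = 0, FS = 0, CR = 0.2,
                                            SO = 0, SS = 0, ST = 0)))
  cohort <- generate_cohort(spec, a)
  tt <- cohort$truth
  arc <- tt$arc_end - tt$arc_start
  shares <- tapply(arc, tt$class, sum) / sum(arc)
  expect_lt(abs(shares[["TT"]] - 0.5), 0.1)
  expect_lt(abs(shares[["SC"]] - 0.3), 0.1)
  expect_lt(abs(shares[["CR"]] - 0.2), 0.1)
})

test_that("auto labels are stratified, bounded and bout-aware", {
  cohort <- small_cohort(seed = 12, sizes = c(s = 4, c = 4), trials = 4)
  sc <- segment_cohort(cohort$trajectories, segmentation_config(250, 0.7))
  labs <- auto_label(sc$segments, cohort$truth, fraction = 0.10, seed = 3)
  expect_s3_class(labs, "mwm_labels")
  expect_lt(nrow(labs), 0.25 * nrow(sc$segments))
  expect_gt(nrow(labs), 0.02 * nrow(sc$segments))
  expect_true(all(labs$segment_id %in% sc$segments$segment_id))

  labs2 <- auto_label(sc$segments, cohort$truth, fraction = 0.10, seed = 3)
  expect_identical(labs, labs2)

  # a segment fully inside one bout gets exactly one label
  one_bout <- sc$segments[1, ]
  bt <- cohort$truth[cohort$truth$traj_id == one_bout$traj_id, ]
  inside <- bt$arc_start <= one_bout$arc_start &
    bt$arc_end >= one_bout$arc_end
  if (any(inside)) {
    cls <- arc_truth_classes(one_bout, cohort$truth)
    expect_equal(cls, bt$class[inside][1])
  }

  # truth classes agree with the dominant-share rule on a constructed case
  seg <- data.frame(traj_id = "x_d1_t1", arc_start = 0, arc_end = 100)
  tr <- data.frame(traj_id = "x_d1_t1", bout = 1:2,
                   class = c("TT", "SC"), start_idx = c(1, 10),
                   end_idx = c(10, 20), arc_start = c(0, 60),
                   arc_end = c(60, 200))
  expect_equal(arc_truth_classes(seg, tr), "TT")
})
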