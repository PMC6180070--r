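circle_segment <- function(r = 80, n = 100, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n)
  pts <- data.frame(t = seq_len(n), x = centre[1] + r * cos(th),
                    y = centre[2] + r * sin(th))
  structure(list(points = pts,
                 arc_length = sum(sqrt(diff(pts$x)^2 + diff(pts$y)^2)),
                 centre = centre),
            class = "mwm_segment")
}

seg_from_xy <- function(x, y) {
  pts <- data.frame(t = seq_along(x), x = x, y = y)
  structure(list(points = pts,
                 arc_length = sum(sqrt(diff(x)^2 + diff(y)^2)),
                 centre = c(mean(x), mean(y))),
            class = "mwm_segment")
}

test_that("features of canonical shapes match geometry", {
  a <- fixture_arena()
  f <- compute_features(circle_segment(80), a)
  expect_equal(unname(f["median_dist_centre"]), 0.8, tolerance = 1e-6)
  expect_lt(f["inner_radius_variation"], 1e-6)
  expect_lt(f["iqr_dist_centre"], 1e-6)

  # straight radial run from centre to wall
  g <- compute_features(seg_from_xy(seq(5, 95, by = 5), rep(0, 19)), a)
  expect_equal(unname(g["efficiency"]), 1)
  expect_equal(unname(g["eccentricity"]), 1)
  expect_equal(unname(g["sum_abs_turn"]), 0)

  # a segment through the platform centre
  pc <- a$platform_centre
  h <- compute_features(seg_from_xy(c(pc[1] - 10, pc[1], pc[1] + 10),
                                    c(pc[2], pc[2], pc[2])), a)
  expect_equal(unname(h["min_dist_platform"]), 0)
})

test_that("degenerate segments are rejected", {
  a <- fixture_arena()
  expect_error(compute_features(seg_from_xy(c(1, 1, 1), c(2, 2, 2)), a),
               "degenerate")
  expect_error(compute_features(seg_from_xy(c(1, 2), c(1, 2)), a),
               "at least 3")
})

test_that("features are invariant to rigid motion and uniform rescaling", {
  set.seed(4)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  x <- 30 + 10 * x / max(abs(x)); y <- 10 * y / max(abs(y))
  a <- fixture_arena()
  f0 <- compute_features(seg_from_xy(x, y), a)

  th <- 1.1
  rot <- function(px, py) list(x = cos(th) * px - sin(th) * py,
                               y = sin(th) * px + cos(th) * py)
  # rotate arena (centre and platform) together with the points
  pr <- rot(x, y)
  pc <- rot(a$platform_centre[1], a$platform_centre[2])
  a_rot <- mwm_arena(radius = a$radius, centre = c(0, 0),
                     platform_centre = c(pc$x, pc$y),
                     platform_radius = a$platform_radius)
  f1 <- compute_features(seg_from_xy(pr$x, pr$y), a_rot)
  expect_equal(f1, f0, tolerance = 1e-9)

  # translation of everything
  a_tr <- mwm_arena(radius = a$radius, centre = c(50, -20),
                    platform_centre = a$platform_centre + c(50, -20),
                    platform_radius = a$platform_radius)
  f2 <- compute_features(seg_from_xy(x + 50, y - 20), a_tr)
  expect_equal(f2, f0, tolerance = 1e-9)

  # uniform rescaling of coordinates and arena
  s <- 2.5
  a_sc <- mwm_arena(radius = s * a$radius, centre = c(0, 0),
                    platform_centre = s * a$platform_centre,
                    platform_radius = s * a$platform_radius)
  f3 <- compute_features(seg_from_xy(s * x, s * y), a_sc)
  expect_equal(f3, f0, tolerance = 1e-9)
})

test_that("feature matrix standardisation is reusable and guards zero IQR", {
  cohort <- small_cohort(seed = 2)
  a <- fixture_arena()
  sc <- segment_cohort(cohort$trajectories, segmentation_config(250, 0.7))
  raw <- feature_matrix(sc$segments, cohort$trajectories, a,
                        standardise = FALSE)
  std <- feature_matrix(sc$segments, cohort$trajectories, a)
  expect_equal(dim(raw), c(nrow(sc$segments), 8))
  expect_equal(rownames(std), sc$segments$segment_id)
  expect_equal(unname(apply(std, 2, median)), rep(0, 8), tolerance = 1e-9)

  again <- apply_feature_scaling(raw, attr(std, "center"),
                                 attr(std, "scale"), attr(std, "clip"))
  expect_equal(unname(again), unname(std[, ]), tolerance = 1e-12)

  # straight path: turn sum and efficiency are constant across segments,
  # so those columns have zero IQR and must warn and fall back to scale 1
  tr <- straight_traj(n = 401, spacing = 2.5)
  st <- segment_trajectory(tr, segmentation_config(250, 0.7))
  expect_warning(
    fm <- feature_matrix(st, setNames(list(tr), st$traj_id[1]),
                         fixture_arena()),
    "zero-IQR")
  expect_equal(unname(attr(fm, "scale")[c("sum_abs_turn", "efficiency")]),
               c(1, 1))
})

test_that("single-segment matrix equals compute_features", {
  cohort <- small_cohort(seed = 3, sizes = c(s = 1, c = 1), trials = 1)
  a <- fixture_arena()
  sc <- segment_cohort(cohort$trajectories, segmentation_config(250, 0.7))
  one <- sc$segments[1, , drop = FALSE]
  fm <- feature_matrix(one, cohort$trajectories, a, standardise = FALSE)
  tr <- cohort$trajectories[[one$traj_id]]
  expect_equal(fm[1, ], compute_features(extract_segment(tr, one), a))
})

test_that("generator output is separable on the key features", {
  a <- fixture_arena()
  params <- strategy_params()
  tt <- generate_strategy_path("TT", a, params, seed = 42)
  df <- generate_strategy_path("DF", a, params, seed = 42)
  st_tt <- segment_trajectory(tt, segmentation_config(250, 0.7))
  f_tt <- feature_matrix(st_tt, setNames(list(tt), st_tt$traj_id[1]), a,
                         standardise = FALSE)
  expect_true(all(f_tt[, "median_dist_centre"] > 0.8))
  pm <- path_metrics(df)
  p <- df$points
  disp <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
  expect_gt(disp / pm$path_length, 0.9)
})
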