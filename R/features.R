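#' Eight geometric features of one path segment
#'
#' Descriptors of the segment's shape and position relative to the arena,
#' used for strategy clustering.  Distances are normalised by the arena
#' radius R so the features are invariant to rotation, translation and
#' uniform rescaling of the setup:
#'
#' * `median_dist_centre`, `iqr_dist_centre`: median and IQR of the
#'   sample distances to the arena centre, in units of R.
#' * `focus`: `1 - 2 * r_spread / L`, clamped to \[0, 1\], where
#'   `r_spread` is the mean distance of the samples to their centroid and
#'   L the segment arc length; near 1 for tight, locally confined search.
#' * `eccentricity`: `sqrt(1 - lambda2/lambda1)` of the coordinate
#'   covariance eigenvalues; 1 for a straight line, 0 for an isotropic
#'   cloud.
#' * `efficiency`: endpoint displacement over arc length, in \[0, 1\].
#' * `inner_radius_variation`: coefficient of variation (sd/mean) of the
#'   distance to the arena centre; near 0 for wall-hugging or circling.
#' * `sum_abs_turn`: summed absolute heading change (radians) over
#'   consecutive displacement steps, with steps shorter than 0.1 cm merged
#'   to suppress tracking jitter.
#' * `min_dist_platform`: minimum distance to the platform centre, in R.
#'
#' @param seg An `mwm_segment` from [extract_segment()] (at least 3 points).
#' @param arena An [mwm_arena()].
#' @return Named numeric vector of the eight features.
#' @export
compute_features <- function(seg, arena) {
  p <- seg$points
  if (nrow(p) < 3) stop("segment needs at least 3 points")
  R <- arena$radius
  dx <- p$x - arena$centre[1]
  dy <- p$y - arena$centre[2]
  r <- sqrt(dx^2 + dy^2)
  if (max(r) - min(r) == 0 && stats::var(p$x) == 0 && stats::var(p$y) == 0) {
    stop("degenerate segment: all points identical")
  }
  L <- seg$arc_length
  if (!is.finite(L) || L <= 0) {
    L <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  }
  if (L <= 0) stop("degenerate segment: zero arc length")

  centroid <- c(mean(p$x), mean(p$y))
  r_spread <- mean(sqrt((p$x - centroid[1])^2 + (p$y - centroid[2])^2))
  focus <- min(1, max(0, 1 - 2 * r_spread / L))

  cv <- cov(cbind(p$x, p$y))
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  eccentricity <- if (ev[1] <= 0) 0 else sqrt(1 - ev[2] / ev[1])

  disp <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
  efficiency <- min(1, disp / L)

  mr <- mean(r)
  irv <- if (mr > 0) sd(r) / mr else 0

  sum_abs_turn <- total_abs_turn(p$x, p$y, min_step = 0.1)

  dp <- sqrt((p$x - arena$platform_centre[1])^2 +
             (p$y - arena$platform_centre[2])^2)

  c(median_dist_centre = median(r) / R,
    iqr_dist_centre = unname(quantile(r, 0.75) - quantile(r, 0.25)) / R,
    focus = focus,
    eccentricity = eccentricity,
    efficiency = efficiency,
    inner_radius_variation = irv,
    sum_abs_turn = sum_abs_turn,
    min_dist_platform = min(dp) / R)
}

# Summed absolute heading change; steps below min_step cm are merged with
# their successors so that stationary jitter does not inflate the turn sum.
total_abs_turn <- function(x, y, min_step = 0.1) {
  n <- length(x)
  kept_x <- x[1]; kept_y <- y[1]
  px <- numeric(n); py <- numeric(n); m <- 0L
  for (i in 2:n) {
    if (sqrt((x[i] - kept_x)^2 + (y[i] - kept_y)^2) >= min_step) {
      m <- m + 1L
      px[m] <- x[i] - kept_x
      py[m] <- y[i] - kept_y
      kept_x <- x[i]; kept_y <- y[i]
    }
  }
  if (m < 2) return(0)
  h <- atan2(py[seq_len(m)], px[seq_len(m)])
  dh <- diff(h)
  dh <- atan2(sin(dh), cos(dh))  # wrap to (-pi, pi]
  sum(abs(dh))
}

#' Feature matrix over a segment table
#'
#' Computes [compute_features()] for every row of a segment table, in row
#' order.  With `standardise = TRUE`, columns are centred by their median
#' and scaled by their IQR; the location/scale parameters are stored as
#' attributes so the identical transform can be re-applied to new data
#' with [apply_feature_scaling()].
#'
#' Standardised values are clamped to `[-clip, clip]` robust units:
#' several features (notably the turn sum) are heavy-tailed and a handful
#' of extreme segments would otherwise dominate every distance
#' computation downstream.
#'
#' @param segtab Segment table from [segment_cohort()] or
#'   [segment_trajectory()].
#' @param trajs Named list of trajectories (names are `traj_id`s).
#' @param arena An [mwm_arena()].
#' @param standardise Standardise columns (default TRUE).
#' @param clip Winsorisation bound in robust units (default 4; `Inf`
#'   disables).
#' @return Numeric matrix (segments x 8) with rownames = `segment_id` and,
#'   when standardised, attributes `center`, `scale` and `clip`.
#' @export
feature_matrix <- function(segtab, trajs, arena, standardise = TRUE,
                           clip = 4) {
  if (nrow(segtab) < 1) stop("no segments")
  feats <- matrix(NA_real_, nrow(segtab), 8)
  for (i in seq_len(nrow(segtab))) {
    seg <- extract_segment(trajs[[segtab$traj_id[i]]], segtab[i, ])
    feats[i, ] <- compute_features(seg, arena)
  }
  colnames(feats) <- names(compute_features(
    extract_segment(trajs[[segtab$traj_id[1]]], segtab[1, ]), arena))
  rownames(feats) <- segtab$segment_id
  if (standardise) {
    ctr <- apply(feats, 2, median)
    scl <- apply(feats, 2, function(v) quantile(v, 0.75) - quantile(v, 0.25))
    zero <- scl <= 0
    if (any(zero)) {
      warning("zero-IQR feature column(s): ",
              paste(colnames(feats)[zero], collapse = ", "),
              "; scale set to 1")
      scl[zero] <- 1
    }
    feats <- sweep(sweep(feats, 2, ctr, "-"), 2, scl, "/")
    feats <- pmin(pmax(feats, -clip), clip)
    attr(feats, "center") <- ctr
    attr(feats, "scale") <- scl
    attr(feats, "clip") <- clip
    attr(feats, "standardised") <- TRUE
  }
  feats
}

#' Re-apply stored feature standardisation
#'
#' @param feats Raw (unstandardised) feature matrix.
#' @param center,scale Per-column location and scale, e.g. the attributes
#'   of a standardised [feature_matrix()].
#' @param clip Winsorisation bound in robust units (default 4).
#' @return Standardised matrix.
#' @export
apply_feature_scaling <- function(feats, center, scale, clip = 4) {
  out <- sweep(sweep(feats, 2, center, "-"), 2, scale, "/")
  pmin(pmax(out, -clip), clip)
}
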