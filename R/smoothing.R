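#' Smoothing configuration for mapping segment classes onto paths
#'
#' Swimming paths are re-divided into consecutive non-overlapping arc
#' intervals of length R (the arena radius) and each interval receives the
#' class winning a Gaussian-weighted vote of the overlapping classified
#' segments.  The kernel width `sigma` defaults to R for proportionality
#' with the arena; segments farther than `2 * sigma` from the interval
#' centre are cut off (kernel value `exp(-2)`, about 0.14).  Class weights
#' are inversely proportional to class frequency, with the frequency
#' clipped into `weight_bounds` so rare classes are neither lost nor
#' explosive.
#'
#' @param sigma Gaussian kernel width in cm (typically the arena radius).
#' @param kernel_cutoff Minimum kernel value for a segment to vote
#'   (default `exp(-2)`, the value at distance `2 * sigma`, inclusive).
#' @param weight_bounds Clipping bounds for class frequencies before
#'   inversion (default `c(0.01, 0.5)`).
#' @return Object of class `mwm_smoothing_config`.
#' @export
smoothing_config <- function(sigma, kernel_cutoff = exp(-2),
                             weight_bounds = c(0.01, 0.5)) {
  stopifnot(sigma > 0, kernel_cutoff > 0, kernel_cutoff < 1,
            length(weight_bounds) == 2, weight_bounds[1] <= weight_bounds[2])
  structure(list(sigma = sigma, kernel_cutoff = kernel_cutoff,
                 weight_bounds = weight_bounds),
            class = "mwm_smoothing_config")
}

#' Divide a trajectory into consecutive arc intervals of length R
#'
#' Intervals abut without overlap; a trailing remainder is kept as a
#' shorter final interval.  The interval centre is the sample nearest the
#' interval's mid arc position.
#'
#' @param traj An `mwm_trajectory`.
#' @param R Interval arc length in cm (the arena radius).
#' @return Data frame: `ordinal`, `arc_start`, `arc_end`, `cx`, `cy`.
#' @export
build_intervals <- function(traj, R) {
  stopifnot(R > 0)
  cum <- cumulative_arc_length(traj)
  L <- cum[length(cum)]
  n_int <- max(1L, ceiling((L - 1e-9) / R))
  starts <- (seq_len(n_int) - 1) * R
  rows <- lapply(seq_along(starts), function(i) {
    a <- starts[i]
    b <- min(a + R, L)
    mid <- which.min(abs(cum - (a + b) / 2))
    data.frame(ordinal = i, arc_start = a, arc_end = b,
               cx = traj$points$x[mid], cy = traj$points$y[mid])
  })
  do.call(rbind, rows)
}

#' Frequency-inverse class weights for the interval vote
#'
#' Class shares are clipped into `bounds`, inverted and normalised to sum
#' to one, so rare classes are up-weighted without being allowed to
#' dominate.  Classes with zero share are excluded.
#'
#' @param P Named numeric vector of class shares over classified segments
#'   (sums to 1).
#' @param bounds Clipping bounds (default `c(0.01, 0.5)`).
#' @return Named numeric weights summing to 1.
#' @export
class_weights <- function(P, bounds = c(0.01, 0.5)) {
  if (all(P == 0)) stop("all class shares are zero")
  P <- P[P > 0]
  w <- 1 / pmin(pmax(P, bounds[1]), bounds[2])
  w / sum(w)
}

#' Gaussian-weighted interval classification
#'
#' For each interval, every classified segment of the same trajectory
#' whose arc range overlaps the interval and whose kernel value
#' `exp(-d^2 / (2 sigma^2))` reaches the cutoff contributes its class
#' weight times the kernel value, where d is the Euclidean distance from
#' the segment centre to the interval centre.  The interval takes the
#' class with the largest vote sum; an empty candidate set or an exact tie
#' yields `UNDEFINED`.
#'
#' @param intervals Interval table from [build_intervals()] for one
#'   trajectory.
#' @param segtab Segment table for the same trajectory with a `class`
#'   column (`UNDEFINED` entries are excluded from voting).
#' @param cfg An [smoothing_config()].
#' @param weights Named class weights from [class_weights()].
#' @return The interval table with columns `class` and one vote-sum column
#'   per weighted class (`vote_<code>`).
#' @export
classify_intervals <- function(intervals, segtab, cfg, weights) {
  classes <- names(weights)
  votes <- matrix(0, nrow(intervals), length(classes),
                  dimnames = list(NULL, classes))
  seg_ok <- segtab$class %in% classes
  out_class <- rep(UNDEFINED, nrow(intervals))
  if (any(seg_ok)) {
    st <- segtab[seg_ok, , drop = FALSE]
    for (i in seq_len(nrow(intervals))) {
      ov <- st$arc_start < intervals$arc_end[i] - 1e-9 &
            st$arc_end > intervals$arc_start[i] + 1e-9
      if (!any(ov)) next
      d2 <- (st$cx[ov] - intervals$cx[i])^2 + (st$cy[ov] - intervals$cy[i])^2
      kern <- exp(-d2 / (2 * cfg$sigma^2))
      pass <- kern >= cfg$kernel_cutoff - 1e-12
      if (!any(pass)) next
      cls <- st$class[ov][pass]
      contrib <- weights[cls] * kern[pass]
      for (k in unique(cls)) {
        votes[i, k] <- sum(contrib[cls == k])
      }
      v <- votes[i, ]
      top <- which(v == max(v) & v > 0)
      if (length(top) == 1) out_class[i] <- classes[top]
    }
  }
  res <- intervals
  res$class <- out_class
  vote_df <- as.data.frame(votes)
  names(vote_df) <- paste0("vote_", classes)
  cbind(res, vote_df)
}

#' Count strategy transitions along one trajectory
#'
#' `UNDEFINED` intervals are removed first, then adjacent pairs with
#' differing classes are counted.
#'
#' @param classes Ordered character vector of interval classes.
#' @return Integer transition count.
#' @export
count_transitions <- function(classes) {
  cl <- classes[classes != UNDEFINED]
  if (length(cl) < 2) return(0L)
  sum(cl[-1] != cl[-length(cl)])
}

#' Smooth segment classes onto the full paths of a cohort
#'
#' Computes the experiment-wide class shares over all classified segments,
#' derives the frequency-inverse class weights, then classifies every
#' trajectory's R-length intervals by the Gaussian-weighted vote.
#' Trajectories flagged short (path below the segment length) get all
#' intervals set to Direct Finding, unless a whole-path label was supplied
#' for them.
#'
#' @param trajs Named list of trajectories.
#' @param segtab Combined segment table with a `class` column.
#' @param arena An [mwm_arena()].
#' @param cfg An [smoothing_config()]; default uses `sigma = arena$radius`.
#' @param short_trajectories Character vector of short trajectory ids.
#' @param whole_path_labels Optional named character vector mapping short
#'   trajectory ids to a manually supplied whole-path class.
#' @return Data frame with one row per interval: `traj_id`, `animal`,
#'   `group`, `day`, `trial`, `ordinal`, `arc_start`, `arc_end`, `class`.
#'   The class weights used are stored in attribute `weights`.
#' @export
smooth_cohort <- function(trajs, segtab, arena, cfg = NULL,
                          short_trajectories = character(),
                          whole_path_labels = NULL) {
  if (is.null(cfg)) cfg <- smoothing_config(sigma = arena$radius)
  classified <- segtab$class[segtab$class != UNDEFINED]
  P <- table(factor(classified, levels = strategy_codes()))
  P <- as.numeric(P) / max(1, length(classified))
  names(P) <- strategy_codes()
  w <- class_weights(P, cfg$weight_bounds)
  out <- vector("list", length(trajs))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    id <- traj_id(tr)
    iv <- build_intervals(tr, arena$radius)
    if (id %in% short_trajectories) {
      cls <- if (!is.null(whole_path_labels) && id %in% names(whole_path_labels))
        whole_path_labels[[id]] else "DF"
      iv$class <- cls
    } else {
      st <- segtab[segtab$traj_id == id, , drop = FALSE]
      iv <- classify_intervals(iv, st, cfg, w)[, c(names(iv), "class")]
    }
    iv <- cbind(data.frame(traj_id = id, animal = tr$animal_id,
                           group = tr$group, day = tr$day, trial = tr$trial,
                           stringsAsFactors = FALSE), iv)
    out[[i]] <- iv
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "weights") <- w
  res
}

#' Per-trial strategy profile of a classified cohort
#'
#' For every group and trial: the percentage of intervals per strategy
#' (`UNDEFINED` excluded from the denominator and reported separately) and
#' the per-animal transition counts.
#'
#' @param interval_df Output of [smooth_cohort()].
#' @return List with `percentages` (group, trial, class, pct),
#'   `per_animal` (group, trial, animal, class, pct — the per-animal
#'   percentages used for group comparisons), `transitions` (group, trial,
#'   animal, transitions) and `undefined` (group, trial, pct_undefined).
#' @export
strategy_profile <- function(interval_df) {
  d <- interval_df
  codes <- strategy_codes()
  grp_trial <- unique(d[, c("group", "trial")])
  pct_rows <- list(); und_rows <- list()
  for (r in seq_len(nrow(grp_trial))) {
    g <- grp_trial$group[r]; tr <- grp_trial$trial[r]
    cls <- d$class[d$group == g & d$trial == tr]
    def <- cls[cls != UNDEFINED]
    denom <- max(1, length(def))
    pct_rows[[r]] <- data.frame(group = g, trial = tr, class = codes,
                                pct = 100 * as.numeric(table(factor(def, levels = codes))) / denom,
                                stringsAsFactors = FALSE)
    und_rows[[r]] <- data.frame(group = g, trial = tr,
                                pct_undefined = 100 * mean(cls == UNDEFINED),
                                stringsAsFactors = FALSE)
  }
  key <- unique(d[, c("group", "trial", "animal", "traj_id")])
  pa_rows <- list(); tr_rows <- list()
  for (r in seq_len(nrow(key))) {
    sel <- d$traj_id == key$traj_id[r]
    cls <- d$class[sel][order(d$ordinal[sel])]
    def <- cls[cls != UNDEFINED]
    denom <- max(1, length(def))
    pa_rows[[r]] <- data.frame(group = key$group[r], trial = key$trial[r],
                               animal = key$animal[r], class = codes,
                               pct = 100 * as.numeric(table(factor(def, levels = codes))) / denom,
                               stringsAsFactors = FALSE)
    tr_rows[[r]] <- data.frame(group = key$group[r], trial = key$trial[r],
                               animal = key$animal[r],
                               transitions = count_transitions(cls),
                               stringsAsFactors = FALSE)
  }
  list(percentages = do.call(rbind, pct_rows),
       per_animal = do.call(rbind, pa_rows),
       transitions = do.call(rbind, tr_rows),
       undefined = do.call(rbind, und_rows))
}
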