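#' Segmentation configuration
#'
#' Segments are constant arc-length, heavily overlapping windows along the
#' swimming path.  Useful regimes put the segment length between 2 and 3
#' times the arena radius with 70--90% overlap.
#'
#' @param segment_length Segment arc length in cm (e.g. `2.5 * arena$radius`).
#' @param overlap Fraction of arc shared by consecutive segments, in \[0, 1).
#' @return Object of class `mwm_segmentation_config`.
#' @examples
#' segmentation_config(250, 0.70)
#' @export
segmentation_config <- function(segment_length, overlap = 0.70) {
  stopifnot(is.numeric(segment_length), segment_length > 0,
            is.numeric(overlap), overlap >= 0, overlap < 1)
  structure(list(segment_length = segment_length, overlap = overlap),
            class = "mwm_segmentation_config")
}

#' Cumulative arc length along a trajectory
#'
#' @param traj An `mwm_trajectory`.
#' @return Numeric vector; element i is the path length from sample 1 to i
#'   (so the first element is 0 and the last equals the total path length).
#' @export
cumulative_arc_length <- function(traj) {
  p <- traj$points
  c(0, cumsum(sqrt(diff(p$x)^2 + diff(p$y)^2)))
}

#' Split a trajectory into overlapping constant-arc-length segments
#'
#' Segment starts are placed at arc positions 0, s, 2s, ... with step
#' `s = segment_length * (1 - overlap)`; boundaries snap to the nearest
#' sample at or beyond the target arc position, so each segment is a true
#' run of samples spanning approximately `segment_length` of arc.  A
#' trailing start is kept only if a full-length segment fits.  Trajectories
#' whose total path length is below the segment length return an empty
#' table with the `short` attribute set; downstream they are treated as
#' Direct Finding.
#'
#' @param traj An `mwm_trajectory`.
#' @param cfg A [segmentation_config()].
#' @return Data frame with one row per segment: `segment_id`, `traj_id`,
#'   `ordinal`, `start_idx`, `end_idx` (1-based sample indices, inclusive),
#'   `arc_start`, `arc_end`, `arc_length` (cm) and the segment centre
#'   `cx`, `cy` (the sample nearest half the segment's arc length).
#'   Attributes: `short` (logical), `traj_id`.
#' @export
segment_trajectory <- function(traj, cfg) {
  stopifnot(inherits(cfg, "mwm_segmentation_config"))
  cum <- cumulative_arc_length(traj)
  L <- cum[length(cum)]
  len <- cfg$segment_length
  id <- traj_id(traj)
  empty <- data.frame(segment_id = character(), traj_id = character(),
                      ordinal = integer(), start_idx = integer(),
                      end_idx = integer(), arc_start = numeric(),
                      arc_end = numeric(), arc_length = numeric(),
                      cx = numeric(), cy = numeric(),
                      stringsAsFactors = FALSE)
  if (L < len) {
    attr(empty, "short") <- TRUE
    attr(empty, "traj_id") <- id
    return(empty)
  }
  step <- len * (1 - cfg$overlap)
  starts <- seq(0, L - len, by = step)
  # smallest sample index at or beyond each target arc position
  si <- findInterval(starts - 1e-9, cum) + 1L
  ei <- findInterval(cum[si] + len - 1e-9, cum) + 1L
  keep <- ei <= length(cum)  # a full-length segment must fit
  si <- si[keep]; ei <- ei[keep]
  n_seg <- length(si)
  if (n_seg == 0L) {
    attr(empty, "short") <- TRUE
    attr(empty, "traj_id") <- id
    return(empty)
  }
  arc_len <- cum[ei] - cum[si]
  mid <- vapply(seq_len(n_seg), function(k) {
    rng <- si[k]:ei[k]
    rng[which.min(abs((cum[rng] - cum[si[k]]) - arc_len[k] / 2))]
  }, integer(1))
  out <- data.frame(
    segment_id = sprintf("%s_s%03d", id, seq_len(n_seg)), traj_id = id,
    ordinal = seq_len(n_seg), start_idx = si, end_idx = ei,
    arc_start = cum[si], arc_end = cum[ei], arc_length = arc_len,
    cx = traj$points$x[mid], cy = traj$points$y[mid],
    stringsAsFactors = FALSE)
  attr(out, "short") <- FALSE
  attr(out, "traj_id") <- id
  out
}

#' Segment every trajectory of a cohort
#'
#' @param trajs Named list of `mwm_trajectory` objects.
#' @param cfg A [segmentation_config()].
#' @return List with `segments` (one combined segment table) and
#'   `short_trajectories` (character vector of trajectory ids whose path
#'   was shorter than the segment length).
#' @export
segment_cohort <- function(trajs, cfg) {
  tabs <- lapply(trajs, segment_trajectory, cfg = cfg)
  short <- names(trajs)[vapply(tabs, function(x) isTRUE(attr(x, "short")),
                               logical(1))]
  segs <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  list(segments = segs, short_trajectories = short)
}

#' Extract the sample run of one segment
#'
#' @param traj The segment's `mwm_trajectory`.
#' @param seg_row One row of a [segment_trajectory()] table.
#' @return List of class `mwm_segment` with `points` (data frame),
#'   `arc_length` and `centre`.
#' @export
extract_segment <- function(traj, seg_row) {
  idx <- seg_row$start_idx:seg_row$end_idx
  structure(list(points = traj$points[idx, , drop = FALSE],
                 arc_length = seg_row$arc_length,
                 centre = c(seg_row$cx, seg_row$cy)),
            class = "mwm_segment")
}
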