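#' Arena geometry for a Morris Water Maze
#'
#' Describes the circular pool and the hidden platform.  Defaults follow a
#' common rat setup: a 200 cm diameter arena with a 12 cm diameter platform
#' placed half-way between the centre and the wall of one quadrant.
#'
#' @param radius Arena radius R in cm.
#' @param centre Numeric length-2, arena centre in cm.
#' @param platform_centre Numeric length-2, platform centre in cm.  Default
#'   places the platform at distance R/2 from the centre in the north-east
#'   quadrant.
#' @param platform_radius Platform radius in cm.
#' @return An object of class `mwm_arena`.
#' @examples
#' arena <- mwm_arena()
#' arena$radius
#' @export
mwm_arena <- function(radius = 100, centre = c(0, 0),
                      platform_centre = NULL, platform_radius = 6) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0,
            is.numeric(centre), length(centre) == 2, all(is.finite(centre)),
            is.numeric(platform_radius), platform_radius > 0)
  if (is.null(platform_centre)) {
    platform_centre <- centre + (radius / 2) * c(cos(pi / 4), sin(pi / 4))
  }
  stopifnot(length(platform_centre) == 2, all(is.finite(platform_centre)))
  d <- sqrt(sum((platform_centre - centre)^2))
  if (d + platform_radius > radius + 1e-9) {
    stop("platform must lie fully inside the arena")
  }
  structure(list(centre = as.numeric(centre), radius = as.numeric(radius),
                 platform_centre = as.numeric(platform_centre),
                 platform_radius = as.numeric(platform_radius)),
            class = "mwm_arena")
}

#' @export
print.mwm_arena <- function(x, ...) {
  cat(sprintf("MWM arena: R = %g cm, platform r = %g cm at (%.1f, %.1f)\n",
              x$radius, x$platform_radius,
              x$platform_centre[1], x$platform_centre[2]))
  invisible(x)
}

#' Single animal-trial swimming path
#'
#' A time-ordered set of (t, x, y) tracking samples with trial metadata.
#' Time must be strictly increasing and at least two samples are required.
#'
#' @param animal_id Animal identifier (character).
#' @param group Group label (character).
#' @param day Day number (positive integer).
#' @param trial Trial number (positive integer).
#' @param t,x,y Numeric vectors: time (s) and coordinates (cm).
#' @param arena Optional [mwm_arena()]; when supplied, samples farther than
#'   `radius * (1 + tol)` from the centre are counted and stored in the
#'   `n_out_of_arena` attribute.
#' @param tol Out-of-arena tolerance as a fraction of R (default 0.05).
#' @return An object of class `mwm_trajectory` with a `points` data frame.
#' @export
mwm_trajectory <- function(animal_id, group, day, trial, t, x, y,
                           arena = NULL, tol = 0.05) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2) stop("trajectory needs at least 2 points")
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("t, x, y must have equal length")
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in trajectory samples")
  }
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  out <- structure(list(animal_id = as.character(animal_id),
                        group = as.character(group),
                        day = as.integer(day), trial = as.integer(trial),
                        points = data.frame(t = t, x = x, y = y)),
                   class = "mwm_trajectory")
  if (!is.null(arena)) {
    r <- sqrt((x - arena$centre[1])^2 + (y - arena$centre[2])^2)
    attr(out, "n_out_of_arena") <- sum(r > arena$radius * (1 + tol))
  }
  out
}

#' @export
print.mwm_trajectory <- function(x, ...) {
  cat(sprintf("MWM trajectory %s (group %s, day %d, trial %d): %d samples, %.1f s\n",
              x$animal_id, x$group, x$day, x$trial, nrow(x$points),
              diff(range(x$points$t))))
  invisible(x)
}

#' Identifier string for one animal-trial trajectory
#' @param traj An `mwm_trajectory`.
#' @return Character id of the form `animal_dDAY_tTRIAL`.
#' @export
traj_id <- function(traj) {
  sprintf("%s_d%d_t%d", traj$animal_id, traj$day, traj$trial)
}

#' Reader options for delimited tracking exports
#'
#' @param sep Field separator.
#' @param dec Decimal separator (`","` supported for continental exports).
#' @param skip Header lines to skip before the column-name row.
#' @param columns Named map from the roles `time`, `x`, `y`, `trial`,
#'   `animal`, `group`, `day` to column names (character) or positions
#'   (numeric).  `group` and `day` are optional roles.
#' @param origin Numeric length-2 offset subtracted from raw coordinates so
#'   that downstream work is in arena-centred cm.
#' @param tol Out-of-arena tolerance as a fraction of R.
#' @return A list of reader options.
#' @export
track_reader_options <- function(sep = ",", dec = ".", skip = 0,
                                 columns = c(time = "t", x = "x", y = "y",
                                             trial = "trial",
                                             animal = "animal",
                                             group = "group", day = "day"),
                                 origin = c(0, 0), tol = 0.05) {
  list(sep = sep, dec = dec, skip = skip, columns = columns,
       origin = origin, tol = tol)
}

resolve_column <- function(df, spec, role, required = TRUE) {
  if (is.na(spec) || !nzchar(as.character(spec))) {
    if (required) stop(sprintf("no column mapped for role '%s'", role))
    return(NULL)
  }
  if (suppressWarnings(!is.na(as.numeric(spec)))) {
    idx <- as.integer(as.numeric(spec))
    if (idx < 1 || idx > ncol(df)) {
      stop(sprintf("column index %d for role '%s' out of range", idx, role))
    }
    return(df[[idx]])
  }
  if (!spec %in% names(df)) {
    if (required) {
      stop(sprintf("column '%s' (role '%s') not found in file", spec, role))
    }
    return(NULL)
  }
  df[[spec]]
}

#' Read a delimited tracking export into trajectories
#'
#' Reads a CSV/TSV export (e.g. from video tracking software), resolves the
#' time/x/y/metadata columns through `options$columns`, drops rows with
#' missing or non-numeric coordinates (with a message reporting the count),
#' and returns one [mwm_trajectory()] per animal-trial.  Samples beyond the
#' out-of-arena tolerance are counted per trajectory, not rejected, so
#' wall-hugging paths with tracking jitter survive.
#'
#' @param path File path.
#' @param arena An [mwm_arena()].
#' @param options Reader options from [track_reader_options()].
#' @return Named list of `mwm_trajectory` objects (names are [traj_id()]s).
#' @export
read_tracks <- function(path, arena, options = track_reader_options()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = options$sep, dec = options$dec,
                   skip = options$skip, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path)
  cols <- options$columns
  getcol <- function(role, required = TRUE) {
    resolve_column(df, if (role %in% names(cols)) cols[[role]] else NA,
                   role, required)
  }
  t <- suppressWarnings(as.numeric(getcol("time")))
  x <- suppressWarnings(as.numeric(getcol("x")))
  y <- suppressWarnings(as.numeric(getcol("y")))
  trial <- getcol("trial")
  animal <- getcol("animal")
  group <- getcol("group", required = FALSE)
  day <- getcol("day", required = FALSE)
  if (is.null(group)) group <- "all"
  if (is.null(day)) day <- 1

  keep <- is.finite(t) & is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("read_tracks: dropped %d row(s) with missing or non-numeric coordinates", dropped))
  }
  dat <- data.frame(t = t[keep],
                    x = x[keep] - options$origin[1],
                    y = y[keep] - options$origin[2],
                    trial = as.integer(trial[keep]),
                    animal = as.character(animal[keep]),
                    group = as.character(group)[if (length(group) > 1) keep else 1],
                    day = as.integer(day)[if (length(day) > 1) keep else 1],
                    stringsAsFactors = FALSE)
  keys <- split(dat, list(dat$animal, dat$day, dat$trial), drop = TRUE)
  out <- list()
  for (piece in keys) {
    piece <- piece[order(piece$t), ]
    if (nrow(piece) < 2) stop("empty or single-sample trial for animal ",
                              piece$animal[1])
    tr <- mwm_trajectory(piece$animal[1], piece$group[1], piece$day[1],
                         piece$trial[1], piece$t, piece$x, piece$y,
                         arena = arena, tol = options$tol)
    out[[traj_id(tr)]] <- tr
  }
  out[order(names(out))]
}

#' Write trajectories to the normalised delimited track format
#'
#' Writes one combined CSV with columns `animal,group,day,trial,t,x,y`
#' (readable back with the default [track_reader_options()] column map)
#' plus an optional JSON metadata sidecar recording the arena geometry.
#'
#' @param trajs List of `mwm_trajectory` objects.
#' @param path Output CSV path.
#' @param arena Optional arena stored in the sidecar.
#' @param sidecar Optional path for the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path, arena = NULL, sidecar = NULL) {
  rows <- lapply(trajs, function(tr) {
    data.frame(animal = tr$animal_id, group = tr$group, day = tr$day,
               trial = tr$trial, t = tr$points$t, x = tr$points$x,
               y = tr$points$y, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(n_trajectories = length(trajs),
                 n_samples = nrow(df),
                 arena = if (is.null(arena)) NULL else unclass(arena))
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Whole-path performance metrics
#'
#' Standard full-trajectory measures: escape latency (elapsed time from the
#' first to the last sample), path length (sum of consecutive Euclidean
#' distances) and mean swimming speed.
#'
#' @param traj An `mwm_trajectory`.
#' @param arena An [mwm_arena()] (kept for interface symmetry; the metrics
#'   are arena-independent).
#' @return List with `escape_latency` (s), `path_length` (cm),
#'   `mean_speed` (cm/s).
#' @export
path_metrics <- function(traj, arena = NULL) {
  p <- traj$points
  elapsed <- p$t[nrow(p)] - p$t[1]
  if (elapsed <= 0) stop("elapsed time is zero")
  len <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  list(escape_latency = elapsed, path_length = len,
       mean_speed = len / elapsed)
}
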