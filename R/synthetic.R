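#' Kinematic parameters for the synthetic swimming-path generator
#'
#' The generator produces correlated random walks shaped per strategy at a
#' fixed swimming speed and sampling rate.  Defaults (25 cm/s at 10 Hz,
#' 90 s trial timeout) give realistic rat path lengths of hundreds of cm
#' within a trial.
#'
#' @param speed Swimming speed in cm/s.
#' @param hz Sampling rate in Hz.
#' @param timeout Trial timeout in s.
#' @return List of generator parameters.
#' @export
strategy_params <- function(speed = 25, hz = 10, timeout = 90) {
  stopifnot(speed > 0, hz > 0, timeout > 0)
  list(speed = speed, hz = hz, timeout = timeout)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# One strategy-shaped bout of at most n_steps samples, continuing from
# `state` (pos, heading, aux).  Positions are arena-centred.  Returns the
# new sample block (without the starting position), the updated state and
# whether the platform was contacted (block trimmed at contact).
sim_bout <- function(strategy, state, n_steps, arena, params) {
  R <- arena$radius
  v <- params$speed
  dt <- 1 / params$hz
  step <- v * dt
  pc <- arena$platform_centre - arena$centre
  pos <- state$pos
  heading <- state$heading
  aux <- state$aux

  # per-bout auxiliary state
  if (is.null(aux$dir)) aux$dir <- sample(c(-1, 1), 1)
  if (strategy == "FS") {
    # focused search targets a small region away from the platform (a
    # search concentrated at the platform is Target Scanning instead)
    repeat {
      ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.5 * R
      aux$q <- rr * c(cos(ang), sin(ang))
      if (sqrt(sum((aux$q - pc)^2)) > 0.35 * R) break
    }
  }
  if (strategy == "IC") aux$phase <- runif(1, 0, 2 * pi)
  if (strategy == "SO") {
    aux$loop_left <- round(1.15 * 2 * pi * (0.22 * R) / step)
  }
  if (strategy == "SS") {
    ang <- runif(1, 0, 2 * pi)
    aux$ss_target <- pc + 1.8 * arena$platform_radius * c(cos(ang), sin(ang))
    aux$ss_mode <- 1
  }

  steer <- function(target_angle, gain, noise_sd) {
    heading <<- wrap_angle(heading + gain * wrap_angle(target_angle - heading) +
                             rnorm(1, 0, noise_sd))
  }
  band_follow <- function(rt, kr, noise_sd) {
    r <- sqrt(sum(pos^2)); phi <- atan2(pos[2], pos[1])
    tangent <- phi + aux$dir * pi / 2
    tv <- c(cos(tangent), sin(tangent)) + kr * (rt - r) / R * c(cos(phi), sin(phi))
    steer(atan2(tv[2], tv[1]), 0.8, noise_sd)
  }

  xs <- matrix(NA_real_, n_steps, 2)
  hit <- FALSE
  m <- 0L
  for (s in seq_len(n_steps)) {
    r <- sqrt(sum(pos^2)); phi <- atan2(pos[2], pos[1])
    if (strategy == "TT") {
      band_follow(0.925 * R, 4, 0.20)
    } else if (strategy == "IC") {
      aux$phase <- aux$phase + 2 * pi / (6 / dt)
      rt <- 0.88 * R - 0.50 * R * max(0, sin(aux$phase))^0.7
      band_follow(rt, 4, 0.25)
    } else if (strategy == "SC") {
      if (r > 0.55 * R) steer(atan2(-pos[2], -pos[1]), 0.6, 0.2)
      else heading <- wrap_angle(heading + rnorm(1, 0, 0.7))
    } else if (strategy == "FS") {
      dq <- aux$q - pos
      if (sqrt(sum(dq^2)) > 0.12 * R) steer(atan2(dq[2], dq[1]), 0.7, 0.25)
      else heading <- wrap_angle(heading + rnorm(1, 0, 0.9))
    } else if (strategy == "CR") {
      band_follow(sqrt(sum(pc^2)), 6, 0.10)
    } else if (strategy == "SO") {
      if (aux$loop_left > 0) {
        aux$loop_left <- aux$loop_left - 1
        heading <- wrap_angle(heading + aux$dir * step / (0.22 * R) +
                                rnorm(1, 0, 0.05))
      } else if (r > 0.8 * R) {
        # reorient towards the interior rather than pinning to the wall
        steer(atan2(-pos[2], -pos[1]), 0.3, 0.15)
      } else {
        heading <- wrap_angle(heading + rnorm(1, 0, 0.08))
      }
    } else if (strategy == "SS") {
      if (aux$ss_mode == 1) {
        dq <- aux$ss_target - pos
        if (sqrt(sum(dq^2)) < 3) aux$ss_mode <- 2
        else steer(atan2(dq[2], dq[1]), 0.6, 0.15)
      }
      if (aux$ss_mode == 2) {
        dp_now <- sqrt(sum((pos - pc)^2))
        if (dp_now < 0.5 * R) {
          away <- pos - pc
          steer(atan2(away[2], away[1]), 0.4, 0.15)
        } else if (r > 0.7 * R) {
          steer(atan2(-pos[2], -pos[1]), 0.4, 0.2)
        } else {
          heading <- wrap_angle(heading + rnorm(1, 0, 0.4))
        }
      }
    } else if (strategy == "ST") {
      dq <- pc - pos
      if (sqrt(sum(dq^2)) > 0.28 * R) steer(atan2(dq[2], dq[1]), 0.5, 0.3)
      else heading <- wrap_angle(heading + rnorm(1, 0, 0.8))
    } else if (strategy == "DF") {
      dq <- pc - pos
      steer(atan2(dq[2], dq[1]), 0.9, 0.05)
    } else {
      stop("unknown strategy: ", strategy)
    }

    pos <- pos + step * c(cos(heading), sin(heading))
    # reflect at the wall: cancel the outward radial velocity component
    rn <- sqrt(sum(pos^2))
    if (rn > R - 1) {
      pos <- pos * (R - 1) / rn
      phi2 <- atan2(pos[2], pos[1])
      heading <- wrap_angle(2 * (phi2 + pi / 2) - heading)
    }
    m <- m + 1L
    xs[m, ] <- pos
    if (strategy != "SS" &&
        sqrt(sum((pos - pc)^2)) <= arena$platform_radius) {
      hit <- TRUE
      break
    }
  }
  list(points = xs[seq_len(m), , drop = FALSE],
       state = list(pos = pos, heading = heading, aux = aux),
       hit = hit)
}

#' Generate one stereotyped single-strategy swimming path
#'
#' Simulates a correlated random walk shaped per strategy: wall hugging
#' (TT), wall walk with inward excursions (IC), central random search
#' (SC), search confined to a small region (FS), circling at the platform
#' distance from the wall (CR), a loop followed by reorientation (SO), a
#' pass close to the platform followed by departure (SS), search around
#' the platform (ST), or a near-straight run to the platform (DF).  The
#' path starts at the arena wall and ends at platform contact or timeout.
#'
#' @param strategy A strategy code from [strategy_codes()].
#' @param arena An [mwm_arena()].
#' @param params [strategy_params()].
#' @param seed Integer seed (same seed, identical path).
#' @param animal_id,group,day,trial Metadata for the returned trajectory.
#' @return An `mwm_trajectory`.
#' @export
generate_strategy_path <- function(strategy, arena, params = strategy_params(),
                                   seed = 1, animal_id = strategy,
                                   group = "synthetic", day = 1, trial = 1) {
  if (!strategy %in% strategy_codes()) stop("unknown strategy: ", strategy)
  set.seed(seed)
  st <- start_state(arena)
  n_max <- round(params$timeout * params$hz)
  bout <- sim_bout(strategy, st, n_max, arena, params)
  pts <- rbind(st$pos, bout$points)
  dt <- 1 / params$hz
  mwm_trajectory(animal_id, group, day, trial,
                 t = seq(0, by = dt, length.out = nrow(pts)),
                 x = pts[, 1] + arena$centre[1],
                 y = pts[, 2] + arena$centre[2], arena = arena)
}

start_state <- function(arena) {
  ang <- runif(1, 0, 2 * pi)
  pos <- 0.96 * arena$radius * c(cos(ang), sin(ang))
  list(pos = pos, heading = wrap_angle(ang + pi + runif(1, -1, 1)),
       aux = list())
}

#' Default per-group strategy mixtures for a two-cohort experiment
#'
#' The first group leans heavily on low-level strategies (thigmotaxis,
#' incursion) and the chaining response, emulating a stressed cohort; the
#' second spreads its behaviour over the spatially informed strategies.
#'
#' @param tt Optional override of the two groups' thigmotaxis weights
#'   (length 2); the remaining mass is rescaled proportionally.
#' @return Named list of two named probability vectors.
#' @export
default_mixtures <- function(tt = NULL) {
  mix <- list(
    stress = c(TT = 0.45, IC = 0.15, SC = 0.07, FS = 0.05, CR = 0.08,
               SO = 0.05, SS = 0.07, ST = 0.05, DF = 0.03),
    control = c(TT = 0.15, IC = 0.12, SC = 0.12, FS = 0.10, CR = 0.05,
                SO = 0.08, SS = 0.13, ST = 0.15, DF = 0.10))
  if (!is.null(tt)) {
    stopifnot(length(tt) == 2)
    for (i in 1:2) {
      m <- mix[[i]]
      rest <- m[names(m) != "TT"]
      mix[[i]] <- c(TT = tt[i], rest * (1 - tt[i]) / sum(rest))[names(m)]
    }
  }
  mix
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate a two-group rat experiment: cohorts of 30 and 27
#' animals, 12 trials each split as 4 trials over 3 consecutive days,
#' 90 s timeout.
#'
#' @param group_sizes Named integer vector of cohort sizes.
#' @param mixtures Named list (one per group) of strategy mixture weights,
#'   each summing to 1.
#' @param trials Trials per animal (default 12).
#' @param trials_per_day Trials per day (default 4).
#' @param seed Master seed.
#' @return List of class `mwm_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(stress = 30, control = 27),
                        mixtures = default_mixtures(), trials = 12,
                        trials_per_day = 4, seed = 1) {
  stopifnot(length(group_sizes) == length(mixtures),
            all(names(group_sizes) %in% names(mixtures)),
            all(group_sizes >= 1))
  for (m in mixtures) {
    stopifnot(abs(sum(m) - 1) < 1e-8, all(m >= 0),
              all(names(m) %in% strategy_codes()))
  }
  structure(list(group_sizes = group_sizes, mixtures = mixtures,
                 trials = trials, trials_per_day = trials_per_day,
                 seed = seed),
            class = "mwm_cohort_spec")
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Every animal-trial is a concatenation of strategy bouts drawn from the
#' group's mixture; each bout targets an arc length between 2 and 4 arena
#' radii (strategies persist at or above the framework's detectable
#' scale, so the truth stays recoverable), and the trial ends at platform
#' contact or timeout.  Deterministic under the spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @param arena An [mwm_arena()].
#' @param params [strategy_params()].
#' @return List with `trajectories` (named list of `mwm_trajectory`) and
#'   `truth` (data frame: `traj_id`, `bout`, `class`, `start_idx`,
#'   `end_idx`, `arc_start`, `arc_end`).
#' @export
generate_cohort <- function(spec, arena, params = strategy_params()) {
  stopifnot(inherits(spec, "mwm_cohort_spec"))
  set.seed(spec$seed)
  v <- params$speed; dt <- 1 / params$hz
  n_max_total <- round(params$timeout * params$hz)
  trajs <- list()
  truth_rows <- list()
  for (g in names(spec$group_sizes)) {
    mix <- spec$mixtures[[g]]
    mix <- mix[mix > 0]
    for (a in seq_len(spec$group_sizes[[g]])) {
      animal <- sprintf("%s%02d", g, a)
      for (tr in seq_len(spec$trials)) {
        day <- (tr - 1) %/% spec$trials_per_day + 1
        st <- start_state(arena)
        pts <- matrix(st$pos, 1, 2)
        bouts <- list()
        done <- FALSE
        while (!done && nrow(pts) - 1 < n_max_total) {
          strategy <- sample(names(mix), 1, prob = mix)
          arc_target <- runif(1, 2.0, 4.0) * arena$radius
          n_steps <- min(ceiling(arc_target / (v * dt)),
                         n_max_total - (nrow(pts) - 1))
          bout <- sim_bout(strategy, st, n_steps, arena, params)
          st <- bout$state
          first <- nrow(pts) + 1L
          pts <- rbind(pts, bout$points)
          bouts[[length(bouts) + 1]] <-
            data.frame(class = strategy, start_idx = first - 1L,
                       end_idx = nrow(pts), stringsAsFactors = FALSE)
          if (bout$hit) done <- TRUE
        }
        traj <- mwm_trajectory(animal, g, day, tr,
                               t = seq(0, by = dt, length.out = nrow(pts)),
                               x = pts[, 1] + arena$centre[1],
                               y = pts[, 2] + arena$centre[2], arena = arena)
        id <- traj_id(traj)
        trajs[[id]] <- traj
        cum <- cumulative_arc_length(traj)
        bt <- do.call(rbind, bouts)
        bt$arc_start <- cum[bt$start_idx]
        bt$arc_end <- cum[bt$end_idx]
        bt <- cbind(data.frame(traj_id = id, bout = seq_len(nrow(bt)),
                               stringsAsFactors = FALSE), bt)
        truth_rows[[length(truth_rows) + 1]] <- bt
      }
    }
  }
  list(trajectories = trajs,
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
}

# Class shares of a segment's (or interval's) arc range over the ground
# truth bouts of its trajectory.
arc_class_shares <- function(traj_ids, arc_start, arc_end, truth) {
  by_traj <- split(truth, truth$traj_id)
  lapply(seq_along(traj_ids), function(i) {
    bt <- by_traj[[traj_ids[i]]]
    ov <- pmin(bt$arc_end, arc_end[i]) - pmax(bt$arc_start, arc_start[i])
    ov[ov < 0] <- 0
    shares <- tapply(ov, bt$class, sum)
    total <- sum(shares)
    if (total <= 0) return(setNames(numeric(0), character(0)))
    sort(shares / total, decreasing = TRUE)
  })
}

#' Ground-truth class of arc ranges (segments or intervals)
#'
#' @param tab Data frame with `traj_id`, `arc_start`, `arc_end`.
#' @param truth Ground-truth bout table from [generate_cohort()].
#' @return Character vector: majority-overlap bout class per row.
#' @export
arc_truth_classes <- function(tab, truth) {
  shares <- arc_class_shares(tab$traj_id, tab$arc_start, tab$arc_end, truth)
  vapply(shares, function(s) if (length(s) == 0) NA_character_ else names(s)[1],
         character(1))
}

#' Automatic stratified labelling of segments from ground truth
#'
#' Emulates the expert labelling stage on synthetic data: a seeded,
#' class-stratified sample of segments is labelled with the majority
#' ground-truth bout class; a segment substantially straddling two bouts
#' of different classes receives both labels (never more than two).  Only
#' segments an expert could plausibly recognise are eligible — those whose
#' dominant bout class covers at least `min_dominant_share` of the arc —
#' mirroring how a human labeller skips ambiguous segments.  The label
#' count is still `fraction` of *all* segments.
#'
#' @param segtab Segment table from [segment_cohort()].
#' @param truth Ground-truth bout table from [generate_cohort()].
#' @param fraction Fraction of segments to label (default 0.10).
#' @param seed Integer seed.
#' @param second_label_share Minimum arc share of the second class for a
#'   two-label record (default 0.25).
#' @param min_dominant_share Minimum arc share of the dominant class for a
#'   segment to be eligible for labelling (default 0.65).
#' @return An `mwm_labels` table.
#' @export
auto_label <- function(segtab, truth, fraction = 0.10, seed = 1,
                       second_label_share = 0.25,
                       min_dominant_share = 0.65) {
  shares <- arc_class_shares(segtab$traj_id, segtab$arc_start,
                             segtab$arc_end, truth)
  lab1 <- vapply(shares, function(s) names(s)[1], character(1))
  lab2 <- vapply(shares, function(s) {
    if (length(s) >= 2 && s[2] >= second_label_share) names(s)[2]
    else NA_character_
  }, character(1))
  dominant <- vapply(shares, function(s) s[1], numeric(1))
  set.seed(seed)
  take <- integer(0)
  for (cls in unique(lab1)) {
    idx <- which(lab1 == cls)
    target <- max(1, round(fraction * length(idx)))
    eligible <- idx[dominant[idx] >= min_dominant_share]
    if (length(eligible) == 0) eligible <- idx  # rare class: take what exists
    n_take <- min(target, length(eligible))
    take <- c(take, eligible[sample.int(length(eligible), n_take)])
  }
  take <- sort(take)
  label_records(segtab$segment_id[take], lab1[take], lab2[take])
}
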