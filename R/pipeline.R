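#' Configuration for a full trajectory-segmentation-analysis run
#'
#' Collects every tunable of the workflow: arena geometry, segmentation,
#' classifier settings and smoothing.  All randomness in a run descends
#' from the single `seed`.
#'
#' @param arena An [mwm_arena()].
#' @param segment_length_factor Segment length as a multiple of the arena
#'   radius (default 2.5).
#' @param overlap Segment overlap fraction (default 0.90; the headline
#'   configuration pairs 2.5 R segments with 90% overlap).
#' @param K_range Target-cluster counts for the classifier pool.
#' @param error_threshold CV-error cutoff for strong classifiers (0.25).
#' @param min_members Minimum ensemble size (default 40).
#' @param max_pairs_per_class Constraint sampling cap (default 500).
#' @param sigma_factor Smoothing kernel width as a multiple of R (1).
#' @param label_fraction Fraction auto-labelled when labels are derived
#'   from synthetic ground truth (default 0.10).
#' @param seed Master seed.
#' @return List of class `mwm_run_config`.
#' @export
run_config <- function(arena = mwm_arena(), segment_length_factor = 2.5,
                       overlap = 0.90, K_range = 10:100,
                       error_threshold = 0.25, min_members = 40,
                       max_pairs_per_class = 500, sigma_factor = 1,
                       label_fraction = 0.10, seed = 1) {
  stopifnot(segment_length_factor > 0, error_threshold > 0,
            error_threshold < 1, min_members >= 1)
  structure(list(arena = arena,
                 segment_length_factor = segment_length_factor,
                 overlap = overlap, K_range = K_range,
                 error_threshold = error_threshold,
                 min_members = min_members,
                 max_pairs_per_class = max_pairs_per_class,
                 sigma_factor = sigma_factor,
                 label_fraction = label_fraction, seed = seed),
            class = "mwm_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "mwmtsa_insufficient_labelling")) stop(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full segmentation-classification-smoothing analysis
#'
#' Executes the workflow end to end: segment the trajectories, compute
#' standardised features, derive constraints from the labels, build the
#' classifier pool over `K_range`, select the strong members (failing
#' early with an "insufficient labelling" error when fewer than
#' `min_members` pass the CV gate), majority-vote the segment classes,
#' smooth them onto R-length path intervals, build the per-trial strategy
#' profiles and compare the two groups per strategy (and for transitions)
#' with Friedman tests, plus the per-classifier binomial significance
#' intervals.
#'
#' @param trajs Named list of `mwm_trajectory` (two groups).
#' @param labels An `mwm_labels` table over segment ids, or NULL to
#'   auto-label from `truth`.
#' @param config An [run_config()].
#' @param truth Optional ground-truth bout table (synthetic cohorts);
#'   required when `labels` is NULL, also used for recovery scoring.
#' @param whole_path_labels Optional named classes for short trajectories.
#' @param member_stats Also compute the per-member significance votes and
#'   their binomial confidence intervals (default TRUE; the ensemble-level
#'   Friedman tests are always computed).
#' @return List of class `mwm_run` with elements `segments`,
#'   `short_trajectories`, `features`, `labels`, `pool_table`, `ensemble`,
#'   `segment_classes`, `intervals`, `profile`, `stats`, `diagnostics`,
#'   `config`.
#' @export
run_analysis <- function(trajs, labels = NULL, config = run_config(),
                         truth = NULL, whole_path_labels = NULL,
                         member_stats = TRUE) {
  arena <- config$arena
  seg_cfg <- segmentation_config(config$segment_length_factor * arena$radius,
                                 config$overlap)
  sc <- stage("segmentation", segment_cohort(trajs, seg_cfg))
  segtab <- sc$segments
  if (is.null(segtab) || nrow(segtab) == 0) stop("stage 'segmentation' failed: no segments produced")

  feats <- stage("features", feature_matrix(segtab, trajs, arena,
                                            standardise = TRUE))

  if (is.null(labels)) {
    if (is.null(truth)) stop("labels or truth must be supplied")
    labels <- stage("labelling",
                    auto_label(segtab, truth, config$label_fraction,
                               seed = config$seed))
  }
  cov <- coverage_report(nrow(labels), nrow(segtab))
  constraints <- stage("constraints",
                       derive_constraints(labels, config$max_pairs_per_class,
                                          seed = config$seed))

  pool <- stage("pool", build_pool(feats, labels, constraints,
                                   K_range = config$K_range,
                                   seed = config$seed))
  ensemble <- select_strong(pool, config$error_threshold,
                            config$min_members)

  seg_classes <- stage("voting", majority_vote(ensemble, feats))
  segtab$class <- unname(seg_classes)
  unc <- unclassified_rate(segtab$class)

  smooth_cfg <- smoothing_config(sigma = config$sigma_factor * arena$radius)
  intervals <- stage("smoothing",
                     smooth_cohort(trajs, segtab, arena, smooth_cfg,
                                   sc$short_trajectories,
                                   whole_path_labels))
  profile <- stage("profile", strategy_profile(intervals))

  stats_tab <- stage("stats",
                     run_group_stats(trajs, segtab, arena, smooth_cfg,
                                     sc$short_trajectories,
                                     whole_path_labels, profile, ensemble,
                                     member_stats = member_stats))

  member_errs <- vapply(ensemble$members, function(m) m$cv_error, numeric(1))
  ens_cv <- ensemble_cv_error(ensemble, labels)
  diagnostics <- list(
    coverage = cov,
    n_segments = nrow(segtab),
    n_pool = length(pool),
    n_strong = length(ensemble$members),
    member_cv_errors = member_errs,
    mean_member_cv_error = mean(member_errs),
    ensemble_cv_error = ens_cv$error,
    unclassified = unc)

  structure(list(segments = segtab,
                 short_trajectories = sc$short_trajectories,
                 features = feats, labels = labels,
                 pool_table = data.frame(
                   K = vapply(pool, `[[`, numeric(1), "K"),
                   seed = vapply(pool, `[[`, numeric(1), "seed"),
                   cv_error = vapply(pool, `[[`, numeric(1), "cv_error"),
                   selected = vapply(pool, `[[`, numeric(1), "cv_error") <
                     config$error_threshold),
                 ensemble = ensemble, segment_classes = seg_classes,
                 intervals = intervals, profile = profile,
                 stats = stats_tab, diagnostics = diagnostics,
                 config = config),
            class = "mwm_run")
}

# Per-strategy (and transitions) two-group Friedman tests for the ensemble
# classification, plus per-member significance votes and their exact
# binomial confidence intervals.
run_group_stats <- function(trajs, segtab, arena, smooth_cfg, short_ids,
                            whole_path_labels, profile, ensemble,
                            member_stats = TRUE) {
  measures <- c(setdiff(strategy_codes(), "DF"), "transitions", "DF")
  ens_p <- setNames(numeric(length(measures)), measures)
  ens_Q <- ens_p
  member_sig <- matrix(NA, length(ensemble$members), length(measures),
                       dimnames = list(NULL, measures))

  test_profile <- function(prof, measure) {
    if (measure == "transitions") {
      v <- prof$transitions
      v$value <- v$transitions
    } else {
      v <- prof$per_animal[prof$per_animal$class == measure, ]
      v$value <- v$pct
    }
    group_compare(v[, c("group", "trial", "animal", "value")])
  }
  for (ms in measures) {
    ft <- test_profile(profile, ms)
    ens_p[ms] <- ft$p; ens_Q[ms] <- ft$Q
  }

  out <- data.frame(measure = measures, Q = unname(ens_Q), p = unname(ens_p),
                    significant = unname(ens_p) < 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!member_stats) return(out)

  for (mi in seq_along(ensemble$members)) {
    member <- ensemble$members[[mi]]
    st_m <- segtab
    # training assignments are already in segment-table row order
    st_m$class <- member$model$cluster_to_class[member$model$assignments]
    st_m$class[is.na(st_m$class)] <- UNDEFINED
    iv_m <- smooth_cohort(trajs, st_m, arena, smooth_cfg, short_ids,
                          whole_path_labels)
    prof_m <- strategy_profile(iv_m)
    for (ms in measures) {
      member_sig[mi, ms] <- test_profile(prof_m, ms)$p < 0.05
    }
  }

  ci <- lapply(measures, function(ms) vote_significance_ci(member_sig[, ms]))
  names(ci) <- measures
  out$member_sig_share <- colMeans(member_sig)
  out$ci_low <- vapply(ci, `[[`, numeric(1), "low")
  out$ci_high <- vapply(ci, `[[`, numeric(1), "high")
  out$confirmed <- vapply(ci, `[[`, logical(1), "confirmed")
  out
}

#' @export
print.mwm_run <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("MWM TSA run: %d segments, %d/%d strong classifiers, unclassified %.2f%%\n",
              d$n_segments, d$n_strong, d$n_pool,
              100 * d$unclassified$rate))
  cat(sprintf("mean member CV error %.1f%%, ensemble CV error %.1f%%\n",
              100 * d$mean_member_cv_error, 100 * d$ensemble_cv_error))
  sig <- x$stats$measure[x$stats$significant]
  cat("significant group differences:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write the artefacts of a run to a directory
#'
#' Emits the segment table, feature matrix, pool report, interval
#' classification, per-trial profiles, statistics table and a
#' machine-readable JSON summary; optionally per-panel figures of the
#' strategy profiles.
#'
#' @param run An `mwm_run`.
#' @param dir Output directory (created if missing).
#' @param figures Also draw profile figures as PNG (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$segments, file.path(dir, "segments.csv"), row.names = FALSE)
  write.csv(data.frame(segment_id = rownames(run$features), run$features),
            file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(run$pool_table, file.path(dir, "pool_report.csv"),
            row.names = FALSE)
  write.csv(run$intervals, file.path(dir, "interval_classes.csv"),
            row.names = FALSE)
  write.csv(run$profile$percentages, file.path(dir, "profile_percentages.csv"),
            row.names = FALSE)
  write.csv(run$profile$transitions, file.path(dir, "transitions.csv"),
            row.names = FALSE)
  write.csv(run$stats, file.path(dir, "group_stats.csv"), row.names = FALSE)
  d <- run$diagnostics
  summary <- list(
    seed = run$config$seed,
    segment_length = run$config$segment_length_factor *
      run$config$arena$radius,
    overlap = run$config$overlap,
    n_segments = d$n_segments, n_pool = d$n_pool, n_strong = d$n_strong,
    labelled_fraction = d$coverage$fraction,
    coverage_status = d$coverage$status,
    mean_member_cv_error = d$mean_member_cv_error,
    ensemble_cv_error = d$ensemble_cv_error,
    unclassified_rate = d$unclassified$rate,
    unclassified_status = d$unclassified$status,
    stats = run$stats)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (figures) plot_profiles(run, file.path(dir, "profiles.png"))
  invisible(dir)
}

plot_profiles <- function(run, path) {
  prof <- run$profile$percentages
  groups <- sort(unique(prof$group))
  codes <- setdiff(strategy_codes(), "DF")
  grDevices::png(path, width = 1400, height = 1000, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(3, 3), mar = c(3, 3, 2, 1))
  for (cls in codes) {
    m <- sapply(groups, function(g) {
      v <- prof[prof$group == g & prof$class == cls, ]
      v$pct[order(v$trial)]
    })
    graphics::matplot(m, type = "b", pch = c(19, 1), lty = 1,
                      col = c("black", "grey50"),
                      xlab = "trial", ylab = "% intervals", main = cls)
  }
  tra <- run$profile$transitions
  graphics::boxplot(transitions ~ group, data = tra, main = "transitions",
                    xlab = "", ylab = "per-trial transitions")
  invisible(path)
}

#' Compare analysis conclusions across segmentation configurations
#'
#' Tabulates, for each strategy (Direct Finding reported separately) and
#' the transition count, the Friedman p-value, the significance flag and
#' the binomial-CI confirmation of every run, and marks the measures whose
#' conclusion is consistent across all runs.
#'
#' @param runs List of `mwm_run` objects over the same cohort.
#' @return Data frame with one row per measure (8 strategies +
#'   transitions) and per-run columns `p_<i>`, `sig_<i>`, `confirmed_<i>`
#'   plus `consistent`; the DF rows are attached as attribute `DF`.
#' @export
compare_segmentations <- function(runs) {
  if (length(runs) < 2) stop("need at least two runs")
  n_traj <- vapply(runs, function(r) length(unique(r$intervals$traj_id)),
                   integer(1))
  if (length(unique(n_traj)) != 1) stop("runs cover different cohorts")
  measures <- c(setdiff(strategy_codes(), "DF"), "transitions")
  out <- data.frame(measure = measures, stringsAsFactors = FALSE)
  sig <- matrix(NA, length(measures), length(runs))
  for (i in seq_along(runs)) {
    st <- runs[[i]]$stats
    idx <- match(measures, st$measure)
    out[[paste0("p_", i)]] <- st$p[idx]
    out[[paste0("sig_", i)]] <- st$significant[idx]
    out[[paste0("confirmed_", i)]] <-
      if (is.null(st$confirmed)) NA else st$confirmed[idx]
    sig[, i] <- st$significant[idx]
  }
  out$consistent <- apply(sig, 1, function(v) length(unique(v)) == 1)
  df_rows <- lapply(runs, function(r) r$stats[r$stats$measure == "DF", ])
  attr(out, "DF") <- do.call(rbind, df_rows)
  out
}
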