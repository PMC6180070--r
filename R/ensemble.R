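#' Generate a pool of MPCK classifiers over target-cluster counts
#'
#' One classifier is fitted per value of `K_range`, each seeded
#' deterministically from the master seed, and assessed by 10-fold
#' cross-validation.  All members share the same fold assignment (derived
#' from the master seed) so ensemble-level hold-out error can reuse the
#' members' folds.
#'
#' @param features Standardised feature matrix over all segments.
#' @param records Labelled records.
#' @param constraints Full constraint set from [derive_constraints()].
#' @param K_range Integer vector of target cluster counts (default 10:100).
#' @param seed Master seed.
#' @param ... Passed to [mpck_fit()].
#' @return List of classifier records (`model`, `K`, `seed`, `cv_error`,
#'   `cv`), with the shared fold vector as attribute `folds`.
#' @export
build_pool <- function(features, records, constraints, K_range = 10:100,
                       seed = 1, ...) {
  folds <- make_folds(records, 10, seed)
  pool <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    member_seed <- seed + K
    cv <- mpck_cross_validate(features, records, constraints, K,
                              seed = member_seed, folds = folds, ...)
    model <- mpck_fit(features, constraints, K, seed = member_seed, ...)
    model <- map_clusters_to_classes(model, features, records)
    pool[[i]] <- list(model = model, K = K, seed = member_seed,
                      cv_error = cv$error, cv = cv)
  }
  attr(pool, "folds") <- folds
  pool
}

#' Select the strong classifiers of a pool into an ensemble
#'
#' Keeps every pool member whose 10-fold cross-validation error is
#' strictly below the threshold.  If fewer than `min_members` qualify the
#' labelling is considered insufficient and the build fails with an error
#' of class `mwmtsa_insufficient_labelling`, pointing the user back to the
#' labelling stage.
#'
#' @param pool Output of [build_pool()].
#' @param threshold Validation-error cutoff (default 0.25, strict `<`).
#' @param min_members Minimum ensemble size (default 40).
#' @return List of class `mwm_ensemble` with `members`, `error_threshold`,
#'   `min_members`.
#' @export
select_strong <- function(pool, threshold = 0.25, min_members = 40) {
  if (length(pool) == 0) stop("empty classifier pool")
  errs <- vapply(pool, function(m) m$cv_error, numeric(1))
  keep <- which(errs < threshold)
  if (length(keep) < min_members) {
    stop(structure(class = c("mwmtsa_insufficient_labelling",
                             "error", "condition"),
                   list(message = sprintf(
      "insufficient labelling: only %d of %d classifiers have CV error < %.0f%% (minimum %d); provide more or better labels",
      length(keep), length(pool), 100 * threshold, min_members),
      call = sys.call(-1))))
  }
  structure(list(members = pool[keep], error_threshold = threshold,
                 min_members = min_members,
                 folds = attr(pool, "folds")),
            class = "mwm_ensemble")
}

#' @export
print.mwm_ensemble <- function(x, ...) {
  errs <- vapply(x$members, function(m) m$cv_error, numeric(1))
  cat(sprintf("MWM classifier ensemble: %d members, CV error %.1f%% [%.1f%% - %.1f%%]\n",
              length(x$members), 100 * mean(errs), 100 * min(errs),
              100 * max(errs)))
  invisible(x)
}

#' Per-member predictions over a feature matrix
#' @param ensemble An `mwm_ensemble`.
#' @param features Feature matrix.
#' @return Character matrix, members x segments.
#' @export
member_predictions <- function(ensemble, features) {
  do.call(rbind, lapply(ensemble$members,
                        function(m) mpck_predict(m$model, features)))
}

# Modal class of one vote vector; UNDEFINED abstentions are discarded
# before counting and a strict tie for the top count yields UNDEFINED.
vote_one <- function(votes) {
  votes <- votes[votes != UNDEFINED]
  if (length(votes) == 0) return(UNDEFINED)
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) UNDEFINED else top
}

#' Equal-weight majority vote of an ensemble
#'
#' Every member casts one vote per segment; `UNDEFINED` votes (member
#' abstentions) are discarded, the class with most votes wins and a strict
#' tie marks the segment `UNDEFINED`.
#'
#' @param ensemble An `mwm_ensemble`.
#' @param features Feature matrix over segments.
#' @return Character vector of strategy codes / `"UNDEFINED"`, named by
#'   the feature matrix rownames.
#' @export
majority_vote <- function(ensemble, features) {
  preds <- member_predictions(ensemble, features)
  setNames(apply(preds, 2, vote_one), rownames(features))
}

#' Ensemble hold-out error from the members' shared CV folds
#'
#' Re-uses each member's held-out fold predictions: for every labelled
#' segment the members' held-out votes are combined by majority vote and
#' scored against the label set (a prediction matching either of a
#' two-label record is correct; `UNDEFINED` is an error).
#'
#' @param ensemble An `mwm_ensemble` (members built with shared folds).
#' @param records The labelled records used during pool construction.
#' @return List with `error` and `predictions`.
#' @export
ensemble_cv_error <- function(ensemble, records) {
  hp <- vapply(ensemble$members, function(m) m$cv$heldout_predictions,
               character(nrow(records)))
  pred <- apply(hp, 1, vote_one)
  ok <- vapply(seq_len(nrow(records)), function(i) {
    pred[i] %in% label_set(records, i)
  }, logical(1))
  list(error = mean(!ok), predictions = setNames(pred, records$segment_id))
}

#' Pairwise agreement matrix of classifiers
#'
#' Entry (i, j) is the percentage of segments on which classifiers i and j
#' assign the identical class; the diagonal is exactly 100.  The overall
#' agreement is the mean of the strict upper triangle.
#'
#' @param predictions Character matrix, classifiers x segments.
#' @return List with `matrix` (symmetric, diagonal 100) and `overall`
#'   (mean off-diagonal agreement; NA for a single classifier).
#' @export
agreement_matrix <- function(predictions) {
  n <- nrow(predictions)
  A <- matrix(100, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        A[i, j] <- A[j, i] <- 100 * mean(predictions[i, ] == predictions[j, ])
      }
    }
  }
  overall <- if (n > 1) mean(A[upper.tri(A)]) else NA_real_
  list(matrix = A, overall = overall)
}

#' Fraction of segments left unclassified
#'
#' A healthy ensemble leaves under 3% of segments `UNDEFINED`; at or above
#' that the status flags a warning.
#'
#' @param final_classes Character vector of assigned classes.
#' @return List with `rate` and `status` (`"OK"` / `"WARN"`).
#' @export
unclassified_rate <- function(final_classes) {
  if (length(final_classes) == 0) stop("no classes supplied")
  rate <- mean(final_classes == UNDEFINED)
  list(rate = rate, status = if (rate >= 0.03) "WARN" else "OK")
}

#' Random-subsample ensembles for the agreement diagnostic
#'
#' Builds several small ensembles by sampling members at random from a
#' larger ensemble (by default 21 ensembles of 11 members) and returns
#' their per-segment majority votes, for the between-ensemble agreement
#' diagnostic.
#'
#' @param ensemble An `mwm_ensemble`.
#' @param features Feature matrix.
#' @param n_ensembles Number of subsampled ensembles (default 21).
#' @param size Members per subsample (default 11).
#' @param seed Integer seed.
#' @return Character matrix, subsampled ensembles x segments.
#' @export
subsample_ensembles <- function(ensemble, features, n_ensembles = 21,
                                size = 11, seed = 1) {
  stopifnot(size <= length(ensemble$members))
  preds <- member_predictions(ensemble, features)
  set.seed(seed)
  out <- matrix(NA_character_, n_ensembles, ncol(preds))
  for (e in seq_len(n_ensembles)) {
    take <- sample.int(nrow(preds), size)
    out[e, ] <- apply(preds[take, , drop = FALSE], 2, vote_one)
  }
  out
}
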