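#' Fit a semi-supervised MPCK-Means model
#'
#' Metric Pairwise Constrained K-Means with per-cluster diagonal metrics.
#' Centroids are initialised from the transitive closure of the must-link
#' graph (largest neighbourhoods first) with the remainder filled by
#' seeded farthest-first traversal.  The main loop alternates a sequential
#' greedy point assignment (weighted squared distance under the cluster's
#' diagonal metric minus its log-determinant, plus must-link/cannot-link
#' violation penalties), a centroid update and an exact per-dimension
#' metric update, until the assignment reaches a fixpoint or `max_iter`
#' iterations.  The objective trace is non-increasing.
#'
#' @param features Numeric matrix (samples x d), rownames used as ids.
#' @param constraints An `mwm_constraints` object over the rownames, or
#'   NULL for unconstrained clustering.
#' @param K Target number of clusters (>= 2).
#' @param seed Integer seed governing the initialisation.
#' @param w_ml,w_cl Constraint-violation penalty weights (defaults 1, in
#'   standardised feature units).
#' @param max_iter Maximum alternation count (default 200).
#' @param learn_metrics Learn per-cluster diagonal metrics (default TRUE);
#'   FALSE freezes identity metrics, reducing the fit to constrained
#'   k-means.
#' @return Object of class `mpck_model`: `K`, `centroids`, `metric_weights`,
#'   `cluster_to_class` (NA until mapped), `assignments` (per training
#'   sample), `objective`, `obj_trace`, `n_iter`, `seed`.
#' @export
mpck_fit <- function(features, constraints = NULL, K, seed = 1,
                     w_ml = 1, w_cl = 1, max_iter = 200,
                     learn_metrics = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0) stop("empty feature matrix")
  if (K < 2) stop("K must be at least 2")
  if (K > n) stop("K exceeds the number of samples")
  idx <- constraint_indices(constraints, rownames(features))
  set.seed(seed)
  centers0 <- init_centroids(features, idx$must, K, idx$cannot)
  fit <- .mpck_core(features, centers0, idx$must, idx$cannot,
                    w_ml, w_cl, max_iter, learn_metrics)
  structure(list(K = K, centroids = fit$centroids,
                 metric_weights = fit$metric_weights,
                 cluster_to_class = rep(NA_character_, K),
                 assignments = as.integer(fit$assignment),
                 objective = fit$objective, obj_trace = fit$obj_trace,
                 n_iter = fit$n_iter, seed = seed,
                 feature_names = colnames(features)),
            class = "mpck_model")
}

#' @export
print.mpck_model <- function(x, ...) {
  mapped <- sum(!is.na(x$cluster_to_class))
  cat(sprintf("MPCK-Means model: K = %d, %d iterations, objective %.3f, %d cluster(s) mapped\n",
              x$K, x$n_iter, x$objective, mapped))
  invisible(x)
}

# Convert id-pair constraints to 0-based index matrices for the C++ core.
constraint_indices <- function(constraints, ids) {
  empty <- matrix(integer(), 0, 2)
  if (is.null(constraints)) return(list(must = empty, cannot = empty))
  conv <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(empty)
    if (is.character(m)) {
      a <- match(m[, 1], ids); b <- match(m[, 2], ids)
      keep <- !is.na(a) & !is.na(b)
      cbind(a[keep], b[keep]) - 1L
    } else {
      matrix(as.integer(m), ncol = 2) - 1L
    }
  }
  list(must = conv(constraints$must_link),
       cannot = conv(constraints$cannot_link))
}

# Must-link transitive closure (union-find) gives one neighbourhood mean
# per connected label group; the remaining centroids are drawn by
# distance-proportional (D^2, k-means++ style) sampling over the
# constraint-anchored points, so every extra centroid starts
# label-adjacent and coverage stays balanced (a deterministic
# farthest-point traversal would repeatedly seed at extreme outliers and
# leave clusters without labelled members).  With no constraints the
# sampling runs over all points.  Uses the current RNG state.
init_centroids <- function(X, must0, K, cannot0 = NULL) {
  n <- nrow(X)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(must0) > 0) {
    for (r in seq_len(nrow(must0))) {
      a <- find(must0[r, 1] + 1L); b <- find(must0[r, 2] + 1L)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_sizes <- table(roots)
  comps <- as.integer(names(comp_sizes)[comp_sizes >= 2])
  comps <- comps[order(-comp_sizes[as.character(comps)])]
  centers <- matrix(NA_real_, 0, ncol(X))
  for (cmp in head(comps, K)) {
    centers <- rbind(centers, colMeans(X[roots == cmp, , drop = FALSE]))
  }
  anchored <- unique(c(must0, cannot0)) + 1L
  cand <- if (length(anchored) >= K) anchored else seq_len(n)
  Xc <- X[cand, , drop = FALSE]
  if (nrow(centers) == 0) {
    centers <- Xc[sample.int(nrow(Xc), 1), , drop = FALSE]
  }
  d2 <- rep(Inf, nrow(Xc))
  for (h in seq_len(nrow(centers))) {
    d2 <- pmin(d2, rowSums(sweep(Xc, 2, centers[h, ], "-")^2))
  }
  while (nrow(centers) < K) {
    pick <- sample.int(nrow(Xc), 1, prob = pmax(d2, 1e-12))
    centers <- rbind(centers, Xc[pick, , drop = FALSE])
    d2 <- pmin(d2, rowSums(sweep(Xc, 2, Xc[pick, ], "-")^2))
  }
  unname(centers[seq_len(K), , drop = FALSE])
}

#' Map clusters to strategy classes from labelled members
#'
#' Each cluster is assigned the modal strategy among its labelled members;
#' a two-label segment contributes weight 1/2 to each of its labels.
#' Clusters with no labelled member, or with a tied top class, stay
#' unassigned and later predict `UNDEFINED`.
#'
#' @param model A fitted `mpck_model`.
#' @param features The training feature matrix (rownames = segment ids).
#' @param records An `mwm_labels` table.
#' @return The model with `cluster_to_class` filled (NA = unassigned).
#' @export
map_clusters_to_classes <- function(model, features, records) {
  ids <- rownames(features)
  pos <- match(records$segment_id, ids)
  keep <- !is.na(pos)
  votes <- matrix(0, model$K, length(strategy_codes()),
                  dimnames = list(NULL, strategy_codes()))
  for (i in which(keep)) {
    cl <- model$assignments[pos[i]]
    labs <- label_set(records, i)
    votes[cl, labs] <- votes[cl, labs] + 1 / length(labs)
  }
  mapping <- rep(NA_character_, model$K)
  for (h in seq_len(model$K)) {
    v <- votes[h, ]
    if (sum(v) == 0) next
    top <- which(v == max(v))
    if (length(top) == 1) mapping[h] <- colnames(votes)[top]
  }
  model$cluster_to_class <- mapping
  model
}

#' Predict strategy classes for segments
#'
#' Assigns each sample to the cluster minimising the weighted squared
#' distance under that cluster's diagonal metric minus its
#' log-determinant (the same cost used during training), then reports the
#' cluster's mapped class, or `UNDEFINED` for unassigned clusters.
#'
#' @param model A fitted and mapped `mpck_model`.
#' @param features Numeric matrix with the model's 8 feature columns.
#' @return Character vector of strategy codes / `"UNDEFINED"`.
#' @export
mpck_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$centroids)) {
    stop("feature dimension mismatch")
  }
  cl <- .mpck_assign(features, model$centroids, model$metric_weights)
  cls <- model$cluster_to_class[cl]
  cls[is.na(cls)] <- UNDEFINED
  cls
}

#' Stratified cross-validation folds over labelled segments
#'
#' @param records An `mwm_labels` table.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold numbers aligned with `records` rows.
#' @export
make_folds <- function(records, k = 10, seed = 1) {
  if (nrow(records) < k) stop("fewer labelled records than folds")
  set.seed(seed)
  fold <- integer(nrow(records))
  for (cls in unique(records$label1)) {
    idx <- which(records$label1 == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' 10-fold cross-validation error of an MPCK classifier
#'
#' Folds are stratified by first label.  For each fold the model is fitted
#' on the full feature matrix (transduction: unlabelled segments always
#' take part in the clustering) but using only train-fold constraints and
#' labels; constraints touching a held-out segment are removed.  A
#' held-out prediction counts as correct when it appears in the record's
#' label set; an `UNDEFINED` prediction counts as an error.
#'
#' @param features Feature matrix over all segments.
#' @param records Labelled records (>= 10).
#' @param constraints Full `mwm_constraints` set.
#' @param K Target cluster count.
#' @param seed Seed for per-fold fits (and folds, when not supplied).
#' @param folds Optional precomputed fold vector from [make_folds()]
#'   (shared folds let ensemble members be scored on identical splits).
#' @param ... Passed to [mpck_fit()].
#' @return List of class `mpck_cv`: `folds` (10), `error`,
#'   `per_fold_errors`, `heldout_predictions` (named by segment id).
#' @export
mpck_cross_validate <- function(features, records, constraints, K,
                                seed = 1, folds = NULL, ...) {
  if (nrow(records) < 10) stop("need at least 10 labelled records")
  if (is.null(folds)) folds <- make_folds(records, 10, seed)
  ids <- rownames(features)
  heldout <- setNames(rep(NA_character_, nrow(records)), records$segment_id)
  per_fold <- numeric(10)
  for (f in 1:10) {
    test <- which(folds == f)
    if (length(test) == 0) { per_fold[f] <- NA; next }
    train_records <- records[-test, , drop = FALSE]
    class(train_records) <- class(records)
    cs <- drop_constraints_touching(constraints, records$segment_id[test])
    model <- mpck_fit(features, cs, K, seed = (seed %% 21470000) * 100 + f,
                      ...)
    model <- map_clusters_to_classes(model, features, train_records)
    pos <- match(records$segment_id[test], ids)
    pred <- mpck_predict(model, features[pos, , drop = FALSE])
    heldout[test] <- pred
    ok <- vapply(seq_along(test), function(q) {
      pred[q] %in% label_set(records, test[q])
    }, logical(1))
    per_fold[f] <- mean(!ok)
  }
  err <- mean(per_fold, na.rm = TRUE)
  structure(list(folds = 10, error = err, per_fold_errors = per_fold,
                 heldout_predictions = heldout, fold_of = folds),
            class = "mpck_cv")
}

drop_constraints_touching <- function(constraints, ids) {
  if (is.null(constraints)) return(NULL)
  filt <- function(m) {
    if (nrow(m) == 0) return(m)
    m[!(m[, 1] %in% ids | m[, 2] %in% ids), , drop = FALSE]
  }
  structure(list(must_link = filt(constraints$must_link),
                 cannot_link = filt(constraints$cannot_link)),
            class = "mwm_constraints")
}

#' Serialise an MPCK model to JSON
#' @param model An `mpck_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
mpck_to_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, centroids = model$centroids,
         metric_weights = model$metric_weights,
         cluster_to_class = model$cluster_to_class,
         seed = model$seed, objective = model$objective),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
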