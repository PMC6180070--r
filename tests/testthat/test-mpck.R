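empty_pairs <- matrix(integer(), 0, 2)

# exhaustive minimum-cost 2-clustering under identity metrics, with the
# same must-link penalty the fitter uses; oracle for tiny fixtures
brute_best_2clust <- function(X, must = NULL, w_ml = 1) {
  n <- nrow(X)
  best <- NULL; best_cost <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    cost <- 0
    for (h in 0:1) {
      idx <- which(lab == h)
      if (length(idx) == 0) next
      mu <- colMeans(X[idx, , drop = FALSE])
      cost <- cost + sum(sweep(X[idx, , drop = FALSE], 2, mu, "-")^2)
    }
    if (!is.null(must)) {
      for (r in seq_len(nrow(must))) {
        i <- must[r, 1]; j <- must[r, 2]
        if (lab[i] != lab[j]) {
          cost <- cost + w_ml * sum((X[i, ] - X[j, ])^2)
        }
      }
    }
    if (cost < best_cost) { best_cost <- cost; best <- lab }
  }
  list(labels = best, cost = best_cost)
}

test_that("without constraints and with frozen metrics the fit is k-means", {
  for (s in 1:5) {
    b <- make_blobs(n_per = 25, centers = rbind(c(0, 0), c(8, 8), c(-8, 8)),
                    sd = 0.8, seed = s)
    fit <- mpck_fit(b$X, NULL, K = 3, seed = s, learn_metrics = FALSE)
    set.seed(s)
    centers0 <- mwmtsa:::init_centroids(b$X, empty_pairs, 3, empty_pairs)
    km <- stats::kmeans(b$X, centers = centers0, algorithm = "Lloyd",
                        iter.max = 200)
    tab <- table(fit$assignments, km$cluster)
    expect_true(all(rowSums(tab > 0) == 1))  # identical partition
    expect_true(all(colSums(tab > 0) == 1))
    expect_true(all(diff(fit$obj_trace) <= 1e-8))
  }
})

test_that("a satisfied cannot-link leaves the partition unchanged", {
  b <- make_blobs(n_per = 20, sd = 0.5, seed = 9)
  ids <- rownames(b$X)
  one <- ids[which(b$truth == 1)[1]]
  two <- ids[which(b$truth == 2)[1]]
  cs <- structure(list(must_link = empty_pairs,
                       cannot_link = rbind(c(one, two))),
                  class = "mwm_constraints")
  f0 <- mpck_fit(b$X, NULL, K = 2, seed = 4, learn_metrics = FALSE)
  f1 <- mpck_fit(b$X, cs, K = 2, seed = 4, learn_metrics = FALSE)
  tab <- table(f0$assignments, f1$assignments)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("a strong must-link forces distant points together, matching brute force", {
  X <- rbind(c(0, 0), c(0.5, 0), c(10, 0), c(10.5, 0))
  rownames(X) <- letters[1:4]
  must <- matrix(c(1L, 3L), 1, 2)  # a with c, across the gap
  oracle <- brute_best_2clust(X, must, w_ml = 100)
  expect_equal(oracle$labels[1], oracle$labels[3])
  cs <- structure(list(must_link = rbind(c("a", "c")),
                       cannot_link = empty_pairs),
                  class = "mwm_constraints")
  fit <- mpck_fit(X, cs, K = 2, seed = 1, w_ml = 100,
                  learn_metrics = FALSE)
  expect_equal(fit$assignments[1], fit$assignments[3])
})

test_that("objective is non-increasing with constraints and metric learning", {
  for (s in 1:4) {
    b <- make_blobs(n_per = 30, centers = rbind(c(0, 0), c(5, 5), c(0, 7)),
                    sd = 1.2, seed = s)
    recs <- label_records(rownames(b$X)[seq(1, 90, by = 3)],
                          c("TT", "IC", "SC")[b$truth[seq(1, 90, by = 3)]])
    cs <- derive_constraints(recs, 50, seed = s)
    fit <- mpck_fit(b$X, cs, K = 4, seed = s)
    expect_true(all(diff(fit$obj_trace) <= 1e-8))
    expect_true(all(fit$metric_weights > 0))
  }
})

test_that("clusters are mapped to the modal labelled class with tie rules", {
  b <- make_blobs(n_per = 10, sd = 0.3, seed = 2)
  fit <- mpck_fit(b$X, NULL, K = 2, seed = 2, learn_metrics = FALSE)
  c1 <- rownames(b$X)[fit$assignments == 1]
  c2 <- rownames(b$X)[fit$assignments == 2]

  # majority: TT,TT,IC -> TT; other cluster unlabelled -> UNASSIGNED
  recs <- label_records(c1[1:3], c("TT", "TT", "IC"))
  m <- map_clusters_to_classes(fit, b$X, recs)
  expect_equal(m$cluster_to_class[1], "TT")
  expect_true(is.na(m$cluster_to_class[2]))
  pred <- mpck_predict(m, b$X)
  expect_equal(unname(pred[match(c1[1], rownames(b$X))]), "TT")
  expect_true(all(pred[match(c2, rownames(b$X))] == UNDEFINED))

  # an exact tie leaves the cluster unassigned
  recs2 <- label_records(c1[1:2], c("TT", "IC"))
  m2 <- map_clusters_to_classes(fit, b$X, recs2)
  expect_true(is.na(m2$cluster_to_class[1]))

  # two-label records contribute half a vote to each label
  recs3 <- label_records(c1[1:3], c("TT", "TT", "IC"),
                         c(NA, NA, "TT"))  # TT: 2.5, IC: 0.5
  m3 <- map_clusters_to_classes(fit, b$X, recs3)
  expect_equal(m3$cluster_to_class[1], "TT")
})

test_that("predictions are invariant to sample order", {
  b <- make_blobs(n_per = 15, sd = 0.4, seed = 6)
  recs <- label_records(rownames(b$X)[1:10],
                        c("TT", "IC")[b$truth[1:10]])
  fit <- map_clusters_to_classes(mpck_fit(b$X, NULL, K = 2, seed = 3),
                                 b$X, recs)
  perm <- sample(nrow(b$X))
  p1 <- mpck_predict(fit, b$X)
  p2 <- mpck_predict(fit, b$X[perm, ])
  expect_equal(p2, p1[perm])
  expect_error(mpck_predict(fit, b$X[, 1, drop = FALSE]), "dimension")
})

test_that("cross-validation is deterministic and tracks separability", {
  # three well-separated classes: near-zero CV error
  b <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(12, 0), c(0, 12)),
                  sd = 0.6, seed = 8)
  cls <- c("TT", "IC", "SC")[b$truth]
  lab_idx <- seq(1, 120, by = 2)
  recs <- label_records(rownames(b$X)[lab_idx], cls[lab_idx])
  cs <- derive_constraints(recs, 30, seed = 8)
  cv <- mpck_cross_validate(b$X, recs, cs, K = 6, seed = 8)
  expect_lt(cv$error, 0.1)
  expect_equal(cv$error, mean(cv$per_fold_errors))

  cv2 <- mpck_cross_validate(b$X, recs, cs, K = 6, seed = 8)
  expect_identical(cv$per_fold_errors, cv2$per_fold_errors)

  # labels assigned at random over 9 classes: error near chance (8/9)
  set.seed(1)
  X <- matrix(rnorm(240 * 4), 240)
  rownames(X) <- paste0("r", 1:240)
  ridx <- 1:72
  rrec <- label_records(rownames(X)[ridx],
                        sample(strategy_codes(), 72, replace = TRUE))
  rcs <- derive_constraints(rrec, 20, seed = 1)
  rcv <- mpck_cross_validate(X, rrec, rcs, K = 12, seed = 1)
  expect_gt(rcv$error, 0.6)

  expect_error(mpck_cross_validate(b$X, recs[1:5, ], cs, K = 4, seed = 1),
               "at least 10")
})

test_that("models serialise to JSON", {
  b <- make_blobs(n_per = 10, sd = 0.4, seed = 3)
  fit <- mpck_fit(b$X, NULL, K = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  mpck_to_json(fit, f)
  doc <- jsonlite::fromJSON(f)
  expect_equal(doc$K, 2)
  expect_equal(dim(doc$centroids), c(2, 2))
})
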