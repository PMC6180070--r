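# Shared fixtures, all built in code.

fixture_arena <- function() mwm_arena(radius = 100)

# collinear horizontal path with constant spacing (cm) sampled at 1 Hz
straight_traj <- function(n = 101, spacing = 10, y = 0, animal = "a1",
                          group = "g", day = 1, trial = 1) {
  mwm_trajectory(animal, group, day, trial,
                 t = seq_len(n) - 1, x = (seq_len(n) - 1) * spacing,
                 y = rep(y, n))
}

# closed axis-aligned square loop of given side, 5 samples
square_traj <- function(side = 25) {
  mwm_trajectory("sq", "g", 1, 1, t = 0:4,
                 x = c(0, side, side, 0, 0), y = c(0, 0, side, side, 0))
}

# jittered random walk trajectory inside the arena
random_traj <- function(n = 200, seed = 1, step = 4) {
  set.seed(seed)
  ang <- cumsum(stats::rnorm(n, 0, 0.6))
  x <- cumsum(c(0, step * cos(ang[-1])))
  y <- cumsum(c(0, step * sin(ang[-1])))
  r <- sqrt(x^2 + y^2)
  shrink <- pmax(1, r / 95)
  mwm_trajectory("rw", "g", 1, 1, t = seq_len(n) - 1,
                 x = x / shrink, y = y / shrink)
}

# isotropic Gaussian blobs, rows shuffled, for clustering fixtures
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(h) {
    cbind(stats::rnorm(n_per, centers[h, 1], sd),
          stats::rnorm(n_per, centers[h, 2], sd))
  }))
  lab <- rep(seq_len(nrow(centers)), each = n_per)
  ord <- sample(nrow(X))
  rownames(X) <- paste0("p", seq_len(nrow(X)))
  list(X = X[ord, ], truth = lab[ord])
}

# a small synthetic cohort shared by several expensive tests
small_cohort <- function(seed = 5, sizes = c(stress = 3, control = 3),
                         trials = 4) {
  mixtures <- setNames(default_mixtures()[seq_along(sizes)], names(sizes))
  spec <- cohort_spec(group_sizes = sizes, mixtures = mixtures,
                      trials = trials, seed = seed)
  generate_cohort(spec, fixture_arena())
}

# labels data frame helper
labels_of <- function(ids, l1, l2 = NA_character_) {
  label_records(ids, l1, l2)
}

# independent brute-force triple loop over intervals x segments x classes,
# the oracle for the Gaussian-weighted interval vote
brute_classify <- function(intervals, segtab, cfg, weights) {
  out <- character(nrow(intervals))
  votes <- matrix(0, nrow(intervals), length(weights),
                  dimnames = list(NULL, names(weights)))
  for (i in seq_len(nrow(intervals))) {
    for (k in names(weights)) {
      tot <- 0
      for (j in seq_len(nrow(segtab))) {
        if (segtab$class[j] != k) next
        ov <- min(segtab$arc_end[j], intervals$arc_end[i]) -
          max(segtab$arc_start[j], intervals$arc_start[i])
        if (ov <= 1e-9) next
        d2 <- (segtab$cx[j] - intervals$cx[i])^2 +
          (segtab$cy[j] - intervals$cy[i])^2
        kern <- exp(-d2 / (2 * cfg$sigma^2))
        if (kern < cfg$kernel_cutoff - 1e-12) next
        tot <- tot + weights[[k]] * kern
      }
      votes[i, k] <- tot
    }
    v <- votes[i, ]
    top <- which(v == max(v) & v > 0)
    out[i] <- if (length(top) == 1) names(weights)[top] else UNDEFINED
  }
  list(class = out, votes = votes)
}

random_smoothing_fixture <- function(seed, n = 250) {
  set.seed(seed)
  tr <- random_traj(n = n, seed = seed, step = 5)
  st <- segment_trajectory(tr, segmentation_config(150, 0.7))
  st$class <- sample(c("TT", "IC", "SC", UNDEFINED), nrow(st),
                     replace = TRUE)
  list(tr = tr, st = st)
}
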