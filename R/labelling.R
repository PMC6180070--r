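#' Load partial expert labels for segments
#'
#' Reads a CSV of the form `segment_id,label1[,label2]` where labels are
#' two-letter strategy codes (see [strategy_codes()]).  A segment may carry
#' one or two labels; a second label marks a segment genuinely straddling
#' two behaviours.
#'
#' @param path CSV path.
#' @return Data frame of class `mwm_labels` with columns `segment_id`,
#'   `label1`, `label2` (NA when absent).
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                   fill = TRUE, na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("labels file needs segment_id and at least one label column")
  if (ncol(df) > 3) stop("at most two labels per segment are allowed")
  names(df)[1:2] <- c("segment_id", "label1")
  if (ncol(df) == 2) df$label2 <- NA_character_ else names(df)[3] <- "label2"
  label_records(df$segment_id, df$label1, df$label2)
}

#' Build a validated label record table
#'
#' @param segment_id Character vector of segment ids.
#' @param label1 First strategy label per segment.
#' @param label2 Optional second label (NA when absent).
#' @return Data frame of class `mwm_labels`.
#' @export
label_records <- function(segment_id, label1, label2 = NA_character_) {
  df <- data.frame(segment_id = as.character(segment_id),
                   label1 = as.character(label1),
                   label2 = as.character(label2),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$segment_id)) {
    stop("duplicate segment id(s): ",
         paste(unique(df$segment_id[duplicated(df$segment_id)]), collapse = ", "))
  }
  valid <- strategy_codes()
  labs <- c(df$label1, df$label2[!is.na(df$label2)])
  bad <- setdiff(unique(labs), valid)
  if (length(bad) > 0) {
    stop("unknown strategy label(s): ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(valid, collapse = ", "))
  }
  same <- !is.na(df$label2) & df$label1 == df$label2
  df$label2[same] <- NA_character_
  class(df) <- c("mwm_labels", "data.frame")
  df
}

label_set <- function(records, i) {
  s <- records$label1[i]
  if (!is.na(records$label2[i])) s <- c(s, records$label2[i])
  s
}

#' Derive must-link / cannot-link constraints from partial labels
#'
#' Must-link pairs are sampled among single-labelled segments that share a
#' label, as a sparse connected graph (a random chain through the class
#' plus random extras); cannot-link pairs are sampled between segments
#' whose label sets are disjoint, so a two-label segment never receives a
#' cannot-link against either of its own labels and never anchors a
#' must-link.  Sampling is capped per class (must-link) and per class pair
#' (cannot-link) for tractability, reproducibly under `seed`.
#'
#' @param records An `mwm_labels` table.
#' @param max_pairs_per_class Sampling cap (default 500).
#' @param seed Integer seed.
#' @return List of class `mwm_constraints` with `must_link` and
#'   `cannot_link`, each a 2-column character matrix of unordered
#'   segment-id pairs.
#' @export
derive_constraints <- function(records, max_pairs_per_class = 500, seed = 1) {
  stopifnot(inherits(records, "mwm_labels"))
  empty <- matrix(character(), 0, 2)
  if (nrow(records) < 2) {
    return(structure(list(must_link = empty, cannot_link = empty),
                     class = "mwm_constraints"))
  }
  single <- is.na(records$label2)
  sets <- lapply(seq_len(nrow(records)), label_set, records = records)
  names(sets) <- records$segment_id

  sample_pairs <- function(ids_a, ids_b, cap, same = FALSE) {
    if (same) {
      n <- length(ids_a)
      if (n < 2) return(empty)
      total <- n * (n - 1) / 2
      if (total <= cap) return(t(utils::combn(ids_a, 2)))
      # oversample index pairs, dedupe, trim to the cap
      i <- sample.int(n, 3 * cap, replace = TRUE)
      j <- sample.int(n, 3 * cap, replace = TRUE)
      keep <- i != j
      lo <- pmin(i[keep], j[keep]); hi <- pmax(i[keep], j[keep])
      dup <- duplicated(paste(lo, hi))
      lo <- lo[!dup]; hi <- hi[!dup]
      take <- min(cap, length(lo))
      cbind(ids_a[lo[seq_len(take)]], ids_a[hi[seq_len(take)]])
    } else {
      total <- length(ids_a) * length(ids_b)
      if (total == 0) return(empty)
      take <- min(cap, total)
      idx <- sample.int(total, take) - 1
      cbind(ids_a[idx %% length(ids_a) + 1],
            ids_b[idx %/% length(ids_a) + 1])
    }
  }

  set.seed(seed)
  # Must-links: a random chain through the class (connected, so the
  # initialisation closure sees one neighbourhood per class) plus random
  # extras up to the cap, keeping the graph thin: a dense same-class graph
  # would weld all labelled members into a single cluster and starve the
  # cluster-to-class mapping at large K.
  ml <- list()
  for (cls in strategy_codes()) {
    ids <- records$segment_id[single & records$label1 == cls]
    n_ids <- length(ids)
    if (n_ids >= 2) {
      ord <- ids[sample.int(n_ids)]
      chain <- cbind(ord[-n_ids], ord[-1])
      extra <- min(max_pairs_per_class, n_ids %/% 2) - 0
      more <- if (extra > 0 && n_ids >= 4) {
        prs <- sample_pairs(ids, NULL, extra, same = TRUE)
        prs
      } else NULL
      ml[[cls]] <- utils::head(rbind(chain, more), max_pairs_per_class)
    }
  }
  cl <- list()
  classes <- strategy_codes()
  has <- function(cls) records$segment_id[vapply(sets, function(s) cls %in% s,
                                                 logical(1))]
  by_class <- lapply(classes, has)
  names(by_class) <- classes
  for (ai in seq_along(classes)) {
    for (bi in seq_along(classes)) {
      if (bi <= ai) next
      a <- classes[ai]; b <- classes[bi]
      prs <- sample_pairs(by_class[[a]], by_class[[b]],
                          max_pairs_per_class)
      if (nrow(prs) == 0) next
      ok <- vapply(seq_len(nrow(prs)), function(r) {
        length(intersect(sets[[prs[r, 1]]], sets[[prs[r, 2]]])) == 0
      }, logical(1))
      prs <- prs[ok, , drop = FALSE]
      if (nrow(prs) > 0) cl[[paste(a, b)]] <- prs
    }
  }
  norm <- function(m) {
    if (length(m) == 0 || nrow(m) == 0) return(empty)
    m <- t(apply(m, 1, sort))
    m[m[, 1] != m[, 2], , drop = FALSE]
  }
  ml <- unique(norm(do.call(rbind, c(ml, list(empty)))))
  cl <- unique(norm(do.call(rbind, c(cl, list(empty)))))
  # a pair must never sit in both sets
  key <- function(m) paste(m[, 1], m[, 2])
  cl <- cl[!key(cl) %in% key(ml), , drop = FALSE]
  structure(list(must_link = ml, cannot_link = cl),
            class = "mwm_constraints")
}

#' Labelling coverage report
#'
#' The labelled fraction of segments should sit roughly between 8% and 12%
#' of the total; fewer labels tend to leave many segments unclassified or
#' misclassified.
#'
#' @param n_labelled Number of labelled segments.
#' @param n_segments Total number of segments (> 0).
#' @return List with `fraction` and `status` (`"OK"`, `"LOW"`, `"HIGH"`).
#' @export
coverage_report <- function(n_labelled, n_segments) {
  stopifnot(n_segments > 0, n_labelled >= 0)
  f <- n_labelled / n_segments
  status <- if (f < 0.08) "LOW" else if (f > 0.12) "HIGH" else "OK"
  list(fraction = f, status = status)
}
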