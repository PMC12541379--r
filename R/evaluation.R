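# Clustering-quality evaluation against taxonomy labels: per-sample
# silhouettes, adjusted mutual information (AMI), AMI-vs-eps profiles, and
# within/between-taxon distance threshold analysis.

#' Per-sample silhouette scores of a labelling over a distance matrix
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)`; samples in singleton
#' clusters score 0, and samples carrying the sentinel label
#' `"unclassified"` (or `NA`) are excluded from the evaluation entirely.
#'
#' @param D Symmetric distance matrix with accession dimnames.
#' @param labels Character/factor labels aligned with `rownames(D)`, or a
#'   named vector matched by accession.
#' @return Tibble with `accession`, `label`, `silhouette` for the evaluated
#'   samples; the mean is in attribute `mean_silhouette`.
#' @export
silhouette_scores <- function(D, labels) {
  D <- as.matrix(D)
  if (!is.null(names(labels))) labels <- labels[rownames(D)]
  stopifnot(length(labels) == nrow(D))
  labels <- as.character(labels)
  keep <- !is_sentinel(labels)
  if (sum(keep) < 2L || length(unique(labels[keep])) < 2L) {
    abort("need at least two distinct non-sentinel labels",
          class = "phagempr_input_error")
  }
  Dk <- D[keep, keep, drop = FALSE]
  lk <- labels[keep]
  cl <- as.integer(factor(lk))
  sil <- cluster::silhouette(cl, stats::as.dist(Dk))
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else {
    # silhouette() returns NA-like scalar only in degenerate cases already
    # excluded above
    rep(0, length(cl))
  }
  out <- tibble(accession = rownames(Dk), label = lk, silhouette = as.numeric(widths))
  attr(out, "mean_silhouette") <- mean(out$silhouette)
  out
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement with the exact
#' expected mutual information under the hypergeometric (fixed-margins)
#' model, normalized by the arithmetic mean of the two entropies:
#' `AMI = (MI - EMI) / (mean(H_a, H_b) - EMI)`. Invariant to label
#' permutation; 1 for identical partitions; approximately 0 for independent
#' labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (`n >= 2`).
#' @return A single number (typically in `[0, 1]`, can be slightly
#'   negative).
#' @export
ami <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("labelings must have equal length", class = "phagempr_input_error")
  }
  n <- length(labels_a)
  if (n < 2L) abort("need n >= 2", class = "phagempr_input_error")
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  # identical-partition fast path covers the trivial single-cluster /
  # all-singletons cases where the adjustment denominator vanishes
  if (identical_partition(a, b)) return(1)
  mi <- mutual_information(tab, n)
  ha <- entropy_counts(ai, n)
  hb <- entropy_counts(bj, n)
  emi <- expected_mi(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

identical_partition <- function(a, b) {
  ta <- tapply(seq_along(a), a, identity)
  tb <- tapply(seq_along(b), b, identity)
  length(ta) == length(tb) &&
    setequal(vapply(ta, paste, character(1), collapse = ","),
             vapply(tb, paste, character(1), collapse = ","))
}

entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(tab, n) {
  nij <- as.numeric(tab)
  ai <- rowSums(tab)[row(tab)]
  bj <- colSums(tab)[col(tab)]
  pos <- nij > 0
  sum((nij[pos] / n) * log(nij[pos] * n / (ai[pos] * bj[pos])))
}

# Exact expected mutual information under random permutations of one
# labeling with both margins fixed (hypergeometric cell distribution).
expected_mi <- function(ai, bj, n) {
  total <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(0L, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < max(lo, 1L)) next
      nij <- seq.int(max(lo, 1L), hi)
      p <- stats::dhyper(nij, bj[j], n - bj[j], ai[i])
      total <- total + sum(p * (nij / n) * log(nij * n / (ai[i] * bj[j])))
    }
  }
  total
}

#' AMI of flat clusterings against an annotation rank over an eps grid
#'
#' For each threshold the hierarchy is cut ([cut_at_eps()]), genomes with a
#' sentinel annotation are dropped, each remaining noise point is given a
#' unique singleton cluster label, and the AMI against the rank annotation
#' is recorded.
#'
#' @param h A `phage_hierarchy`.
#' @param annotations Annotation tibble (`accession` + rank columns).
#' @param rank Rank column to evaluate (needs >= 2 distinct non-sentinel
#'   labels).
#' @param eps_grid Thresholds; default is a logarithmic 64-point grid
#'   spanning the range of positive merge heights.
#' @return An `ami_profile` tibble: `eps`, `ami`, `n_clusters`; attributes
#'   `rank` and `n_evaluated`.
#' @export
ami_vs_eps <- function(h, annotations, rank, eps_grid = NULL) {
  stopifnot(inherits(h, "phage_hierarchy"))
  if (is.null(eps_grid)) eps_grid <- default_eps_grid(merge_heights(h))
  if (length(eps_grid) == 0L) abort("empty eps grid", class = "phagempr_input_error")
  lab <- annotations[[rank]][match(h$accessions, annotations$accession)]
  keep <- !is_sentinel(lab)
  if (length(unique(lab[keep])) < 2L) {
    abort(sprintf("rank '%s' needs at least two non-sentinel labels", rank),
          class = "phagempr_input_error")
  }
  rows <- purrr::map(eps_grid, function(eps) {
    cl <- cut_at_eps(h, eps)
    pred <- cl$cluster
    # each noise point becomes its own singleton cluster
    noise_ids <- seq_len(sum(cl$is_noise)) + max(c(0L, pred), na.rm = TRUE)
    pred[cl$is_noise] <- noise_ids
    tibble(
      eps = eps,
      ami = ami(lab[keep], pred[keep]),
      n_clusters = attr(cl, "n_clusters")
    )
  })
  out <- bind_rows(rows)
  attr(out, "rank") <- rank
  attr(out, "n_evaluated") <- sum(keep)
  class(out) <- c("ami_profile", class(out))
  out
}

default_eps_grid <- function(distances, length_out = 64L) {
  pos <- distances[distances > 0]
  if (length(pos) == 0L) return(numeric(0))
  exp(seq(log(min(pos)), log(max(pos)), length.out = length_out))
}

#' Within/between-taxon distance threshold analysis
#'
#' Samples `n_pairs` within-taxon and `n_pairs` between-taxon genome pairs
#' uniformly with replacement at the given rank (sentinel-labelled genomes
#' excluded), then finds the distance threshold maximizing Youden's
#' J = TPR - FPR, where positives are within-taxon pairs classified by
#' `distance <= threshold`. Candidate thresholds are midpoints between
#' consecutive distinct sampled distances, so in a separable dataset the
#' chosen threshold lies strictly inside the within/between gap.
#'
#' @param D Distance matrix with accession dimnames.
#' @param annotations Annotation tibble.
#' @param rank Rank column (e.g. `"genus"`).
#' @param n_pairs Pairs sampled per pool.
#' @param seed Local seed for the pair sampling.
#' @return A `threshold_report` list: `rank`, `n_pairs_within`,
#'   `n_pairs_between`, `within_distances`, `between_distances`,
#'   `best_threshold`, `tpr`, `fpr`, `youden`, `criterion`.
#' @export
threshold_analysis <- function(D, annotations, rank, n_pairs = 10000L, seed = 1L) {
  D <- as.matrix(D)
  lab <- annotations[[rank]][match(rownames(D), annotations$accession)]
  keep <- which(!is_sentinel(lab))
  lab <- lab[keep]
  idx <- keep
  if (length(idx) < 2L) abort("not enough annotated genomes", class = "phagempr_input_error")
  pairs <- utils::combn(seq_along(idx), 2L)
  same <- lab[pairs[1, ]] == lab[pairs[2, ]]
  if (!any(same)) {
    abort(sprintf("no within-taxon pairs at rank '%s'", rank),
          class = "phagempr_input_error")
  }
  if (all(same)) {
    abort(sprintf("no between-taxon pairs at rank '%s'", rank),
          class = "phagempr_input_error")
  }
  dvals <- D[cbind(idx[pairs[1, ]], idx[pairs[2, ]])]
  within_pool <- dvals[same]
  between_pool <- dvals[!same]
  withr_seed(seed, {
    within <- within_pool[sample.int(length(within_pool), n_pairs, replace = TRUE)]
    between <- between_pool[sample.int(length(between_pool), n_pairs, replace = TRUE)]
  })
  cand <- sort(unique(c(within, between)))
  cand <- c(cand[1] - 1, (head(cand, -1) + cand[-1]) / 2, cand[length(cand)] + 1)
  tpr <- vapply(cand, function(t) mean(within <= t), numeric(1))
  fpr <- vapply(cand, function(t) mean(between <= t), numeric(1))
  j <- tpr - fpr
  best <- which.max(j)
  structure(list(
    rank = rank,
    n_pairs_within = as.integer(n_pairs),
    n_pairs_between = as.integer(n_pairs),
    within_distances = within,
    between_distances = between,
    best_threshold = cand[best],
    tpr = tpr[best],
    fpr = fpr[best],
    youden = j[best],
    criterion = "youden-j",
    seed = seed
  ), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> rank %s: best threshold %.4g (TPR %.3f, FPR %.3f, J %.3f)\n",
    x$rank, x$best_threshold, x$tpr, x$fpr, x$youden
  ))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy threshold_report
#' @export
tidy.threshold_report <- function(x, ...) {
  bind_rows(
    tibble(pair_type = "within", distance = x$within_distances),
    tibble(pair_type = "between", distance = x$between_distances)
  )
}

#' @rdname tidiers
#' @method glance threshold_report
#' @export
glance.threshold_report <- function(x, ...) {
  tibble(rank = x$rank, best_threshold = x$best_threshold, tpr = x$tpr,
         fpr = x$fpr, youden = x$youden, criterion = x$criterion,
         n_pairs_within = x$n_pairs_within, n_pairs_between = x$n_pairs_between)
}

#' @rdname tidiers
#' @method glance ami_profile
#' @export
glance.ami_profile <- function(x, ...) {
  tibble(rank = attr(x, "rank"), n_evaluated = attr(x, "n_evaluated"),
         max_ami = max(x$ami), eps_at_max = x$eps[which.max(x$ami)])
}
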