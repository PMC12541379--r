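# Density-based hierarchy over MPRs. With a minimum neighbourhood of two
# points (minPts = 2), every point's core distance is its nearest-neighbour
# distance, so the mutual-reachability distance between any pair equals the
# raw distance and the density hierarchy's merge heights coincide with
# single-linkage agglomeration on the same distance matrix. The hierarchy is
# built by single linkage; flat cluster extraction at a distance threshold
# `eps` yields the connected components of the graph whose edges are pairs
# at distance <= eps, with singleton components labelled noise.

#' Build the cluster hierarchy over a distance matrix
#'
#' @param D Symmetric distance matrix with accession dimnames (from
#'   [pairwise_distances()]), `n >= 2`.
#' @return A `phage_hierarchy` object wrapping the single-linkage merge
#'   structure: fields `hclust`, `accessions`, `n`, plus the parameters
#'   `min_pts = 2`, `min_cluster_size = 2`.
#' @export
build_hierarchy <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) abort("need at least two points", class = "phagempr_input_error")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- sprintf("g%04d", seq_len(n))
  hc <- hclust(stats::as.dist(D), method = "single")
  hc$labels <- rownames(D)
  structure(
    list(hclust = hc, accessions = rownames(D), n = n,
         min_pts = 2L, min_cluster_size = 2L),
    class = "phage_hierarchy"
  )
}

#' @export
print.phage_hierarchy <- function(x, ...) {
  cat(sprintf("<phage_hierarchy> %d leaves, merge heights [%.3g, %.3g]\n",
              x$n, min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Merge heights of a hierarchy
#'
#' @param h A `phage_hierarchy`.
#' @return Non-decreasing numeric vector of the n - 1 merge distances.
#' @export
merge_heights <- function(h) h$hclust$height

#' Node table of a hierarchy
#'
#' One row per node: n leaves (accession set, height 0) followed by n - 1
#' internal cluster nodes with the distance at which their children join and
#' the number of leaves below. `parent` uses the same node ids (root has
#' `parent = NA`). Distances are non-increasing from the root toward the
#' leaves.
#'
#' @param h A `phage_hierarchy`.
#' @return Tibble with columns `node`, `type`, `accession`, `height`,
#'   `n_leaves`, `parent`.
#' @export
hierarchy_nodes <- function(h) {
  hc <- h$hclust
  n <- h$n
  n_leaves <- integer(n - 1L)
  parent <- rep(NA_integer_, 2L * n - 1L)  # ids: 1..n leaves, n+1..2n-1 internal
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    ids <- ifelse(kids < 0, -kids, kids + n)
    parent[ids] <- i + n
    n_leaves[i] <- sum(ifelse(kids < 0, 1L, n_leaves[pmax(kids, 1L)]))
  }
  tibble(
    node = seq_len(2L * n - 1L),
    type = rep(c("leaf", "cluster"), c(n, n - 1L)),
    accession = c(hc$labels, rep(NA_character_, n - 1L)),
    height = c(rep(0, n), hc$height),
    n_leaves = c(rep(1L, n), n_leaves),
    parent = parent
  )
}

# Leaf accession sets below each internal node (list of length n-1).
node_leaf_sets <- function(h) {
  hc <- h$hclust
  n <- h$n
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    sets[[i]] <- c(
      if (kids[1] < 0) hc$labels[-kids[1]] else sets[[kids[1]]],
      if (kids[2] < 0) hc$labels[-kids[2]] else sets[[kids[2]]]
    )
  }
  sets
}

#' Extract flat clusters at a distance threshold
#'
#' Clusters are the connected components of the graph whose edges are pairs
#' at distance `<= eps`; single-point components are labelled noise
#' (`is_noise = TRUE`, `cluster = NA`), following the DBSCAN* convention
#' with a minimum neighbourhood of two.
#'
#' @param h A `phage_hierarchy` from [build_hierarchy()].
#' @param eps Distance threshold, `>= 0`.
#' @return A `phage_clustering` tibble: `accession`, `cluster` (contiguous
#'   integer ids in order of first appearance, `NA` for noise), `is_noise`;
#'   attributes `eps` and `n_clusters`.
#' @export
cut_at_eps <- function(h, eps) {
  stopifnot(inherits(h, "phage_hierarchy"))
  assert_scalar_number(eps, "eps")
  if (eps < 0) abort("eps must be non-negative", class = "phagempr_input_error")
  # union-find over the merge list: apply every merge with height <= eps
  # (exact <=, matching the pairs-at-distance-<=-eps graph semantics)
  hc <- h$hclust
  n <- h$n
  uf <- seq_len(n)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  merge_leaf <- integer(max(n - 1L, 1L))  # one leaf below each merge node
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    la <- if (kids[1] < 0) -kids[1] else merge_leaf[kids[1]]
    lb <- if (kids[2] < 0) -kids[2] else merge_leaf[kids[2]]
    merge_leaf[i] <- la
    if (hc$height[i] <= eps) uf[find(lb)] <- find(la)
  }
  raw <- vapply(seq_len(n), find, integer(1))
  sizes <- table(raw)
  noise <- sizes[as.character(raw)] == 1L
  ids <- rep(NA_integer_, h$n)
  keep <- !noise
  if (any(keep)) {
    first_seen <- raw[keep]
    ids[keep] <- match(first_seen, unique(first_seen))
  }
  out <- tibble(accession = h$accessions, cluster = ids, is_noise = as.logical(noise))
  attr(out, "eps") <- eps
  attr(out, "n_clusters") <- length(unique(ids[!is.na(ids)]))
  class(out) <- c("phage_clustering", class(out))
  out
}

#' Extract the branch best matching an annotated taxon
#'
#' Scans every internal node of the hierarchy and returns the one whose leaf
#' set maximizes the F1 score against the set of genomes annotated with
#' `taxon` at `rank` (ties broken toward fewer leaves, then lower height) —
#' an explicit operationalization of picking "the top node of the taxon's
#' phages and all its successors". In-taxon and other leaf counts are
#' reported alongside.
#'
#' @param h A `phage_hierarchy`.
#' @param annotations Annotation tibble with `accession` and rank columns.
#' @param rank Rank column name (e.g. `"family"`).
#' @param taxon Taxon name; must be annotated on at least one leaf.
#' @return A `phage_branch` list: `node`, `leaves`, `members` (tibble of
#'   leaf accessions with an `in_taxon` flag), `n_in_taxon`, `n_other`,
#'   `precision`, `recall`, `f1`, `height`, `rank`, `taxon`.
#' @export
extract_branch <- function(h, annotations, rank, taxon) {
  stopifnot(inherits(h, "phage_hierarchy"))
  if (!rank %in% names(annotations)) {
    abort(sprintf("rank column '%s' missing from annotations", rank),
          class = "phagempr_input_error")
  }
  lab <- annotations[[rank]][match(h$accessions, annotations$accession)]
  target <- h$accessions[!is.na(lab) & lab == taxon]
  if (length(target) == 0L) {
    abort(sprintf("taxon '%s' absent at rank '%s'", taxon, rank),
          class = "phagempr_input_error")
  }
  sets <- node_leaf_sets(h)
  stats <- vapply(sets, function(s) {
    tp <- length(intersect(s, target))
    prec <- tp / length(s)
    rec <- tp / length(target)
    f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
    c(f1 = f1, size = length(s))
  }, numeric(2))
  hts <- merge_heights(h)
  ord <- order(-stats["f1", ], stats["size", ], hts)
  best <- ord[[1]]
  leaves <- sets[[best]]
  tp <- length(intersect(leaves, target))
  structure(list(
    node = best + h$n,
    leaves = leaves,
    members = tibble(accession = leaves, in_taxon = leaves %in% target),
    n_in_taxon = tp,
    n_other = length(leaves) - tp,
    precision = tp / length(leaves),
    recall = tp / length(target),
    f1 = max(stats["f1", ]),
    height = hts[best],
    rank = rank, taxon = taxon
  ), class = "phage_branch")
}

#' @export
print.phage_branch <- function(x, ...) {
  cat(sprintf("<phage_branch> %s '%s': %d leaves (%d in taxon / %d other), F1 = %.3f\n",
              x$rank, x$taxon, length(x$leaves), x$n_in_taxon, x$n_other, x$f1))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy phage_hierarchy
#' @export
tidy.phage_hierarchy <- function(x, ...) hierarchy_nodes(x)

#' @rdname tidiers
#' @method glance phage_hierarchy
#' @export
glance.phage_hierarchy <- function(x, ...) {
  tibble(n_leaves = x$n, n_merges = x$n - 1L,
         min_height = min(merge_heights(x)), max_height = max(merge_heights(x)),
         min_pts = x$min_pts)
}

#' @rdname tidiers
#' @method tidy phage_branch
#' @export
tidy.phage_branch <- function(x, ...) x$members

#' @rdname tidiers
#' @method glance phage_branch
#' @export
glance.phage_branch <- function(x, ...) {
  tibble(rank = x$rank, taxon = x$taxon, n_leaves = length(x$leaves),
         n_in_taxon = x$n_in_taxon, n_other = x$n_other,
         precision = x$precision, recall = x$recall, f1 = x$f1,
         height = x$height)
}

#' Serialize a hierarchy to JSON
#'
#' @param h A `phage_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy_json <- function(h, path) {
  nodes <- hierarchy_nodes(h)
  jsonlite::write_json(
    list(n_leaves = h$n, min_pts = h$min_pts, nodes = nodes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
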