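# Independent oracles used across the suite. These re-derive expected
# results by routes that share no code with the implementation under test.

# Single-linkage merge heights via a Prim minimum-spanning-tree scan:
# the sorted MST edge weights are exactly the single-linkage dendrogram
# heights.
oracle_single_linkage_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[, 1]
  weights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    weights[step] <- best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[, nxt])
  }
  sort(weights)
}

# Connected components of the graph with edges at distance <= eps, by plain
# union-find over the edge list.
oracle_components <- function(D, eps) {
  D <- as.matrix(D)
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ed <- which(upper.tri(D) & D <= eps, arr.ind = TRUE)
  if (nrow(ed) > 0L) {
    for (r in seq_len(nrow(ed))) {
      a <- find(ed[r, 1])
      b <- find(ed[r, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a partition for equality checks (noise = singleton ids).
canonical_partition <- function(cluster, is_noise = NULL) {
  x <- cluster
  if (!is.null(is_noise) && any(is_noise)) {
    x[is_noise] <- max(c(0L, x[!is_noise]), 0L) + seq_len(sum(is_noise))
  }
  match(x, unique(x))
}

same_partition <- function(a, b) {
  all(tapply(a, b, function(v) length(unique(v))) == 1L) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1L)
}

# Is partition `fine` a refinement of `coarse` (every fine cluster inside
# one coarse cluster)?
is_coarsening <- function(fine, coarse) {
  all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
}

# Exact expected mutual information by full enumeration of permutations of
# one labeling (the hypergeometric fixed-margins model); n! terms, so tiny
# n only.
oracle_emi_permutations <- function(a, b) {
  n <- length(a)
  perms <- all_permutations(n)
  mis <- apply(perms, 1L, function(p) oracle_mi(a, b[p]))
  mean(mis)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

oracle_mi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        mi <- mi + (nij / n) * log(nij * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  mi
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# Silhouette by direct evaluation of the defining formula.
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    same <- which(labels == labels[i])
    if (length(same) == 1L) return(0)
    a <- mean(D[i, setdiff(same, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Random distance matrix from points in a low-dimensional cube.
random_distance_matrix <- function(n, d = 4L) {
  pts <- matrix(runif(n * d), n, d)
  rownames(pts) <- sprintf("acc%04d", seq_len(n))
  pairwise_distances(pts)
}
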