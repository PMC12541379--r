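# Mean proteome representation (MPR): the plain average of a proteome's
# unit protein vectors. The average is deliberately NOT re-normalized — its
# norm carries meaning (angular spread of the proteome's protein functions).

#' Compute the mean proteome representation of one proteome
#'
#' `phi = (1/m) sum_i u_i` over the proteome's unit protein vectors. The
#' result is not re-normalized; `||phi|| <= 1` with equality iff all protein
#' vectors coincide. Duplicate proteins are kept (a bag, not a set).
#'
#' @param representations Numeric matrix (m x d) of unit rows, e.g. from
#'   [embed_proteome()].
#' @param check_unit Verify that rows are unit-norm to 1e-6.
#' @return Numeric d-vector with attribute `m` (the proteome size used).
#' @export
compute_mpr <- function(representations, check_unit = TRUE) {
  representations <- as.matrix(representations)
  m <- nrow(representations)
  if (m == 0L) abort("empty proteome", class = "phagempr_input_error")
  if (check_unit) {
    norms <- sqrt(rowSums(representations^2))
    if (any(abs(norms - 1) > 1e-6)) {
      abort("protein representations must be unit vectors",
            class = "phagempr_input_error")
    }
  }
  phi <- colMeans(representations)
  attr(phi, "m") <- m
  phi
}

#' Build the MPR matrix for a set of proteomes
#'
#' @param representations Numeric matrix of unit protein rows whose rownames
#'   are protein ids, or a list of per-proteome matrices.
#' @param accessions When `representations` is a single matrix: character
#'   vector (one per row) assigning proteins to genome accessions. Ignored
#'   for a named list input.
#' @return Matrix (n_genomes x d) of MPRs, rownames = accessions
#'   (first-appearance order), with attribute `m` (named proteome sizes).
#' @export
mpr_matrix <- function(representations, accessions = NULL) {
  if (is.list(representations) && !is.data.frame(representations)) {
    mats <- representations
    if (is.null(names(mats))) abort("list input must be named by accession")
  } else {
    representations <- as.matrix(representations)
    stopifnot(length(accessions) == nrow(representations))
    acc <- unique(accessions)
    mats <- lapply(acc, function(a) representations[accessions == a, , drop = FALSE])
    names(mats) <- acc
  }
  out <- do.call(rbind, lapply(mats, compute_mpr))
  rownames(out) <- names(mats)
  attr(out, "m") <- vapply(mats, nrow, integer(1))
  out
}

#' Squared norm, dot product and Euclidean distance of MPR vectors
#'
#' Small float64 helpers satisfying the decomposition
#' `distance^2 == norm_sq(u) + norm_sq(v) - 2 dot(u, v)` (used as a
#' cross-check in the tests, not as the computation path for the distance).
#'
#' @param u,v Numeric vectors of equal dimension.
#' @return A single number.
#' @export
mpr_norm_sq <- function(u) sum(as.numeric(u)^2)

#' @rdname mpr_norm_sq
#' @export
mpr_dot <- function(u, v) {
  check_same_dim(u, v)
  sum(as.numeric(u) * as.numeric(v))
}

#' @rdname mpr_norm_sq
#' @export
mpr_distance <- function(u, v) {
  check_same_dim(u, v)
  sqrt(sum((as.numeric(u) - as.numeric(v))^2))
}

check_same_dim <- function(u, v) {
  if (length(u) != length(v)) {
    abort("dimension mismatch between MPR vectors", class = "phagempr_input_error")
  }
}

#' Pairwise Euclidean distance matrix between MPRs
#'
#' @param mprs Numeric matrix (n x d) with unique accession rownames.
#' @return Symmetric n x n matrix of Euclidean distances (float64), zero
#'   diagonal, accession dimnames.
#' @export
pairwise_distances <- function(mprs) {
  mprs <- as.matrix(mprs)
  if (nrow(mprs) < 2L) abort("need at least two MPRs", class = "phagempr_input_error")
  if (is.null(rownames(mprs))) rownames(mprs) <- sprintf("g%04d", seq_len(nrow(mprs)))
  if (anyDuplicated(rownames(mprs))) {
    abort("duplicate accessions in MPR matrix", class = "phagempr_input_error")
  }
  D <- as.matrix(dist(mprs, method = "euclidean"))
  diag(D) <- 0
  D
}
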