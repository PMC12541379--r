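# Closed-form expectations for MPR moments under the protein-family mixture
# model: protein i belongs to a fixed family k(i) whose embedding cluster has
# unit direction mu_k and compactness alpha_k (mean resultant length), so
# that E[u_i] = alpha_k(i) mu_k(i), with proteins drawn independently.
# Cluster membership is fixed; only the embeddings are random.

#' Construct a protein-family mixture model
#'
#' @param mu Matrix (K x d) of unit family directions.
#' @param kappa Optional vector of K sampling concentrations; when given,
#'   `alpha` defaults to the exact mean resultant length
#'   [alpha_from_kappa()] realized by the von Mises-Fisher sampler.
#' @param alpha Optional vector of K compactness values in `[0, 1]`.
#' @return A `family_model` list with fields `K`, `d`, `mu`, `alpha`,
#'   `kappa`.
#' @export
family_model <- function(mu, kappa = NULL, alpha = NULL) {
  mu <- as.matrix(mu)
  K <- nrow(mu)
  d <- ncol(mu)
  norms <- sqrt(rowSums(mu^2))
  if (any(abs(norms - 1) > 1e-8)) {
    abort("family directions must be unit vectors", class = "phagempr_input_error")
  }
  if (is.null(alpha)) {
    if (is.null(kappa)) abort("provide kappa or alpha")
    kappa <- rep_len(kappa, K)
    alpha <- alpha_from_kappa(kappa, d)
  } else {
    alpha <- rep_len(alpha, K)
    if (any(alpha < 0 | alpha > 1)) {
      abort("alpha must lie in [0, 1]", class = "phagempr_input_error")
    }
  }
  structure(list(K = K, d = d, mu = mu, alpha = as.numeric(alpha),
                 kappa = if (is.null(kappa)) rep(NA_real_, K) else as.numeric(kappa)),
            class = "family_model")
}

#' Draw K unit family directions
#'
#' Uniform random directions (near-orthogonal in high dimension) or exactly
#' orthogonal axes for analytic tests.
#'
#' @param K Number of directions (for `orthogonal = TRUE`, `K <= d`).
#' @param d Dimension.
#' @param orthogonal Use the first K coordinate axes.
#' @param seed Optional local seed.
#' @return Matrix (K x d) of unit rows.
#' @export
random_directions <- function(K, d, orthogonal = FALSE, seed = NULL) {
  if (orthogonal) {
    stopifnot(K <= d)
    return(diag(1, K, d))
  }
  run <- function() {
    m <- matrix(rnorm(K * d), K, d)
    m / sqrt(rowSums(m^2))
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

check_families <- function(model, k) {
  if (length(k) == 0L) abort("empty assignment", class = "phagempr_input_error")
  if (any(k < 1L | k > model$K)) {
    abort("family index outside model", class = "phagempr_input_error")
  }
}

#' Expected squared norm of an MPR
#'
#' `E[||phi||^2] = 1/m + (1/m^2) sum_{i != j} alpha_k(i) alpha_k(j)
#' mu_k(i)' mu_k(j)` over the ordered pairs of a fixed family assignment.
#' Large values indicate proteins concentrated in few, aligned families
#' (low functional diversity); for m = 1 the value is exactly 1.
#'
#' @param model A [family_model()].
#' @param assignment Integer vector of length m of family indices, one per
#'   protein.
#' @return A single number.
#' @export
expected_sq_norm <- function(model, assignment) {
  assignment <- as.integer(assignment)
  check_families(model, assignment)
  m <- length(assignment)
  # sum over ordered pairs i != j of a_i a_j mu_i' mu_j computed via the
  # composition counts: ||sum_i alpha_i mu_i||^2 minus the diagonal
  amu <- model$alpha[assignment] * model$mu[assignment, , drop = FALSE]
  s <- colSums(amu)
  cross <- sum(s * s) - sum(model$alpha[assignment]^2)
  1 / m + cross / m^2
}

#' Composition profile of a proteome over protein families
#'
#' @param assignment Integer vector of family indices (length m).
#' @param K Number of families in the model.
#' @return Integer vector of length K of per-family protein counts `n_k`.
#' @export
composition_counts <- function(assignment, K) {
  tabulate(as.integer(assignment), nbins = K)
}

#' Expected dot product between two MPRs
#'
#' `E[phi_u' phi_v] = (1/(m_u m_v)) (sum_k n^u_k n^v_k alpha_k^2 +
#' sum_{k != l} n^u_k n^v_l alpha_k alpha_l mu_k' mu_l)`: shared protein
#' families weighted by their compactness, plus cross-talk between distinct
#' families that lie close in embedding space.
#'
#' @param model A [family_model()].
#' @param profile_u,profile_v Integer vectors of length K of family counts
#'   (see [composition_counts()]), each with a positive total.
#' @return A single number, symmetric in `u` and `v`.
#' @export
expected_dot <- function(model, profile_u, profile_v) {
  profile_u <- as.numeric(profile_u)
  profile_v <- as.numeric(profile_v)
  if (length(profile_u) != model$K || length(profile_v) != model$K) {
    abort("profiles must have one count per model family",
          class = "phagempr_input_error")
  }
  m_u <- sum(profile_u)
  m_v <- sum(profile_v)
  if (m_u < 1 || m_v < 1) abort("profiles non-empty required",
                                class = "phagempr_input_error")
  a_u <- profile_u * model$alpha
  a_v <- profile_v * model$alpha
  gram_full <- as.numeric((a_u %*% model$mu) %*% t(a_v %*% model$mu))
  diag_term <- sum(profile_u * profile_v * model$alpha^2)
  # full double sum = diagonal(with mu_k'mu_k = 1) + off-diagonal
  off <- gram_full - diag_term
  (diag_term + off) / (m_u * m_v)
}

#' Expected squared Euclidean distance between two MPRs
#'
#' Evaluated through the decomposition
#' `E[||phi_u - phi_v||^2] = E[||phi_u||^2] + E[||phi_v||^2] -
#' 2 E[phi_u' phi_v]`, treating the two proteomes' embeddings as
#' independent draws.
#'
#' @param model A [family_model()].
#' @param assignment_u,assignment_v Integer family assignments of the two
#'   proteomes.
#' @return A single number.
#' @export
expected_sq_distance <- function(model, assignment_u, assignment_v) {
  pu <- composition_counts(assignment_u, model$K)
  pv <- composition_counts(assignment_v, model$K)
  expected_sq_norm(model, assignment_u) + expected_sq_norm(model, assignment_v) -
    2 * expected_dot(model, pu, pv)
}

#' Monte-Carlo replicates of an MPR under the mixture model
#'
#' Draws `n_rep` independent proteomes with the given fixed family
#' assignment (each protein sampled from its family's von Mises-Fisher
#' cluster) and returns the replicate MPRs; the empirical moments of these
#' replicates are the simulation side of the analytic-vs-Monte-Carlo checks.
#'
#' @param model A [family_model()] with finite `kappa`.
#' @param assignment Integer family assignment (length m).
#' @param n_rep Number of replicate proteomes.
#' @param seed Local seed.
#' @param chunk Replicates per memory chunk.
#' @return Matrix (n_rep x d) of MPR replicates.
#' @export
simulate_mpr <- function(model, assignment, n_rep, seed = NULL, chunk = 2000L) {
  assignment <- as.integer(assignment)
  check_families(model, assignment)
  if (any(!is.finite(model$kappa))) {
    abort("model has no sampling concentration kappa", class = "phagempr_input_error")
  }
  m <- length(assignment)
  counts <- composition_counts(assignment, model$K)
  run <- function() {
    out <- matrix(0, n_rep, model$d)
    done <- 0L
    while (done < n_rep) {
      r <- min(chunk, n_rep - done)
      acc <- matrix(0, r, model$d)
      for (k in which(counts > 0L)) {
        nk <- counts[k]
        draws <- sample_vmf(model$mu[k, ], model$kappa[k], nk * r)
        acc <- acc + rowsum(draws, rep(seq_len(r), each = nk))
      }
      out[done + seq_len(r), ] <- acc / m
      done <- done + r
    }
    out
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}
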