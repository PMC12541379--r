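# von Mises-Fisher sampling on the unit hypersphere and the exact
# concentration -> mean-resultant-length mapping.
#
# Sampling uses the tangent-normal decomposition with Wood's rejection
# scheme for the cosine t = u' mu: f(t) proportional to
# (1 - t^2)^((d-3)/2) exp(kappa t) on [-1, 1]. The same marginal density
# gives alpha(kappa, d) = E[t] by 1-D quadrature, evaluated with the
# exp(kappa (t - 1)) scaling so it is stable for any kappa.

#' Sample unit vectors from a von Mises-Fisher distribution
#'
#' @param mu Unit mean-direction vector (length d >= 2).
#' @param kappa Concentration, `kappa >= 0`; `kappa = 0` is uniform on the
#'   sphere.
#' @param n Number of samples.
#' @param seed Optional seed applied locally.
#' @return Matrix (n x d) of unit rows.
#' @export
sample_vmf <- function(mu, kappa, n, seed = NULL) {
  mu <- as.numeric(mu)
  d <- length(mu)
  stopifnot(d >= 2L, n >= 0L)
  if (kappa < 0) abort("kappa must be non-negative", class = "phagempr_input_error")
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-8) {
    abort("mu must be a unit vector", class = "phagempr_input_error")
  }
  run <- function() {
    if (n == 0L) return(matrix(numeric(0), 0L, d))
    t <- vmf_cosines(kappa, d, n)
    # tangent direction: gaussian, projected orthogonal to mu, normalized
    z <- matrix(rnorm(n * d), n, d)
    z <- z - (z %*% mu) %*% rbind(mu)  # remove component along mu
    zn <- sqrt(rowSums(z^2))
    degenerate <- zn < 1e-300
    if (any(degenerate)) {            # astronomically rare; resample those rows
      z[degenerate, ] <- rnorm(sum(degenerate) * d)
      z[degenerate, ] <- z[degenerate, , drop = FALSE] -
        (z[degenerate, , drop = FALSE] %*% mu) %*% rbind(mu)
      zn <- sqrt(rowSums(z^2))
    }
    xi <- z / zn
    out <- t * matrix(mu, n, d, byrow = TRUE) + sqrt(pmax(0, 1 - t^2)) * xi
    out / sqrt(rowSums(out^2))        # renormalize against rounding
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

# Vectorized Wood (1994) rejection sampler for the vMF cosine.
vmf_cosines <- function(kappa, d, n) {
  if (kappa == 0) {
    # uniform sphere: t has density (1-t^2)^((d-3)/2); (t+1)/2 ~ Beta((d-1)/2,(d-1)/2)
    return(2 * rbeta(n, (d - 1) / 2, (d - 1) / 2) - 1)
  }
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (d - 1) * log1p(-x0^2)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 64L)
    m <- ceiling(m * 1.3)
    z <- rbeta(m, (d - 1) / 2, (d - 1) / 2)
    t <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- runif(m)
    keep <- kappa * t + (d - 1) * log1p(-x0 * t) - c0 >= log(u)
    out <- c(out, t[keep])
  }
  out[seq_len(n)]
}

#' Mean resultant length of a von Mises-Fisher distribution
#'
#' `alpha(kappa, d) = E[u' mu]`, computed by exact quadrature of the tangent
#' marginal density (no Bessel-ratio evaluation, so stable at any
#' concentration and dimension). This is the compactness parameter of a
#' protein-family cluster: `E[u] = alpha * mu`.
#'
#' @param kappa Concentration(s), `>= 0`.
#' @param d Dimension, `>= 2`.
#' @return Values in `[0, 1)`, vectorized over `kappa`.
#' @export
alpha_from_kappa <- function(kappa, d) {
  stopifnot(d >= 2L, all(kappa >= 0))
  vapply(kappa, function(k) {
    if (k == 0) return(0)
    p <- (d - 3) / 2
    f <- function(t) exp(p * log1p(-t^2) + k * (t - 1))
    num <- integrate(function(t) t * f(t), -1, 1, rel.tol = 1e-12,
                     subdivisions = 500L)$value
    den <- integrate(f, -1, 1, rel.tol = 1e-12, subdivisions = 500L)$value
    num / den
  }, numeric(1))
}
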