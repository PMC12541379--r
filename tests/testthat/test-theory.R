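# Frozen hand evaluations of the three expectation formulas, plus
# summation oracles that re-derive them term by term.

oracle_sq_norm <- function(model, assignment) {
  m <- length(assignment)
  total <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) {
        total <- total + model$alpha[assignment[i]] * model$alpha[assignment[j]] *
          sum(model$mu[assignment[i], ] * model$mu[assignment[j], ])
      }
    }
  }
  1 / m + total / m^2
}

oracle_dot <- function(model, nu, nv) {
  m_u <- sum(nu)
  m_v <- sum(nv)
  total <- 0
  for (k in seq_len(model$K)) {
    for (l in seq_len(model$K)) {
      w <- if (k == l) model$alpha[k]^2 else
        model$alpha[k] * model$alpha[l] * sum(model$mu[k, ] * model$mu[l, ])
      total <- total + nu[k] * nv[l] * w
    }
  }
  total / (m_u * m_v)
}

test_that("expected squared norm matches hand-evaluated cases and the pair-sum oracle", {
  m1 <- family_model(random_directions(3, 8, seed = 1), alpha = c(0.5, 0.9, 0.2))
  expect_equal(expected_sq_norm(m1, 2L), 1)

  ortho <- family_model(diag(1, 2, 4), alpha = c(0.7, 0.3))
  expect_equal(expected_sq_norm(ortho, c(1L, 2L)), 0.5)

  one_fam <- family_model(diag(1, 2, 4), alpha = c(0.8, 0.8))
  expect_equal(expected_sq_norm(one_fam, c(1L, 1L, 1L)), 0.76)

  set.seed(8)
  for (i in 1:10) {
    model <- family_model(random_directions(4, 16), alpha = runif(4))
    assign <- sample.int(4, sample(1:12, 1), replace = TRUE)
    expect_equal(expected_sq_norm(model, assign), oracle_sq_norm(model, assign),
                 tolerance = 1e-12)
  }
  expect_error(expected_sq_norm(m1, integer(0)), class = "phagempr_input_error")
  expect_error(expected_sq_norm(m1, 7L), class = "phagempr_input_error")
})

test_that("expected dot product matches hand-evaluated cases and the double-sum oracle", {
  ortho <- family_model(diag(1, 2, 4), alpha = c(1, 1))
  expect_equal(expected_dot(ortho, c(1, 0), c(0, 1)), 0)
  expect_equal(expected_dot(ortho, c(1, 0), c(1, 0)), 1)

  two <- family_model(diag(1, 2, 4), alpha = c(0.9, 0.7))
  expect_equal(expected_dot(two, c(2, 1), c(1, 3)), 0.2575)

  set.seed(9)
  for (i in 1:10) {
    model <- family_model(random_directions(3, 8), alpha = runif(3))
    nu <- c(rmultinom(1, sample(1:15, 1), c(1, 1, 1)))
    nv <- c(rmultinom(1, sample(1:15, 1), c(1, 2, 1)))
    expect_equal(expected_dot(model, nu, nv), oracle_dot(model, nu, nv),
                 tolerance = 1e-12)
    expect_equal(expected_dot(model, nu, nv), expected_dot(model, nv, nu))
  }
  expect_error(expected_dot(two, c(1, 0, 1), c(1, 0)), class = "phagempr_input_error")
})

test_that("expected squared distance follows the norm/dot decomposition", {
  det_fam <- family_model(diag(1, 2, 4), alpha = c(1, 1))
  expect_equal(expected_sq_distance(det_fam, c(1L, 1L), c(1L, 1L)), 0)
  expect_equal(expected_sq_distance(det_fam, 1L, 2L), 2)

  set.seed(10)
  for (i in 1:10) {
    model <- family_model(random_directions(4, 12), alpha = runif(4))
    au <- sample.int(4, sample(1:10, 1), replace = TRUE)
    av <- sample.int(4, sample(1:10, 1), replace = TRUE)
    expect_gte(expected_sq_distance(model, au, av), -1e-12)
    expect_equal(
      expected_sq_distance(model, au, av),
      expected_sq_norm(model, au) + expected_sq_norm(model, av) -
        2 * expected_dot(model, composition_counts(au, 4),
                         composition_counts(av, 4))
    )
  }
})

test_that("quadrature compactness equals the sampler's mean resultant length", {
  set.seed(12)
  for (cfg in list(c(0.5, 3), c(5, 8), c(50, 64), c(200, 16))) {
    kappa <- cfg[1]
    d <- cfg[2]
    mu <- normalize_unit(rnorm(d))
    n <- 20000L
    t_obs <- as.numeric(sample_vmf(mu, kappa, n) %*% mu)
    se <- stats::sd(t_obs) / sqrt(n)
    expect_lt(abs(mean(t_obs) - alpha_from_kappa(kappa, d)), 3 * se)
  }
  expect_equal(alpha_from_kappa(0, 16), 0)
  expect_true(all(diff(alpha_from_kappa(c(1, 5, 25, 125), 16)) > 0))
})

test_that("analytic moments agree with Monte-Carlo simulation", {
  model <- family_model(random_directions(3, 16, seed = 21), kappa = c(30, 60, 90))
  au <- c(1L, 1L, 2L, 3L, 3L)
  av <- c(2L, 2L, 3L)
  R <- 4000L
  phi_u <- simulate_mpr(model, au, R, seed = 22)
  phi_v <- simulate_mpr(model, av, R, seed = 23)

  check_z <- function(obs, expected) {
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - expected) / se, 3)
  }
  check_z(rowSums(phi_u^2), expected_sq_norm(model, au))
  check_z(rowSums(phi_u * phi_v),
          expected_dot(model, composition_counts(au, 3), composition_counts(av, 3)))
  check_z(rowSums((phi_u - phi_v)^2), expected_sq_distance(model, au, av))
})
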