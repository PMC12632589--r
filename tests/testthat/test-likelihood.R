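test_that("polynomial evaluation matches a scalar-loop oracle", {
  set.seed(1)
  K <- 5; D <- 3; P <- 4; S <- 2
  theta <- array(rnorm(D * P * S), dim = c(D, P, S))
  basis <- build_basis(K, D)
  M <- evaluate_progression(theta, basis)

  for (s in 1:S) for (k in 0:K) for (p in 1:P) {
    mu <- sum(theta[, p, s] * (k / K)^(1:D))
    expect_equal(M[k + 1, p, s], mu, tolerance = 1e-12)
  }
  expect_equal(M[1, , ], matrix(0, P, S))  # zero intercept at stage 0

  expect_equal(evaluate_progression(array(0, dim = c(D, P, S)), basis),
               array(0, dim = c(K + 1, P, S)))
  # cancellation at t = 1 for theta = (1, -1)
  th <- array(c(1, -1), dim = c(2, 1, 1))
  M2 <- evaluate_progression(th, build_basis(4, 2))
  expect_equal(M2[5, 1, 1], 0)
  expect_error(evaluate_progression(theta, build_basis(K, D + 1)),
               "degree mismatch")
})

test_that("observation log-likelihood sums per-feature log-densities", {
  g <- gaussian_constants(1)
  basis <- build_basis(10, 1)
  # single feature at zero against an all-zero model: every cell is the
  # standard normal peak
  M0 <- evaluate_progression(array(0, dim = c(1, 1, 2)), basis)
  phi0 <- observation_loglik(0, M0, g)
  expect_equal(dim(phi0), c(2, 11))
  expect_true(all(abs(phi0 - (-0.9189385)) < 1e-7))

  # two-feature toy matches exp-then-product of per-feature densities
  set.seed(2)
  theta <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2))
  b2 <- build_basis(4, 2)
  M <- evaluate_progression(theta, b2)
  x <- c(0.3, -1.1)
  phi <- observation_loglik(x, M, g)
  for (s in 1:2) for (k in 0:4) {
    direct <- prod(dnorm(x, M[k + 1, , s], 1))
    expect_equal(exp(phi[s, k + 1]), direct, tolerance = 1e-10)
  }

  # translation invariance of (x - mu)^2
  M_shift <- M
  M_shift[, 1, ] <- M_shift[, 1, ] + 3.7
  x_shift <- x + c(3.7, 0)
  expect_equal(observation_loglik(x_shift, M_shift, g), phi,
               tolerance = 1e-12)

  expect_error(observation_loglik(c(1, 2, 3), M, g), "features")
})

test_that("log-domain dataset likelihood matches the product domain", {
  set.seed(3)
  g <- gaussian_constants(1)
  theta <- array(rnorm(2 * 3 * 2, sd = 0.5), dim = c(2, 3, 2))
  basis <- build_basis(5, 2)
  M <- evaluate_progression(theta, basis)
  X <- matrix(rnorm(8 * 3), 8, 3)
  log_lik <- 0
  prod_lik <- 1
  for (n in 1:8) {
    phi <- observation_loglik(X[n, ], M, g)
    log_lik <- log_lik + max(phi)
    prods <- matrix(NA_real_, 2, 6)
    for (s in 1:2) for (k in 0:5) {
      prods[s, k + 1] <- prod(dnorm(X[n, ], M[k + 1, , s], 1))
    }
    prod_lik <- prod_lik * max(prods)
  }
  expect_equal(exp(log_lik), prod_lik, tolerance = 1e-8)
})

test_that("argmax assignment matches an exhaustive scan with stage-first ties", {
  phi <- matrix(-5, 3, 9)
  phi[2, 8] <- -1
  a <- assign_observation(phi)
  expect_equal(a$subtype, 2)
  expect_equal(a$stage, 7)
  expect_equal(a$loglik, -1)

  # constant surface: lowest stage, then lowest subtype
  tie <- assign_observation(matrix(-2, 4, 6))
  expect_equal(tie$subtype, 1)
  expect_equal(tie$stage, 0)

  set.seed(4)
  for (i in 1:50) {
    phi <- matrix(rnorm(3 * 11), 3, 11)
    a <- assign_observation(phi)
    best <- -Inf; bs <- NA; bk <- NA
    for (k in 0:10) for (s in 1:3) {        # scan in tie-break order
      if (phi[s, k + 1] > best) { best <- phi[s, k + 1]; bs <- s; bk <- k }
    }
    expect_equal(a$subtype, bs)
    expect_equal(a$stage, bk)
    expect_equal(a$loglik, best)
  }
})

test_that("total loss equals the brute-force assembly", {
  g <- gaussian_constants(1)
  # single zero record against a zero model
  d1 <- data_matrix(matrix(0, 1, 1), zscored = TRUE)
  th1 <- array(0, dim = c(1, 1, 1))
  b1 <- build_basis(5, 1)
  expect_equal(total_loss(d1, th1, b1, g, 0), 0.9189385, tolerance = 1e-7)

  set.seed(5)
  theta <- array(rnorm(2 * 3 * 2), dim = c(2, 3, 2))
  basis <- build_basis(6, 2)
  X <- matrix(rnorm(10 * 3), 10, 3)
  d <- data_matrix(X, zscored = TRUE)
  M <- evaluate_progression(theta, basis)
  naive <- 0
  for (n in 1:10) {
    naive <- naive - max(observation_loglik(X[n, ], M, g))
  }
  expect_equal(total_loss(d, theta, basis, g, 0), naive, tolerance = 1e-10)

  # linear in lambda with slope sum|theta|
  delta <- 0.37
  expect_equal(total_loss(d, theta, basis, g, 0.1 + delta) -
                 total_loss(d, theta, basis, g, 0.1),
               delta * sum(abs(theta)), tolerance = 1e-10)
})
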