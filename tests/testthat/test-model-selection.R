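test_that("stage-distribution metric is the population sd of stage counts", {
  asg <- data.frame(subtype = 1L, stage = c(0, 1, 2, 3))
  expect_equal(metric_stage_distribution(asg, K = 3), 0)

  asg2 <- data.frame(subtype = 1L, stage = rep(0L, 10))
  expect_equal(metric_stage_distribution(asg2, K = 1), 5)

  # hand-tallied 7-record toy: counts (2, 1, 3, 1) over stages 0..3
  asg3 <- data.frame(subtype = 1L, stage = c(0, 0, 1, 2, 2, 2, 3))
  counts <- c(2, 1, 3, 1)
  expect_equal(metric_stage_distribution(asg3, K = 3),
               sqrt(sum((counts - mean(counts))^2) / 4), tolerance = 1e-12)
})

test_that("evaluation distance averages pairwise centroid distances", {
  M_same <- array(1.5, dim = c(4, 3, 2))
  expect_equal(metric_evaluation_distance(M_same), 0)
  expect_equal(metric_evaluation_distance(array(rnorm(12), dim = c(4, 3, 1))),
               0)  # single subtype convention

  # rows differing by a constant vector of norm c at every stage
  v <- c(3, 4)                       # norm 5
  M <- array(0, dim = c(6, 2, 2))
  M[, , 1] <- matrix(rnorm(12), 6, 2)
  M[, , 2] <- M[, , 1] + matrix(v, 6, 2, byrow = TRUE)
  expect_equal(metric_evaluation_distance(M), 5, tolerance = 1e-12)
})

test_that("silhouette matches a brute-force per-record scan", {
  set.seed(50)
  theta <- array(runif(2 * 2 * 2, -2, 2), dim = c(2, 2, 2))
  model <- make_model(theta, K = 4)
  M <- evaluate_progression(theta, model$basis)
  X <- matrix(rnorm(5 * 2), 5, 2)
  d <- data_matrix(X, feature_names = model$feature_names, zscored = TRUE)
  asg <- predict(model, d)

  sil <- numeric(5)
  for (n in 1:5) {
    s_own <- asg$subtype[n]
    a <- sqrt(sum((X[n, ] - M[asg$stage[n] + 1, , s_own])^2))
    b <- Inf
    for (s in setdiff(1:2, s_own)) for (k in 0:4) {
      b <- min(b, sqrt(sum((X[n, ] - M[k + 1, , s])^2)))
    }
    sil[n] <- (b - a) / max(a, b)
  }
  expect_equal(metric_silhouette(d, M, asg), mean(sil), tolerance = 1e-12)

  # record exactly at its centroid scores 1
  d1 <- data_matrix(matrix(M[3, , 1], 1, 2),
                    feature_names = model$feature_names, zscored = TRUE)
  a1 <- predict(model, d1)
  expect_equal(metric_silhouette(d1, M, a1), 1)

  # identical subtype curves score 0 everywhere (the nearest centroid of
  # the other subtype coincides with the assigned one)
  theta_id <- theta
  theta_id[, , 2] <- theta_id[, , 1]
  model_id <- make_model(theta_id, K = 4)
  M_id <- evaluate_progression(theta_id, model_id$basis)
  expect_equal(metric_silhouette(d, M_id, predict(model_id, d)), 0)

  # undefined for a single-subtype model
  expect_true(is.na(metric_silhouette(d, M[, , 1, drop = FALSE], asg)))
})

test_that("correlation comparison tracks model-implied covariance", {
  # zero-noise data spread over stages correlates near 1
  p <- generator_params(noise_min = 1e-9, noise_max = 1e-9,
                        n_subtypes = 2, n_polynomials = 8,
                        subtype_class_imbalance_index = 0,
                        record_count = 300, seed = 51)
  tr <- generate_truth(p)
  d <- sample_dataset(tr)
  model <- make_model(tr$theta_true, K = 10)
  M <- evaluate_progression(tr$theta_true, model$basis)
  asg <- predict(model, d)
  cc <- metric_correlation_comparison(d, M, asg)
  expect_gt(cc, 0.9)

  # permuting feature order leaves the metric unchanged
  perm <- sample(8)
  d_p <- data_matrix(d$X[, perm], feature_names = d$feature_names[perm],
                     zscored = TRUE)
  expect_equal(metric_correlation_comparison(d_p, M[, perm, , drop = FALSE],
                                             asg),
               cc, tolerance = 1e-10)

  # subtypes with too few records or degenerate covariance are skipped
  asg_one <- asg
  asg_one$subtype <- 1L
  expect_true(is.na(metric_correlation_comparison(
    d, M, transform(asg_one, subtype = 2L), min_records = nrow(d$X) + 1)))
})

test_that("AIC is parameter count minus twice the dataset log-likelihood", {
  d <- data_matrix(matrix(0, 1, 1), zscored = TRUE)
  model <- make_model(array(0, dim = c(1, 1, 1)), K = 5)
  expect_equal(metric_aic(model, d), 2 * 1 - 2 * (-0.9189385),
               tolerance = 1e-6)

  # agrees with the loss at lambda = 0 on a 3-record toy
  set.seed(52)
  theta <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2))
  m2 <- make_model(theta, K = 6)
  d2 <- data_matrix(matrix(rnorm(6), 3, 2),
                    feature_names = m2$feature_names, zscored = TRUE)
  loglik <- -total_loss(d2, theta, m2$basis, gaussian_constants(1), 0)
  expect_equal(metric_aic(m2, d2), 2 * 8 - 2 * loglik, tolerance = 1e-10)

  # doubling S at identical log-likelihood adds 2 * D * P * S parameters
  theta4 <- array(0, dim = c(2, 2, 4))
  theta4[, , 1:2] <- theta
  theta4[, , 3:4] <- theta
  m4 <- make_model(theta4, K = 6)
  expect_equal(metric_aic(m4, d2) - metric_aic(m2, d2), 2 * 8,
               tolerance = 1e-10)
})

test_that("Euclidean R-squared matches a scalar-loop oracle", {
  set.seed(53)
  theta <- array(runif(1 * 2 * 1, 1, 2), dim = c(1, 2, 1))
  model <- make_model(theta, K = 3)
  M <- evaluate_progression(theta, model$basis)
  X <- matrix(rnorm(8), 4, 2)
  d <- data_matrix(X, feature_names = model$feature_names, zscored = TRUE)
  asg <- predict(model, d)

  ss_res <- 0
  for (n in 1:4) {
    mu <- M[asg$stage[n] + 1, , 1]
    ss_res <- ss_res + sum((X[n, ] - mu)^2)
  }
  ss_tot <- sum(sweep(X, 2, colMeans(X))^2)
  expect_equal(metric_euclidean_r2(d, M, asg), 1 - ss_res / ss_tot,
               tolerance = 1e-12)

  # exact centroids give 1
  Xc <- M[c(1, 3, 4), , 1]
  dc <- data_matrix(Xc, feature_names = model$feature_names, zscored = TRUE)
  ac <- predict(model, dc)
  expect_equal(metric_euclidean_r2(dc, M, ac), 1)

  # a model predicting the global mean everywhere gives 0
  Mbar <- array(rep(colMeans(X), each = 4), dim = c(4, 2, 1))
  expect_equal(metric_euclidean_r2(d, Mbar, asg), 0, tolerance = 1e-12)
})

test_that("sweep grid has one row per order, subtype count and fold", {
  p <- generator_params(n_polynomials = 4, record_count = 60, seed = 54)
  d <- sample_dataset(generate_truth(p))
  cheap <- fit_config(K = 6, iterations = 40, seed = 1)
  sw <- run_sweep(d, orders = 2, subtype_counts = 2, folds = 2,
                  config = cheap, seed = 9)
  expect_equal(nrow(sw), 2)
  expect_setequal(sw$fold, 1:2)
  expect_true(all(c("stage_distribution", "evaluation_distance",
                    "silhouette", "correlation_comparison", "aic",
                    "euclidean_r2", "train_loss") %in% names(sw)))
  # single-subtype rows carry the S = 1 conventions
  sw1 <- run_sweep(d, orders = 1, subtype_counts = 1, folds = 2,
                   config = cheap, seed = 9)
  expect_equal(sw1$evaluation_distance, c(0, 0))
  expect_true(all(is.na(sw1$silhouette)))
  expect_error(run_sweep(subset_records(d, 1:3), folds = 10,
                         config = cheap), "folds")
})
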