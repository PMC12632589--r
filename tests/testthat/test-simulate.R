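test_that("Atkinson index follows its closed form", {
  expect_equal(atkinson_index(rep(0.25, 4)), 0)
  expect_equal(atkinson_index(c(0.5, 0.5)), 0)
  expect_equal(atkinson_index(c(0.9, 0.1)), 1 - sqrt(0.09) / 0.5,
               tolerance = 1e-12)  # = 0.4
  set.seed(20)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1)); p <- p / sum(p)
    idx <- atkinson_index(p)
    expect_true(idx >= 0 && idx < 1)
  }
  expect_error(atkinson_index(c(0.5, 0.5, 0)), "positive")
  expect_error(atkinson_index(c(0.7, 0.7)), "sum")
})

test_that("proportion targeting round-trips through the index", {
  expect_equal(proportions_for_target(4, 0), rep(0.25, 4))
  for (n in 2:6) for (target in c(0.05, 0.1, 0.2)) {
    p <- proportions_for_target(n, target)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(atkinson_index(p), target, tolerance = 1e-6)
  }
  expect_error(proportions_for_target(1, 0.1), "n_classes")
  expect_error(proportions_for_target(3, 1), "achievable")
})

test_that("ground truth generation is seeded and structurally valid", {
  params <- generator_params(seed = 31)
  t1 <- generate_truth(params)
  t2 <- generate_truth(params)
  expect_identical(t1$theta_true, t2$theta_true)
  expect_identical(t1$record_stage, t2$record_stage)

  expect_true(all(t1$record_stage >= 0 & t1$record_stage <= 1))
  expect_true(all(t1$record_subtype %in% seq_len(params$n_subtypes)))
  expect_equal(dim(t1$theta_true),
               c(params$dimensions, params$n_polynomials,
                 params$n_subtypes))

  # realized cluster sizes reach the imbalance target
  sizes <- table(t1$cluster_assignment)
  expect_lt(abs(atkinson_index(as.numeric(sizes) / sum(sizes)) -
                  params$polydist_imbalance_index), 0.05)

  expect_error(generator_params(n_polynomials = 3, n_clusters = 5),
               "n_clusters")
})

test_that("shared clusters produce less separated subtypes", {
  p_ind <- generator_params(seed = 77, shared_clusters = FALSE)
  p_sh <- generator_params(seed = 77, shared_clusters = TRUE)
  sep <- function(truth) {
    mean(abs(truth$theta_true[, , 1] - truth$theta_true[, , 2]))
  }
  expect_lt(sep(generate_truth(p_sh)), sep(generate_truth(p_ind)))
})

test_that("sampled datasets follow the polynomial surface plus noise", {
  # zero-noise limit: records lie exactly on the surface
  p0 <- generator_params(noise_min = 1e-12, noise_max = 1e-12,
                         n_subtypes = 1, n_polynomials = 6,
                         record_count = 50, seed = 41)
  tr0 <- generate_truth(p0)
  d0 <- sample_dataset(tr0)
  V <- outer(tr0$record_stage, seq_len(p0$dimensions), `^`)
  exact <- V %*% matrix(tr0$theta_true[, , 1], p0$dimensions,
                        p0$n_polynomials)
  expect_equal(d0$X, exact, tolerance = 1e-9)
  expect_true(d0$zscored)

  # a record at stage 0 with zero noise has all-zero features
  tr0$record_stage[1] <- 0
  d00 <- sample_dataset(tr0)
  expect_equal(unname(d00$X[1, ]), rep(0, 6), tolerance = 1e-9)

  # empirical residual sd per feature matches the noise coefficient
  pn <- generator_params(n_subtypes = 1, n_polynomials = 4,
                         record_count = 10000, seed = 42)
  trn <- generate_truth(pn)
  dn <- sample_dataset(trn)
  Vn <- outer(trn$record_stage, seq_len(pn$dimensions), `^`)
  resid <- dn$X - Vn %*% matrix(trn$theta_true[, , 1], pn$dimensions, 4)
  expect_equal(unname(apply(resid, 2, sd)), trn$noise_coefficients,
               tolerance = 0.05)

  # determinism of the sampling stage
  expect_identical(sample_dataset(trn)$X, dn$X)
})

test_that("class-imbalance targeting shapes realized subtype counts", {
  p <- generator_params(n_subtypes = 3, record_count = 600,
                        subtype_class_imbalance_index = 0.15, seed = 43)
  tr <- generate_truth(p)
  prop <- as.numeric(table(tr$record_subtype)) / 600
  expect_equal(atkinson_index(prop), 0.15, tolerance = 0.02)

  p0 <- generator_params(n_subtypes = 2, record_count = 500,
                         subtype_class_imbalance_index = 0, seed = 44)
  expect_equal(as.numeric(table(generate_truth(p0)$record_subtype)),
               c(250, 250))
})
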