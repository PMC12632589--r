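# Small in-code fixtures shared across tests.

# A model object built directly from a known coefficient tensor, without
# fitting. theta: D x P x S array.
make_model <- function(theta, K, sigma = 1, feature_names = NULL) {
  d <- dim(theta)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d[2]))
  cfg <- fit_config(K = K, D = d[1], S = d[3], sigma = sigma)
  structure(
    list(theta = theta, config = cfg, feature_names = feature_names,
         basis = build_basis(K, d[1]), final_loss = NA_real_,
         loss_history = NULL),
    class = "ppsi_model"
  )
}

# Noiseless dataset whose records sit exactly on the stage centroids of a
# known single-subtype model; returns data, true theta and true stages.
make_centroid_dataset <- function(K = 5, D = 2, P = 5, per_stage = 30,
                                  coef_range = 2, seed = 7) {
  set.seed(seed)
  theta_true <- array(runif(D * P, -coef_range, coef_range), dim = c(D, P, 1))
  basis <- build_basis(K, D)
  M <- evaluate_progression(theta_true, basis)
  stages <- rep(0:K, each = per_stage)
  X <- matrix(M[stages + 1, , 1], ncol = P)
  list(data = data_matrix(X, zscored = TRUE), theta = theta_true,
       stages = stages, basis = basis)
}

# Easy-regime simulated cohort: well separated subtypes, low noise.
make_easy_cohort <- function(seed, n_subtypes = 2, dimensions = 2,
                             n_polynomials = 20, record_count = 500,
                             noise_min = 0.2, noise_max = 0.4) {
  params <- generator_params(
    noise_min = noise_min, noise_max = noise_max,
    n_subtypes = n_subtypes, dimensions = dimensions,
    n_polynomials = n_polynomials,
    subtype_class_imbalance_index = 0,
    record_count = record_count, seed = seed)
  truth <- generate_truth(params)
  list(truth = truth, data = sample_dataset(truth))
}
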