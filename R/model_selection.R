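#' Stage-distribution metric
#'
#' Standard deviation (population form, denominator `K + 1`) of the number
#' of records assigned to each of the `K + 1` stages. Quantifies how evenly
#' the data spread across the inferred progression; lower is better.
#'
#' @param assignments Assignment data frame from [predict.ppsi_model()].
#' @param K Integer, number of non-zero stages.
#' @return A nonnegative number.
#' @export
metric_stage_distribution <- function(assignments, K) {
  stopifnot(nrow(assignments) > 0L)
  counts <- tabulate(assignments$stage + 1L, nbins = K + 1L)
  sqrt(mean((counts - mean(counts))^2))
}

#' Evaluation-distance metric
#'
#' Mean over unordered subtype pairs of the mean Euclidean distance between
#' the two subtypes' stage centroids (corresponding rows of their
#' evaluation matrices). Higher means more differentiated subtype curves;
#' 0 by convention for a single-subtype model.
#'
#' @param M Evaluation tensor from [evaluate_progression()].
#' @return A nonnegative number.
#' @export
metric_evaluation_distance <- function(M) {
  S <- dim(M)[3]
  if (S < 2L) return(0)
  Kp1 <- dim(M)[1]; P <- dim(M)[2]
  pairs <- utils::combn(S, 2L)
  d <- apply(pairs, 2L, function(pr) {
    diff <- matrix(M[, , pr[1]] - M[, , pr[2]], Kp1, P)
    mean(sqrt(rowSums(diff^2)))
  })
  mean(d)
}

#' Subtype silhouette metric
#'
#' For each record, `a` is its Euclidean distance to its assigned stage
#' centroid and `b` the minimum distance to any stage centroid of another
#' subtype; the silhouette is `(b - a) / max(a, b)` and the metric its mean
#' over records. Undefined for a single-subtype model, where `NA` is
#' returned.
#'
#' @param data A [data_matrix()] object.
#' @param M Evaluation tensor.
#' @param assignments Assignment data frame aligned with `data`.
#' @return A number in `[-1, 1]`, or `NA` when `S = 1`.
#' @export
metric_silhouette <- function(data, M, assignments) {
  S <- dim(M)[3]
  if (S < 2L) return(NA_real_)
  Kp1 <- dim(M)[1]; P <- dim(M)[2]
  X <- data$X
  N <- nrow(X)
  x2 <- rowSums(X^2)
  # distances to every centroid of every subtype: N x (K+1) per subtype
  dist_s <- lapply(seq_len(S), function(s) {
    Ms <- matrix(M[, , s], Kp1, P)
    d2 <- outer(x2, rowSums(Ms^2), `+`) - 2 * (X %*% t(Ms))
    sqrt(pmax(d2, 0))
  })
  a <- vapply(seq_len(N), function(n) {
    dist_s[[assignments$subtype[n]]][n, assignments$stage[n] + 1L]
  }, numeric(1))
  b <- vapply(seq_len(N), function(n) {
    min(vapply(setdiff(seq_len(S), assignments$subtype[n]),
               function(s) min(dist_s[[s]][n, ]), numeric(1)))
  }, numeric(1))
  sil <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  mean(sil)
}

#' Correlation-comparison metric
#'
#' Per subtype with at least `min_records` assigned records: the Pearson
#' correlation between the upper triangle (including the diagonal) of the
#' feature covariance matrix of the subtype's records and the same
#' triangle of the covariance of the subtype's stage-centroid rows. A
#' model whose curves move through feature space the way the data do
#' scores near 1. Subtypes with degenerate (zero-variance) covariances are
#' skipped; `NA` is returned when no subtype qualifies.
#'
#' @param data A [data_matrix()] object.
#' @param M Evaluation tensor.
#' @param assignments Assignment data frame aligned with `data`.
#' @param min_records Minimum records per subtype for inclusion (default 3).
#' @return Mean correlation over qualifying subtypes, or `NA`.
#' @export
metric_correlation_comparison <- function(data, M, assignments,
                                          min_records = 3L) {
  S <- dim(M)[3]
  Kp1 <- dim(M)[1]; P <- dim(M)[2]
  ut <- upper.tri(diag(P), diag = TRUE)
  vals <- numeric(0)
  for (s in seq_len(S)) {
    rows <- which(assignments$subtype == s)
    if (length(rows) < min_records) next
    cov_data <- stats::cov(data$X[rows, , drop = FALSE])[ut]
    cov_model <- stats::cov(matrix(M[, , s], Kp1, P))[ut]
    if (stats::sd(cov_data) == 0 || stats::sd(cov_model) == 0) next
    vals <- c(vals, stats::cor(cov_data, cov_model))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Akaike information criterion of a fitted model on a dataset
#'
#' The standard definition, `2 * (D * P * S) - 2 * logLik`, where the
#' trainable parameter count is the cardinality of the coefficient tensor
#' and the log-likelihood is the sum over records of each record's maximal
#' stage/subtype log-likelihood.
#'
#' @param model A fitted [fit_ppsi()] model.
#' @param data A [data_matrix()] object.
#' @return A number; lower is better.
#' @export
metric_aic <- function(model, data) {
  stopifnot(inherits(model, "ppsi_model"), inherits(data, "ppsi_data"))
  d <- dim(model$theta)
  n_par <- prod(d)
  constants <- gaussian_constants(model$config$sigma)
  M <- evaluate_progression(model$theta, model$basis)
  a <- assign_block(data$X, M, constants)
  2 * n_par - 2 * sum(a$loglik)
}

#' Euclidean R-squared metric
#'
#' One minus the ratio of the summed squared Euclidean distances from each
#' record to its assigned stage centroid over the summed squared distances
#' to the per-feature mean vector - the multivariate analogue of the usual
#' coefficient of determination. Returns `NA` when the total sum of
#' squares is zero.
#'
#' @param data A [data_matrix()] object.
#' @param M Evaluation tensor.
#' @param assignments Assignment data frame aligned with `data`.
#' @return A number at most 1, or `NA`.
#' @export
metric_euclidean_r2 <- function(data, M, assignments) {
  X <- data$X
  stopifnot(nrow(X) >= 2L)
  Kp1 <- dim(M)[1]; P <- dim(M)[2]
  tmp <- vapply(seq_len(nrow(X)), function(n) {
    matrix(M[, , assignments$subtype[n]], Kp1, P)[assignments$stage[n] + 1L, ]
  }, numeric(P))
  mu <- if (P == 1L) matrix(tmp, ncol = 1L) else t(tmp)
  ss_res <- sum((X - mu)^2)
  xbar <- colMeans(X)
  ss_tot <- sum(sweep(X, 2L, xbar)^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Cross-validated subtype sweep
#'
#' Fits a grid of models over polynomial orders and subtype counts, one
#' model per cross-validation fold (records partitioned once from the
#' sweep seed), and reports the six model-selection metrics computed on
#' each model's held-out fold, plus the training loss. With the defaults -
#' orders 1:3, subtype counts 1:4, 10 folds - exactly 120 models are
#' fitted. The sweep makes no automatic choice: the metric table (usually
#' viewed as boxplots, see [plot_suite()]) supports a holistic, human
#' selection of order and subtype count.
#'
#' @param data A [data_matrix()] object.
#' @param orders Integer vector of polynomial orders to evaluate.
#' @param subtype_counts Integer vector of subtype counts to evaluate.
#' @param folds Integer number of cross-validation folds (>= 2).
#' @param config A [fit_config()] template; its `D`, `S` and `seed` are
#'   overridden per grid cell.
#' @param seed Integer seed for the fold partition and per-fit seeds.
#' @return A data frame of class `ppsi_sweep`, one row per
#'   (order, subtype count, fold): columns `order`, `subtypes`, `fold`,
#'   `stage_distribution`, `evaluation_distance`, `silhouette`,
#'   `correlation_comparison`, `aic`, `euclidean_r2`, `train_loss`.
#' @export
run_sweep <- function(data, orders = 1:3, subtype_counts = 1:4,
                      folds = 10L, config = fit_config(), seed = 1L) {
  stopifnot(inherits(data, "ppsi_data"), folds >= 2L)
  N <- nrow(data$X)
  if (N < folds) stop("need at least `folds` records", call. = FALSE)

  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), N))

  grid <- expand.grid(fold = seq_len(folds), subtypes = subtype_counts,
                      order = orders, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    D <- grid$order[i]; S <- grid$subtypes[i]; f <- grid$fold[i]
    cfg <- config
    cfg$D <- as.integer(D); cfg$S <- as.integer(S)
    cfg$seed <- as.integer((seed + i * 101L) %% .Machine$integer.max)
    train <- subset_records(data, fold_id != f)
    test <- subset_records(data, fold_id == f)
    model <- fit_ppsi(train, cfg)
    M <- evaluate_progression(model$theta, model$basis)
    asg <- stats::predict(model, test)
    rows[[i]] <- data.frame(
      order = D, subtypes = S, fold = f,
      stage_distribution = metric_stage_distribution(asg, cfg$K),
      evaluation_distance = metric_evaluation_distance(M),
      silhouette = metric_silhouette(test, M, asg),
      correlation_comparison = metric_correlation_comparison(test, M, asg),
      aic = metric_aic(model, test),
      euclidean_r2 = metric_euclidean_r2(test, M, asg),
      train_loss = model$final_loss)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ppsi_sweep", "data.frame")
  out
}
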