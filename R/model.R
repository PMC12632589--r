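#' Evaluate all subtype feature polynomials at every stage
#'
#' Computes the evaluation tensor `M` with `M[, , s] = T %*% Theta_s`: the
#' expected (mean) value of every feature at every stage for every subtype.
#' Row `k + 1` of `M[, , s]` is the subtype-`s` stage-`k` cluster centroid
#' in feature space. The first row (stage 0) is always zero because the
#' basis has no constant term.
#'
#' @param theta Numeric array `D x P x S` of polynomial coefficients.
#' @param basis A [build_basis()] object whose `D` matches `dim(theta)[1]`.
#' @return Numeric array `(K+1) x P x S`.
#' @export
evaluate_progression <- function(theta, basis) {
  stopifnot(inherits(basis, "ppsi_basis"))
  theta <- as_theta(theta)
  d <- dim(theta)
  if (d[1] != basis$D) {
    stop(sprintf("degree mismatch: theta has D = %d but basis has D = %d",
                 d[1], basis$D), call. = FALSE)
  }
  K <- basis$K
  M <- array(0, dim = c(K + 1L, d[2], d[3]))
  for (s in seq_len(d[3])) {
    M[, , s] <- basis$T %*% matrix(theta[, , s], d[1], d[2])
  }
  M
}

# coerce/validate a coefficient tensor
as_theta <- function(theta) {
  if (is.matrix(theta)) theta <- array(theta, dim = c(dim(theta), 1L))
  if (!is.array(theta) || length(dim(theta)) != 3L || !is.numeric(theta)) {
    stop("`theta` must be a numeric D x P x S array", call. = FALSE)
  }
  if (any(!is.finite(theta))) {
    stop("`theta` contains non-finite entries", call. = FALSE)
  }
  theta
}

#' Stage/subtype log-likelihood matrix for one observation
#'
#' Entry `(s, k+1)` is the log-likelihood of the observation under the
#' Gaussian stage-cluster of subtype `s` at stage `k`: the sum over
#' features of the fixed-sigma log-density [log_pdf()] centred on the
#' evaluated polynomial mean. Working in the log domain replaces the
#' cumulative product over features with a sum and avoids underflow.
#'
#' @param x_n Numeric vector of length `P`, one observation row.
#' @param M Evaluation tensor from [evaluate_progression()].
#' @param constants A [gaussian_constants()] object.
#' @return Numeric matrix `S x (K+1)` of finite log-likelihoods.
#' @export
observation_loglik <- function(x_n, M, constants) {
  stopifnot(is.array(M), length(dim(M)) == 3L)
  P <- dim(M)[2]
  if (length(x_n) != P) {
    stop(sprintf("observation has %d values but model expects %d features",
                 length(x_n), P), call. = FALSE)
  }
  S <- dim(M)[3]
  Kp1 <- dim(M)[1]
  phi <- matrix(NA_real_, S, Kp1)
  for (s in seq_len(S)) {
    Ms <- matrix(M[, , s], Kp1, P)
    d2 <- rowSums((Ms - matrix(x_n, Kp1, P, byrow = TRUE))^2)
    phi[s, ] <- P * constants$log_alpha - d2 / constants$beta
  }
  phi
}

#' Maximum-likelihood subtype and stage for one observation
#'
#' Returns the `(subtype, stage)` cell maximizing the observation's
#' log-likelihood matrix. Ties are broken toward the lowest stage index and
#' then the lowest subtype index, deterministically biasing ambiguous
#' records toward the less-progressed interpretation.
#'
#' @param phi Numeric `S x (K+1)` log-likelihood matrix
#'   (see [observation_loglik()]).
#' @return A list with `subtype` (1-based), `stage` (0-based) and `loglik`,
#'   the maximal entry.
#' @export
assign_observation <- function(phi) {
  if (!is.matrix(phi) || any(!is.finite(phi))) {
    stop("`phi` must be a finite numeric matrix", call. = FALSE)
  }
  hits <- which(phi == max(phi), arr.ind = TRUE)
  ord <- order(hits[, "col"], hits[, "row"])
  best <- hits[ord[1L], ]
  list(subtype = unname(best["row"]),
       stage = unname(best["col"]) - 1L,
       loglik = max(phi))
}

# Batched log-likelihoods for all records. Returns an N x (S*(K+1)) matrix
# whose column j corresponds to stage k = (j-1) %/% S and subtype
# s = (j-1) %% S + 1 (stage-major order so that max.col(ties = "first")
# realizes the lowest-stage-then-lowest-subtype tie-break).
loglik_block <- function(X, M, constants) {
  N <- nrow(X)
  P <- ncol(X)
  Kp1 <- dim(M)[1]
  S <- dim(M)[3]
  out <- matrix(NA_real_, N, S * Kp1)
  x2 <- rowSums(X^2)
  base <- P * constants$log_alpha
  for (s in seq_len(S)) {
    Ms <- matrix(M[, , s], Kp1, P)
    m2 <- rowSums(Ms^2)
    cross <- X %*% t(Ms)                       # N x (K+1)
    d2 <- outer(x2, m2, `+`) - 2 * cross
    out[, s + S * (0:(Kp1 - 1L))] <- base - d2 / constants$beta
  }
  out
}

# Hard assignment for all records: list(subtype, stage, loglik), vectorized.
assign_block <- function(X, M, constants) {
  S <- dim(M)[3]
  phi <- loglik_block(X, M, constants)
  j <- max.col(phi, ties.method = "first")
  list(subtype = (j - 1L) %% S + 1L,
       stage = (j - 1L) %/% S,
       loglik = phi[cbind(seq_len(nrow(phi)), j)])
}

#' Regularized negative log-likelihood of a dataset
#'
#' The training loss: the negative of the dataset log-likelihood (the sum
#' over records of each record's maximal stage/subtype log-likelihood) plus
#' `l1_penalty` times the sum of absolute coefficient values.
#'
#' @param data A [data_matrix()] object.
#' @param theta Numeric `D x P x S` coefficient array.
#' @param basis A [build_basis()] object.
#' @param constants A [gaussian_constants()] object.
#' @param l1_penalty Nonnegative real, the L1 weight lambda.
#' @return A single number.
#' @export
total_loss <- function(data, theta, basis, constants, l1_penalty = 0) {
  stopifnot(inherits(data, "ppsi_data"), l1_penalty >= 0)
  theta <- as_theta(theta)
  if (dim(theta)[2] != ncol(data$X)) {
    stop(sprintf("theta covers %d features but data has %d",
                 dim(theta)[2], ncol(data$X)), call. = FALSE)
  }
  M <- evaluate_progression(theta, basis)
  a <- assign_block(data$X, M, constants)
  -sum(a$loglik) + l1_penalty * sum(abs(theta))
}

#' Training configuration
#'
#' Hyperparameters of the gradient-descent fit. Defaults: `K = 15` stages
#' (the middle of the commonly swept 10/15/20 range), fixed `sigma = 1` on
#' the z-score scale, L1 penalty 0.05, scheduled maximum learning rate 0.1
#' (higher maxima improve both staging and subtyping), 2000 iterations,
#' minibatch fraction 0.2.
#'
#' @param K Integer, number of non-zero stages.
#' @param D Integer, polynomial order.
#' @param S Integer, number of subtypes.
#' @param sigma Positive real, fixed cluster standard deviation.
#' @param l1_penalty Nonnegative real, L1 weight lambda.
#' @param max_lr Positive real, maximum scheduled learning rate eta.
#' @param iterations Positive integer, gradient steps.
#' @param minibatch_fraction Real in (0, 1], fraction of records per step.
#' @param seed Integer seed controlling initialization and batch sampling.
#' @return An object of class `ppsi_config`.
#' @export
fit_config <- function(K = 15L, D = 2L, S = 2L, sigma = 1.0,
                       l1_penalty = 0.05, max_lr = 0.1, iterations = 2000L,
                       minibatch_fraction = 0.2, seed = 1L) {
  stopifnot(is_count(K), is_count(D), is_count(S), is_count(iterations))
  if (!(sigma > 0)) stop("`sigma` must be positive", call. = FALSE)
  if (l1_penalty < 0) stop("`l1_penalty` must be nonnegative", call. = FALSE)
  if (!(max_lr > 0)) stop("`max_lr` must be positive", call. = FALSE)
  if (!(minibatch_fraction > 0 && minibatch_fraction <= 1)) {
    stop("`minibatch_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(K = as.integer(K), D = as.integer(D), S = as.integer(S),
         sigma = sigma, l1_penalty = l1_penalty, max_lr = max_lr,
         iterations = as.integer(iterations),
         minibatch_fraction = minibatch_fraction, seed = as.integer(seed)),
    class = "ppsi_config"
  )
}

# learning-rate schedule: linear warmup over the first 10% of iterations to
# max_lr, then cosine annealing down to 1% of max_lr.
lr_schedule <- function(i, iterations, max_lr) {
  warm <- max(1L, floor(0.1 * iterations))
  if (i <= warm) return(max_lr * i / warm)
  min_lr <- 0.01 * max_lr
  span <- max(1L, iterations - warm)
  min_lr + 0.5 * (max_lr - min_lr) * (1 + cos(pi * (i - warm) / span))
}

#' Fit a polynomial progression model
#'
#' Trains the coefficient tensor by minibatch gradient descent on the
#' regularized hard-assignment negative log-likelihood. Each iteration: a
#' minibatch of `ceiling(minibatch_fraction * N)` records is sampled
#' without replacement; every batch record is assigned to its current
#' maximum-likelihood (subtype, stage) cell; the gradient flows only
#' through each record's assigned cell (a hard-assignment subgradient, as
#' in k-means / hard EM), with the likelihood term rescaled by `N / batch`
#' so the L1 balance is batch-size invariant; the step is taken with
#' adaptive moment estimation (decay 0.9 / 0.999, eps 1e-8) under a linear
#' warmup + cosine annealing learning-rate schedule. Coefficients are
#' initialized from N(0, 0.1) draws, which respects the zero-intercept
#' prior while breaking subtype symmetry. Deterministic given
#' `config$seed`.
#'
#' @param data A [data_matrix()] object (warned about when not flagged as
#'   z-scored).
#' @param config A [fit_config()] object.
#' @return An object of class `ppsi_model`: list with `theta`, `config`,
#'   `feature_names`, `basis`, `final_loss` (full-data loss at the fitted
#'   coefficients) and `loss_history` (one minibatch-scaled loss per
#'   iteration).
#' @export
fit_ppsi <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "ppsi_data"), inherits(config, "ppsi_config"))
  if (!data$zscored) {
    warning("input data is not flagged as z-scored; the model assumes ",
            "features on the normative z-score scale", call. = FALSE)
  }
  X <- data$X
  N <- nrow(X)
  P <- ncol(X)
  D <- config$D
  S <- config$S
  basis <- build_basis(config$K, D)
  constants <- gaussian_constants(config$sigma)
  lambda <- config$l1_penalty
  B <- ceiling(config$minibatch_fraction * N)

  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  theta <- array(stats::rnorm(D * P * S, 0, 0.1), dim = c(D, P, S))
  m1 <- m2 <- array(0, dim = c(D, P, S))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(config$iterations)
  scale <- N / B

  for (i in seq_len(config$iterations)) {
    idx <- if (B < N) sample.int(N, B) else seq_len(N)
    Xb <- X[idx, , drop = FALSE]
    M <- evaluate_progression(theta, basis)
    a <- assign_block(Xb, M, constants)
    loss_i <- -sum(a$loglik) * scale + lambda * sum(abs(theta))
    if (!is.finite(loss_i)) {
      stop(sprintf("non-finite loss at iteration %d; try a smaller learning rate", i),
           call. = FALSE)
    }
    loss_history[i] <- loss_i

    G <- array(0, dim = c(D, P, S))
    for (s in seq_len(S)) {
      rows <- which(a$subtype == s)
      if (length(rows) == 0L) next
      k1 <- a$stage[rows] + 1L
      Ms <- matrix(M[, , s], basis$K + 1L, P)
      resid <- Xb[rows, , drop = FALSE] - Ms[k1, , drop = FALSE]
      Tk <- basis$T[k1, , drop = FALSE]
      G[, , s] <- -(2 / constants$beta) * scale * crossprod(Tk, resid)
    }
    G <- G + lambda * sign(theta)

    lr <- lr_schedule(i, config$iterations, config$max_lr)
    m1 <- b1 * m1 + (1 - b1) * G
    m2 <- b2 * m2 + (1 - b2) * G^2
    mhat <- m1 / (1 - b1^i)
    vhat <- m2 / (1 - b2^i)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  }

  final_loss <- total_loss(data, theta, basis, constants, lambda)
  structure(
    list(theta = theta, config = config, feature_names = data$feature_names,
         basis = basis, final_loss = final_loss,
         loss_history = loss_history),
    class = "ppsi_model"
  )
}

#' @export
print.ppsi_model <- function(x, ...) {
  cat(sprintf(
    "<ppsi_model> S = %d subtypes, order D = %d, K = %d stages, P = %d features\n  final loss %.4f\n",
    x$config$S, x$config$D, x$config$K, length(x$feature_names),
    x$final_loss))
  invisible(x)
}

#' Assign every record to its maximum-likelihood subtype and stage
#'
#' @param object A fitted [fit_ppsi()] model.
#' @param data A [data_matrix()] whose features match the model's, in order.
#' @param ... Unused.
#' @return A data frame with one row per record: `record_id`, `subtype`
#'   (1-based), `stage` (0-based) and `loglik`.
#' @export
predict.ppsi_model <- function(object, data, ...) {
  stopifnot(inherits(data, "ppsi_data"))
  if (!identical(data$feature_names, object$feature_names)) {
    missing_f <- setdiff(object$feature_names, data$feature_names)
    extra_f <- setdiff(data$feature_names, object$feature_names)
    stop(sprintf(
      "feature mismatch between model and data: missing [%s], extra [%s] (order must match)",
      paste(missing_f, collapse = ", "), paste(extra_f, collapse = ", ")),
      call. = FALSE)
  }
  constants <- gaussian_constants(object$config$sigma)
  M <- evaluate_progression(object$theta, object$basis)
  a <- assign_block(data$X, M, constants)
  data.frame(record_id = data$record_ids, subtype = a$subtype,
             stage = a$stage, loglik = a$loglik,
             stringsAsFactors = FALSE)
}

# Snapshot the global RNG state (NULL if none). Pair with restore_seed() in
# an on.exit() so seeded functions do not disturb the caller's RNG stream.
snapshot_seed <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
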