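#' Fit a normative confounder model on a control sample
#'
#' For each progression feature, fits an ordinary least squares model of
#' the feature on the confounders (plus intercept) within the control
#' sample, and records the standard deviation of the residuals
#' (denominator `C - Q - 1`). Z-scoring an observation then expresses it
#' as standard deviations away from the value the control model predicts
#' for its confounder values. Categorical confounders must be numerically
#' encoded by the caller. Control rows with missing confounder values are
#' dropped with a message.
#'
#' @param controls Numeric matrix or data frame `C x P` of control-sample
#'   feature values.
#' @param confounders Numeric matrix or data frame `C x Q` of confounder
#'   values, or `NULL` for an intercept-only (mean/sd) model.
#' @return An object of class `ppsi_normative`: list with `coefficients`
#'   (`(Q+1) x P`, intercept row first), `residual_std` (length `P`),
#'   `confounder_names` and `feature_names`.
#' @export
fit_normative <- function(controls, confounders = NULL) {
  Y <- as.matrix(controls)
  if (!is.numeric(Y)) stop("`controls` must be numeric", call. = FALSE)
  feature_names <- colnames(Y)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(Y)))
  if (is.null(confounders)) {
    Z <- matrix(numeric(0), nrow(Y), 0L)
    confounder_names <- character(0)
  } else {
    Z <- as.matrix(confounders)
    if (!is.numeric(Z)) {
      stop("`confounders` must be numeric (encode categorical confounders first)",
           call. = FALSE)
    }
    confounder_names <- colnames(Z)
    if (is.null(confounder_names)) {
      confounder_names <- paste0("c", seq_len(ncol(Z)))
    }
  }
  if (nrow(Z) > 0L && nrow(Z) != nrow(Y)) {
    stop("`controls` and `confounders` must have the same number of rows",
         call. = FALSE)
  }
  keep <- if (ncol(Z) > 0L) stats::complete.cases(Z) else rep(TRUE, nrow(Y))
  if (any(!keep)) {
    message(sprintf("dropping %d control rows with missing confounders",
                    sum(!keep)))
    Y <- Y[keep, , drop = FALSE]
    Z <- Z[keep, , drop = FALSE]
  }
  if (anyNA(Y)) {
    stop("`controls` contain missing feature values", call. = FALSE)
  }
  C <- nrow(Y)
  Q <- ncol(Z)
  if (C <= Q + 1L) {
    stop(sprintf("need more than Q + 1 = %d controls, got %d", Q + 1L, C),
         call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, Z)
  colnames(Xd) <- c("(Intercept)", confounder_names)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop(sprintf("confounder matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm.fit(Xd, Y)
  coefs <- as.matrix(fit$coefficients)
  resid <- as.matrix(fit$residuals)
  residual_std <- sqrt(colSums(resid^2) / (C - Q - 1L))
  degenerate <- which(residual_std < sqrt(.Machine$double.eps))
  if (length(degenerate) > 0L) {
    stop(sprintf("degenerate features with (near-)zero residual variance: %s",
                 paste(feature_names[degenerate], collapse = ", ")),
         call. = FALSE)
  }
  colnames(coefs) <- feature_names
  names(residual_std) <- feature_names
  structure(
    list(coefficients = coefs, residual_std = residual_std,
         confounder_names = confounder_names, feature_names = feature_names),
    class = "ppsi_normative"
  )
}

#' Normative z-scoring of observations
#'
#' Applies a fitted control model: each feature value has the control
#' prediction for the observation's confounders subtracted and is divided
#' by that feature's control residual standard deviation,
#' `Z = (Y - Yhat) / s_eps`. A z-score of 0 therefore means "exactly the
#' value expected of a control with these confounders".
#'
#' @param model A [fit_normative()] object.
#' @param observations Numeric matrix or data frame `N x P`; column names,
#'   when present, must match the fitted feature names.
#' @param confounders Numeric matrix or data frame `N x Q` with columns
#'   matching the fitted confounder names in order (or `NULL` when the
#'   model was fitted without confounders).
#' @return A [data_matrix()] flagged as z-scored.
#' @export
zscore <- function(model, observations, confounders = NULL) {
  stopifnot(inherits(model, "ppsi_normative"))
  Y <- as.matrix(observations)
  record_ids <- rownames(observations)
  if (!is.null(colnames(Y)) &&
      !identical(colnames(Y), model$feature_names)) {
    stop("observation feature names do not match the fitted normative model",
         call. = FALSE)
  }
  if (ncol(Y) != length(model$feature_names)) {
    stop("observation column count does not match the fitted features",
         call. = FALSE)
  }
  Q <- length(model$confounder_names)
  if (Q == 0L) {
    Z <- matrix(numeric(0), nrow(Y), 0L)
  } else {
    if (is.null(confounders)) {
      stop("model was fitted with confounders; supply them", call. = FALSE)
    }
    Z <- as.matrix(confounders)
    if (!is.null(colnames(Z)) &&
        !identical(colnames(Z), model$confounder_names)) {
      stop(sprintf("confounder names/order mismatch: expected [%s], got [%s]",
                   paste(model$confounder_names, collapse = ", "),
                   paste(colnames(Z), collapse = ", ")), call. = FALSE)
    }
    if (ncol(Z) != Q) {
      stop("confounder column count does not match the fitted model",
           call. = FALSE)
    }
  }
  Xd <- cbind(1, Z)
  Yhat <- Xd %*% model$coefficients
  Zs <- sweep(Y - Yhat, 2L, model$residual_std, `/`)
  data_matrix(Zs, feature_names = model$feature_names,
              record_ids = record_ids, zscored = TRUE)
}
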