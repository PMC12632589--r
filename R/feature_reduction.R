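#' Feature-dropout importance report
#'
#' Measures each feature's contribution to inference by recomputing every
#' record's maximum-likelihood (subtype, stage) assignment with that
#' feature's log-density terms omitted from the likelihood sums - no
#' refitting, and no zero-imputation (which would inject the normative mean
#' as fake evidence). A feature's importance is the fraction of records
#' whose subtype or stage changes relative to the all-feature baseline.
#'
#' @param model A fitted [fit_ppsi()] model.
#' @param data A [data_matrix()] with at least two features, matching the
#'   model.
#' @return A data frame of class `ppsi_dropout`, one row per feature:
#'   `feature`, `changed_subtype_fraction`, `changed_stage_fraction`,
#'   `importance` (fraction changing subtype or stage).
#' @export
dropout_report <- function(model, data) {
  stopifnot(inherits(model, "ppsi_model"), inherits(data, "ppsi_data"))
  P <- ncol(data$X)
  if (P < 2L) stop("need at least two features to withhold one", call. = FALSE)
  if (!identical(data$feature_names, model$feature_names)) {
    stop("data features do not match the model", call. = FALSE)
  }
  constants <- gaussian_constants(model$config$sigma)
  M <- evaluate_progression(model$theta, model$basis)
  X <- data$X
  N <- nrow(X)
  S <- dim(M)[3]
  Kp1 <- dim(M)[1]

  # per-feature log-density contributions, so that withholding feature p is
  # a subtraction from the full sum
  contrib <- vector("list", P)  # each N x (S*(K+1)), stage-major columns
  full <- matrix(0, N, S * Kp1)
  for (p in seq_len(P)) {
    cp <- matrix(NA_real_, N, S * Kp1)
    for (s in seq_len(S)) {
      mu <- M[, p, s]                                 # length K+1
      d2 <- outer(X[, p], mu, `-`)^2                  # N x (K+1)
      cp[, s + S * (0:(Kp1 - 1L))] <-
        constants$log_alpha - d2 / constants$beta
    }
    contrib[[p]] <- cp
    full <- full + cp
  }

  pick <- function(phi) {
    j <- max.col(phi, ties.method = "first")
    cbind(subtype = (j - 1L) %% S + 1L, stage = (j - 1L) %/% S)
  }
  base <- pick(full)
  out <- data.frame(feature = data$feature_names,
                    changed_subtype_fraction = NA_real_,
                    changed_stage_fraction = NA_real_,
                    importance = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(P)) {
    red <- pick(full - contrib[[p]])
    ds <- red[, "subtype"] != base[, "subtype"]
    dk <- red[, "stage"] != base[, "stage"]
    out$changed_subtype_fraction[p] <- mean(ds)
    out$changed_stage_fraction[p] <- mean(dk)
    out$importance[p] <- mean(ds | dk)
  }
  class(out) <- c("ppsi_dropout", "data.frame")
  out
}

#' Select features above an importance cutoff
#'
#' @param report A [dropout_report()] data frame.
#' @param cutoff Real in `[0, 1]`; features with importance strictly
#'   greater than the cutoff are kept, in their original order.
#' @return Character vector of feature names (warns when empty).
#' @export
select_features <- function(report, cutoff) {
  stopifnot(inherits(report, "data.frame"),
            is.numeric(cutoff), length(cutoff) == 1L,
            cutoff >= 0, cutoff <= 1)
  keep <- report$feature[report$importance > cutoff]
  if (length(keep) == 0L) {
    warning("no feature exceeds the importance cutoff", call. = FALSE)
  }
  keep
}
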