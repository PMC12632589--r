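#' Construct a data matrix of z-scored progression features
#'
#' The model input: an `N x P` numeric matrix, rows are observations and
#' columns are features. Values are assumed (but not enforced) to come from
#' the normative z-scoring procedure ([zscore()]), so that 0 is the
#' confounder-adjusted control value of every feature. Missing values are
#' rejected here; imputation is the caller's responsibility.
#'
#' @param X Numeric matrix (or data frame coercible to one), `N x P`.
#' @param feature_names Character vector of length `P`; defaults to
#'   `colnames(X)`.
#' @param record_ids Character vector of length `N`; defaults to
#'   `rownames(X)` or `"r1" ... "rN"`.
#' @param zscored Logical provenance flag; set to `TRUE` by [zscore()] and
#'   by the simulator (whose outputs are generated on the z-score scale).
#'   [fit_ppsi()] warns when it is `FALSE`.
#'
#' @return An object of class `ppsi_data`: a list with elements `X`,
#'   `feature_names`, `record_ids`, `zscored`.
#' @export
data_matrix <- function(X, feature_names = colnames(X),
                        record_ids = rownames(X), zscored = FALSE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("`X` must have at least one row and one column", call. = FALSE)
  }
  n_miss <- sum(!is.finite(X))
  if (n_miss > 0L) {
    stop(sprintf(
      "`X` contains %d missing/non-finite values; resolve missingness upstream (the model accepts complete data only)",
      n_miss
    ), call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  if (is.null(record_ids)) record_ids <- paste0("r", seq_len(nrow(X)))
  feature_names <- as.character(feature_names)
  record_ids <- as.character(record_ids)
  if (length(feature_names) != ncol(X)) {
    stop("`feature_names` length must equal ncol(X)", call. = FALSE)
  }
  if (length(record_ids) != nrow(X)) {
    stop("`record_ids` length must equal nrow(X)", call. = FALSE)
  }
  dimnames(X) <- NULL
  structure(
    list(X = X, feature_names = feature_names, record_ids = record_ids,
         zscored = isTRUE(zscored)),
    class = "ppsi_data"
  )
}

#' @export
print.ppsi_data <- function(x, ...) {
  cat(sprintf("<ppsi_data> %d records x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' @export
dim.ppsi_data <- function(x) dim(x$X)

#' Subset the records of a data matrix
#'
#' @param data A [data_matrix()] object.
#' @param idx Integer or logical index over records (rows).
#' @return A `ppsi_data` object with the selected records.
#' @export
subset_records <- function(data, idx) {
  stopifnot(inherits(data, "ppsi_data"))
  data_matrix(data$X[idx, , drop = FALSE],
              feature_names = data$feature_names,
              record_ids = data$record_ids[idx],
              zscored = data$zscored)
}
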