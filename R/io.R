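#' Read a dataset from CSV or TSV
#'
#' First row is a header of feature names; an optional first column named
#' `id` (case-insensitive) supplies record ids. The delimiter (comma or
#' tab) is sniffed from the header line. Non-numeric cells and missing
#' values are rejected with their coordinates: the model contract requires
#' complete numeric data, with imputation handled upstream.
#'
#' @param path Path to a CSV/TSV file.
#' @param zscored Logical provenance flag to set on the result (use `TRUE`
#'   when the file holds output of [zscore()]).
#' @return A [data_matrix()] object.
#' @export
read_dataset <- function(path, zscored = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  record_ids <- NULL
  if (ncol(df) > 0L && tolower(names(df)[1]) == "id") {
    record_ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  vals <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = FALSE))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  raw <- as.matrix(df)
  missing_token <- is.na(raw) | raw == "NA" | trimws(raw) == ""
  bad <- which(is.na(vals) & !missing_token, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row %d, column \"%s\"",
                 bad[1, 1], names(df)[bad[1, 2]]), call. = FALSE)
  }
  miss <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    stop(sprintf(
      "missing value at row %d, column \"%s\"; the model requires complete data (impute upstream)",
      miss[1, 1], names(df)[miss[1, 2]]), call. = FALSE)
  }
  data_matrix(vals, feature_names = names(df), record_ids = record_ids,
              zscored = zscored)
}

#' Write a dataset to CSV
#'
#' Writes an `id` column followed by one column per feature.
#'
#' @param data A [data_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "ppsi_data"))
  df <- data.frame(id = data$record_ids, data$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", data$feature_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model as JSON
#'
#' The document stores the feature names, every hyperparameter, the
#' coefficient tensor as a nested `D x P x S` array at full double
#' precision (17 significant digits, so reloading is bit-exact) and the
#' final loss under `format_version` 1.
#'
#' @param model A fitted [fit_ppsi()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppsi_model"))
  d <- dim(model$theta)
  theta_nested <- lapply(seq_len(d[1]), function(dd) {
    lapply(seq_len(d[2]), function(pp) model$theta[dd, pp, ])
  })
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    feature_names = model$feature_names,
    K = model$config$K, D = model$config$D, S = model$config$S,
    sigma = model$config$sigma, l1_penalty = model$config$l1_penalty,
    max_lr = model$config$max_lr, iterations = model$config$iterations,
    minibatch_fraction = model$config$minibatch_fraction,
    seed = model$config$seed,
    theta = theta_nested,
    final_loss = model$final_loss
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path Path to a document written by [save_model()].
#' @return A `ppsi_model` object (without training history).
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) ||
      doc$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf("unsupported model format_version %s (this build reads version %d)",
                 format(doc$format_version), MODEL_FORMAT_VERSION),
         call. = FALSE)
  }
  D <- doc$D; S <- doc$S
  P <- length(doc$feature_names)
  th <- doc$theta
  # fromJSON simplifies the nested D x P x S lists to an array when shapes
  # are regular; validate either way
  if (is.array(th) && length(dim(th)) == 3L) {
    if (!identical(dim(th), as.integer(c(D, P, S)))) {
      stop(sprintf("theta shape [%s] inconsistent with D = %d, P = %d, S = %d",
                   paste(dim(th), collapse = " x "), D, P, S), call. = FALSE)
    }
    theta <- th
  } else {
    flat <- unlist(th)
    if (length(flat) != D * P * S) {
      stop(sprintf("theta has %d entries but D*P*S = %d",
                   length(flat), D * P * S), call. = FALSE)
    }
    theta <- array(NA_real_, dim = c(D, P, S))
    for (dd in seq_len(D)) for (pp in seq_len(P)) {
      theta[dd, pp, ] <- th[[dd]][[pp]]
    }
  }
  cfg <- fit_config(K = doc$K, D = D, S = S, sigma = doc$sigma,
                    l1_penalty = doc$l1_penalty, max_lr = doc$max_lr,
                    iterations = doc$iterations,
                    minibatch_fraction = doc$minibatch_fraction,
                    seed = doc$seed)
  structure(
    list(theta = theta, config = cfg, feature_names = doc$feature_names,
         basis = build_basis(doc$K, D), final_loss = doc$final_loss,
         loss_history = NULL),
    class = "ppsi_model"
  )
}

#' Read a run configuration from YAML
#'
#' Accepts any subset of the [generator_params()] fields plus `seed`;
#' unknown keys are rejected by name so typos never silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [generator_params()] object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- names(formals(generator_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(generator_params, cfg)
}
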