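#' Diagnostic plot suite for a fitted model
#'
#' Writes a set of PNG figures for subject-matter review: (a) per-subtype
#' polynomial trajectories with the assigned data overlaid, faceted by
#' feature; (b) per-stage assignment count histograms; (c) boxplots of the
#' sweep metrics when a [run_sweep()] report is supplied; (d) a
#' subtype-by-stage log-likelihood heatmap for one record. Panels are
#' best-effort: a panel that cannot be drawn is skipped with a message.
#'
#' @param model A fitted [fit_ppsi()] model.
#' @param data A [data_matrix()] object.
#' @param assignments Assignment data frame from [predict.ppsi_model()];
#'   computed when `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param sweep Optional [run_sweep()] report for the metric boxplots.
#' @param record Index of the record for the likelihood heatmap.
#' @param features Feature names to include in the trajectory panel
#'   (default: first six).
#' @return Character vector of the files written, invisibly.
#' @export
plot_suite <- function(model, data, assignments = NULL, out_dir,
                       sweep = NULL, record = 1L, features = NULL) {
  stopifnot(inherits(model, "ppsi_model"), inherits(data, "ppsi_data"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(assignments)) assignments <- stats::predict(model, data)
  if (is.null(features)) {
    features <- utils::head(model$feature_names, 6L)
  }
  written <- character(0)
  emit <- function(name, plot_fn) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      p <- plot_fn()
      ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 100)
      TRUE
    }, error = function(e) {
      message(sprintf("skipping panel %s: %s", name, conditionMessage(e)))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }

  M <- evaluate_progression(model$theta, model$basis)
  K <- model$config$K
  S <- model$config$S

  emit("trajectories.png", function() {
    sel <- match(features, model$feature_names)
    curve_df <- do.call(rbind, lapply(seq_len(S), function(s) {
      do.call(rbind, lapply(sel, function(p) {
        data.frame(stage = 0:K, value = M[, p, s],
                   feature = model$feature_names[p],
                   subtype = factor(s))
      }))
    }))
    pts <- do.call(rbind, lapply(sel, function(p) {
      data.frame(stage = assignments$stage, value = data$X[, p],
                 feature = model$feature_names[p],
                 subtype = factor(assignments$subtype))
    }))
    ggplot2::ggplot(curve_df,
                    ggplot2::aes(x = .data$stage, y = .data$value,
                                 colour = .data$subtype)) +
      ggplot2::geom_point(data = pts, alpha = 0.3, size = 0.8) +
      ggplot2::geom_line(linewidth = 1) +
      ggplot2::facet_wrap(~feature, scales = "free_y") +
      ggplot2::labs(x = "stage", y = "z-score",
                    title = "Fitted progression trajectories")
  })

  emit("stage_counts.png", function() {
    df <- as.data.frame(table(stage = factor(assignments$stage,
                                             levels = 0:K),
                              subtype = factor(assignments$subtype)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$Freq,
                                     fill = .data$subtype)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "records", title = "Stage assignment counts")
  })

  if (!is.null(sweep)) {
    emit("sweep_metrics.png", function() {
      metrics <- c("stage_distribution", "evaluation_distance", "silhouette",
                   "correlation_comparison", "aic", "euclidean_r2")
      long <- do.call(rbind, lapply(metrics, function(m) {
        data.frame(order = sweep$order, subtypes = factor(sweep$subtypes),
                   metric = m, value = sweep[[m]])
      }))
      long <- long[is.finite(long$value), ]
      ggplot2::ggplot(long, ggplot2::aes(x = .data$subtypes,
                                         y = .data$value)) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(title = "Cross-validated sweep metrics")
    })
  }

  emit("record_likelihood.png", function() {
    constants <- gaussian_constants(model$config$sigma)
    phi <- observation_loglik(data$X[record, ], M, constants)
    df <- expand.grid(subtype = seq_len(S), stage = 0:K)
    df$loglik <- phi[cbind(df$subtype, df$stage + 1L)]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$stage,
                                     y = factor(.data$subtype),
                                     fill = .data$loglik)) +
      ggplot2::geom_tile() +
      ggplot2::labs(y = "subtype",
                    title = sprintf("Log-likelihood surface, record %s",
                                    data$record_ids[record]))
  })

  invisible(written)
}
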