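#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model, computed from the contingency table. Identical partitions score
#' 1 regardless of label names; independent partitions score about 0. When
#' either labeling has fewer than two distinct labels the index is
#' undefined (comparing a single-subtype with a multi-subtype solution)
#' and `NA` is returned.
#'
#' @param labels_a,labels_b Vectors of equal length (>= 2) of cluster
#'   labels.
#' @return A number at most 1, or `NA` when undefined.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 2L) {
    stop("labelings must have equal length >= 2", call. = FALSE)
  }
  if (length(unique(labels_a)) < 2L || length(unique(labels_b)) < 2L) {
    return(NA_real_)
  }
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(NA_real_)
  (sum_ij - expected) / (max_index - expected)
}

#' Correlation of assigned stages with ground-truth stages
#'
#' Pearson correlation between continuous ground-truth stages and assigned
#' integer stages. Because the likelihood is invariant to reversing the
#' pseudotime axis, the fitted orientation can be inverted relative to
#' truth; the absolute correlation and an orientation flag are reported
#' alongside the signed value.
#'
#' @param true_stage Numeric vector of ground-truth stages.
#' @param assigned_stage Numeric/integer vector of assigned stages.
#' @return A list with `r` (signed), `abs_r` and `inverted` (`TRUE` when
#'   `r < 0`). All `NA` when either vector has zero variance.
#' @export
staging_correlation <- function(true_stage, assigned_stage) {
  if (length(true_stage) != length(assigned_stage)) {
    stop("stage vectors must have equal length", call. = FALSE)
  }
  if (stats::sd(true_stage) == 0 || stats::sd(assigned_stage) == 0) {
    return(list(r = NA_real_, abs_r = NA_real_, inverted = NA))
  }
  r <- stats::cor(true_stage, assigned_stage)
  list(r = r, abs_r = abs(r), inverted = r < 0)
}

#' Longitudinal hold-out validation metrics
#'
#' Compares baseline and follow-up assignments of the same subjects:
#' subtype consistency (fraction keeping their subtype), stage monotony
#' (fraction whose follow-up stage is greater than or equal to baseline)
#' and stage progression (fraction strictly advancing). Chance baselines
#' come from permuting the baseline-to-follow-up pairing across subjects,
#' which preserves both marginal distributions; for each metric the
#' permutation mean, percentile 95% interval and a one-sided p-value (the
#' fraction of permuted values at least as large as observed) are
#' reported.
#'
#' @param baseline,followup Assignment data frames (as from
#'   [predict.ppsi_model()]) with columns `record_id`, `subtype`, `stage`;
#'   matched by `record_id`.
#' @param n_permutations Integer number of pairing permutations.
#' @param seed Integer seed for the permutations.
#' @return An object of class `ppsi_longitudinal`: list with `observed`,
#'   `chance_means`, `chance_CIs` and `p_values`, each covering the three
#'   metrics, plus `n_subjects` and `n_permutations`.
#' @export
longitudinal_metrics <- function(baseline, followup, n_permutations = 1000L,
                                 seed = 1L) {
  stopifnot(is.data.frame(baseline), is.data.frame(followup))
  if (nrow(baseline) != nrow(followup) || nrow(baseline) < 2L) {
    stop("baseline and followup must have the same length >= 2", call. = FALSE)
  }
  if (!setequal(baseline$record_id, followup$record_id) ||
      anyDuplicated(baseline$record_id) > 0L) {
    stop("baseline and followup record ids do not align", call. = FALSE)
  }
  followup <- followup[match(baseline$record_id, followup$record_id), ]

  calc <- function(fu_subtype, fu_stage) {
    c(subtype_consistency = mean(fu_subtype == baseline$subtype),
      stage_monotony = mean(fu_stage >= baseline$stage),
      stage_progression = mean(fu_stage > baseline$stage))
  }
  observed <- calc(followup$subtype, followup$stage)

  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  n <- nrow(baseline)
  perms <- matrix(NA_real_, n_permutations, 3L)
  for (i in seq_len(n_permutations)) {
    p <- sample.int(n)
    perms[i, ] <- calc(followup$subtype[p], followup$stage[p])
  }
  colnames(perms) <- names(observed)
  chance_means <- colMeans(perms)
  chance_CIs <- apply(perms, 2L, stats::quantile, probs = c(0.025, 0.975))
  p_values <- vapply(seq_along(observed),
                     function(j) mean(perms[, j] >= observed[j]),
                     numeric(1))
  names(p_values) <- names(observed)
  structure(
    list(observed = observed, chance_means = chance_means,
         chance_CIs = chance_CIs, p_values = p_values,
         n_subjects = n, n_permutations = n_permutations),
    class = "ppsi_longitudinal"
  )
}

#' @export
print.ppsi_longitudinal <- function(x, ...) {
  cat(sprintf("<ppsi_longitudinal> %d subjects, %d permutations\n",
              x$n_subjects, x$n_permutations))
  for (m in names(x$observed)) {
    cat(sprintf("  %-20s %.3f (chance %.3f [%.3f, %.3f], p = %.4g)\n",
                m, x$observed[m], x$chance_means[m],
                x$chance_CIs[1, m], x$chance_CIs[2, m], x$p_values[m]))
  }
  invisible(x)
}
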