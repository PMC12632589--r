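#' Atkinson inequality index of a proportion vector
#'
#' With inequality-aversion parameter 1, the Atkinson index is one minus
#' the ratio of the geometric to the arithmetic mean of the proportions: 0
#' for perfect equality, approaching 1 as mass concentrates on one class.
#' The simulator uses it to target how unevenly features are spread over
#' coefficient clusters and records over subtypes.
#'
#' @param proportions Positive numeric vector summing to 1.
#' @return A number in `[0, 1)`.
#' @export
atkinson_index <- function(proportions) {
  if (any(!is.finite(proportions)) || any(proportions <= 0)) {
    stop("all proportions must be positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  gm <- exp(mean(log(proportions)))
  1 - gm / mean(proportions)
}

#' Proportions achieving a target Atkinson index
#'
#' Searches a one-parameter geometric family `p_i` proportional to `r^i`
#' (ratio `r` in (0, 1]) by bisection until [atkinson_index()] of the
#' result matches `target_index` within 1e-6. `target_index = 0` returns
#' equal proportions.
#'
#' @param n_classes Integer, at least 2.
#' @param target_index Real in `[0, 1)`.
#' @return Numeric vector of `n_classes` proportions summing to 1, in
#'   decreasing order.
#' @export
proportions_for_target <- function(n_classes, target_index) {
  if (!is_count(n_classes) || n_classes < 2) {
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(target_index) || target_index < 0 || target_index >= 1) {
    stop(sprintf(
      "`target_index` (%s) outside the achievable range [0, 1) of the geometric family",
      format(target_index)), call. = FALSE)
  }
  if (target_index == 0) return(rep(1 / n_classes, n_classes))
  props <- function(r) {
    p <- r^(seq_len(n_classes) - 1L)
    p / sum(p)
  }
  lo <- 1e-12; hi <- 1  # index decreasing in r: f(hi) = 0, f(lo) near 1
  if (atkinson_index(props(lo)) < target_index) {
    stop(sprintf(
      "target %g unreachable; achievable range is [0, %g)",
      target_index, atkinson_index(props(lo))), call. = FALSE)
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f <- atkinson_index(props(mid))
    if (abs(f - target_index) < 1e-9) break
    if (f > target_index) lo <- mid else hi <- mid
  }
  out <- props(mid)
  if (abs(atkinson_index(out) - target_index) > 1e-6) {
    stop("bisection failed to reach the target index", call. = FALSE)
  }
  out
}

#' Ground-truth progression generator parameters
#'
#' Parameterizes the simulator that emulates the statistical structure of
#' cross-sectional progression cohorts: per-subtype polynomial feature
#' trajectories whose coefficients cluster in groups, additive Gaussian
#' feature noise, Beta-distributed stage-sampling bias, and Atkinson-index
#' targeted imbalance of cluster sizes and subtype membership. Defaults sit
#' mid-range of the simulation-study parameterization (cluster coefficient
#' means with magnitude 1-4, cluster spreads 0.3-0.8, per-feature noise
#' 0.5-1.0, Beta shapes in 1-4, both imbalance targets 0.1).
#'
#' @param means_range Length-2 numeric, magnitude range of cluster
#'   coefficient means (signs are random).
#' @param stdev_min,stdev_max Positive reals bounding the per-cluster
#'   coefficient standard deviation.
#' @param noise_min,noise_max Positive reals bounding the per-feature noise
#'   standard deviation (on the z-score scale).
#' @param n_subtypes Integer, ground-truth subtype count.
#' @param dimensions Integer, ground-truth polynomial order.
#' @param n_polynomials Integer, feature count.
#' @param n_clusters Integer, number of coefficient clusters
#'   (at most `n_polynomials`).
#' @param sampling_bias_minmax Length-2 numeric, range of Beta shape
#'   parameters for per-subtype stage-sampling distributions. Equal bounds
#'   force every subtype to the same shape pair.
#' @param polydist_imbalance_index Real in `[0, 1)`, target Atkinson index
#'   for feature-to-cluster allocation.
#' @param subtype_class_imbalance_index Real in `[0, 1)`, target Atkinson
#'   index for subtype membership.
#' @param record_count Integer, number of records to draw.
#' @param shared_clusters Logical; when `TRUE` all subtypes draw their
#'   feature coefficients around one shared set of cluster means, giving
#'   much less separable subtypes. Default `FALSE`: each subtype's cluster
#'   means are drawn independently, so subtypes differ by construction.
#' @param seed Integer seed.
#' @return An object of class `ppsi_genparams`.
#' @export
generator_params <- function(means_range = c(1, 4),
                             stdev_min = 0.3, stdev_max = 0.8,
                             noise_min = 0.5, noise_max = 1.0,
                             n_subtypes = 2L, dimensions = 2L,
                             n_polynomials = 20L, n_clusters = 4L,
                             sampling_bias_minmax = c(1, 4),
                             polydist_imbalance_index = 0.1,
                             subtype_class_imbalance_index = 0.1,
                             record_count = 500L, shared_clusters = FALSE,
                             seed = 1L) {
  stopifnot(length(means_range) == 2L, means_range[1] <= means_range[2],
            stdev_min > 0, stdev_min <= stdev_max,
            noise_min >= 0, noise_min <= noise_max,
            is_count(n_subtypes), is_count(dimensions),
            is_count(n_polynomials), is_count(n_clusters),
            length(sampling_bias_minmax) == 2L,
            sampling_bias_minmax[1] > 0,
            sampling_bias_minmax[1] <= sampling_bias_minmax[2],
            polydist_imbalance_index >= 0, polydist_imbalance_index < 1,
            subtype_class_imbalance_index >= 0,
            subtype_class_imbalance_index < 1,
            is_count(record_count))
  if (n_clusters > n_polynomials) {
    stop("`n_clusters` cannot exceed `n_polynomials`", call. = FALSE)
  }
  structure(
    list(means_range = as.numeric(means_range),
         stdev_min = stdev_min, stdev_max = stdev_max,
         noise_min = noise_min, noise_max = noise_max,
         n_subtypes = as.integer(n_subtypes),
         dimensions = as.integer(dimensions),
         n_polynomials = as.integer(n_polynomials),
         n_clusters = as.integer(n_clusters),
         sampling_bias_minmax = as.numeric(sampling_bias_minmax),
         polydist_imbalance_index = polydist_imbalance_index,
         subtype_class_imbalance_index = subtype_class_imbalance_index,
         record_count = as.integer(record_count),
         shared_clusters = isTRUE(shared_clusters),
         seed = as.integer(seed)),
    class = "ppsi_genparams"
  )
}

# integer class sizes matching target proportions (largest-remainder, every
# class gets at least one member), shuffled assignment vector
sizes_from_proportions <- function(p, total) {
  base <- floor(p * total)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- p * total - base
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[bump] <- base[bump] + 1L
  }
  while (any(base == 0L)) {
    i <- which.max(base)
    j <- which(base == 0L)[1L]
    base[i] <- base[i] - 1L
    base[j] <- base[j] + 1L
  }
  as.integer(base)
}

#' Generate a ground-truth polynomial progression
#'
#' Draws the latent structure a simulated cohort is sampled from:
#' per-subtype, per-feature polynomial coefficients clustered around
#' cluster means (each subtype's cluster means drawn independently, so
#' subtypes differ by construction), per-feature noise levels, per-subtype
#' Beta stage-sampling distributions, each record's true subtype (sizes
#' targeting the class-imbalance index) and continuous stage in `[0, 1]`.
#' Deterministic given `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return An object of class `ppsi_truth`: list with `theta_true`
#'   (`dimensions x n_polynomials x n_subtypes`), `cluster_assignment`,
#'   `noise_coefficients`, `beta_shapes` (`n_subtypes x 2`),
#'   `record_subtype`, `record_stage` and `params`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "ppsi_genparams"))
  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(params$seed)

  D <- params$dimensions
  P <- params$n_polynomials
  S <- params$n_subtypes
  C <- params$n_clusters
  N <- params$record_count

  cl_prop <- if (C == 1L) 1 else {
    proportions_for_target(C, params$polydist_imbalance_index)
  }
  cl_sizes <- sizes_from_proportions(cl_prop, P)
  cluster_assignment <- sample(rep.int(seq_len(C), cl_sizes))

  draw_cluster_means <- function() {
    # magnitude uniform in means_range, random sign
    mag <- matrix(stats::runif(D * C, params$means_range[1],
                               params$means_range[2]), D, C)
    sgn <- matrix(sample(c(-1, 1), D * C, replace = TRUE), D, C)
    list(mu = mag * sgn,
         sd = stats::runif(C, params$stdev_min, params$stdev_max))
  }
  shared <- if (params$shared_clusters) draw_cluster_means() else NULL
  theta_true <- array(0, dim = c(D, P, S))
  for (s in seq_len(S)) {
    cl_par <- if (params$shared_clusters) shared else draw_cluster_means()
    for (p in seq_len(P)) {
      cl <- cluster_assignment[p]
      theta_true[, p, s] <- stats::rnorm(D, cl_par$mu[, cl], cl_par$sd[cl])
    }
  }

  noise_coefficients <- stats::runif(P, params$noise_min, params$noise_max)

  beta_shapes <- matrix(
    stats::runif(2L * S, params$sampling_bias_minmax[1],
                 params$sampling_bias_minmax[2]),
    nrow = S, ncol = 2L, dimnames = list(NULL, c("a", "b")))

  st_prop <- if (S == 1L) 1 else {
    proportions_for_target(S, params$subtype_class_imbalance_index)
  }
  st_sizes <- sizes_from_proportions(st_prop, N)
  record_subtype <- sample(rep.int(seq_len(S), st_sizes))
  record_stage <- stats::rbeta(N, beta_shapes[record_subtype, 1L],
                               beta_shapes[record_subtype, 2L])

  structure(
    list(theta_true = theta_true, cluster_assignment = cluster_assignment,
         noise_coefficients = noise_coefficients, beta_shapes = beta_shapes,
         record_subtype = record_subtype, record_stage = record_stage,
         params = params),
    class = "ppsi_truth"
  )
}

#' Sample a cross-sectional dataset from a ground truth
#'
#' Record `n`'s value for feature `p` is the subtype-`n` polynomial
#' evaluated at the record's continuous stage plus the feature's noise
#' coefficient times a standard normal draw. The output is flagged as
#' z-scored: the generator produces data directly on the normative z-score
#' scale (zero intercept at stage 0).
#'
#' @param truth A [generate_truth()] object.
#' @param seed Integer seed for the noise draws; defaults to
#'   `params$seed + 1` (the truth generation consumed `params$seed`).
#' @return A [data_matrix()] with `record_count` rows.
#' @export
sample_dataset <- function(truth, seed = truth$params$seed + 1L) {
  stopifnot(inherits(truth, "ppsi_truth"))
  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  p <- truth$params
  N <- p$record_count
  P <- p$n_polynomials
  D <- p$dimensions
  V <- outer(truth$record_stage, seq_len(D), `^`)  # N x D stage powers
  X <- matrix(0, N, P)
  for (s in seq_len(p$n_subtypes)) {
    rows <- which(truth$record_subtype == s)
    if (length(rows) == 0L) next
    X[rows, ] <- V[rows, , drop = FALSE] %*%
      matrix(truth$theta_true[, , s], D, P)
  }
  eps <- matrix(stats::rnorm(N * P), N, P)
  X <- X + eps * matrix(truth$noise_coefficients, N, P, byrow = TRUE)
  data_matrix(X,
              feature_names = paste0("f", seq_len(P)),
              record_ids = sprintf("r%04d", seq_len(N)),
              zscored = TRUE)
}
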