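#' Generate a pure-noise cohort
#'
#' Simulates a cohort in which every per-probe deviation from the cohort
#' mean is nothing but random fluctuation: all values are i.i.d. standard
#' normal. Under sigma-relative ternary discretization the noise scale is
#' irrelevant, so unit variance is used throughout.
#'
#' @param n_samples,n_probes Positive counts.
#' @param seed Integer seed; the output is fully determined by it.
#' @return Numeric matrix (probes x samples) with ids `p1..` / `s1..`.
#' @export
generate_noise_cohort <- function(n_samples, n_probes, seed = 1L) {
  stopifnot(n_samples >= 1L, n_probes >= 1L)
  set.seed(seed)
  matrix(stats::rnorm(n_probes * n_samples), nrow = n_probes,
         dimnames = list(paste0("p", seq_len(n_probes)),
                         paste0("s", seq_len(n_samples))))
}

#' Generate a cohort with three planted expression groups
#'
#' Test-bed generator emulating the structure the CTP method assumes: three
#' sample groups whose signal probes carry group-specific mean shifts on top
#' of Gaussian noise. Signal probes cycle through the three rotations of the
#' offset pattern (+1, 0, -1) scaled by `effect_size * noise_sd`, so the
#' three planted ternary prototypes are pairwise distinct; the remaining
#' probes are pure noise.
#'
#' @param n_samples Total number of samples (default 150).
#' @param n_probes Number of probes (default 2000).
#' @param group_proportions Length-3 vector of group proportions summing to
#'   1 (default equal thirds). Proportions implying an empty group are an
#'   error: the CTP contract requires three populated groups.
#' @param signal_fraction Fraction of probes carrying group-specific shifts
#'   (default 0.3).
#' @param effect_size Mean shift of signal probes, in units of `noise_sd`
#'   (default 3).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 1).
#' @param seed Integer seed.
#' @return List of class `planted_cohort`: `x` (expression matrix),
#'   `labels` (named character vector, planted group A/B/C per sample),
#'   `signal_probes` (character), and the generating parameters.
#' @details With `signal_fraction = 0` the generator reduces to
#'   [generate_noise_cohort()] distributionally (up to `noise_sd` scaling).
#' @export
generate_planted_cohort <- function(n_samples = 150L, n_probes = 2000L,
                                    group_proportions = rep(1, 3) / 3,
                                    signal_fraction = 0.3, effect_size = 3,
                                    noise_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 3L, n_probes >= 1L,
            signal_fraction >= 0, signal_fraction <= 1,
            effect_size >= 0, noise_sd > 0)
  if (length(group_proportions) != 3L || any(group_proportions < 0) ||
      sum(group_proportions) <= 0)
    stop("group_proportions must be three non-negative values")
  p <- group_proportions / sum(group_proportions)
  sizes <- floor(p * n_samples)
  rem <- n_samples - sum(sizes)
  if (rem > 0) {                       # largest-remainder apportionment
    o <- order(p * n_samples - sizes, decreasing = TRUE)
    sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1L
  }
  if (any(sizes == 0L))
    stop("group_proportions would leave a planted group empty; ",
         "all three groups must be populated")
  set.seed(seed)
  labels <- sample(rep(c("A", "B", "C"), times = sizes))
  names(labels) <- paste0("s", seq_len(n_samples))
  n_signal <- round(signal_fraction * n_probes)
  signal_idx <- if (n_signal > 0) sort(sample.int(n_probes, n_signal))
                else integer(0)
  # group offset patterns: rotations of (+1, 0, -1), cycled over signal probes
  patterns <- rbind(A = c(1, -1, 0), B = c(0, 1, -1), C = c(-1, 0, 1))
  x <- matrix(stats::rnorm(n_probes * n_samples, sd = noise_sd),
              nrow = n_probes,
              dimnames = list(paste0("p", seq_len(n_probes)), names(labels)))
  if (n_signal > 0) {
    rot <- (seq_len(n_signal) - 1L) %% 3L + 1L     # which rotation per probe
    shift <- patterns[labels, ] * effect_size * noise_sd
    x[signal_idx, ] <- x[signal_idx, ] +
      t(shift[, rot, drop = FALSE])
  }
  structure(
    list(x = x, labels = labels,
         signal_probes = rownames(x)[signal_idx],
         group_sizes = stats::setNames(sizes, c("A", "B", "C")),
         signal_fraction = signal_fraction, effect_size = effect_size,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "planted_cohort"
  )
}

#' Pure-noise null simulation of the CTP protocol
#'
#' Runs the full deviation-profiling protocol on cohorts in which expression
#' deviations are pure Gaussian noise, to quantify how much apparent CTP
#' structure random fluctuation alone can produce. For each of `n_groups`
#' independent "virtual cancer types", a noise cohort of `n_patients` is
#' generated, discretized at the standard cut, clustered into three CTPs,
#' and the per-group centroid profiles are restricted to one random probe
#' subset of size `subset_size` (shared across groups, mimicking selection
#' of a functional gene set). Matched-label centroids are then correlated
#' across every pair of virtual types; genuinely structureless data yields
#' cross-type correlations scattered around zero.
#'
#' @param n_groups Number of virtual cancer types (default 14).
#' @param n_patients Patients per virtual type (default 50).
#' @param n_probes Probes per cohort (default 20000).
#' @param subset_size Size of the random probe subset the centroids are
#'   restricted to (default 716).
#' @param threshold_factor Discretization cut (default 0.43).
#' @param method Clustering method, `"kmeans"` (default) or `"som"`.
#' @param n_restarts Clustering restarts per cohort.
#' @param seed Integer seed controlling every random draw.
#' @return Object of class `simulation_report`: list with
#'   `cross_type_mean_correlation` (mean Pearson r over all cross-type
#'   matched-label centroid pairs), `cross_type_correlations` (the
#'   individual pair values), `within_type_pair_correlations` (named means
#'   of the A-B, A-C and B-C centroid correlations within a type), and the
#'   configuration including `seed`.
#' @export
run_null_simulation <- function(n_groups = 14L, n_patients = 50L,
                                n_probes = 20000L, subset_size = 716L,
                                threshold_factor = 0.43,
                                method = c("kmeans", "som"),
                                n_restarts = 10L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_groups >= 2L, n_patients >= 3L, n_probes >= 1L,
            subset_size >= 2L, subset_size <= n_probes)
  set.seed(seed)
  subset_idx <- sort(sample.int(n_probes, subset_size))
  group_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_groups)
  labels <- c("A", "B", "C")
  centroids <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    x <- generate_noise_cohort(n_patients, n_probes,
                               seed = group_seeds[2L * g - 1L])
    codes <- ternarize(x, threshold_factor)
    grouping <- cluster_ternary(codes, method = method,
                                seed = group_seeds[2L * g],
                                n_restarts = n_restarts)
    model <- compute_centroids(codes, grouping,
                               threshold_factor = threshold_factor)
    centroids[[g]] <- vapply(labels,
                             function(lab) model$centroids[[lab]][subset_idx],
                             numeric(subset_size))
  }
  pairs <- utils::combn(n_groups, 2L)
  cross <- apply(pairs, 2L, function(gh) {
    vapply(seq_along(labels), function(l)
      stats::cor(centroids[[gh[1L]]][, l], centroids[[gh[2L]]][, l]),
      numeric(1))
  })                                   # 3 x n_pairs, rows = labels
  within <- vapply(centroids, function(cm)
    c(AB = stats::cor(cm[, 1L], cm[, 2L]),
      AC = stats::cor(cm[, 1L], cm[, 3L]),
      BC = stats::cor(cm[, 2L], cm[, 3L])), numeric(3))
  structure(
    list(cross_type_mean_correlation = mean(cross),
         cross_type_correlations = as.numeric(cross),
         cross_type_by_label = stats::setNames(rowMeans(cross), labels),
         within_type_pair_correlations = rowMeans(within),
         n_groups = n_groups, n_patients = n_patients,
         n_probes = n_probes, subset_size = subset_size,
         threshold_factor = threshold_factor, method = method,
         seed = as.integer(seed)),
    class = "simulation_report"
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf(paste0("Pure-noise CTP null simulation: %d virtual types x ",
                     "%d patients, %d probes, %d-probe subset (seed %d)\n"),
              x$n_groups, x$n_patients, x$n_probes, x$subset_size, x$seed))
  cat(sprintf("  cross-type matched-label centroid correlation: %.5f\n",
              x$cross_type_mean_correlation))
  cat(sprintf("  within-type pair correlations: AB %.3f, AC %.3f, BC %.3f\n",
              x$within_type_pair_correlations[["AB"]],
              x$within_type_pair_correlations[["AC"]],
              x$within_type_pair_correlations[["BC"]]))
  invisible(x)
}
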