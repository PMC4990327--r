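#' Cluster diameter: mean member-centroid correlation per CTP
#'
#' For every CTP label, collects the samples assigned to that label and
#' averages their winning Pearson correlations with the label's centroid.
#' The average is an estimate of how tightly the group's members sit around
#' their target vector: cohorts with genuine group structure show larger
#' diameters than weakly structured (e.g. normal-tissue) cohorts.
#'
#' @param assignments Assignment data frame from [assign_cohort()], produced
#'   against `model`.
#' @param model The `ctp_model` the assignments were made with.
#' @param cohort_tag Free-text tag recorded in the report.
#' @return Object of class `diameter_report`: data frame with one row per
#'   label (`label`, `n`, `mean_correlation`) plus attribute `cohort_tag`.
#'   A label with no assigned members is reported with `n = 0` and
#'   `mean_correlation = NA` (flagged, never 0).
#' @export
cluster_diameter <- function(assignments, model, cohort_tag = "") {
  model <- validate_ctp_model(model)
  stopifnot(is.data.frame(assignments))
  rows <- lapply(model$labels, function(lab) {
    members <- assignments[assignments$label == lab, , drop = FALSE]
    data.frame(label = lab, n = nrow(members),
               mean_correlation = if (nrow(members))
                 mean(members[[paste0("r_", lab)]]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cohort_tag") <- cohort_tag
  class(out) <- c("diameter_report", "data.frame")
  out
}

#' Compare cluster diameters between two groups of cohorts
#'
#' Two-sided two-sample location test on per-cohort mean diameter values,
#' e.g. tumor cohorts versus normal-tissue cohorts. Both a Welch t test and
#' a Wilcoxon rank-sum test are computed; `test` selects which one provides
#' the headline statistic and p-value.
#'
#' @param group1,group2 Numeric vectors of per-cohort diameter values (each
#'   of length >= 2).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `test`, and the full `welch`
#'   and `wilcoxon` htest objects.
#' @export
compare_diameters <- function(group1, group2, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 per-cohort diameter values")
  if (stats::sd(c(group1, group2)) == 0)
    stop("degenerate input: all diameter values identical")
  welch <- stats::t.test(group1, group2, var.equal = FALSE)
  wilcox <- suppressWarnings(stats::wilcox.test(group1, group2))
  chosen <- if (test == "welch") welch else wilcox
  list(statistic = unname(chosen$statistic),
       p_value = chosen$p.value,
       test = test, welch = welch, wilcoxon = wilcox)
}

#' Robustness of CTP assignment under gene subsetting
#'
#' Measures how stable CTP affiliation is when the model is rebuilt from a
#' restricted gene set. The expression matrix is restricted to the subset's
#' probes, centroids are recomputed on the restricted ternary data reusing
#' the full model's training-sample grouping (so the comparison isolates the
#' gene-subset effect from clustering instability), every sample is
#' re-assigned with the restricted model, and the similarity is the
#' permutation-matched percentage of samples whose subset-model label equals
#' their full-model label. For random subsets the draw is repeated
#' `n_replicates` times and the mean and standard deviation are reported.
#'
#' @param x Expression matrix of the model's training cohort.
#' @param full_model The `ctp_model` built on all probes of `x`; must carry
#'   `training_groups`.
#' @param subset A `gene_subset` (or character vector of probe ids) for a
#'   fixed subset, or `NULL` to draw random subsets.
#' @param size Random-subset size (required when `subset` is `NULL`).
#' @param n_replicates Number of random draws, default 20.
#' @param seed Seed for the random draws.
#' @param recluster If `TRUE`, the restricted ternary data is re-clustered
#'   de novo instead of reusing the full model's grouping.
#' @inheritParams assign_sample
#' @return Object of class `robustness_report`: list with `subset_name`,
#'   `subset_size`, `similarity` (mean percent, in \[0, 100\]), `sd`
#'   (NA for a fixed subset), and `replicates` (per-replicate percents).
#' @export
subset_robustness <- function(x, full_model, subset = NULL, size = NULL,
                              n_replicates = 20L, seed = 1L,
                              recluster = FALSE, min_common_probes = 10L) {
  full_model <- validate_ctp_model(full_model)
  if (is.null(full_model$training_groups))
    stop("full_model carries no training_groups; rebuild it with build_model")
  x <- validate_expression_matrix(x)
  if (!all(colnames(x) %in% names(full_model$training_groups)))
    stop("x must be the model's training cohort (sample ids differ)")
  full_assign <- assign_cohort(x, full_model,
                               min_common_probes = min_common_probes)
  full_labels <- stats::setNames(full_assign$label, full_assign$sample_id)
  codes <- ternarize(x, full_model$threshold_factor)

  one_draw <- function(ids, draw_seed) {
    ids <- intersect(ids, rownames(x))
    if (!length(ids)) stop("subset has no probes in common with the matrix")
    if (length(ids) < 10L)
      stop("subset too small after intersection (", length(ids),
           " probes); need at least 10")
    sub_codes <- codes[ids, , drop = FALSE]
    model_sub <- if (recluster) {
      grouping <- cluster_ternary(sub_codes, method =
          if (full_model$clustering_method %in% c("kmeans", "som"))
            full_model$clustering_method else "kmeans",
        seed = draw_seed)
      compute_centroids(sub_codes, grouping,
                        threshold_factor = full_model$threshold_factor)
    } else {
      compute_centroids(sub_codes, full_model$training_groups,
                        labels = full_model$labels,
                        threshold_factor = full_model$threshold_factor,
                        clustering_method = "predefined")
    }
    sub_assign <- assign_cohort(x[ids, , drop = FALSE], model_sub,
                                min_common_probes =
                                  min(min_common_probes, length(ids)))
    sub_labels <- stats::setNames(sub_assign$label, sub_assign$sample_id)
    100 * overlap(full_labels, sub_labels)$agreement_fraction
  }

  if (!is.null(subset)) {
    ids <- if (inherits(subset, "gene_subset")) subset$ids
           else as.character(subset)
    missing_ids <- setdiff(ids, rownames(x))
    if (length(missing_ids) && length(missing_ids) < length(ids))
      warning(length(missing_ids),
              " subset probe(s) absent from the matrix; intersecting")
    sims <- one_draw(ids, seed)
    name <- if (inherits(subset, "gene_subset")) subset$name else "fixed"
    res <- list(subset_name = name,
                subset_size = length(intersect(ids, rownames(x))),
                similarity = sims, sd = NA_real_, replicates = sims)
  } else {
    if (is.null(size)) stop("either 'subset' or 'size' must be given")
    if (size > nrow(x)) stop("size exceeds the number of probes")
    set.seed(seed)
    sims <- vapply(seq_len(n_replicates), function(i)
      one_draw(sample(rownames(x), size), seed + i), numeric(1))
    res <- list(subset_name = sprintf("random_%d", size),
                subset_size = as.integer(size),
                similarity = mean(sims), sd = stats::sd(sims),
                replicates = sims)
  }
  structure(res, class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Gene-subset robustness (", x$subset_name, ", ", x$subset_size,
      " probes): ", sprintf("%.1f", x$similarity), "%", sep = "")
  if (!is.na(x$sd)) cat(" +/-", sprintf("%.1f", x$sd), "over",
                        length(x$replicates), "draws")
  cat("\n")
  invisible(x)
}
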