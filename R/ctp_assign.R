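#' Assign one ternary profile to a CTP
#'
#' Computes the Pearson correlation between a sample's ternary profile and
#' each of the three CTP centroid target vectors, over the intersection of
#' probe identifiers (in model probe order), and assigns the label with the
#' highest correlation. Exact correlation ties are broken by model label
#' order and flagged.
#'
#' @param profile Named numeric vector of ternary codes (names = probe ids).
#' @param model A `ctp_model`.
#' @param min_common_probes Minimum number of shared probes required between
#'   profile and model (default 100); transfer to a new platform assumes
#'   near-complete overlap, so a thin intersection is an error rather than a
#'   silent weak correlation.
#' @return One-row data frame with `sample_id` (NA here; filled by
#'   [assign_cohort()]), `label`, one correlation column `r_<label>` per
#'   model label, `margin` (winning correlation minus runner-up, >= 0) and
#'   `tie` (logical).
#' @details A profile or centroid that is constant on the common probe
#'   support has no defined Pearson correlation and raises an error.
#' @export
assign_sample <- function(profile, model, min_common_probes = 100L) {
  model <- validate_ctp_model(model)
  if (is.null(names(profile)))
    stop("profile must be a named vector keyed by probe identifiers")
  common <- model$probe_ids[model$probe_ids %in% names(profile)]
  if (length(common) < min_common_probes)
    stop("only ", length(common), " probes shared between profile and model ",
         "(minimum ", min_common_probes, "); transfer assumes ",
         "near-complete probe overlap")
  p <- as.numeric(profile[common])
  if (stats::sd(p) == 0)
    stop("undefined correlation: profile is constant on the common probes")
  r <- vapply(model$labels, function(lab) {
    cv <- model$centroids[[lab]][match(common, model$probe_ids)]
    if (stats::sd(cv) == 0)
      stop("undefined correlation: centroid '", lab,
           "' is constant on the common probes")
    stats::cor(p, cv)
  }, numeric(1))
  win <- which.max(r)                     # first max = model label order
  tie <- sum(r == r[win]) > 1L
  res <- data.frame(sample_id = NA_character_,
                    label = model$labels[win],
                    t(r), margin = r[win] - max(r[-win]), tie = tie,
                    stringsAsFactors = FALSE)
  names(res)[3:5] <- paste0("r_", model$labels)
  res
}

#' Assign every sample of a cohort to a CTP
#'
#' Discretizes the cohort against its own per-probe means and standard
#' deviations — the step that makes assignment invariant to tissue-of-origin
#' expression-level differences — and then assigns each single-sample ternary
#' profile to the model CTP with the highest Pearson correlation.
#'
#' @inheritParams compute_deviations
#' @param model A `ctp_model`.
#' @param threshold_factor Discretization cut; defaults to the model's.
#' @inheritParams assign_sample
#' @return Data frame with one row per sample: `sample_id`, `label`,
#'   `r_<label>` columns, `margin`, `tie`.
#' @export
assign_cohort <- function(x, model, threshold_factor = NULL,
                          std_mode = c("sample", "population"),
                          min_common_probes = 100L) {
  model <- validate_ctp_model(model)
  threshold_factor <- threshold_factor %||% model$threshold_factor
  codes <- ternarize(x, threshold_factor, match.arg(std_mode))
  rows <- lapply(colnames(codes), function(s) {
    res <- assign_sample(codes[, s], model,
                         min_common_probes = min_common_probes)
    res$sample_id <- s
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best-permutation agreement between two three-group labelings
#'
#' Group labels coming out of a clustering are arbitrary, so two labelings of
#' the same samples are compared under the best of the six bijections of
#' three labels: the reported agreement fraction is the maximum fraction of
#' samples on which the relabeled test partition matches the gold partition.
#'
#' @param gold,test Named character vectors (names = sample ids) mapping each
#'   sample to one of three labels. The two must cover the same sample set.
#' @return Object of class `overlap_report`: list with `n_samples`,
#'   `agreement_fraction`, `permutation` (named character vector, test label
#'   -> gold label) and `confusion` (3x3 table, gold x relabeled test).
#' @details `overlap()` is symmetric in its arguments and equals 1 exactly
#'   when the two partitions coincide.
#' @export
overlap <- function(gold, test) {
  if (is.null(names(gold)) || is.null(names(test)))
    stop("gold and test must be named by sample id")
  if (!setequal(names(gold), names(test))) {
    only_g <- setdiff(names(gold), names(test))
    only_t <- setdiff(names(test), names(gold))
    stop("sample sets differ; only in gold: ",
         paste(only_g, collapse = ", "), "; only in test: ",
         paste(only_t, collapse = ", "))
  }
  test <- test[names(gold)]
  glab <- sort(unique(as.character(gold)))
  tlab <- sort(unique(as.character(test)))
  if (length(glab) > 3L || length(tlab) > 3L)
    stop("labelings must use at most 3 labels")
  # pad to 3 label slots so permutations are over full bijections
  pad3 <- function(v) {
    if (length(v) >= 3L) return(v)
    c(v, paste0(".unused", seq.int(length(v) + 1L, 3L)))
  }
  tlab3 <- pad3(tlab)
  glab3 <- pad3(glab)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  for (p in perms) {
    map <- stats::setNames(glab3[p], tlab3)
    agree <- mean(map[as.character(test)] == as.character(gold))
    if (is.null(best) || agree > best$agreement_fraction)
      best <- list(agreement_fraction = agree, map = map)
  }
  relabeled <- best$map[as.character(test)]
  confusion <- table(gold = factor(as.character(gold), levels = glab3),
                     test = factor(relabeled, levels = glab3))
  structure(
    list(n_samples = length(gold),
         agreement_fraction = best$agreement_fraction,
         permutation = best$map[tlab3 %in% tlab],
         confusion = confusion),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Partition overlap over", x$n_samples, "samples:",
      sprintf("%.1f%%", 100 * x$agreement_fraction), "\n")
  cat("  label map (test -> gold):",
      paste(names(x$permutation), "->", x$permutation, collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Reverse transfer of the CTP concept between cohorts
#'
#' Builds a fresh CTP model on the `source` cohort by clustering its ternary
#' profiles, assigns every sample of the `target` cohort with that model, and
#' scores the permutation-matched agreement of the resulting labels with a
#' reference labeling of the target (for example the target's own original
#' grouping). A high agreement indicates that the group structure found in
#' one cancer type carries over to the other.
#'
#' @param source Expression matrix used to build the model.
#' @param target Expression matrix to classify.
#' @param target_gold Named character vector: reference labels of the target
#'   samples.
#' @inheritParams build_model
#' @inheritParams assign_sample
#' @return A list with `report` (the `overlap_report`), `model` and
#'   `assignments`.
#' @export
reverse_transfer <- function(source, target, target_gold,
                             method = c("kmeans", "som"), seed = 1L,
                             threshold_factor = 0.43, n_restarts = 10L,
                             min_common_probes = 100L) {
  method <- match.arg(method)
  model <- build_model(source, threshold_factor = threshold_factor,
                       method = method, seed = seed,
                       n_restarts = n_restarts, source_tag = "reverse-source")
  assignments <- assign_cohort(target, model,
                               min_common_probes = min_common_probes)
  test <- stats::setNames(assignments$label, assignments$sample_id)
  list(report = overlap(target_gold, test), model = model,
       assignments = assignments)
}
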