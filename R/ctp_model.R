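#' Construct a CTP model object
#'
#' Low-level constructor; most users will obtain models from
#' [compute_centroids()], [build_model()] or [read_ctp_model()].
#'
#' @param labels Character vector of exactly three group names.
#' @param probe_ids Ordered probe identifiers.
#' @param centroids Named list (one element per label) of numeric centroid
#'   vectors over `probe_ids`, entries in \[-1, 1\].
#' @param threshold_factor Discretization cut used when the model was built.
#' @param clustering_method `"kmeans"`, `"som"` or `"predefined"`.
#' @param seed Integer seed used for clustering (NA when predefined).
#' @param source_tag Free-text provenance tag for the training cohort.
#' @param training_groups Optional named character vector mapping the
#'   training sample identifiers to their final group label; kept so that
#'   gene-subset models can reuse the same sample grouping
#'   (see [subset_robustness()]).
#' @return Object of class `ctp_model`.
#' @export
new_ctp_model <- function(labels, probe_ids, centroids,
                          threshold_factor = 0.43,
                          clustering_method = "predefined",
                          seed = NA_integer_, source_tag = "",
                          training_groups = NULL) {
  centroids <- lapply(centroids, function(v) unname(as.numeric(v)))
  structure(
    list(labels = labels, probe_ids = probe_ids,
         centroids = centroids, threshold_factor = threshold_factor,
         clustering_method = clustering_method,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         source_tag = source_tag, training_groups = training_groups),
    class = "ctp_model"
  )
}

validate_ctp_model <- function(model) {
  if (!inherits(model, "ctp_model")) stop("not a ctp_model object")
  if (length(model$labels) != 3L || anyDuplicated(model$labels))
    stop("a CTP model must have exactly 3 distinct labels")
  if (!length(model$probe_ids) || anyDuplicated(model$probe_ids))
    stop("model probe_ids must be non-empty and unique")
  if (!setequal(names(model$centroids), model$labels))
    stop("model is missing centroid(s) for label(s): ",
         paste(setdiff(model$labels, names(model$centroids)), collapse = ", "))
  for (lab in model$labels) {
    v <- model$centroids[[lab]]
    if (length(v) != length(model$probe_ids))
      stop("centroid '", lab, "' has length ", length(v),
           " but the model has ", length(model$probe_ids), " probes")
    if (!all(is.finite(v)) || any(v < -1 | v > 1))
      stop("centroid '", lab, "' has entries outside [-1, 1]")
  }
  if (!is.null(model$training_groups) &&
      !all(model$training_groups %in% model$labels))
    stop("training_groups contain labels not in the model")
  model
}

#' @export
print.ctp_model <- function(x, ...) {
  cat("CTP model (", x$clustering_method, "): ",
      length(x$probe_ids), " probes, labels ",
      paste(x$labels, collapse = "/"), "\n", sep = "")
  cat("  threshold_factor = ", x$threshold_factor,
      ", seed = ", x$seed,
      if (nzchar(x$source_tag %||% "")) paste0(", source = ", x$source_tag),
      "\n", sep = "")
  if (!is.null(x$training_groups))
    cat("  training cohort: ", length(x$training_groups), " samples (",
        paste(table(factor(x$training_groups, levels = x$labels)),
              collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Cluster ternary sample profiles into three groups
#'
#' Clusters the columns (samples) of a ternary profile matrix into k = 3
#' groups, either by k-means on the raw codes (squared-Euclidean objective,
#' best of `n_restarts` by total within-cluster sum of squares) or by a
#' one-dimensional self-organizing map with three units, each unit being one
#' group. Both methods are deterministic given `seed`.
#'
#' @param codes Integer matrix of ternary codes, probes in rows, samples in
#'   columns (from [ternarize()] / [discretize()]).
#' @param method `"kmeans"` or `"som"`.
#' @param k Number of groups; must be 3 (the CTP concept is three groups).
#' @param seed Integer seed for initialization.
#' @param n_restarts Number of random restarts (k-means) / independent
#'   trainings (SOM); the run with the best objective is kept.
#' @return Object of class `ctp_grouping`: list with `sample_ids`,
#'   `group_index` (integer in 1..3 per sample, groups numbered by decreasing
#'   size with ties broken by the lexicographically smallest member sample
#'   id), `sizes`, `objective` (total within-group sum of squares), `method`
#'   and `seed`.
#' @details An empty group after convergence is an error (the model contract
#'   assumes three populated groups); a different seed usually resolves it.
#' @export
cluster_ternary <- function(codes, method = c("kmeans", "som"), k = 3L,
                            seed = 1L, n_restarts = 10L) {
  method <- match.arg(method)
  codes <- validate_ternary_matrix(codes)
  if (k != 3L)
    stop("k must be 3: a CTP model has exactly 3 labels")
  if (ncol(codes) < k)
    stop("need at least ", k, " samples to form ", k, " groups")
  pts <- t(codes)                     # samples as points in probe space
  if (method == "kmeans") {
    set.seed(seed)
    fit <- suppressWarnings(
      stats::kmeans(pts, centers = k, nstart = n_restarts, iter.max = 100L)
    )
    idx <- fit$cluster
    objective <- fit$tot.withinss
  } else {
    set.seed(seed)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- som_1d3(pts)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    idx <- best$cluster
    objective <- best$objective
  }
  if (length(unique(idx)) < k)
    stop("clustering produced an empty group; try a different seed")
  ord <- order_groups_by_size(idx, colnames(codes))
  structure(
    list(sample_ids = colnames(codes),
         group_index = ord$rank[idx],
         sizes = ord$sizes,
         objective = objective,
         method = method,
         seed = as.integer(seed)),
    class = "ctp_grouping"
  )
}

# Deterministic group numbering: 1..3 by decreasing size, ties broken by the
# lexicographically smallest member sample id. Returns rank[old_index] and
# the ordered sizes.
order_groups_by_size <- function(idx, sample_ids) {
  sizes <- tabulate(idx, nbins = max(idx))
  first_id <- vapply(seq_along(sizes), function(g) {
    m <- sample_ids[idx == g]
    if (length(m)) min(m) else ""
  }, character(1))
  o <- order(-sizes, first_id)
  rank <- integer(length(sizes))
  rank[o] <- seq_along(o)
  list(rank = rank, sizes = sizes[o])
}

# Minimal 1x3 self-organizing map on rows of `pts`. Linear chain topology
# (units 1-2-3); learning rate and neighborhood radius decay linearly over a
# fixed number of epochs; samples are presented in a freshly shuffled order
# each epoch. Returns the best-matching-unit partition and its quantization
# objective (total squared distance to the BMU codebook vectors).
som_1d3 <- function(pts, epochs = 20L, alpha0 = 0.5, alpha1 = 0.01) {
  n <- nrow(pts)
  codebook <- pts[sample.int(n, 3L), , drop = FALSE] + 0
  steps <- epochs * n
  step <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      frac <- step / steps
      alpha <- alpha0 + (alpha1 - alpha0) * frac
      radius <- if (frac < 0.5) 1 else 0     # shrink neighborhood mid-training
      d2 <- rowSums((codebook - matrix(pts[i, ], 3L, ncol(pts),
                                       byrow = TRUE))^2)
      bmu <- which.min(d2)
      for (u in 1:3) {
        dist_units <- abs(u - bmu)
        if (dist_units <= radius) {
          h <- if (dist_units == 0L) 1 else 0.5
          codebook[u, ] <- codebook[u, ] +
            alpha * h * (pts[i, ] - codebook[u, ])
        }
      }
    }
  }
  d2 <- as.matrix(stats::dist(rbind(codebook, pts)))[-(1:3), 1:3]^2
  cluster <- max.col(-d2)
  list(cluster = cluster,
       objective = sum(d2[cbind(seq_len(n), cluster)]))
}

#' Average ternary profile of each group: the CTP target vectors
#'
#' For each group, the centroid is the arithmetic mean of the ternary codes
#' of the group's member samples, probe by probe. Entries therefore lie in
#' \[-1, 1\]; a single-member group's centroid is that member's profile.
#'
#' @param codes Ternary matrix (probes x samples).
#' @param grouping A `ctp_grouping` from [cluster_ternary()], or a named
#'   character vector mapping every sample of `codes` to a label.
#' @param labels Group names, default `c("A", "B", "C")`. For a
#'   `ctp_grouping`, label i names group i (groups are size-ordered).
#' @param threshold_factor,seed,source_tag,clustering_method Provenance
#'   recorded in the model (filled automatically by [build_model()]).
#' @return A validated `ctp_model` whose `training_groups` records the
#'   sample-to-label map used.
#' @export
compute_centroids <- function(codes, grouping, labels = c("A", "B", "C"),
                              threshold_factor = 0.43,
                              clustering_method = NULL,
                              seed = NA_integer_, source_tag = "") {
  codes <- validate_ternary_matrix(codes)
  if (length(labels) != 3L)
    stop("exactly 3 labels are required")
  if (inherits(grouping, "ctp_grouping")) {
    if (!identical(grouping$sample_ids, colnames(codes)))
      stop("grouping does not cover the samples of the ternary matrix")
    sample_labels <- labels[grouping$group_index]
    names(sample_labels) <- grouping$sample_ids
    clustering_method <- clustering_method %||% grouping$method
    if (is.na(seed)) seed <- grouping$seed
  } else {
    if (!all(colnames(codes) %in% names(grouping)))
      stop("grouping is missing sample(s): ",
           paste(setdiff(colnames(codes), names(grouping)), collapse = ", "))
    sample_labels <- as.character(grouping[colnames(codes)])
    names(sample_labels) <- colnames(codes)
    if (!all(sample_labels %in% labels))
      stop("grouping contains label(s) outside ",
           paste(labels, collapse = "/"))
    clustering_method <- clustering_method %||% "predefined"
  }
  centroids <- lapply(labels, function(lab) {
    members <- names(sample_labels)[sample_labels == lab]
    if (!length(members))
      stop("group '", lab, "' is empty; centroids require 3 populated groups")
    rowMeans(codes[, members, drop = FALSE])
  })
  names(centroids) <- labels
  validate_ctp_model(new_ctp_model(
    labels = labels, probe_ids = rownames(codes), centroids = centroids,
    threshold_factor = threshold_factor,
    clustering_method = clustering_method, seed = seed,
    source_tag = source_tag, training_groups = sample_labels
  ))
}

#' Build a CTP model from an expression matrix
#'
#' Full model-building pipeline: per-probe mean-centering, ternary
#' discretization at `threshold_factor` standard deviations, clustering of
#' the sample profiles into three groups (unless a predefined grouping is
#' supplied), and per-group centroid computation. Provenance (threshold,
#' method, seed, source tag) is recorded in the returned model.
#'
#' @inheritParams compute_deviations
#' @inheritParams discretize
#' @inheritParams cluster_ternary
#' @param groups Optional named character vector mapping every sample to a
#'   label in `labels`; when supplied, clustering is skipped (the grouping is
#'   "known a priori", e.g. from an earlier study or planted truth).
#' @param labels Group names, default `c("A", "B", "C")`.
#' @param source_tag Free-text tag identifying the training cohort.
#' @return A validated `ctp_model`.
#' @export
build_model <- function(x, threshold_factor = 0.43,
                        std_mode = c("sample", "population"),
                        method = c("kmeans", "som"), seed = 1L,
                        n_restarts = 10L, groups = NULL,
                        labels = c("A", "B", "C"), source_tag = "") {
  std_mode <- match.arg(std_mode)
  method <- match.arg(method)
  codes <- ternarize(x, threshold_factor, std_mode)
  grouping <- if (is.null(groups)) {
    cluster_ternary(codes, method = method, seed = seed,
                    n_restarts = n_restarts)
  } else {
    groups
  }
  compute_centroids(codes, grouping, labels = labels,
                    threshold_factor = threshold_factor,
                    clustering_method = if (is.null(groups)) method
                                        else "predefined",
                    seed = if (is.null(groups)) seed else NA_integer_,
                    source_tag = source_tag)
}
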