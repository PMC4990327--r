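#' Barycentric weights from three centroid correlations
#'
#' Maps a sample's three CTP correlations onto the 2-simplex via shifted
#' similarities: each correlation r in \[-1, 1\] becomes the similarity
#' 1 + r = 2 - d, where d = 1 - r is the Pearson correlation distance to the
#' centroid, and the three similarities are normalized to sum to one. A
#' sample with uniformly weak correlations (as the model predicts for normal
#' tissue) therefore sits near the triangle center, while a sample strongly
#' correlated with one centroid and anti-correlated with the others
#' approaches that centroid's vertex.
#'
#' @param correlations Numeric vector of three correlations in \[-1, 1\]
#'   (order A, B, C).
#' @return Numeric weight triple, each >= 0, summing to 1. The degenerate
#'   triple (-1, -1, -1) maps to the center (1/3, 1/3, 1/3).
#' @export
to_barycentric <- function(correlations) {
  r <- as.numeric(correlations)
  if (length(r) != 3L || !all(is.finite(r)) || any(r < -1 | r > 1))
    stop("correlations must be three finite values in [-1, 1]")
  s <- 1 + r
  tot <- sum(s)
  if (tot <= 0) return(rep(1 / 3, 3L))
  s / tot
}

# Fixed reference triangle: A lower-left, B lower-right, C top.
DEFINETTI_VERTICES <- matrix(
  c(0, 0,
    1, 0,
    0.5, sqrt(3) / 2),
  nrow = 3L, byrow = TRUE,
  dimnames = list(c("A", "B", "C"), c("x", "y"))
)

#' Cartesian position of a barycentric weight triple
#'
#' Places a weight triple inside the fixed equilateral reference triangle
#' with vertices A = (0, 0), B = (1, 0), C = (0.5, sqrt(3)/2).
#'
#' @param weights Numeric triple of non-negative weights summing to 1.
#' @return Numeric vector `c(x, y)`.
#' @export
to_cartesian <- function(weights) {
  w <- as.numeric(weights)
  if (length(w) != 3L || any(w < -1e-9) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be a non-negative triple summing to 1")
  as.numeric(w %*% DEFINETTI_VERTICES)
}

#' De Finetti mapping of a cohort's CTP assignments
#'
#' Converts each sample's three centroid correlations into barycentric
#' weights and Cartesian coordinates inside the reference triangle,
#' producing a plot-ready table (one row per sample).
#'
#' @param assignments Assignment data frame from [assign_cohort()].
#' @return Data frame with columns `sample_id`, `w_A`, `w_B`, `w_C`, `x`,
#'   `y`, `label`. Weight columns are named after positions in the triangle
#'   (A lower-left, B lower-right, C top), matching the order of the
#'   correlation columns.
#' @export
map_cohort <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  rcols <- grep("^r_", names(assignments), value = TRUE)
  if (length(rcols) != 3L)
    stop("assignments must have exactly three r_<label> columns")
  w <- t(apply(as.matrix(assignments[rcols]), 1L, to_barycentric))
  xy <- w %*% DEFINETTI_VERTICES
  data.frame(sample_id = assignments$sample_id,
             w_A = w[, 1L], w_B = w[, 2L], w_C = w[, 3L],
             x = xy[, 1L], y = xy[, 2L],
             label = assignments$label,
             stringsAsFactors = FALSE)
}

#' Plot a de Finetti mapping
#'
#' Renders the reference triangle with vertex labels and one point per
#' sample, colored by assigned CTP. Requires ggplot2.
#'
#' @param points Data frame from [map_cohort()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_definetti <- function(points, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tri <- data.frame(DEFINETTI_VERTICES[c(1:3, 1), ])
  vl <- data.frame(DEFINETTI_VERTICES,
                   lab = rownames(DEFINETTI_VERTICES))
  nudge <- c(-0.03, 0.03, 0)
  ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1.5,
                        alpha = 0.8) +
    ggplot2::geom_text(data = vl,
                       ggplot2::aes(label = .data$lab),
                       nudge_x = nudge,
                       nudge_y = c(-0.03, -0.03, 0.03)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, colour = "CTP")
}

# Distance of mapped points from the triangle center, as a fraction of the
# center-to-vertex distance. Used by cohort-level diagnostics and tests.
center_distance <- function(points) {
  ctr <- colMeans(DEFINETTI_VERTICES)
  d <- sqrt((points$x - ctr[1])^2 + (points$y - ctr[2])^2)
  d / sqrt(sum((DEFINETTI_VERTICES[1, ] - ctr)^2))
}
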