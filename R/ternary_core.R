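#' Per-probe deviations from the cohort mean
#'
#' For every probe (row) of a normalized log2 expression matrix, computes the
#' mean expression over all samples of the cohort, subtracts it from each
#' sample's value, and records the per-probe standard deviation of the
#' resulting deviations. The deviation of a sample from the cohort mean is the
#' quantity that is subsequently discretized into the three-level profile.
#'
#' @param x Numeric matrix of normalized log2 expression values, probes in
#'   rows (rownames = probe identifiers), samples in columns (colnames =
#'   sample identifiers). See [read_expression_matrix()].
#' @param std_mode Standard-deviation estimator: `"sample"` (n - 1
#'   denominator, the default) or `"population"` (n denominator).
#' @return An object of class `deviation_matrix`: a list with components
#'   `deviations` (matrix, same shape and dimnames as `x`), `probe_mean`
#'   (numeric, per probe), `probe_sigma` (numeric, per probe, >= 0) and
#'   `std_mode`.
#' @details Each probe's deviations sum to zero by construction. A matrix with
#'   fewer than two samples is rejected: the cohort mean and standard
#'   deviation are meaningless for a single sample.
#' @seealso [discretize()], [ternarize()]
#' @examples
#' x <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' d <- compute_deviations(x)
#' d$deviations["p1", ]   # -1 0 1
#' @export
compute_deviations <- function(x, std_mode = c("sample", "population")) {
  std_mode <- match.arg(std_mode)
  x <- validate_expression_matrix(x)
  if (ncol(x) < 2L)
    stop("at least 2 samples are required to compute per-probe deviations")
  mu <- rowMeans(x)
  dev <- x - mu
  n <- ncol(x)
  ss <- rowSums(dev^2)
  sigma <- sqrt(ss / if (std_mode == "sample") n - 1L else n)
  structure(
    list(deviations = dev, probe_mean = mu, probe_sigma = sigma,
         std_mode = std_mode),
    class = "deviation_matrix"
  )
}

#' Ternary discretization of deviation values
#'
#' Discretizes per-probe deviations into the three-level codes -1, 0, +1.
#' For probe g with standard deviation sigma_g, a deviation strictly below
#' `-threshold_factor * sigma_g` is coded -1, strictly above
#' `+threshold_factor * sigma_g` is coded +1, and anything in between
#' (boundaries included) is coded 0. The default cut of 0.43 sigma makes the
#' three codes equally frequent under Gaussian deviations (see
#' [equal_tercile_threshold()]).
#'
#' @param d A `deviation_matrix` from [compute_deviations()].
#' @param threshold_factor Positive scalar, the cut expressed as a fraction of
#'   the per-probe standard deviation. Default 0.43.
#' @return Integer matrix of codes in \{-1, 0, 1\} with the dimnames of the
#'   input.
#' @details Probes with zero standard deviation (constant across the cohort)
#'   are uninformative and receive all-zero codes. Codes are invariant under
#'   adding a constant to a probe's expression row and under scaling it by a
#'   positive constant, since both the deviations and the threshold scale
#'   together.
#' @export
discretize <- function(d, threshold_factor = 0.43) {
  if (!inherits(d, "deviation_matrix"))
    stop("'d' must be a deviation_matrix (see compute_deviations)")
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      !is.finite(threshold_factor) || threshold_factor <= 0)
    stop("'threshold_factor' must be a single positive number")
  cut <- threshold_factor * d$probe_sigma        # per-probe threshold
  codes <- (d$deviations > cut) - (d$deviations < -cut)
  storage.mode(codes) <- "integer"
  dimnames(codes) <- dimnames(d$deviations)
  codes
}

#' Mean-center and discretize an expression matrix
#'
#' Convenience composition of [compute_deviations()] and [discretize()]:
#' turns a normalized log2 expression matrix directly into the ternary
#' profile matrix that all downstream clustering and assignment operates on.
#'
#' @inheritParams compute_deviations
#' @inheritParams discretize
#' @return Integer matrix of codes in \{-1, 0, 1\}.
#' @export
ternarize <- function(x, threshold_factor = 0.43,
                      std_mode = c("sample", "population")) {
  discretize(compute_deviations(x, std_mode = std_mode), threshold_factor)
}

#' Equal-tercile discretization threshold
#'
#' The threshold z* (as a multiple of sigma) at which a centered Gaussian
#' deviation falls into each of the three codes with equal probability 1/3:
#' the standard-normal quantile at 2/3. Rounded to two decimals this is 0.43,
#' the package-wide default `threshold_factor`.
#'
#' @return The quantile `qnorm(2/3)`, approximately 0.4307.
#' @export
equal_tercile_threshold <- function() {
  stats::qnorm(2 / 3)
}

# Shared input validation: numeric matrix, unique dimnames, finite values.
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (", what, ")")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty ", what, ": ", nrow(x), " probes x ", ncol(x), " samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry probe rownames and sample colnames")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    stop("duplicate probe identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value at probe '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'")
  }
  x
}

# Validation for ternary code matrices.
validate_ternary_matrix <- function(codes) {
  codes <- validate_expression_matrix(codes, what = "ternary matrix")
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("ternary matrix entries must be -1, 0 or +1")
  storage.mode(codes) <- "integer"
  codes
}
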