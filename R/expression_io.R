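#' Read an expression matrix from delimited text
#'
#' Reads a probes-by-samples matrix of normalized log2 expression values. The
#' first row is the sample header, the first column holds probe identifiers,
#' and the body is numeric. Row and column order are preserved exactly as in
#' the file.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @param transpose If `TRUE`, the file is stored samples-in-rows and is
#'   transposed on read so that the in-memory convention (probes in rows) is
#'   preserved.
#' @param impute_row_mean If `TRUE`, missing cells (NA) are replaced by the
#'   probe's mean over the non-missing samples, which maps them to deviation
#'   zero — the neutral ternary state. By default missing values are an error.
#' @return Numeric matrix, probes in rows, samples in columns.
#' @details Duplicated probe or sample identifiers and non-numeric cells are
#'   hard errors naming the offending identifier or coordinate; rows and
#'   columns are never silently dropped.
#' @export
read_expression_matrix <- function(path, delimiter = "\t", transpose = FALSE,
                                   impute_row_mean = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression matrix in ", path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate probe identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body) &
                 !(toupper(trimws(body)) %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at probe '", ids[bad[1L, 1L]], "', sample '",
         colnames(body)[bad[1L, 2L]], "': '",
         body[bad[1L, 1L], bad[1L, 2L]], "'")
  dimnames(vals) <- list(ids, colnames(body))
  if (transpose) vals <- t(vals)
  if (anyNA(vals)) {
    if (!impute_row_mean) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value at probe '", rownames(vals)[bad[1L]],
           "', sample '", colnames(vals)[bad[2L]],
           "' (use impute_row_mean = TRUE to impute to the probe mean)")
    }
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1L]]
  }
  validate_expression_matrix(vals)
}

#' Write an expression (or ternary) matrix as delimited text
#'
#' Writes the matrix in the same layout [read_expression_matrix()] reads:
#' sample header row, probe identifiers in the first column. The round trip
#' write-then-read reproduces identifiers and values exactly.
#'
#' @param x Numeric matrix with probe rownames and sample colnames.
#' @param path Output file path.
#' @param delimiter Field delimiter, default tab.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  x <- validate_expression_matrix(x)
  # 17 significant digits: doubles survive the text round trip bitwise
  body <- if (is.integer(x)) x else
    array(formatC(x, digits = 17, format = "g"), dim = dim(x))
  df <- data.frame(probe_id = rownames(x), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene subset from a plain-text list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. Duplicated identifiers are collapsed with a warning. Membership is
#' order-independent.
#'
#' @param path Path to the list file.
#' @param name Label for the subset; defaults to the file name without
#'   extension.
#' @return A list of class `gene_subset` with components `ids` (character)
#'   and `name`.
#' @export
read_gene_subset <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("gene subset file ", path, " contains no identifiers")
  dup <- unique(lines[duplicated(lines)])
  if (length(dup))
    warning("duplicate identifier(s) collapsed: ", paste(dup, collapse = ", "))
  structure(
    list(ids = unique(lines),
         name = name %||% sub("\\.[^.]*$", "", basename(path))),
    class = "gene_subset"
  )
}

CTP_MODEL_SCHEMA_VERSION <- 1L

#' Write a CTP model to JSON
#'
#' Serializes the three centroid target vectors together with their probe
#' order and provenance (threshold factor, clustering method, seed, source
#' tag, and — when available — the training-sample grouping) as a single
#' versioned JSON document. The round trip through [read_ctp_model()] is
#' lossless.
#'
#' @param model A `ctp_model`, see [compute_centroids()] / [build_model()].
#' @param path Output file path.
#' @export
write_ctp_model <- function(model, path) {
  model <- validate_ctp_model(model)
  doc <- list(
    schema_version = CTP_MODEL_SCHEMA_VERSION,
    labels = model$labels,
    probe_ids = model$probe_ids,
    centroids = model$centroids,
    threshold_factor = model$threshold_factor,
    clustering_method = model$clustering_method,
    seed = model$seed,
    source_tag = model$source_tag
  )
  if (!is.null(model$training_groups))
    doc$training_groups <- as.list(model$training_groups)
  # 17 significant digits: centroid doubles survive the round trip bitwise
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a CTP model from JSON
#'
#' @param path Path to a model file written by [write_ctp_model()].
#' @return A validated `ctp_model`.
#' @export
read_ctp_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("truncated or malformed CTP model file ", path,
                         ": ", conditionMessage(e)))
  if (is.null(doc$schema_version) ||
      doc$schema_version != CTP_MODEL_SCHEMA_VERSION)
    stop("CTP model schema version mismatch in ", path, ": found '",
         doc$schema_version %||% "<missing>", "', expected ",
         CTP_MODEL_SCHEMA_VERSION)
  tg <- if (!is.null(doc$training_groups)) {
    unlist(doc$training_groups)
  }
  seed <- doc$seed
  if (is.null(seed) || !is.numeric(seed)) seed <- NA_integer_
  model <- new_ctp_model(
    labels = as.character(doc$labels),
    probe_ids = as.character(doc$probe_ids),
    centroids = lapply(doc$centroids, as.numeric),
    threshold_factor = doc$threshold_factor,
    clustering_method = doc$clustering_method %||% "predefined",
    seed = seed,
    source_tag = doc$source_tag %||% "",
    training_groups = tg
  )
  validate_ctp_model(model)
}

#' Write a table of CTP assignments
#'
#' TSV with columns `sample_id`, `label`, `r_A`, `r_B`, `r_C`, `margin`,
#' `tie` (correlation columns named after the model labels).
#'
#' @param assignments Data frame from [assign_cohort()].
#' @param path Output file path.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(is.data.frame(assignments))
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a table of CTP assignments
#'
#' @param path Path written by [write_assignments()].
#' @return Data frame with one row per sample.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
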