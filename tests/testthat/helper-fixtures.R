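# Shared fixtures, built in code.

# Small expression matrix with known values.
tiny_matrix <- function() {
  matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
         dimnames = list(paste0("p", 1:3), paste0("s", 1:2)))
}

# Three mutually distinct (pairwise non-identical, mutually low-correlation)
# ternary prototypes over n_probes, cycling rotations of (1, 0, -1).
ternary_prototypes <- function(n_probes = 30L) {
  rot <- (seq_len(n_probes) - 1L) %% 3L + 1L
  pat <- rbind(A = c(1, -1, 0), B = c(0, 1, -1), C = c(-1, 0, 1))
  sapply(c("A", "B", "C"), function(g) pat[g, rot])
}

# Zero-noise cohort: n_per exact copies of each prototype column.
prototype_cohort <- function(n_per = 10L, n_probes = 30L) {
  proto <- ternary_prototypes(n_probes)
  codes <- proto[, rep(1:3, each = n_per)]
  labels <- rep(c("A", "B", "C"), each = n_per)
  colnames(codes) <- paste0("s", seq_len(3L * n_per))
  rownames(codes) <- paste0("p", seq_len(n_probes))
  storage.mode(codes) <- "integer"
  list(codes = codes, labels = stats::setNames(labels, colnames(codes)))
}

# A standard well-separated planted cohort used across tests.
standard_planted <- function(seed = 7L, ...) {
  generate_planted_cohort(n_samples = 90L, n_probes = 600L,
                          signal_fraction = 0.3, effect_size = 3,
                          seed = seed, ...)
}

# Independent Pearson oracle from the raw covariance/sd formula.
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

labels_of <- function(assignments)
  stats::setNames(assignments$label, assignments$sample_id)
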