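test_that("cluster diameter is the mean winning correlation per label", {
  m <- new_ctp_model(labels = c("A", "B", "C"), probe_ids = paste0("p", 1:3),
                     centroids = list(A = c(1, 0, -1), B = c(-1, 0, 1),
                                      C = c(0, 1, -1)))
  a <- data.frame(sample_id = paste0("s", 1:3),
                  label = c("A", "A", "B"),
                  r_A = c(0.4, 0.5, -0.2),
                  r_B = c(0.1, 0.0, 0.3),
                  r_C = c(-0.1, 0.2, 0.1))
  rep <- cluster_diameter(a, m)
  expect_equal(rep$mean_correlation[rep$label == "A"], 0.45)
  expect_equal(rep$mean_correlation[rep$label == "B"], 0.3)  # single member
  expect_true(is.na(rep$mean_correlation[rep$label == "C"]))  # empty: NA not 0
  expect_equal(rep$n, c(2L, 1L, 0L))
})

test_that("a cohort of exact centroid copies has diameter 1 per label", {
  pc <- prototype_cohort(n_per = 4, n_probes = 30)
  m <- compute_centroids(pc$codes, pc$labels)
  a <- do.call(rbind, lapply(colnames(pc$codes), function(s) {
    r <- assign_sample(pc$codes[, s], m, min_common_probes = 30)
    r$sample_id <- s
    r
  }))
  rep <- cluster_diameter(a, m)
  expect_equal(rep$mean_correlation, rep(1, 3), tolerance = 1e-12)
})

test_that("planted cohorts have larger diameters than noise cohorts", {
  for (i in 1:5) {
    pc <- generate_planted_cohort(n_samples = 60, n_probes = 1000,
                                  seed = 600 + i)
    m <- build_model(pc$x, seed = i)
    dp <- cluster_diameter(assign_cohort(pc$x, m), m)
    noise <- generate_noise_cohort(60, 1000, seed = 700 + i)
    mn <- build_model(noise, seed = i)
    dn <- cluster_diameter(assign_cohort(noise, mn), mn)
    expect_true(all(dp$mean_correlation > dn$mean_correlation))
  }
})

test_that("diameter comparison matches the closed-form Welch t oracle", {
  g1 <- c(0.10, 0.11, 0.09, 0.12, 0.10, 0.08, 0.11, 0.09)
  g2 <- c(0.45, 0.43, 0.47, 0.44, 0.46, 0.42, 0.48, 0.45)
  res <- compare_diameters(g1, g2)
  # closed-form Welch statistic and Welch-Satterthwaite df
  se2 <- var(g1) / 8 + var(g2) / 8
  tstat <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((var(g1) / 8)^2 / 7 + (var(g2) / 8)^2 / 7)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  # swapping groups flips the sign, p unchanged
  swapped <- compare_diameters(g2, g1)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  # null case: identical groups (jittered to avoid degeneracy)
  gj <- g1 + c(1e-6, -1e-6, 0, 0, 0, 0, 0, 0)
  null <- compare_diameters(g1, gj)
  expect_gt(null$p_value, 0.99)
  expect_lt(abs(null$statistic), 0.01)
  expect_error(compare_diameters(rep(0.1, 4), rep(0.1, 4)), "degenerate")

  # rank-sum alternative is also computed
  expect_lt(compare_diameters(g1, g2, test = "wilcoxon")$p_value, 0.001)
})

test_that("the identity subset reproduces full-model labels exactly", {
  pc <- standard_planted()
  m <- build_model(pc$x, seed = 1)
  rep <- subset_robustness(pc$x, m, subset = rownames(pc$x))
  expect_equal(rep$similarity, 100)
  expect_identical(rep$subset_size, length(rownames(pc$x)))
})

test_that("random 700-probe subsets keep assignments stable on a planted cohort", {
  pc <- generate_planted_cohort(n_samples = 90, n_probes = 2000, seed = 7)
  m <- build_model(pc$x, seed = 1)
  rep <- subset_robustness(pc$x, m, size = 700, n_replicates = 20, seed = 2)
  expect_gte(rep$similarity, 80)
  expect_length(rep$replicates, 20)
  expect_true(all(rep$replicates >= 0 & rep$replicates <= 100))

  # two disjoint equal-size subsets give similar similarities
  set.seed(31)
  ids <- sample(rownames(pc$x))
  s1 <- subset_robustness(pc$x, m, subset = ids[1:700])$similarity
  s2 <- subset_robustness(pc$x, m, subset = ids[701:1400])$similarity
  expect_lt(abs(s1 - s2), 15)
})

test_that("subset robustness is non-decreasing in subset size (medians over seeds)", {
  pc <- generate_planted_cohort(n_samples = 60, n_probes = 500,
                                effect_size = 1, seed = 17)
  m <- build_model(pc$x, seed = 1)
  sizes <- c(50, 100, 400, 500)
  med <- vapply(sizes, function(sz) {
    if (sz == nrow(pc$x))
      return(subset_robustness(pc$x, m, subset = rownames(pc$x))$similarity)
    median(vapply(1:10, function(i)
      subset_robustness(pc$x, m, size = sz, n_replicates = 1,
                        seed = 40 + i)$similarity, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-9))
})

test_that("subset robustness validates its inputs", {
  pc <- standard_planted()
  m <- build_model(pc$x, seed = 1)
  expect_error(subset_robustness(pc$x, m, subset = c("nope1", "nope2")),
               "no probes in common")
  expect_warning(
    rep <- subset_robustness(pc$x, m,
                             subset = c(rownames(pc$x)[1:50], "nope")),
    "absent")
  expect_equal(rep$subset_size, 50L)
  m_bare <- new_ctp_model(labels = m$labels, probe_ids = m$probe_ids,
                          centroids = m$centroids)
  expect_error(subset_robustness(pc$x, m_bare, size = 100),
               "training_groups")
})
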