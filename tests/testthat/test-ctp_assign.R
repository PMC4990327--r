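toy_model <- function() {
  new_ctp_model(labels = c("A", "B", "C"), probe_ids = paste0("p", 1:3),
                centroids = list(A = c(1, 0, -1), B = c(-1, 0, 1),
                                 C = c(0, 1, -1)))
}

test_that("a profile identical to a centroid is assigned to it with r = 1", {
  m <- toy_model()
  prof <- c(p1 = 1, p2 = 0, p3 = -1)
  res <- assign_sample(prof, m, min_common_probes = 3)
  expect_identical(res$label, "A")
  expect_equal(res$r_A, 1)
  expect_equal(res$margin, res$r_A - max(res$r_B, res$r_C))
  expect_false(res$tie)

  # negation of centroid B anti-correlates perfectly with B
  res2 <- assign_sample(-c(p1 = -1, p2 = 0, p3 = 1), m,
                        min_common_probes = 3)
  expect_equal(res2$r_B, -1)
  expect_identical(res2$label, "A")   # r_A = 1 for this profile too
})

test_that("correlations match an independent covariance/sd oracle", {
  set.seed(8)
  ids <- paste0("p", 1:200)
  m <- new_ctp_model(
    labels = c("A", "B", "C"), probe_ids = ids,
    centroids = lapply(stats::setNames(1:3, c("A", "B", "C")),
                       function(i) round(runif(200, -1, 1), 3)))
  for (rep in 1:5) {
    prof <- stats::setNames(sample(c(-1, 0, 1), 200, replace = TRUE), ids)
    res <- assign_sample(prof, m, min_common_probes = 100)
    for (lab in c("A", "B", "C"))
      expect_equal(res[[paste0("r_", lab)]],
                   pearson_oracle(prof, m$centroids[[lab]]),
                   tolerance = 1e-12)
  }
})

test_that("degenerate correlations and thin probe overlap are errors", {
  m <- toy_model()
  expect_error(assign_sample(c(p1 = 0, p2 = 0, p3 = 0), m,
                             min_common_probes = 3), "constant")
  expect_error(assign_sample(c(p1 = 1, p2 = -1), m, min_common_probes = 3),
               "2 probes shared")
  mc <- new_ctp_model(labels = c("A", "B", "C"), probe_ids = paste0("p", 1:3),
                      centroids = list(A = c(0, 0, 0), B = c(-1, 0, 1),
                                       C = c(0, 1, -1)))
  expect_error(assign_sample(c(p1 = 1, p2 = 0, p3 = -1), mc,
                             min_common_probes = 3), "'A'")
})

test_that("self-assignment reproduces training groups on planted cohorts", {
  pc <- standard_planted()
  m <- build_model(pc$x, seed = 2)
  a <- assign_cohort(pc$x, m)
  rep <- overlap(m$training_groups, labels_of(a))
  expect_gte(rep$agreement_fraction, 0.9)
  expect_gte(overlap(pc$labels, labels_of(a))$agreement_fraction, 0.9)
})

test_that("pure-noise samples assign weakly and spread over all labels", {
  x <- generate_noise_cohort(n_samples = 60, n_probes = 10000, seed = 12)
  m <- build_model(x, seed = 3)
  a <- assign_cohort(x, m)
  expect_setequal(unique(a$label), c("A", "B", "C"))
  winning <- apply(as.matrix(a[paste0("r_", m$labels)]), 1, max)
  expect_lt(mean(winning), 0.25)
})

test_that("assignment is invariant to probe order and per-probe offsets", {
  pc <- standard_planted()
  m <- build_model(pc$x, seed = 2)
  a <- assign_cohort(pc$x, m)

  perm <- sample(nrow(pc$x))
  a_perm <- assign_cohort(pc$x[perm, ], m)
  expect_equal(a_perm, a, tolerance = 1e-12)

  shifted <- sweep(pc$x, 1, rnorm(nrow(pc$x)), "+")
  a_shift <- assign_cohort(shifted, m)
  expect_identical(a_shift$label, a$label)
  expect_equal(a_shift$margin, a$margin, tolerance = 1e-12)
})

test_that("overlap maximizes agreement over the six label permutations", {
  gold <- stats::setNames(c("A", "A", "B", "B", "C", "C"), paste0("s", 1:6))
  expect_equal(overlap(gold, gold)$agreement_fraction, 1)

  swapped <- stats::setNames(c("B", "B", "A", "A", "C", "C"), paste0("s", 1:6))
  rep <- overlap(gold, swapped)
  expect_equal(rep$agreement_fraction, 1)
  expect_identical(unname(rep$permutation[c("A", "B")]), c("B", "A"))

  test <- stats::setNames(c("A", "A", "B", "B", "C", "A"), paste0("s", 1:6))
  rep2 <- overlap(gold, test)
  # exhaustive oracle over all 6 permutations
  perms <- list(c("A","B","C"), c("A","C","B"), c("B","A","C"),
                c("B","C","A"), c("C","A","B"), c("C","B","A"))
  best <- max(vapply(perms, function(p) {
    map <- stats::setNames(p, c("A", "B", "C"))
    mean(map[test] == gold)
  }, numeric(1)))
  expect_equal(rep2$agreement_fraction, best)
  expect_equal(rep2$agreement_fraction, 5 / 6)

  # symmetry
  expect_equal(overlap(test, gold)$agreement_fraction,
               rep2$agreement_fraction)
  expect_error(overlap(gold, test[-1]), "s1")
})

test_that("reverse transfer recovers planted structure and not noise", {
  pc <- standard_planted()
  rt <- reverse_transfer(pc$x, pc$x, pc$labels, seed = 6)
  expect_gte(rt$report$agreement_fraction, 0.95)

  # deterministic given seed
  rt2 <- reverse_transfer(pc$x, pc$x, pc$labels, seed = 6)
  expect_identical(rt2$report$agreement_fraction,
                   rt$report$agreement_fraction)
  expect_identical(rt2$assignments$label, rt$assignments$label)

  # a noise-built model transfers no structure (about chance level)
  agree <- vapply(1:5, function(i) {
    noise <- generate_noise_cohort(60, nrow(pc$x), seed = 100 + i)
    rownames(noise) <- rownames(pc$x)
    reverse_transfer(noise, pc$x, pc$labels,
                     seed = i)$report$agreement_fraction
  }, numeric(1))
  expect_lt(mean(agree), 0.6)
})

test_that("agreement with planted labels rises with signal fraction", {
  med <- vapply(c(0.02, 0.1, 0.3), function(sf) {
    vals <- vapply(1:5, function(i) {
      pc <- generate_planted_cohort(n_samples = 60, n_probes = 400,
                                    signal_fraction = sf, effect_size = 1.5,
                                    seed = 300 + i)
      m <- build_model(pc$x, seed = i)
      overlap(pc$labels, labels_of(assign_cohort(pc$x, m)))$agreement_fraction
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
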