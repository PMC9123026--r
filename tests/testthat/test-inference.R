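test_that("permutation test: identical samples give base 0 and p = 1", {
  s <- sample_von_mises_torus(von_mises_spec(), 30, seed = 1)
  pt <- permutation_test(s, s, K = 25, seed = 2)
  expect_equal(pt$base_statistic, 0)
  expect_equal(pt$eta, 25L)
  expect_equal(pt$p_value, 1)
})

test_that("well-separated clusters reach the analytic p-value floor", {
  x <- sample_von_mises_torus(von_mises_spec(c(-60, -45), 5, 5), 200, seed = 1)
  y <- sample_von_mises_torus(von_mises_spec(c(120, 135), 5, 5), 200, seed = 2)
  pt <- permutation_test(x, y, K = 99, seed = 3)
  expect_equal(pt$p_value, 1 / 100)
  expect_equal(pt$eta, 0L)
  # the floor 1/(1+K) is never undercut
  expect_gte(pt$p_value, 1 / (1 + pt$K))
})

test_that("permutation test is seed-reproducible and validates input", {
  s <- sample_von_mises_torus(von_mises_spec(), 24, seed = 5)
  a <- permutation_test(s[1:12, ], s[13:24, ], K = 30, seed = 9)
  b <- permutation_test(s[1:12, ], s[13:24, ], K = 30, seed = 9)
  expect_identical(a$permuted, b$permuted)
  expect_error(permutation_test(s[0, , drop = FALSE], s, K = 5), "non-empty")
})

test_that("null p-values are roughly uniform over repeated small trials", {
  spec <- von_mises_spec()
  p <- vapply(1:60, function(i) {
    x <- sample_von_mises_torus(spec, 40, seed = 1000 + i)
    y <- sample_von_mises_torus(spec, 40, seed = 5000 + i)
    permutation_test(x, y, K = 39, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
})

test_that("equalized sample size is the capped group minimum", {
  expect_equal(equalized_sample_size(c(500, 120, 300, 250)), 120L)
  expect_equal(equalized_sample_size(c(500, 220, 300, 250)), 200L)
  expect_equal(equalized_sample_size(37), 37L)
  expect_error(equalized_sample_size(c(10, 0)), "zero")
})

test_that("bootstrap aggregation pools B * K permutations", {
  s <- sample_von_mises_torus(von_mises_spec(), 12, seed = 3)
  fit <- bootstrap_pair_test(s, s, N = 12, B = 25, K = 200, seed = 4)
  expect_equal(fit$B * fit$K + 1L, 5001L)
  expect_equal(fit$p_value, (1 + fit$eta_total) / 5001)
  expect_gte(fit$p_value, 1 / 5001)
  expect_length(fit$per_bootstrap, 25L)
})

test_that("B = 1 reduces to one bootstrap round plus one permutation test", {
  x <- sample_von_mises_torus(von_mises_spec(), 20, seed = 6)
  y <- rotate_sample(x, c(15, 0))
  fit <- bootstrap_pair_test(x, y, N = 10, B = 1, K = 50, seed = 7)
  expect_length(fit$per_bootstrap, 1L)
  expect_equal(fit$p_value, (1 + fit$per_bootstrap[[1]]$eta) / 51)
  expect_equal(fit$mean_distance, fit$per_bootstrap[[1]]$base_statistic)
  # resampling is with replacement, so N above the pool size is legal
  expect_no_error(bootstrap_pair_test(x, y, N = 40, B = 1, K = 5, seed = 8))
})

test_that("self-comparisons do not produce spuriously small p-values", {
  s <- sample_von_mises_torus(von_mises_spec(), 150, seed = 11)
  p <- vapply(1:10, function(i)
    bootstrap_pair_test(s, s, N = 60, B = 2, K = 30,
                        seed = 100 + i)$p_value, numeric(1))
  expect_gt(median(p), 0.2)
  expect_gt(min(p), 1 / 61)
})

test_that("BH procedure follows the strict printed rejection rule", {
  p <- c(0.001, 0.002, 0.003, 0.9)
  dec <- bh_procedure(p, q = 0.05)
  expect_equal(dec$i0, 3L)
  expect_equal(dec$alpha_M, 0.003)
  expect_equal(sum(dec$reject), 2L)
  expect_equal(dec$rejected, c("1", "2"))
  # textbook step-up keeps the threshold p-value itself
  expect_equal(sum(bh_procedure(p, q = 0.05, textbook = TRUE)$reject), 3L)
  expect_equal(sum(bh_procedure(rep(1, 10), q = 0.05)$reject), 0L)
  expect_error(bh_procedure(numeric(0)), "non-empty")
  expect_error(bh_procedure(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("BH rejections grow monotonically with q", {
  set.seed(13)
  p <- c(runif(20, 0, 0.01), runif(30))
  r <- vapply(c(0.01, 0.05, 0.1), function(q)
    sum(bh_procedure(p, q = q)$reject), numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("BH agrees with a brute-force scan on random p-vectors", {
  set.seed(17)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    dec <- bh_procedure(p, q = 0.05)
    ref <- brute_bh(p, 0.05)
    expect_equal(dec$reject, ref$reject)
    if (dec$i0 > 0) expect_equal(dec$alpha_M, ref$alpha)
  }
})

test_that("distance-matrix normalization fixes the diagonal at one", {
  raw <- matrix(c(0.04, 0.10, 0.10, 0.09), 2)
  nm <- normalize_distance_matrix(raw)
  expect_equal(diag(nm), c(1, 1))
  expect_equal(nm[1, 2], 0.10 / sqrt(0.04 * 0.09))
  expect_equal(nm[1, 2], 1.666667, tolerance = 1e-6)
  expect_equal(normalize_distance_matrix(3.7 * raw), nm)
  expect_error(normalize_distance_matrix(matrix(c(0, 1, 1, 1), 2)),
               "positive")
  expect_error(normalize_distance_matrix(matrix(1, 2, 3)), "square")
})

test_that("pairwise harness enumerates self and synonymous tests per group", {
  # a two-codon amino acid alone: 2 self + 1 pair = 3 tests
  obs <- synthetic_codon_dataset(n_per_codon = 10, ss_classes = "E", seed = 2)
  obs <- obs[obs$codon %in% c("AAA", "AAG"), ]
  cfg <- default_config(b_test = 1L, k_perm = 3L, n_max = 10L)
  res <- suppressWarnings(run_all_pairwise_tests(obs, cfg, ss_classes = "E"))
  expect_equal(nrow(res$results), 3L)
  expect_equal(sum(res$results$codon_a == res$results$codon_b), 2L)
  expect_equal(res$fdr$E$M, 3L)
  # normalized self-distance is exactly 1
  self <- res$results$codon_a == res$results$codon_b
  expect_equal(res$results$normalized_distance[self], c(1, 1))
})

test_that("an incompletely observed codon group is skipped with a warning", {
  obs <- synthetic_codon_dataset(n_per_codon = 10, ss_classes = "E", seed = 3)
  obs <- obs[obs$codon %in% c("AAA", "TGG"), ]  # K missing AAG; W complete
  cfg <- default_config(b_test = 1L, k_perm = 3L, n_max = 10L)
  expect_warning(res <- run_all_pairwise_tests(obs, cfg, ss_classes = "E"),
                 "AAG")
  expect_equal(nrow(res$results), 1L)          # W self-test only
  expect_equal(res$results$codon_a, "TGG")
  expect_true("K" %in% res$skipped$amino_acid[res$skipped$reason == "partial"])
})
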