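test_that("classification constants derive from the kinship coefficients", {
  th <- degree_thresholds()
  expect_equal(unname(th$expected),
               c(0.5, 0.75, 0.875, 0.9375, 1))
  # interior cutoffs are midpoints of adjacent expectations
  expect_equal(th$cutoffs[1:3], c(0.625, 0.8125, 0.90625))
  expect_equal(th$cutoffs[3], (0.875 + 0.9375) / 2)
  # the upper third-degree bound is the fixed conservative constant
  expect_equal(th$cutoffs[4], 0.953125)
  expect_true(all(diff(th$cutoffs) > 0))
})

test_that("normalization uses median/mean/user with small-dataset warning", {
  pt <- data.frame(p0 = c(0.25, 0.19, 0.24, 0.26))
  expect_warning(nm <- compute_normalization(pt), "only 4")
  expect_equal(nm$value, 0.245)
  expect_warning(expect_equal(compute_normalization(pt, "mean")$value,
                              mean(pt$p0)))
  u <- compute_normalization(pt, "user", user_value = 0.2488)
  expect_equal(u$value, 0.2488)
  expect_error(compute_normalization(data.frame(p0 = numeric(0))),
               "no pairs")
  expect_error(compute_normalization(pt, "user"), "positive user_value")
  # technical-replicate workflow: 2 x duplicate-pair P0 as the baseline
  expect_equal(compute_normalization(pt, "user",
                                     user_value = 2 * 0.123)$value, 0.246)
})

test_that("expected mismatches is overlap times the baseline", {
  nm <- compute_normalization(data.frame(p0 = NA), "user",
                              user_value = 0.247)
  expect_equal(expected_mismatches(1878, nm), 463.866)
  expect_equal(expected_mismatches(0, nm), 0)
  # inverting the subtype gate at a typical ancient-DNA baseline
  expect_equal(expected_mismatches(40816, 0.245), 10000, tolerance = 1e-4)
})

test_that("degree intervals are half-open with a gated third degree", {
  th <- degree_thresholds()
  expect_equal(classify_degree(0.49, 1e6), "IdenticalTwin")
  expect_equal(classify_degree(0.75, 1e6), "FirstDegree")
  expect_equal(classify_degree(0.93, 5000), "ThirdDegree")
  expect_equal(classify_degree(0.93, 2500), "Unrelated_consistent_with_3rd")
  expect_equal(classify_degree(1.02, 1e6), "Unrelated")
  # left-closed boundaries
  expect_equal(classify_degree(c(0.625, 0.8125, 0.90625, 0.953125), 1e6),
               c("FirstDegree", "SecondDegree", "ThirdDegree", "Unrelated"))
  # monotone step function of normalized P0 at fixed expected mismatches
  x <- seq(0, 1.2, by = 0.001)
  k <- match(classify_degree(x, 1e6),
             c("IdenticalTwin", "FirstDegree", "SecondDegree",
               "ThirdDegree", "Unrelated"))
  expect_true(all(diff(k) >= 0))
})

test_that("window classes use the same intervals without a gate", {
  expect_equal(window_class(c(0.55, 1.0, 0.92, 0.75, 0.85)),
               c("identical", "unrelated", "third", "first", "second"))
})

test_that("k0+k2 proportion counts identical/third/unrelated windows", {
  nm <- compute_normalization(data.frame(p0 = NA), "user", user_value = 0.25)
  mkw <- function(p0) data.frame(chrom = 1L,
                                 window_start_bp = seq_along(p0),
                                 window_size_bp = 20e6,
                                 overlap_n = 100, p0 = p0)
  # pure one-chromosome sharing everywhere -> 0
  expect_equal(k02_proportion(mkw(rep(0.75 * 0.25, 10)), nm), 0)
  # half identical, half unrelated -> 1
  expect_equal(k02_proportion(mkw(rep(c(0.5, 1) * 0.25, 5)), nm), 1)
  expect_warning(p <- k02_proportion(mkw(0.2)[0, ], nm), "no windows")
  expect_true(is.na(p))
  # third-degree windows are excluded when toggled off
  th2 <- degree_thresholds(count_third_in_k02 = FALSE)
  expect_equal(k02_proportion(mkw(rep(0.92 * 0.25, 4)), nm, th2), 0)
  expect_equal(k02_proportion(mkw(rep(0.92 * 0.25, 4)), nm), 1)
})

test_that("subtype calls respect the proportion bands and the data gate", {
  expect_equal(classify_subtype(0.10, 20000), "ParentOffspring")
  expect_equal(classify_subtype(0.50, 20000), "Siblings")
  expect_equal(classify_subtype(0.50, 8000), "NotApplicable")
  expect_equal(classify_subtype(0.32, 20000), "NotApplicable")
  expect_equal(classify_subtype(0.70, 20000), "NotApplicable")
  expect_equal(classify_subtype(c(0.35, 0.60), 20000),
               c("Siblings", "Siblings"))
  # the gate is monotone: lowering data never upgrades a call
  for (p in c(0.1, 0.5))
    expect_equal(classify_subtype(p, 9999), "NotApplicable")
})

test_that("theta and its CI follow from the normalized P0", {
  nm <- compute_normalization(data.frame(p0 = NA), "user", user_value = 0.25)
  tc <- theta_with_ci(c(0.125, 0.25, 0.25 * 0.9375), c(0.01, 0, 0.002), nm)
  expect_equal(tc$theta, c(0.5, 0, 0.0625))
  expect_equal(tc$ci_high - tc$ci_low, 2 * 1.96 * c(0.01, 0, 0.002) / 0.25)
  # identity: theta + normalized P0 = 1
  p0 <- runif(20, 0.1, 0.3)
  expect_equal(theta_with_ci(p0, 0, nm)$theta + p0 / 0.25, rep(1, 20))
})

test_that("the full classifier recovers a small pedigree end-to-end", {
  cfg <- tiny_sim_config(n_snps = 8000, coverage = 5, error_rate = 0.002,
                         counts = c(parent_offspring = 2, unrelated = 8),
                         seed = 202)
  sim <- simulate_dataset(cfg)
  calls <- run_classifier(sim$dataset)
  tr <- merge(calls, sim$truth, by = c("sample_a", "sample_b"))
  expect_equal(nrow(tr), nrow(calls))
  first <- tr$true_degree == "first"
  expect_true(all(tr$degree[first] == "FirstDegree"))
  expect_true(mean(tr$degree[!first] %in%
                     c("Unrelated", "Unrelated_consistent_with_3rd")) > 0.95)
  # theta/CI internal consistency on every pair
  expect_equal(tr$theta + tr$normalized_p0, rep(1, nrow(tr)))
  ok <- !is.na(tr$se_normalized)
  expect_equal(tr$theta_ci_high[ok] - tr$theta_ci_low[ok],
               2 * 1.96 * tr$se_normalized[ok])
  # subtype attempted only for first-degree pairs; em ~ 8000*0.25 < 10000
  expect_true(all(tr$subtype[!first] == "NotAttempted"))
  expect_true(all(tr$subtype[first] == "NotApplicable"))
})

test_that("classifier output is deterministic and exports a results TSV", {
  cfg <- tiny_sim_config(n_snps = 2000, coverage = 1,
                         counts = c(unrelated = 5), seed = 17)
  c1 <- run_classifier(simulate_dataset(cfg)$dataset)
  c2 <- run_classifier(simulate_dataset(cfg)$dataset)
  expect_identical(c1, c2)
  path <- file.path(withr::local_tempdir(), "results.tsv")
  write_kinship_tsv(c1, path, seed = 17)
  head2 <- readLines(path, n = 3)
  expect_match(head2[1], "^# kinmatch")
  expect_match(head2[2], "seed: 17")
  expect_match(head2[2], "normalization: 0\\.[0-9]{6}")
  tab <- read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), choose(5, 2))
  expect_equal(names(tab)[1:3],
               c("PairIndividual1", "PairIndividual2", "OverlapNSNPs"))
})
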