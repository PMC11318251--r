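# brute-force oracle: average mismatch over all ordered allele draws from
# each genotype (dosage 0 -> {a1,a1}, 0.5 -> {a1,a2}, 1 -> {a2,a2})
enumerated_mismatch <- function(d1, d2) {
  alleles <- function(d) switch(as.character(d), "0" = c(0, 0),
                                "0.5" = c(0, 1), "1" = c(1, 1))
  g1 <- alleles(d1)
  g2 <- alleles(d2)
  mean(outer(g1, g2, "!="))
}

test_that("closed-form site mismatch equals allele-pair enumeration on all 9 pairs", {
  for (d1 in c(0, 0.5, 1)) for (d2 in c(0, 0.5, 1))
    expect_equal(site_mismatch(d1, d2), enumerated_mismatch(d1, d2),
                 info = paste(d1, d2))
  # the half-mismatch rule: a heterozygote against anything is 1/2
  expect_equal(site_mismatch(0.5, c(0, 0.5, 1)), c(0.5, 0.5, 0.5))
  expect_error(site_mismatch(c(0, NA), c(1, 1)), "missing")
})

test_that("genome-wide P0 matches hand evaluation and handles missingness", {
  sites <- data.frame(chrom = 1L, id = c("s1", "s2", "s3"),
                      pos = c(100L, 200L, 300L),
                      allele1 = "A", allele2 = "C")
  d <- rbind(a = c(0, 1, 0.5), b = c(1, 1, NA))
  ds <- genotype_dataset(d, data.frame(id = c("a", "b"),
                                       ploidy = c("diploid", "diploid")),
                         sites)
  p <- pair_p0_genomewide(ds, "a", "b")
  expect_equal(p$overlap_n, 2)
  expect_equal(p$mismatch_sum, 1.0)
  expect_equal(p$p0, 0.5)
  # identical copies mismatch nowhere
  dup <- genotype_dataset(rbind(a = c(0, 1, 1), b = c(0, 1, 1)),
                          ds$samples, sites)
  expect_equal(pair_p0_genomewide(dup, "a", "b")$p0, 0)
  expect_error(pair_p0_genomewide(ds, "a", "zz"), "unknown sample")
})

test_that("P0 is symmetric and converges to 2p(1-p) for unrelated draws", {
  ds <- random_dataset(n_samples = 5, n_sites = 300, diploid = TRUE,
                       seed = 31)
  for (pair in list(c(1, 2), c(2, 5))) {
    a <- ds$samples$id[pair[1]]
    b <- ds$samples$id[pair[2]]
    expect_equal(pair_p0_genomewide(ds, a, b)$p0,
                 pair_p0_genomewide(ds, b, a)$p0)
  }
  # pseudo-haploid draws at p = 0.5 everywhere: E[P0] = 0.5
  set.seed(8)
  n <- 50000
  d <- rbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  sites <- data.frame(chrom = 1L, id = paste0("s", 1:n),
                      pos = seq_len(n) * 50L, allele1 = "A", allele2 = "T")
  ds2 <- genotype_dataset(d, data.frame(id = c("a", "b"),
                                        ploidy = "pseudo_haploid"), sites)
  expect_lt(abs(pair_p0_genomewide(ds2, "a", "b")$p0 - 0.5),
            4 * sqrt(0.25 / n))
})

test_that("windows tile from bp 1 and their weighted mean is the genome-wide P0", {
  # 59-Mb chromosome, 20-Mb windows -> starts 1, 20e6+1, 40e6+1
  set.seed(12)
  pos <- sort(sample.int(59e6, 500))
  sites <- data.frame(chrom = 1L, id = paste0("s", 1:500), pos = pos,
                      allele1 = "A", allele2 = "C")
  d <- matrix(sample(c(0, 1, NA), 1000, TRUE, prob = c(.4, .4, .2)), 2, 500)
  ds <- genotype_dataset(d, data.frame(id = c("a", "b"),
                                       ploidy = "pseudo_haploid"), sites)
  w <- pair_p0_windows(ds, "a", "b", 20e6)
  expect_equal(w$window_start_bp, c(1, 20e6 + 1, 40e6 + 1))
  g <- pair_p0_genomewide(ds, "a", "b")
  expect_equal(weighted.mean(w$p0, w$overlap_n), g$p0, tolerance = 1e-12)
  expect_equal(sum(w$overlap_n), g$overlap_n)

  # property over random multi-chromosome fixtures and window sizes
  for (seed in 1:5) {
    ds <- random_dataset(n_samples = 3, n_sites = 400, diploid = TRUE,
                         n_chrom = 3, seed = seed)
    for (W in c(1e6, 5e6, 12e6)) {
      w <- pair_p0_windows(ds, "ind1", "ind3", W)
      g <- pair_p0_genomewide(ds, "ind1", "ind3")
      expect_equal(weighted.mean(w$p0, w$overlap_n), g$p0,
                   tolerance = 1e-12)
      expect_true(all(w$overlap_n >= 1))
    }
  }
})

test_that("single-window chromosomes reproduce the genome-wide estimate", {
  ds <- random_dataset(n_samples = 2, n_sites = 100, n_chrom = 1,
                       chrom_len = 9e5, seed = 77)
  w <- pair_p0_windows(ds, "ind1", "ind2", 1e6)
  expect_equal(nrow(w), 1)
  expect_equal(w$p0, pair_p0_genomewide(ds, "ind1", "ind2")$p0)
})

test_that("block jackknife matches the hand-computed delete-one formula", {
  # 3 blocks of 10 sites each on one 15-Mb chromosome; per-block mismatch
  # rates 0.2, 0.3, 0.4 in pseudo-haploid dosages
  pos <- c(seq(1e5, 4.9e6, length.out = 10),
           seq(5.1e6, 9.9e6, length.out = 10),
           seq(10.1e6, 14.9e6, length.out = 10))
  sites <- data.frame(chrom = 1L, id = paste0("s", 1:30),
                      pos = as.integer(pos), allele1 = "A", allele2 = "C")
  a <- rep(0, 30)
  b <- rep(0, 30)
  b[c(1:2, 11:13, 21:24)] <- 1 # 2, 3, 4 mismatches
  ds <- genotype_dataset(rbind(a = a, b = b),
                         data.frame(id = c("a", "b"),
                                    ploidy = "pseudo_haploid"), sites)
  # unweighted delete-one jackknife by hand (equal block sizes)
  th_del <- c((9 - 2) / 20, (9 - 3) / 20, (9 - 4) / 20)
  se_hand <- sqrt((2 / 3) * sum((th_del - mean(th_del))^2))
  expect_equal(jackknife_se(ds, "a", "b"), se_hand)
})

test_that("jackknife SE is 0 without variance and NA with fewer than 2 blocks", {
  # identical per-block mismatch rates across 10 blocks
  pos <- as.integer(seq(1e5, 49.9e6, length.out = 100))
  sites <- data.frame(chrom = 1L, id = paste0("s", 1:100), pos = pos,
                      allele1 = "A", allele2 = "C")
  b <- rep(c(1, rep(0, 9)), 10) # one mismatch per block of 10
  ds <- genotype_dataset(rbind(a = rep(0, 100), b = b),
                         data.frame(id = c("a", "b"),
                                    ploidy = "pseudo_haploid"), sites)
  expect_equal(jackknife_se(ds, "a", "b"), 0)
  one_block <- subset_sites(ds, 1:10)
  expect_warning(se <- jackknife_se(one_block, "a", "b"),
                 "fewer than 2")
  expect_true(is.na(se))
})

test_that("jackknife SE shrinks like 1/sqrt(2) when the overlap doubles", {
  set.seed(99)
  ratios <- replicate(50, {
    cfg <- tiny_sim_config(n_snps = 6000, coverage = 100)
    freqs <- sample_frequencies(cfg)
    sites <- kinmatch:::.sample_sites(cfg, freqs)
    g <- list(a = make_founder(freqs), b = make_founder(freqs))
    ds <- pseudo_haploidize(g, sites, cfg)
    half <- subset_sites(ds, seq(1, 6000, by = 2))
    jackknife_se(ds, "a", "b") / jackknife_se(half, "a", "b")
  })
  expect_lt(abs(mean(ratios) - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("all_pairs_p0 agrees with the per-pair route and counts pairs", {
  ds <- random_dataset(n_samples = 6, n_sites = 400, diploid = TRUE,
                       n_chrom = 3, seed = 55)
  pt <- all_pairs_p0(ds)
  expect_equal(nrow(pt), choose(6, 2))
  expect_equal(pt$sample_a[1:5], rep("ind1", 5)) # input-order, first major
  for (k in seq_len(nrow(pt))) {
    slow <- pair_p0_genomewide(ds, pt$sample_a[k], pt$sample_b[k])
    expect_equal(pt$p0[k], slow$p0, tolerance = 1e-12)
    expect_equal(pt$overlap_n[k], slow$overlap_n)
    expect_equal(pt$se_p0[k],
                 jackknife_se(ds, pt$sample_a[k], pt$sample_b[k]),
                 tolerance = 1e-12)
  }
  expect_equal(nrow(all_pairs_p0(subset_samples(ds, c("ind1", "ind2")))), 1)
})

test_that("window-mode statistic is the unweighted mean of window P0", {
  ds <- random_dataset(n_samples = 3, n_sites = 500, n_chrom = 3,
                       seed = 14)
  pt <- all_pairs_p0(ds, window_size_bp = 5e6, jackknife = FALSE)
  for (k in seq_len(nrow(pt))) {
    w <- pair_p0_windows(ds, pt$sample_a[k], pt$sample_b[k], 5e6)
    expect_equal(pt$p0[k], mean(w$p0), tolerance = 1e-12)
  }
})
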