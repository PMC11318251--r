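# In-code fixtures shared across test files.

# Random small dataset on a couple of chromosomes. Pseudo-haploid samples
# never receive dosage 0.5.
random_dataset <- function(n_samples = 4, n_sites = 60, miss = 0.2,
                           diploid = FALSE, n_chrom = 2, chrom_len = 30e6,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- as.vector(table(factor(sample.int(n_chrom, n_sites, replace = TRUE),
                                seq_len(n_chrom))))
  chrom <- rep(seq_len(n_chrom), cnt)
  pos <- unlist(lapply(cnt, function(k) sort(sample.int(chrom_len, k))))
  pairs <- combn(c("A", "C", "G", "T"), 2)
  ap <- pairs[, sample.int(6, n_sites, replace = TRUE), drop = FALSE]
  sites <- data.frame(chrom = chrom, id = paste0("s", seq_len(n_sites)),
                      pos = pos, allele1 = ap[1, ], allele2 = ap[2, ],
                      stringsAsFactors = FALSE)
  vals <- if (diploid) c(0, 0.5, 1) else c(0, 1)
  d <- matrix(sample(vals, n_samples * n_sites, replace = TRUE),
              n_samples, n_sites)
  d[matrix(runif(n_samples * n_sites) < miss, n_samples, n_sites)] <- NA
  samples <- data.frame(
    id = paste0("ind", seq_len(n_samples)),
    ploidy = if (diploid) "diploid" else "pseudo_haploid",
    stringsAsFactors = FALSE)
  genotype_dataset(d, samples, sites)
}

# Exact expectation of 2p(1-p) under the truncated power-law frequency
# spectrum, by numerical integration (independent of the package's sampler).
expected_unrelated_p0 <- function(alpha, error_rate = 0, a = 0.01, b = 0.5) {
  f <- function(p) p^(-alpha)
  z <- integrate(f, a, b)$value
  e2pq <- integrate(function(p) 2 * p * (1 - p) * f(p) / z, a, b)$value
  e2pq + 2 * error_rate * (1 - error_rate) * (1 - 2 * e2pq)
}

# A sim_config small enough for unit tests: 4 equal chromosomes.
tiny_sim_config <- function(n_snps = 4000, coverage = 5, error_rate = 0,
                            counts = c(unrelated = 2), seed = NULL,
                            n_chrom = 4, chrom_len = 50e6, ...) {
  sim_config(n_snps = n_snps, coverage = coverage, error_rate = error_rate,
             chromosome_lengths_bp = rep(chrom_len, n_chrom),
             pedigree_counts = counts, seed = seed, ...)
}
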