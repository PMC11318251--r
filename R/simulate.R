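#' Human-scale autosome lengths
#'
#' The 22 autosome lengths (bp) used by default for simulated genomes,
#' GRCh37 scale (~2.88 Gb total). They define the recombination map and the
#' window/block tiling of simulated data.
#'
#' @return named integer vector of length 22.
#' @export
default_autosome_lengths <- function() {
  stats::setNames(c(
    249250621L, 243199373L, 198022430L, 191154276L, 180915260L, 171115067L,
    159138663L, 146364022L, 141213431L, 135534747L, 135006516L, 133851895L,
    115169878L, 107349540L, 102531392L, 90354753L, 81195210L, 78077248L,
    63025520L, 59128983L, 48129895L, 51304566L), paste0("chr", 1:22))
}

#' Default pedigree counts
#'
#' Number of pedigrees simulated per relationship type. Each pedigree emits
#' a fixed set of individuals (ancillary co-parents are simulated but not
#' emitted): trios of 3 for parent-offspring, quartets of 4 for siblings,
#' 3 for half-siblings and grandparent-grandchild, 4 for avuncular,
#' great-grandparent, first-cousin and grand-avuncular pedigrees, plus
#' optional singleton unrelated individuals. The defaults emit 696
#' individuals in total (72 for each 3-generation-chain type, 96 for the
#' remaining types).
#'
#' @return named integer vector.
#' @export
default_pedigree_counts <- function() {
  c(parent_offspring = 24L, siblings = 24L, half_siblings = 32L,
    grandparent_grandchild = 24L, avuncular = 24L, great_grandparent = 18L,
    first_cousin = 24L, grand_avuncular = 24L, unrelated = 0L)
}

#' Simulation configuration
#'
#' @param n_snps number of biallelic SNPs on the panel.
#' @param maf_alpha exponent of the allele-frequency density
#'   `f(p) ~ p^(-maf_alpha)` truncated to \[0.01, 0.5\]; the default 0.6
#'   yields an unrelated pseudo-haploid mismatch baseline of ~0.25,
#'   typical of ascertained SNP panels.
#' @param chromosome_lengths_bp chromosome lengths in bp (index = chromosome
#'   label).
#' @param cm_per_mb sex-averaged recombination rate; 1 cM/Mb approximates
#'   the human genome average.
#' @param coverage mean sequencing depth per site; per-site depths are
#'   Poisson, a site with depth 0 is missing. Default 0.3, the depth from
#'   which classification up to the third degree is reliable.
#' @param error_rate probability that a pseudo-haploid call reports the
#'   other allele (sequencing error plus residual post-mortem damage),
#'   identical for all individuals.
#' @param pedigree_counts named vector as in [default_pedigree_counts];
#'   unknown names are an error.
#' @param mode `"pseudo_haploid"` (coverage-thinned single-allele calls) or
#'   `"diploid"` (true dosages, no thinning or error).
#' @param seed integer seed making [simulate_dataset] fully reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200000L, maf_alpha = 0.6,
                       chromosome_lengths_bp = default_autosome_lengths(),
                       cm_per_mb = 1, coverage = 0.3, error_rate = 0.005,
                       pedigree_counts = default_pedigree_counts(),
                       mode = c("pseudo_haploid", "diploid"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_snps >= 1, coverage >= 0, error_rate >= 0, error_rate < 0.5,
            cm_per_mb >= 0, all(chromosome_lengths_bp > 0))
  known <- names(default_pedigree_counts())
  if (is.null(names(pedigree_counts)) ||
      !all(names(pedigree_counts) %in% known))
    stop("pedigree_counts must be named with types from: ",
         paste(known, collapse = ", "))
  counts <- stats::setNames(rep(0L, length(known)), known)
  counts[names(pedigree_counts)] <- as.integer(pedigree_counts)
  structure(list(n_snps = as.integer(n_snps), maf_alpha = maf_alpha,
                 chromosome_lengths_bp = chromosome_lengths_bp,
                 cm_per_mb = cm_per_mb, coverage = coverage,
                 error_rate = error_rate, pedigree_counts = counts,
                 mode = mode, seed = seed),
            class = "sim_config")
}

#' Draw panel allele frequencies
#'
#' Inverse-CDF sampling from `f(p) ~ p^(-maf_alpha)` on \[0.01, 0.5\]. The
#' negative exponent skews the panel towards rare variants, mimicking the
#' site-frequency spectrum of large SNP panels.
#'
#' @param config a [sim_config].
#' @return numeric vector of length `n_snps` in \[0.01, 0.5\].
#' @export
sample_frequencies <- function(config) {
  a <- 0.01
  b <- 0.5
  al <- config$maf_alpha
  u <- stats::runif(config$n_snps)
  if (abs(al - 1) < 1e-12) a * (b / a)^u
  else {
    e <- 1 - al
    (a^e + u * (b^e - a^e))^(1 / e)
  }
}

#' Generate an unrelated founder genome
#'
#' Two independent haplotypes; the allele2 indicator at site j is Bernoulli
#' with the panel frequency. Sites are unlinked between founders, which
#' removes background relatedness and runs of homozygosity by construction.
#'
#' @param freqs per-site allele2 frequencies.
#' @return list with integer haplotypes `h1`, `h2` (0 = allele1,
#'   1 = allele2).
#' @export
make_founder <- function(freqs) {
  list(h1 = as.integer(stats::runif(length(freqs)) < freqs),
       h2 = as.integer(stats::runif(length(freqs)) < freqs))
}

# crossover positions for one chromosome: Poisson count at the map length
# in Morgans (no interference), positions uniform along the chromosome.
.sample_crossovers <- function(length_bp, cm_per_mb) {
  morgans <- length_bp / 1e6 * cm_per_mb / 100
  k <- stats::rpois(1L, morgans)
  if (k == 0L) numeric(0) else sort(stats::runif(k, min = 1, max = length_bp))
}

.chrom_index <- function(sites) {
  ci <- attr(sites, "chrom_index")
  if (is.null(ci)) ci <- split(seq_len(nrow(sites)), sites$chrom)
  ci
}

#' Simulate one meiosis
#'
#' Produces a gamete as a mosaic of the parent's two haplotypes: per
#' chromosome the crossover count is Poisson with mean equal to the map
#' length in Morgans, crossover positions are uniform, and the starting
#' haplotype is chosen with probability 1/2.
#'
#' @param parent a genome as returned by [make_founder].
#' @param sites site table (`chrom`, `pos`) the genome is defined on.
#' @param config a [sim_config] (recombination map).
#' @return integer haplotype vector.
#' @export
meiosis <- function(parent, sites, config) {
  gam <- parent$h1
  ci <- .chrom_index(sites)
  for (cc in names(ci)) {
    idx <- ci[[cc]]
    L <- config$chromosome_lengths_bp[[as.integer(cc)]]
    cx <- .sample_crossovers(L, config$cm_per_mb)
    start <- stats::runif(1) < 0.5
    seg2 <- xor(start, findInterval(sites$pos[idx], cx) %% 2L == 1L)
    take2 <- idx[seg2]
    gam[take2] <- parent$h2[take2]
  }
  gam
}

.mate <- function(p1, p2, sites, config) {
  list(h1 = meiosis(p1, sites, config), h2 = meiosis(p2, sites, config))
}

.REL_DEGREE <- c(
  "parent-offspring" = "first", "siblings" = "first",
  "half-siblings" = "second", "grandparent-grandchild" = "second",
  "avuncular" = "second", "first-cousin" = "third",
  "great-grandparent" = "third", "grand-avuncular" = "third",
  "unrelated" = "unrelated")
.DEGREE_THETA <- c(first = 0.25, second = 0.125, third = 0.0625,
                   unrelated = 0)

# One pedigree of the given type. Members named by role; `visible` lists
# the roles emitted into the dataset (ancillary co-parents stay silent);
# `relations` labels every visible non-unrelated pair.
.build_one_pedigree <- function(type, sites, freqs, config) {
  F <- function() make_founder(freqs)
  C <- function(p1, p2) .mate(p1, p2, sites, config)
  rel <- function(a, b, type)
    data.frame(a = a, b = b, type = type, stringsAsFactors = FALSE)
  switch(type,
    parent_offspring = {
      g <- list(f1 = F(), f2 = F())
      g$c1 <- C(g$f1, g$f2)
      list(genomes = g, visible = c("f1", "f2", "c1"),
           relations = rel(c("f1", "f2"), "c1", "parent-offspring"))
    },
    siblings = {
      g <- list(f1 = F(), f2 = F())
      g$c1 <- C(g$f1, g$f2)
      g$c2 <- C(g$f1, g$f2)
      list(genomes = g, visible = c("f1", "f2", "c1", "c2"),
           relations = rbind(
             rel(c("f1", "f1", "f2", "f2"), c("c1", "c2", "c1", "c2"),
                 "parent-offspring"),
             rel("c1", "c2", "siblings")))
    },
    half_siblings = {
      g <- list(s = F(), u1 = F(), u2 = F())
      g$c1 <- C(g$s, g$u1)
      g$c2 <- C(g$s, g$u2)
      list(genomes = g, visible = c("s", "c1", "c2"),
           relations = rbind(
             rel(c("s", "s"), c("c1", "c2"), "parent-offspring"),
             rel("c1", "c2", "half-siblings")))
    },
    grandparent_grandchild = {
      g <- list(g1 = F(), g2 = F(), q = F())
      g$p <- C(g$g1, g$g2)
      g$x <- C(g$p, g$q)
      list(genomes = g, visible = c("g1", "p", "x"),
           relations = rbind(
             rel(c("g1", "p"), c("p", "x"), "parent-offspring"),
             rel("g1", "x", "grandparent-grandchild")))
    },
    avuncular = {
      g <- list(g1 = F(), g2 = F(), q = F())
      g$a <- C(g$g1, g$g2)
      g$b <- C(g$g1, g$g2)
      g$n <- C(g$b, g$q)
      list(genomes = g, visible = c("g1", "a", "b", "n"),
           relations = rbind(
             rel(c("g1", "g1", "b"), c("a", "b", "n"), "parent-offspring"),
             rel("a", "b", "siblings"),
             rel("g1", "n", "grandparent-grandchild"),
             rel("a", "n", "avuncular")))
    },
    great_grandparent = {
      g <- list(g1 = F(), g2 = F(), q1 = F(), q2 = F())
      g$p1 <- C(g$g1, g$g2)
      g$p2 <- C(g$p1, g$q1)
      g$x <- C(g$p2, g$q2)
      list(genomes = g, visible = c("g1", "p1", "p2", "x"),
           relations = rbind(
             rel(c("g1", "p1", "p2"), c("p1", "p2", "x"),
                 "parent-offspring"),
             rel(c("g1", "p1"), c("p2", "x"), "grandparent-grandchild"),
             rel("g1", "x", "great-grandparent")))
    },
    first_cousin = {
      g <- list(g1 = F(), g2 = F(), qa = F(), qb = F())
      g$a <- C(g$g1, g$g2)
      g$b <- C(g$g1, g$g2)
      g$x <- C(g$a, g$qa)
      g$y <- C(g$b, g$qb)
      list(genomes = g, visible = c("a", "b", "x", "y"),
           relations = rbind(
             rel(c("a", "b"), c("x", "y"), "parent-offspring"),
             rel("a", "b", "siblings"),
             rel(c("a", "b"), c("y", "x"), "avuncular"),
             rel("x", "y", "first-cousin")))
    },
    grand_avuncular = {
      g <- list(g1 = F(), g2 = F(), q1 = F(), q2 = F())
      g$s1 <- C(g$g1, g$g2)
      g$s2 <- C(g$g1, g$g2)
      g$c <- C(g$s1, g$q1)
      g$x <- C(g$c, g$q2)
      list(genomes = g, visible = c("s1", "s2", "c", "x"),
           relations = rbind(
             rel(c("s1", "c"), c("c", "x"), "parent-offspring"),
             rel("s1", "s2", "siblings"),
             rel("s1", "x", "grandparent-grandchild"),
             rel("s2", "c", "avuncular"),
             rel("s2", "x", "grand-avuncular")))
    },
    unrelated = list(genomes = list(u = F()), visible = "u",
                     relations = data.frame(a = character(0),
                                            b = character(0),
                                            type = character(0))),
    stop("unknown pedigree type: ", type))
}

.PED_ABBREV <- c(parent_offspring = "po", siblings = "sib",
                 half_siblings = "hs", grandparent_grandchild = "gp",
                 avuncular = "av", great_grandparent = "ggp",
                 first_cousin = "fc", grand_avuncular = "ga",
                 unrelated = "un")

# truth over every unordered pair of ids (first-sample-major order),
# defaulting to unrelated for unlabelled pairs.
.truth_table <- function(ids, relations) {
  n <- length(ids)
  pi <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  pj <- sequence((n - 1L):1L) + pi
  type <- rep("unrelated", length(pi))
  if (nrow(relations)) {
    key <- paste(ids[pi], ids[pj], sep = "\r")
    hit <- match(key, c(paste(relations$a, relations$b, sep = "\r"),
                        paste(relations$b, relations$a, sep = "\r")))
    found <- which(!is.na(hit))
    type[found] <- relations$type[(hit[found] - 1L) %% nrow(relations) + 1L]
  }
  degree <- unname(.REL_DEGREE[type])
  data.frame(sample_a = ids[pi], sample_b = ids[pj], true_degree = degree,
             true_type = type, true_theta = unname(.DEGREE_THETA[degree]),
             stringsAsFactors = FALSE)
}

#' Simulate pedigrees of true diploid genomes
#'
#' Builds the configured number of pedigrees per relationship type by
#' repeated founder generation and meiosis, and labels the true
#' relationship of every pair of emitted individuals. Individuals from
#' distinct pedigrees, founder couples, and all unlabelled within-pedigree
#' pairs are unrelated. Does not touch the seed; call via
#' [simulate_dataset] (or `set.seed` yourself) for reproducibility.
#'
#' @param config a [sim_config].
#' @param sites,freqs optional pre-generated site table and frequencies
#'   (generated from `config` when `NULL`).
#' @return list with `genomes` (named list of emitted diploid genomes),
#'   `truth` (data frame over every emitted pair: `sample_a`, `sample_b`,
#'   `true_degree`, `true_type`, `true_theta`), `relations`, `sites`,
#'   `frequencies`.
#' @export
build_pedigrees <- function(config, sites = NULL, freqs = NULL) {
  if (is.null(freqs)) freqs <- sample_frequencies(config)
  if (is.null(sites)) sites <- .sample_sites(config, freqs)
  genomes <- list()
  rels <- list()
  for (type in names(config$pedigree_counts)) {
    for (i in seq_len(config$pedigree_counts[[type]])) {
      ped <- .build_one_pedigree(type, sites, freqs, config)
      pre <- sprintf("%s%03d_", .PED_ABBREV[[type]], i)
      vis <- ped$genomes[ped$visible]
      names(vis) <- paste0(pre, ped$visible)
      genomes <- c(genomes, vis)
      if (nrow(ped$relations)) {
        r <- ped$relations
        r$a <- paste0(pre, r$a)
        r$b <- paste0(pre, r$b)
        rels[[length(rels) + 1L]] <- r
      }
    }
  }
  if (length(genomes) == 0) stop("pedigree_counts produce no individuals")
  relations <- if (length(rels)) do.call(rbind, rels) else
    data.frame(a = character(0), b = character(0), type = character(0))
  truth <- if (length(genomes) >= 2)
    .truth_table(names(genomes), relations) else
    .truth_table(c(names(genomes), ""), relations)[0, ]
  list(genomes = genomes, truth = truth, relations = relations,
       sites = sites, frequencies = freqs)
}

# random SNP panel: site counts proportional to chromosome length (largest
# remainder), positions uniform without replacement, allele pairs uniform
# over the 12 ordered distinct base pairs.
.sample_sites <- function(config, freqs) {
  L <- as.numeric(config$chromosome_lengths_bp)
  names(L) <- names(config$chromosome_lengths_bp)
  n <- config$n_snps
  raw <- n * L / sum(L)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1
  }
  chrom <- rep(seq_along(L), cnt)
  pos <- unlist(lapply(seq_along(L), function(cc)
    sort(sample.int(L[[cc]], cnt[[cc]]))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- sample(bases[-1], n, replace = TRUE)
  a2 <- ifelse(a2 == a1, "A", a2)  # uniform over the 3 other bases
  sites <- data.frame(chrom = chrom, id = sprintf("%d_%d", chrom, pos),
                      pos = pos, allele1 = a1, allele2 = a2,
                      stringsAsFactors = FALSE)
  attr(sites, "chrom_index") <- split(seq_len(nrow(sites)), sites$chrom)
  sites
}

#' Turn true genomes into an observed genotype dataset
#'
#' Site-level sequencing model: per sample and site the depth is
#' Poisson(`coverage`); depth 0 is missing, otherwise the call is one of
#' the two true alleles chosen uniformly (a pseudo-haploid call), flipped
#' to the other allele with probability `error_rate`. With
#' `ploidy = "diploid"` the true dosage `(h1+h2)/2` is emitted for that
#' sample without thinning or error, modelling a high-quality diploid
#' genotype.
#'
#' @param genomes named list of diploid genomes.
#' @param sites site table the genomes are defined on.
#' @param config a [sim_config] (`coverage`, `error_rate`).
#' @param ploidy `"pseudo_haploid"`, `"diploid"`, or a character vector
#'   named by sample for mixed datasets.
#' @return a [genotype_dataset].
#' @export
pseudo_haploidize <- function(genomes, sites, config,
                              ploidy = "pseudo_haploid") {
  ids <- names(genomes)
  n <- length(ids)
  m <- nrow(sites)
  if (length(ploidy) == 1L) pl <- rep(ploidy, n)
  else {
    pl <- ploidy[ids]
    if (anyNA(pl)) stop("ploidy vector must name every sample")
  }
  dos <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    g <- genomes[[i]]
    if (pl[i] == "diploid") {
      dos[i, ] <- (g$h1 + g$h2) / 2
      next
    }
    obs <- stats::rpois(m, config$coverage) > 0L
    val <- g$h1
    two <- stats::runif(m) >= 0.5
    val[two] <- g$h2[two]
    if (config$error_rate > 0) {
      fl <- stats::runif(m) < config$error_rate
      val[fl] <- 1L - val[fl]
    }
    dos[i, obs] <- val[obs]
  }
  genotype_dataset(dos,
                   data.frame(id = ids, ploidy = pl,
                              stringsAsFactors = FALSE),
                   as.data.frame(sites))
}

#' Simulate a complete benchmark dataset
#'
#' End-to-end composition: seed, allele frequencies, SNP panel, pedigrees
#' with recombination, coverage thinning / error model, and (optionally)
#' PLINK output plus a relationship truth table. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config].
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.bed/.bim/.fam` and `<prefix>.truth.tsv`.
#' @param keep_genomes also return the true diploid genomes (memory-heavy
#'   for large panels).
#' @return list with `dataset` ([genotype_dataset]), `truth`,
#'   `frequencies`, `sites`, `config`, and `genomes` when requested.
#' @export
simulate_dataset <- function(config, out_prefix = NULL,
                             keep_genomes = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  freqs <- sample_frequencies(config)
  sites <- .sample_sites(config, freqs)
  ped <- build_pedigrees(config, sites, freqs)
  dataset <- pseudo_haploidize(ped$genomes, sites, config,
                               ploidy = config$mode)
  if (!is.null(out_prefix)) {
    write_plink(dataset, out_prefix)
    utils::write.table(ped$truth, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out <- list(dataset = dataset, truth = ped$truth, frequencies = freqs,
              sites = sites, config = config)
  if (keep_genomes) out$genomes <- ped$genomes
  out
}
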