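#' Assemble a genotype dataset
#'
#' The exchange object used by every other function in kinmatch: a
#' samples-by-sites dosage matrix plus site and sample metadata. A dosage is
#' the fraction of `allele2` copies observed at a site: `0` and `1` for
#' homozygous calls (and for all pseudo-haploid calls), `0.5` for a diploid
#' heterozygote, `NA` for missing. Dosages are defined relative to the
#' `allele1`/`allele2` labels of the site table, not to major/minor alleles;
#' the mismatch statistic is invariant to that labelling.
#'
#' @param dosages numeric matrix, one row per sample, one column per site,
#'   entries in `{0, 0.5, 1, NA}`.
#' @param samples data frame with columns `id` (unique character) and
#'   `ploidy` (`"pseudo_haploid"` or `"diploid"`). Pseudo-haploid samples
#'   must not carry dosage 0.5 anywhere.
#' @param sites data frame with columns `chrom` (integer, autosomes 1-22),
#'   `id`, `pos` (1-based bp), `allele1`, `allele2` (distinct bases from
#'   A/C/G/T). Rows must be sorted by chromosome and strictly increasing
#'   position within a chromosome.
#' @param validate run the invariant checks (set `FALSE` only for internal
#'   subsetting where the invariants are preserved by construction).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, samples, sites, validate = TRUE) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(dosages) <- samples$id
  obj <- structure(list(samples = samples, sites = sites, dosages = dosages),
                   class = "genotype_dataset")
  if (validate) validate_genotype_dataset(obj)
  obj
}

#' Check the invariants of a genotype dataset
#'
#' Stops with an informative message on the first violated invariant:
#' matching dimensions, unique sample ids, legal ploidy flags, no
#' heterozygous dosage for pseudo-haploid samples, sorted biallelic
#' autosomal sites, and dosage entries restricted to `{0, 0.5, 1, NA}`.
#'
#' @param x a `genotype_dataset`.
#' @return `x`, invisibly.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  n <- nrow(x$samples)
  m <- nrow(x$sites)
  if (!identical(dim(x$dosages), c(n, m)))
    stop("dosage matrix is ", nrow(x$dosages), " x ", ncol(x$dosages),
         " but there are ", n, " samples and ", m, " sites")
  if (anyDuplicated(x$samples$id))
    stop("sample identifiers are not unique")
  if (!all(x$samples$ploidy %in% c("pseudo_haploid", "diploid")))
    stop("ploidy must be 'pseudo_haploid' or 'diploid'")
  d <- x$dosages
  bad <- !is.na(d) & d != 0 & d != 0.5 & d != 1
  if (any(bad))
    stop("dosages must be 0, 0.5, 1 or NA")
  ph <- x$samples$ploidy == "pseudo_haploid"
  if (any(ph) && m > 0) {
    has_het <- d[ph, , drop = FALSE] == 0.5
    if (any(has_het, na.rm = TRUE))
      stop("pseudo-haploid sample(s) carry heterozygous dosage 0.5: ",
           paste(x$samples$id[ph][rowSums(has_het, na.rm = TRUE) > 0],
                 collapse = ", "))
  }
  if (m > 0) {
    if (!is.numeric(x$sites$chrom) || !all(x$sites$chrom %in% 1:22))
      stop("site chromosomes must be autosomes 1-22")
    o <- order(x$sites$chrom, x$sites$pos)
    if (!identical(o, seq_len(m)))
      stop("sites must be sorted by (chromosome, position)")
    same <- duplicated(data.frame(x$sites$chrom, x$sites$pos))
    if (any(same))
      stop("duplicated site positions present")
    ok <- x$sites$allele1 %in% c("A", "C", "G", "T") &
      x$sites$allele2 %in% c("A", "C", "G", "T") &
      x$sites$allele1 != x$sites$allele2
    if (!all(ok))
      stop("site alleles must be two distinct bases from A/C/G/T")
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(factor(x$samples$ploidy, c("pseudo_haploid", "diploid")))
  cat(sprintf(
    "genotype_dataset: %d samples (%d pseudo-haploid, %d diploid) x %d sites\n",
    nrow(x$samples), tab[["pseudo_haploid"]], tab[["diploid"]],
    nrow(x$sites)))
  if (nrow(x$sites) > 0) {
    miss <- mean(is.na(x$dosages))
    cat(sprintf("  chromosomes %s; missingness %.1f%%\n",
                paste(range(x$sites$chrom), collapse = "-"), 100 * miss))
  }
  invisible(x)
}

#' Number of samples / sites in a dataset
#' @param x a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a dataset to a set of sites
#'
#' Keeps the given site indices (in their original order, so sortedness is
#' preserved when `idx` is increasing).
#'
#' @param x a `genotype_dataset`.
#' @param idx increasing integer vector of site indices to keep.
#' @return a `genotype_dataset`.
#' @export
subset_sites <- function(x, idx) {
  genotype_dataset(x$dosages[, idx, drop = FALSE], x$samples,
                   x$sites[idx, , drop = FALSE], validate = FALSE)
}

#' Subset a dataset to a set of samples
#' @param x a `genotype_dataset`.
#' @param ids character vector of sample ids to keep.
#' @return a `genotype_dataset`.
#' @export
subset_samples <- function(x, ids) {
  keep <- match(ids, x$samples$id)
  if (anyNA(keep)) stop("unknown sample id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  genotype_dataset(x$dosages[keep, , drop = FALSE],
                   x$samples[keep, , drop = FALSE], x$sites,
                   validate = FALSE)
}

.sample_row <- function(x, id) {
  i <- match(id, x$samples$id)
  if (is.na(i)) stop("unknown sample id: ", id)
  x$dosages[i, ]
}

# genomic tile key: chrom * 1e9 + 1-based start of the tile containing pos.
# Tiles anchor at bp 1 on every chromosome; exact in doubles (max ~2.3e10).
.tile_key <- function(chrom, pos, size_bp) {
  as.numeric(chrom) * 1e9 + (((pos - 1) %/% size_bp) * size_bp + 1)
}
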