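#' Read PLINK binary genotypes
#'
#' Reads a bed/bim/fam triplet (PLINK 1.x binary, SNP-major) into a
#' [genotype_dataset]. The 2-bit codes follow the PLINK 1.9 convention:
#' `00` homozygous allele1 (dosage 0), `01` missing, `10` heterozygous
#' (dosage 0.5), `11` homozygous allele2 (dosage 1). Non-autosomal sites
#' (anything outside chromosome labels 1-22) are dropped with a message;
#' sites with non-ACGT or identical alleles and sites sharing a duplicated
#' position are dropped with a warning. Sites are sorted by genome position
#' if the bim is unsorted.
#'
#' Each sample's ploidy is auto-detected: a sample with at least one
#' heterozygous code is flagged `diploid`, otherwise `pseudo_haploid`. Use
#' `ploidy` to override, e.g. when truly diploid samples happen to carry no
#' heterozygote in the retained sites.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @param ploidy `NULL` for auto-detection, a single string applied to all
#'   samples, or a character vector named by sample id for selective
#'   overrides.
#' @return a [genotype_dataset].
#' @export
read_plink <- function(prefix, ploidy = NULL) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("PLINK input file not found: ", p, call. = FALSE)

  fam <- .read_plink_table(paths[3], 6)
  ids <- fam[[2]]
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", paths[3])
  n <- length(ids)

  bim <- .read_plink_table(paths[2], 6)
  names(bim) <- c("chrom", "id", "cm", "pos", "allele1", "allele2")
  m <- nrow(bim)

  bed <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(bed) < 3L || bed[1] != as.raw(0x6c) || bed[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", paths[1])
  if (bed[3] != as.raw(0x01))
    stop("bed file not in SNP-major layout: ", paths[1])
  bps <- ceiling(n / 4)
  if (length(bed) - 3L != bps * m)
    stop(sprintf("bed file size inconsistent with %d samples x %d sites: %s",
                 n, m, paths[1]))
  geno <- .decode_bed(bed[-(1:3)], n, m, bps)

  # site filters: autosomes only, biallelic ACGT, unique positions
  auto <- bim$chrom %in% as.character(1:22)
  if (!all(auto))
    message("read_plink: dropped ", sum(!auto), " non-autosomal site(s)")
  bim <- bim[auto, , drop = FALSE]
  geno <- geno[, auto, drop = FALSE]

  ok <- bim$allele1 %in% c("A", "C", "G", "T") &
    bim$allele2 %in% c("A", "C", "G", "T") & bim$allele1 != bim$allele2
  if (!all(ok)) {
    warning("dropped ", sum(!ok), " non-biallelic site(s)")
    bim <- bim[ok, , drop = FALSE]
    geno <- geno[, ok, drop = FALSE]
  }

  chrom <- as.integer(bim$chrom)
  pos <- as.integer(bim$pos)
  key <- paste(chrom, pos)
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    warning("dropped ", sum(dup), " site(s) at duplicated positions")
    bim <- bim[!dup, , drop = FALSE]
    geno <- geno[, !dup, drop = FALSE]
    chrom <- chrom[!dup]
    pos <- pos[!dup]
  }

  o <- order(chrom, pos)
  if (!identical(o, seq_along(chrom))) {
    message("read_plink: sites were unsorted; sorted by (chromosome, position)")
    bim <- bim[o, , drop = FALSE]
    geno <- geno[, o, drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
  }

  pl <- .resolve_ploidy(geno, ids, ploidy)
  genotype_dataset(
    geno,
    data.frame(id = ids, ploidy = pl, stringsAsFactors = FALSE),
    data.frame(chrom = chrom, id = bim$id, pos = pos,
               allele1 = bim$allele1, allele2 = bim$allele2,
               stringsAsFactors = FALSE))
}

.read_plink_table <- function(path, ncol) {
  if (file.size(path) == 0)
    return(as.data.frame(matrix(character(0), 0, ncol),
                         stringsAsFactors = FALSE))
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

.decode_bed <- function(body, n, m, bps) {
  map <- c(0, NA_real_, 0.5, 1)
  ints <- as.integer(body)
  out <- matrix(NA_real_, n, m)
  for (k in 1:4) {
    if (k > n) break
    srows <- seq.int(k, n, by = 4L)
    code <- bitwAnd(bitwShiftR(ints, 2L * (k - 1L)), 3L)
    dim(code) <- c(bps, m)
    out[srows, ] <- map[code[seq_along(srows), , drop = FALSE] + 1L]
  }
  out
}

.resolve_ploidy <- function(geno, ids, ploidy) {
  auto <- ifelse(rowSums(geno == 0.5, na.rm = TRUE) > 0,
                 "diploid", "pseudo_haploid")
  if (is.null(ploidy)) return(auto)
  if (length(ploidy) == 1L && is.null(names(ploidy)))
    return(rep(ploidy, length(ids)))
  if (is.null(names(ploidy)))
    stop("ploidy override must be a single value or named by sample id")
  out <- auto
  hit <- match(names(ploidy), ids)
  if (anyNA(hit)) stop("ploidy override names unknown sample(s): ",
                       paste(names(ploidy)[is.na(hit)], collapse = ", "))
  out[hit] <- ploidy
  out
}

#' Write PLINK binary genotypes
#'
#' Writes a [genotype_dataset] as a bed/bim/fam triplet readable by
#' [read_plink] and by PLINK itself. Dosage 0.5 is encoded as the
#' heterozygous code; the dataset invariants are enforced first, so a
#' pseudo-haploid sample carrying 0.5 is refused. The bim genetic-map
#' column is written as 0.
#'
#' @param dataset a valid [genotype_dataset].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  validate_genotype_dataset(dataset)
  if (!dir.exists(dirname(prefix)))
    stop("cannot write PLINK files: directory does not exist: ",
         dirname(prefix))
  d <- dataset$dosages
  n <- nrow(d)
  m <- ncol(d)

  codes <- matrix(1L, n, m) # 01 = missing
  codes[!is.na(d) & d == 0] <- 0L
  codes[!is.na(d) & d == 0.5] <- 2L
  codes[!is.na(d) & d == 1] <- 3L
  if (n %% 4L)
    codes <- rbind(codes, matrix(0L, 4L - n %% 4L, m))
  r <- nrow(codes)
  bytes <- codes[seq.int(1L, r, 4L), , drop = FALSE] +
    4L * codes[seq.int(2L, r, 4L), , drop = FALSE] +
    16L * codes[seq.int(3L, r, 4L), , drop = FALSE] +
    64L * codes[seq.int(4L, r, 4L), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(bytes)) writeBin(as.raw(bytes), con)

  utils::write.table(
    data.frame(dataset$sites$chrom, dataset$sites$id, rep(0L, m),
               dataset$sites$pos,
               dataset$sites$allele1, dataset$sites$allele2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(dataset$samples$id, dataset$samples$id, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Filter sites by mutation class and random thinning
#'
#' `transversions_only` removes transition polymorphisms (allele pairs
#' C/T and G/A), the classes inflated by post-mortem cytosine deamination in
#' ancient DNA; the remaining sites are transversions. Thinning then keeps
#' each remaining site independently with probability `thin_fraction`.
#' Site order is always preserved and the transversion filter is idempotent.
#'
#' @param dataset a [genotype_dataset].
#' @param mode `"all"` (no class filter) or `"transversions_only"`.
#' @param thin_fraction keep probability in (0, 1]; 1 disables thinning.
#' @param seed optional integer making the thinning reproducible; the
#'   caller's RNG state is restored afterwards.
#' @return a filtered [genotype_dataset] (possibly with zero sites, warned).
#' @export
filter_sites <- function(dataset, mode = c("all", "transversions_only"),
                         thin_fraction = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(thin_fraction), length(thin_fraction) == 1,
            thin_fraction > 0, thin_fraction <= 1)
  keep <- rep(TRUE, n_sites(dataset))
  if (mode == "transversions_only" && n_sites(dataset) > 0) {
    pair <- paste(pmin(dataset$sites$allele1, dataset$sites$allele2),
                  pmax(dataset$sites$allele1, dataset$sites$allele2))
    keep <- !(pair %in% c("C T", "A G"))
  }
  if (thin_fraction < 1 && any(keep)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = .GlobalEnv))
        get(".Random.seed", envir = .GlobalEnv) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    keep[keep] <- stats::runif(sum(keep)) < thin_fraction
  }
  if (!any(keep)) warning("all sites removed by filtering")
  subset_sites(dataset, which(keep))
}
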