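#' Per-site mismatch between two dosage calls
#'
#' The average allele mismatch between two genotypes when one allele is
#' drawn at random from each: `d1 + d2 - 2*d1*d2`. This closed form equals
#' the case enumeration over genotype pairs — identical homozygotes 0,
#' opposite homozygotes 1, and any comparison involving a heterozygote
#' contributes exactly 1/2, which is what makes diploid and pseudo-haploid
#' calls comparable on the same scale.
#'
#' @param d1,d2 dosage vectors in `{0, 0.5, 1}`; missing values are a
#'   contract violation (callers must restrict to jointly observed sites).
#' @return numeric vector of mismatch contributions in `{0, 0.5, 1}`.
#' @export
site_mismatch <- function(d1, d2) {
  if (anyNA(d1) || anyNA(d2))
    stop("site_mismatch: missing dosages; restrict to jointly observed sites")
  d1 + d2 - 2 * d1 * d2
}

.pair_rows <- function(dataset, a, b) {
  if (a == b) stop("a pair must consist of two distinct samples")
  list(da = .sample_row(dataset, a), db = .sample_row(dataset, b))
}

#' Genome-wide pairwise mismatch rate P0
#'
#' Sums [site_mismatch] over all sites covered in both samples. P0 is the
#' core relatedness statistic: the closer two individuals are related, the
#' more alleles they share and the lower their mismatch rate.
#'
#' @param dataset a [genotype_dataset].
#' @param a,b sample identifiers (distinct, both present).
#' @return a list with `sample_a`, `sample_b`, `overlap_n` (jointly covered
#'   sites), `mismatch_sum` and `p0 = mismatch_sum / overlap_n` (`NA` with a
#'   warning when the overlap is empty).
#' @export
pair_p0_genomewide <- function(dataset, a, b) {
  v <- .pair_rows(dataset, a, b)
  joint <- !is.na(v$da) & !is.na(v$db)
  n <- sum(joint)
  s <- if (n > 0) sum(site_mismatch(v$da[joint], v$db[joint])) else 0
  if (n == 0) warning("pair ", a, "-", b, " shares no covered sites")
  list(sample_a = a, sample_b = b, overlap_n = n, mismatch_sum = s,
       p0 = if (n > 0) s / n else NA_real_)
}

#' Per-window pairwise mismatch rates
#'
#' Tiles every chromosome with non-overlapping windows anchored at bp 1
#' (`[1, W]`, `[W+1, 2W]`, ...) and computes P0 per window from the jointly
#' covered sites. Windows with no joint coverage are omitted. The
#' overlap-weighted mean of the returned window P0 values equals the
#' genome-wide P0 exactly.
#'
#' @param dataset a [genotype_dataset].
#' @param a,b sample identifiers.
#' @param window_size_bp window width in bp (at least 100 kb).
#' @return data frame with `chrom`, `window_start_bp`, `window_size_bp`,
#'   `overlap_n`, `p0`, ordered along the genome.
#' @export
pair_p0_windows <- function(dataset, a, b, window_size_bp) {
  stopifnot(window_size_bp >= 1e5)
  v <- .pair_rows(dataset, a, b)
  joint <- which(!is.na(v$da) & !is.na(v$db))
  if (length(joint) == 0)
    return(data.frame(chrom = integer(0), window_start_bp = numeric(0),
                      window_size_bp = numeric(0), overlap_n = numeric(0),
                      p0 = numeric(0)))
  m <- site_mismatch(v$da[joint], v$db[joint])
  key <- .tile_key(dataset$sites$chrom[joint], dataset$sites$pos[joint],
                   window_size_bp)
  s <- rowsum(m, key)                       # groups sorted by numeric key
  n <- rowsum(rep(1, length(m)), key)
  k <- as.numeric(rownames(s))
  data.frame(chrom = as.integer(k %/% 1e9), window_start_bp = k %% 1e9,
             window_size_bp = window_size_bp, overlap_n = drop(n),
             p0 = drop(s) / drop(n), row.names = NULL)
}

#' Block-jackknife standard error of the genome-wide P0
#'
#' Delete-one-block jackknife over contiguous genomic blocks (default 5 Mb),
#' the standard way to get an SE for a genome-wide statistic in the presence
#' of local correlation. Because missingness in low-coverage data makes the
#' per-block site counts very unequal, blocks are weighted by their joint
#' overlap counts (Busing's weighted delete-one jackknife); with equal
#' blocks this reduces exactly to the familiar unweighted formula.
#'
#' @param dataset a [genotype_dataset].
#' @param a,b sample identifiers.
#' @param block_size_bp jackknife block width in bp.
#' @return the standard error (0 when all leave-one-out estimates agree;
#'   `NA` with a warning when fewer than two blocks carry data).
#' @export
jackknife_se <- function(dataset, a, b, block_size_bp = 5e6) {
  v <- .pair_rows(dataset, a, b)
  joint <- which(!is.na(v$da) & !is.na(v$db))
  if (length(joint) < 2) {
    warning("pair ", a, "-", b, ": fewer than 2 jackknife blocks with data")
    return(NA_real_)
  }
  m <- site_mismatch(v$da[joint], v$db[joint])
  key <- .tile_key(dataset$sites$chrom[joint], dataset$sites$pos[joint],
                   block_size_bp)
  sv <- drop(rowsum(m, key))
  nv <- drop(rowsum(rep(1, length(m)), key))
  se <- .weighted_jackknife_se(nv, sv)
  if (is.na(se))
    warning("pair ", a, "-", b, ": fewer than 2 jackknife blocks with data")
  se
}

# Weighted delete-one jackknife SE for a ratio statistic sum(s)/sum(n),
# block weights = n. Busing et al. (1999) formulation; returns NA when
# fewer than 2 non-empty blocks are available.
.weighted_jackknife_se <- function(nv, sv) {
  keep <- nv > 0
  nv <- nv[keep]
  sv <- sv[keep]
  g <- length(nv)
  if (g < 2) return(NA_real_)
  N <- sum(nv)
  S <- sum(sv)
  theta <- S / N
  theta_del <- (S - sv) / (N - nv)
  h <- N / nv
  theta_j <- g * theta - sum((1 - nv / N) * theta_del)
  tau <- h * theta - (h - 1) * theta_del
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  sqrt(max(v, 0))
}

#' P0 for every pair of samples
#'
#' Computes the genome-wide pairwise mismatch rate, overlap and
#' block-jackknife SE for all `n*(n-1)/2` unordered pairs, ordered by the
#' input sample order (first sample major). The computation is blocked by
#' genomic tile and expressed as three matrix cross-products per tile, so
#' large datasets stay tractable; results agree with the per-pair functions
#' to machine precision.
#'
#' With `window_size_bp` set, the pair statistic `p0` is instead the
#' unweighted mean of per-window P0 values (the legacy window mode);
#' `overlap_n`, `mismatch_sum` and the jackknife SE remain genome-wide.
#'
#' @param dataset a [genotype_dataset] with at least two samples.
#' @param block_size_bp jackknife block width in bp.
#' @param jackknife compute `se_p0` (set `FALSE` to skip, e.g. for quick
#'   normalization scans).
#' @param window_size_bp `NULL` for the genome-wide estimator (default), or
#'   a window width in bp for the window-mean estimator.
#' @return data frame with one row per pair: `sample_a`, `sample_b`,
#'   `overlap_n`, `mismatch_sum`, `p0`, `se_p0`.
#' @export
all_pairs_p0 <- function(dataset, block_size_bp = 5e6, jackknife = TRUE,
                         window_size_bp = NULL) {
  n <- n_samples(dataset)
  if (n < 2) stop("need at least two samples")
  ids <- dataset$samples$id
  pi <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  pj <- sequence((n - 1L):1L) + pi
  lin <- (pj - 1L) * n + pi
  P <- length(pi)

  M <- !is.na(dataset$dosages)
  storage.mode(M) <- "double"
  D0 <- dataset$dosages
  D0[is.na(D0)] <- 0

  bs <- .pair_tile_stats(M, D0, dataset$sites, block_size_bp, lin)
  overlap <- colSums(bs$n)
  msum <- colSums(bs$s)
  p0 <- ifelse(overlap > 0, msum / overlap, NA_real_)
  if (any(overlap == 0))
    warning(sum(overlap == 0),
            " pair(s) share no covered sites; P0 reported as NA")

  if (!is.null(window_size_bp)) {
    ws <- .pair_tile_stats(M, D0, dataset$sites, window_size_bp, lin)
    wp0 <- ws$s / ws$n                      # NaN where window empty
    p0 <- colMeans(wp0, na.rm = TRUE)
    p0[colSums(ws$n > 0) == 0] <- NA_real_
  }

  se <- rep(NA_real_, P)
  if (jackknife) {
    for (k in seq_len(P))
      se[k] <- .weighted_jackknife_se(bs$n[, k], bs$s[, k])
    thin <- sum(is.na(se) & overlap > 0)
    if (thin > 0)
      warning(thin, " pair(s) have fewer than 2 jackknife blocks with data;",
              " SE reported as NA")
  }

  data.frame(sample_a = ids[pi], sample_b = ids[pj], overlap_n = overlap,
             mismatch_sum = msum, p0 = p0, se_p0 = se,
             stringsAsFactors = FALSE)
}

# Per-tile overlap and mismatch sums for all pairs.
# Returns list(n, s): tile x pair matrices. For a tile with indicator M and
# zero-filled dosages D, overlap = M M', and the pair mismatch sum is
# A + A' - 2 D D' with A = D M' (the bilinear expansion of d1+d2-2*d1*d2
# restricted to jointly observed sites).
.pair_tile_stats <- function(M, D0, sites, tile_bp, lin) {
  key <- .tile_key(sites$chrom, sites$pos, tile_bp)
  idxs <- split(seq_len(nrow(sites)), key)
  g <- length(idxs)
  bn <- matrix(0, g, length(lin))
  bsum <- matrix(0, g, length(lin))
  for (b in seq_len(g)) {
    cols <- idxs[[b]]
    Mb <- M[, cols, drop = FALSE]
    Db <- D0[, cols, drop = FALSE]
    O <- tcrossprod(Mb)
    A <- tcrossprod(Db, Mb)
    S <- A + t(A) - 2 * tcrossprod(Db)
    bn[b, ] <- O[lin]
    bsum[b, ] <- pmax(S[lin], 0)
  }
  list(n = bn, s = bsum)
}
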