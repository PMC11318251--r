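#' Classification constants for relatedness degrees
#'
#' Expected normalized P0 per class follows from the kinship coefficient
#' theta of each degree (`1 - theta`): 0.5 for identical/twins, 0.75 for
#' first degree, 0.875 for second, 0.9375 for third, 1 for unrelated.
#' Interior cutoffs are the midpoints between adjacent expectations; the
#' upper bound of the third-degree interval is fixed at 0.953125 rather
#' than the midpoint to unrelated, keeping the third-degree window
#' deliberately narrow against false positives.
#'
#' Data-amount gates are expressed in "expected mismatches" (overlap count
#' times the normalization value): third-degree calls require at least
#' 3000, first-degree subtyping at least 10000. Subtype bands on the
#' k0+k2 window proportion: parent-offspring below 0.30, siblings within
#' \[0.35, 0.60\].
#'
#' @param third_upper upper bound of the third-degree interval.
#' @param third_degree_gate,subtype_gate gates in expected mismatches.
#' @param subtype_po_max,subtype_sib_range subtype proportion bands.
#' @param count_third_in_k02 whether windows classified third-degree count
#'   towards the k0+k2 proportion (they indicate no full-chromosome
#'   sharing); `FALSE` restricts the numerator to identical + unrelated.
#' @return a list of class `degree_thresholds`.
#' @export
degree_thresholds <- function(third_upper = 0.953125,
                              third_degree_gate = 3000,
                              subtype_gate = 10000,
                              subtype_po_max = 0.30,
                              subtype_sib_range = c(0.35, 0.60),
                              count_third_in_k02 = TRUE) {
  theta <- c(identical = 0.5, first = 0.25, second = 0.125,
             third = 0.0625, unrelated = 0)
  expected <- 1 - theta
  cutoffs <- (expected[-length(expected)] + expected[-1]) / 2
  cutoffs[length(cutoffs)] <- third_upper
  names(cutoffs) <- NULL
  structure(list(expected = expected, cutoffs = cutoffs,
                 third_degree_gate = third_degree_gate,
                 subtype_gate = subtype_gate,
                 subtype_po_max = subtype_po_max,
                 subtype_sib_range = subtype_sib_range,
                 count_third_in_k02 = count_third_in_k02),
            class = "degree_thresholds")
}

.DEGREE_LABELS <- c("IdenticalTwin", "FirstDegree", "SecondDegree",
                    "ThirdDegree", "Unrelated")
.WINDOW_LABELS <- c("identical", "first", "second", "third", "unrelated")

#' Estimate the normalization value (expected unrelated P0)
#'
#' Every P0 is interpreted relative to the mismatch expected for an
#' unrelated pair from the same population and SNP panel, which absorbs
#' population diversity and ascertainment. By default this baseline is the
#' median P0 across all pairs in the dataset — robust as long as most pairs
#' are unrelated; it is unreliable for very small datasets (a warning is
#' issued below 6 pairs, i.e. fewer than 4 samples), where a `user` value
#' from external data (or twice the P0 of a technical-replicate pair)
#' should be supplied instead.
#'
#' @param pair_table output of [all_pairs_p0].
#' @param method `"median"` (default), `"mean"`, or `"user"`.
#' @param user_value positive baseline used verbatim when `method="user"`.
#' @return a list of class `normalization_context` with `value`, `method`
#'   and `n_pairs`.
#' @export
compute_normalization <- function(pair_table,
                                  method = c("median", "mean", "user"),
                                  user_value = NULL) {
  method <- match.arg(method)
  if (method == "user") {
    if (is.null(user_value) || !is.finite(user_value) || user_value <= 0)
      stop("method='user' requires a positive user_value")
    return(structure(list(value = user_value, method = "user",
                          n_pairs = NA_integer_),
                     class = "normalization_context"))
  }
  p0 <- pair_table$p0
  p0 <- p0[!is.na(p0)]
  if (length(p0) == 0)
    stop("no pairs with data to estimate the normalization value from")
  if (length(p0) < 6)
    warning("normalization estimated from only ", length(p0),
            " pair(s); supply a user value for small datasets")
  value <- if (method == "median") stats::median(p0) else mean(p0)
  if (!is.finite(value) || value <= 0)
    stop("estimated normalization value is not positive: ", value)
  structure(list(value = value, method = method, n_pairs = length(p0)),
            class = "normalization_context")
}

#' @export
print.normalization_context <- function(x, ...) {
  cat(sprintf("normalization value %.6f (method: %s%s)\n", x$value, x$method,
              if (is.na(x$n_pairs)) "" else sprintf(", %d pairs", x$n_pairs)))
  invisible(x)
}

.norm_value <- function(norm) {
  if (inherits(norm, "normalization_context")) norm$value
  else if (is.numeric(norm) && length(norm) == 1 && norm > 0) norm
  else stop("norm must be a normalization_context or a positive number")
}

#' Expected number of mismatches for a pair
#'
#' `overlap_n * normalization value`: the number of allele differences the
#' pair would show if unrelated. This is the method's measure of the
#' information available for a pair — comparable across SNP panels and
#' populations, unlike the raw SNP count — and is what the classification
#' gates are expressed in.
#'
#' @param overlap_n jointly covered site count(s).
#' @param norm a `normalization_context` or positive number.
#' @return numeric vector.
#' @export
expected_mismatches <- function(overlap_n, norm) {
  stopifnot(all(overlap_n >= 0))
  overlap_n * .norm_value(norm)
}

#' Classify a normalized P0 into a relatedness degree
#'
#' Half-open intervals, closed on the left: `[0, 0.625)` identical/twin,
#' `[0.625, 0.8125)` first degree, `[0.8125, 0.90625)` second degree,
#' `[0.90625, 0.953125)` third degree, `[0.953125, Inf)` unrelated. A pair
#' in the third-degree interval with fewer than `third_degree_gate`
#' expected mismatches is reported as `Unrelated_consistent_with_3rd`: at
#' that data level the second/third/unrelated ranges overlap too much for a
#' confident call.
#'
#' @param normalized_p0 numeric vector of P0 / normalization value.
#' @param expected_mismatches numeric vector (recycled) of expected
#'   mismatches, see [expected_mismatches].
#' @param thresholds a [degree_thresholds] list.
#' @return character vector of degree labels.
#' @export
classify_degree <- function(normalized_p0, expected_mismatches,
                            thresholds = degree_thresholds()) {
  stopifnot(all(normalized_p0 >= 0, na.rm = TRUE))
  k <- findInterval(normalized_p0, thresholds$cutoffs)
  lab <- .DEGREE_LABELS[k + 1L]
  em <- rep_len(expected_mismatches, length(lab))
  gate <- !is.na(lab) & lab == "ThirdDegree" &
    em < thresholds$third_degree_gate
  lab[gate] <- "Unrelated_consistent_with_3rd"
  lab
}

#' Classify a single window's normalized P0
#'
#' Same intervals as [classify_degree] but without any data gate; used for
#' the per-window pass behind first-degree subtyping.
#'
#' @param normalized_window_p0 per-window P0 divided by the genome-wide
#'   normalization value.
#' @param thresholds a [degree_thresholds] list.
#' @return factor-free character vector in
#'   `c("identical","first","second","third","unrelated")`.
#' @export
window_class <- function(normalized_window_p0,
                         thresholds = degree_thresholds()) {
  .WINDOW_LABELS[findInterval(normalized_window_p0, thresholds$cutoffs) + 1L]
}

#' Proportion of windows sharing zero or two chromosomes
#'
#' For a first-degree pair, the fraction of windows classified as
#' "identical" (both chromosomes shared, Cotterman k2) or
#' "unrelated"/"third" (no chromosome fully shared, k0). Parent-offspring
#' pairs share exactly one chromosome everywhere, so this proportion is
#' near 0; full siblings are in k0 or k2 for about half the genome, so it
#' is near 0.5. Computed from large (20 Mb) windows where IBD state is
#' nearly constant.
#'
#' @param windows data frame from [pair_p0_windows].
#' @param norm the genome-wide `normalization_context` (a single baseline
#'   is used for all windows).
#' @param thresholds a [degree_thresholds] list.
#' @return proportion in \[0, 1\], or `NA` when no window has data.
#' @export
k02_proportion <- function(windows, norm, thresholds = degree_thresholds()) {
  if (nrow(windows) == 0) {
    warning("no windows with data; k0+k2 proportion is NA")
    return(NA_real_)
  }
  cls <- window_class(windows$p0 / .norm_value(norm), thresholds)
  counted <- c("identical", "unrelated",
               if (thresholds$count_third_in_k02) "third")
  mean(cls %in% counted)
}

#' Resolve a first-degree pair into parent-offspring or siblings
#'
#' Requires at least `subtype_gate` (default 10000) expected mismatches;
#' below that, window classifications are too noisy and the proportion
#' drifts upward, which would turn parent-offspring pairs into spurious
#' "siblings". Above the gate: proportion < 0.30 is `ParentOffspring`,
#' within \[0.35, 0.60\] is `Siblings`, anything else `NotApplicable`.
#'
#' @param proportion k0+k2 window proportion from [k02_proportion].
#' @param expected_mismatches the pair's expected mismatches.
#' @param thresholds a [degree_thresholds] list.
#' @return character vector of subtype labels.
#' @export
classify_subtype <- function(proportion, expected_mismatches,
                             thresholds = degree_thresholds()) {
  out <- rep("NotApplicable", max(length(proportion),
                                  length(expected_mismatches)))
  p <- rep_len(proportion, length(out))
  em <- rep_len(expected_mismatches, length(out))
  open <- !is.na(p) & em >= thresholds$subtype_gate
  out[open & p < thresholds$subtype_po_max] <- "ParentOffspring"
  out[open & p >= thresholds$subtype_sib_range[1] &
        p <= thresholds$subtype_sib_range[2]] <- "Siblings"
  out
}

#' Kinship coefficient and confidence interval from P0
#'
#' `theta = 1 - P0/normalization`; the 95% interval is the normal
#' approximation `theta +/- 1.96 * se_p0/normalization`, reported
#' untruncated (a negative lower bound simply reflects noise around an
#' unrelated pair).
#'
#' @param p0 raw P0 value(s).
#' @param se_p0 jackknife SE(s) of P0.
#' @param norm a `normalization_context` or positive number.
#' @return data frame with `theta`, `ci_low`, `ci_high`.
#' @export
theta_with_ci <- function(p0, se_p0, norm) {
  stopifnot(all(se_p0 >= 0, na.rm = TRUE))
  v <- .norm_value(norm)
  theta <- 1 - p0 / v
  half <- 1.96 * se_p0 / v
  data.frame(theta = theta, ci_low = theta - half, ci_high = theta + half)
}

#' Configuration for the full classifier
#'
#' @param norm_method,norm_value see [compute_normalization].
#' @param window_size_bp `NULL` for the genome-wide P0 estimator (default,
#'   the most accurate choice) or a window width in bp for the legacy
#'   window-mean estimator.
#' @param subtype_window_size_bp window width for the first-degree subtype
#'   pass; 20 Mb keeps IBD state nearly constant within a window
#'   (IBD segments average 50 cM at ~1 cM/Mb).
#' @param block_size_bp jackknife block width.
#' @param thresholds a [degree_thresholds] list.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(norm_method = "median", norm_value = NULL,
                              window_size_bp = NULL,
                              subtype_window_size_bp = 20e6,
                              block_size_bp = 5e6,
                              thresholds = degree_thresholds()) {
  structure(list(norm_method = norm_method, norm_value = norm_value,
                 window_size_bp = window_size_bp,
                 subtype_window_size_bp = subtype_window_size_bp,
                 block_size_bp = block_size_bp, thresholds = thresholds),
            class = "classifier_config")
}

#' Run the full kinship classification pipeline
#'
#' For every pair of samples: genome-wide P0 with block-jackknife SE,
#' normalization, degree classification with data-amount gating, a 20-Mb
#' window pass with subtype resolution for first-degree pairs, and the
#' kinship coefficient theta with its 95% interval. No pair is ever
#' dropped; pairs without joint coverage are reported with `NA` statistics.
#'
#' @param dataset a [genotype_dataset] with at least two samples.
#' @param config a [classifier_config].
#' @return data frame of class `kinship_calls`, one row per pair, with the
#'   normalization context attached as attribute `"normalization"`.
#' @export
run_classifier <- function(dataset, config = classifier_config()) {
  th <- config$thresholds
  pt <- all_pairs_p0(dataset, block_size_bp = config$block_size_bp,
                     window_size_bp = config$window_size_bp)
  norm <- compute_normalization(pt, config$norm_method, config$norm_value)
  v <- norm$value
  npo <- pt$p0 / v
  em <- expected_mismatches(pt$overlap_n, norm)
  degree <- classify_degree(npo, em, th)

  k02 <- rep(NA_real_, nrow(pt))
  subtype <- rep("NotAttempted", nrow(pt))
  for (k in which(!is.na(degree) & degree == "FirstDegree")) {
    w <- pair_p0_windows(dataset, pt$sample_a[k], pt$sample_b[k],
                         config$subtype_window_size_bp)
    k02[k] <- if (nrow(w)) k02_proportion(w, norm, th) else NA_real_
    subtype[k] <- classify_subtype(k02[k], em[k], th)
  }

  tc <- theta_with_ci(pt$p0, pt$se_p0, norm)
  res <- data.frame(
    sample_a = pt$sample_a, sample_b = pt$sample_b,
    overlap_n = pt$overlap_n, p0 = pt$p0, se_p0 = pt$se_p0,
    normalized_p0 = npo, se_normalized = pt$se_p0 / v,
    theta = tc$theta, theta_ci_low = tc$ci_low, theta_ci_high = tc$ci_high,
    expected_mismatches = em, degree = degree, subtype = subtype,
    k02_proportion = k02, stringsAsFactors = FALSE)
  attr(res, "normalization") <- norm
  attr(res, "config") <- config
  class(res) <- c("kinship_calls", class(res))
  res
}

#' Write classification results as a tab-separated table
#'
#' One row per pair with the columns of the standard results table
#' (`PairIndividual1` ... `K02Proportion`), preceded by comment lines
#' recording the package version, seed and normalization value (printed to
#' 6 decimals, since classifications near a cutoff can flip with the
#' normalization). `NotApplicable` subtypes are rendered as `N/A`,
#' `NotAttempted` as `-`.
#'
#' @param calls a `kinship_calls` data frame from [run_classifier].
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(calls, path, seed = NULL) {
  norm <- attr(calls, "normalization")
  subtype <- calls$subtype
  subtype[subtype == "NotApplicable"] <- "N/A"
  subtype[subtype == "NotAttempted"] <- "-"
  out <- data.frame(
    PairIndividual1 = calls$sample_a, PairIndividual2 = calls$sample_b,
    OverlapNSNPs = calls$overlap_n, P0_raw = calls$p0,
    P0_normalized = calls$normalized_p0, SE_normalized = calls$se_normalized,
    Theta = calls$theta, Theta_CI95_low = calls$theta_ci_low,
    Theta_CI95_high = calls$theta_ci_high,
    ExpectedMismatches = calls$expected_mismatches,
    Degree = calls$degree, FirstDegreeSubtype = subtype,
    K02Proportion = calls$k02_proportion, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# kinmatch ", as.character(utils::packageVersion("kinmatch"))),
    paste0("# seed: ", if (is.null(seed)) "none" else seed,
           "  normalization: ",
           if (is.null(norm)) "none" else
             sprintf("%.6f (%s)", norm$value, norm$method))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
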