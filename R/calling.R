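#' Build reference statistics from a euploid cohort
#'
#' Summarises per-chromosome percentages over a cohort of euploid reference
#' profiles: mean and standard deviation (n-1 denominator) per target
#' chromosome, keeping the raw percentage vectors for the rank-based z
#' variant.  References must be processed by the same pipeline arm as the
#' samples scored against them (size-selected references for size-selected
#' samples), so that the null distribution of the z-score is standard
#' normal.
#'
#' @param profiles List of [chromosome_profile()] results (>= 20).
#' @param chroms Target chromosomes (default chr13, chr18, chr21).
#' @return Object of class `reference_stats`: list with `mean`, `sd`,
#'   `values` (matrix cohort x chromosome) and `n`.
#' @export
build_reference <- function(profiles, chroms = c("chr13", "chr18", "chr21")) {
  if (!is.list(profiles) || length(profiles) < 20)
    stop("need at least 20 euploid reference profiles", call. = FALSE)
  if (!all(vapply(profiles, inherits, logical(1), "chrom_profile")))
    stop("'profiles' must be a list of chrom_profile objects", call. = FALSE)
  vals <- t(vapply(profiles, function(p) p$pct[chroms], numeric(length(chroms))))
  colnames(vals) <- chroms
  m <- colMeans(vals)
  s <- apply(vals, 2, stats::sd)
  if (any(s == 0))
    stop("degenerate reference: zero variance on ",
         paste(chroms[s == 0], collapse = ", "), call. = FALSE)
  structure(list(mean = m, sd = s, values = vals, n = nrow(vals),
                 chroms = chroms), class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("reference_stats: n = %d\n", x$n))
  for (ch in x$chroms)
    cat(sprintf("  %s: mean %.5f, sd %.6f\n", ch, x$mean[ch], x$sd[ch]))
  invisible(x)
}

#' z-score of a chromosome percentage against a reference cohort
#'
#' The primary method is the standard reference-cohort z-score
#' `z = (p - mean_ref) / sd_ref`, the statistic universally used for
#' shallow-sequencing aneuploidy screening.  A rank-based alternative is
#' available: the sample percentage's Mann-Whitney placement among the
#' reference values, normal-approximated as
#' `z = (U - n/2) / sqrt(n (n + 2) / 12)` with `U` the number of reference
#' values below the sample (ties counted half).
#'
#' @param profile A [chromosome_profile()] result.
#' @param ref A [build_reference()] result.
#' @param chrom Target chromosome, one of the reference's chromosomes.
#' @param method `"zscore"` (default) or `"rank"`.
#' @return A single z value.
#' @export
z_score <- function(profile, ref, chrom, method = c("zscore", "rank")) {
  method <- match.arg(method)
  if (!inherits(ref, "reference_stats")) stop("'ref' must be reference_stats", call. = FALSE)
  if (!chrom %in% ref$chroms)
    stop("'chrom' must be one of: ", paste(ref$chroms, collapse = ", "), call. = FALSE)
  p <- unname(profile$pct[chrom])
  if (method == "zscore") {
    s <- ref$sd[chrom]
    if (s == 0) stop("reference sd is zero", call. = FALSE)
    return(unname((p - ref$mean[chrom]) / s))
  }
  v <- ref$values[, chrom]
  u <- sum(v < p) + 0.5 * sum(v == p)
  n <- length(v)
  (u - n / 2) / sqrt(n * (n + 2) / 12)
}

#' Three-way aneuploidy classification from a z-score
#'
#' `z > 4.00` is called affected, `z < 2.58` unaffected, and anything in the
#' closed band \[2.58, 4.00\] is a "no call" (the boundaries themselves are
#' no calls: the quoted decision rule uses strict inequalities on both
#' sides).
#'
#' @param z Finite z-score(s); vectorised.
#' @param affected_threshold,unaffected_threshold Decision thresholds
#'   (defaults 4.00 and 2.58).
#' @return Character vector in `{"affected", "unaffected", "no_call"}`.
#' @export
classify <- function(z, affected_threshold = 4.00, unaffected_threshold = 2.58) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric", call. = FALSE)
  out <- rep("no_call", length(z))
  out[z > affected_threshold] <- "affected"
  out[z < unaffected_threshold] <- "unaffected"
  out
}

#' Call aneuploidy for the target chromosomes of one sample
#'
#' @param profile A [chromosome_profile()] result.
#' @param ref A [build_reference()] result.
#' @param chroms Chromosomes to call (default: all in the reference).
#' @param arm Pipeline tag recorded with the calls (e.g. `"NIPS"`,
#'   `"iNIPS"`).
#' @param method z-score method, see [z_score()].
#' @return data.frame with columns chrom, z, class, arm.
#' @export
call_aneuploidy <- function(profile, ref, chroms = ref$chroms, arm = "NIPS",
                            method = c("zscore", "rank")) {
  method <- match.arg(method)
  z <- vapply(chroms, function(ch) z_score(profile, ref, ch, method), numeric(1))
  data.frame(chrom = chroms, z = unname(z), class = classify(unname(z)),
             arm = arm, row.names = NULL)
}

#' Trisomic fetal DNA fraction from chromosome over-representation
#'
#' Under a trisomy carried by a fraction of fetal DNA, the target
#' chromosome's percentage is elevated by half that fraction, so the
#' trisomic fetal fraction is recovered as `2 (p / mean_ref - 1)`, clamped
#' below at 0 for under-represented chromosomes.
#'
#' @param p Observed chromosome percentage (autosome-denominated fraction).
#' @param mean_ref Euploid reference mean of the same percentage (> 0).
#' @return Trisomic fetal DNA fraction in \[0, ...\].
#' @examples
#' trisomic_ff_from_ratio(1.028, 1)  # 0.056
#' @export
trisomic_ff_from_ratio <- function(p, mean_ref) {
  if (any(mean_ref <= 0)) stop("'mean_ref' must be positive", call. = FALSE)
  pmax(2 * (p / mean_ref - 1), 0)
}

#' Degree of placental mosaicism
#'
#' The fraction of the fetal lineage carrying the trisomy: trisomic fetal
#' DNA fraction divided by the total fetal fraction.  A sample with a
#' trisomic fraction of 5.6% and a total fetal fraction of 44% has a
#' mosaicism degree of 12.7%.
#'
#' @param ff_trisomic Trisomic fetal DNA fraction, `0 <= ff_trisomic <= ff_total`.
#' @param ff_total Total fetal fraction, in (0, 1].
#' @return Mosaicism degree in \[0, 1\].
#' @examples
#' mosaicism_degree(0.056, 0.44)
#' @export
mosaicism_degree <- function(ff_trisomic, ff_total) {
  if (any(ff_total <= 0 | ff_total > 1))
    stop("'ff_total' must lie in (0, 1]", call. = FALSE)
  if (any(ff_trisomic < 0)) stop("'ff_trisomic' must be nonnegative", call. = FALSE)
  if (any(ff_trisomic > ff_total))
    stop("'ff_trisomic' cannot exceed 'ff_total'", call. = FALSE)
  ff_trisomic / ff_total
}
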