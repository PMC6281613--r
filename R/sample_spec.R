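#' Simulation parameters for one maternal-plasma sample
#'
#' Bundles everything that defines a simulated sample: fetal fraction, fetal
#' sex, fetal aneuploidy state with optional placental mosaicism, maternal
#' copy-number abnormalities, sequencing depth and RNG seed.
#'
#' Mosaicism is the fraction `m` of the fetal (placental) lineage carrying
#' the trisomy; a non-mosaic trisomy has `m = 1`, which multiplies the
#' target chromosome's fetal weight by 1.5 (three copies instead of two).
#' In general the fetal weight is `1 + 0.5 m`.
#'
#' @param ff Fetal fraction in \[0, 1\].
#' @param fetal_sex `"male"` or `"female"`.
#' @param aneuploidy `"none"`, `"chr13"`, `"chr18"` or `"chr21"` (trisomy).
#' @param mosaicism Degree of placental mosaicism in \[0, 1\]; defaults to 1
#'   when an aneuploidy is set and 0 otherwise.  Positive mosaicism with
#'   `aneuploidy = "none"` is an error.
#' @param maternal_cnv Optional data.frame with columns `chrom` and
#'   `copy_ratio` describing maternal aneuploidies/CNVs (copy_ratio 1.5 =
#'   maternal trisomy, 1.05 = small duplication, etc.).
#' @param n_fragments Total fragments to simulate before any selection
#'   (default 5e6).
#' @param seed Optional RNG seed used by [simulate_sample()].
#' @param sample_id Optional identifier.
#' @return Object of class `sample_spec`.
#' @export
sample_spec <- function(ff, fetal_sex = c("male", "female"),
                        aneuploidy = c("none", "chr13", "chr18", "chr21"),
                        mosaicism = NULL, maternal_cnv = NULL,
                        n_fragments = 5e6, seed = NULL, sample_id = NULL) {
  stopifnot_scalar_prob(ff, "ff")
  fetal_sex <- match.arg(fetal_sex)
  aneuploidy <- match.arg(aneuploidy)
  if (is.null(mosaicism)) mosaicism <- if (aneuploidy == "none") 0 else 1
  stopifnot_scalar_prob(mosaicism, "mosaicism")
  if (aneuploidy == "none" && mosaicism > 0)
    stop("mosaicism > 0 requires a fetal aneuploidy", call. = FALSE)
  if (!is.null(maternal_cnv)) {
    if (!is.data.frame(maternal_cnv) ||
        !all(c("chrom", "copy_ratio") %in% names(maternal_cnv)))
      stop("'maternal_cnv' must be a data.frame with columns chrom, copy_ratio",
           call. = FALSE)
    if (any(maternal_cnv$copy_ratio <= 0))
      stop("maternal copy ratios must be positive", call. = FALSE)
  }
  if (!is.numeric(n_fragments) || length(n_fragments) != 1L || n_fragments <= 0)
    stop("'n_fragments' must be a positive number", call. = FALSE)

  structure(list(
    ff = ff, fetal_sex = fetal_sex, aneuploidy = aneuploidy,
    mosaicism = mosaicism, maternal_cnv = maternal_cnv,
    n_fragments = as.integer(round(n_fragments)), seed = seed,
    sample_id = if (is.null(sample_id)) "sample" else as.character(sample_id)
  ), class = "sample_spec")
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf(
    "sample_spec '%s': FF = %.3f, %s fetus, aneuploidy = %s (m = %g), %d fragments\n",
    x$sample_id, x$ff, x$fetal_sex, x$aneuploidy, x$mosaicism, x$n_fragments))
  if (!is.null(x$maternal_cnv))
    cat("  maternal CNV:", paste(x$maternal_cnv$chrom, x$maternal_cnv$copy_ratio,
                                 sep = "x", collapse = ", "), "\n")
  invisible(x)
}
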