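#' Fetal fraction from the chrY read percentage
#'
#' For a male-fetus pregnancy the fetal fraction follows from the chrY read
#' share by linear interpolation between the female background and the
#' adult-male level:
#' \deqn{FF = (\%chrY_{MF} - \%chrY_{FF}) / (\%chrY_{AM} - \%chrY_{FF})}
#' where `MF` is the measured sample, `FF` the female-pregnancy background
#' (misalignment floor) and `AM` the average of adult male plasma (0.170%).
#' All arguments are autosome-denominated fractions (0.170% = 0.0017).
#' Estimates are clamped to \[0, 1\]; a negative raw value (sampling noise
#' near FF = 0) maps to 0 with a warning.
#'
#' @param pct_y_mf Measured chrY fraction of the sample.
#' @param pct_y_ff Female-background chrY fraction (default 2e-5).
#' @param pct_y_am Adult-male chrY fraction (default 0.0017).
#' @return Object of class `ff_estimate`: list with `value`, `method`,
#'   `inputs`.
#' @examples
#' ff_from_chry(0.000188)$value  # ~0.10
#' @export
ff_from_chry <- function(pct_y_mf, pct_y_ff = 2e-5, pct_y_am = 0.0017) {
  if (pct_y_am <= pct_y_ff)
    stop("adult-male chrY level must exceed the female background", call. = FALSE)
  raw <- (pct_y_mf - pct_y_ff) / (pct_y_am - pct_y_ff)
  if (any(raw < 0))
    warning("negative raw fetal-fraction estimate clamped to 0")
  structure(list(
    value = clamp(raw, 0, 1), method = "chrY",
    inputs = c(pct_y_mf = pct_y_mf, pct_y_ff = pct_y_ff, pct_y_am = pct_y_am)
  ), class = "ff_estimate")
}

#' @export
print.ff_estimate <- function(x, ...) {
  cat(sprintf("ff_estimate (%s): %.4f\n", x$method, x$value))
  invisible(x)
}

#' Enrichment metrics comparing fetal fractions before and after selection
#'
#' `ff_fold = ff_after / ff_before` measures the fetal enrichment;
#' `maternal_decrease = (1 - ff_before) / (1 - ff_after)` measures how much
#' the maternal background shrank.  Vectorised over samples.
#'
#' @param ff_before,ff_after Fetal fractions in (0, 1).
#' @return data.frame of class `enrichment_metrics` with columns ff_before,
#'   ff_after, ff_fold, maternal_decrease.
#' @examples
#' enrichment_metrics(0.15, 0.375)
#' @export
enrichment_metrics <- function(ff_before, ff_after) {
  if (any(ff_before <= 0 | ff_before >= 1))
    stop("'ff_before' must lie in (0, 1)", call. = FALSE)
  if (any(ff_after <= 0 | ff_after >= 1))
    stop("'ff_after' must lie in (0, 1)", call. = FALSE)
  out <- data.frame(
    ff_before = ff_before, ff_after = ff_after,
    ff_fold = ff_after / ff_before,
    maternal_decrease = (1 - ff_before) / (1 - ff_after)
  )
  class(out) <- c("enrichment_metrics", "data.frame")
  out
}
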