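#' Size window
#'
#' An inclusive fragment-size window, either in the insert frame (the cfDNA
#' fragment itself) or in the library frame (insert plus sequencing
#' adapters).  Both bounds are inclusive, matching the way electrophoretic
#' windows such as "125-135 bp" are quoted.
#'
#' @param low,high Window bounds in bp, `low <= high`, both positive.
#' @param frame `"insert"` (default) or `"library"`.
#' @return Object of class `size_window`.
#' @export
size_window <- function(low, high, frame = c("insert", "library")) {
  frame <- match.arg(frame)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L || length(high) != 1L)
    stop("'low' and 'high' must be single numbers", call. = FALSE)
  if (low <= 0 || high < low)
    stop("need 0 < low <= high", call. = FALSE)
  structure(list(low = as.numeric(low), high = as.numeric(high), frame = frame),
            class = "size_window")
}

as_size_window <- function(x) {
  if (inherits(x, "size_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(size_window(x[1], x[2]))
  stop("expected a size_window or a numeric (low, high) pair", call. = FALSE)
}

#' @export
print.size_window <- function(x, ...) {
  cat(sprintf("size_window [%g, %g] bp (%s frame)\n", x$low, x$high, x$frame))
  invisible(x)
}

#' Convert a library-size window to an insert-size window
#'
#' Sequencing libraries carry adapters on both ends; a gel selection quoted
#' in library size corresponds to inserts shorter by the total adapter
#' length.  With the default 90 bp of adapter, a 190-240 bp library window
#' selects 100-150 bp inserts.
#'
#' @param window A [size_window()] in the library frame.
#' @param adapter_total Total adapter length in bp added to an insert
#'   (default 90).
#' @return A `size_window` in the insert frame.
#' @examples
#' library_to_insert(size_window(190, 240, frame = "library"))
#' @export
library_to_insert <- function(window, adapter_total = 90) {
  window <- as_size_window(window)
  if (window$frame != "library")
    stop("'window' must be in the library frame", call. = FALSE)
  if (window$low <= adapter_total)
    stop("library window lower bound must exceed the total adapter length",
         call. = FALSE)
  size_window(window$low - adapter_total, window$high - adapter_total,
              frame = "insert")
}

#' Closed-form fetal fraction after size selection
#'
#' Selecting a fragment subset in which fetal fragments fall with
#' probability `p_f` and maternal fragments with probability `p_m` turns a
#' fetal fraction `ff` into
#' \deqn{ff' = ff \, p_f / (ff \, p_f + (1 - ff)\, p_m).}
#' This is the analytic oracle the simulation-based enrichment results are
#' checked against.
#'
#' @param ff Fetal fraction(s) in \[0, 1\] (vectorised).
#' @param probs A [window_probability()] result (or any list with `p_f`,
#'   `p_m`).
#' @return Post-selection fetal fraction(s).
#' @examples
#' m <- length_model()
#' predict_enriched_ff(0.02, window_probability(m, size_window(125, 135)))
#' @export
predict_enriched_ff <- function(ff, probs) {
  if (any(ff < 0 | ff > 1, na.rm = TRUE)) stop("'ff' must lie in [0, 1]", call. = FALSE)
  p_f <- probs$p_f; p_m <- probs$p_m
  if (p_f == 0 && p_m == 0) stop("p_f and p_m are both zero", call. = FALSE)
  den <- ff * p_f + (1 - ff) * p_m
  if (any(den == 0)) stop("selection denominator is zero", call. = FALSE)
  ff * p_f / den
}

#' Apply in-silico size selection to a sample
#'
#' The electronic analogue of a gel cut: fragments whose insert length lies
#' inside the (inclusive) window are retained.  In fragment mode the records
#' are filtered directly.  In count mode with `renormalize_depth = TRUE`
#' (the default) selection precedes sequencing: the selected library is
#' treated as an effectively unlimited molecular pool whose composition is
#' the sample's (bin, origin) counts tilted by the origin window
#' probabilities, and it is sequenced back to the original depth by a fresh
#' multinomial draw from those proportions.  With
#' `renormalize_depth = FALSE` each (bin, origin) count is thinned
#' binomially with its origin's window probability, matching fragment-mode
#' filtering read for read.
#'
#' @param sample A [fragment_set].
#' @param window A [size_window()] in the insert frame.
#' @param renormalize_depth Resample count-mode totals back to the
#'   pre-selection depth (ignored in fragment mode, which only filters).
#' @param seed Optional seed for the count-mode thinning/resampling.
#' @return A `fragment_set` marked as post-selection.
#' @export
apply_size_selection <- function(sample, window, renormalize_depth = TRUE,
                                 seed = NULL) {
  if (!inherits(sample, "fragment_set")) stop("'sample' must be a fragment_set", call. = FALSE)
  window <- as_size_window(window)
  if (window$frame != "insert")
    stop("window must be in the insert frame; use library_to_insert()", call. = FALSE)

  out <- sample
  out$selection <- list(window = window, renormalized = renormalize_depth)
  out$provenance <- "post_selection"

  if (sample$mode == "fragment") {
    len <- sample$fragments$length
    keep <- len >= window$low & len <= window$high
    if (!any(keep)) stop("no fragments survive the size selection", call. = FALSE)
    out$fragments <- sample$fragments[keep, , drop = FALSE]
    rownames(out$fragments) <- NULL
    out$n_total <- nrow(out$fragments)
    return(out)
  }

  probs <- window_probability(sample$model, window)
  with_seed(seed, {
    nb <- nrow(sample$counts)
    if (renormalize_depth) {
      # Selection precedes sequencing, and a plasma library holds far more
      # molecules than are ever sequenced: the selected library is the
      # sample's generating population tilted by the window probabilities,
      # and sequencing it back to the original depth is one fresh
      # multinomial draw over (bin, origin) from those proportions.
      if (is.null(sample$joint_probs))
        stop("sample carries no population distribution; cannot renormalize depth",
             call. = FALSE)
      v <- c(sample$joint_probs[, "maternal"] * probs$p_m,
             sample$joint_probs[, "fetal"] * probs$p_f)
      if (sum(v) == 0) stop("no fragments survive the size selection", call. = FALSE)
      n0 <- sum(sample$counts)
      drawn <- stats::rmultinom(1, n0, v)[, 1]
      new_counts <- matrix(drawn, nrow = nb,
                           dimnames = list(NULL, c("maternal", "fetal")))
      out$joint_probs <- matrix(v / sum(v), nrow = nb,
                                dimnames = list(NULL, c("maternal", "fetal")))
    } else {
      # Thinning only: each sequenced fragment is kept independently with
      # its origin's window probability (matches fragment-mode filtering).
      new_counts <- cbind(
        maternal = stats::rbinom(nb, sample$counts[, "maternal"], probs$p_m),
        fetal = stats::rbinom(nb, sample$counts[, "fetal"], probs$p_f)
      )
      if (sum(new_counts) == 0)
        stop("no fragments survive the size selection", call. = FALSE)
      if (!is.null(sample$joint_probs)) {
        v <- c(sample$joint_probs[, "maternal"] * probs$p_m,
               sample$joint_probs[, "fetal"] * probs$p_f)
        out$joint_probs <- matrix(v / sum(v), nrow = nb,
                                  dimnames = list(NULL, c("maternal", "fetal")))
      }
    }
    out$counts <- new_counts
    out$n_total <- sum(new_counts)
  })
  out
}
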