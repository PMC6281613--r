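#' Filter fragments by mapping quality, length and duplicate status
#'
#' Retains fragment records with MAPQ strictly greater than `min_mapq`,
#' insert length strictly greater than `min_len` bp, and no duplicate flag.
#' Count-mode samples pass through unchanged: the quality filters are
#' independent of genomic position, so they only rescale the depth, and
#' count mode represents the post-filter joint distribution directly.
#'
#' @param fragments A [fragment_set].
#' @param min_mapq Exclusive MAPQ threshold (default 10).
#' @param min_len Exclusive length threshold in bp (default 35).
#' @return A filtered `fragment_set` (possibly empty).
#' @export
filter_fragments <- function(fragments, min_mapq = 10, min_len = 35) {
  if (!inherits(fragments, "fragment_set")) stop("'fragments' must be a fragment_set", call. = FALSE)
  if (fragments$mode == "count") return(fragments)
  fr <- fragments$fragments
  keep <- fr$mapq > min_mapq & fr$length > min_len & !fr$duplicate
  fragments$fragments <- fr[keep, , drop = FALSE]
  rownames(fragments$fragments) <- NULL
  fragments$n_total <- sum(keep)
  fragments
}

#' Bin fragment counts over the genome model
#'
#' Assigns each fragment to the fixed-size bin containing its start
#' coordinate (0-based, half-open bins) and attaches per-bin GC content
#' rounded to 0.1%.  Count-mode samples already carry per-bin counts and are
#' tabulated directly.
#'
#' @param fragments A (filtered) [fragment_set].
#' @param genome The genome model; defaults to the one attached to the sample.
#' @return A `bin_table`: data.frame with columns chrom, start, end, gc
#'   (rounded to 0.001), n_mask, raw, masked, corrected.
#' @export
bin_counts <- function(fragments, genome = fragments$genome) {
  if (!inherits(fragments, "fragment_set")) stop("'fragments' must be a fragment_set", call. = FALSE)
  if (!inherits(genome, "genome_model")) stop("'genome' must be a genome_model", call. = FALSE)
  bins <- genome$bins
  if (fragments$mode == "count") {
    raw <- as.numeric(rowSums(fragments$counts))
    if (nrow(fragments$counts) != nrow(bins))
      stop("count matrix does not match the genome's bin layout", call. = FALSE)
  } else {
    fr <- fragments$fragments
    chrom <- as.character(fr$chrom)
    unknown <- !(chrom %in% names(genome$chrom_lengths))
    if (any(unknown)) stop("fragment on unknown chromosome: ", chrom[which(unknown)[1]], call. = FALSE)
    lens <- genome$chrom_lengths[chrom]
    if (any(fr$start < 0 | fr$start >= lens))
      stop("fragment start outside the genome", call. = FALSE)
    idx <- genome$bin_offset[chrom] + fr$start %/% genome$bin_size + 1
    raw <- tabulate(idx, nbins = nrow(bins))
  }
  bt <- data.frame(
    chrom = bins$chrom, start = bins$start, end = bins$end,
    gc = round(bins$gc, 3), n_mask = bins$n_mask,
    raw = raw, masked = FALSE, corrected = NA_real_
  )
  attr(bt, "autosomes") <- genome$autosomes
  class(bt) <- c("bin_table", "data.frame")
  bt
}

#' Mask uninformative bins
#'
#' Flags bins with zero reads and bins overlapping assembly N runs; masked
#' bins are excluded from the GC fit and from all downstream sums.
#'
#' @param table A `bin_table` with raw counts.
#' @return The table with its `masked` column set.
#' @export
filter_bins <- function(table) {
  if (!inherits(table, "bin_table")) stop("'table' must be a bin_table", call. = FALSE)
  table$masked <- table$n_mask | table$raw == 0
  if (all(table$masked)) stop("all bins are masked", call. = FALSE)
  table
}

#' LOESS GC correction of binned counts
#'
#' Fits a degree-1 LOESS of the per-bp read rate (raw count / bin width)
#' against rounded GC over the unmasked autosomal bins (aggregated by unique
#' GC value, width-weighted; the rate scale keeps short terminal bins from
#' distorting the GC profile) and rescales every unmasked bin by
#' `median(rate) / fitted(GC)`.  The median scaling keeps the corrected
#' total close to the raw total.  Bins whose fitted value is non-positive are
#' masked.  If the GC values are (nearly) degenerate the correction is the
#' identity, with a warning.
#'
#' @param table A `bin_table` after [filter_bins()].
#' @param span LOESS span (default 0.3).
#' @return The table with `corrected` filled in for unmasked bins.
#' @export
gc_correct <- function(table, span = 0.3) {
  if (!inherits(table, "bin_table")) stop("'table' must be a bin_table", call. = FALSE)
  autosomes <- attr(table, "autosomes")
  un <- !table$masked
  auto_un <- un & table$chrom %in% autosomes
  if (sum(auto_un) < 50)
    stop("need at least 50 unmasked autosomal bins for GC correction", call. = FALSE)

  gcs <- table$gc[auto_un]
  if (length(unique(gcs)) < 10) {
    warning("GC content is (nearly) degenerate; correction is the identity")
    table$corrected[un] <- table$raw[un]
    return(table)
  }

  # Fit on per-bp rates so that short terminal bins do not distort the GC
  # profile; weight each rounded-GC value by the genomic width behind it.
  width <- table$end - table$start
  agg <- stats::aggregate(
    list(count = table$raw[auto_un], w = width[auto_un]),
    by = list(gc = gcs), FUN = sum
  )
  agg$rate <- agg$count / agg$w
  fit <- stats::loess(rate ~ gc, data = agg, weights = agg$w,
                      span = span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  gc_all <- clamp(table$gc, min(agg$gc), max(agg$gc))
  fitted <- stats::predict(fit, newdata = data.frame(gc = gc_all))

  med <- stats::median(table$raw[auto_un] / width[auto_un])
  corrected <- table$raw * med / fitted
  bad <- un & (!is.finite(fitted) | fitted <= 0)
  table$masked <- table$masked | bad
  un <- !table$masked
  table$corrected <- NA_real_
  table$corrected[un] <- corrected[un]
  table
}

#' Per-chromosome read percentages
#'
#' Computes, for every chromosome, the corrected read count divided by the
#' total corrected count on all autosomes (so the autosomal percentages sum
#' to 1 and %chrY shares the same denominator, keeping the chrY-based
#' fetal-fraction formula self-consistent).  Masked bins are excluded.
#'
#' @param table A `bin_table` with corrected counts.
#' @return Object of class `chrom_profile`: list with `pct` (named vector of
#'   autosome-denominated fractions), `pct_y`, `total_corrected`,
#'   `total_raw`.
#' @export
chromosome_profile <- function(table) {
  if (!inherits(table, "bin_table")) stop("'table' must be a bin_table", call. = FALSE)
  un <- !table$masked
  if (!any(un) || all(is.na(table$corrected[un])))
    stop("corrected counts missing; run gc_correct() first", call. = FALSE)
  autosomes <- attr(table, "autosomes")
  sums <- c(tapply(table$corrected[un], table$chrom[un], sum, default = 0))
  sums[is.na(sums)] <- 0
  auto_total <- sum(sums[names(sums) %in% autosomes])
  if (auto_total <= 0) stop("zero autosomal read total", call. = FALSE)
  pct <- sums / auto_total
  structure(list(
    pct = pct,
    pct_y = unname(pct["chrY"]),
    total_corrected = sum(sums),
    total_raw = sum(table$raw[un])
  ), class = "chrom_profile")
}

#' @export
print.chrom_profile <- function(x, ...) {
  cat(sprintf("chrom_profile: %d chromosomes, %%chrY = %.4f%%, %.0f corrected reads\n",
              length(x$pct), 100 * x$pct_y, x$total_corrected))
  invisible(x)
}

#' Run the per-sample QC/normalisation pipeline
#'
#' Convenience wrapper: quality filtering, binning, bin masking, GC-LOESS
#' correction and chromosome-percentage computation in one call.
#'
#' @param sample A [fragment_set].
#' @param span LOESS span passed to [gc_correct()].
#' @param min_mapq,min_len Filter thresholds passed to [filter_fragments()].
#' @return A [chromosome_profile()] result.
#' @export
profile_sample <- function(sample, span = 0.3, min_mapq = 10, min_len = 35) {
  sample <- filter_fragments(sample, min_mapq = min_mapq, min_len = min_len)
  bt <- bin_counts(sample)
  bt <- filter_bins(bt)
  bt <- gc_correct(bt, span = span)
  chromosome_profile(bt)
}
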