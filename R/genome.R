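# hg19 reference chromosome lengths in bp (GRCh37 primary assembly).
.hg19_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

#' hg19 chromosome lengths
#'
#' Named vector of GRCh37/hg19 chromosome lengths in base pairs
#' (chr1..chr22, chrX, chrY), used as the template for scaled genome models.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
hg19_chrom_lengths <- function() .hg19_lengths

#' Build a (scaled) genome model with fixed-size bins
#'
#' Constructs the binned genome the whole pipeline operates on: every
#' chromosome is partitioned into consecutive bins of `bin_size` bp (the last
#' bin of a chromosome may be short), each bin carries a GC content and an
#' N-mask flag.  By default the hg19 chromosome lengths are divided by
#' `scale = 500`, which keeps the full karyotype (22 autosomes, chrX, chrY)
#' while shrinking the genome to a few hundred 20-kb bins so that whole-cohort
#' simulations run in seconds.  Set `scale = 1` for a full-scale genome.
#'
#' Per-bin GC is drawn from a Beta distribution whose mean is shifted by a
#' chromosome-specific offset, so GC composition differs systematically
#' between chromosomes (this is what makes GC bias distort chromosome
#' representation, and what the LOESS correction has to remove).
#'
#' @param bin_size Bin width in bp (default 20000).
#' @param scale Divisor applied to the chromosome lengths (default 500).
#' @param n_mask_rate Fraction of bins flagged as containing assembly N runs.
#' @param gc_mean Genome-wide mean GC fraction.
#' @param gc_sd Between-bin GC standard deviation.
#' @param gc_chrom_sd Standard deviation of the per-chromosome GC mean offsets.
#' @param chrom_lengths Named vector of chromosome lengths in bp; defaults to
#'   [hg19_chrom_lengths()].
#' @param seed Optional integer seed; the same seed reproduces the same genome.
#' @return An object of class `genome_model`: a list with `bins`
#'   (data.frame: chrom, start, end, width, gc, n_mask), `chrom_lengths`
#'   (scaled, bp), `bin_size`, `scale`, `autosomes`, and `bin_offset`
#'   (0-based global bin index of each chromosome's first bin).
#' @examples
#' g <- build_genome(seed = 1)
#' table(g$bins$chrom)["chr21"]  # 5 bins at scale 500
#' @export
build_genome <- function(bin_size = 20000, scale = 500, n_mask_rate = 0.03,
                         gc_mean = 0.41, gc_sd = 0.05, gc_chrom_sd = 0.015,
                         chrom_lengths = NULL, seed = NULL) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("'bin_size' must be a positive number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a positive number", call. = FALSE)
  stopifnot_scalar_prob(n_mask_rate, "n_mask_rate")
  if (is.null(chrom_lengths)) chrom_lengths <- .hg19_lengths
  if (is.null(names(chrom_lengths)) || anyNA(chrom_lengths) || any(chrom_lengths <= 0))
    stop("'chrom_lengths' must be a named vector of positive lengths", call. = FALSE)

  chroms <- names(chrom_lengths)
  scaled <- ceiling(chrom_lengths / scale)
  n_bins_chrom <- as.integer(ceiling(scaled / bin_size))

  with_seed(seed, {
    starts <- unlist(lapply(seq_along(chroms), function(i) {
      seq(0, by = bin_size, length.out = n_bins_chrom[i])
    }), use.names = FALSE)
    chrom_col <- factor(rep(chroms, n_bins_chrom), levels = chroms)
    ends <- pmin(starts + bin_size, rep(scaled, n_bins_chrom))
    n <- length(starts)

    # chromosome-specific GC mean offsets, then per-bin Beta draws
    offsets <- stats::rnorm(length(chroms), 0, gc_chrom_sd)
    mu <- clamp(gc_mean + offsets[as.integer(chrom_col)], 0.25, 0.60)
    conc <- gc_mean * (1 - gc_mean) / gc_sd^2 - 1
    gc <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
    n_mask <- stats::runif(n) < n_mask_rate

    bins <- data.frame(
      chrom = chrom_col, start = starts, end = ends, width = ends - starts,
      gc = gc, n_mask = n_mask
    )
    structure(list(
      bins = bins,
      chrom_lengths = scaled,
      bin_size = bin_size,
      scale = scale,
      autosomes = paste0("chr", 1:22)[paste0("chr", 1:22) %in% chroms],
      bin_offset = stats::setNames(cumsum(c(0L, n_bins_chrom[-length(n_bins_chrom)])), chroms),
      seed = seed
    ), class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosomes, %d bins of %g bp (scale 1/%g), %.1f%% N-masked\n",
    length(x$chrom_lengths), nrow(x$bins), x$bin_size, x$scale,
    100 * mean(x$bins$n_mask)
  ))
  invisible(x)
}
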