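# Per-origin chromosome copy weights, with chrY calibrated so that the
# GC-corrected %chrY (chrY reads / autosomal reads) of a pure sample of that
# origin equals `y_rate`.  Calibration uses GC-unweighted width x copy mass
# over non-N-masked bins: the LOESS correction removes the GC acceptance
# factor and N-masked bins are excluded from the pipeline's denominators, so
# the corrected read share of a chromosome is proportional to its unmasked
# width x copy mass.
.copy_weights <- function(genome, origin, spec, pct_y_male, pct_y_background) {
  chroms <- names(genome$chrom_lengths)
  w <- stats::setNames(rep(1, length(chroms)), chroms)
  if (origin == "fetal") {
    if (spec$aneuploidy != "none")
      w[spec$aneuploidy] <- 1 + 0.5 * spec$mosaicism
    if (spec$fetal_sex == "male") {
      w["chrX"] <- 0.5
      y_rate <- pct_y_male
    } else {
      y_rate <- pct_y_background
    }
  } else {
    if (!is.null(spec$maternal_cnv)) {
      bad <- setdiff(spec$maternal_cnv$chrom, chroms)
      if (length(bad)) stop("unknown maternal CNV chromosome: ", bad[1], call. = FALSE)
      w[spec$maternal_cnv$chrom] <- spec$maternal_cnv$copy_ratio
    }
    y_rate <- pct_y_background
  }
  bins <- genome$bins
  auto <- bins$chrom %in% genome$autosomes & !bins$n_mask
  yb <- bins$chrom == "chrY" & !bins$n_mask
  s_auto <- sum(bins$width[auto] * w[as.character(bins$chrom[auto])])
  s_y <- sum(bins$width[yb])
  if (s_y > 0) w["chrY"] <- y_rate * s_auto / s_y
  w
}

# GC acceptance factor: linear in GC, clamped.
.gc_accept <- function(gc, beta, gc_ref, gc_clamp) {
  clamp(1 + beta * (gc - gc_ref), gc_clamp[1], gc_clamp[2])
}

# Normalised per-bin sampling probabilities for one origin.
.bin_probs <- function(genome, copy_w, gc_beta, gc_ref, gc_clamp) {
  bins <- genome$bins
  g <- .gc_accept(bins$gc, gc_beta, gc_ref, gc_clamp)
  u <- bins$width * g * unname(copy_w[as.integer(bins$chrom)])
  u / sum(u)
}

#' Simulate one maternal-plasma cfDNA sample
#'
#' Draws fragments from a maternal/fetal mixture over a binned genome.  Each
#' fragment's origin is Bernoulli(FF); its bin is drawn with probability
#' proportional to bin width x GC acceptance x chromosome copy weight, where
#' a fetal trisomy multiplies the target chromosome's fetal weight by
#' `1 + 0.5 m` and maternal CNVs multiply maternal weights by their copy
#' ratio.  chrY receives fetal-male fragments at a rate calibrated so that a
#' 100% male-DNA sample shows a corrected %chrY of `pct_y_male` (0.170% by
#' default) and a pure-female sample shows the misalignment floor
#' `pct_y_background` (0.002%).  GC bias is a linear acceptance factor
#' `g(GC) = clamp(1 + beta (GC - gc_ref), 0.2, 1.8)` that the downstream
#' LOESS correction is expected to remove.
#'
#' Two modes produce the same joint distribution over (bin, origin):
#' \describe{
#'   \item{count}{a per-bin, per-origin count matrix (fast; used for cohort
#'     studies). Insert lengths are represented implicitly through the
#'     attached [length_model()].}
#'   \item{fragment}{individual records with start, continuous insert length,
#'     mapping quality (90% at 60, 5% uniform 11-59, 5% uniform 0-10) and a
#'     duplicate flag (rate 2%).}
#' }
#'
#' @param genome A [build_genome()] result.
#' @param spec A [sample_spec()].
#' @param mode `"count"` or `"fragment"`.
#' @param model A [length_model()].
#' @param gc_beta Slope of the GC acceptance factor (0 = no bias).
#' @param gc_ref GC value at which the acceptance factor is 1.
#' @param gc_clamp Acceptance clamp bounds.
#' @param pct_y_male Corrected chrY/autosome read ratio of 100% male DNA
#'   (fraction; default 0.0017, i.e. 0.170%).
#' @param pct_y_background Female-background chrY ratio (fraction; default
#'   2e-5, i.e. 0.002%).
#' @param mapq_probs Probabilities of the three MAPQ strata (60, 11-59, 0-10).
#' @param dup_rate PCR/optical duplicate rate.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return Object of class `fragment_set`.
#' @export
simulate_sample <- function(genome, spec, mode = c("count", "fragment"),
                            model = length_model(), gc_beta = 2,
                            gc_ref = 0.41, gc_clamp = c(0.2, 1.8),
                            pct_y_male = 0.0017, pct_y_background = 2e-5,
                            mapq_probs = c(0.90, 0.05, 0.05), dup_rate = 0.02,
                            seed = spec$seed) {
  if (!inherits(genome, "genome_model")) stop("'genome' must be a genome_model", call. = FALSE)
  if (!inherits(spec, "sample_spec")) stop("'spec' must be a sample_spec", call. = FALSE)
  mode <- match.arg(mode)

  w_m <- .copy_weights(genome, "maternal", spec, pct_y_male, pct_y_background)
  w_f <- .copy_weights(genome, "fetal", spec, pct_y_male, pct_y_background)
  p_m <- .bin_probs(genome, w_m, gc_beta, gc_ref, gc_clamp)
  p_f <- .bin_probs(genome, w_f, gc_beta, gc_ref, gc_clamp)

  with_seed(seed, {
    n <- spec$n_fragments
    n_fetal <- stats::rbinom(1, n, spec$ff)
    n_maternal <- n - n_fetal

    # Joint population distribution over (bin, origin): the library the
    # sample's reads are drawn from.  Size selection with depth
    # renormalisation re-sequences a tilted version of this population.
    joint_probs <- cbind(maternal = (1 - spec$ff) * p_m,
                         fetal = spec$ff * p_f)

    if (mode == "count") {
      counts <- cbind(
        maternal = stats::rmultinom(1, n_maternal, p_m)[, 1],
        fetal = stats::rmultinom(1, n_fetal, p_f)[, 1]
      )
      fs <- list(
        sample_id = spec$sample_id, mode = "count", counts = counts,
        fragments = NULL, genome = genome, model = model, spec = spec,
        joint_probs = joint_probs,
        provenance = "pre_selection", selection = NULL, n_total = n,
        gc_beta = gc_beta
      )
      return(structure(fs, class = "fragment_set"))
    }

    bins <- genome$bins
    one_origin <- function(n_o, p_o, origin) {
      if (n_o == 0) {
        return(data.frame(chrom = factor(character(), levels = levels(bins$chrom)),
                          start = numeric(), length = numeric(),
                          origin = character(), mapq = integer(),
                          duplicate = logical()))
      }
      cnt <- stats::rmultinom(1, n_o, p_o)[, 1]
      idx <- rep.int(seq_along(cnt), cnt)
      start <- bins$start[idx] + floor(stats::runif(n_o) * bins$width[idx])
      len <- rlength(model, n_o, origin)
      stratum <- sample.int(3L, n_o, replace = TRUE, prob = mapq_probs)
      mapq <- integer(n_o)
      mapq[stratum == 1L] <- 60L
      mapq[stratum == 2L] <- sample(11:59, sum(stratum == 2L), replace = TRUE)
      mapq[stratum == 3L] <- sample(0:10, sum(stratum == 3L), replace = TRUE)
      data.frame(chrom = bins$chrom[idx], start = start, length = len,
                 origin = origin, mapq = mapq,
                 duplicate = stats::runif(n_o) < dup_rate)
    }
    frags <- rbind(one_origin(n_maternal, p_m, "maternal"),
                   one_origin(n_fetal, p_f, "fetal"))
    rownames(frags) <- NULL
    fs <- list(
      sample_id = spec$sample_id, mode = "fragment", counts = NULL,
      fragments = frags, genome = genome, model = model, spec = spec,
      joint_probs = joint_probs,
      provenance = "pre_selection", selection = NULL, n_total = nrow(frags),
      gc_beta = gc_beta
    )
    structure(fs, class = "fragment_set")
  })
}

#' Realised origin fractions of a fragment set
#'
#' Ground-truth fetal fraction of a simulated sample (fetal fragments /
#' total).  In count mode this is exact from the per-origin counts; in
#' fragment mode it is the fraction of records labelled fetal.
#'
#' @param sample A `fragment_set`.
#' @return Named vector `c(fetal = ..., maternal = ...)` of fractions.
#' @export
origin_fractions <- function(sample) {
  if (!inherits(sample, "fragment_set")) stop("'sample' must be a fragment_set", call. = FALSE)
  if (sample$mode == "count") {
    tot <- colSums(sample$counts)
  } else {
    tot <- c(maternal = sum(sample$fragments$origin == "maternal"),
             fetal = sum(sample$fragments$origin == "fetal"))
  }
  (tot / sum(tot))[c("fetal", "maternal")]
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s' (%s mode, %s): %d fragments\n",
              x$sample_id, x$mode, x$provenance, x$n_total))
  if (!is.null(x$selection))
    cat(sprintf("  selection: [%g, %g] bp, depth %s\n",
                x$selection$window$low, x$selection$window$high,
                if (x$selection$renormalized) "renormalised" else "thinned"))
  invisible(x)
}
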