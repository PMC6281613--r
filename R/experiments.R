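# Cohort-level studies: window comparison, low-FF gradient, enrichment
# cohort, maternal-interference scenario, and screening metrics.

# Log-normal fetal fractions parameterised by their median, clamped to a
# plausibility range (cohort FF distributions are declared, not inferred).
rlnorm_ff <- function(n, median, sdlog, range) {
  clamp(stats::rlnorm(n, log(median), sdlog), range[1], range[2])
}

new_metrics_report <- function(experiment, config, per_sample, summary) {
  structure(list(experiment = experiment, config = config,
                 per_sample = per_sample, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %s (%d samples)\n", x$experiment,
              if (is.data.frame(x$per_sample)) nrow(x$per_sample) else length(x$per_sample)))
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Clopper-Pearson confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param confidence Two-sided confidence level (default 0.99).
#' @return Named vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, confidence = 0.99) {
  if (n <= 0 || x < 0 || x > n) stop("need 0 <= x <= n, n > 0", call. = FALSE)
  a <- (1 - confidence) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Screening performance with exact confidence intervals
#'
#' Sensitivity is the fraction of affected truths called affected and
#' specificity the fraction of unaffected truths called unaffected; a
#' "no call" is counted as a non-detection in both denominators (the
#' conservative reading) and additionally tabulated separately.
#' Clopper-Pearson intervals at the stated confidence.
#'
#' @param calls Character vector in `{"affected", "unaffected", "no_call"}`.
#' @param truths Character vector in `{"affected", "unaffected"}`.
#' @param confidence Confidence level for the intervals (default 0.99).
#' @return List of class `confusion_metrics` with sensitivity/specificity,
#'   their intervals, no-call counts and the full call-by-truth table.
#' @export
confusion_metrics <- function(calls, truths, confidence = 0.99) {
  if (length(calls) == 0 || length(calls) != length(truths))
    stop("'calls' and 'truths' must be non-empty and of equal length", call. = FALSE)
  if (!all(calls %in% c("affected", "unaffected", "no_call")))
    stop("invalid call class", call. = FALSE)
  if (!all(truths %in% c("affected", "unaffected")))
    stop("invalid truth class", call. = FALSE)
  n_aff <- sum(truths == "affected")
  n_un <- sum(truths == "unaffected")
  tp <- sum(calls == "affected" & truths == "affected")
  tn <- sum(calls == "unaffected" & truths == "unaffected")
  structure(list(
    sensitivity = if (n_aff > 0) tp / n_aff else NA_real_,
    sensitivity_ci = if (n_aff > 0) clopper_pearson(tp, n_aff, confidence) else c(lower = NA_real_, upper = NA_real_),
    specificity = if (n_un > 0) tn / n_un else NA_real_,
    specificity_ci = if (n_un > 0) clopper_pearson(tn, n_un, confidence) else c(lower = NA_real_, upper = NA_real_),
    n_affected = n_aff, n_unaffected = n_un,
    n_no_call = sum(calls == "no_call"),
    table = table(call = factor(calls, c("affected", "unaffected", "no_call")),
                  truth = factor(truths, c("affected", "unaffected"))),
    confidence = confidence
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.4f (%d/%d), specificity %.4f (%d/%d), no-calls %d [%g%% CI]\n",
              x$sensitivity, round(x$sensitivity * x$n_affected), x$n_affected,
              x$specificity, round(x$specificity * x$n_unaffected), x$n_unaffected,
              x$n_no_call, 100 * x$confidence))
  invisible(x)
}

# chrY-based FF estimate from a profile, as a bare number.
.ff_chry <- function(profile, pct_y_ff, pct_y_am) {
  ff_from_chry(profile$pct_y, pct_y_ff = pct_y_ff, pct_y_am = pct_y_am)$value
}

#' Pre-clinical enrichment cohort
#'
#' Simulates a cohort of euploid male-fetus samples with log-normal fetal
#' fractions, estimates each sample's fetal fraction from %chrY before and
#' after in-silico size selection, and reports per-sample enrichment
#' metrics plus cohort medians of the FF fold-increase and the
#' maternal-background decrease.
#'
#' @param n_samples Cohort size (default 50).
#' @param ff_median,ff_sdlog,ff_range Log-normal FF distribution: median,
#'   log-sd and clamp range.
#' @param window Selection window (insert frame; default 125-135 bp).
#' @param n_fragments Fragments per sample.
#' @param ff_method `"chry"` (estimate FF from %chrY) or `"truth"` (use the
#'   simulator's realised origin fractions).
#' @param genome,model Genome and length models (defaults built internally).
#' @param gc_beta GC-bias slope used in simulation.
#' @param span LOESS span for GC correction.
#' @param pct_y_ff,pct_y_am chrY constants for the FF formula (fractions).
#' @param seed RNG seed; the full run is reproducible from it.
#' @return A `metrics_report` with per-sample metrics and
#'   `summary$median_ff_fold`, `summary$median_maternal_decrease`.
#' @export
run_enrichment_cohort <- function(n_samples = 50, ff_median = 0.1458,
                                  ff_sdlog = 0.45, ff_range = c(0.03, 0.56),
                                  window = size_window(125, 135),
                                  n_fragments = 5e6,
                                  ff_method = c("chry", "truth"),
                                  genome = NULL, model = length_model(),
                                  gc_beta = 2, span = 0.3,
                                  pct_y_ff = 2e-5, pct_y_am = 0.0017,
                                  seed = NULL) {
  ff_method <- match.arg(ff_method)
  if (n_samples < 1) stop("empty cohort", call. = FALSE)
  window <- as_size_window(window)
  with_seed(seed, {
    if (is.null(genome)) genome <- build_genome()
    ffs <- rlnorm_ff(n_samples, ff_median, ff_sdlog, ff_range)
    rows <- lapply(seq_len(n_samples), function(i) {
      spec <- sample_spec(ffs[i], fetal_sex = "male",
                          n_fragments = n_fragments,
                          sample_id = sprintf("S%02d", i))
      fs <- simulate_sample(genome, spec, mode = "count", model = model,
                            gc_beta = gc_beta, pct_y_male = pct_y_am,
                            pct_y_background = pct_y_ff, seed = NULL)
      fs_sel <- apply_size_selection(fs, window)
      if (ff_method == "chry") {
        ff0 <- .ff_chry(profile_sample(fs, span = span), pct_y_ff, pct_y_am)
        ff1 <- .ff_chry(profile_sample(fs_sel, span = span), pct_y_ff, pct_y_am)
      } else {
        ff0 <- origin_fractions(fs)[["fetal"]]
        ff1 <- origin_fractions(fs_sel)[["fetal"]]
      }
      cbind(data.frame(sample = spec$sample_id, ff_true = ffs[i]),
            enrichment_metrics(ff0, ff1))
    })
    per_sample <- do.call(rbind, rows)
    new_metrics_report(
      "enrichment_cohort",
      list(n_samples = n_samples, ff_median = ff_median, ff_sdlog = ff_sdlog,
           ff_range = ff_range, window = window, n_fragments = n_fragments,
           ff_method = ff_method, gc_beta = gc_beta, seed = seed),
      per_sample,
      list(median_ff_fold = stats::median(per_sample$ff_fold),
           median_maternal_decrease = stats::median(per_sample$maternal_decrease),
           n = n_samples)
    )
  })
}

#' Size-window comparison on a small male-fetus cohort
#'
#' Simulates a cohort once and applies each candidate size window to the
#' same pre-selection samples, reporting the median chrY-based FF
#' fold-increase per window and the window that maximises it.
#'
#' @inheritParams run_enrichment_cohort
#' @param windows List of windows (insert frame) to compare.
#' @return A `metrics_report`; `summary$per_window` holds the median fold
#'   per window and `summary$best_window` the argmax label.
#' @export
run_window_comparison <- function(n_samples = 9, ff_median = 0.08,
                                  ff_sdlog = 0.25, ff_range = c(0.03, 0.20),
                                  windows = list(size_window(115, 125),
                                                 size_window(125, 135),
                                                 size_window(135, 145)),
                                  n_fragments = 5e6,
                                  ff_method = c("chry", "truth"),
                                  genome = NULL, model = length_model(),
                                  gc_beta = 2, span = 0.3,
                                  pct_y_ff = 2e-5, pct_y_am = 0.0017,
                                  seed = NULL) {
  ff_method <- match.arg(ff_method)
  if (n_samples < 1) stop("empty cohort", call. = FALSE)
  if (length(windows) < 1) stop("need at least one window", call. = FALSE)
  windows <- lapply(windows, as_size_window)
  labels <- vapply(windows, function(w) sprintf("%g-%g", w$low, w$high), character(1))
  with_seed(seed, {
    if (is.null(genome)) genome <- build_genome()
    ffs <- rlnorm_ff(n_samples, ff_median, ff_sdlog, ff_range)
    rows <- lapply(seq_len(n_samples), function(i) {
      spec <- sample_spec(ffs[i], fetal_sex = "male",
                          n_fragments = n_fragments,
                          sample_id = sprintf("S%02d", i))
      fs <- simulate_sample(genome, spec, mode = "count", model = model,
                            gc_beta = gc_beta, pct_y_male = pct_y_am,
                            pct_y_background = pct_y_ff, seed = NULL)
      ff0 <- if (ff_method == "chry")
        .ff_chry(profile_sample(fs, span = span), pct_y_ff, pct_y_am)
      else origin_fractions(fs)[["fetal"]]
      do.call(rbind, lapply(seq_along(windows), function(k) {
        fs_sel <- apply_size_selection(fs, windows[[k]])
        ff1 <- if (ff_method == "chry")
          .ff_chry(profile_sample(fs_sel, span = span), pct_y_ff, pct_y_am)
        else origin_fractions(fs_sel)[["fetal"]]
        cbind(data.frame(sample = spec$sample_id, ff_true = ffs[i],
                         window = labels[k]),
              enrichment_metrics(ff0, ff1))
      }))
    })
    per_sample <- do.call(rbind, rows)
    med <- tapply(per_sample$ff_fold, per_sample$window, stats::median)
    per_window <- data.frame(window = labels,
                             median_ff_fold = as.numeric(med[labels]))
    new_metrics_report(
      "window_comparison",
      list(n_samples = n_samples, ff_median = ff_median, windows = labels,
           n_fragments = n_fragments, ff_method = ff_method, seed = seed),
      per_sample,
      list(per_window = per_window,
           best_window = labels[which.max(per_window$median_ff_fold)])
    )
  })
}

#' Low fetal-fraction gradient experiment
#'
#' The sensitivity study: trisomy-21 male-fetus samples are simulated at a
#' grid of fetal fractions (default 1-10%), each analysed by both arms --
#' NIPS (no selection) and iNIPS (125-135 bp selection with depth
#' renormalisation) -- and z-scored against arm-matched euploid reference
#' cohorts.  Per fraction the report carries each arm's sensitivity (the
#' affected-call rate, z > 4.00) with exact confidence intervals; pooled
#' over the gradient it carries median FF fold-increase and maternal
#' decrease, computed from the simulator's realised origin fractions (chrY
#' estimates are too noisy at FF = 1% to define a meaningful fold).
#'
#' @inheritParams run_enrichment_cohort
#' @param fractions Fetal fractions of the gradient.
#' @param n_per_fraction Samples per fraction (default 30).
#' @param aneuploidy Trisomic chromosome (default chr21).
#' @param n_reference Euploid references per arm (default 100).
#' @param ref_ff_median,ref_ff_sdlog,ref_ff_range FF distribution of the
#'   reference pregnancies.
#' @param confidence Confidence level for sensitivity intervals.
#' @return A `metrics_report`; `summary$per_fraction` has per-fraction
#'   sensitivities, `summary$median_ff_fold` and
#'   `summary$median_maternal_decrease` the pooled medians.
#' @export
run_gradient_experiment <- function(fractions = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.10),
                                    n_per_fraction = 30, aneuploidy = "chr21",
                                    n_fragments = 5e6, n_reference = 100,
                                    ref_ff_median = 0.1458, ref_ff_sdlog = 0.45,
                                    ref_ff_range = c(0.03, 0.56),
                                    window = size_window(125, 135),
                                    genome = NULL, model = length_model(),
                                    gc_beta = 2, span = 0.3,
                                    pct_y_ff = 2e-5, pct_y_am = 0.0017,
                                    confidence = 0.99, seed = NULL) {
  if (n_reference < 20) stop("need at least 20 reference samples per arm", call. = FALSE)
  if (length(fractions) < 1 || n_per_fraction < 1) stop("empty gradient", call. = FALSE)
  window <- as_size_window(window)
  with_seed(seed, {
    if (is.null(genome)) genome <- build_genome()

    ref_ffs <- rlnorm_ff(n_reference, ref_ff_median, ref_ff_sdlog, ref_ff_range)
    ref_profiles <- lapply(seq_len(n_reference), function(i) {
      spec <- sample_spec(ref_ffs[i], fetal_sex = "male",
                          n_fragments = n_fragments,
                          sample_id = sprintf("R%03d", i))
      fs <- simulate_sample(genome, spec, mode = "count", model = model,
                            gc_beta = gc_beta, pct_y_male = pct_y_am,
                            pct_y_background = pct_y_ff, seed = NULL)
      list(nips = profile_sample(fs, span = span),
           inips = profile_sample(apply_size_selection(fs, window), span = span))
    })
    ref_nips <- build_reference(lapply(ref_profiles, `[[`, "nips"))
    ref_inips <- build_reference(lapply(ref_profiles, `[[`, "inips"))

    rows <- lapply(fractions, function(f) {
      do.call(rbind, lapply(seq_len(n_per_fraction), function(j) {
        spec <- sample_spec(f, fetal_sex = "male", aneuploidy = aneuploidy,
                            mosaicism = 1, n_fragments = n_fragments,
                            sample_id = sprintf("F%g_%02d", 100 * f, j))
        fs <- simulate_sample(genome, spec, mode = "count", model = model,
                              gc_beta = gc_beta, pct_y_male = pct_y_am,
                              pct_y_background = pct_y_ff, seed = NULL)
        fs_sel <- apply_size_selection(fs, window)
        pr0 <- profile_sample(fs, span = span)
        pr1 <- profile_sample(fs_sel, span = span)
        z0 <- z_score(pr0, ref_nips, aneuploidy)
        z1 <- z_score(pr1, ref_inips, aneuploidy)
        ff0 <- origin_fractions(fs)[["fetal"]]
        ff1 <- origin_fractions(fs_sel)[["fetal"]]
        cbind(data.frame(sample = spec$sample_id, fraction = f),
              enrichment_metrics(ff0, ff1),
              data.frame(z_nips = z0, class_nips = classify(z0),
                         z_inips = z1, class_inips = classify(z1)))
      }))
    })
    per_sample <- do.call(rbind, rows)

    per_fraction <- do.call(rbind, lapply(fractions, function(f) {
      sub <- per_sample[per_sample$fraction == f, ]
      truths <- rep("affected", nrow(sub))
      cm0 <- confusion_metrics(sub$class_nips, truths, confidence)
      cm1 <- confusion_metrics(sub$class_inips, truths, confidence)
      data.frame(
        fraction = f, n = nrow(sub),
        sens_nips = cm0$sensitivity,
        sens_nips_lo = cm0$sensitivity_ci[["lower"]],
        sens_nips_hi = cm0$sensitivity_ci[["upper"]],
        sens_inips = cm1$sensitivity,
        sens_inips_lo = cm1$sensitivity_ci[["lower"]],
        sens_inips_hi = cm1$sensitivity_ci[["upper"]],
        no_call_nips = sum(sub$class_nips == "no_call"),
        no_call_inips = sum(sub$class_inips == "no_call"),
        median_ff_fold = stats::median(sub$ff_fold),
        median_maternal_decrease = stats::median(sub$maternal_decrease)
      )
    }))

    new_metrics_report(
      "gradient",
      list(fractions = fractions, n_per_fraction = n_per_fraction,
           aneuploidy = aneuploidy, n_fragments = n_fragments,
           n_reference = n_reference, window = window, gc_beta = gc_beta,
           confidence = confidence, seed = seed),
      per_sample,
      list(per_fraction = per_fraction,
           median_ff_fold = stats::median(per_sample$ff_fold),
           median_maternal_decrease = stats::median(per_sample$maternal_decrease))
    )
  })
}

#' Maternal-interference scenario
#'
#' Simulates pregnancies whose mother carries a copy-number abnormality (or,
#' alternatively, a fetal trisomy) and measures the target chromosome's
#' over-representation `p / mean_ref - 1` in both arms against euploid,
#' CNV-free arm-matched references.  A maternal-driven excess shrinks after
#' selection by roughly the maternal-decrease factor, while a fetal-driven
#' excess grows by roughly the FF fold-increase.
#'
#' @inheritParams run_gradient_experiment
#' @param maternal_cnv data.frame(chrom, copy_ratio) or NULL.
#' @param fetal_aneuploidy `"none"` or a trisomic chromosome; at least one
#'   of `maternal_cnv` / `fetal_aneuploidy` must describe an abnormality.
#' @param ff Fetal fraction of the simulated samples.
#' @param n_samples Number of affected samples.
#' @return A `metrics_report`; `summary` carries the mean excess per arm and
#'   the NIPS/iNIPS excess ratio.
#' @export
run_maternal_interference <- function(maternal_cnv = data.frame(chrom = "chr21",
                                                                copy_ratio = 1.05),
                                      fetal_aneuploidy = "none", ff = 0.15,
                                      n_samples = 10, n_reference = 30,
                                      n_fragments = 5e6,
                                      window = size_window(125, 135),
                                      genome = NULL, model = length_model(),
                                      gc_beta = 2, span = 0.3,
                                      pct_y_ff = 2e-5, pct_y_am = 0.0017,
                                      seed = NULL) {
  no_cnv <- is.null(maternal_cnv) || nrow(maternal_cnv) == 0
  if (no_cnv && fetal_aneuploidy == "none")
    stop("no abnormality configured: supply a maternal CNV or a fetal aneuploidy",
         call. = FALSE)
  if (n_reference < 20) stop("need at least 20 reference samples per arm", call. = FALSE)
  target <- if (!no_cnv) maternal_cnv$chrom[1] else fetal_aneuploidy
  window <- as_size_window(window)
  with_seed(seed, {
    if (is.null(genome)) genome <- build_genome()
    chroms <- unique(c("chr13", "chr18", "chr21", target))

    ref_profiles <- lapply(seq_len(n_reference), function(i) {
      spec <- sample_spec(ff, fetal_sex = "male", n_fragments = n_fragments,
                          sample_id = sprintf("R%03d", i))
      fs <- simulate_sample(genome, spec, mode = "count", model = model,
                            gc_beta = gc_beta, pct_y_male = pct_y_am,
                            pct_y_background = pct_y_ff, seed = NULL)
      list(nips = profile_sample(fs, span = span),
           inips = profile_sample(apply_size_selection(fs, window), span = span))
    })
    ref_nips <- build_reference(lapply(ref_profiles, `[[`, "nips"), chroms = chroms)
    ref_inips <- build_reference(lapply(ref_profiles, `[[`, "inips"), chroms = chroms)

    rows <- lapply(seq_len(n_samples), function(i) {
      spec <- sample_spec(ff, fetal_sex = "male", aneuploidy = fetal_aneuploidy,
                          mosaicism = if (fetal_aneuploidy == "none") 0 else 1,
                          maternal_cnv = if (no_cnv) NULL else maternal_cnv,
                          n_fragments = n_fragments,
                          sample_id = sprintf("S%02d", i))
      fs <- simulate_sample(genome, spec, mode = "count", model = model,
                            gc_beta = gc_beta, pct_y_male = pct_y_am,
                            pct_y_background = pct_y_ff, seed = NULL)
      pr0 <- profile_sample(fs, span = span)
      pr1 <- profile_sample(apply_size_selection(fs, window), span = span)
      data.frame(
        sample = spec$sample_id,
        excess_nips = pr0$pct[target] / ref_nips$mean[target] - 1,
        excess_inips = pr1$pct[target] / ref_inips$mean[target] - 1,
        row.names = NULL
      )
    })
    per_sample <- do.call(rbind, rows)
    mean_nips <- mean(per_sample$excess_nips)
    mean_inips <- mean(per_sample$excess_inips)
    new_metrics_report(
      "maternal_interference",
      list(maternal_cnv = maternal_cnv, fetal_aneuploidy = fetal_aneuploidy,
           ff = ff, target = target, n_samples = n_samples,
           n_reference = n_reference, n_fragments = n_fragments,
           window = window, seed = seed),
      per_sample,
      list(mean_excess_nips = mean_nips, mean_excess_inips = mean_inips,
           excess_ratio_nips_over_inips = mean_nips / mean_inips)
    )
  })
}
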