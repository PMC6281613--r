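test_that("Clopper-Pearson intervals match the exact binomial test", {
  for (case in list(c(30, 30), c(7, 7), c(25, 30), c(0, 12))) {
    x <- case[1]; n <- case[2]
    ci <- clopper_pearson(x, n, 0.99)
    oracle <- stats::binom.test(x, n, conf.level = 0.99)$conf.int
    expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-8)
  }
  expect_error(clopper_pearson(5, 4), "x <= n")
})

test_that("confusion metrics count no-calls as non-detections", {
  cm <- confusion_metrics(rep("affected", 30), rep("affected", 30))
  expect_equal(cm$sensitivity, 1)
  expect_equal(unname(cm$sensitivity_ci["lower"]),
               stats::binom.test(30, 30, conf.level = 0.99)$conf.int[1])
  cm7 <- confusion_metrics(rep("affected", 7), rep("affected", 7))
  expect_equal(cm7$sensitivity, 1)  # 100% (7/7)
  cm_nc <- confusion_metrics(rep("no_call", 10), rep("affected", 10))
  expect_equal(cm_nc$sensitivity, 0)
  expect_equal(cm_nc$n_no_call, 10)
  mixed <- confusion_metrics(c("affected", "unaffected", "no_call", "unaffected"),
                             c("affected", "unaffected", "unaffected", "unaffected"))
  expect_equal(mixed$sensitivity, 1)
  expect_equal(mixed$specificity, 2 / 3)
  expect_error(confusion_metrics(character(), character()), "non-empty")
  expect_error(confusion_metrics("maybe", "affected"), "invalid call")
})

test_that("window comparison ranks 125-135 first and is reproducible", {
  rep_a <- run_window_comparison(n_samples = 5, n_fragments = 1e6,
                                 ff_method = "truth", seed = 81)
  rep_b <- run_window_comparison(n_samples = 5, n_fragments = 1e6,
                                 ff_method = "truth", seed = 81)
  expect_identical(rep_a$per_sample, rep_b$per_sample)
  expect_identical(rep_a$summary$best_window, "125-135")
  pw <- rep_a$summary$per_window
  best <- pw$median_ff_fold[pw$window == "125-135"]
  expect_true(all(best > pw$median_ff_fold[pw$window != "125-135"]))
})

test_that("a single full-support window yields a median fold of 1", {
  rep1 <- run_window_comparison(n_samples = 4, n_fragments = 5e5,
                                windows = list(size_window(60, 250)),
                                ff_method = "truth", seed = 82)
  expect_lt(abs(rep1$summary$per_window$median_ff_fold - 1), 0.01)
})

test_that("gradient experiment: selection rescues sensitivity at low FF", {
  rep_g <- run_gradient_experiment(fractions = c(0.02, 0.10),
                                   n_per_fraction = 6, n_fragments = 2e6,
                                   n_reference = 25, seed = 83)
  pf <- rep_g$summary$per_fraction
  # iNIPS detects every T21 at 10% FF; dominance over NIPS at every fraction
  expect_equal(pf$sens_inips[pf$fraction == 0.10], 1)
  expect_true(all(pf$sens_inips >= pf$sens_nips))
  # enrichment medians sit near the closed-form working points
  wp <- window_probability(fix_model, fix_w125)
  for (f in c(0.02, 0.10)) {
    pred <- predict_enriched_ff(f, wp) / f
    expect_lt(abs(pf$median_ff_fold[pf$fraction == f] - pred), 0.1)
  }
  # confusion-matrix counts add up per fraction
  expect_true(all(pf$n == 6))
})

test_that("enrichment cohort medians track the analytic prediction (truth mode)", {
  rep_c <- run_enrichment_cohort(n_samples = 12, n_fragments = 1e6,
                                 ff_method = "truth", seed = 84)
  wp <- window_probability(fix_model, fix_w125)
  med_ff <- stats::median(rep_c$per_sample$ff_true)
  pred_fold <- predict_enriched_ff(med_ff, wp) / med_ff
  expect_lt(abs(rep_c$summary$median_ff_fold - pred_fold), 0.15)
  expect_true(all(rep_c$per_sample$maternal_decrease > 1))
})

test_that("maternal CNV interference shrinks after selection; fetal signal grows", {
  rep_m <- run_maternal_interference(
    maternal_cnv = data.frame(chrom = "chr21", copy_ratio = 1.05),
    ff = 0.15, n_samples = 10, n_reference = 20, n_fragments = 2e6, seed = 85)
  s <- rep_m$summary
  expect_gt(s$mean_excess_nips, 0.03)
  expect_lt(s$mean_excess_nips, 0.055)
  # excess shrinks by roughly the maternal-decrease factor at FF = 0.15
  expect_gt(s$excess_ratio_nips_over_inips, 1.1)
  expect_lt(s$excess_ratio_nips_over_inips, 1.6)

  rep_f <- run_maternal_interference(
    maternal_cnv = NULL, fetal_aneuploidy = "chr21",
    ff = 0.15, n_samples = 10, n_reference = 20, n_fragments = 2e6, seed = 86)
  ratio_growth <- rep_f$summary$mean_excess_inips / rep_f$summary$mean_excess_nips
  wp <- window_probability(fix_model, fix_w125)
  pred_fold <- predict_enriched_ff(0.15, wp) / 0.15
  expect_lt(abs(ratio_growth - pred_fold), 0.45)

  expect_error(run_maternal_interference(maternal_cnv = NULL), "no abnormality")
})

test_that("neutral maternal copy ratio produces no excess in either arm", {
  rep0 <- run_maternal_interference(
    maternal_cnv = data.frame(chrom = "chr21", copy_ratio = 1.0),
    ff = 0.15, n_samples = 6, n_reference = 20, n_fragments = 2e6, seed = 87)
  expect_lt(abs(rep0$summary$mean_excess_nips), 0.01)
  expect_lt(abs(rep0$summary$mean_excess_inips), 0.01)
})

test_that("euploid cohorts are almost never called affected (specificity)", {
  set.seed(88)
  n <- 300
  refs <- lapply(1:40, function(i) {
    fs <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 1e6))
    list(nips = profile_sample(fs),
         inips = profile_sample(apply_size_selection(fs, fix_w125)))
  })
  ref_nips <- build_reference(lapply(refs, `[[`, "nips"))
  ref_inips <- build_reference(lapply(refs, `[[`, "inips"))
  hits <- 0L
  for (i in seq_len(n)) {
    fs <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 1e6))
    pr0 <- profile_sample(fs)
    pr1 <- profile_sample(apply_size_selection(fs, fix_w125))
    z0 <- vapply(ref_nips$chroms, function(ch) z_score(pr0, ref_nips, ch), numeric(1))
    z1 <- vapply(ref_inips$chroms, function(ch) z_score(pr1, ref_inips, ch), numeric(1))
    hits <- hits + sum(classify(c(z0, z1)) == "affected")
  }
  # 300 samples x 3 chromosomes x 2 arms = 1800 calls; affected-rate <= 1e-3
  expect_lte(hits / (n * 3 * 2), 1e-3)
})
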