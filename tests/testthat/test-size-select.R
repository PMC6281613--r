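test_that("library-to-insert conversion subtracts the adapter total", {
  w <- library_to_insert(size_window(190, 240, frame = "library"))
  expect_equal(c(w$low, w$high), c(100, 150))
  expect_identical(w$frame, "insert")
  w2 <- library_to_insert(size_window(215, 225, frame = "library"))
  expect_equal(c(w2$low, w2$high), c(125, 135))
  # generic identity for any (a, b) with default adapters
  a <- 37; b <- 129
  w3 <- library_to_insert(size_window(90 + a, 90 + b, frame = "library"))
  expect_equal(c(w3$low, w3$high), c(a, b))
  expect_error(library_to_insert(size_window(80, 240, frame = "library")),
               "adapter")
  expect_error(library_to_insert(size_window(125, 135)), "library frame")
})

test_that("predict_enriched_ff obeys its boundary and neutrality identities", {
  wp <- window_probability(fix_model, fix_w125)
  expect_equal(predict_enriched_ff(0, wp), 0)
  expect_equal(predict_enriched_ff(1, wp), 1)
  neutral <- list(p_f = 0.3, p_m = 0.3)
  expect_equal(predict_enriched_ff(0.123, neutral), 0.123)
  # documented working point: ff = 0.1458 under the default 125-135 window
  fold <- predict_enriched_ff(0.1458, wp) / 0.1458
  expect_lt(abs(fold - 2.48), 0.01)
  expect_error(predict_enriched_ff(0.5, list(p_f = 0, p_m = 0)), "zero")
})

test_that("predict_enriched_ff is monotone and its fold decreases with ff", {
  wp <- window_probability(fix_model, fix_w125)
  ff <- seq(0.01, 0.5, by = 0.01)
  out <- predict_enriched_ff(ff, wp)
  expect_true(all(diff(out) > 0))
  expect_true(all(diff(out / ff) < 0))  # fold-change decreasing when r > 1
})

test_that("count-mode selection matches the closed-form prediction (4-sigma)", {
  set.seed(31)
  for (ff in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    for (w in list(c(115, 125), c(125, 135), c(135, 145))) {
      win <- size_window(w[1], w[2])
      wp <- window_probability(fix_model, win)
      n <- 1e6
      fs <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n))
      sel <- apply_size_selection(fs, win)
      expected <- predict_enriched_ff(ff, wp)
      realised <- origin_fractions(sel)[["fetal"]]
      # renormalised draw at depth n plus the Bernoulli(ff) origin split
      tol <- 4 * sqrt(expected * (1 - expected) / n +
                        (ff * (1 - ff) / n) * (expected / ff)^2)
      expect_lt(abs(realised - expected), tol)
    }
  }
})

test_that("thinning-only selection keeps the expected totals", {
  set.seed(32)
  n <- 1e6
  ff <- 0.1
  fs <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n))
  wp <- window_probability(fix_model, fix_w125)
  sel <- apply_size_selection(fs, fix_w125, renormalize_depth = FALSE)
  expected_total <- n * (ff * wp$p_f + (1 - ff) * wp$p_m)
  expect_lt(abs(sel$n_total - expected_total), 4 * sqrt(expected_total))
})

test_that("full-support selection is neutral", {
  set.seed(33)
  fs <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 1e5))
  sel <- apply_size_selection(fs, size_window(60, 250), renormalize_depth = FALSE)
  expect_identical(sel$counts, fs$counts)
  ffr <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 2e4),
                         mode = "fragment")
  self <- apply_size_selection(ffr, size_window(60, 250))
  expect_equal(nrow(self$fragments), nrow(ffr$fragments))
})

test_that("fragment-mode and count-mode selection agree in distribution", {
  set.seed(34)
  n <- 2e5
  ff <- 0.2
  wp <- window_probability(fix_model, fix_w125)
  fsf <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n),
                         mode = "fragment")
  self <- apply_size_selection(fsf, fix_w125)
  # per-origin survival matches the window probabilities within 4 sigma
  for (origin in c("maternal", "fetal")) {
    n_o <- sum(fsf$fragments$origin == origin)
    kept <- sum(self$fragments$origin == origin)
    p <- if (origin == "fetal") wp$p_f else wp$p_m
    expect_lt(abs(kept / n_o - p), 4 * sqrt(p * (1 - p) / n_o))
  }
  # count mode (thinning) produces the same survival in distribution
  fsc <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n))
  selc <- apply_size_selection(fsc, fix_w125, renormalize_depth = FALSE)
  for (origin in c("maternal", "fetal")) {
    n_o <- sum(fsc$counts[, origin])
    kept <- sum(selc$counts[, origin])
    p <- if (origin == "fetal") wp$p_f else wp$p_m
    expect_lt(abs(kept / n_o - p), 4 * sqrt(p * (1 - p) / n_o))
  }
})

test_that("empty selection raises an explicit error", {
  set.seed(35)
  fs <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 1e4))
  # window entirely outside the length support: zero survival probability
  expect_error(apply_size_selection(fs, size_window(300, 400)), "survive")
  # window in the far tail: thinning kills every read at this depth
  expect_error(
    apply_size_selection(fs, size_window(245, 250), renormalize_depth = FALSE),
    "survive")
  fsf <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = 1e3),
                         mode = "fragment")
  expect_error(apply_size_selection(fsf, size_window(300, 400)), "survive")
})
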