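test_that("sample specs validate their inputs", {
  expect_error(sample_spec(1.2), "ff")
  expect_error(sample_spec(0.1, mosaicism = 0.5), "aneuploidy")
  expect_error(sample_spec(0.1, aneuploidy = "chr21", mosaicism = 2), "mosaicism")
  expect_error(sample_spec(0.1, n_fragments = 0), "n_fragments")
  s <- sample_spec(0.1, aneuploidy = "chr21")
  expect_equal(s$mosaicism, 1)  # non-mosaic trisomy by default
})

test_that("FF = 0 yields no fetal fragments in either mode", {
  set.seed(41)
  fs <- simulate_sample(fix_genome, sample_spec(0, "male", n_fragments = 1e4))
  expect_identical(sum(fs$counts[, "fetal"]), 0L)
  fsf <- simulate_sample(fix_genome, sample_spec(0, "male", n_fragments = 1e4),
                         mode = "fragment")
  expect_identical(sum(fsf$fragments$origin == "fetal"), 0L)
})

test_that("simulation is deterministic given the seed, in both modes", {
  spec <- sample_spec(0.1, "male", n_fragments = 5e4, seed = 99)
  expect_identical(simulate_sample(fix_genome, spec),
                   simulate_sample(fix_genome, spec))
  expect_identical(simulate_sample(fix_genome, spec, mode = "fragment"),
                   simulate_sample(fix_genome, spec, mode = "fragment"))
})

test_that("realised origin fraction recovers the specified FF", {
  set.seed(42)
  for (ff in c(0.02, 0.195)) {
    n <- 1e6
    fs <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n))
    expect_lt(abs(origin_fractions(fs)[["fetal"]] - ff),
              3 * sqrt(ff * (1 - ff) / n))
  }
})

test_that("fetal trisomy elevates the fetal target-chromosome share by 1 + m/2", {
  set.seed(43)
  n <- 2e6
  fs_eu <- simulate_sample(fix_genome, sample_spec(0.195, "male", n_fragments = n))
  fs_t21 <- simulate_sample(fix_genome,
                            sample_spec(0.195, "male", aneuploidy = "chr21",
                                        mosaicism = 1, n_fragments = n))
  i21 <- fix_genome$bins$chrom == "chr21"
  share <- function(fs) sum(fs$counts[i21, "fetal"]) / sum(fs$counts[, "fetal"])
  ratio <- share(fs_t21) / share(fs_eu)
  p <- share(fs_eu)
  n_f <- sum(fs_t21$counts[, "fetal"])
  # expected 1.5x (minus the slight renormalisation of the fetal genome)
  expected <- 1.5 / (1 + 0.5 * p)
  expect_lt(abs(ratio - expected), 4 * sqrt(2 * (1 - p) / (p * n_f)))
})

test_that("maternal CNV scales the maternal target-chromosome share", {
  set.seed(44)
  n <- 2e6
  cnv <- data.frame(chrom = "chr21", copy_ratio = 1.5)
  fs0 <- simulate_sample(fix_genome, sample_spec(0.1, "male", n_fragments = n))
  fs1 <- simulate_sample(fix_genome, sample_spec(0.1, "male", maternal_cnv = cnv,
                                                 n_fragments = n))
  i21 <- fix_genome$bins$chrom == "chr21"
  share <- function(fs) sum(fs$counts[i21, "maternal"]) / sum(fs$counts[, "maternal"])
  p <- share(fs0)
  expect_lt(abs(share(fs1) / p - 1.5 / (1 + 0.5 * p)),
            4 * sqrt(2 * (1 - p) / (p * n * 0.9)))
})

test_that("expected %chrY composes linearly in FF (male fetus)", {
  set.seed(45)
  n <- 5e6
  for (ff in c(0, 0.1, 1)) {
    fs <- simulate_sample(fix_genome, sample_spec(ff, "male", n_fragments = n))
    target <- ff * 0.0017 + (1 - ff) * 2e-5
    iy <- fix_genome$bins$chrom == "chrY" & !fix_genome$bins$n_mask
    ia <- fix_genome$bins$chrom %in% fix_genome$autosomes & !fix_genome$bins$n_mask
    # raw ratio over unmasked bins carries the GC-acceptance distortion of
    # this genome; allow 10% relative on top of counting noise
    raw_ratio <- sum(fs$counts[iy, ]) / sum(fs$counts[ia, ])
    expect_lt(abs(raw_ratio - target),
              0.1 * target + 4 * sqrt(max(target * n, 1)) / (n * 0.95))
  }
  # female fetus: chrY stays at the background floor regardless of FF
  fsf <- simulate_sample(fix_genome, sample_spec(0.3, "female", n_fragments = n))
  iy <- fix_genome$bins$chrom == "chrY"
  expect_lt(sum(fsf$counts[iy, ]) / n, 1e-4)
})

test_that("count mode and fragment mode agree in distribution per (chrom, origin)", {
  set.seed(46)
  n <- 3e5
  spec <- sample_spec(0.2, "male", aneuploidy = "chr21", n_fragments = n)
  fsf <- simulate_sample(fix_genome, spec, mode = "fragment")
  fsc <- simulate_sample(fix_genome, spec, mode = "count")
  # shared theoretical cell probabilities (the generating population)
  jp <- fsc$joint_probs
  for (origin in c("maternal", "fetal")) {
    for (ch in c("chr1", "chr21", "chrX")) {
      idx <- fix_genome$bins$chrom == ch
      p <- sum(jp[idx, origin])
      f_frag <- mean(fsf$fragments$origin == origin &
                       fsf$fragments$chrom == ch)
      f_count <- sum(fsc$counts[idx, origin]) / n
      tol <- 4 * sqrt(p * (1 - p) / n)
      expect_lt(abs(f_frag - p), tol)
      expect_lt(abs(f_count - p), tol)
    }
  }
  # in-window fractions per origin match the length-model probabilities
  wp <- window_probability(fix_model, fix_w125)
  for (origin in c("maternal", "fetal")) {
    sub <- fsf$fragments[fsf$fragments$origin == origin, ]
    p <- if (origin == "fetal") wp$p_f else wp$p_m
    phat <- mean(sub$length >= 125 & sub$length <= 135)
    expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / nrow(sub)))
  }
})

test_that("uniform (bias-free) simulation gives multinomial-consistent bin counts", {
  set.seed(47)
  g <- build_genome(n_mask_rate = 0, gc_chrom_sd = 0, seed = 7)
  fs <- simulate_sample(g, sample_spec(0, "female", n_fragments = 5e5),
                        gc_beta = 0)
  idx <- g$bins$chrom == "chr1"
  counts <- fs$counts[idx, "maternal"]
  p <- g$bins$width[idx] / sum(g$bins$width[idx])
  gof <- stats::chisq.test(counts, p = p)
  expect_gt(gof$p.value, 1e-4)
})
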