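# Shared fixtures: one deterministic scaled genome and the default length
# model, built once per test run.
fix_genome <- build_genome(seed = 11)
fix_model <- length_model()
fix_w125 <- size_window(125, 135)

# Wrap a hand-built fragment data.frame as a fragment-mode sample.
make_fragment_fs <- function(df, genome = fix_genome, model = fix_model) {
  df$chrom <- factor(df$chrom, levels = names(genome$chrom_lengths))
  if (is.null(df$origin)) df$origin <- "maternal"
  if (is.null(df$mapq)) df$mapq <- 60L
  if (is.null(df$duplicate)) df$duplicate <- FALSE
  structure(list(
    sample_id = "fixture", mode = "fragment", counts = NULL, fragments = df,
    genome = genome, model = model, spec = NULL, joint_probs = NULL,
    provenance = "pre_selection", selection = NULL, n_total = nrow(df),
    gc_beta = 0
  ), class = "fragment_set")
}

# Hand-built bin table (one row per entry), for unit tests that need full
# control over counts/GC/masks.
make_bin_table <- function(chrom, raw, gc = 0.41, n_mask = FALSE,
                           corrected = NA_real_, width = 20000) {
  n <- length(chrom)
  bt <- data.frame(
    chrom = factor(chrom, levels = unique(chrom)),
    start = rep(0, n), end = rep(width, n),
    gc = rep_len(gc, n), n_mask = rep_len(n_mask, n),
    raw = raw, masked = FALSE, corrected = rep_len(corrected, n)
  )
  attr(bt, "autosomes") <- paste0("chr", 1:22)
  class(bt) <- c("bin_table", "data.frame")
  bt
}

# Independent fine-grid Riemann-sum oracle for window probabilities: built
# directly from the mixture parameters, not from the package's integrator.
riemann_window_prob <- function(model, origin, lo, hi, dx = 1e-3) {
  comp <- model[[origin]]
  dens <- function(x) {
    vapply(x, function(xi) sum(comp$weight * stats::dnorm(xi, comp$mean, comp$sd)),
           numeric(1))
  }
  grid_in <- seq(max(lo, model$support[1]) + dx / 2, min(hi, model$support[2]), by = dx)
  grid_all <- seq(model$support[1] + dx / 2, model$support[2], by = dx)
  if (!length(grid_in)) return(0)
  sum(dens(grid_in)) / sum(dens(grid_all))
}
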