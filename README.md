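# inips

Simulation and analysis of **non-invasive prenatal screening (NIPS)** for
fetal trisomy 13/18/21, with **in-silico fragment-size selection** of
maternal-plasma cell-free DNA (cfDNA).

## The problem

Plasma of a pregnant woman contains a mixture of maternal and fetal
(placental) cfDNA. Shallow whole-genome sequencing detects fetal trisomy as
a small over-representation of the target chromosome: a trisomy carried by
a fetal fraction *FF* raises the chromosome's read share by only
*FF*/2. Screening therefore fails when the fetal fraction is low
(conventionally below ~4%), and maternal copy-number abnormalities can
mimic or mask a fetal signal.

Fetal cfDNA is shorter than maternal cfDNA: both share a mono-nucleosomal
peak at ~166 bp, but the fetal molecules carry a pronounced
sub-nucleosomal component below 150 bp, concentrated around 125–135 bp.
Selecting a narrow insert-size window before sequencing therefore enriches
the fetal fraction. If a fetal fragment falls in the window with
probability *p*<sub>f</sub> and a maternal fragment with probability
*p*<sub>m</sub>, selection maps the fetal fraction as

```
FF' = FF · p_f / (FF · p_f + (1 − FF) · p_m)
```

so the enrichment is governed by the single ratio *r* = *p*<sub>f</sub> /
*p*<sub>m</sub> (≈ 3.32 for the default length model and the 125–135 bp
window). `inips` implements the whole pipeline on synthetic data:

* **Simulator** — maternal/fetal cfDNA mixtures over a scaled hg19 genome
  (20-kb bins), with truncated Gaussian-mixture fragment-length models,
  configurable fetal fraction, fetal sex, trisomy 13/18/21 with placental
  mosaicism, maternal CNVs, GC bias, MAPQ strata and duplicates. Fast
  count mode for cohorts, fragment mode (BED6 I/O) for read-level work.
* **Size selection** — inclusive insert windows, library↔insert
  conversion (190–240 bp library ↔ 100–150 bp insert at 90 bp of
  adapter), analytic enrichment predictor, and depth-renormalised
  in-silico selection.
* **QC and normalisation** — MAPQ/length/duplicate filters, 20-kb
  binning, zero-read and N-bin masking, LOESS GC correction, and
  autosome-denominated chromosome percentages.
* **Calling** — reference-cohort z-scores with the 2.58/4.00 no-call
  band (affected if z > 4.00, unaffected if z < 2.58, otherwise "no
  call"), chrY-based fetal-fraction estimation
  (FF = (%chrY<sub>MF</sub> − %chrY<sub>FF</sub>) / (%chrY<sub>AM</sub> −
  %chrY<sub>FF</sub>) with %chrY<sub>AM</sub> = 0.170%), trisomic-fraction
  and mosaicism-degree arithmetic.
* **Experiments** — cohort drivers for the size-window comparison, the
  low-fetal-fraction sensitivity gradient, the 50-sample enrichment
  cohort and the maternal-interference scenario, with exact
  (Clopper–Pearson) confidence intervals.

## Worked example

A trisomy-21 male-fetus sample at 2% fetal fraction, analysed without and
with 125–135 bp selection:

```r
library(inips)
genome <- build_genome(seed = 1)
model  <- length_model()
window_probability(model, size_window(125, 135))
#> window [125, 135] bp (insert): p_f = 0.14592, p_m = 0.04393, r = 3.322

spec   <- sample_spec(ff = 0.02, fetal_sex = "male", aneuploidy = "chr21",
                      n_fragments = 5e6, seed = 7, sample_id = "case_T21")
sample   <- simulate_sample(genome, spec)
enriched <- apply_size_selection(sample, size_window(125, 135))
origin_fractions(sample)[["fetal"]]    # 0.0202
origin_fractions(enriched)[["fetal"]]  # 0.0635  (~3.2x enrichment)

# 30 euploid references per arm, then call the sample in both arms
set.seed(100)
refs_nips <- refs_inips <- vector("list", 30)
for (i in 1:30) {
  r <- simulate_sample(genome, sample_spec(0.15, "male", n_fragments = 5e6))
  refs_nips[[i]]  <- profile_sample(r)
  refs_inips[[i]] <- profile_sample(apply_size_selection(r, size_window(125, 135)))
}
call_aneuploidy(profile_sample(sample),   build_reference(refs_nips),  arm = "NIPS")
#>   chrom          z      class  arm
#> 1 chr13 -2.6391312 unaffected NIPS
#> 2 chr18  0.2342061 unaffected NIPS
#> 3 chr21  2.3999010 unaffected NIPS     <- trisomy missed at FF = 2%
call_aneuploidy(profile_sample(enriched), build_reference(refs_inips), arm = "iNIPS")
#>   chrom          z      class   arm
#> 1 chr13 -0.1369035 unaffected iNIPS
#> 2 chr18  0.9967341 unaffected iNIPS
#> 3 chr21  9.0942269   affected iNIPS    <- detected after size selection
```

The same machinery quantifies placental mosaicism: a sample whose
trisomic fetal DNA fraction is 5.6% at a total fetal fraction of 44% has

```r
mosaicism_degree(0.056, 0.44)
#> [1] 0.1272727   # a 12.7% degree of mosaicism
```

Cohort studies run from single calls, e.g.
`run_gradient_experiment(seed = 1)` (sensitivity of both arms across
fetal fractions 1–10%) or `run_enrichment_cohort(seed = 1)` (chrY-based
enrichment metrics over 50 simulated pregnancies).

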