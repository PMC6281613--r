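---
title: "Size-selection enriched prenatal screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-selection enriched prenatal screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inips)
```

This vignette explains the statistical model behind `inips`, the choices
made where the design was genuinely open, and what the synthetic cohorts
do and do not demonstrate about real plasma sequencing data.

## The screening model

Shallow whole-genome sequencing of maternal-plasma cfDNA detects fetal
trisomy as an over-representation of the target chromosome. Writing $p_c$
for a chromosome's read share (its corrected read count divided by the
total corrected count on all autosomes), a trisomy carried by a fetal
fraction $FF$ multiplies the fetal contribution to chromosome $c$ by
$3/2$, so the expected share rises by a relative $FF/2$. Samples are
scored against a euploid reference cohort:

$$z_c = \frac{p_c - \hat\mu_c}{\hat\sigma_c},$$

with $\hat\mu_c$, $\hat\sigma_c$ the reference mean and standard
deviation ($n-1$ denominator). Classification uses a no-call band:
affected if $z > 4.00$, unaffected if $z < 2.58$, no call in the closed
band $[2.58, 4.00]$ — the band's boundaries themselves are no calls,
because the decision rule is quoted with strict inequalities on both
sides. A rank-based variant (the sample's Mann–Whitney placement among
the reference values, normal-approximated) is available through
`z_score(..., method = "rank")` for sensitivity analyses; the primary
statistic is the plain reference-cohort z-score, which is what the
printed z values of clinical screening reports correspond to.

At the default depth of $5\times10^6$ fragments per sample the Poisson
coefficient of variation of the chr21 share is about 0.4%, so an
unenriched trisomic sample at $FF = 4\%$ sits near $z \approx 5$ while
$FF = 2\%$ sits near $z \approx 2.6$ — the classical failure of routine
screening below 4% emerges from counting statistics rather than from any
hard-coded threshold.

## Fragment-length model and size selection

Both cfDNA origins share a mono-nucleosomal component at 166 bp; each
adds its own sub-nucleosomal component. The defaults are truncated
two-component Gaussian mixtures on [60, 250] bp:

| origin   | shared component | short component | weights |
|----------|------------------|-----------------|---------|
| maternal | N(166, 9)        | N(140, 14)      | 0.80 / 0.20 |
| fetal    | N(166, 9)        | N(132, 8)       | 0.68 / 0.32 |

These parameters are a calibration, not a measurement: they encode the
established fragmentomics (maternal peak at 166 bp, fetal excess below
150 bp, fetal enrichment maximal at 125–135 bp) and are tuned so that the
125–135 bp window-probability ratio is

$$r = \frac{P_{fetal}(125\text{–}135)}{P_{maternal}(125\text{–}135)} \approx 3.32 .$$

Selecting a window in which fetal fragments survive with probability
$p_f$ and maternal fragments with $p_m$ maps the fetal fraction through

$$FF' = \frac{FF\,p_f}{FF\,p_f + (1-FF)\,p_m},$$

implemented in `predict_enriched_ff()` and used throughout as the
analytic oracle for the simulation. With $r \approx 3.32$ the closed form
reproduces the working points the synthetic studies are validated
against: a cohort at median $FF = 0.1458$ enriches $\approx 2.5\times$
(maternal background $\approx 1.3\times$ down), the 1–10% gradient pools
to a median fold of $\approx 3.1$ (maternal decrease $\approx 1.08$), and
at $FF = 0.08$ the 125–135 bp window gives $\approx 2.8\times$, above the
115–125 and 135–145 bp windows ($r \approx 2.65$ and $1.62$). All model
parameters are arguments of `length_model()`.

Insert lengths are kept **continuous** in memory and quantised to
integer bp only on BED export. The window probabilities, the count-mode
thinning and the fragment-mode filter then share one convention
(inclusive continuous bounds); quantising lengths first would shift the
narrow-window probabilities by several percent and break the exact
agreement between the analytic predictor and both simulation modes.
Window bounds are inclusive on both ends, matching how electrophoretic
windows such as "125–135 bp" are quoted. Library-frame windows convert
to insert frame by subtracting 90 bp of total adapter
(`library_to_insert()`), the value implied by the 190–240 bp library ↔
100–150 bp insert correspondence.

### Depth renormalisation

Gel selection happens **before** sequencing, and a plasma library
contains far more molecules than are ever sequenced. The default
count-mode selection (`renormalize_depth = TRUE`) therefore treats the
selected library as an effectively unlimited pool whose composition is
the sample's generating (bin, origin) distribution tilted by the window
probabilities, and sequences it back to the original depth with a single
multinomial draw. Thinning the *sequenced* reads instead (available as
`renormalize_depth = FALSE`, and what fragment-mode selection does by
construction) models a bottleneck at sequencing depth: the effective
post-selection depth drops to $n (FF\,p_f + (1-FF)\,p_m) \approx 5\%$ of
the reads, which inflates the chr21 CV about four-fold and would, at
desk scale, erase the very sensitivity gain the selection exists to
provide. The renormalised model is the faithful description of the bench
protocol; the thinning mode is kept for studies of the bottleneck
itself.

## The synthetic genome and simulator

The genome model is the hg19 karyotype with every chromosome length
divided by `scale = 500` and partitioned into 20-kb bins (last bin of a
chromosome may be short): 322 bins in total, of which chr21 holds 5.
This keeps whole-cohort simulations in seconds while exercising every
pipeline stage; z-scores operate on chromosome-level sums, so their
behaviour is driven by total depth, not bin count. `scale = 1` gives a
full-scale genome. Per-bin GC is Beta-distributed around
chromosome-specific mean offsets (so GC bias distorts chromosome
representation, which is what makes the correction consequential), and a
configurable fraction of bins (default 3%) is N-masked.

Each fragment draws its origin Bernoulli($FF$), its bin with probability
proportional to bin width × GC acceptance × chromosome copy weight, and
its length from the origin's mixture. Copy weights encode the biology:

* fetal trisomy multiplies the target chromosome's fetal weight by
  $1 + m/2$, where $m \in [0,1]$ is the degree of placental mosaicism
  (the fraction of the placental lineage carrying the trisomy; $m = 1$
  is a non-mosaic trisomy);
* maternal CNVs multiply maternal weights by their copy ratio;
* a male fetus carries chrX at half weight, and chrY at a weight
  calibrated so that the *GC-corrected* chrY/autosome read ratio of 100%
  male DNA is 0.170% (the adult-male constant) while pure female
  background sits at a 0.002% misalignment floor. The calibration uses
  GC-unweighted, non-N-masked width sums because the pipeline measures
  %chrY after LOESS correction and after N-bin exclusion; this keeps the
  chrY fetal-fraction formula self-consistent, with expected
  %chrY $= FF \cdot 0.170\% + (1-FF) \cdot 0.002\%$ for a male fetus.

GC bias is a linear acceptance factor
$g(GC) = \mathrm{clamp}(1 + \beta (GC - 0.41),\ 0.2,\ 1.8)$ with default
$\beta = 2$: simple, monotone, and removable by LOESS — the correction
stage only assumes *some* smooth bias, not this shape. Mapping quality is
stratified (90% at MAPQ 60, 5% uniform 11–59, 5% uniform 0–10) and
duplicates occur at 2%; both rates are invented defaults (real pipelines
filter on these but rarely report rates) and configurable. Coordinates
are 0-based half-open; fragments belong to the bin containing their
start.

Count mode and fragment mode realise the same joint distribution over
(bin, origin, in-window); the test suite verifies their agreement within
4σ binomial bounds and the recovery of every declared parameter (fetal
fraction, trisomy weight, %chrY composition).

## QC, binning and GC correction

Fragment-mode samples are filtered to MAPQ $> 10$, length $> 35$ bp,
non-duplicate (strict inequalities; count mode folds these
position-independent filters into its rates). Bins with zero reads or
assembly Ns are masked per sample and excluded from every downstream sum.
GC correction fits a degree-1 LOESS (span 0.3, configurable; no span is
canonical in the screening literature) of the per-bp read rate against GC
rounded to 0.1%, aggregated by unique GC value and weighted by genomic
width — fitting rates rather than raw counts keeps the short terminal
bins from denting the GC profile. Corrected counts are
$raw \times \mathrm{median\ rate} / \mathrm{fitted}(GC)$; non-positive
fitted values mask the bin; degenerate GC (fewer than 10 distinct values)
degrades to the identity with a warning. The median scaling preserves
totals within a few percent. Correction is genome-wide (not
per-chromosome), and GC values outside the autosomal fitting range are
clamped to it before prediction.

Chromosome percentages — including %chrY — all use the same denominator,
the total corrected autosomal count. The simulator's 0.170% calibration
is defined under exactly this convention.

## Fetal fraction and screening metrics

For male-fetus pregnancies,
$FF = (\%chrY_{MF} - \%chrY_{FF}) / (\%chrY_{AM} - \%chrY_{FF})$ with
$\%chrY_{AM} = 0.170\%$ and the female background $\%chrY_{FF} = 0.002\%$
(a configuration scalar mirroring an empirical female-cohort average).
Estimates are clamped to $[0,1]$, with a warning when sampling noise
near $FF = 0$ produces a negative raw value. The male fetus's
half-weight chrX slightly perturbs the autosomal denominator of the
mixture, giving the estimator a small positive bias (about $+0.002$ at
$FF = 0.1$, $+0.005$ at $FF = 0.3$) that is inherent to the
interpolation formula and cancels almost entirely in pre/post-selection
fold ratios. Regression-based estimators for female-fetus pregnancies
are out of scope; experiments needing female-fetus fetal fractions use
the simulator's ground-truth labels and say so.

Enrichment is summarised per sample by the fold-increase
$FF'/FF$ and the maternal-background decrease $(1-FF)/(1-FF')$.
Screening performance uses sensitivity (affected calls among affected
truths) and specificity (unaffected among unaffected), with no-calls
counted as non-detections — the conservative reading — and tabulated
separately; intervals are exact Clopper–Pearson at 99%.

The trisomic fetal DNA fraction is recovered from over-representation as
$2(p/\mu_{ref} - 1)$, clamped below at zero, and the degree of placental
mosaicism is its ratio to the total fetal fraction — e.g. 5.6% trisomic
over 44% total gives 12.7%.

## Cohort experiments and their problem sizes

Cohort fetal fractions are log-normal, parameterised by their median and
clamped to a declared plausibility range — cohorts in this field are
reported by median and range, and the log-normal is the standard
positive-skew choice; the exact distributions are declared in each run's
configuration rather than inferred. Defaults: the 50-sample enrichment
cohort uses median 0.1458 (sdlog 0.45, clamped to 0.03–0.56), the
9-sample window comparison median 0.08 (sdlog 0.25, clamped to
0.03–0.20), and reference pregnancies follow the enrichment-cohort
distribution. The gradient study uses exact fractions
{1, 2, 3, 4, 5, 10}% × 30 trisomy-21 samples at $5\times10^6$ fragments,
with 100 euploid references **per arm**: references must be arm-matched
(selected references for selected samples) for the null z to be standard
normal, since selection changes the origin mixture that underlies the
reference spread. Gradient enrichment medians use the simulator's
ground-truth origin fractions — at $FF = 1\%$ a chrY-based estimate is
dominated by counting noise and a per-sample fold would be meaningless —
while the enrichment cohort reports chrY-based estimates, as a real
laboratory would. All experiment drivers are bit-reproducible from
(configuration, seed).

These sizes keep the full test suite under a minute and the acceptance
script under ten seconds on one core; they are also the sizes at which
the studied effects are already decisive (e.g. the enriched $z$ at
$FF = 2\%$ sits near 9, far beyond the 4.00 threshold).

## What the synthetic cohorts do not show

The simulator reproduces the statistical structure the analysis relies
on, not plasma biology in full. It has no 10-bp periodicity fine
structure in the length distributions, no sequencing-error or alignment
model (fragments are emitted downstream of alignment and deduplication),
no mappability variation beyond the N-mask, no between-sample GC-bias
variation, no gel-extraction efficiency curve (the window is a sharp
inclusive cut), and no PCR-duplicate amplification structure. Passing
tests therefore demonstrate that the pipeline's inference is correct
under its stated assumptions and calibrations — they do not certify
performance on real libraries, where fragmentomic contrast, GC structure
and fetal-fraction distributions differ by laboratory. Sex-chromosome
aneuploidies and sub-chromosomal events (microdeletions,
microduplications) are out of scope of the caller.
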