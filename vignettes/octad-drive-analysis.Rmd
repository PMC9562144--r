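---
title: "Detecting and modelling spore-killing meiotic drive from octad dissections"
author: "octadrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling spore-killing meiotic drive from octad dissections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadrive)
```

## The biology and the statistical problem

Killer meiotic drivers are selfish genes that destroy the meiotic products
(spores) that fail to inherit them, and thereby reach more than half of a
heterozygote's viable offspring. In the *wtf* family of fission yeast
drivers, a single gene encodes both a poison, expressed from a short
transcript and affecting all spores, and an antidote, expressed from a long
transcript only in spores that inherit the gene, which rescues them.

Eight-spored fission yeasts such as *Schizosaccharomyces octosporus* perform
a mitosis after meiosis and before spore packaging, so a dissected ascus
(an *octad*) contains eight spores in four genetically identical pairs. In a
cross of a wild-type strain (*wtf+*, antibiotic **S**ensitive) to a deletion
strain (marker-carrying, antibiotic **R**esistant), each octad carries
exactly four S and four R spores. Drive by the *wtf+* allele shows up in
three ways, each with its own statistic in this package:

* reduced overall spore viability in heterozygous but not homozygous
  crosses (`viability_comparison()`, Fisher's exact test);
* an excess of S among viable genotyped spores
  (`transmission_test()`, exact binomial test; the transmission distortion
  ratio, TDR, is the S fraction);
* asymmetry between mirror octad types — e.g. 4R3S should be as common as
  3R4S without drive (`octad_ratio_tests()`).

## Data model and filtering

Dissection data arrive as one row per spore (cross, ascus, spore label A–H,
viability, genotype R/S/U). Genotypes come from replica plating of colonies,
so an inviable spore is by construction ungenotyped (U); validation enforces
this. Two standard filters are applied in a fixed order, so every excluded
octad falls under exactly one rule:

1. asci with fewer than eight dissected spores are excluded (incomplete
   dissections);
2. heterozygous octads with more than four *viable* spores of one allele are
   excluded (aberrant segregation, e.g. gene conversion). "Spores harboring
   one allele" is read as viable genotyped spores, because genotypes only
   exist for colonies.

The order (incomplete first) is a package convention; the rules themselves
do not overlap in their counts because the filter report attributes each
octad to the first rule it violates. Viable-but-ungenotyped spores are
rejected by default in heterozygous analyses and can be skipped explicitly
with `allow_ungenotyped = TRUE`.

## Exact-test conventions

Both exact tests use the minimum-likelihood (point-probability) two-sided
rule: the p-value is the total null probability of all outcomes whose point
probability does not exceed the observed one, with a relative tie tolerance
of 1e-12 so results are platform-stable. Point probabilities are evaluated
in log space, so tables with thousands of counts do not underflow. This
convention was chosen because it reproduces, to their printed precision,
two-sided p-values published for these tests in the spore-killer literature
(e.g. 0.0055 for the table (9,1;2,8) and 0.016 for (17,3;14,14)); it is
also the convention of R's `fisher.test` and `binom.test`, which the test
suite uses as independent cross-checks alongside brute-force enumeration
oracles. No multiple-testing correction is applied anywhere, matching
standard practice in dissection studies where a handful of planned
contrasts are reported.

Mirror-pair ratio p-values are only reported when the pair has more than
five octads in total; below that the two-sided exact binomial test cannot
reach 0.05 even in the most extreme outcome (2/2^5 = 0.0625), so reporting
a p-value would only invite over-interpretation. Gated pairs are marked
explicitly in all outputs.

## Driver classification rules

`classify_driver()` encodes the decision logic as used in dissection
studies of *wtf* drivers:

* **active_driver** — viability reduction above `min_reduction_pp`
  (default 5 percentage points) with Fisher p below `alpha` (default
  0.05), transmission-test p below `alpha`, and TDR above 0.5. The TDR
  direction gate is a deliberate addition so that distortion favouring
  the deletion allele is never auto-labelled a *wtf* driver.
* **weak_driver** — not active, but at least one non-gated mirror pair
  deviates significantly with the bias favouring the wild-type allele.
* **no_drive** otherwise.

The rule is monotone in the p-values: worsening evidence can never promote
a cross to a stronger category (property-tested).

## The generative killing model

The model has two parameters: background per-spore viability `v` and kill
probability `k` for spores lacking the driver. Carrier spores suffer only
background death — the antidote is treated as fully protective, consistent
with homozygous deletion crosses showing no viability loss. Centromere
linkage (first- versus second-division segregation) is not modelled; every
heterozygous octad carries four spores of each genotype.

Two killing units are offered:

* `"spore"` (default): each non-carrier spore is killed independently, so
  viable counts are `r ~ Binomial(4, v(1-k))` and `s ~ Binomial(4, v)`.
  This is the natural reading of per-spore poison action after packaging.
* `"meiotic_product"`: each non-carrier *pair* is killed jointly with
  probability `k` (sister spores are genetically identical and may be
  jointly exposed), survivors then die at the background rate. Both units
  share the marginal mean `E[r] = 4v(1-k)` but the pair model is
  overdispersed, which is what the likelihood can discriminate.

Under either unit, the expected transmission distortion ratio is
`1/(2-k)`, independent of `v`: background death removes R and S spores at
equal rates, so only killing distorts the viable-allele ratio.

Estimation: for the spore unit the MLE is closed form
(`v̂ = mean(s)/4`, `k̂ = 1 − mean(r)/(4v̂)`, clipped to [0, 1]); for the
pair unit the likelihood is maximized numerically over the unit square
(21×21 grid then L-BFGS-B refinement; grid ties within 1e-9 log-likelihood
resolve to the smaller `k`, preferring the weaker-drive explanation).
Confidence intervals are percentile bootstrap over octads (default 1000
replicates, explicit seed required), chosen over profile likelihood
because they remain usable at boundary estimates `k̂ ∈ {0, 1}`.

## What the synthetic data emulates — and what it does not

`simulate_octads()` is a forward model of the biology above: 4+4 genotype
pairing from the post-meiotic mitosis, driver-dependent killing, independent
background death, incomplete dissections (spores dropped uniformly at
random, rate per ascus), and occasional aberrant 5:3 or 6:2 genotype
constitutions standing in for gene-conversion events. Defaults are chosen
to resemble a real dissection experiment: `v = 0.95` (wild-type crosses
are ~95% viable), 20 octads per cross (a typical plate is 10–25), and
aberrant/incomplete rates of zero unless a test needs them (real excluded
octads are rare, under 2%).

The generator does not emulate: centromere linkage, partial antidote
protection, genotyping errors, or any spatial plate structure. Passing
tests therefore demonstrate correctness of the statistics under the
model's assumptions, not robustness to these unmodelled features.

A consequence worth knowing: under the null (`k = 0`) the transmission
test is *very* conservative on simulated octads at high viability, because
allele counts are balanced 4+4 within every octad and only spore death
introduces variance — far less than the binomial test's assumption of
independent allele draws. The null-calibration test accordingly asserts
only that the rejection rate does not exceed the nominal level.

`simulate_gene_table()` emulates a candidate-gene table in which carrying
a confident regulatory-motif hit in intron 1 raises short-transcript
(poison isoform) detection and level: a latent normal expression level is
shifted up by `flex_shift` (default 1.7, calibrated so detection is ~85%
for motif-positive vs ~50% for motif-negative genes, matching the margins
of a 48-gene candidate table with 20 motif-positive genes), detection is
logistic in the latent level, and detected genes get a negative binomial
read count (dispersion 1.0, mimicking noisy long-read counts).
`simulate_fimo_hits()` draws a two-component mixture of signal hits
(log10 p in [−9, −6.5], inside the upstream window of target genes) and
noise hits (log10 p in [−5.5, −4], anywhere), which is the structure the
cutoff calibration exploits.

## Motif-hit cutoff calibration and enrichment

`classify_hits()` partitions scanner hits at `p ≤ cutoff` — inclusive,
since scan p-values landing exactly on the cutoff are measure-zero in
practice. `calibrate_cutoff()` scores each candidate cutoff by sensitivity
(fraction of known target genes with a confident hit in the upstream
window, default 1000 bp measured at the hit start) minus the false-positive
fraction among background genes, and picks the maximizer, breaking ties
toward the most stringent cutoff. "Maximize hits in targets while
minimizing hits elsewhere" is informal; the difference objective is this
package's concrete reading, and the full per-cutoff table is returned so
users can apply another objective. The default candidate grid is a
decade/half-decade ladder from 1e-4 (a scanner's default output cutoff)
down to 1e-8. Gene-level enrichment and the two gene-feature association
tests all delegate to the same Fisher implementation, so the enumeration
oracle guarantees carry over.

## Problem sizes and numerical choices

The shipped test-suite and acceptance sizes are chosen to make sampling
error small relative to the asserted tolerances while keeping each run in
seconds: parameter recovery at 1000 octads (binomial standard errors
~0.01–0.02, asserted at 3× that), TDR checks at 10,000 octads, null
calibration at 2000 replicates of 20 octads, power at 100–200 Monte-Carlo
replicates. Exact-test oracle comparisons run over all totals up to 25,
where enumeration is instantaneous. All simulations take explicit integer
seeds and restore the caller's RNG state; identical spec plus seed yields
byte-identical TSV output.

## Worked example

```{r example}
octads <- read_octad_table(
  system.file("extdata", "example_octads.tsv", package = "octadrive"),
  read_cross_table(
    system.file("extdata", "example_crosses.tsv", package = "octadrive")))
het <- filter_octads(octads$wtf25_het)
ctrl <- filter_octads(octads$wt_control)
het$filter_report[c("n_input", "n_excluded_incomplete",
                    "n_excluded_aberrant", "n_retained")]
drive_report(het, ctrl)
```

```{r model}
ds <- filter_octads(simulate_octads(octad_sim_spec(
  v = 0.9, k = 0.8, n_octads = 1000, seed = 11)))
fit_mle(tabulate_types(ds), "spore", bootstrap = 200, seed = 5)
expected_tdr(0.8)
```

## Known limitations

* The aberrant-octad generator (5:3 / 6:2 constitutions) is a synthetic
  convention; real gene-conversion spectra are more varied.
* The killing model assumes a fully protective antidote and no
  centromere linkage; poison-only or antidote-only alleles can be
  represented as parameter settings (`k` at an unlinked locus, or
  `k = 0`) but have no dedicated types.
* `tdr_expression_correlation()` uses Spearman rank correlation as a
  labelled, exploratory choice; small gene sets give it little power.
* The calibration objective weights a target-gene hit and a
  background-gene false positive equally; with very unbalanced gene sets
  users may prefer a different trade-off via the audit table.
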