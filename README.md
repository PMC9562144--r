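# octadrive

Octad dissection analysis of killer meiotic drivers in eight-spored
fission yeasts.

## What this package is for

Killer meiotic drivers — such as the *wtf* genes of fission yeast — are
selfish genes that destroy the spores that do not inherit them, and so are
transmitted to more than half of a heterozygote's viable offspring.
*Schizosaccharomyces octosporus* packages eight spores per ascus (meiosis
followed by a post-meiotic mitosis), so a dissected **octad** from a
*wtf+* × *wtfΔ* cross carries four wild-type (antibiotic **S**ensitive)
and four deletion-marked (**R**esistant) spores, in genetically identical
pairs. `octadrive` turns per-spore dissection tables into drive calls, and
provides the generative model and synthetic-data machinery to study when
such calls are trustworthy.

For geneticists running dissection experiments it provides:

* validation, standard filtering (incomplete dissections; aberrant
  \>4-of-one-allele octads) and nRmS octad-type classification;
* the field's exact statistics, all with the two-sided
  minimum-likelihood convention: Fisher's exact test for spore-viability
  contrasts, the exact binomial test for allele transmission and for
  mirror octad-type ratios (4R3S:3R4S, …, 4R0S:0R4S, gated when a pair
  has ≤ 5 octads), and the transmission distortion ratio
  TDR = n_S / (n_S + n_R);
* the decision rules that call a gene an `active_driver` (viability
  reduction > 5 pp, Fisher p < 0.05, binomial p < 0.05, TDR > 0.5), a
  `weak_driver` (significant mirror-pair bias toward *wtf+* only), or
  `no_drive`.

For modelling, a two-parameter poison/antidote killing model over octads:
background per-spore viability *v* and kill probability *k* for
non-carrier spores (per spore, or jointly per sister-spore pair), with
exact octad-type PMF, closed-form/numerical maximum-likelihood fits,
bootstrap confidence intervals, the closed-form expected distortion
E[TDR] = 1/(2 − *k*), and Monte-Carlo power analysis.

For regulatory-motif analyses of driver candidates, FIMO-style hit tables
can be classified at a p-value cutoff, the cutoff calibrated against known
target genes, and gene-level enrichment / feature associations tested with
the same Fisher machinery.

Reproducible simulators (`simulate_octads()`, `simulate_gene_table()`,
`simulate_fimo_hits()`) generate every input format the pipeline reads.

## Worked example

A small dissection table ships with the package: a heterozygous *wtf25*
deletion cross (10 dissected octads) and a wild-type control cross.

```r
library(octadrive)
octads <- read_octad_table(
  system.file("extdata", "example_octads.tsv", package = "octadrive"),
  read_cross_table(
    system.file("extdata", "example_crosses.tsv", package = "octadrive")))
het  <- filter_octads(octads$wtf25_het)
ctrl <- filter_octads(octads$wt_control)
het
#> <cross_dataset> wtf25_het (heterozygous, gene wtf25): 7 octad(s), 56 spore(s)
#>   filtered: 10 input, 2 incomplete, 1 aberrant, 7 retained
drive_report(het, ctrl)
#> <drive_report> cross wtf25_het (gene wtf25): active_driver
#>   viability 35/56 (62.5%) vs control 76/80 (95.0%): reduction 32.5 pp, p = 2e-06
#>   transmission: 27 S vs 8 R, TDR = 0.771, p = 0.00188
#>   4R3S:3R4S: 0 vs 0, gated (total <= 5)
#>   4R2S:2R4S: 0 vs 1, gated (total <= 5)
#>   4R1S:1R4S: 0 vs 2, gated (total <= 5)
#>   4R0S:0R4S: 0 vs 2, gated (total <= 5)
```

Two incomplete asci and one aberrant octad were excluded; among the 56
spores of the 7 retained octads, viability is 62.5% versus 95.0% in the
control (32.5 percentage-point reduction, Fisher p = 2e-06), and 27 of the
35 viable genotyped spores carry *wtf25+* (TDR 0.77, exact binomial
p = 0.0019) — the cross is called an active driver. Every mirror
octad-type pair has five or fewer octads, so no ratio p-values are
reported.

Fitting the killing model to a simulated experiment recovers its
parameters:

```r
ds <- filter_octads(simulate_octads(octad_sim_spec(
  v = 0.9, k = 0.8, n_octads = 1000, seed = 11)))
fit_mle(tabulate_types(ds), "spore", bootstrap = 200, seed = 5)
#> <mle_fit> (spore, closed_form) on 1000 octad(s)
#>   v_hat = 0.8998 [0.8892, 0.9083]
#>   k_hat = 0.8088 [0.7951, 0.8213]
#>   loglik = -1882.5287
expected_tdr(0.8)
#> [1] 0.8333333
```

See `vignettes/octad-drive-analysis.Rmd` for the model, its assumptions,
and the reasoning behind the conventions (filter order, two-sided test
rules, ratio-test gating, bootstrap intervals, simulator defaults).

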