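---
title: "Dissecting heterosis in partial-diallel hybrid populations with hetgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting heterosis in partial-diallel hybrid populations with hetgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetgwas)
```

## The study design this package models

Two-line hybrid rice crosses an environment-sensitive genic male-sterile
(maternal) line to a fertile restorer (paternal) line. In a partial diallel,
every paternal line is crossed to every maternal line, so each F1 hybrid is
fully determined by one inbred mother and one inbred father. `hetgwas`
implements the full analysis chain for such populations:

1. genotype QC, KNN imputation, and F1 genotype assembly from inbred parents;
2. heterosis phenotypes — better-paternal value (BPaV = F1 − Pat), mid-parent
   value (MPV = F1 − (Pat + Mat)/2), and the combining-ability decomposition
   GCA~i~ = ȳ~i·~ − ȳ~··~, SCA~ij~ = ȳ~ij~ − ȳ~··~ − GCA~mat~ − GCA~pat~
   computed on cross means;
3. a forward-selection resampling GWAS with a kinship-corrected mixed-model
   score test under four inheritance codings, aggregated as resample model
   inclusion probabilities (RMIP);
4. QTL characterization: genotype-class structure, joint additive/dominance
   (d/a) regression, superiority calls, variance explained, and
   superior-allele parental provenance;
5. a windowed Tajima's D selection scan of each parental group, with
   QTL/low-diversity overlap.

A diallel simulator with known QTL architecture backs every stage, so each
claim the package makes is testable against planted ground truth.

## The mixed model and the score test

For a phenotype vector $y$ over $n$ F1s with covariates $X$ the null model is
$y = X\beta + g + e$, $g \sim N(0, \sigma_g^2 K)$, $e \sim N(0, \sigma_e^2 I)$,
where $K$ is a VanRaden frequency-standardized genomic relationship matrix
computed once on all F1s. The likelihood is profiled over the variance ratio
$\delta = \sigma_g^2/\sigma_e^2$ on the eigenbasis of $K$: given $\delta$,
$\beta$ and $\sigma_e^2$ have closed forms, so the fit is a one-dimensional
optimization (`polygenic_fit()`). A marker coded under an inheritance model is
then tested with a one-degree-of-freedom chi-square score statistic on the
whitened residuals (`score_test()`); with $K = I$ this reduces exactly to the
ordinary least-squares score test, which the test suite verifies to 1e-8.

The four codings act on (hom-major, het, hom-minor) calls: additive (0, 1, 2),
dominance (0, 0, 2), recessive (0, 2, 2) and overdominance (0, 1, 0). A locus
fixed in one parental group produces only two F1 genotype classes, and some
codings are then blind to it (dominance collapses AA and Aa); running all four
and keeping the per-marker maximum RMIP is what makes such loci discoverable.

When the likelihood is flat in $\delta$ (identity kinship makes $\sigma_g^2$
and $\sigma_e^2$ jointly unidentifiable), the fit resolves to the
parsimonious boundary $\sigma_g^2 \approx 0$. Kinship matrices are bent by
flooring eigenvalues at 1e-6 before solving.

## Forward-selection resampling GWAS and its threshold

Each analysis draws `n_resamples` subsamples of 80% of the F1s without
replacement (default 300; the scaled testing mode uses 50). On each subsample
and coding, variance components are re-estimated and a forward selection is
run: the genome-wide best marker is added as a fixed covariate — with the
polygenic model refitted, so the variance just moved into the fixed part no
longer inflates $\hat\delta$ — and the scan repeats until nothing passes the
threshold. RMIP is 100 × (inclusions / resamples), maximized over codings;
markers at RMIP ≥ 5 are reported.

The significance threshold deserves its own paragraph, because the obvious
choice is wrong for this engine. A classic permutation threshold (the
`fdr`-quantile of per-permutation genome-wide minimum p, provided by
`permutation_threshold()`) controls the error of *one* scan. But the 80%
subsamples share most of their samples: a null marker whose full-data p sits
just above a single-scan threshold crosses it in several of the 50 correlated
subsamples far more often than 5%, and in simulation roughly one null trait
in eight then reports a marker at RMIP ≥ 5. `resample_rmip()` therefore
calibrates its threshold on the permutation null of the reporting statistic
itself: for each permuted trait it computes, over the actual subsample draws,
the smallest p-value threshold at which any marker would reach the reporting
RMIP (the `count_min`-th smallest subsample p of a marker, minimized over
markers and codings, with `count_min = ceiling(rmip_threshold/100 ×
n_resamples)`), and takes the largest permutation value whose empirical rank
stays below `fdr`. Under a pure-noise trait the engine then reports anything
at all in about `fdr` of runs, which the acceptance suite verifies over 50
seeded runs. Per permutation the minimizing marker is searched among its ten
best full-data markers — markers outside that set cannot plausibly win the
subsample-count race. With one resample at fraction 1.0 the statistic
degenerates to the per-permutation genome-wide minimum p, recovering the
classic threshold, and the engine reduces to plain forward selection (also
verified against an independent `lm()` implementation).

The threshold is computed once per trait on the full data and reused across
subsamples; recomputing permutations inside every subsample would multiply
cost three-hundred-fold for no measurable calibration gain in our
simulations. Permutations shuffle the phenotype against genotypes and kinship
alike, deliberately breaking polygenic structure as well — the standard,
admittedly blunt, exchangeability assumption.

Significant markers on a chromosome are merged into signals by single-linkage
chaining (within 800 kb *and* pairwise genotype R² ≥ 0.2 — the distance rule
alone would fuse unrelated hits in gene-dense regions; 0.2 is our default, as
the correlation requirement has no published cutoff). The QTL interval is the
Gabriel-style D′-confidence-interval haplotype block containing the lead SNP,
built on the trivially phased inbred parental haplotypes; the block search is
restricted to ±25 markers around the lead, which is ample for the marker
densities this design produces.

## QTL characterization

F1s are split by lead-SNP genotype; a QTL is three-genotype only when all
three classes hold at least 15 F1s with non-missing calls (counted after
removing missing calls — the rule's sample base is otherwise ambiguous).
Three-genotype QTLs get a joint regression on additive (0, 1, 2) and
dominance (0, 1, 0) codings with the top 10 genomic PCs as covariates; the
degree of dominance |d/a| is binned additive [0, 0.2), partial dominance
[0.2, 0.8], dominance (0.8, 1.2], overdominance > 1.2, with the ratio rounded
at 1e-9 so floating error cannot move a boundary case out of its printed bin.
Two-genotype QTLs are called hetero- or homo-superior by comparing the
heterozygote mean with the dominant homozygote class (a handful of calls of
the rarer homozygote may survive the 15-sample rule and are excluded from the
comparison); exact ties resolve conservatively to homo-superior.

The favorable direction is configuration, not inference: yield-type traits
favor higher values, heading date favors lower. Defaults are per-trait
arguments (`direction`) because no universal rule exists. For derived
categories (BPaV, SCA) the derived phenotype itself is the comparison scale.

Superior-allele provenance is exact in this design: parents are inbred, so
each F1 allele copy is attributable to its mother or father. The accounting
reports the superior-allele frequency in each parental group and among F1
copies, the contribution source (female_only / male_only / both), and the
maternal-derived fraction of superior copies.

## The simulator: what it emulates and what it does not

`simulate_parents()` builds inbred parents with the structure the analysis
assumes: paternal lines are recombinant mosaics of two family founders
(Poisson crossovers, default mean 2 per chromosome — a single collapsed draw
standing in for the map expansion of repeated selfing); maternal lines are
mosaics over a 3-founder pool. Founder minor-allele frequencies are
Beta(0.5, 0.5) truncated to [0.05, 0.95]. Maternal founder frequencies are
shifted on the logit scale *toward the nearer extreme* (sd 2 by default):
this single mechanism produces the two divergent parental clusters, drives
maternal minor-allele frequencies down (male-sterile pools are narrow and
heavily selected), and puts default-scale F1 heterozygosity at ~21–23%,
inside the 17.5–28.4% range reported for real two-line panels. F1 PCs then
separate paternal families first and maternal origins later, as observed in
real data.

QTLs are planted to segregate *within* every non-fixed paternal family (the
two RIL founders carry opposite alleles). A frequency drawn per family would
often align the locus with family structure, making engine power a lottery
over founder draws rather than a property of the method; within-family
segregation is also what makes a diallel informative in practice. A QTL with
`fixed_in = "maternal"` is monomorphic in mothers, and the simulator lays
down a post-sweep footprint around it (default ±150 kb): the swept group
keeps only low-frequency escape variation (8% per call). Fixing a single site
would not depress Tajima's D — the statistic responds to a rare-variant
excess across a tract, which is exactly what a real sweep leaves behind.

Phenotypes follow $\mu + \sum_q a_q x_q + d_q [x_q = 1]$ plus a polygenic
term drawn from $N(0, \sigma_g^2 K)$ (variance set so it contributes the
`h2_polygenic` fraction of total variance) and independent per-replicate
Gaussian noise. Parental phenotypes come from the same model — homozygous, so
without dominance deviations — which is what makes BPaV and MPV derivable.
One trait per call; multi-trait tables are built by repeated calls.

What the simulator does not emulate: realistic rice LD maps and recombination
hotspots, epistasis, genotype-by-environment structure beyond independent
environment draws, genotyping error, and any mutation process (so Tajima's D
levels are meaningful only in contrasts between groups, not in absolute
terms). Passing tests therefore demonstrate the machinery is correct on data
with the assumed structure, not that the assumptions hold for any particular
field dataset.

## Numerical and interface choices

* Phenotype normalization is a rank-based inverse-normal transform with the
  Blom offset, applied per derived phenotype; it is deterministic and
  monotone, achieving the Gaussian-residual goal of learned-warp approaches
  without their fitted parameters. Whether to normalize before or after
  deriving BPaV/SCA is exposed as a switch (`normalize`), defaulting to
  normalizing the derived phenotype.
* SNPP (seed number per panicle) = GYPP / (PN × TGW/1000): TGW is a
  1000-grain weight in grams, so the divisor converts it to a per-grain
  weight; without that the counts are off a thousandfold.
* Unbalanced diallels: the grand mean is the unweighted mean over observed
  cross means, matching the mean-based combining-ability formulas.
* Coordinates are 1-based; windows are half-open [start, start + W), so
  window tiling never double-counts and a QTL ending exactly at a region
  start does not overlap it.
* Tajima's D: inbred lines contribute one haplotype each; residual
  heterozygous calls are excluded per site. Sites need ≥ 4 observed
  haplotypes; windows need ≥ 3 segregating sites, else D is NA. With missing
  data, π and S use per-site sample sizes and the variance constants use the
  rounded mean per-site n (exact when data are complete). Terminal windows
  shorter than the nominal size are retained and flagged.
* KNN imputation distance is the mean absolute call difference over shared
  non-missing markers; neighbour ties break by sample order and mode ties by
  the smaller call code (deterministic). Parental heterozygous calls are
  treated as missing before imputation, since parents are declared inbred.
* All randomness flows through counter-based child seeds of one master seed,
  so any resample or stage is reproducible in isolation, and the pipeline's
  stages always consume their on-disk outputs, making first runs and resumed
  runs bit-identical.

## Problem sizes used in the tests

The bundled test and acceptance suites run the engine in a scaled mode chosen
to exercise every code path on a laptop-class budget: panels of ~300 F1s ×
2,000 markers with 50 resamples and 100 permutations, 50-seed null
calibration, 20-seed power and overdominance checks, 100 replicate d/a
recoveries at 546 F1s, and pipeline runs at 360 F1s × 600 markers.
Paper-scale settings (300 resamples, 300 permutations, ~27k markers, ~500
F1s) are configuration, not code: `pipeline_config()` defaults to them.

## Known limitations

* In the d/a regression, the 10 genomic PC covariates absorb part of the
  additive dosage contrast of a structure-aligned locus (dosage is linear in
  parental-line identity; the heterozygote indicator, a mother-by-father
  product, is much less so). The differential shrinkage inflates apparent
  |d/a| for such loci, biasing their bin toward dominance/overdominance. The
  simulator makes this visible: a planted d/a of 0.5 at a locus segregating
  across paternal lines can bin as dominance after PC adjustment while being
  recovered accurately without covariates or on the BPaV scale. Any
  PC-adjusted dominance regression in a diallel with few parental lines
  shares this behavior; interpret dominance-class tallies accordingly.
* Kinship includes the tested marker (no leave-one-chromosome-out option), so
  large QTLs aligned with family structure lose power — visible in the
  simulations as inflated $\hat h^2$ under strong planted effects. This
  mirrors the behavior of the standard single-kinship mixed model.
* The permutation null breaks polygenic structure along with marker effects;
  thresholds are therefore calibrated for exchangeable traits.
* Overdominance and pseudo-overdominance (two linked repulsion-phase QTLs)
  are not distinguishable at these marker densities, and the d/a machinery
  does not attempt to.
* The haplotype-block search is local to the lead SNP; the package does not
  produce a genome-wide block partition.
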