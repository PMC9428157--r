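---
title: "Models and methods behind plasmidfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plasmidfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidfate)
```

## The scientific setting

Manure composting is meant to turn a microbiologically risky waste stream
into fertilizer. One of the risks it must control is the conjugative spread
of multidrug-resistance plasmids from an introduced (or resident) donor
population into the indigenous community. The experimental design this
package analyzes tracks a fluorescently tagged *Pseudomonas putida* donor
(chromosomal *dsRed*) carrying a broad-host-range IncP plasmid tagged with a
repressed *gfp* cassette: *gfp* fluoresces only in recipients, so
transconjugants can be sorted by flow cytometry and profiled by 16S
amplicon sequencing, while droplet digital PCR (ddPCR) of *dsRed*, *gfp*
and 16S rRNA gives absolute marker concentrations in copies per gram dry
weight. Two composting regimes are compared: a normal thermophilic run (NT)
and a continuous run (CT) whose thermophilic phase is extended by ~15 days.

The package implements three analysis layers plus a synthetic-data
generator with recoverable ground truth.

## Decay kinetics and D-values

Marker concentrations are transformed to `lg(Ct/C0)` (`log_ratio()`) and
fitted by ordinary least squares. The decimal reduction time is
`D = |1/slope|`, the number of days per 1-log10 decrease; non-negative
slopes map to `D = Inf`. Decay during composting is biphasic: fast during
the hot phase, slow (CT) or slightly rebounding (NT) afterwards.
`fit_biphasic()` fits the two segments independently around a breakpoint,
with the breakpoint day assigned to phase I.

Two design choices deserve comment:

* **Breakpoint policy.** The default breakpoint is fixed at day 15, the
  boundary between fast and slow decay in the experimental system. An
  optional grid search minimizes the total residual sum of squares over
  candidate sampling days. Because the generating curve is *continuous* at
  the knot, the knot-day observation lies exactly on both segments, and the
  RSS criterion provably cannot distinguish the true breakpoint day from
  the sampling day immediately before it (both splits have identical
  expected RSS). The grid search therefore localizes the breakpoint to that
  adjacent pair, and the tests assert exactly that, not a unique winner.
* **Replicate handling.** Whether published decay regressions pool
  replicates or fit them separately is usually unstated. Both modes are
  provided (`fit_decay_table(per_replicate = )`); the default fits each
  replicate series and summarizes D-values as mean ± sd, which matches the
  way D-value ranges such as 6.9–7.4 days arise.

Below-detection observations are excluded from regressions rather than
substituted, to avoid inventing a detection limit.

Treatment contrasts use one-way ANOVA with Tukey HSD pairwise comparisons
(`compare_groups()`), marking 0.05 and 0.01. For alpha-diversity tables,
`compare_alpha_groups()` adds a compact letter display; Tukey HSD stands in
for Duncan's multiple range test (flagged in the output), a deliberate,
slightly conservative substitution.

## Spread potential

The spread potential summarizes plasmid dissemination as transconjugants
per recipient:

\[
SP = \frac{C_{gfp} - C_{dsRed}}{C_{16S}/k - C_{dsRed}}
\]

`C_gfp − C_dsRed` counts plasmid copies beyond the donor pool (each donor
carries one plasmid), and `C_16S/k − C_dsRed` estimates recipients, with
`k` the assumed 16S copies per cell. The divisor default is `k = 4`, the
value used in the printed formula, although the rRNA-database average is
4.1; both are supported and the package does not resolve the discrepancy —
switching between them changes SP by under 3% whenever recipients outnumber
donors a hundredfold, which the tests assert. Negative numerators (noise)
are clamped to zero with a flag; non-positive denominators are flagged
invalid. Per-treatment aggregation uses geometric means because SP spans
orders of magnitude.

## Community analysis of sorted transconjugant pools

All community statistics are implemented from their formulas so they can be
cross-checked against independent oracles (brute-force re-implementations
in the tests, and `vegan` as an external reference):

* **Alpha diversity** (`alpha_diversity()`): observed OTUs; bias-corrected
  Chao1 `S + n1(n1−1)/(2(n2+1))`; ACE with rare-abundance cutoff 10
  (falling back to Chao1 when every rare OTU is a singleton, where the
  coverage term is undefined); Shannon entropy in nats (the Mothur
  convention, consistent with published index magnitudes of ~2–3.3);
  Simpson as the dominance form Σp² (low = diverse); Good's coverage
  `1 − n1/N`. Note the bias-corrected Chao1 equals Sobs not only without
  singletons but also with exactly one.
* **Bray–Curtis** dissimilarity, and **PCoA** by classical metric scaling:
  double-center `−D²/2`, eigendecompose, scale eigenvectors by √eigenvalue.
  Negative eigenvalues (expected for Bray–Curtis) are reported raw, with no
  Lingoes/Cailliez correction, and excluded from the variance-explained
  denominator. Axis orientation is made deterministic by forcing the
  largest-magnitude coordinate of each axis positive.
* **PERMANOVA** (`permanova()`): Anderson's pseudo-F from the partition of
  squared dissimilarities, p-value by seeded label permutation with the
  `(exceedances + 1)/(B + 1)` convention, so the minimal attainable p is
  `1/(B+1)`. With few samples per group, permutations that re-create the
  observed partition tie with the observed F, which bounds the attainable
  p from below — visible at 3 + 3 samples, where that bound is ~0.1.
* **Taxonomic aggregation** labels OTUs unresolved at the target rank by
  their nearest resolved coarser rank with a prefix (`f__Bacillaceae`), so
  family-level "genera" can participate in host-range sets, matching how
  sorted-pool studies report them.
* **Host-range sets** (`host_range_summary()`): pairwise shared counts,
  per-group unique counts, the core (intersection) set, and the shared
  percentage under *both* candidate denominators (union and per-group
  size), since published "shared %" figures rarely state which one they
  used.

Rarefaction is not applied by default; a seeded `rarefy_table()` is
provided for parity with Mothur-style workflows.

## The synthetic experiment generator

The generator encodes the study conditions as defaults so that every
estimator in the package can be tested against known truth:

* **Design**: treatments NT and CT, 3 replicates, sampling days
  0, 1, 4, 7, 11, 15, 19, 27, 40. Both treatments are simulated over the
  full day grid (the real NT run ended at day 27; users can subset).
  Phases: day 0 = IP, TP through day 11 (NT) / 26 (CT), MP afterwards.
* **Decay truth**: piecewise log-linear. C0 defaults 3.30e6 (*dsRed*) and
  1.04e7 (*gfp*) copies/g DW; phase-I D-value 7.0 days; breakpoint day 15;
  NT rebounds at +0.03 log10/day after the breakpoint while CT continues
  slow decay. The 16S pool is flat at 7.264747e10 copies/g DW — total
  bacterial load is far more stable than the introduced donor. That value
  and the CT phase-II D-value of 563 days are the package's calibration of
  the two quantities the source experiment does not print: together with
  the printed C0s they put the true spread potential at 3.91e-4 on day 0
  and 2.54e-6 on day 40, the published endpoints. Remarkably, the published
  endpoint *concentrations* are almost exactly self-consistent with this
  flat-16S reconstruction.
* **ddPCR observation**: the standard Poisson occupancy model for a QX200
  style instrument — 20,000 droplets of 0.85 nL, each positive with
  probability `1 − exp(−λv)`; the estimator inverts the observed positive
  fraction. By default each measurement is auto-diluted to an expected
  occupancy of 0.3, mimicking laboratory practice of staying mid-range; a
  fixed dilution factor can be supplied instead, enabling saturation and
  below-detection behavior. The estimator's relative bias is below 2%
  across the quantifiable range (tested by Monte Carlo).
* **Replicate noise**: true concentrations get lognormal replicate-level
  jitter (`bio_sd_log10`, default 0.1 log10) before ddPCR counting, because
  droplet statistics alone would make replicate reactors unrealistically
  tight; 0.1 log reproduces per-fit D-value spreads like 6.9–7.4 days.
* **Communities**: per-group expected compositions over eight phyla with
  Firmicutes at 75–90%, a Proteobacteria rebound at maturation (4.3% → 16.8%
  in NT, 8.2% → 22.2% in CT), dominant-genus anchors (Oceanobacillus 27.41%
  in raw material, Bacillus 44.66% in CT-TP and 48.41% in NT-MP, etc.), and
  group-specific OTU support sizes encoding the richness ordering
  NT-TP > NT-MP ≈ IP > CT-MP ≈ CT-TP. Samples are Dirichlet-multinomial
  with precision 100 at 60,000 reads (the study's per-sample effective
  depth), so column sums are exactly the depth. Support sizes and the
  geometric tail (ratio 0.985) were calibrated once so that mean simulated
  richness approximates the published magnitudes under that precision.

What the generator does **not** emulate: conjugation mechanism (outcomes
are imposed, not modeled by mass action), extraction/sorting losses
(Nycodenz recovery, FACS purity), chimeras or classification error, spatial
heterogeneity within reactors, and any coupling between marker decay and
community composition. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated observation models, not that
real composting data meet those models.

## Numerical and testing choices

* All randomness flows through explicit seeds; identical configuration and
  seed give byte-identical outputs at every stage, including file writers.
* Simulation sizes in the test-suite (200 fit-recovery seeds, 1,000
  droplet-level SP simulations, 1,000 null simulations for type-I error
  calibration of ANOVA and PERMANOVA at 199 permutations, 500
  oracle-equivalence communities) were chosen to keep Monte-Carlo error
  comfortably below the asserted tolerances while running in well under a
  minute per block.
* Published quantities that depend on the deposited sequencing data
  (exact alpha-diversity values, ordination coordinates, Venn counts) are
  not desk-reproducible; for these the package asserts directional
  recovery on synthetic data — lower richness and diversity under CT,
  phase separation by PERMANOVA at the generator's effect sizes — rather
  than numeric reproduction. Two published gfp log-reduction figures (1.73
  and 1.71) cannot be recomputed exactly from the printed concentrations
  (they back out to 1.69/1.70, presumably due to per-replicate C0s); the
  package reports the values computed from the printed inputs.

## Known limitations

* The biphasic fitter estimates a fixed- or grid-searched breakpoint; it is
  not a segmented-regression estimator with a continuity constraint, and it
  reports no confidence interval for the breakpoint.
* PERMANOVA is one-factor only (group labels), without strata or
  interactions.
* The ddPCR model ignores droplet-volume variation, rain (partial
  amplification), and multi-well merging.
* Duncan's test is approximated by Tukey HSD, which is more conservative;
  letter displays may merge groups Duncan would separate.
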