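---
title: "Inferring the demographic origin of a weedy population from STS panels"
author: "stsDemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the demographic origin of a weedy population from STS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conspecific agricultural weeds — weedy rice being the canonical case —
arise inside the same interfertile species complex as a crop and its wild
relatives.  Given multi-locus haplotype data from a weedy population and a
candidate progenitor (cultivated or wild), three questions recur: how much
of the progenitor's diversity does the weed carry, when did the two
lineages diverge, and how severe was the founding bottleneck?  This
package implements a complete, testable pipeline for those questions on
sequence-tagged-site (STS) panels: a few dozen unlinked, PCR-amplified
fragments of roughly 400-900 bp, sequenced as one haplotype per individual
in a highly selfing species.

## The founder-bottleneck model

`DemographicModel` parameterises the history sketched below (backwards in
time from the present, population 0 = weed, population 1 = progenitor):

* the progenitor evolves at constant effective size `etaC`;
* the weed founder lineage (size `etaP`, constrained equal to `etaC`)
  splits from the progenitor `tauS` years before present;
* at `tauF` the founder lineages arrive in the new range and pass through
  a bottleneck of size `etaB`;
* the weed recovers instantaneously to its current size `etaR` at `tauG`.

All sizes are effective numbers of individuals, all times years before
present, with `tauS >= tauF >= tauG >= 0`.  Size changes are
instantaneous; there is no post-split migration and no growth curve.
Weedy and cultivated rice are effectively complete selfers, which halves
the effective size of a lineage relative to an outcrossing diploid of the
same census size.  With `weedSelfing = TRUE` (default) every weed-lineage
size (`etaR`, `etaB`, `etaP`) is multiplied by 0.5 in coalescent units —
equivalent to scaling weed timing by 2N rather than 4N — while the
progenitor is left unscaled.  The simulator does not additionally suppress
effective recombination in the selfing lineage; that is a known
simplification (full selfing would also shrink the effective
recombination rate), documented here rather than silently approximated.

## Units and scaling

Everything is conditioned on the population mutation rate.  The reference
size is derived from a reference silent-site diversity via
`deriveReference4N()`: with the default Watterson's theta of 7.787 per kb
(the observed silent-site mean of the wild relative *O. rufipogon*, whose
frequency spectrum is consistent with constant size) and a neutral
mutation rate of 1e-8 per site per generation,

```{r}
deriveReference4N(7.787, mu = 1e-8)$nRef  # ~194,675
```

Simulation uses MS conventions: time in units of `4 * nRef` generations,
sizes relative to `nRef`, and per-locus `theta = 4 * nRef * mu * L`.  The
population recombination rate is set equal to theta (`rhoOverTheta = 1`)
by default.  Generation time defaults to one year (annual field
populations), making the years-to-coalescent conversion
`t = years / (4 * nRef)`.

One wording ambiguity deserves note: the progenitor size prior is
expressed as a ratio "to the reference population size" in the source
analyses, with bounds 0.1-0.7 justified by observed crop-to-wild
silent-diversity ratios.  Because diversity ratios estimate ratios of
effective sizes on the same scale, the package reads the prior as
`etaC / nRef` in `[0.1, 0.7]`; the literal reading (a ratio to `4 * nRef`)
would make every crop larger than its wild ancestor, contradicting the
stated justification.

## Statistics and their aggregation conventions

All statistics operate on an `SNPMatrix` (a `SummarizedExperiment` of
biallelic haploid sites).  `buildSNPMatrix()` applies the panel filtering
rules: alignment columns overlapping an indel are removed entirely
(including from the per-kb length denominators); columns with more than
two allele states *among the targeted groups* are excluded, so third
alleles contributed only by outgroups never remove a site; the major
allele among targeted samples is coded 0, with an alphabetical tie-break
at 50/50 (no polarity convention is standard for such panels, so the rule
is fixed and documented).  Rare heterozygous base calls (IUPAC codes) are
treated as missing in the haploid matrix; a per-sample "first/random
allele" collapse was considered and rejected because the panels carry one
sequenced haplotype per individual to begin with.

* **theta_W, theta_pi** (`wattersonTheta`, `piTheta`): per locus, per kb
  of the requested site class, then averaged over loci.  With missing
  data, each site uses its own effective sample size, both in the
  harmonic-number weight `1/a(n-1)` and in pairwise denominators —
  standard practice that avoids bias from partially sequenced samples.
  `"silent"` pools noncoding and synonymous columns.
* **Tajima's D** (`tajimasD`): the 1989 statistic computed per locus from
  S and the summed pairwise differences, averaged over loci with at least
  one segregating site; undefined (NA) otherwise.
* **Site partitions** (`sitePartition`): shared polymorphisms, private
  polymorphisms and fixed differences, with a parallel count excluding
  singletons (minor allele seen exactly once in the pooled
  two-population sample).
* **F_st** (`weirCockerhamFst`): the haploid two-population
  Weir-Cockerham estimator per SNP, with three conventions applied in
  this order: union-sample singleton SNPs are dropped; negative per-SNP
  values are set to zero; the per-locus value is the mean over retained
  SNPs, and the grand mean and median over loci count non-polymorphic or
  empty loci as zeros.  Note the zero-clamping gives the grand mean a
  positive O(1/n) bias under panmixia; the package's panmixia test uses
  30 + 30 haplotypes, where the bias (~0.015) is within its 0.02 band.
* **The ABC summary vector** (`abcSummaryVector`): eight statistics
  pooled over all loci — pairwise diversity of the combined sample per
  kb; segregating sites in the weed and in the progenitor; fixed,
  private-to-weed, private-to-progenitor and shared sites; and a
  configurable eighth slot.  The source text enumerates seven
  quantities under the heading of eight; the package defaults the eighth
  to segregating sites in the union sample (a natural completion that is
  highly informative about `etaC`) and exposes
  `eighth = "wattersonPooled"` as the alternative.  Statistics default to
  all site classes (the pooled observed data are not class-restricted);
  a silent-only switch is available via `siteClass = "silent"`.

## The coalescent simulator

`simulateLocus()`/`simulateDataset()` drive a compiled Hudson-style
ancestral recombination graph (src/coalescent.cpp).  Lineages carry
ordered ancestral-segment lists; coalescences merge overlapping segments
(recording child-parent edges with their genomic interval and time span),
segments that reach the full sample count are dropped (local MRCA), and
recombination splits a lineage at a uniform breakpoint within its
ancestral span, at rate `rho * span`.  In these units a lineage pair in a
population of relative size `x` coalesces at rate `2/x` and mutations
fall on edges as a Poisson process with intensity `theta` per unit of
branch area, giving the textbook `E[S] = theta * a(n-1)` and
`E[pi] = theta`.  Mutations follow the infinite-sites model on the
continuous unit interval; when a dataset is rendered to FASTA
(`renderAlignments`), positions map to distinct integer columns
(collisions resolved by redraw, implemented as sampling without
replacement) on a random ancestral sequence.

Randomness: every entry point takes an explicit seed; per-locus streams
are derived from (seed, locus index) with a splitmix64 hash, so changing
the locus count never reshuffles earlier loci, and the same seed
reproduces a dataset byte-for-byte — including through the fast
statistics-only path used by the ABC engine, which the test suite holds
to exact equality against the R statistics layer.

Simulated mutations are labelled noncoding/synonymous/nonsynonymous with
default proportions 0.5/0.125/0.375 (half of an STS fragment noncoding;
coding sites roughly 1:3 synonymous:nonsynonymous under the standard
code).  The labels partition sites for class-restricted statistics and
carry no selective effect — the simulator is strictly neutral, so
class-specific diversity differences in real data (e.g. reduced
nonsynonymous variation) are *not* emulated.

## Rejection ABC over divergence scenarios

Four scenarios differ only in the rule for the split time: divergence at
introduction (`tauS = tauF`), after domestication
(`tauF < tauS <= 12,000`), at domestication (`tauS = 12,000`), or before
domestication (`12,000 <= tauS <= 50,000`).  Shared priors: expansion
time `tauG` in (0, 140] years — the upper bound encodes the onset of
rapid expansion of cultivation around 1870 against a circa-2010 sampling
date and is configurable; founding time `tauF` in (`tauG`, 400];
progenitor relative size in [0.1, 0.7]; and the ratios `etaR/etaC` and
`etaB/etaR` uniform on (0, 1], with sizes floored at one individual.
Timing parameters and the progenitor size are discretised on a grid
(default 7 points per parameter, endpoints included; tuples violating the
time ordering are excluded and counted), cycled evenly across
simulations; the exact grid of the original analyses is not public, so
resolution is configuration, not a fact.

Acceptance uses Euclidean distance on statistics standardised by a robust
scale computed once from the pooled simulations of *all* scenarios (the
pilot pool), so that acceptance proportions are directly comparable
across scenarios — the per-scenario acceptance proportion is the
approximate likelihood, and proportions are deliberately *not* forced
equal by per-scenario quantile tolerances.  The scale is the MAD, falling
back to the standard deviation (then 1, with a warning) for count
statistics whose pilot MAD collapses to zero.  The default tolerance of
1.0 standardised unit was fixed once from a pilot study on synthetic
panels: it yields acceptance proportions of order 0.1-2% at the default
panel size (matching the magnitude of published scenario likelihoods) and
recovered the generating scenario in 20/20 pseudo-observed datasets per
condition at 10,000 simulations per scenario.  Surface mapping
(`likelihoodSurface`) benefits from more acceptances than scenario
choice; the packaged experiments use tolerance 1.25 with 20,000
simulations and a coarse 5 x 4 binning, under which the surface mode for
a planted 99% decline was stable across pilot seeds.  Reference tables
(`scenarioReferenceTable`) may be reused across observed datasets —
standard for rejection ABC with a fixed prior — which is how the
recovery experiments stay within desk-scale budgets.

Approximate likelihoods are acceptance counts over simulation counts and
need not sum to one across scenarios.  Marginal posterior densities
(`posteriorDensity`) are histogram densities of accepted draws with the
prior marginal overlaid; the bottleneck-intensity surface maps accepted
draws over current-weed-size ratio and percent decline
`100 * (1 - etaB/etaR)`.  The recovery experiments also exposed a genuine
identifiability ridge: a draw with a very small *current* weed size
mimics a severe bottleneck, so single accepted draws can sit at low
nominal intensity; the mode of the surface, not individual draws, is the
supported summary.

## Synthetic data and what passing tests show

`makePseudoObserved()` provides two presets, labelled illustrative rather
than estimates: `"SH-shaped"` (straw-hull-like: divergence at founding
300 ybp, progenitor at 0.285 of the reference size, current weed a tenth
of the progenitor, 99% founding decline, expansion 100 ybp) and
`"BHA1-shaped"` (black-hull-awned-like: split 7,000 ybp, progenitor at
0.18, milder 70% decline).  They encode the qualitative structure the
pipeline must resolve — the weed holding a nested subset of progenitor
diversity, with bottleneck severity and divergence age differing between
presets.  `makeToyAlignment()` plants exact site-partition counts;
`makeCytotypePanel()` draws cytoplasm-marker panels from specified
cytotype frequencies (the published frequency table ships as
`weedyCytotypeFrequencies()`, rows renormalised from their two-decimal
rounding).

The generators share every assumption of the simulator: neutrality,
unlinked loci, no migration, no gene conversion, no sequencing error, no
alignment artefacts, complete data.  Passing tests therefore demonstrate
the *inference machinery* is correct and well calibrated under the
model; they cannot show that real panels satisfy the model.

## Problem sizes and numerical choices

Default experiment sizes (chosen as desk-scale analyses a single CPU
completes in minutes): simulator calibration uses 2,000 replicate
500-bp loci at n = 10; statistic oracles run 500 random matrices at
1e-12; scenario recovery uses 20 pseudo-observed datasets per condition
against shared 10,000-simulation reference tables; the bottleneck
signature uses 100 replicate 48-locus panels and a 20,000-simulation
surface.  Production-scale runs (hundreds of thousands of simulations
per scenario, as in the original analyses) use the same code paths with
larger `simsPerScenario`.

Other numerical choices: per-locus seeds below 2^53 (exact in doubles);
ties in most-frequent-haplotype selection broken by the
lexicographically smallest sequence; degenerate inputs (monomorphic
panels, empty populations, zero acceptances) return flagged empties or
typed errors (`stsDemog_config_error`, `stsDemog_data_error`) rather
than silent zeros; the ARG event loop carries an iteration cap so that
isolated-population misconfigurations fail loudly instead of hanging.

## Known limitations

No migration after the split (isolation-only), no gene conversion, no
selection, two populations only, instantaneous size changes only.
Selfing is a 0.5 size multiplier on the weed lineage, not a full
selfing-rate model.  Tajima's D uses the population sample size rather
than a per-site effective size, so heavy missingness biases it slightly.
F_st is the two-population haploid estimator; multi-population panels
must be analysed pairwise.
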