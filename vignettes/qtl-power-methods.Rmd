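---
title: "Methods: simulating QTL mapping power in eight-founder RI panels"
author: "ccpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating QTL mapping power in eight-founder RI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccpower)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what its tests do and do not
establish about real data.

## The phenotype model

A single QTL acts at a causal locus through the design

$$X = D\,A\,M,$$

where $D$ (strains × 36) is the hard-called diplotype incidence at the
locus, $A$ (36 × 8) maps each diplotype to founder haplotype dosages (the
homozygote $kk$ is two doses of founder $k$; a heterozygote one dose of
each parent), and $M$ (8 × $m$) is the merge matrix of the allelic series,
a set partition of the founders into $m$ functional alleles.  Strain means
are generated as

$$\bar y = \mu + X\beta + u + \bar\varepsilon, \qquad \mu = 0,$$

with polygenic strain effects $u$ and mean residuals $\bar\varepsilon$.
Replicates never need to be simulated individually: mapping on strain
means with $r$ replicates is identical to a single-observation experiment
with residual variance $\sigma^2/r$, so the generator works at the
strain-mean level throughout.  This is mathematically equivalent for
every analysis in scope and substantially faster.

**Exact variance decomposition.**  All random effects are *rescaled*,
not merely drawn, so that population variances (denominator $N$) match
the configured fractions exactly per draw: $\mathrm{pvar}(u) =
h^2_{strain}$, $\mathrm{pvar}(\bar\varepsilon) = \sigma^2/r$, and the
QTL term per its effect-size definition.  The fractions must sum to
exactly 1.  This makes simulations noiseless in their *settings* (a "40%
QTL" explains exactly 40% under Definition DAMB) and lets tests assert
the decomposition to machine precision rather than in expectation.

**Effect-size definitions.**  Raw allele effects are standard normal,
then scaled so that:

* **B** — $\mathrm{pvar}(2\beta) = h^2_{QTL}$: the variance explained in
  a theoretical population balanced in the functional alleles.  Allele
  values are constant across populations, so imbalanced series (e.g. a
  variant private to one wild-derived founder, `7v1`) explain less
  variance in the realized sample and are harder to detect.
* **MB** — $\mathrm{pvar}(2M\beta) = h^2_{QTL}$: balanced founder
  contributions; exposed for completeness, not used in default grids.
* **DAMB** — $\mathrm{pvar}(X\beta) = h^2_{QTL}$: the realized variance
  explained in the sampled strains (an $R^2$).  At a locus monomorphic in
  the sampled strains this is undefined; the scaler signals a typed
  degenerate-locus condition and the driver resamples the experiment,
  keeping a count (reported as `n_degenerate_resampled`).

Whether the original effect scaling under DAMB used hard-called or
probabilistic diplotypes is not something we could pin down externally;
we scale on the hard-called design, which matches the simulation truth
being hard calls, and note the soft alternative would differ only at
loci with genuine inference uncertainty.

## Mapping and thresholds

Mapping is Haley–Knott regression of strain means on the intercept plus
the eight *probabilistic* dosages $PA$ — an eight-allele model regardless
of the simulated series, mirroring practice where the series is unknown.
Simulation truth uses hard calls $D$; mapping uses soft $P$.  The F-test
against the intercept-only null is reported as logP.  Numerical
conventions: the dosage columns always alias the intercept (they sum
to 2), and founders absent from the sampled strains alias further, so the
design rank is determined by a pivoted QR and the numerator degrees of
freedom are `rank − 1`; a constant phenotype yields logP 0 (p = 1
convention); p-values below 1e-300 are capped at logP 300; logP is
computed on the log scale (`pf(..., log.p = TRUE)`), so it is exact well
past ordinary underflow.

**Permutation thresholds.**  Strain means are permuted (the panel is
treated as exchangeable), each permutation's genome-wide maximum logP is
recorded, a generalized extreme value distribution is fitted to the
maxima by maximum likelihood (Nelder–Mead from Gumbel moment starts —
written in-package, with the Gumbel special case handled analytically),
and the threshold is the fitted upper-$\alpha$ quantile.  If the fit
fails to converge the empirical $1-\alpha$ quantile is used and flagged.
Because the per-locus decomposition does not depend on the phenotype, one
QR per locus serves all permutation columns through a single matrix
product; the batched scan is bit-equivalent (to 1e-10) to scanning each
permutation independently, and the suite asserts this.

## Detection rules and summaries

A true positive is a significant locus within ±5 Mb of the simulated
QTL (distance taken between locus midpoints on the scan map); a false
positive is any significant locus on another chromosome; simulations
whose only on-chromosome signal falls outside the window are disregarded
and count toward neither numerator (which loses their off-chromosome
false positives and so biases FPR slightly downward — the accounting is
deliberate and documented in `classify_detection()`).  Power and FPR are
proportions over *all* simulations, with Jeffreys intervals
(boundary-adjusted so the interval always contains the point estimate).

Location error is regularized toward the behaviour of an arbitrarily
weak but detected QTL — peak uniform in the window, hence mean 2.5 Mb
and 95% quantile 4.75 Mb — using pseudo-observations numbering 1% of the
simulations (minimum 1; 10 at the reference 1,000 simulations).  The 95%
quantile is computed on the pseudo-augmented sample; the wording
"weighted averages and prior pseudo-observations" admits either a
weighted-quantile or an augmentation reading, and augmentation is the
one pinned here.

## Genome representation and reduction

Genomes are tables of 36-state diplotype probabilities per strain and
locus, in the fixed order homozygotes `AA..HH` then heterozygote pairs
`AB..GH`, validated to sum to 1 within 1e-6.  Adjacent loci whose
probability vectors lie within an L2 distance of `0.1 × 2 = 0.2` for
every strain are averaged.  Two open points are worth stating: the
geometric maximum L2 distance between unit-sum probability vectors is
$\sqrt 2$, not 2, but the absolute threshold 0.2 follows the established
convention for this reduction; and run semantics are not uniquely
determined by "adjacent intervals were averaged", so the package pins a
greedy left-to-right run accumulation against the running mean (with a
plain adjacent-pair policy as an option) — greedy accumulation is
order-deterministic and idempotent on blocky mosaic genomes, which the
suite checks.

Kinship is pinned as $K_{ij} = L^{-1}\sum_l \langle f_{il},
f_{jl}\rangle$ on haplotype-probability shares $f = \text{dosage}/2$, so
identical inbred genomes have similarity 1 and founder-disjoint genomes
0.  Published variants of this realized-relationship calculation differ
in normalization; with this one, diagnostics based on eigenvalue
concentration (`pcs_for_variance()`) behave as expected on structured
vs. balanced matrices, but counts on realized CC data may shift slightly
under other normalizations.

## The synthetic-genome generator

`simulate_ri_panel()` emulates what the pipeline needs from CC-like
genomes and nothing more: per strain and chromosome a first-order Markov
chain over founder labels with switch probability `spacing /
block_length` yields geometric haplotype blocks; blocks are homozygous
(residual heterozygosity optional, default 0); one-hot states may be
softened by smearing a fixed mass fraction uniformly over the other 35
states (default 0; 0.05 mimics confident HMM output with ≥ 0.95 on
truth).  The smearing is deterministic given the mosaic rather than a
Dirichlet draw — it satisfies the same contract, keeps cache round-trips
exact, and adds no RNG stream.

Defaults, chosen once as a desk-scale stand-in: 20 chromosomes ("1"–"19"
plus an "X" treated identically to an autosome, as appropriate for an
all-female design) of 90 Mb at 1 Mb spacing (~1,800 loci), expected
block length 15 Mb, i.e. roughly six recombination blocks per
chromosome, in the range seen in realized CC mosaics.

What it does *not* emulate: realized CC founder imbalance (reduced
wild-derived contributions), breeding-funnel relatedness, inference
uncertainty that varies along the genome, or marker-density
heterogeneity.  Consequently, passing tests demonstrate the method's
internal correctness and calibration under exchangeability — not that
power numbers transfer quantitatively to the realized CC, where founder
imbalance lowers power for private-allele QTL and mild structure
inflates the FPR when strain effects dominate.  Experiments on realized
panels should load the corresponding probability cache instead.

## Experiment drivers and problem sizes

`run_power_grid()` crosses settings, and per simulation samples strains,
causal locus and series uniformly, so estimates average over these
sources of variation; per-simulation seeds are `base + counter`, making
any single simulation independently reproducible.
`structured_null_experiment()` keeps the mapping protocol unchanged
while drawing $u \sim N(0, K h^2_{strain})$; with a panel containing a
duplicated cousin pair and fully heritable strain effects the FPR
inflates well above the nominal 0.05, and returns to nominal when $K$ is
the identity or the strain effect vanishes.  `beavis_experiment()`
conditions on detection and reports mean peak-$R^2$ / simulated-$h^2$
ratios; inflation shrinks with more strains or larger effects and
vanishes in the noiseless limit.

The shipped test and acceptance runs use a 50-strain, ~1,800-locus
synthetic panel with 100 permutations per simulation and 300–500
simulations per condition — sizes at which the batched scan keeps a full
condition under a couple of minutes on one core while binomial
Monte-Carlo error on a 5% rate is about ±2.5 percentage points at the
99% level.  Full-scale runs (1,000 simulations per setting over the
complete strain/effect grids, `default_settings()`) use the identical
code path.

One empirical subtlety surfaced by the package's own checks: under
Definition DAMB the signal logP at the causal locus is
distribution-identical across balance classes, but heavily imbalanced
series produce skewed phenotypes whose permutation maxima — and hence
thresholds — run slightly higher, so DAMB power is constant across
series only to good approximation, not exactly.  The acceptance check
treats equality at the 1% significance level accordingly.

## Known limitations

No epistasis, dominance, covariates, batch effects, or variance
heterogeneity; no linear-mixed-model mapping (the fixed-effect scan is
what makes the permutation batching exact — mixed-model scans belong to
dedicated mapping packages); no HMM inference of mosaics from genotypes;
no genome-build liftover.  The X chromosome is treated as an autosome
throughout.
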