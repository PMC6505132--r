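# ccpower

Simulation-based QTL mapping power analysis for eight-founder recombinant
inbred panels such as the Collaborative Cross (CC).

## The problem

The CC is a panel of recombinant inbred mouse strains whose genomes are
fixed mosaics of eight founder haplotypes (labelled A–H).  Designing a QTL
mapping study in such a panel means choosing how many strains to phenotype,
how many replicates per strain, and judging what effect sizes are
detectable — all of which depend on the genetic architecture of the QTL,
in particular its *allelic series*: the way the eight founder haplotypes
collapse into `m ≤ 8` functionally distinct alleles.  `ccpower` estimates
mapping power by simulating the whole experiment — genomes, phenotypes,
genome scans, significance thresholds, detection calls — and is aimed at
researchers planning haplotype-based association studies in multiparental
panels.

## The model

Phenotypes are generated from the linear model

    y = 1 mu + Z X beta + Z u + e,        X = D A M

where `D` is the strain-by-36 diplotype incidence at the causal locus, `A`
the 36×8 additive matrix mapping diplotypes to haplotype dosages, and `M`
the 8×`m` merge matrix encoding the allelic series.  Variance fractions
`h2_qtl` (QTL), `h2_strain` (polygenic strain effects) and `sigma2`
(noise) sum to 1, and all effects are rescaled to population variances so
the realized decomposition is exact per draw.  Allele effects `beta` can
be scaled so `h2_qtl` is the variance explained in a population balanced
in the alleles (**Definition B**), balanced in the founders (**MB**), or
in the realized mapping sample (**DAMB**, essentially an R²).

Mapping is Haley–Knott regression of strain means on the probabilistic
founder haplotype dosages `P A` (an eight-allele model, since the true
series is unknown in practice), with an F-test against the intercept-only
null reported as logP = −log10(p).  Genome-wide thresholds come from 100
permutations of the strain means, whose per-scan maxima are smoothed by a
maximum-likelihood generalized extreme value (GEV) fit; the upper-`alpha`
quantile is the significance threshold.  A detection within ±5 Mb of the
simulated QTL is a true positive; any significant locus on another
chromosome is a false positive.  Replicates act through the strain-mean
noise `sigma2 / r`, giving the equivalence
`h2_eff = h2_qtl / (h2_qtl + h2_strain + sigma2 / r)`.

A synthetic-genome generator (`simulate_ri_panel()`) produces CC-like
founder mosaics so the entire pipeline runs without downloading realized
CC data; realized founder-probability caches in the same per-chromosome
layout load with `load_genome_cache()`.

## Worked example

```r
library(ccpower)

# a 50-strain CC-like panel: 20 chromosomes x 90 Mb, 1 Mb marker spacing
tab <- simulate_ri_panel(synthetic_genome_config(n_strains = 50, seed = 101))
#> founder_prob_table: 50 strains x 1800 loci on 20 chromosome(s)

# one simulated experiment: bi-allelic QTL, 60% effect size (Definition B)
exper <- sample_experiment(tab, n_strains = 50, m_alleles = 2, seed = 42)
exper$series
#> allelic_series: 12211212 (2 alleles, 4v4)

spec <- qtl_sim_spec(exper$locus, exper$series,
                     variance_config(h2_qtl = 0.6), "B", seed = 42)
phe  <- simulate_phenotypes(spec, tab)

scan <- scan_genome(phe$ybar, tab)
scan
#> cc_scan: 1800 loci, max logP 6.83 at c7_0021 (chr 7)

thr <- permutation_thresholds(phe$ybar, tab, n_perm = 100, seed = 42)
thr
#> cc_threshold: logP >= 4.245 at alpha = 0.05 (gev, 100 permutations)

classify_detection(scan, thr, exper$locus)$label
#> [1] "true_positive"
```

The scan peak (logP 6.83) falls exactly at the simulated locus `c7_0021`
and clears the permutation threshold of 4.25, so this simulation counts as
a true positive with zero location error.  Power over many such draws:

```r
grid <- data.frame(n_strains = 50, h2_qtl = c(0.2, 0.4),
                   m_alleles = 2, definition = "B")
res <- run_power_grid(tab, grid, n_sims = 40, n_perm = 100, seed = 1)
res$summary[, c("h2_qtl", "power", "power_lo", "power_hi", "fpr", "mean_loc_err_Mb")]
#>   h2_qtl power power_lo power_hi  fpr mean_loc_err_Mb
#> 1    0.2 0.000    0.000   0.0605 0.05           2.500
#> 2    0.4 0.275    0.156   0.4255 0.05           0.958
```

A 20% bi-allelic QTL is essentially undetectable with single observations
of 50 strains, while a 40% QTL is found about a quarter of the time; the
false positive rate stays at the nominal 0.05, and detected 40% QTL
localise well (regularized mean location error ~1 Mb; with no detections
the estimate falls back to the 2.5 Mb prior).  Increase `n_sims` (the
full-scale protocol uses 1,000 per setting, see `default_settings()`) for
publication-quality estimates.

Related entry points: `structured_null_experiment()` (false positive
inflation under population structure, using `compute_kinship()`),
`beavis_experiment()` (winner's-curse inflation of effect-size estimates),
`reduce_adjacent_loci()` (scan-grid reduction), and `run_from_config()` /
`inst/cli/ccpower` for config-driven runs.

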