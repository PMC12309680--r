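# tempogen

Temporal population genomics of two interbreeding ecotypes, as a tested R
package. The motivating setting is a century-long archive of a migratory
marine fish sampled at its spawning ground (1907–2014) alongside its
nonmigratory coastal ecotype: the two forms are nearly indistinguishable
across most of the genome but are separated by a handful of chromosomal
inversions that behave as supergenes, and the scientific questions are
whether allele frequencies have shifted more than drift allows, whether
coastal ancestry has been introgressing into the migratory population, and
whether inversion karyotype frequencies have moved over time.

tempogen implements the full analysis chain plus the simulator needed to
test it against a known truth:

* **`simulate_cohorts()`** — forward Wright–Fisher simulation of a migratory
  and a coastal population with time-varying gene flow, inversion supergenes
  (a Mendelian arrangement locus plus tag-SNP blocks), optional
  karyotype-dependent viability selection, plan-II temporal sampling, and
  era-specific missingness (`inject_missingness()`); outputs VCF, metadata
  TSV, truth tables and BED (`write_sim_outputs()`).
* **`read_vcf()` / `filter_sites()` / `ld_prune()` / `exclude_regions()`** —
  genotype IO and construction of the "neutral" LD-pruned,
  inversion-excluded dataset.
* **`run_pca()` / `call_karyotypes()` / `het_fraction()`** — genotype PCA
  and three-cluster inversion karyotyping, validated by plotting PC1 against
  the heterozygous-site fraction.
* **`fs_prime()` / `estimate_ne()`** — the temporal allele-frequency-shift
  statistic `Fs = Σ(x−y)² / Σ z(1−z)` (ratio of sums over loci,
  `z = (x+y)/2`), corrected for sampling noise under plan II, with
  delete-one-locus jackknife CIs and `Ne = t/(2 Fs')` (infinity when
  `Fs' ≤ 0`). Calibrated so that `E(Fs') = t/(2Ne)` under pure drift.
* **`site_fst()` / `window_fst()` / `permutation_q()` / `afd()` /
  `shared_outliers()`** — Weir–Cockerham variance components, weighted
  30-kb/15-kb windowed FST `Σa/Σ(a+b+c)`, label-permutation p-values with
  per-chromosome Benjamini–Hochberg q-values, allele-frequency-difference
  outliers at the 99.9th quantile, and outlier intersection across year
  pairs.
* **`tajimas_d_windows()` / `pi_windows()` / `region_contrast()`** —
  genotype-based Tajima's D (30-kb windows) and nucleotide diversity π
  (50-kb windows), with inside-vs-outside-inversion contrasts.
* **`hwe_chisq()` / `fisher_years()` / `hb_diplotype()` /
  `kruskal_dunn()`** — genotype-frequency trajectory tests: HWE χ²,
  Fisher exact across years with Bonferroni-adjusted pairwise tests and a
  compact letter display, two-SNP hemoglobin diplotype classes, and
  tie-corrected Kruskal–Wallis with Dunn post hocs.
* **`panel_freqs()` / `fit_q()` / `cohort_summary()`** — supervised
  ancestry proportions by binomial-mixture EM against reference panels,
  aggregated into 3-year birth cohorts and tested across cohorts.
* **`pipeline_config()` / `run_pipeline()`** — the end-to-end workflow with
  stage caching, derived seeds and a JSON manifest; reruns are
  byte-identical under the same seed.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` figures (PCA, karyotype validation, Fs' per year
pair, cohort ancestry).

## Worked example

Simulate a small two-ecotype world with one inversion, build the neutral
dataset, estimate temporal shifts, and karyotype the inversion:

```r
library(tempogen)

cfg <- sim_config(
  n_neutral_snps = 2000, n_chromosomes = 4, chromosome_length_bp = 1e6,
  inversions = list(inversion_spec("inv_LG01", "LG01", 2.5e5, 6.5e5,
                                   n_block_snps = 120,
                                   init_freq_migratory = 0.9,
                                   init_freq_coastal = 0.15)),
  sampling = data.frame(
    year = c(1907, 1975, 2014, 2014),
    population = c("migratory", "migratory", "migratory", "coastal"),
    n = c(25, 25, 25, 25)),
  seed = 42)
sim <- simulate_cohorts(cfg)
sim
#> <cohort_sim> 100 samples, 1926 sites, 1 inversions, years 1907/1975/2014

neutral <- ld_prune(exclude_regions(sim$geno, inversion_regions(cfg)))
fs <- fs_prime_pairs(neutral, sim$samples, "NEAC", generation_time_years = 8)
dplyr::select(fs, year0, year1, fs_prime, ci_low, ci_high, ne_estimate)
#> # A tibble: 3 × 6
#>   year0 year1 fs_prime    ci_low ci_high ne_estimate
#>   <int> <int>    <dbl>     <dbl>   <dbl>       <dbl>
#> 1  1907  1975  0.00483 0.00150   0.00816        828.
#> 2  1907  2014  0.00916 0.00563   0.0127         709.
#> 3  1975  2014  0.00333 0.0000835 0.00657        752.
```

Every pair's corrected shift is positive with a CI above zero — more change
than pure sampling noise, as expected here: the default migration schedule
leaks coastal alleles into the migratory pool, so the drift-only reading of
`Ne = t/(2 Fs')` (700–830 diploids against a census of 1,000) understates
the true effective size. In a no-migration world `fs_prime` centres on
`t/(2Ne)` exactly (this is the package's binding calibration test), and
identical samples give `fs_prime < 0` with `ne_estimate = Inf`.

```r
calls <- call_karyotypes(sim$geno, inversion_regions(cfg))
genotype_freq_table(calls, dplyr::filter(sim$samples, population == "NEAC"))
#> # A tibble: 9 × 4
#>   group class         n  freq
#>   <int> <chr>     <int> <dbl>
#> 1  1907 ANCESTRAL     1  0.04
#> 2  1907 DERIVED      16  0.64
#> 3  1907 HET           8  0.32
#> 4  1975 ANCESTRAL     2  0.08
#> 5  1975 DERIVED      16  0.64
#> 6  1975 HET           7  0.28
#> 7  2014 ANCESTRAL     1  0.04
#> 8  2014 DERIVED      16  0.64
#> 9  2014 HET           8  0.32
```

The migratory samples are dominated by the DERIVED homokaryotype, the calls
agree 100% with the simulator's truth table in this run, and
`fisher_years()` puts all three years in one letter group (overall p = 1) —
no trajectory shift at this scale and sample size. `autoplot(calls)` draws
the PC1-vs-heterozygosity validation panel.

The whole workflow, end to end with caching and a manifest:

```r
run_pipeline(pipeline_config(seed = 1), "demo_run")
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
the full demonstration pipeline (two populations, 5,000 neutral SNPs, four
inversions, seven sampling years: simulate → filter/prune → PCA →
karyotype → Fs' → FST scan → diversity → genotype tests → ancestry) — and
writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The accompanying property checks (drift calibration of Fs', karyotype
recovery, statistic oracles, null calibration, ancestry recovery, the
selection trajectory, and byte-identical pipeline reruns) live in
`tests/testthat/test-acceptance.R`.
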