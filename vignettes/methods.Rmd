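---
title: "Models and methods in tempogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tempogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempogen)
```

tempogen is a pipeline for century-scale temporal population genomics of two
partially diverged, interbreeding ecotypes — a migratory population sampled
repeatedly at its spawning ground over ~100 years, and a nonmigratory coastal
population that hybridizes with it. This vignette is the package's account of
its models: what each stage assumes, which tunable parameters matter, what
the built-in simulator does and does not emulate, and where a genuinely open
design choice was resolved one way rather than another.

## The simulator: a stated world, not a dial

`simulate_cohorts()` implements a two-population Wright–Fisher model at the
allele-frequency level:

* **Background differentiation.** Each neutral SNP draws one ancestral
  frequency from Beta(0.8, 0.8), then each population drifts independently
  for `burn_in_generations` (default 40) before the calendar timeline starts.
  At the default census sizes (1,000 migratory, 500 coastal diploids) this
  yields the weak genome-wide differentiation characteristic of the two
  ecotypes — most of the signal separating them lives in the inversions, not
  the genomic background.
* **Per-generation update.** Migration is applied as deterministic mixing of
  gene pools (`p_mig' = (1 - m) p_mig + m p_coast`), then viability
  selection (inversions only), then binomial resampling of `2N` allele
  copies. Generation `g` maps to calendar year
  `year_start + g * generation_time_years` with rounding; the default
  generation time is 8 years, a standard figure for a long-lived demersal
  fish. It is deliberately exposed as a parameter because the temporal
  estimator consumes *generations*, while samples are dated in *years*, and
  the conversion materially changes the Ne scale.
* **Inversions.** Each inversion is one Mendelian biallelic locus
  (ANCESTRAL vs DERIVED arrangement) transmitted without recombination, plus
  a block of tag SNPs whose alleles follow the arrangement on their
  haplotype with probability `tag_fidelity` (default 0.98; 1 minus the
  gene-flux error). The four default inversions mirror the canonical
  ecotype-discriminating architecture: migratory fish nearly fixed for the
  DERIVED arrangement on LG01 and LG07 and for ANCESTRAL on LG02 and LG12,
  the coastal population the reverse.
* **Sampling (plan II).** Sampled fish are caught at their catch year before
  reproducing and never contribute to later generations. Individuals are
  instantiated only when sampled: genotypes are drawn from Hardy–Weinberg
  proportions at the frequencies of their birth generation (catch year minus
  an age drawn from a truncated geometric on 4–14 years, decay 0.25 — a
  plausible spawning-age distribution; the real stock's otolith age
  structure is not reproduced). True coastal-ancestry fractions are tracked
  through a short explicit pedigree: each parent is an immigrant with that
  generation's migration rate, and a child's ancestry is the mean of its
  parents', resolved to the population mean beyond the pedigree depth
  (max age in generations + 1).
* **Default schedules.** The default migration schedule is directional
  coastal-to-migratory flow, cyclic over the century with post-millennium
  intensification (1%/generation baseline, 5% around the turn of the 20th
  century, 8% after 1996), matching the qualitative admixture history the
  study design targets. The default selection schedule is *empty*: whether
  the modern rise of inversion heterozygotes reflects more hybridization or
  higher heterokaryotype survival is an open question in the real system, so
  the simulator exposes both knobs (migration schedule vs viability
  schedule) and the defaults assert only the migration mechanism. The
  acceptance suite exercises the selection knob separately with a
  heterozygote-advantage epoch (`w_het = 1.3`), strong enough to move HET
  frequency from ~0.26 toward its 0.5 equilibrium within ~15 generations.
* **Missingness.** `inject_missingness()` degrades genotypes by era:
  pre-2000 samples default to 15% missing genotypes and a 0.5% genotype
  error rate; modern samples 2% and 0.1% — the signature of low-coverage
  historical DNA, without modelling damage patterns beyond the optional
  C/T–G/A site drop in `filter_sites()`.

What a green recovery test establishes is therefore limited: the generator
has no recombination map, no sequence context, no overlapping generations
beyond the age-at-catch device, no environmental covariates, and its
individuals are exchangeable within a population-generation. It validates
the *estimators* under a known truth, not the biology of any particular
dataset.

## The temporal estimator Fs'

`fs_prime()` measures standardized allele-frequency shift between two
samples of the same population taken `t` generations apart:

* Raw statistic: `Fs = Σ(x_i − y_i)² / Σ z_i (1 − z_i)`, `z = (x + y)/2`,
  summed over loci (**ratio of sums**, not a mean of per-locus ratios:
  averaging per-locus ratios is dominated by low-MAF loci and does not
  calibrate; the unweighted mean remains available via
  `ratio_of_sums = FALSE`). Loci monomorphic in the pooled pair are
  excluded — their denominator is zero.
* Sampling correction:
  `Fs' = (Fs (1 − 1/(4Ñ)) − 1/Ñ) / ((1 + Fs/4)(1 − 1/(2 n_t)))`, with `Ñ`
  the harmonic mean of the two samples' mean per-site non-missing sizes and
  `n_t` the later sample's. The formula alone does not pin down whether
  these sizes count individuals or alleles; we fixed the convention by
  simulation: with sizes
  in **diploid individuals** the estimator's mean across 200 pure-drift
  replicates (Ne = 500, t = 10, 2,000 loci, 50 diploids per sample) is
  0.0099 against a truth of `t/(2Ne) = 0.01`, while the allele convention
  overshoots twofold. The calibration is re-run as a binding acceptance
  test.
* Uncertainty: delete-one-locus jackknife on the full corrected estimator,
  CI = Fs' ± 1.96 SE. Coverage of the true drift signal, and of zero when
  both samples come from the same generation, is checked at 90–99%.
* `estimate_ne()` returns `t / (2 Fs')`, and **infinity** whenever
  Fs' ≤ 0 — a negative corrected shift means the observed frequency
  differences are within sampling noise, which is the expected outcome for
  a large stable population sampled a century apart.

## PCA karyotyping

`run_pca()` uses the standard genotype PCA normalization (center by `2p̂`,
scale by `sqrt(p̂(1−p̂))`, mean-impute missing dosages, drop monomorphic
sites) and eigendecomposes the sample covariance. Axis significance testing
is deliberately *not* reimplemented; explained-variance fractions are
reported instead. Signs are fixed by orienting each axis so the first
group's mean score is non-positive — eigenvectors are only defined up to
sign, and a deterministic rule keeps runs reproducible.

`call_karyotypes()` restricts to an inversion's sites (karyotyping must use
the *unpruned* matrix: the diagnostic signal is the block LD that pruning
removes), clusters PC1 with a 1-D Lloyd k-means initialized at the
10/50/90th percentiles (deterministic; no random restarts), and labels the
middle cluster HET. The outer clusters are polarized by an anchor sample set
known to be DERIVED when available; otherwise by mean alternate-allele
dosage, flagged `anchored = FALSE`. Two numerical guards matter:

* a call is withheld (NA) when `1 − d₁/d₂ < min_confidence` (default 0.05),
  with `d₁, d₂` the distances to the nearest and second-nearest centre;
* all calls for a region are flagged `low_confidence` when adjacent centres
  sit closer than `min_separation` (default 4) pooled within-cluster
  standard deviations. Genuine three-cluster karyotype structure separates
  by far more than 4; a unimodal score distribution split into thirds sits
  near 2.7, which is what the default is calibrated to reject.

The validation plot (`autoplot()` on the calls) is PC1 against
heterozygous-site fraction: heterokaryotypes are heterozygous across the
block, so the HET cluster must show the strictly highest fraction — this is
asserted on simulations in the acceptance suite.

## Differentiation and diversity scans

`site_fst()` implements the two-population Weir–Cockerham variance
components (`a`, `b`, `c`, including the observed-heterozygosity term) from
genotype counts; `window_fst()` aggregates them as `Σa / Σ(a+b+c)` in 30-kb
windows stepped by 15 kb, anchored at position 1 — the weighted estimator,
never a mean of per-site ratios. Negative per-site estimates are reported
as-is; clamping would bias the window sums. Significance comes from
`permutation_q()`: group labels are permuted across samples, the windowed
statistic recomputed per chromosome, and `p = (1 + #{null ≥ obs})/(B + 1)`
(the plus-one rule avoids p = 0). Whether the original analysis permuted at
site or window level is not recoverable; window-level permutation is
implemented because the window is the inferential unit. q-values are
Benjamini–Hochberg within chromosome — a tuning-free, conservative stand-in
for Storey's estimator. `afd()` flags sites beyond the genome-wide 99.9th
quantile of absolute frequency difference, and `shared_outliers()`
intersects outlier sets across year-pair comparisons, mirroring the logic
that only shifts recurring in several comparisons are candidate signals
rather than noise.

`tajimas_d_windows()` and `pi_windows()` are genotype-based (the pipeline
never phases): per-site heterozygosity `2p(1−p)·n/(n−1)` feeds the pairwise
estimator, segregating-site counts feed Watterson's, and the standard
constants are evaluated at the window's harmonic-mean allele count, rounded
to an integer under missingness. This differs in detail from per-window
behaviour of the common command-line tools when missingness varies within a
window; the deviation is tolerated and documented here because no convention
is canonical for genotype matrices with holes. Windows with no segregating
sites carry an undefined (missing) D, never a zero. `region_contrast()`
assigns windows by midpoint and reports inside/outside/chromosome means —
the balanced-inversion signature is an elevated inside mean, which
disappears when a single karyotype class is analysed alone.

## Genotype trajectory tests and ancestry

`hwe_chisq()` is the 1-df goodness-of-fit test with allele frequencies
estimated from the data; expected cells below 5 are flagged rather than
silently trusted. `fisher_years()` tests homogeneity of genotype classes
across years: exact where `fisher.test` can enumerate, Monte Carlo over
fixed-margin tables (≥10⁵ draws, seeded) otherwise, pairwise tests
Bonferroni-adjusted, and a compact letter display built by the
insert-and-absorb greedy so that sharing a letter is exactly pairwise
non-significance at `alpha`. `kruskal_dunn()` is the tie-corrected
Kruskal–Wallis H with Dunn's pairwise z tests and Benjamini–Hochberg
adjustment; a fully tied input collapses to H = 0 rather than 0/0.

`fit_q()` replaces an unsupervised admixture analysis with a **supervised**
mixture estimator, and this is the package's most consequential modeling
substitution: coastal-ancestry fractions are estimated relative to
user-chosen reference panels by maximizing the binomial mixture likelihood
`g ~ Binomial(2, Σ_k q_k p_k)` over the simplex via EM (uniform start,
deterministic, tolerance 1e-8 on the log-likelihood, 1,000-iteration cap
with a non-convergence flag). The rationale: the scientific claim —
coastal ancestry in the migratory population, referenced to known groups —
is inherently supervised, and the supervised likelihood is fully specified
and testable (simplex constraint to 1e-12, non-decreasing likelihood, exact
0.5 for an all-het F1 between fixed-difference panels). Panel frequencies
are clipped to `[ε, 1−ε]`, `ε = 1/(2n+2)`, so fixed panels cannot produce
infinite log-likelihoods. Linkage among sites is ignored, as in the standard
admixture likelihood; LD-pruned input is therefore expected.
`cohort_summary()` bins by birth year in fixed-width classes (default 3
years) from the earliest observed birth year and tests cohort differences
with the Kruskal–Wallis machinery; cohorts of one are shown but not tested.

In the demonstration pipeline the coastal panel is all coastal samples and
the migratory panel is the 1975 catch — a low-admixture era in the default
migration schedule — a choice the user should revisit for other worlds;
bycatch/straying exclusions are metadata-driven and left to the user.

## Scale of the acceptance checks

The desk-scale world uses thousands of SNPs where the motivating studies
use 10⁵–10⁶. Recovery tests compensate with per-site information, not with
relaxed thresholds: the ancestry pulse test uses a 60-generation burn-in
(per-site differentiation around FST ≈ 0.1) so that 2,000 sites carry power
comparable to 10⁵ weakly differentiated ones, and the selection test uses a
heterozygote advantage strong enough to act within 15 generations. Replicate
counts (200 for the drift calibration, 20 for the power properties) keep
the whole acceptance suite within its runtime budget on one CPU.

## Known limitations

* Frequency-level simulation: no linked neutral variation around the
  inversions beyond the tag blocks, no recombination map, no sequence
  evolution — positions and ref/alt bases are placeholders.
* Depth-, mappability- and damage-aware filtering of real historical data
  happen upstream of this package; `filter_sites()` covers only the
  genotype-level rules (biallelic, missingness, MAF, transition drop).
* The exact LD-pruning parameters behind any particular published neutral
  set are typically unstated; the defaults (50-SNP window, step 5,
  r² ≤ 0.5) are the common plink idiom and are logged in the filter stage.
* Ne from a single temporal pair assumes closed-population drift; gene flow
  biases Fs' upward, which is precisely the deviation the year-pair scan is
  designed to surface, not an error to correct.
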