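---
title: "Simulating and diagnosing parallel polygenic adaptation in E&R experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing parallel polygenic adaptation in E&R experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Replicated Evolve-and-Resequence (E&R) experiments expose independent lines
of a population to the same selective pressure and sequence them as pools at
several timepoints. When many standing variants respond, a central question
is how *parallel* the response is across replicate lines: does drift scatter
the selected-allele sets, or does some force align them? `erparallel`
implements a simulation-plus-inference framework built around one mechanism
that can align them: **synergistic (positive) epistasis**, in which the
fitness benefit of a beneficial allele grows with the number of other
beneficial alleles an individual carries.

The package simulates the full experiment (selection, drift, pooled
sequencing), detects selected alleles the way an empiricist would, measures
parallelism, and estimates the epistasis strength by approximate Bayesian
computation (ABC) — all under the design of a ten-generation laboratory
selection experiment: 10 treatment lines (2 lost before the final
generation), 4 control lines, sampling at generations 0, 6 and 10, pooled
sequencing of 100 individuals at 10–200x coverage, and an effective
population size of 1750 per line.

## Fitness models

An individual's genotype at the `N` selected loci is summarized by the
phenotype

$$x = \frac{\sum_i h_i s_i}{\sum_i s_i} \in [0, 1],$$

where `s_i` is the selection coefficient of the rising allele at locus `i`
and `h_i` is 0, 1/2 or 1 for 0, 1 or 2 copies. `x` is the
effect-weighted dosage of beneficial alleles: 0 when no beneficial allele is
carried, 1 when homozygous for all of them. (This phenotype is sometimes
written with product signs, `∏ h_i s_i / ∏ s_i`; that form is degenerate — a
single `h_i = 0` collapses it to zero — and contradicts the haploid
reduction to `x = n/N` that the equal-effect closed form relies on, so the
package implements the normalized sum, which reproduces that reduction
exactly.)

Two model families map genotypes to fitness:

* **Population-genetic family.**
  `w = ∏_i (1 + h_i s_i) · exp(α (x − δ)²)`.
  `α = 0` is the classical multiplicative model; `α > 0` is positive
  (synergistic) epistasis, `α < 0` negative. On an equal-effect
  haploid-style architecture this reduces to `(1+s)^n · exp(α (n/N)²)`, so
  the fitness ratio of adjacent allele counts is
  `(1+s)·exp(α(2n−1)/N²)` — e.g. with `N = 121`, `α = 36.5` the first
  beneficial allele multiplies fitness by ≈1.002·(1+s), while the 121st
  multiplies it by ≈1.823·(1+s). That asymmetry is the synergy.
* **Quantitative-genetic family.** Fitness depends on the phenotype only:
  a Gaussian *shifted optimum* `exp(−((x−δ)−μ)²/σ²)`, a saturating
  *directional* model `(1 + s_q e^{r((x−δ)+b)})^{−1/s_q}` (with `r < 0` so
  benefits saturate), and a *truncating* model
  `max{0, 1 − e^{−a((x−δ)+b)}}` in which low phenotypes are lethal.

The **horizontal shift** `δ` is the difference between the mean initial
phenotype of the current simulation and that of the baseline architecture.
It re-centres the fitness function when starting frequencies or locus
numbers are modified, so that modified simulations start from the same
effective position on the fitness curve.

### Reconstructed quantitative-genetic parameters

The exact shape parameters of the quantitative-genetic models behind the
empirical comparison are not available in published form, so
`qt_default_model()` reconstructs them from the design constraints they
were chosen to satisfy,
anchored to the initial phenotype distribution (closed-form mean and SD
under Hardy-Weinberg/linkage equilibrium): the truncating threshold sits at
the 25th percentile of initial phenotypes (≈25% of founders culled) with
steepness `3/SD` (benefits saturate within about one SD); the directional
model is a logistic of the same scale and midpoint; the optimum model puts
`μ` four initial SDs above the starting mean (reached near the end of the
experiment) with width `2·SD`. These are reconstructions, not fitted
values, and results under them should be read accordingly.

## The synthetic-data generator

`gen_architecture()` draws the genetic architecture; its defaults encode
the emulated experimental design:

* starting frequencies `p0 ~ Beta(7.1, 17.3)` truncated to (0.05, 0.95),
  mean ≈ 0.29 — intermediate-frequency standing variants, polarized as the
  rising allele;
* selection coefficients `s ~ Gamma(shape 3, rate 23.8)` truncated to
  [0.04, 0.45], giving a truncated mean of 0.133 and a maximum across 121
  draws near 0.37. The lower bound reflects that the empirical blocks are
  *detected* selected alleles, whose estimated effects cannot be
  arbitrarily small; the dispersion (shape 3) is a modelling choice — the
  empirical per-block values are not available in published form, and per-block
  heterogeneity in `s` is the quantity parallelism statistics are most
  sensitive to (see *Limitations*);
* 121 haplotype-block loci ≥ 1 Mb apart on 4 scaffolds; SNP-level
  architectures place ~41 SNPs per block.

`gen_experiment()` then emulates the design end to end: a founding
population at Hardy-Weinberg/linkage equilibrium, duplicate pooled
sequencing of it at generation 0, independent Wright-Fisher lines
(treatment under the fitness model, controls neutral), extinction of
randomly chosen treatment lines before the final generation, and a
two-stage Pool-seq observation (pool of 100 individuals sampled without
replacement, then binomial read sampling at uniform 10–200x coverage; the
uniform shape is a choice — the empirical depth distribution is not
published).

What the generator does **not** emulate: initial linkage disequilibrium
(lines start at linkage equilibrium), overlapping generations (the real
experiment had them; the simulations use discrete non-overlapping
generations), sequencing error, mapping bias, and any explicit environment
variable — selection enters only through the fitness model. Passing tests
therefore validate the machinery under these idealizations, not the full
messiness of real Pool-seq data.

## Detection, inference and parallelism

* **Selection calls** (`neutral_quantiles()`, `call_selected()`): an allele
  is selected in a line when its observed frequency increase over the
  baseline exceeds the 99.9th percentile of 10,000 neutral Wright-Fisher
  iterations at its starting frequency. Thresholds are calibrated at the
  final generation and applied at every timepoint by default
  (`threshold_generation = "final"`, matching how the empirical calls this
  emulates were made); per-generation thresholds are available. Neutral simulations are frequency-level drift by default;
  the Pool-seq layer can be switched on.
* **Selection coefficients** (`estimate_s()`): per-locus regression of
  logit-transformed frequencies on generation, either as a linear mixed
  model with a random line intercept and `N_eff` weights
  (`N_eff = 2·pool·coverage/(2·pool + coverage)`), or as averaged per-line
  slopes. Under the codominant diploid model the expected logit slope is
  `s/2`, so the default `scaling = "codominant"` reports twice the slope;
  `scaling = "slope"` reports the raw slope, which is the right scale for
  genic/haploid-style trajectories. Frequencies are squeezed to
  `[1/(2N_eff+2), 1 − 1/(2N_eff+2)]` before the logit.
* **Tests** (`cmh_drift_test()`, `chisq_line_test()`,
  `lmm_treatment_test()`): a stratified CMH-type statistic whose stratum
  variances are inflated for drift (`p(1−p)(1−(1−1/2N_e)^t)`) and two-stage
  Pool-seq sampling, with covariances for the shared drift path within a
  line and the shared baseline sample; it reduces exactly to the classical
  CMH statistic when those noise sources vanish, and its null calibration
  is verified by simulation. The treatment-vs-control test compares
  maximum-likelihood mixed models on angular-transformed frequency changes
  (LRT against chi-square with 2 df). Multiple testing uses
  Benjamini-Hochberg q-values (conservative relative to adaptive-pi0
  q-values, and dependency-free).
* **Parallelism** (`parallelism_summary()`): pairwise Jaccard overlap of
  per-line selected-allele sets over surviving lines, and the replicate
  frequency spectrum (per allele, the fraction of lines calling it). Pairs
  of empty sets count as J = 0 and are flagged; an exclusion policy is
  available.
* **ABC** (`abc_estimate_alpha()`): adaptive sequential ABC in the
  Lenormand style — keep the best half of the particle cloud by Euclidean
  distance on (mean J gen 6, mean J gen 10), propose by weighted resampling
  with Gaussian perturbation (variance twice the weighted cloud variance,
  reflected at the prior bounds), stop when fewer than 5% of proposals
  improve on the previous tolerance. The default prior is uniform on
  [0, 50] and the posterior is summarized by the weighted mean of the
  retained particles; the retention fraction (50%) and stopping threshold
  (5%) are the standard values for this scheme. A plain rejection sampler
  (`abc_reject()`) cross-checks the sequential scheme. One simulated
  experiment ensemble is run per particle by default; replication is
  configurable.

## Numerical and design choices

* Parent sampling is fitness-proportional multinomial with replacement
  (selfing permitted) — the standard Wright-Fisher scheme; finer mating
  details are a modeling choice.
* Linked mode tracks haplotypes explicitly; crossover probabilities come
  from the Haldane map function applied to physical distance × 1.6 cM/Mb,
  with free recombination across scaffolds. Unlinked mode samples gametes
  per locus (`Bernoulli(copies/2)`), which is exact under free
  recombination and faster.
* The multiplicative fitness product is accumulated in log space; the
  directional model's exponential is evaluated through `log1p(exp(·))` to
  avoid overflow.
* Every stochastic stage takes a seed; `run_pipeline()` derives per-stage
  sub-seeds from the master seed and logs them. Given a seed, all output is
  bit-reproducible.
* Test problem sizes: the test suite simulates 100-iteration parallelism
  distributions for the model-comparison checks, 25×400 locus-trajectories
  for drift-law checks, 600–800 neutral loci for test calibration, and a
  reduced 6-line ensemble for the ABC recovery experiment. These sizes were
  chosen to give stable Monte-Carlo estimates at interactive runtimes.

## Limitations

* The per-block empirical architecture (the exact `(s, p0)` pairs) is not
  published in extractable form; the generator reconstructs the printed
  summary statistics (means, ranges) but not the empirical joint
  distribution. Absolute Jaccard levels are sensitive to the *dispersion*
  of call probabilities across loci: heterogeneous `s` makes some loci
  always-called and others never-called, which raises the mean Jaccard
  index relative to a homogeneous architecture with the same mean call
  rate. Comparisons *between* models on the same architecture (the
  package's main use) are robust to this; absolute levels should be
  compared to published values with that caveat. Loading empirical
  per-block values via `architecture()`/`read_architecture_tsv()` removes
  the caveat.
* `N_e` is an input, not an estimand — temporal `N_e` estimation is out of
  scope.
* Haplotype-block discovery from SNP data is out of scope; block membership
  is taken as given.
* The mixed-model LRT is asymptotic; at 14 lines × 2 timepoints it runs
  slightly hot (empirically ~6–8% rejections at nominal 5% under the
  null), which the calibration tests bound but do not remove.

## A worked run

```{r}
library(erparallel)

cfg <- run_config(
  seed = 1,
  outdir = "run1",
  architecture = list(n_loci = 121),
  design = experiment_design(),
  model = list(kind = "positive_epistasis", alpha = 36.5),
  neutral_iter = 10000
)
res <- run_pipeline(cfg)
res$parallelism$gen10$mean_jaccard
res$abc # NULL unless an abc config is supplied
```

The same run is available from a shell via
`inst/scripts/run_pipeline.R --config cfg.yaml --seed 1`.
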