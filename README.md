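# erparallel

Simulation and inference of **parallel polygenic adaptation** in replicated
Evolve-and-Resequence (E&R) experiments.

When independent selection lines adapt from the same standing variation,
how similar are their selected-allele sets? Genetic drift and sampling make
replicate lines diverge; `erparallel` asks what it takes to make them agree
— in particular, whether **synergistic (positive) epistasis** among selected
alleles can explain empirically observed levels of parallelism that a
standard multiplicative model cannot.

The package is aimed at population geneticists analyzing or designing
replicated selection experiments with Pool-seq time series.

## What it implements

* **Forward Wright-Fisher simulation** of diploid multilocus populations
  (unlinked, or linked via the Haldane map at a physical recombination
  rate), from standing variation, with replicate treatment and control
  lines, line extinction, and duplicate baseline sequencing.
* **Fitness models**: with phenotype `x = Σ h_i s_i / Σ s_i` (the
  effect-weighted dosage of beneficial alleles, `h_i ∈ {0, ½, 1}`),

  | model | fitness |
  |---|---|
  | multiplicative | `∏ (1 + h_i s_i)` |
  | positive / negative epistasis | `∏ (1 + h_i s_i) · e^{α(x−δ)²}`, `α > 0` / `α < 0` |
  | shifted optimum | `e^{−((x−δ)−μ)²/σ²}` |
  | directional | `(1 + s e^{r((x−δ)+b)})^{−1/s}`, `r < 0` |
  | truncating | `max{0, 1 − e^{−a((x−δ)+b)}}` |

  On an equal-effect haploid-style architecture the epistatic model reduces
  to `(1+s)^n e^{α(n/N)²}`, so each additional beneficial allele multiplies
  fitness by `(1+s)·e^{α(2n−1)/N²}` — synergy in closed form.
* **Pool-seq observation**: pool subsampling without replacement, binomial
  read sampling at bounded coverage, and the effective-copy weight
  `N_eff = 2·pool·cov / (2·pool + cov)`.
* **Selection inference**: neutral-quantile selection calls (top 0.1% of
  10,000 neutral iterations per starting frequency), per-locus selection
  coefficients from logit-slope regressions (mixed model with line random
  effect, or per-line slopes), drift-adjusted CMH and per-line chi-square
  tests, a treatment-vs-control linear-mixed-model LRT, and BH q-values.
* **Parallelism statistics**: pairwise Jaccard overlap of selected-allele
  sets, the replicate frequency spectrum, empirical p-values against
  simulated distributions, and parallelism as a function of the number of
  contributing loci.
* **Sequential ABC** (Lenormand-style adaptive population Monte Carlo) to
  estimate the epistasis strength `α` from observed mean Jaccard indices,
  with a rejection-ABC cross-check.
* **Pipeline**: `run_pipeline()` orchestrates synthesize → simulate →
  observe → call → summarize → ABC with derived, logged sub-seeds and TSV +
  JSON outputs; `inst/scripts/run_pipeline.R` is a shell wrapper. TSV
  trajectory tables and popoolation2-style sync files are read and written.

## A worked example

```r
library(erparallel)

arch   <- gen_architecture(n_loci = 121, seed = 42)  # study-like architecture
design <- experiment_design()                         # 10+4 lines, Ne 1750, gens 0/6/10
nq     <- neutral_quantiles(setNames(arch$loci$p0, arch$loci$locus_id),
                            Ne = 1750, generations = c(6, 10),
                            n_iter = 10000, seed = 3)

traj  <- gen_experiment(arch, design, fitness_model("multiplicative"), seed = 7)
calls <- call_selected(traj, nq)
calls
#> <er_calls> q = 0.999; selected per line x generation:
#>   gen  6: mean 61.2 (range 49-69) over 10 lines
#>   gen 10: mean 84.1 (range 81-88) over 8 lines

parallelism_summary(calls, 10)
#> <er_parallelism> gen 10, 8 lines: mean pairwise Jaccard = 0.648
#>   RFS: 29.8% of alleles selected in all lines
```

Under the multiplicative (no-epistasis) model, half to two-thirds of
the 121 selected alleles shift significantly per line, but the lines only
partly agree on *which* (mean pairwise Jaccard ≈ 0.65 here). Re-running
`gen_experiment` with
`fitness_model("positive_epistasis", alpha = 36.5)` pushes the per-line
counts and the overlap up — selected alleles rise together — which is the
signature the parallelism statistics and the ABC machinery quantify:

```r
sims <- simulate_parallelism(arch, design,
                             fitness_model("positive_epistasis", alpha = 36.5),
                             nq, n_iter = 20, seed = 9)
aggregate(mean_jaccard ~ generation, sims, mean)
#>   generation mean_jaccard
#> 1          6    0.6088032
#> 2         10    0.7173556
```

`abc_estimate_alpha(target, simulator)` then inverts this mapping: given
observed mean Jaccard indices at generations six and ten, it returns a
posterior sample of `α` (uniform [0, 50] prior) whose weighted mean is the
point estimate.

See `vignettes/parallel-adaptation.Rmd` for the models, the reconstruction
choices behind the synthetic-data defaults, and known limitations.

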