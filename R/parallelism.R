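# Parallelism statistics: pairwise Jaccard overlap of selected-allele sets,
# replicate frequency spectrum (RFS), empirical p-values against simulated
# distributions, and the parallelism-vs-architecture-size experiment.

#' Jaccard index of two selected-allele sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets give 0 (flagged via the
#' `"empty"` attribute).
#' @param set_a,set_b character vectors of locus ids
#' @export
jaccard <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0) return(structure(0, empty = TRUE))
  length(intersect(set_a, set_b)) / u
}

#' Summarize parallelism across replicate lines at one generation
#'
#' Computes the pairwise Jaccard matrix over the per-line selected-allele
#' sets, its mean over unordered distinct pairs, and the replicate frequency
#' spectrum (per allele, the fraction of surviving lines in which it was
#' called selected).
#'
#' @param calls an `er_calls`
#' @param generation generation to summarize (only lines with calls at that
#'   generation — the survivors — are included)
#' @param empty_pairs `"zero"` counts pairs of empty sets as J = 0 (default);
#'   `"exclude"` drops them from the mean
#' @return object of class `er_parallelism`: list with `jaccard_matrix`,
#'   `mean_jaccard`, `rfs` (named numeric), `generation`, `n_lines`
#' @export
parallelism_summary <- function(calls, generation,
                                empty_pairs = c("zero", "exclude")) {
  empty_pairs <- match.arg(empty_pairs)
  sets <- selected_sets(calls, generation)
  L <- length(sets)
  if (L < 2) stop_config("need >= 2 lines with calls at generation ",
                         generation)
  jm <- matrix(NA_real_, L, L, dimnames = list(names(sets), names(sets)))
  diag(jm) <- 1
  empties <- 0L
  vals <- c()
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    v <- jaccard(sets[[i]], sets[[j]])
    if (isTRUE(attr(v, "empty"))) {
      empties <- empties + 1L
      if (empty_pairs == "exclude") {
        jm[i, j] <- jm[j, i] <- NA_real_
        next
      }
    }
    jm[i, j] <- jm[j, i] <- as.numeric(v)
    vals <- c(vals, as.numeric(v))
  }
  cc <- calls[calls$generation == generation, , drop = FALSE]
  rfs_agg <- tapply(cc$called, cc$locus_id, mean)
  structure(
    list(jaccard_matrix = jm,
         mean_jaccard = if (length(vals)) mean(vals) else NA_real_,
         rfs = rfs_agg[sort(names(rfs_agg))],
         generation = generation, n_lines = L, n_empty_pairs = empties),
    class = "er_parallelism")
}

#' @export
print.er_parallelism <- function(x, ...) {
  cat(sprintf(
    "<er_parallelism> gen %d, %d lines: mean pairwise Jaccard = %.3f\n",
    x$generation, x$n_lines, x$mean_jaccard))
  cat(sprintf("  RFS: %.1f%% of alleles selected in all lines\n",
              100 * mean(x$rfs == 1)))
  invisible(x)
}

#' Empirical p-value of an observed statistic against simulations
#'
#' Two-sided: `2 * min(frac(sim >= obs), frac(sim <= obs))` capped at 1;
#' one-sided variants available.
#' @param observed observed value
#' @param simulated vector of >= 100 simulated values
#' @param side `"two"`, `"greater"` (P(sim >= obs)) or `"less"`
#' @export
empirical_pvalue <- function(observed, simulated,
                             side = c("two", "greater", "less")) {
  side <- match.arg(side)
  if (length(simulated) < 100)
    stop_config("need >= 100 simulated values")
  ge <- mean(simulated >= observed)
  le <- mean(simulated <= observed)
  switch(side,
         two = min(1, 2 * min(ge, le)),
         greater = ge,
         less = le)
}

#' Simulate the parallelism distribution under a fitness model
#'
#' Repeatedly generates a full synthetic experiment, calls selected alleles
#' against the supplied neutral thresholds and records the mean pairwise
#' Jaccard index at each requested generation. This is the simulation
#' engine behind model comparison and the ABC estimation of the epistasis
#' strength.
#'
#' @inheritParams gen_experiment
#' @param nq neutral thresholds (computed once per architecture/Ne; see
#'   [neutral_quantiles()])
#' @param n_iter number of independent experiment replicates
#' @param generations generations at which to record mean Jaccard
#' @param seed integer seed (per-iteration sub-seeds are derived)
#' @return data.frame (iteration, generation, mean_jaccard)
#' @export
simulate_parallelism <- function(arch, design, model, nq, n_iter,
                                 generations = c(6, 10), seed = NULL) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    traj <- gen_experiment(arch, design, model, seed = derive_seed(seed, it))
    calls <- call_selected(traj, nq)
    mj <- vapply(generations, function(g)
      parallelism_summary(calls, g)$mean_jaccard, numeric(1))
    out[[it]] <- data.frame(iteration = it, generation = generations,
                            mean_jaccard = mj)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parallelism as a function of the number of contributing loci
#'
#' For each grid value, repeatedly subsamples that many loci from the
#' architecture, applies a horizontal shift so the initial phenotype mean
#' matches the full-architecture baseline, simulates the experiment and
#' summarizes the mean Jaccard index at the final sampled generation.
#'
#' @inheritParams simulate_parallelism
#' @param nloci_grid integer vector of locus counts (each <= arch$n_loci)
#' @param generation generation summarized (default: last sampled)
#' @return data.frame (n_loci, mean_j, iqr_lo, iqr_hi) where `mean_j`
#'   averages over iterations and the IQR spans them
#' @export
parallelism_vs_nloci <- function(arch, design, model, nloci_grid,
                                 n_iter = 20, generation = NULL,
                                 seed = NULL) {
  stopifnot(inherits(arch, "er_architecture"))
  if (any(nloci_grid > arch$n_loci) || any(nloci_grid < 1))
    stop_config("nloci_grid values must lie in [1, n_loci]")
  generation <- generation %||% max(design$sampled_generations)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  base_mean <- initial_phenotype_moments(arch)$mean
  out <- vector("list", length(nloci_grid))
  for (gi in seq_along(nloci_grid)) {
    nl <- nloci_grid[gi]
    mjs <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      sseed <- derive_seed(seed, gi * 10000L + it)
      sub <- with_seed(sseed, sample.int(arch$n_loci, nl))
      sub_arch <- architecture(arch$loci[sort(sub), , drop = FALSE],
                               level = arch$level,
                               linkage_mode = arch$linkage_mode,
                               recomb_rate_cM_per_Mb =
                                 arch$recomb_rate_cM_per_Mb)
      mod <- model
      mod$delta <- horizontal_shift(
        initial_phenotype_moments(sub_arch)$mean, base_mean)
      nq <- neutral_quantiles(
        stats::setNames(sub_arch$loci$p0, sub_arch$loci$locus_id),
        Ne = design$Ne, generations = generation,
        n_iter = 2000, seed = derive_seed(sseed, 1))
      traj <- gen_experiment(sub_arch, design, mod,
                             seed = derive_seed(sseed, 2))
      calls <- call_selected(traj, nq)
      mjs[it] <- parallelism_summary(calls, generation)$mean_jaccard
    }
    qs <- stats::quantile(mjs, c(0.25, 0.75), names = FALSE)
    out[[gi]] <- data.frame(n_loci = nl, mean_j = mean(mjs),
                            iqr_lo = qs[1], iqr_hi = qs[2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
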