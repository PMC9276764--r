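# Pool-seq observation layer and synthetic experiment generator.
#
# Observation is two-stage: a pool of individuals is sampled from the
# population without replacement (hypergeometric at the allele level, since
# whole diploid individuals enter the pool), then reads are drawn
# binomially from the pool allele frequency at a per-locus coverage. This
# is the standard Pool-seq error model: no sequencing-error or mapping-bias
# component.

new_trajectories <- function(df) {
  need <- c("line", "treatment", "generation", "locus_id", "block_id",
            "alt_count", "coverage", "pool_n", "freq")
  stopifnot(all(need %in% names(df)))
  bad <- !is.na(df$coverage) &
    (df$coverage < 1 | df$alt_count < 0 | df$alt_count > df$coverage)
  if (any(bad)) stop_config("invalid counts: need 0 <= alt_count <= coverage")
  if (any(df$freq < 0 | df$freq > 1)) stop_config("frequencies outside [0, 1]")
  rownames(df) <- NULL
  structure(df, class = c("er_trajectories", "data.frame"))
}

#' @export
print.er_trajectories <- function(x, ...) {
  cat(sprintf(
    "<er_trajectories> %d records: %d lines x %d loci, generations %s\n",
    nrow(x), length(unique(x$line)), length(unique(x$locus_id)),
    paste(sort(unique(x$generation)), collapse = "/")))
  invisible(x)
}

#' Effective number of allele copies of a Pool-seq sample
#'
#' Harmonic-style combination of pool size and read depth,
#' `N_eff = 2 * pool_n * coverage / (2 * pool_n + coverage)`, bounded above
#' by both the number of chromosomes pooled and the coverage. Used as a
#' regression weight in [estimate_s()] and [lmm_treatment_test()].
#'
#' @param pool_n diploid individuals in the pool (>= 1)
#' @param coverage read depth (>= 1)
#' @return effective number of allele copies
#' @export
n_eff <- function(pool_n, coverage) {
  if (any(pool_n < 1) || any(coverage < 1))
    stop_config("pool_n and coverage must be >= 1")
  (2 * pool_n * coverage) / (2 * pool_n + coverage)
}

#' Observe a population through the Pool-seq layer
#'
#' Samples `pool_n` individuals without replacement, computes the pool
#' allele frequency per locus, then draws `alt_count ~ Binomial(coverage,
#' q_pool)` with per-locus coverage from `coverage_sampler`.
#'
#' @param pop an `er_population`
#' @param pool_n number of individuals pooled (<= population size)
#' @param coverage_sampler function(n_loci) returning integer coverages, or
#'   a single number for fixed coverage
#' @param seed optional integer seed
#' @return data.frame with columns alt_count, coverage, pool_n, freq
#' @export
observe <- function(pop, pool_n, coverage_sampler, seed = NULL) {
  stopifnot(inherits(pop, "er_population"))
  N <- nrow(pop$copies)
  if (pool_n > N) stop_config("pool_n (", pool_n, ") exceeds population size (", N, ")")
  if (is.numeric(coverage_sampler)) {
    cov_fixed <- as.integer(coverage_sampler)
    coverage_sampler <- function(L) rep(cov_fixed, L)
  }
  with_seed(seed, {
    idx <- sample.int(N, pool_n)
    q_pool <- colMeans(pop$copies[idx, , drop = FALSE]) / 2
    L <- length(q_pool)
    cov <- as.integer(coverage_sampler(L))
    if (any(cov < 1)) stop_config("coverage sampler returned depth < 1")
    alt <- stats::rbinom(L, cov, q_pool)
    data.frame(alt_count = alt, coverage = cov,
               pool_n = as.integer(pool_n), freq = alt / cov)
  })
}

#' Uniform coverage sampler over the design's depth bounds
#' @param design an `er_design`
#' @return function(n) returning integer coverages uniform on
#'   \[coverage_min, coverage_max\]
#' @export
coverage_sampler_uniform <- function(design) {
  lo <- design$coverage_min
  hi <- design$coverage_max
  function(n) sample(seq.int(lo, hi), n, replace = TRUE)
}

#' Generate a full synthetic Evolve-and-Resequence experiment
#'
#' Emulates the study design end to end: a founding population at HWE is
#' sequenced twice at generation zero (two independent pool+read samples,
#' matching duplicate baseline sequencing of the shared starting
#' population); treatment lines evolve under the fitness model and control
#' lines neutrally, each from a fresh HWE draw; all surviving lines are
#' observed through the Pool-seq layer at the post-baseline sampled
#' generations. Extinct treatment lines (chosen uniformly at random) have no
#' final-generation sample.
#'
#' @param arch an `er_architecture`
#' @param design an `er_design`
#' @param model an `er_fitness_model` applied to treatment lines (controls
#'   always evolve neutrally)
#' @param seed integer seed; the full output is reproducible given the seed
#' @param observe_layer set `FALSE` to record true frequencies instead of
#'   Pool-seq observations
#' @return an `er_trajectories` data.frame; baseline samples appear as lines
#'   `"S0a"`/`"S0b"` with `treatment = NA`, treatment lines as `"T01"...`,
#'   control lines as `"C01"...`
#' @export
gen_experiment <- function(arch, design, model, seed = NULL,
                           observe_layer = TRUE) {
  stopifnot(inherits(arch, "er_architecture"), inherits(design, "er_design"),
            is.null(model) || inherits(model, "er_fitness_model"))
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  covs <- coverage_sampler_uniform(design)
  post_gens <- setdiff(design$sampled_generations, 0L)
  rec_fun <- function(pop) {
    if (observe_layer) observe(pop, design$pool_n_individuals, covs)
    else data.frame(alt_count = NA_integer_, coverage = NA_integer_,
                    pool_n = NA_integer_, freq = allele_freq(pop))
  }
  row_block <- function(line, treatment, gen, obs) {
    data.frame(line = line, treatment = treatment, generation = gen,
               locus_id = arch$loci$locus_id, block_id = arch$loci$block_id,
               alt_count = obs$alt_count, coverage = obs$coverage,
               pool_n = obs$pool_n, freq = obs$freq,
               stringsAsFactors = FALSE)
  }

  out <- with_seed(seed, {
    recs <- list()
    # duplicate baseline sequencing of the shared founding population
    founder <- initialize_population(arch, design$Ne)
    recs[[1]] <- row_block("S0a", NA, 0L, rec_fun(founder))
    recs[[2]] <- row_block("S0b", NA, 0L, rec_fun(founder))
    extinct <- if (design$n_extinct_at_final > 0)
      sample.int(design$n_treatment_lines, design$n_extinct_at_final)
    else integer(0)
    k <- 2L
    run_line <- function(label, mod, gens) {
      obs <- evolve_line(arch, mod, design$Ne, gens,
                         max(gens), NULL, recorder = rec_fun)
      lapply(names(obs), function(g)
        row_block(label, !is.null(mod), as.integer(g), obs[[g]]))
    }
    for (i in seq_len(design$n_treatment_lines)) {
      gens <- if (i %in% extinct)
        post_gens[post_gens < design$final_generation] else post_gens
      if (length(gens) == 0L) next
      blocks <- run_line(sprintf("T%02d", i), model, gens)
      for (b in blocks) { k <- k + 1L; recs[[k]] <- b }
    }
    for (i in seq_len(design$n_control_lines)) {
      blocks <- run_line(sprintf("C%02d", i), NULL, post_gens)
      for (b in blocks) { k <- k + 1L; recs[[k]] <- b }
    }
    do.call(rbind, recs)
  })
  new_trajectories(out)
}
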