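# Diploid Wright-Fisher forward engine.
#
# Populations are constant-size collections of diploid multilocus genotypes.
# Each generation, every offspring draws two parents with probability
# proportional to fitness (with replacement; selfing permitted) and receives
# one gamete from each. In unlinked mode loci assort freely, so a gamete
# carries each parental allele with probability copies/2 independently per
# locus; in linked mode parental haplotypes are tracked explicitly and
# crossovers occur between adjacent loci with probabilities given by the
# Haldane map function applied to physical distance times the recombination
# rate (loci on different scaffolds assort independently). There is no
# mutation or migration: evolution proceeds from standing variation only.

#' Initialize a population at Hardy-Weinberg / linkage equilibrium
#'
#' Each individual draws, independently per locus, allele copies from
#' HWE at the locus's starting frequency (0 copies with probability
#' (1-p)^2, one with 2p(1-p), two with p^2); loci are independent
#' (linkage equilibrium).
#'
#' @param arch an `er_architecture`
#' @param N population size (>= 2)
#' @param seed optional integer seed
#' @return object of class `er_population`: list with `copies`
#'   (N x n_loci integer matrix), `hap` (two haplotype matrices, linked
#'   mode only), `generation`, `arch`
#' @export
initialize_population <- function(arch, N, seed = NULL) {
  stopifnot(inherits(arch, "er_architecture"))
  if (N < 2) stop_config("N must be >= 2")
  N <- as.integer(N)
  L <- arch$n_loci
  p <- arch$loci$p0
  with_seed(seed, {
    if (arch$linkage_mode == "linked") {
      h1 <- matrix(stats::rbinom(N * L, 1L, rep(p, each = N)), N, L)
      h2 <- matrix(stats::rbinom(N * L, 1L, rep(p, each = N)), N, L)
      pop <- list(copies = h1 + h2, hap = list(h1 = h1, h2 = h2),
                  generation = 0L, arch = arch)
    } else {
      copies <- matrix(stats::rbinom(N * L, 2L, rep(p, each = N)), N, L)
      pop <- list(copies = copies, hap = NULL, generation = 0L, arch = arch)
    }
    class(pop) <- "er_population"
    pop
  })
}

#' @export
print.er_population <- function(x, ...) {
  cat(sprintf("<er_population> N = %d, %d loci, generation %d (%s)\n",
              nrow(x$copies), ncol(x$copies), x$generation,
              x$arch$linkage_mode))
  invisible(x)
}

#' Per-locus allele frequencies of a population
#' @param pop an `er_population`
#' @return numeric vector (mean copies / 2)
#' @export
allele_freq <- function(pop) {
  colMeans(pop$copies) / 2
}

# crossover probabilities between adjacent loci (Haldane map function);
# loci on different scaffolds recombine freely
recomb_probs <- function(arch) {
  L <- arch$n_loci
  if (L < 2) return(numeric(0))
  d_bp <- diff(arch$loci$position_bp)
  morgans <- d_bp / 1e6 * arch$recomb_rate_cM_per_Mb / 100
  r <- 0.5 * (1 - exp(-2 * morgans))
  same <- arch$loci$scaffold[-1] == arch$loci$scaffold[-L]
  r[!same] <- 0.5
  r
}

# population fitness for the reproduction step (compiled kernel for the
# multiplicative/epistatic family; R path for the phenotype-only models)
pop_fitness <- function(pop, model) {
  arch <- pop$arch
  if (model$kind %in% c("multiplicative", "positive_epistasis",
                        "negative_epistasis")) {
    s <- arch$loci$s
    logw <- .logw_popgen(pop$copies, log1p(s / 2), log1p(s), s,
                         model$alpha, model$delta, sum(s))
    if (any(logw > 700)) stop_config("fitness overflow: log-fitness exceeds 700")
    exp(logw)
  } else {
    fitness(pop$copies, arch, model)
  }
}

#' Advance a population by one Wright-Fisher generation
#'
#' @param pop an `er_population`
#' @param model an `er_fitness_model`, or `NULL` for neutral reproduction
#'   (all fitnesses equal)
#' @return the next-generation `er_population`
#' @export
step_generation <- function(pop, model = NULL) {
  stopifnot(inherits(pop, "er_population"))
  N <- nrow(pop$copies)
  if (is.null(model)) {
    w <- NULL
  } else {
    w <- pop_fitness(pop, model)
    if (all(w == 0))
      stop(structure(
        class = c("er_extinction_error", "error", "condition"),
        list(message = sprintf(
          "population extinct at generation %d: total fitness is 0",
          pop$generation), call = sys.call(-1))))
  }
  mom <- sample.int(N, N, replace = TRUE, prob = w)
  dad <- sample.int(N, N, replace = TRUE, prob = w)
  if (is.null(pop$hap)) {
    nxt <- list(copies = .offspring_unlinked(pop$copies, mom, dad),
                hap = NULL, generation = pop$generation + 1L, arch = pop$arch)
  } else {
    g <- .offspring_linked(pop$hap$h1, pop$hap$h2, mom, dad,
                           recomb_probs(pop$arch))
    nxt <- list(copies = g$g1 + g$g2, hap = list(h1 = g$g1, h2 = g$g2),
                generation = pop$generation + 1L, arch = pop$arch)
  }
  class(nxt) <- "er_population"
  nxt
}

# evolve one line from a fresh HWE draw, calling `recorder(pop)` at each
# sampled generation; returns list keyed by generation
evolve_line <- function(arch, model, Ne, sample_gens, final_gen, seed,
                        recorder = function(pop) allele_freq(pop)) {
  with_seed(seed, {
    pop <- initialize_population(arch, Ne)
    out <- list()
    if (0L %in% sample_gens) out[["0"]] <- recorder(pop)
    for (g in seq_len(final_gen)) {
      pop <- step_generation(pop, model)
      if (g %in% sample_gens) out[[as.character(g)]] <- recorder(pop)
    }
    out
  })
}

#' Simulate replicate lines and record true allele frequencies
#'
#' Each line is an independent population initialized by a fresh HWE draw
#' from the same architecture and evolved to the final generation under the
#' given fitness model. True (pre-observation) allele frequencies are
#' recorded at the sampled generations.
#'
#' @param arch an `er_architecture`
#' @param design an `er_design` (supplies Ne, sampled generations, final
#'   generation)
#' @param model an `er_fitness_model`, or `NULL` for neutral lines
#' @param n_lines number of replicate lines
#' @param seed optional integer seed
#' @return an `er_trajectories` data.frame (columns line, treatment,
#'   generation, locus_id, block_id, alt_count, coverage, pool_n, freq) with
#'   `alt_count`/`coverage`/`pool_n` set to NA (no observation layer)
#' @export
run_replicates <- function(arch, design, model, n_lines, seed = NULL) {
  stopifnot(inherits(arch, "er_architecture"), inherits(design, "er_design"))
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  recs <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    freqs <- tryCatch(
      evolve_line(arch, model, design$Ne, design$sampled_generations,
                  design$final_generation, derive_seed(seed, i)),
      er_extinction_error = function(e)
        stop_config(sprintf("line T%d: %s", i, conditionMessage(e)))
    )
    recs[[i]] <- do.call(rbind, lapply(names(freqs), function(g) {
      data.frame(line = sprintf("T%02d", i), treatment = TRUE,
                 generation = as.integer(g),
                 locus_id = arch$loci$locus_id,
                 block_id = arch$loci$block_id,
                 alt_count = NA_integer_, coverage = NA_integer_,
                 pool_n = NA_integer_, freq = freqs[[g]],
                 stringsAsFactors = FALSE)
    }))
  }
  new_trajectories(do.call(rbind, recs))
}

#' Neutral drift quantiles for selection calling
#'
#' For each starting frequency, simulates `n_iter` frequency-level neutral
#' Wright-Fisher trajectories (binomial resampling of 2*Ne allele copies per
#' generation) and returns, per sampled generation, the `q`-quantile of the
#' frequency increase `p_t - p0`. A locus in an experimental line is called
#' selected when its observed increase exceeds this threshold (see
#' [call_selected()]). Optionally the Pool-seq observation layer (pool
#' subsampling then read sampling at uniform coverage) is applied to the
#' simulated trajectories so the thresholds include observation noise.
#'
#' @param p0_values numeric vector of starting frequencies (one per locus);
#'   names are carried through as locus ids
#' @param Ne effective population size
#' @param generations integer vector of generations at which thresholds are
#'   needed
#' @param n_iter neutral iterations per starting frequency (>= 1000)
#' @param q quantile (default 0.999, the top 0.1% of neutral simulations)
#' @param pool_n,coverage_min,coverage_max when all supplied, thresholds are
#'   computed on observed rather than true frequencies
#' @param seed optional integer seed
#' @return object of class `er_neutral_quantiles`: data.frame (locus_id, p0,
#'   generation, threshold) with attributes q, n_iter, Ne
#' @export
neutral_quantiles <- function(p0_values, Ne, generations, n_iter = 10000,
                              q = 0.999, pool_n = NULL, coverage_min = NULL,
                              coverage_max = NULL, seed = NULL) {
  if (n_iter < 1000) stop_config("n_iter must be >= 1000")
  if (q <= 0 || q >= 1) stop_config("q must lie in (0, 1)")
  assert_scalar_num(Ne, "Ne", lower = 2)
  generations <- sort(unique(as.integer(generations)))
  observe_layer <- !is.null(pool_n) && !is.null(coverage_min) &&
    !is.null(coverage_max)
  m <- length(p0_values)
  ids <- names(p0_values) %||% sprintf("p0_%03d", seq_len(m))
  two_ne <- round(2 * Ne)
  with_seed(seed, {
    P <- matrix(rep(as.numeric(p0_values), each = n_iter), n_iter, m)
    out <- vector("list", length(generations))
    gi <- 0L
    record <- function(gen) {
      Pobs <- P
      if (observe_layer) {
        q_pool <- matrix(stats::rbinom(n_iter * m, 2L * pool_n, P),
                         n_iter, m) / (2 * pool_n)
        cov <- matrix(sample(seq.int(coverage_min, coverage_max),
                             n_iter * m, replace = TRUE), n_iter, m)
        Pobs <- matrix(stats::rbinom(n_iter * m, as.vector(cov),
                                     as.vector(q_pool)), n_iter, m) / cov
      }
      D <- sweep(Pobs, 2L, as.numeric(p0_values), `-`)
      thr <- apply(D, 2L, stats::quantile, probs = q, names = FALSE)
      data.frame(locus_id = ids, p0 = as.numeric(p0_values),
                 generation = gen, threshold = thr,
                 stringsAsFactors = FALSE)
    }
    if (0L %in% generations) {
      gi <- gi + 1L
      out[[gi]] <- record(0L)
    }
    for (g in seq_len(max(generations))) {
      P <- matrix(stats::rbinom(n_iter * m, two_ne, P), n_iter, m) / two_ne
      if (g %in% generations) {
        gi <- gi + 1L
        out[[gi]] <- record(g)
      }
    }
    res <- do.call(rbind, out[seq_len(gi)])
    structure(res, q = q, n_iter = n_iter, Ne = Ne,
              observed = observe_layer,
              class = c("er_neutral_quantiles", "data.frame"))
  })
}
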