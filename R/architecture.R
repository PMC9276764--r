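# Genetic architectures for replicated selection experiments.
#
# An architecture is the set of selected loci: the rising-allele starting
# frequency p0, the selection coefficient s, and genomic coordinates
# (scaffold, position, haplotype-block membership). Architectures can be
# simulated at the haplotype-block level (one locus per block, the unit at
# which parallelism is scored) or at SNP level (many SNPs per block).

#' Distribution specification for architecture parameters
#'
#' Small tagged lists describing the distribution from which starting
#' frequencies or selection coefficients are drawn. Supported:
#' `dist_beta(shape1, shape2, lower, upper)` (truncated by rejection),
#' `dist_gamma(shape, rate, upper)` (upper-truncated),
#' `dist_point(value)`, `dist_uniform(min, max)` and
#' `dist_empirical(values)` (resampled with replacement, or used as-is when
#' the requested number of draws equals `length(values)`).
#'
#' @param shape1,shape2 Beta parameters (> 0)
#' @param lower,upper truncation bounds
#' @param shape,rate Gamma parameters (> 0)
#' @param value point mass location
#' @param min,max uniform bounds
#' @param values numeric vector of empirical values
#' @return an object of class `er_dist`
#' @export
dist_beta <- function(shape1, shape2, lower = 0, upper = 1) {
  if (shape1 <= 0 || shape2 <= 0 || lower >= upper)
    stop_config("invalid Beta distribution parameters")
  structure(list(kind = "beta", shape1 = shape1, shape2 = shape2,
                 lower = lower, upper = upper), class = "er_dist")
}

#' @rdname dist_beta
#' @export
dist_gamma <- function(shape, rate, lower = 0, upper = Inf) {
  if (shape <= 0 || rate <= 0 || upper <= lower || lower < 0)
    stop_config("invalid Gamma distribution parameters")
  structure(list(kind = "gamma", shape = shape, rate = rate,
                 lower = lower, upper = upper), class = "er_dist")
}

#' @rdname dist_beta
#' @export
dist_point <- function(value) {
  structure(list(kind = "point", value = value), class = "er_dist")
}

#' @rdname dist_beta
#' @export
dist_uniform <- function(min, max) {
  if (min >= max) stop_config("invalid uniform bounds")
  structure(list(kind = "uniform", min = min, max = max), class = "er_dist")
}

#' @rdname dist_beta
#' @export
dist_empirical <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values))
    stop_config("empirical distribution needs a non-empty numeric vector")
  structure(list(kind = "empirical", values = values), class = "er_dist")
}

draw_dist <- function(d, n) {
  stopifnot(inherits(d, "er_dist"))
  switch(d$kind,
    point = rep(d$value, n),
    uniform = stats::runif(n, d$min, d$max),
    empirical = if (n == length(d$values)) d$values else
      sample(d$values, n, replace = TRUE),
    beta = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rbeta(2L * (n - length(out)) + 8L, d$shape1, d$shape2)
        out <- c(out, x[x > d$lower & x < d$upper])
      }
      out[seq_len(n)]
    },
    gamma = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rgamma(2L * (n - length(out)) + 8L, d$shape, d$rate)
        out <- c(out, x[x >= d$lower & x <= d$upper])
      }
      out[seq_len(n)]
    },
    stop_config("unknown distribution kind: ", d$kind)
  )
}

#' Default starting-frequency distribution
#'
#' Beta(7.1, 17.3) truncated to (0.05, 0.95): mean ~0.29 with most mass
#' between 0.1 and 0.5, emulating the intermediate starting frequencies of
#' the selected haplotype-block alleles (rising-allele polarization).
#' @export
default_freq_dist <- function() dist_beta(7.1, 17.3, lower = 0.05, upper = 0.95)

#' Default selection-coefficient distribution
#'
#' Gamma(shape 3) truncated to \[0.04, 0.45\] with rate 23.8, chosen so the
#' truncated mean is 0.133, emulating the estimated per-block selection
#' coefficients (mean 0.133, maximum ~0.37). The lower truncation reflects
#' that the selected blocks are detected alleles, whose estimated effects
#' are bounded away from zero by the detection procedure itself.
#' @export
default_s_dist <- function()
  dist_gamma(shape = 3, rate = 23.8, lower = 0.04, upper = 0.45)

#' Generate a genetic architecture
#'
#' Draws `n_loci` selected loci with starting frequencies from `freq_dist`
#' and selection coefficients from `s_dist`, and assigns genomic positions.
#' Block-level architectures place one locus per haplotype block, blocks
#' spaced 2 Mb apart across `n_scaffolds` scaffolds; SNP-level architectures
#' place `snps_per_block` SNPs within a 50 kb window per block, all SNPs of a
#' block sharing its s and p0 jittered positionally.
#'
#' @param n_loci number of loci (blocks, or SNPs when `level = "snp"` —
#'   then `n_loci` is the number of blocks and total SNPs is
#'   `n_loci * snps_per_block`)
#' @param freq_dist,s_dist `er_dist` specs (see [dist_beta()])
#' @param level `"block"` or `"snp"`
#' @param linkage_mode `"unlinked"` (free recombination) or `"linked"`
#'   (crossovers from physical distance)
#' @param recomb_rate_cM_per_Mb recombination rate used in linked mode
#'   (default 1.6, a copepod genome-wide estimate)
#' @param n_scaffolds scaffolds over which blocks are distributed
#' @param snps_per_block SNPs per block at `level = "snp"` (default 41,
#'   giving 4961 SNPs for 121 blocks, near the empirical 4977)
#' @param seed integer seed; the same seed reproduces the architecture
#' @return an object of class `er_architecture`: list with `loci`
#'   (data.frame: locus_id, block_id, scaffold, position_bp, s, p0),
#'   `n_loci`, `level`, `linkage_mode`, `recomb_rate_cM_per_Mb`
#' @export
gen_architecture <- function(n_loci = 121,
                             freq_dist = default_freq_dist(),
                             s_dist = default_s_dist(),
                             level = c("block", "snp"),
                             linkage_mode = c("unlinked", "linked"),
                             recomb_rate_cM_per_Mb = 1.6,
                             n_scaffolds = 4,
                             snps_per_block = 41,
                             seed = NULL) {
  level <- match.arg(level)
  linkage_mode <- match.arg(linkage_mode)
  if (!is.numeric(n_loci) || n_loci < 1) stop_config("n_loci must be >= 1")
  n_loci <- as.integer(n_loci)
  assert_scalar_num(recomb_rate_cM_per_Mb, "recomb_rate_cM_per_Mb", lower = 0)

  with_seed(seed, {
    n_blocks <- n_loci
    p0_blk <- draw_dist(freq_dist, n_blocks)
    s_blk <- draw_dist(s_dist, n_blocks)
    if (any(p0_blk <= 0 | p0_blk >= 1)) stop_config("p0 must lie in (0, 1)")
    if (any(s_blk < 0)) stop_config("s must be >= 0")
    scaffold <- rep_len(seq_len(n_scaffolds), n_blocks)
    within_idx <- stats::ave(seq_len(n_blocks), scaffold, FUN = seq_along)
    block_pos <- as.integer(within_idx) * 2000000L # blocks >= 1 Mb apart

    if (level == "block") {
      loci <- data.frame(
        locus_id = sprintf("B%03d", seq_len(n_blocks)),
        block_id = sprintf("B%03d", seq_len(n_blocks)),
        scaffold = sprintf("scf%d", scaffold),
        position_bp = block_pos,
        s = s_blk, p0 = p0_blk,
        stringsAsFactors = FALSE
      )
    } else {
      k <- as.integer(snps_per_block)
      off <- sort(sample.int(50000L, k)) # SNPs within a 50 kb block window
      loci <- data.frame(
        locus_id = sprintf("B%03d_S%02d", rep(seq_len(n_blocks), each = k),
                           rep(seq_len(k), n_blocks)),
        block_id = sprintf("B%03d", rep(seq_len(n_blocks), each = k)),
        scaffold = sprintf("scf%d", rep(scaffold, each = k)),
        position_bp = rep(block_pos, each = k) + rep(off, n_blocks),
        s = rep(s_blk, each = k), p0 = rep(p0_blk, each = k),
        stringsAsFactors = FALSE
      )
    }
    ord <- order(loci$scaffold, loci$position_bp)
    loci <- loci[ord, , drop = FALSE]
    rownames(loci) <- NULL
    new_architecture(loci, level, linkage_mode, recomb_rate_cM_per_Mb)
  })
}

new_architecture <- function(loci, level, linkage_mode, recomb_rate) {
  stopifnot(is.data.frame(loci))
  need <- c("locus_id", "block_id", "scaffold", "position_bp", "s", "p0")
  if (!all(need %in% names(loci)))
    stop_config("architecture table must have columns: ",
                paste(need, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) stop_config("locus_id must be unique")
  if (any(loci$p0 <= 0 | loci$p0 >= 1)) stop_config("p0 must lie in (0, 1)")
  if (any(loci$s < 0)) stop_config("s must be >= 0")
  if (level == "block" && anyDuplicated(loci$block_id))
    stop_config("block-level architecture requires one locus per block")
  structure(
    list(loci = loci, n_loci = nrow(loci), level = level,
         linkage_mode = linkage_mode,
         recomb_rate_cM_per_Mb = recomb_rate),
    class = "er_architecture"
  )
}

#' Construct an architecture from an explicit locus table
#'
#' Use this to load empirical per-block values from a table instead of
#' drawing them from distributions.
#' @param loci data.frame with columns locus_id, block_id, scaffold,
#'   position_bp, s, p0
#' @inheritParams gen_architecture
#' @export
architecture <- function(loci, level = c("block", "snp"),
                         linkage_mode = c("unlinked", "linked"),
                         recomb_rate_cM_per_Mb = 1.6) {
  new_architecture(loci, match.arg(level), match.arg(linkage_mode),
                   recomb_rate_cM_per_Mb)
}

#' @export
print.er_architecture <- function(x, ...) {
  cat(sprintf("<er_architecture> %d loci (%s level, %s; %.2f cM/Mb)\n",
              x$n_loci, x$level, x$linkage_mode, x$recomb_rate_cM_per_Mb))
  cat(sprintf("  p0: mean %.3f range [%.3f, %.3f]; s: mean %.3f max %.3f\n",
              mean(x$loci$p0), min(x$loci$p0), max(x$loci$p0),
              mean(x$loci$s), max(x$loci$s)))
  invisible(x)
}

#' Read / write an architecture as TSV
#' @param path file path
#' @param arch an `er_architecture`
#' @inheritParams gen_architecture
#' @export
write_architecture_tsv <- function(arch, path) {
  stopifnot(inherits(arch, "er_architecture"))
  utils::write.table(arch$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_architecture_tsv
#' @export
read_architecture_tsv <- function(path, level = c("block", "snp"),
                                  linkage_mode = c("unlinked", "linked"),
                                  recomb_rate_cM_per_Mb = 1.6) {
  loci <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  architecture(loci, level = level, linkage_mode = linkage_mode,
               recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb)
}

#' Experiment design for a replicated selection experiment
#'
#' Captures the sampling design of an E&R experiment: replicate treatment
#' and control lines evolved from a common starting population, sampled by
#' pooled sequencing at fixed generations. Defaults mirror a 10-generation
#' laboratory selection experiment: 10 treatment lines of which 2 go extinct
#' before the final generation, 4 control lines, sampling at generations
#' 0/6/10, pools of 100 individuals, read coverage bounded \[10, 200\] and
#' effective population size 1750.
#'
#' @param n_treatment_lines,n_control_lines replicate line counts
#' @param n_extinct_at_final treatment lines lost before the final sampled
#'   generation (no final-generation sample)
#' @param sampled_generations integer vector, ascending, starting at 0
#' @param pool_n_individuals individuals pooled per sample (empirical pools
#'   of 50; simulated pools of 100)
#' @param coverage_min,coverage_max per-locus read-depth bounds
#' @param Ne effective (here: census) population size per line
#' @param final_generation last generation of the experiment
#' @return an object of class `er_design`
#' @export
experiment_design <- function(n_treatment_lines = 10, n_control_lines = 4,
                              n_extinct_at_final = 2,
                              sampled_generations = c(0, 6, 10),
                              pool_n_individuals = 100,
                              coverage_min = 10, coverage_max = 200,
                              Ne = 1750, final_generation = 10) {
  sampled_generations <- as.integer(sampled_generations)
  if (is.unsorted(sampled_generations, strictly = TRUE) ||
      sampled_generations[1] != 0L)
    stop_config("sampled_generations must be strictly ascending and start at 0")
  if (n_extinct_at_final < 0 || n_extinct_at_final >= n_treatment_lines)
    stop_config("need 0 <= n_extinct_at_final < n_treatment_lines")
  if (coverage_min < 1 || coverage_max < coverage_min)
    stop_config("invalid coverage bounds")
  assert_scalar_num(Ne, "Ne", lower = 2)
  if (max(sampled_generations) > final_generation)
    stop_config("sampled_generations beyond final_generation")
  structure(
    list(n_treatment_lines = as.integer(n_treatment_lines),
         n_control_lines = as.integer(n_control_lines),
         n_extinct_at_final = as.integer(n_extinct_at_final),
         sampled_generations = sampled_generations,
         pool_n_individuals = as.integer(pool_n_individuals),
         coverage_min = as.integer(coverage_min),
         coverage_max = as.integer(coverage_max),
         Ne = as.integer(Ne),
         final_generation = as.integer(final_generation)),
    class = "er_design"
  )
}

#' @export
print.er_design <- function(x, ...) {
  cat(sprintf(
    "<er_design> %d treatment (+%d extinct by gen %d) / %d control lines\n",
    x$n_treatment_lines, x$n_extinct_at_final, x$final_generation,
    x$n_control_lines))
  cat(sprintf("  sampled generations: %s; pool %d; coverage [%d, %d]; Ne %d\n",
              paste(x$sampled_generations, collapse = ", "),
              x$pool_n_individuals, x$coverage_min, x$coverage_max, x$Ne))
  invisible(x)
}
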