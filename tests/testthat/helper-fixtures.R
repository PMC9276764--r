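# Shared fixture builders (everything is generated in code; no stored data).

# equal-effect architecture on a single scaffold
equal_arch <- function(n_loci, s = 0.1, p0 = 0.3, spacing_bp = 2e6,
                       linkage_mode = "unlinked", scaffold = NULL) {
  architecture(data.frame(
    locus_id = sprintf("L%04d", seq_len(n_loci)),
    block_id = sprintf("L%04d", seq_len(n_loci)),
    scaffold = scaffold %||% rep("scf1", n_loci),
    position_bp = seq_len(n_loci) * spacing_bp,
    s = rep_len(s, n_loci), p0 = rep_len(p0, n_loci),
    stringsAsFactors = FALSE
  ), linkage_mode = linkage_mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# haploid-style genotype: k loci homozygous for the beneficial allele
haploid_genotype <- function(k, n_loci) {
  g <- rep(0L, n_loci)
  if (k > 0) g[seq_len(k)] <- 2L
  g
}

# construct an er_calls object directly from a logical matrix
# (lines x loci), one generation
calls_from_matrix <- function(m, generation = 10, q = 0.999) {
  df <- data.frame(
    line = rep(rownames(m), ncol(m)),
    locus_id = rep(colnames(m), each = nrow(m)),
    generation = generation,
    delta_p = as.vector(m) * 0.1,
    threshold = 0.05,
    called = as.vector(m),
    stringsAsFactors = FALSE
  )
  structure(df, q = q, class = c("er_calls", "data.frame"))
}

# flat trajectories with treatment and control lines (for LMM edge cases)
flat_traj_with_controls <- function(p0 = 0.3, n_loci = 3) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  mk <- function(ln, trt) data.frame(
    line = ln, treatment = trt, generation = rep(c(6L, 10L), each = n_loci),
    locus_id = rep(loci, 2), block_id = rep(loci, 2),
    alt_count = as.integer(round(p0 * 1000)), coverage = 1000L,
    pool_n = 1000L, freq = round(p0 * 1000) / 1000)
  base <- data.frame(
    line = rep(c("S0a", "S0b"), each = n_loci), treatment = NA,
    generation = 0L, locus_id = rep(loci, 2), block_id = rep(loci, 2),
    alt_count = as.integer(round(p0 * 1000)), coverage = 1000L,
    pool_n = 1000L, freq = round(p0 * 1000) / 1000)
  trt <- do.call(rbind, lapply(paste0("T0", 1:3), mk, trt = TRUE))
  ctl <- do.call(rbind, lapply(paste0("C0", 1:3), mk, trt = FALSE))
  erparallel:::new_trajectories(rbind(base, trt, ctl))
}

# small fast design for pipeline-level tests
small_design <- function(...) {
  experiment_design(n_treatment_lines = 4, n_control_lines = 2,
                    n_extinct_at_final = 0, sampled_generations = c(0, 6, 10),
                    pool_n_individuals = 50, Ne = 300, ...)
}
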