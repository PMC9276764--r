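# helper: hand-built trajectory table following deterministic frequencies
traj_from_freqs <- function(freqs, p0, coverage = 1000, pool_n = 1000) {
  # freqs: list line -> data.frame(generation, matrix of loci freqs)
  loci <- colnames(freqs[[1]]$f)
  rows <- list()
  for (s0 in c("S0a", "S0b")) {
    rows[[length(rows) + 1]] <- data.frame(
      line = s0, treatment = NA, generation = 0L, locus_id = loci,
      block_id = loci, alt_count = as.integer(round(p0 * coverage)),
      coverage = as.integer(coverage), pool_n = as.integer(pool_n),
      freq = round(p0 * coverage) / coverage)
  }
  for (ln in names(freqs)) {
    fr <- freqs[[ln]]
    for (k in seq_along(fr$generation)) {
      f <- fr$f[k, ]
      rows[[length(rows) + 1]] <- data.frame(
        line = ln, treatment = fr$treatment, generation = fr$generation[k],
        locus_id = loci, block_id = loci,
        alt_count = as.integer(round(f * coverage)),
        coverage = as.integer(coverage), pool_n = as.integer(pool_n),
        freq = round(f * coverage) / coverage)
    }
  }
  erparallel:::new_trajectories(do.call(rbind, rows))
}

flat_traj <- function(p0 = 0.3, n_loci = 4, lines = paste0("T0", 1:3)) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  f <- matrix(p0, 2, n_loci, dimnames = list(NULL, loci))
  traj_from_freqs(
    setNames(lapply(lines, function(l)
      list(generation = c(6L, 10L), f = f, treatment = TRUE)), lines),
    p0 = rep(p0, n_loci))
}

fake_nq <- function(loci, p0, thresholds, generations = c(6, 10)) {
  df <- expand.grid(locus_id = loci, generation = generations,
                    stringsAsFactors = FALSE)
  df$p0 <- p0[match(df$locus_id, loci)]
  df$threshold <- thresholds[match(df$generation, generations)]
  structure(df[, c("locus_id", "p0", "generation", "threshold")],
            q = 0.999, n_iter = 1000, Ne = 1750,
            class = c("er_neutral_quantiles", "data.frame"))
}

test_that("flat trajectories yield zero selection calls", {
  tr <- flat_traj()
  nq <- fake_nq(sprintf("L%02d", 1:4), rep(0.3, 4), c(0.05, 0.075))
  calls <- call_selected(tr, nq)
  expect_equal(sum(calls$called), 0)
})

test_that("a deterministic rise beyond the threshold is called", {
  loci <- c("L01", "L02")
  f6 <- matrix(c(0.8, 0.31), 1, 2, dimnames = list(NULL, loci))
  tr <- traj_from_freqs(list(
    T01 = list(generation = c(6L, 10L),
               f = rbind(f6, c(0.8, 0.32)), treatment = TRUE),
    T02 = list(generation = c(6L, 10L),
               f = rbind(f6, c(0.8, 0.32)), treatment = TRUE)),
    p0 = c(0.3, 0.3))
  nq <- fake_nq(loci, c(0.3, 0.3), c(0.075, 0.075))
  calls <- call_selected(tr, nq)
  # rise of 0.5 called everywhere; rise of 0.01-0.02 nowhere
  expect_true(all(calls$called[calls$locus_id == "L01"]))
  expect_false(any(calls$called[calls$locus_id == "L02"]))
  # monotone in observed delta_p at fixed threshold
  g10 <- calls[calls$generation == 10, ]
  expect_true(all(tapply(seq_len(nrow(g10)), g10$line, function(i)
    !is.unsorted(g10$called[i][order(g10$delta_p[i])]))))
  # missing thresholds are an error
  nq_partial <- fake_nq("L01", 0.3, c(0.075, 0.075))
  expect_error(call_selected(tr, nq_partial), "missing neutral threshold")
})

test_that("final-generation thresholds are the default and per-generation optional", {
  loci <- "L01"
  tr <- traj_from_freqs(list(
    T01 = list(generation = c(6L, 10L),
               f = matrix(c(0.36, 0.36), 2, 1, dimnames = list(NULL, loci)),
               treatment = TRUE),
    T02 = list(generation = c(6L, 10L),
               f = matrix(c(0.36, 0.36), 2, 1, dimnames = list(NULL, loci)),
               treatment = TRUE)), p0 = 0.3)
  nq <- fake_nq(loci, 0.3, c(0.05, 0.075)) # gen-6 thr 0.05, gen-10 thr 0.075
  # delta_p = 0.06: below the final-generation threshold
  expect_equal(sum(call_selected(tr, nq)$called), 0)
  # but above the generation-6 threshold under matched thresholds
  calls_m <- call_selected(tr, nq, threshold_generation = "match")
  expect_equal(sum(calls_m$called[calls_m$generation == 6]), 2)
})

test_that("the logit slope of a noiseless logistic trajectory recovers s exactly", {
  s <- 0.15; p0 <- 0.2
  gens <- c(0, 6, 10)
  p_t <- p0 * exp(s * gens) / (1 - p0 + p0 * exp(s * gens))
  loci <- "L01"
  tr <- traj_from_freqs(list(
    T01 = list(generation = c(6L, 10L),
               f = matrix(p_t[2:3], 2, 1, dimnames = list(NULL, loci)),
               treatment = TRUE)),
    p0 = p_t[1], coverage = 1e6, pool_n = 1e6)
  est <- estimate_s(tr, use_random_line_effect = FALSE, scaling = "slope")
  expect_equal(est$s_hat, s, tolerance = 1e-4)
  # codominant scaling doubles the slope
  est2 <- estimate_s(tr, use_random_line_effect = FALSE)
  expect_equal(est2$s_hat, 2 * s, tolerance = 1e-4)
  # flat trajectory: slope 0
  est0 <- estimate_s(flat_traj(), use_random_line_effect = FALSE)
  expect_true(all(abs(est0$s_hat) < 1e-9))
})

test_that("the two selection-coefficient estimators agree on simulated data", {
  arch <- gen_architecture(n_loci = 60, seed = 21)
  design <- experiment_design(n_treatment_lines = 8, n_control_lines = 2,
                              n_extinct_at_final = 0, Ne = 1750)
  traj <- gen_experiment(arch, design, fitness_model("multiplicative"),
                         seed = 22)
  e_mixed <- estimate_s(traj, use_random_line_effect = TRUE)
  e_plain <- estimate_s(traj, use_random_line_effect = FALSE)
  expect_equal(e_mixed$locus_id, e_plain$locus_id)
  expect_gt(cor(e_mixed$s_hat, e_plain$s_hat), 0.7)
  # both should track the generating coefficients
  truth <- arch$loci$s[match(e_mixed$locus_id, arch$loci$locus_id)]
  expect_gt(cor(e_mixed$s_hat, truth), 0.6)
})

test_that("drift-adjusted CMH reduces to the classical CMH without overdispersion", {
  # independent baselines per stratum, Ne and pools -> Inf
  set.seed(31)
  K <- 6
  x0 <- rbinom(K, 80, 0.3); xt <- rbinom(K, 90, 0.45)
  n0 <- rep(80, K); nt <- rep(90, K)
  stat <- erparallel:::cmh_drift_stat(
    x0, n0, xt, nt, t = rep(10, K), line = paste0("T", 1:K),
    Ne = 1e12, pool0 = Inf, poolt = Inf, shared_baseline = FALSE)
  tab <- array(0, c(2, 2, K))
  for (k in 1:K) {
    tab[, , k] <- rbind(c(xt[k], nt[k] - xt[k]), c(x0[k], n0[k] - x0[k]))
  }
  classical <- mantelhaen.test(tab, correct = FALSE)$statistic
  expect_equal(stat, unname(classical), tolerance = 1e-6)
})

test_that("CMH and chi-square tests are near-null on unchanged frequencies", {
  tr <- flat_traj(p0 = 0.3, n_loci = 5)
  res <- cmh_drift_test(tr, Ne = 1750)
  expect_true(all(res$statistic < 0.5))
  expect_true(all(res$p_value > 0.4))
  res1 <- chisq_line_test(tr, Ne = 1750, line = "T01")
  expect_true(all(res1$p_value > 0.4))
  expect_error(cmh_drift_test(tr, Ne = -5), "Ne")
})

test_that("a strong deterministic rise is highly significant in a single line", {
  loci <- "L01"
  # s = 0.3-style rise over 10 generations at coverage ~ hundreds
  tr <- traj_from_freqs(list(
    T01 = list(generation = c(6L, 10L),
               f = matrix(c(0.55, 0.7), 2, 1, dimnames = list(NULL, loci)),
               treatment = TRUE)),
    p0 = 0.3, coverage = 300, pool_n = 1000)
  res <- chisq_line_test(tr, Ne = 1750, line = "T01")
  expect_lt(res$p_value, 1e-3)
})

test_that("drift-adjusted tests hold their type-I error under the neutral null", {
  arch <- equal_arch(800, s = 0, p0 = 0.4)
  design <- experiment_design(n_treatment_lines = 8, n_control_lines = 2,
                              n_extinct_at_final = 0, Ne = 1750)
  traj <- gen_experiment(arch, design, fitness_model("multiplicative"),
                         seed = 41)
  res <- cmh_drift_test(traj, Ne = 1750)
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("LMM treatment test is null-calibrated and detects real treatment effects", {
  # null: treatment and control both neutral
  arch <- equal_arch(250, s = 0, p0 = 0.4)
  design <- experiment_design(n_treatment_lines = 8, n_control_lines = 6,
                              n_extinct_at_final = 0, Ne = 1750)
  traj <- gen_experiment(arch, design, fitness_model("multiplicative"),
                         seed = 51)
  res <- suppressWarnings(lmm_treatment_test(traj))
  lrt <- res$statistic[!is.na(res$statistic)]
  ks <- ks.test(lrt, pchisq, df = 2)
  expect_gt(ks$p.value, 0.01)
  # power: s = 0.2 treatment effect is detected for most loci
  arch_s <- equal_arch(60, s = 0.2, p0 = 0.3)
  traj_s <- gen_experiment(arch_s, design, fitness_model("multiplicative"),
                           seed = 52)
  res_s <- suppressWarnings(lmm_treatment_test(traj_s))
  expect_gt(mean(res_s$p_value < 0.05, na.rm = TRUE), 0.8)
  # all-identical frequencies: LRT collapses to 0
  res0 <- suppressWarnings(lmm_treatment_test(flat_traj_with_controls()))
  expect_true(all(res0$statistic < 1e-6))
})

test_that("BH adjustment reproduces the arithmetic and controls the FDR", {
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(61)
  p <- runif(1e4)
  q <- fdr_adjust(p)
  expect_true(all(q[order(p)] == cummax(q[order(p)])))
  expect_lte(mean(q < 0.05), 0.05 * (1 + 3 * sqrt(0.05 * 0.95 / 1e4) / 0.05))
  expect_error(fdr_adjust(c(0.5, 2)), "\\[0, 1\\]")
})
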