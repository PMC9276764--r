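# Selection inference from replicated allele-frequency time series:
# neutral-quantile selection calls, selection-coefficient estimation,
# drift-adjusted CMH / chi-square tests, treatment-vs-control LMM test.

baseline_freqs <- function(traj) {
  base <- traj[is.na(traj$treatment), , drop = FALSE]
  if (nrow(base) == 0) return(NULL)
  agg <- stats::aggregate(freq ~ locus_id, data = base, FUN = mean)
  stats::setNames(agg$freq, agg$locus_id)
}

# combined baseline counts per locus (summed over the duplicate samples)
baseline_counts <- function(traj) {
  base <- traj[is.na(traj$treatment) & !is.na(traj$coverage), , drop = FALSE]
  if (nrow(base) == 0) return(NULL)
  x <- stats::aggregate(cbind(alt_count, coverage, pool_n) ~ locus_id,
                        data = base, FUN = sum)
  x
}

#' Call selected alleles against neutral drift thresholds
#'
#' An allele is called selected in a line at a sampled generation when its
#' observed frequency increase over the experiment-wide baseline exceeds the
#' neutral `q`-quantile threshold for its starting frequency and that
#' generation (one-sided: increases only). The baseline frequency is the
#' mean of the duplicate generation-zero samples when present, otherwise the
#' `p0` recorded in the thresholds.
#'
#' @param traj an `er_trajectories`
#' @param nq an `er_neutral_quantiles` covering every locus and sampled
#'   generation in `traj`
#' @param lines lines to call (default: all treatment lines)
#' @param threshold_generation `"final"` (default) applies the
#'   final-generation neutral threshold at every timepoint (thresholds
#'   calibrated at generation ten, as in the empirical calling procedure
#'   this emulates); `"match"` uses each timepoint's own
#'   generation-specific threshold
#' @return object of class `er_calls`: data.frame (line, locus_id,
#'   generation, delta_p, threshold, called) with attribute `q`
#' @export
call_selected <- function(traj, nq, lines = NULL,
                          threshold_generation = c("final", "match")) {
  stopifnot(inherits(traj, "er_trajectories"),
            inherits(nq, "er_neutral_quantiles"))
  threshold_generation <- match.arg(threshold_generation)
  p0 <- baseline_freqs(traj)
  if (is.null(p0)) p0 <- stats::setNames(nq$p0, nq$locus_id)
  obs <- traj[!is.na(traj$treatment) & traj$treatment & traj$generation > 0, ,
              drop = FALSE]
  if (!is.null(lines)) obs <- obs[obs$line %in% lines, , drop = FALSE]
  thr_gen <- if (threshold_generation == "final")
    rep(max(nq$generation), nrow(obs)) else obs$generation
  key_obs <- paste(obs$locus_id, thr_gen)
  key_thr <- paste(nq$locus_id, nq$generation)
  idx <- match(key_obs, key_thr)
  if (anyNA(idx)) {
    miss <- unique(key_obs[is.na(idx)])
    stop_config("missing neutral threshold for: ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  if (anyNA(match(obs$locus_id, names(p0))))
    stop_config("missing baseline frequency for some loci")
  delta_p <- obs$freq - unname(p0[obs$locus_id])
  out <- data.frame(line = obs$line, locus_id = obs$locus_id,
                    generation = obs$generation, delta_p = delta_p,
                    threshold = nq$threshold[idx],
                    called = delta_p > nq$threshold[idx],
                    stringsAsFactors = FALSE)
  structure(out, q = attr(nq, "q"),
            class = c("er_calls", "data.frame"))
}

#' @export
print.er_calls <- function(x, ...) {
  per <- stats::aggregate(called ~ line + generation, data = x, FUN = sum)
  cat(sprintf("<er_calls> q = %s; selected per line x generation:\n",
              format(attr(x, "q"))))
  for (g in sort(unique(per$generation))) {
    v <- per$called[per$generation == g]
    cat(sprintf("  gen %2d: mean %.1f (range %d-%d) over %d lines\n",
                g, mean(v), min(v), max(v), length(v)))
  }
  invisible(x)
}

#' Per-line selected-allele sets at a generation
#' @param calls an `er_calls`
#' @param generation generation to extract
#' @return named list of locus-id character vectors, one per line
#' @export
selected_sets <- function(calls, generation) {
  cc <- calls[calls$generation == generation, , drop = FALSE]
  if (nrow(cc) == 0) stop_config("no calls at generation ", generation)
  lapply(split(cc, cc$line), function(d) d$locus_id[d$called])
}

#' Estimate per-locus selection coefficients from frequency trajectories
#'
#' Fits, per locus, a linear regression of logit-transformed allele
#' frequencies on generation across the treatment lines (generation-zero
#' frequency taken from the duplicate baseline samples, shared across
#' lines). With `use_random_line_effect = TRUE` the fit is a linear mixed
#' model with a random line intercept and weights proportional to the
#' effective number of allele copies (`N_eff`), fitted by maximum
#' likelihood; otherwise unweighted per-line slopes are averaged.
#'
#' Frequencies are squeezed to `[1/(2*N_eff + 2), 1 - 1/(2*N_eff + 2)]`
#' before the logit. Under the codominant diploid Wright-Fisher model
#' (genotype fitnesses 1, 1 + s/2, 1 + s) the expected logit slope per
#' generation is s/2, so the default `scaling = "codominant"` reports twice
#' the slope; `scaling = "slope"` reports the raw logit slope (appropriate
#' for haploid/genic trajectories where the allele ratio grows by (1+s) per
#' generation).
#'
#' @param traj an `er_trajectories`
#' @param use_random_line_effect logical; see above
#' @param scaling `"codominant"` (default) or `"slope"`
#' @return data.frame (locus_id, s_hat, se, n_lines); loci whose
#'   frequencies are fixed at 0 or 1 everywhere get `NA` estimates
#' @export
estimate_s <- function(traj, use_random_line_effect = TRUE,
                       scaling = c("codominant", "slope")) {
  stopifnot(inherits(traj, "er_trajectories"))
  scaling <- match.arg(scaling)
  mult <- if (scaling == "codominant") 2 else 1

  obs <- traj[!is.na(traj$treatment) & traj$treatment & traj$generation > 0, ,
              drop = FALSE]
  if (nrow(obs) == 0) stop_config("no treatment observations")
  lines <- unique(obs$line)
  bl <- traj[is.na(traj$treatment), , drop = FALSE]
  if (nrow(bl) > 0) {
    # shared generation-0 record replicated into every line
    bl_comb <- stats::aggregate(cbind(freq = freq) ~ locus_id, data = bl,
                                FUN = mean)
    neff0 <- if (!anyNA(bl$coverage)) {
      bl$ne0 <- n_eff(bl$pool_n, bl$coverage)
      agg <- stats::aggregate(ne0 ~ locus_id, data = bl, FUN = sum)
      stats::setNames(agg$ne0, agg$locus_id)
    } else NULL
    base_rows <- do.call(rbind, lapply(lines, function(ln)
      data.frame(line = ln, generation = 0L, locus_id = bl_comb$locus_id,
                 freq = bl_comb$freq,
                 neff = if (is.null(neff0)) NA_real_ else
                   unname(neff0[bl_comb$locus_id]),
                 stringsAsFactors = FALSE)))
  } else base_rows <- NULL

  obs_rows <- data.frame(line = obs$line, generation = obs$generation,
                         locus_id = obs$locus_id, freq = obs$freq,
                         neff = ifelse(is.na(obs$coverage), NA_real_,
                                       n_eff(ifelse(is.na(obs$pool_n), 1e6,
                                                    obs$pool_n),
                                             ifelse(is.na(obs$coverage), 1e6,
                                                    obs$coverage))),
                         stringsAsFactors = FALSE)
  dat <- rbind(base_rows, obs_rows)
  dat$neff[is.na(dat$neff)] <- 1000 # true-frequency records: flat weights

  out <- lapply(split(dat, dat$locus_id), function(d) {
    fixed <- all(d$freq %in% c(0, 1)) &&
      (all(d$freq == 0) || all(d$freq == 1))
    if (fixed)
      return(data.frame(locus_id = d$locus_id[1], s_hat = NA_real_,
                        se = NA_real_, n_lines = length(unique(d$line))))
    d$y <- logit(squeeze_freq(d$freq, d$neff))
    if (use_random_line_effect && length(unique(d$line)) > 1) {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ generation + (1 | line), data = d, weights = d$neff,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      co <- summary(fit)$coefficients
      slope <- co["generation", "Estimate"]
      se <- co["generation", "Std. Error"]
    } else {
      slopes <- vapply(split(d, d$line), function(dd) {
        if (length(unique(dd$generation)) < 2) return(NA_real_)
        stats::coef(stats::lm(y ~ generation, data = dd))[["generation"]]
      }, numeric(1))
      slopes <- slopes[!is.na(slopes)]
      slope <- mean(slopes)
      se <- if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes))
            else NA_real_
    }
    data.frame(locus_id = d$locus_id[1], s_hat = mult * slope,
               se = mult * se, n_lines = length(unique(d$line)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_test_result <- function(locus_id, statistic, p_value, test_name) {
  data.frame(locus_id = locus_id, statistic = statistic, p_value = p_value,
             q_value = fdr_adjust(p_value), test_name = test_name,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values vector of p-values in \[0, 1\]
#' @return BH-adjusted values (monotone in p-value rank)
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Core of the drift-adjusted stratified test for ONE locus.
# Each stratum is a (baseline vs timepoint-t) 2x2 count table within a line.
# The classical CMH deviation a - E[a] equals c * (p_t - p_0) with
# c = n0*nt/(n0+nt); the statistic is (sum dev)^2 / Var(sum dev) where the
# variance sums the hypergeometric stratum variances plus drift variance
# p(1-p)(1 - (1 - 1/(2Ne))^t), founder-sampling rounds (the baseline
# population and each replicate line are independent binomial draws of 2Ne
# copies from the shared source frequencies), Pool-seq pool-stage variance
# at both timepoints, and the covariances induced by the shared drift path
# within a line and by a shared baseline sample across strata.
cmh_drift_stat <- function(x0, n0, xt, nt, t, line, Ne,
                           pool0 = Inf, poolt = Inf,
                           shared_baseline = FALSE,
                           founder_rounds = 0) {
  K <- length(xt)
  stopifnot(length(x0) == K, length(n0) == K, length(nt) == K,
            length(t) == K, length(line) == K)
  if (Ne <= 0) stop_config("Ne must be > 0")
  x0 <- as.numeric(x0); n0 <- as.numeric(n0)
  xt <- as.numeric(xt); nt <- as.numeric(nt)
  poolt <- rep_len(poolt, K)
  pool0 <- rep_len(pool0, K)
  cc <- n0 * nt / (n0 + nt)
  dev <- cc * (xt / nt - x0 / n0)
  S <- x0 + xt
  NT <- n0 + nt
  v_hyper <- n0 * nt * S * (NT - S) / (NT^2 * pmax(NT - 1, 1))
  pt_hat <- S / NT
  pq <- pt_hat * (1 - pt_hat)
  drift <- function(tt) 1 - (1 - 1 / (2 * Ne))^tt
  fpc <- function(m) ifelse(is.finite(m), pmax(0, 1 - (2 * m) / (2 * Ne)), 0)
  pool_var_t <- ifelse(is.finite(poolt), pq / (2 * poolt) * fpc(poolt), 0)
  pool_var_0 <- ifelse(is.finite(pool0), pq / (2 * pool0) * fpc(pool0), 0)
  founder <- founder_rounds / (2 * Ne)
  V <- diag(v_hyper + cc^2 * (pq * (drift(t) + founder) +
                                pool_var_t + pool_var_0), K, K)
  if (K > 1) {
    p_bar <- sum(xt + x0) / sum(nt + n0)
    pq_bar <- p_bar * (1 - p_bar)
    base_founder <- if (founder_rounds > 0) 1 / (2 * Ne) else 0
    for (k in 1:(K - 1)) for (l in (k + 1):K) {
      cov_kl <- 0
      if (shared_baseline)
        cov_kl <- cov_kl + pq_bar * (1 / n0[k] + base_founder +
          (if (is.finite(pool0[k])) fpc(pool0[k]) / (2 * pool0[k]) else 0))
      if (line[k] == line[l])
        cov_kl <- cov_kl + pq_bar * (drift(min(t[k], t[l])) + founder)
      V[k, l] <- V[l, k] <- cc[k] * cc[l] * cov_kl
    }
  }
  denom <- sum(V)
  stat <- if (denom > 0) sum(dev)^2 / denom else 0
  stat
}

# build per-locus strata from a trajectory table
build_strata <- function(traj, lines) {
  base <- baseline_counts(traj)
  use_counts <- !is.null(base)
  obs <- traj[traj$line %in% lines & traj$generation > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop_config("no post-baseline observations for ",
                                  paste(lines, collapse = ","))
  if (anyNA(obs$coverage)) {
    # true-frequency records: treat frequencies as counts at a nominal depth
    obs$coverage <- 1000L
    obs$alt_count <- round(obs$freq * 1000)
    obs$pool_n <- NA_integer_
  }
  if (!use_counts) {
    p0 <- baseline_freqs(traj)
    if (is.null(p0)) stop_config("no baseline records in trajectory table")
    base <- data.frame(locus_id = names(p0), alt_count = round(p0 * 1000),
                       coverage = 1000L, pool_n = NA_integer_)
  }
  list(obs = obs, base = base)
}

#' Drift-adjusted CMH test across replicate lines and timepoints
#'
#' Stratified test of allele-frequency change from the shared baseline,
#' one stratum per line x post-baseline timepoint, with stratum variances
#' inflated for genetic drift (`p(1-p)(1 - (1 - 1/(2Ne))^t)`) and two-stage
#' Pool-seq sampling, and stratum covariances for the shared drift path
#' within a line and the shared baseline sample. The statistic is referred
#' to chi-square with 1 df. As `Ne -> Inf` and pool sizes `-> Inf` with
#' independent baselines it reduces to the classical
#' Cochran-Mantel-Haenszel statistic.
#'
#' @param traj an `er_trajectories` with >= 2 replicate lines and >= 2
#'   timepoints
#' @param Ne effective population size used for the drift variance
#' @param lines lines to include (default: all treatment lines)
#' @param founder_rounds binomial sampling rounds separating a line from the
#'   sequenced baseline population besides drift: the default 2 counts the
#'   founding of the baseline population and the founding of each replicate
#'   line as independent draws of 2*Ne allele copies from the shared source
#'   (set 0 when the baseline was sequenced from the lines' common ancestor
#'   population itself)
#' @return data.frame (locus_id, statistic, p_value, q_value, test_name)
#' @export
cmh_drift_test <- function(traj, Ne, lines = NULL, founder_rounds = 2) {
  stopifnot(inherits(traj, "er_trajectories"))
  assert_scalar_num(Ne, "Ne", lower = 1e-9)
  lines <- lines %||%
    unique(traj$line[!is.na(traj$treatment) & traj$treatment])
  if (length(lines) < 2) stop_config("need >= 2 replicate lines")
  st <- build_strata(traj, lines)
  if (length(unique(st$obs$generation)) < 2)
    stop_config("need >= 2 post-baseline timepoints")
  per_locus_stat(st, Ne, "CMH_drift", founder_rounds)
}

#' Single-line drift-adjusted chi-square test
#'
#' Line-specific analogue of [cmh_drift_test()]: the strata are the
#' post-baseline timepoints of one line.
#' @inheritParams cmh_drift_test
#' @param line the line to test
#' @export
chisq_line_test <- function(traj, Ne, line, founder_rounds = 2) {
  stopifnot(inherits(traj, "er_trajectories"))
  assert_scalar_num(Ne, "Ne", lower = 1e-9)
  st <- build_strata(traj, line)
  per_locus_stat(st, Ne, paste0("chisq_", line), founder_rounds)
}

per_locus_stat <- function(st, Ne, test_name, founder_rounds = 2) {
  obs <- st$obs
  base <- st$base
  b_idx <- match(obs$locus_id, base$locus_id)
  if (anyNA(b_idx)) stop_config("baseline missing for some loci")
  stats_out <- vapply(split(seq_len(nrow(obs)), obs$locus_id), function(ii) {
    k <- b_idx[ii][1]
    cmh_drift_stat(
      x0 = rep(base$alt_count[k], length(ii)),
      n0 = rep(base$coverage[k], length(ii)),
      xt = obs$alt_count[ii], nt = obs$coverage[ii],
      t = obs$generation[ii], line = obs$line[ii], Ne = Ne,
      pool0 = if (is.na(base$pool_n[k])) Inf else base$pool_n[k],
      poolt = ifelse(is.na(obs$pool_n[ii]), Inf, obs$pool_n[ii]),
      shared_baseline = TRUE, founder_rounds = founder_rounds)
  }, numeric(1))
  new_test_result(names(stats_out), unname(stats_out),
                  stats::pchisq(unname(stats_out), df = 1,
                                lower.tail = FALSE),
                  test_name)
}

#' Treatment-vs-control linear mixed-model test
#'
#' Per locus, the response is the angular-transformed frequency change from
#' baseline, `asin(sqrt(p_t)) - asin(sqrt(p_0))`, for every surviving line
#' and post-baseline generation, weighted by `N_eff`. Two maximum-likelihood
#' fits are compared by likelihood ratio: `y ~ generation + (1|line)` versus
#' `y ~ generation + treatment + generation:treatment + (1|line)` (generation
#' and treatment as factors); the LRT statistic is referred to chi-square
#' with 2 df. Loci with singular or failed fits get `NA` and are flagged via
#' a warning.
#'
#' @param traj an `er_trajectories` with treatment and control lines and the
#'   duplicate baseline samples
#' @return data.frame (locus_id, statistic, p_value, q_value, test_name)
#' @export
lmm_treatment_test <- function(traj) {
  stopifnot(inherits(traj, "er_trajectories"))
  p0 <- baseline_freqs(traj)
  if (is.null(p0)) stop_config("baseline samples required")
  obs <- traj[!is.na(traj$treatment) & traj$generation > 0, , drop = FALSE]
  if (length(unique(obs$line[obs$treatment])) < 2 ||
      length(unique(obs$line[!obs$treatment])) < 2)
    stop_config("need >= 2 treatment and >= 2 control lines")
  obs$y <- asin(sqrt(obs$freq)) - asin(sqrt(unname(p0[obs$locus_id])))
  obs$w <- ifelse(is.na(obs$coverage), 1000,
                  n_eff(ifelse(is.na(obs$pool_n), 1e6, obs$pool_n),
                        obs$coverage))
  obs$gen_f <- factor(obs$generation)
  obs$trt_f <- factor(obs$treatment, levels = c(FALSE, TRUE))
  n_bad <- 0L
  res <- vapply(split(obs, obs$locus_id), function(d) {
    if (stats::var(d$y) == 0) return(0) # no change anywhere: LRT is 0
    out <- tryCatch({
      m1 <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ gen_f + (1 | line), data = d, weights = d$w,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))))
      m2 <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ gen_f + trt_f + gen_f:trt_f + (1 | line), data = d,
                   weights = d$w, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))))
      max(0, 2 * (as.numeric(stats::logLik(m2)) -
                    as.numeric(stats::logLik(m1))))
    }, error = function(e) NA_real_)
    out
  }, numeric(1))
  n_bad <- sum(is.na(res))
  if (n_bad > 0)
    warning(n_bad, " loci had singular/failed mixed-model fits (NA returned)")
  new_test_result(names(res), unname(res),
                  stats::pchisq(unname(res), df = 2, lower.tail = FALSE),
                  "LMM_LRT")
}
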