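# Sequential approximate Bayesian computation for the epistasis strength.
#
# The target statistics are the mean pairwise Jaccard indices at the two
# post-baseline sampled generations; the simulator maps a candidate alpha
# to the same pair of statistics by simulating a full experiment ensemble.
# The sequential scheme is an adaptive population-Monte-Carlo ABC in the
# style of Lenormand et al.: at every step the best half of the particle
# cloud (by Euclidean distance to the target) is retained, new particles
# are proposed by weighted resampling plus Gaussian perturbation (kernel
# variance twice the weighted variance of the retained cloud, reflected at
# the prior bounds), and the algorithm stops when fewer than `p_acc_min` of
# the proposals improve on the previous tolerance.

weighted_var <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sum(w * (x - mu)^2)
}

#' Estimate the epistasis strength alpha by sequential ABC
#'
#' @param target numeric vector of observed summary statistics (mean
#'   Jaccard at generations six and ten)
#' @param simulator function(alpha) returning a numeric vector of the same
#'   length as `target`; stochastic. Errors or non-finite values reject the
#'   particle with a warning.
#' @param prior uniform prior bounds for alpha (default \[0, 50\])
#' @param n_particles particle cloud size per wave (the retained posterior
#'   sample has `round(keep_frac * n_particles)` particles)
#' @param keep_frac fraction of the cloud retained each step (default 0.5)
#' @param p_acc_min stopping threshold on the proposal acceptance rate
#'   (default 0.05: stop when < 5% of new particles improve on the previous
#'   tolerance)
#' @param max_steps hard cap on refinement steps
#' @param seed integer seed (simulator calls consume the session RNG stream
#'   seeded from it)
#' @return object of class `er_abc`: list with `alphas`, `weights`
#'   (normalized), `point_estimate` (weighted mean), `prior`, `steps`,
#'   `eps_history`, `p_acc_history`, `target`
#' @export
abc_estimate_alpha <- function(target, simulator, prior = c(0, 50),
                               n_particles = 200, keep_frac = 0.5,
                               p_acc_min = 0.05, max_steps = 50,
                               seed = NULL) {
  stopifnot(is.numeric(target), length(prior) == 2, prior[1] < prior[2])
  if (any(!is.finite(target))) stop_config("target must be finite")
  n_keep <- max(2L, round(keep_frac * n_particles))
  sim_safe <- function(a) {
    out <- tryCatch(simulator(a), error = function(e) {
      warning("simulator failed at alpha = ", format(a), ": ",
              conditionMessage(e))
      rep(NA_real_, length(target))
    })
    if (length(out) != length(target) || any(!is.finite(out)))
      return(Inf)
    sqrt(sum((out - target)^2))
  }
  reflect <- function(x) {
    lo <- prior[1]; hi <- prior[2]; span <- hi - lo
    x <- abs(x - lo) %% (2 * span)
    lo + ifelse(x > span, 2 * span - x, x)
  }
  with_seed(seed, {
    alphas <- stats::runif(n_particles, prior[1], prior[2])
    d <- vapply(alphas, sim_safe, numeric(1))
    ord <- order(d)[seq_len(n_keep)]
    alphas <- alphas[ord]
    d <- d[ord]
    w <- rep(1 / n_keep, n_keep)
    eps <- max(d[is.finite(d)], 0)
    eps_hist <- eps
    pacc_hist <- numeric(0)
    steps <- 0L
    n_new <- n_particles - n_keep
    while (steps < max_steps && n_new > 0) {
      steps <- steps + 1L
      sd_k <- sqrt(max(2 * weighted_var(alphas, w), 1e-12))
      idx <- sample.int(n_keep, n_new, replace = TRUE, prob = w)
      prop <- reflect(alphas[idx] + stats::rnorm(n_new, 0, sd_k))
      d_new <- vapply(prop, sim_safe, numeric(1))
      p_acc <- mean(d_new < eps)
      pacc_hist <- c(pacc_hist, p_acc)
      all_a <- c(alphas, prop)
      all_d <- c(d, d_new)
      ord <- order(all_d)[seq_len(n_keep)]
      # PMC importance weights against the previous cloud's proposal
      # mixture, recomputed for the whole retained cloud so weight scales
      # stay comparable across steps (uniform prior cancels)
      w_prev <- w
      a_prev <- alphas
      alphas <- all_a[ord]
      d <- all_d[ord]
      dens <- vapply(alphas, function(a)
        sum(w_prev * stats::dnorm(a, a_prev, sd_k)), numeric(1))
      w <- ifelse(dens > 0, 1 / dens, 0)
      if (sum(w) <= 0) w <- rep(1, n_keep)
      w <- w / sum(w)
      eps <- max(d[is.finite(d)], 0)
      eps_hist <- c(eps_hist, eps)
      if (p_acc < p_acc_min) break
    }
    if (all(!is.finite(d)))
      stop_config("all particles rejected: simulator returned no finite ",
                  "statistics (tolerance schedule cannot start)")
    structure(
      list(alphas = alphas, weights = w,
           point_estimate = sum(w * alphas),
           prior = prior, steps = steps,
           eps_history = eps_hist, p_acc_history = pacc_hist,
           target = target),
      class = "er_abc")
  })
}

#' @export
print.er_abc <- function(x, ...) {
  qs <- weighted_quantile(x$alphas, x$weights, c(0.05, 0.5, 0.95))
  cat(sprintf(
    "<er_abc> alpha = %.2f (weighted mean; 90%% CI [%.2f, %.2f]); %d particles, %d steps\n",
    x$point_estimate, qs[1], qs[3], length(x$alphas), x$steps))
  invisible(x)
}

#' Weighted quantiles of a posterior particle sample
#' @param x values
#' @param w weights (normalized internally)
#' @param probs quantile probabilities
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Plain rejection ABC (cross-check for the sequential scheme)
#'
#' Draws `n_sims` parameters from the prior and keeps the `accept_frac`
#' fraction closest to the target (equal weights).
#' @inheritParams abc_estimate_alpha
#' @param n_sims prior draws
#' @param accept_frac fraction retained
#' @export
abc_reject <- function(target, simulator, prior = c(0, 50), n_sims = 200,
                       accept_frac = 0.1, seed = NULL) {
  with_seed(seed, {
    alphas <- stats::runif(n_sims, prior[1], prior[2])
    d <- vapply(alphas, function(a) {
      out <- tryCatch(simulator(a), error = function(e) NA_real_)
      if (any(!is.finite(out))) Inf else sqrt(sum((out - target)^2))
    }, numeric(1))
    keep <- order(d)[seq_len(max(2L, round(accept_frac * n_sims)))]
    structure(
      list(alphas = alphas[keep],
           weights = rep(1 / length(keep), length(keep)),
           point_estimate = mean(alphas[keep]),
           prior = prior, steps = 1L,
           eps_history = max(d[keep]), p_acc_history = numeric(0),
           target = target),
      class = "er_abc")
  })
}
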