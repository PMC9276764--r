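# End-to-end orchestration: synthesize -> simulate -> observe -> call ->
# summarize -> (optionally) ABC, with per-stage derived sub-seeds, TSV
# outputs and a machine-readable JSON summary.

#' Build a pipeline run configuration
#'
#' @param seed master seed; every stochastic stage receives a derived,
#'   logged sub-seed
#' @param outdir output directory (created if missing); `NULL` disables all
#'   file output
#' @param architecture either an `er_architecture`, a path to an
#'   architecture TSV, or a list of arguments for [gen_architecture()]
#' @param design an `er_design` or list of arguments for
#'   [experiment_design()]
#' @param model an `er_fitness_model` or list of arguments for
#'   [fitness_model()] (`kind` plus named parameters)
#' @param neutral_iter neutral iterations behind the selection thresholds
#' @param q neutral quantile for selection calls
#' @param q_cut q-value significance cutoff reported for the per-locus tests
#' @param run_tests run the CMH / per-line chi-square / LMM tests and
#'   selection-coefficient estimation
#' @param abc `NULL`, or a list with `target` (length-2 numeric),
#'   `n_particles`, and optionally `prior`, `sim_generations`
#' @return an `er_run_config`
#' @export
run_config <- function(seed = 1, outdir = NULL,
                       architecture = list(), design = list(),
                       model = list(kind = "multiplicative"),
                       neutral_iter = 10000, q = 0.999, q_cut = 0.05,
                       run_tests = TRUE, abc = NULL) {
  if (is.list(model) && !inherits(model, "er_fitness_model"))
    model <- do.call(fitness_model, model) # validate before any simulation
  if (is.list(design) && !inherits(design, "er_design"))
    design <- do.call(experiment_design, design)
  structure(
    list(seed = as.integer(seed), outdir = outdir,
         architecture = architecture, design = design, model = model,
         neutral_iter = neutral_iter, q = q, q_cut = q_cut,
         run_tests = isTRUE(run_tests), abc = abc),
    class = "er_run_config")
}

pipeline_log <- function(lines, msgs) {
  c(lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msgs))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) architecture (generated or loaded), (2) synthetic experiment,
#' (3) neutral thresholds, (4) selection calls, (5) parallelism summaries
#' per post-baseline generation, (6) per-locus tests and selection
#' coefficients, (7) optional ABC estimation of alpha. Deterministic given
#' `config$seed`. When `outdir` is set, each stage writes its TSV and a
#' `summary.json` plus `run.log` are produced.
#'
#' @param config an `er_run_config` (see [run_config()])
#' @return (invisibly) list with elements `arch`, `traj`, `nq`, `calls`,
#'   `parallelism`, `tests`, `s_hat`, `abc`, `summary`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "er_run_config"))
  seed <- config$seed
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- pipeline_log(log_lines, sprintf(...))
  }
  say("pipeline start: seed %d (%s %s)", seed, "erparallel",
      as.character(utils::packageVersion("erparallel")))

  # stage 1: architecture
  arch <- config$architecture
  if (is.character(arch)) {
    say("stage synth: loading architecture from %s", arch)
    arch <- read_architecture_tsv(arch)
  } else if (!inherits(arch, "er_architecture")) {
    s1 <- derive_seed(seed, 1)
    say("stage synth: generating architecture (sub-seed %d)", s1)
    arch$seed <- arch$seed %||% s1
    arch <- do.call(gen_architecture, arch)
  }
  design <- config$design

  # stage 2: synthetic experiment
  s2 <- derive_seed(seed, 2)
  say("stage simulate: %d+%d lines, Ne %d (sub-seed %d)",
      design$n_treatment_lines, design$n_control_lines, design$Ne, s2)
  traj <- gen_experiment(arch, design, config$model, seed = s2)

  # stage 3: neutral thresholds
  s3 <- derive_seed(seed, 3)
  say("stage neutral: %d iterations, q %.4f (sub-seed %d)",
      config$neutral_iter, config$q, s3)
  post_gens <- setdiff(design$sampled_generations, 0L)
  nq <- neutral_quantiles(stats::setNames(arch$loci$p0, arch$loci$locus_id),
                          Ne = design$Ne, generations = post_gens,
                          n_iter = config$neutral_iter, q = config$q,
                          seed = s3)

  # stage 4: selection calls
  calls <- call_selected(traj, nq)
  say("stage call: %d selected-allele calls", sum(calls$called))

  # stage 5: parallelism
  par_sum <- lapply(post_gens, function(g) parallelism_summary(calls, g))
  names(par_sum) <- paste0("gen", post_gens)
  for (g in seq_along(post_gens))
    say("stage stats: gen %d mean Jaccard %.3f over %d lines",
        post_gens[g], par_sum[[g]]$mean_jaccard, par_sum[[g]]$n_lines)

  # stage 6: per-locus tests
  tests <- NULL
  s_hat <- NULL
  if (config$run_tests) {
    say("stage tests: CMH, line chi-square, LMM, s estimation")
    cmh <- cmh_drift_test(traj, Ne = design$Ne)
    trt_lines <- unique(traj$line[!is.na(traj$treatment) & traj$treatment])
    chis <- do.call(rbind, lapply(trt_lines, function(ln)
      chisq_line_test(traj, Ne = design$Ne, line = ln)))
    lmm <- tryCatch(lmm_treatment_test(traj), error = function(e) {
      say("stage tests: LMM skipped (%s)", conditionMessage(e))
      NULL
    })
    tests <- rbind(cmh, chis, lmm)
    s_hat <- estimate_s(traj)
  }

  # stage 7: ABC
  abc_res <- NULL
  if (!is.null(config$abc)) {
    s7 <- derive_seed(seed, 7)
    say("stage abc: %d particles (sub-seed %d)",
        config$abc$n_particles %||% 200, s7)
    sim_gens <- config$abc$sim_generations %||% post_gens
    simulator <- function(alpha) {
      mod <- if (alpha > 0)
        fitness_model("positive_epistasis", alpha = alpha)
      else fitness_model("multiplicative")
      sims <- simulate_parallelism(arch, design, mod, nq, n_iter = 1,
                                   generations = sim_gens,
                                   seed = sample.int(2147483646, 1))
      sims$mean_jaccard
    }
    abc_res <- abc_estimate_alpha(
      target = config$abc$target, simulator = simulator,
      prior = config$abc$prior %||% c(0, 50),
      n_particles = config$abc$n_particles %||% 200, seed = s7)
    say("stage abc: alpha point estimate %.2f", abc_res$point_estimate)
  }

  summary_obj <- list(
    seed = seed,
    model = config$model$kind,
    n_loci = arch$n_loci,
    mean_jaccard = lapply(par_sum, function(p) p$mean_jaccard),
    n_selected_per_line = lapply(
      stats::setNames(post_gens, paste0("gen", post_gens)),
      function(g) {
        cc <- calls[calls$generation == g, ]
        as.list(tapply(cc$called, cc$line, sum))
      }),
    rfs = lapply(par_sum, function(p) as.list(p$rfs)),
    n_significant = if (!is.null(tests))
      as.list(tapply(tests$q_value < config$q_cut, tests$test_name, sum,
                     na.rm = TRUE)) else NULL,
    mean_s_hat = if (!is.null(s_hat)) mean(s_hat$s_hat, na.rm = TRUE)
      else NULL,
    abc_alpha = if (!is.null(abc_res)) abc_res$point_estimate else NULL)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$outdir, f)
    write_architecture_tsv(arch, op("architecture.tsv"))
    write_trajectories_tsv(traj, op("trajectories.tsv"))
    utils::write.table(as.data.frame(nq), op("neutral_quantiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(calls), op("selection_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tests))
      utils::write.table(tests, op("tests.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    if (!is.null(s_hat))
      utils::write.table(s_hat, op("selection_coefficients.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(abc_res))
      utils::write.table(
        data.frame(alpha = abc_res$alphas, weight = abc_res$weights),
        op("abc_particles.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(summary_obj, op("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("outputs written to %s", config$outdir)
    writeLines(log_lines, op("run.log"))
  }

  invisible(list(arch = arch, traj = traj, nq = nq, calls = calls,
                 parallelism = par_sum, tests = tests, s_hat = s_hat,
                 abc = abc_res, summary = summary_obj, log = log_lines))
}
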