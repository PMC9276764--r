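# Fitness models mapping multilocus genotypes to fitness.
#
# Two families are implemented. The population-genetic family multiplies
# per-locus factors (1 + h_i s_i), optionally scaled by an epistatic term
# exp(alpha * (x - delta)^2) in the aggregate phenotype x. The
# quantitative-genetic family makes fitness a function of x alone
# (Gaussian shifted-optimum, saturating directional, truncating). The
# phenotype is the normalized weighted dosage of beneficial alleles,
#   x = sum_i h_i s_i / sum_i s_i  in [0, 1],
# with dominance weights h_i = copies_i / 2 (0, 1/2, 1). Under equal
# effects and haploid-style genotypes (h in {0,1}) with n carried alleles,
# the epistatic model reduces to (1+s)^n * exp(alpha * (n/N)^2).

MODEL_KINDS <- c("multiplicative", "positive_epistasis", "negative_epistasis",
                 "shifted_optimum", "directional", "truncating")

#' Construct a fitness model
#'
#' @param kind one of `"multiplicative"`, `"positive_epistasis"`,
#'   `"negative_epistasis"` (population-genetic family), or
#'   `"shifted_optimum"`, `"directional"`, `"truncating"`
#'   (quantitative-genetic family).
#' @param alpha epistasis strength; must be > 0 for positive epistasis,
#'   < 0 for negative epistasis, and is fixed at 0 for multiplicative.
#' @param mu,sigma optimum and width of the Gaussian shifted-optimum model
#'   (`sigma > 0`); fitness is `exp(-(((x - delta) - mu)^2) / sigma^2)`.
#' @param s_q,r,b_dir directional-model shape parameters: fitness
#'   `(1 + s_q * exp(r * ((x - delta) + b_dir)))^(-1/s_q)`; `s_q > 0` and
#'   `r < 0` so that fitness saturates as the phenotype increases
#'   (set `allow_positive_r = TRUE` to override the sign check).
#' @param a_tr,b_tr truncating-model parameters: fitness
#'   `max(0, 1 - exp(-a_tr * ((x - delta) + b_tr)))`; phenotypes at or below
#'   `-b_tr` (after shift) are lethal; `a_tr > 0`.
#' @param delta horizontal shift aligning the initial phenotype distribution
#'   with a baseline simulation (see [horizontal_shift()]); default 0.
#' @param allow_positive_r bypass the `r < 0` validation.
#' @return object of class `er_fitness_model`
#' @export
fitness_model <- function(kind, alpha = NULL, mu = NULL, sigma = NULL,
                          s_q = NULL, r = NULL, b_dir = NULL,
                          a_tr = NULL, b_tr = NULL, delta = 0,
                          allow_positive_r = FALSE) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% MODEL_KINDS))
    stop_config("unknown fitness model kind: ", paste(kind, collapse = ","),
                " (expected one of ", paste(MODEL_KINDS, collapse = ", "), ")")
  assert_scalar_num(delta, "delta")
  m <- list(kind = kind, delta = delta)
  if (kind == "multiplicative") {
    if (!is.null(alpha) && alpha != 0)
      stop_config("multiplicative model fixes alpha = 0")
    m$alpha <- 0
  } else if (kind %in% c("positive_epistasis", "negative_epistasis")) {
    if (is.null(alpha)) stop_config("epistasis models require alpha")
    assert_scalar_num(alpha, "alpha")
    if (kind == "positive_epistasis" && alpha <= 0)
      stop_config("positive_epistasis requires alpha > 0")
    if (kind == "negative_epistasis" && alpha >= 0)
      stop_config("negative_epistasis requires alpha < 0")
    m$alpha <- alpha
  } else if (kind == "shifted_optimum") {
    if (is.null(mu) || is.null(sigma)) stop_config("shifted_optimum requires mu, sigma")
    assert_scalar_num(sigma, "sigma")
    if (sigma <= 0) stop_config("sigma must be > 0")
    m$mu <- mu; m$sigma <- sigma
  } else if (kind == "directional") {
    if (is.null(s_q) || is.null(r) || is.null(b_dir))
      stop_config("directional requires s_q, r, b_dir")
    if (s_q <= 0) stop_config("s_q must be > 0")
    if (r >= 0 && !allow_positive_r)
      stop_config("directional model expects r < 0 (saturating benefits); ",
                  "use allow_positive_r = TRUE to override")
    m$s_q <- s_q; m$r <- r; m$b_dir <- b_dir
  } else if (kind == "truncating") {
    if (is.null(a_tr) || is.null(b_tr)) stop_config("truncating requires a_tr, b_tr")
    if (a_tr <= 0) stop_config("a_tr must be > 0")
    m$a_tr <- a_tr; m$b_tr <- b_tr
  }
  structure(m, class = "er_fitness_model")
}

#' @export
print.er_fitness_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("<er_fitness_model> %s (%s)\n", x$kind,
              paste(sprintf("%s=%.4g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

as_copies_matrix <- function(g, arch) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  if (ncol(g) != arch$n_loci)
    stop_config("genotype has ", ncol(g), " loci; architecture has ", arch$n_loci)
  if (any(g < 0 | g > 2)) stop_config("allele copy counts must be in {0, 1, 2}")
  g
}

#' Aggregate phenotype of diploid genotypes
#'
#' `x = sum_i h_i s_i / sum_i s_i` with `h_i = copies_i / 2`; `x` lies in
#' \[0, 1\] and equals 1 iff the genotype is homozygous for every beneficial
#' allele. Note the phenotype weights each locus by its selection
#' coefficient, so alleles of larger effect move the phenotype more.
#'
#' @param g integer vector (one individual) or matrix (individuals x loci)
#'   of beneficial-allele copy counts in {0, 1, 2}
#' @param arch an `er_architecture`
#' @return numeric vector of phenotypes, one per individual
#' @export
phenotype <- function(g, arch) {
  stopifnot(inherits(arch, "er_architecture"))
  g <- as_copies_matrix(g, arch)
  s <- arch$loci$s
  tot <- sum(s)
  if (tot <= 0) stop_config("phenotype undefined: sum of selection coefficients is 0")
  as.numeric(g %*% s) / (2 * tot)
}

#' Horizontal shift between two initial phenotype distributions
#'
#' `delta = mean_pheno_current - mean_pheno_baseline`. Used when the
#' architecture is modified (different starting frequencies or locus count)
#' so that the fitness function sees the same initial phenotype distribution
#' as the baseline simulation.
#' @param mean_pheno_current,mean_pheno_baseline mean initial phenotypes in \[0, 1\]
#' @export
horizontal_shift <- function(mean_pheno_current, mean_pheno_baseline) {
  assert_scalar_num(mean_pheno_current, "mean_pheno_current", 0, 1)
  assert_scalar_num(mean_pheno_baseline, "mean_pheno_baseline", 0, 1)
  mean_pheno_current - mean_pheno_baseline
}

#' Moments of the initial phenotype distribution under HWE
#'
#' At linkage equilibrium with per-locus frequencies p, the phenotype mean
#' is `sum(s*p)/sum(s)` and its variance `sum(s^2 p (1-p) / 2) / sum(s)^2`
#' (each locus contributes the variance of a Binomial(2, p)/2 dosage).
#' @param arch an `er_architecture`
#' @return list with `mean` and `sd`
#' @export
initial_phenotype_moments <- function(arch) {
  s <- arch$loci$s; p <- arch$loci$p0
  tot <- sum(s)
  if (tot <= 0) stop_config("sum of selection coefficients is 0")
  list(mean = sum(s * p) / tot,
       sd = sqrt(sum(s^2 * p * (1 - p) / 2)) / tot)
}

# log(1 + exp(z)) without overflow
log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(z)))

#' Fitness of diploid genotypes under a fitness model
#'
#' Population-genetic models: `w = prod_i (1 + h_i s_i)` times, for the
#' epistatic variants, `exp(alpha * (x - delta)^2)`; the product is
#' evaluated in log space. Quantitative-genetic models are functions of the
#' shifted phenotype `x - delta` only (see [fitness_model()]).
#'
#' @inheritParams phenotype
#' @param model an `er_fitness_model`
#' @return numeric vector of fitnesses (>= 0, finite)
#' @export
fitness <- function(g, arch, model) {
  stopifnot(inherits(arch, "er_architecture"), inherits(model, "er_fitness_model"))
  g <- as_copies_matrix(g, arch)
  s <- arch$loci$s
  kind <- model$kind
  if (kind %in% c("multiplicative", "positive_epistasis", "negative_epistasis")) {
    het <- g == 1L
    hom <- g == 2L
    logw <- as.numeric(het %*% log1p(s / 2)) + as.numeric(hom %*% log1p(s))
    if (model$alpha != 0) {
      x <- phenotype(g, arch)
      logw <- logw + model$alpha * (x - model$delta)^2
    }
    if (any(logw > 700)) stop_config("fitness overflow: log-fitness exceeds 700")
    return(exp(logw))
  }
  x <- phenotype(g, arch) - model$delta
  w <- switch(kind,
    shifted_optimum = exp(-((x - model$mu)^2) / model$sigma^2),
    directional = {
      z <- model$r * (x + model$b_dir)
      exp(-log1pexp(z + log(model$s_q)) / model$s_q)
    },
    truncating = pmax(0, 1 - exp(-model$a_tr * (x + model$b_tr)))
  )
  if (any(!is.finite(w))) stop_config("non-finite fitness under ", kind)
  w
}

#' Closed-form fitness ratio for equal-effect haploid-style genotypes
#'
#' For an architecture of `N` loci of equal effect `s` and genotypes carrying
#' `n` vs `n - 1` beneficial alleles (dominance weight 1 per carried allele),
#' the epistatic fitness ratio is `(1 + s) * exp(alpha * (2n - 1) / N^2)`.
#' With `alpha = 0` this is exactly the multiplicative `(1 + s)`.
#'
#' @param n number of beneficial alleles carried (1 <= n <= N)
#' @param N total number of loci
#' @param s common selection coefficient
#' @param alpha epistasis strength
#' @return the ratio `w_n / w_(n-1)`
#' @export
fitness_ratio_haploid <- function(n, N, s, alpha) {
  stopifnot(n >= 1, n <= N)
  (1 + s) * exp(alpha * (2 * n - 1) / N^2)
}

#' Reconstructed quantitative-genetic model defaults
#'
#' The three quantitative-genetic fitness functions require shape parameters
#' that are anchored to the initial phenotype distribution of the baseline
#' architecture. These defaults are reconstructions from design constraints,
#' not fitted values: the truncating model culls ~25% of the starting
#' population (lethal threshold at the 25th percentile of the initial
#' phenotype, normal approximation) and saturates within about one
#' phenotypic SD above it; the directional model is a logistic of matching
#' scale centred on the same threshold; the shifted-optimum model places the
#' optimum four initial SDs above the starting mean (reached near the end of
#' a ten-generation experiment) with width two SDs.
#'
#' @param kind `"shifted_optimum"`, `"directional"` or `"truncating"`
#' @param arch architecture whose initial phenotype distribution anchors the
#'   parameters (the baseline architecture)
#' @param delta horizontal shift (default 0)
#' @return an `er_fitness_model`
#' @export
qt_default_model <- function(kind = c("shifted_optimum", "directional",
                                      "truncating"),
                             arch, delta = 0) {
  kind <- match.arg(kind)
  mo <- initial_phenotype_moments(arch)
  thr <- mo$mean + stats::qnorm(0.25) * mo$sd # ~25% of founders below
  steep <- 3 / mo$sd
  switch(kind,
    truncating = fitness_model("truncating", a_tr = steep, b_tr = -thr,
                               delta = delta),
    directional = fitness_model("directional", s_q = 1, r = -steep,
                                b_dir = -thr, delta = delta),
    shifted_optimum = fitness_model("shifted_optimum",
                                    mu = mo$mean + 4 * mo$sd,
                                    sigma = 2 * mo$sd, delta = delta)
  )
}
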