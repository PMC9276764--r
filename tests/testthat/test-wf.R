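test_that("initialization draws Hardy-Weinberg genotypes at linkage equilibrium", {
  arch <- equal_arch(20, p0 = 0.5)
  pop <- initialize_population(arch, 1e4, seed = 1)
  f <- allele_freq(pop)
  se <- sqrt(0.5 * 0.5 / (2 * 1e4))
  expect_true(all(abs(f - 0.5) < 4 * se))
  # genotype proportions ~ (0.25, 0.5, 0.25)
  props <- table(factor(pop$copies[, 1], levels = 0:2)) / 1e4
  se_g <- sqrt(0.25 * 0.75 / 1e4)
  expect_lt(abs(props[[1]] - 0.25), 4 * se_g)
  expect_lt(abs(props[[2]] - 0.50), 4 * sqrt(0.5 * 0.5 / 1e4))
  # across-locus genotype correlation ~ 0
  cors <- cor(pop$copies[, 1:10])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)
  # boundary frequency
  arch_hi <- equal_arch(1, p0 = 1 - 1e-12)
  pop_hi <- initialize_population(arch_hi, 500, seed = 2)
  expect_equal(unname(allele_freq(pop_hi)), 1)
})

test_that("neutral drift matches the Wright-Fisher variance closed form", {
  # quasi-replicates: many neutral loci across several populations
  Ne <- 1750; p0 <- 0.3; t_gen <- 10
  arch <- equal_arch(400, s = 0, p0 = p0)
  set.seed(7)
  # displacement from the realized founder frequency isolates the t
  # generations of reproduction from the founder-sampling round
  deltas <- unlist(lapply(1:20, function(r) {
    pop <- initialize_population(arch, Ne)
    f0 <- allele_freq(pop)
    for (g in 1:t_gen) pop <- step_generation(pop, NULL)
    allele_freq(pop) - f0
  }))
  v_expected <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * Ne))^t_gen)
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas) / 3))
  expect_lt(abs(var(deltas) - v_expected) / v_expected, 0.10)
})

test_that("one generation of selection matches the deterministic recursion", {
  # fitnesses (1, 1+s/2, 1+s): p' = p (1 + s/2 + s p/2) / (1 + s p)
  s <- 0.1; p0 <- 0.2; N <- 2e5
  arch <- equal_arch(5, s = s, p0 = p0)
  pop <- initialize_population(arch, N, seed = 31)
  p_start <- allele_freq(pop)
  pop1 <- step_generation(pop, fitness_model("multiplicative"))
  p_exp <- p_start * (1 + s / 2 + s * p_start / 2) / (1 + s * p_start)
  se <- sqrt(p0 * (1 - p0) / (2 * N))
  expect_true(all(abs(allele_freq(pop1) - p_exp) < 4 * se))
})

test_that("heterozygosity decays like (1 - 1/(2N))^t under neutrality", {
  N <- 50; t_gen <- 10
  arch <- equal_arch(150, s = 0, p0 = 0.5)
  set.seed(11)
  het <- colMeans(do.call(rbind, lapply(1:40, function(r) {
    pop <- initialize_population(arch, N)
    for (g in 1:t_gen) pop <- step_generation(pop, NULL)
    f <- allele_freq(pop)
    2 * f * (1 - f)
  })))
  expect_lt(abs(mean(het) / (0.5 * (1 - 1 / (2 * N))^t_gen) - 1), 0.05)
})

test_that("positive epistasis fixes more beneficial alleles than the multiplicative model", {
  arch <- equal_arch(30, s = 0.25, p0 = 0.3)
  run_fix <- function(model, seed) {
    n_fixed <- 0
    for (r in 1:20) {
      pop <- initialize_population(arch, 200, seed = derive_seed(seed, r))
      for (g in 1:10) pop <- step_generation(pop, model)
      n_fixed <- n_fixed + sum(allele_freq(pop) == 1)
    }
    n_fixed
  }
  set.seed(5)
  f_epi <- run_fix(fitness_model("positive_epistasis", alpha = 36.5,
                                 delta = 0.3), 1)
  set.seed(5)
  f_mult <- run_fix(fitness_model("multiplicative"), 1)
  expect_gte(f_epi, f_mult)
})

test_that("replicate lines are independent and reproducible", {
  arch <- equal_arch(30, s = 0, p0 = 0.4)
  design <- small_design()
  t1 <- run_replicates(arch, design, fitness_model("multiplicative"), 4,
                       seed = 9)
  t2 <- run_replicates(arch, design, fitness_model("multiplicative"), 4,
                       seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$freq >= 0 & t1$freq <= 1))
  # across-line frequency correlation at generation 10 for neutral loci
  g10 <- t1[t1$generation == 10, ]
  m <- do.call(cbind, lapply(split(g10$freq, g10$line), identity))
  cors <- cor(m)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.35)
})

test_that("total fitness zero raises an extinction error with the line label", {
  arch <- equal_arch(4, s = 0.1, p0 = 0.2)
  lethal <- fitness_model("truncating", a_tr = 50, b_tr = -2) # x <= 1 < 2
  pop <- initialize_population(arch, 50, seed = 1)
  expect_error(step_generation(pop, lethal), class = "er_extinction_error")
  expect_error(
    run_replicates(arch, small_design(), lethal, 2, seed = 1), "line T1")
})

test_that("Haldane crossover probabilities follow distance and scaffold breaks", {
  loci <- data.frame(locus_id = c("a", "b", "c"), block_id = c("a", "b", "c"),
                     scaffold = c("s1", "s1", "s2"),
                     position_bp = c(1e6, 3e6, 1e6), s = 0.1, p0 = 0.3)
  arch <- architecture(loci, linkage_mode = "linked",
                       recomb_rate_cM_per_Mb = 1.6)
  r <- erparallel:::recomb_probs(arch)
  # 2 Mb * 1.6 cM/Mb = 3.2 cM = 0.032 Morgans
  expect_equal(r[1], 0.5 * (1 - exp(-2 * 0.032)), tolerance = 1e-12)
  expect_equal(r[2], 0.5) # scaffold break: free recombination
  # distant loci approach free recombination (Haldane saturates at 0.5)
  far <- equal_arch(2, spacing_bp = 150e6, linkage_mode = "linked")
  expect_gt(erparallel:::recomb_probs(far)[1], 0.495)
})

test_that("linked-mode allele frequency change matches unlinked mode for distant loci", {
  set.seed(21)
  mkarch <- function(mode) equal_arch(10, s = 0.15, p0 = 0.3,
                                      spacing_bp = 40e6, linkage_mode = mode)
  run10 <- function(arch, seed) {
    pop <- initialize_population(arch, 400, seed = seed)
    for (g in 1:10) pop <- step_generation(pop, fitness_model("multiplicative"))
    mean(allele_freq(pop))
  }
  du <- sapply(1:25, function(r) run10(mkarch("unlinked"), r))
  dl <- sapply(1:25, function(r) run10(mkarch("linked"), 1000 + r))
  se <- sqrt(var(du) / 25 + var(dl) / 25)
  expect_lt(abs(mean(du) - mean(dl)), 3.5 * se)
})

test_that("neutral quantiles behave like drift quantiles", {
  # enormous Ne: no drift, thresholds collapse to zero
  nq_big <- neutral_quantiles(c(a = 0.3, b = 0.5), Ne = 1e8,
                              generations = 10, n_iter = 1000, seed = 2)
  expect_true(all(nq_big$threshold < 0.005))
  # normal-approximation oracle at p0 = 0.286, Ne = 1750, generation 10
  p0 <- 0.286
  nq <- neutral_quantiles(c(x = p0), Ne = 1750, generations = c(6, 10),
                          n_iter = 20000, seed = 3)
  oracle <- qnorm(0.999) *
    sqrt(p0 * (1 - p0) * (1 - (1 - 1 / (2 * 1750))^10))
  thr10 <- nq$threshold[nq$generation == 10]
  expect_lt(abs(thr10 - oracle) / oracle, 0.15)
  # thresholds grow with generation
  expect_gt(thr10, nq$threshold[nq$generation == 6])
  # median drift displacement ~ 0
  nq_med <- neutral_quantiles(c(x = 0.3), Ne = 1750, generations = 10,
                              n_iter = 10000, q = 0.5, seed = 4)
  expect_lt(abs(nq_med$threshold), 0.01)
  expect_error(neutral_quantiles(0.3, Ne = 1750, generations = 10,
                                 n_iter = 10), "n_iter")
})
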