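test_that("phenotype is the normalized s-weighted dosage", {
  arch <- equal_arch(4, s = 0.1)
  expect_equal(phenotype(rep(2L, 4), arch), 1)
  expect_equal(phenotype(rep(0L, 4), arch), 0)
  a2 <- architecture(data.frame(locus_id = c("a", "b"), block_id = c("a", "b"),
                                scaffold = "s", position_bp = c(1e6, 3e6),
                                s = c(0.1, 0.3), p0 = c(0.3, 0.3)))
  expect_equal(phenotype(c(2L, 0L), a2), 0.1 / 0.4)
  # haploid-style reduction: n of N equal-effect alleles gives x = n/N
  aN <- equal_arch(10)
  for (n in c(0, 3, 10))
    expect_equal(phenotype(haploid_genotype(n, 10), aN), n / 10)
  # invariant under locus reordering
  g <- c(0L, 1L, 2L, 1L)
  perm <- c(3, 1, 4, 2)
  arch_p <- architecture(arch$loci[perm, ])
  expect_equal(phenotype(g, arch), phenotype(g[perm], arch_p))
  # degenerate architecture
  a0 <- equal_arch(2, s = 0)
  expect_error(phenotype(c(1L, 1L), a0), "undefined")
})

test_that("multiplicative fitness multiplies per-locus factors", {
  a1 <- equal_arch(1, s = 0.1)
  m <- fitness_model("multiplicative")
  expect_equal(fitness(1L, a1, m), 1.05)
  expect_equal(fitness(2L, a1, m), 1.1)
  expect_equal(fitness(0L, a1, m), 1)
  # product over loci, evaluated in log space
  a3 <- equal_arch(3, s = c(0.1, 0.2, 0.3))
  expect_equal(fitness(c(2L, 1L, 0L), a3, m), 1.1 * 1.1, tolerance = 1e-12)
})

test_that("epistatic model with alpha = 0 is impossible but matches the multiplicative limit", {
  expect_error(fitness_model("positive_epistasis", alpha = 0), "alpha > 0")
  expect_error(fitness_model("negative_epistasis", alpha = 0.5), "alpha < 0")
  expect_error(fitness_model("multiplicative", alpha = 2), "alpha = 0")
  # continuity: tiny alpha approaches the multiplicative fitness
  arch <- equal_arch(5, s = 0.2)
  g <- matrix(sample(0:2, 50, replace = TRUE), 10, 5)
  w_mult <- fitness(g, arch, fitness_model("multiplicative"))
  w_eps <- fitness(g, arch, fitness_model("positive_epistasis", alpha = 1e-14))
  expect_equal(w_eps, w_mult, tolerance = 1e-12)
})

test_that("closed-form haploid fitness ratios reproduce the printed approximations", {
  # N = 121, alpha = 36.5: ratio/(1+s) = 1.002 at n = 1 and 1.823 at n = 121
  arch <- equal_arch(121, s = 0.1)
  mod <- fitness_model("positive_epistasis", alpha = 36.5)
  r1 <- fitness(haploid_genotype(1, 121), arch, mod) /
    fitness(haploid_genotype(0, 121), arch, mod)
  r121 <- fitness(haploid_genotype(121, 121), arch, mod) /
    fitness(haploid_genotype(120, 121), arch, mod)
  expect_lt(abs(r1 / 1.1 - 1.002), 1e-3)
  expect_lt(abs(r121 / 1.1 - 1.823), 1e-3)
  # the shortcut formula equals the general fitness ratio for all n
  for (n in c(1, 2, 60, 121)) {
    rn <- fitness(haploid_genotype(n, 121), arch, mod) /
      fitness(haploid_genotype(n - 1, 121), arch, mod)
    expect_equal(fitness_ratio_haploid(n, 121, 0.1, 36.5), rn,
                 tolerance = 1e-10)
  }
  expect_equal(fitness_ratio_haploid(7, 121, 0.1, 0), 1.1)
})

test_that("fitness matches the closed form (1+s)^n * exp(a (n/N)^2) exactly", {
  N <- 40; s <- 0.15; alpha <- 12
  arch <- equal_arch(N, s = s)
  mod <- fitness_model("positive_epistasis", alpha = alpha)
  for (n in c(0, 1, 17, 40)) {
    w <- fitness(haploid_genotype(n, N), arch, mod)
    expect_equal(w, (1 + s)^n * exp(alpha * (n / N)^2), tolerance = 1e-12)
  }
})

test_that("synergy direction: ratio increases in n for a > 0, decreases for a < 0", {
  rp <- sapply(1:20, fitness_ratio_haploid, N = 20, s = 0.1, alpha = 10)
  rn <- sapply(1:20, fitness_ratio_haploid, N = 20, s = 0.1, alpha = -10)
  expect_true(all(diff(rp) > 0))
  expect_true(all(diff(rn) < 0))
})

test_that("quantitative-genetic fitness functions behave as specified", {
  arch <- equal_arch(10, s = 0.1)
  x_of <- function(g) phenotype(g, arch)
  # shifted optimum peaks at 1 when (x - delta) = mu
  g_half <- haploid_genotype(5, 10) # x = 0.5
  so <- fitness_model("shifted_optimum", mu = 0.5, sigma = 0.2)
  expect_equal(fitness(g_half, arch, so), 1)
  expect_lt(fitness(haploid_genotype(10, 10), arch, so), 1)
  # truncating is 0 at the lethal threshold and saturates toward 1
  tr <- fitness_model("truncating", a_tr = 20, b_tr = -0.5)
  expect_equal(fitness(g_half, arch, tr), 0)
  expect_equal(fitness(haploid_genotype(4, 10), arch, tr), 0) # below threshold
  expect_equal(fitness(haploid_genotype(0, 10), arch, tr), 0)
  expect_gt(fitness(haploid_genotype(10, 10), arch, tr), 0.99)
  # directional with r < 0 is monotone increasing and bounded by 1
  di <- fitness_model("directional", s_q = 1, r = -15, b_dir = -0.5)
  w_seq <- sapply(0:10, function(n) fitness(haploid_genotype(n, 10), arch, di))
  expect_true(all(diff(w_seq) > 0))
  expect_true(all(w_seq > 0 & w_seq < 1))
  expect_error(fitness_model("directional", s_q = 1, r = 5, b_dir = 0),
               "r < 0")
  m <- fitness_model("directional", s_q = 1, r = 5, b_dir = 0,
                     allow_positive_r = TRUE)
  expect_s3_class(m, "er_fitness_model")
})

test_that("horizontal shift is the difference of mean initial phenotypes", {
  expect_equal(horizontal_shift(0.4, 0.4), 0)
  expect_equal(horizontal_shift(0.6, 0.4), 0.2)
  # Monte-Carlo oracle over HWE genotypes for the closed-form moments
  set.seed(42)
  arch <- gen_architecture(n_loci = 30, seed = 7)
  mc <- replicate(1, {
    g <- matrix(rbinom(1e5 * 30, 2, rep(arch$loci$p0, each = 1e5)), 1e5, 30)
    mean(phenotype(g, arch))
  })
  mo <- initial_phenotype_moments(arch)
  expect_equal(mo$mean, mc, tolerance = 1e-2)
  # initializing every locus at 0.5 shifts the phenotype up when the
  # baseline starts below 0.5
  arch5 <- architecture(transform(arch$loci, p0 = 0.5))
  d <- horizontal_shift(initial_phenotype_moments(arch5)$mean, mo$mean)
  expect_gt(d, 0)
  expect_equal(d, 0.5 - mo$mean, tolerance = 1e-12)
})

test_that("reconstructed QT defaults cull about a quarter of founders (truncating)", {
  arch <- gen_architecture(n_loci = 121, seed = 13)
  tr <- qt_default_model("truncating", arch)
  set.seed(1)
  g <- matrix(rbinom(4000 * 121, 2, rep(arch$loci$p0, each = 4000)), 4000, 121)
  w <- fitness(g, arch, tr)
  expect_gt(mean(w == 0), 0.15)
  expect_lt(mean(w == 0), 0.35)
  expect_true(all(w >= 0 & w <= 1))
  di <- qt_default_model("directional", arch)
  so <- qt_default_model("shifted_optimum", arch)
  expect_true(all(fitness(g, arch, di) > 0))
  expect_true(all(fitness(g, arch, so) <= 1))
})

test_that("compiled population fitness kernel agrees with the reference implementation", {
  set.seed(3)
  arch <- gen_architecture(n_loci = 25, seed = 3)
  pop <- initialize_population(arch, 150, seed = 4)
  for (mod in list(fitness_model("multiplicative"),
                   fitness_model("positive_epistasis", alpha = 36.5,
                                 delta = 0.2),
                   fitness_model("negative_epistasis", alpha = -10))) {
    expect_equal(erparallel:::pop_fitness(pop, mod),
                 fitness(pop$copies, arch, mod), tolerance = 1e-12)
  }
})
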