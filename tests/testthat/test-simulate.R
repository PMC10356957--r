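test_that("genotypes follow the configured frequencies and HWE", {
  cfg <- sim_config(10000, 1, 1, 0.5, maf_low = 0.5, maf_high = 0.5,
                    seed = 7)
  g <- simulate_genotypes(cfg)
  expect_equal(mean(g$dosages), 1.0, tolerance = 0.02)

  cfg2 <- sim_config(20000, 5, 0, 0.5, maf_low = 0.1, maf_high = 0.4,
                     seed = 3)
  g2 <- simulate_genotypes(cfg2)
  for (j in 1:5) {
    f <- g2$freqs[j]
    counts <- tabulate(g2$dosages[, j] + 1L, nbins = 3) / 20000
    hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    # binomial error on each genotype class at n = 20000
    expect_true(all(abs(counts - hwe) < 4 * sqrt(hwe * (1 - hwe) / 20000)))
  }
})

test_that("same seed and config give bit-identical output", {
  cfg <- sim_config(200, 50, 5, 0.4, prevalence = 0.2, seed = 99)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  a1 <- simulate_architecture(g1, cfg)
  a2 <- simulate_architecture(g2, cfg)
  expect_identical(a1, a2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(0, 10, 1, 0.5), "positive")
  expect_error(sim_config(10, 10, 11, 0.5), "n_causal")
  expect_error(sim_config(10, 10, 1, 1.5), "h2")
  expect_error(sim_config(10, 10, 1, 0.5, maf_low = 0), "maf")
  expect_error(sim_config(10, 10, 1, 0.5, ld_rho = 1), "ld_rho")
})

test_that("LD blocks produce the copula's adjacent-SNP correlation", {
  cfg <- sim_config(5000, 10, 0, 0.5, maf_low = 0.3, maf_high = 0.5,
                    ld_block_size = 2, ld_rho = 0.8, seed = 5)
  g <- simulate_genotypes(cfg)
  for (j in c(1, 3, 5)) {
    emp <- cor(g$dosages[, j], g$dosages[, j + 1])
    theo <- oracle_ld_corr(0.8, g$freqs[j], g$freqs[j + 1])
    expect_gt(emp, 0.5)
    expect_equal(emp, theo, tolerance = 0.08)
  }
  # block boundaries stay uncorrelated
  expect_lt(abs(cor(g$dosages[, 2], g$dosages[, 3])), 0.06)
})

test_that("architecture hits the target heritability exactly in sample", {
  fx <- make_fixture(n = 5000, p = 200, s = 20, h2 = 0.5, seed = 11)
  a <- fx$arch
  expect_equal(var(a$genetic_values), 0.5, tolerance = 1e-12)
  expect_equal(cor(a$phenotype, a$genetic_values)^2, 0.5, tolerance = 0.03)

  cfg0 <- sim_config(500, 50, 5, 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  a0 <- simulate_architecture(g0, cfg0)
  expect_true(all(a0$causal_effects == 0))
  expect_true(all(a0$genetic_values == 0))

  cfg1 <- sim_config(500, 50, 5, 1, seed = 2)
  a1 <- simulate_architecture(simulate_genotypes(cfg1), cfg1)
  expect_true(all(a1$environmental_values == 0))
  expect_equal(cor(a1$phenotype, a1$genetic_values), 1)
})

test_that("equal-magnitude effect mode draws sign-only effects", {
  cfg <- sim_config(500, 100, 10, 0.5, effect_dist = "equal", seed = 4)
  a <- simulate_architecture(simulate_genotypes(cfg), cfg)
  expect_equal(length(unique(abs(a$causal_effects))), 1)
  expect_equal(var(a$genetic_values), 0.5, tolerance = 1e-12)
})

test_that("liability threshold reproduces the prevalence", {
  expect_equal(stats::qnorm(1 - 0.5), 0) # median split at prevalence 0.5
  set.seed(1)
  liab <- rnorm(100000)
  lab <- apply_liability_threshold(liab, 0.1)
  expect_equal(mean(lab), 0.1, tolerance = 0.003)
  expect_true(all(apply_liability_threshold(liab, 1) == 1))
  expect_error(apply_liability_threshold(rep(1, 10), 0.5), "degenerate")
  expect_error(apply_liability_threshold(liab, 0), "prevalence")
})

test_that("sibling pairs show the expected genotype correlation", {
  cfg <- sim_config(2200, 300, 10, 0.5, seed = 21)
  g <- simulate_genotypes(cfg)
  sib <- simulate_siblings(g, 1000, cfg)
  expect_equal(nrow(sib$genotypes$dosages), 2000)
  expect_equal(nrow(sib$pedigree), 1000)
  ia <- seq(1, 2000, by = 2)
  ib <- seq(2, 2000, by = 2)
  percor <- vapply(seq_len(300), function(j) {
    x <- sib$genotypes$dosages[ia, j]
    y <- sib$genotypes$dosages[ib, j]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  # expected full-sib additive correlation 0.5
  expect_equal(mean(percor, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("sibling transmission bookkeeping is exact", {
  cfg <- sim_config(10, 20, 2, 0.5, seed = 3)
  g <- simulate_genotypes(cfg)
  # monomorphic SNP: all offspring dosage 0
  g$dosages[, 1] <- 0L
  sib <- simulate_siblings(g, 4, cfg)
  expect_true(all(sib$genotypes$dosages[, 1] == 0))
  # same two parents for every pair: offspring frequency matches the
  # parental mean within binomial error
  pp <- matrix(rep(c(1L, 2L), each = 400), ncol = 2)
  sib2 <- simulate_siblings(g, 400, cfg, parent_pairs = pp)
  par_mean <- colMeans(g$dosages[1:2, ]) / 2
  off_freq <- colMeans(sib2$genotypes$dosages) / 2
  se <- sqrt(pmax(par_mean * (1 - par_mean), 1e-9) / (2 * 800))
  expect_true(all(abs(off_freq - par_mean) <= 4 * se + 0.02))
  # empty request
  sib0 <- simulate_siblings(g, 0, cfg)
  expect_equal(nrow(sib0$genotypes$dosages), 0)
  expect_equal(nrow(sib0$pedigree), 0)
})

test_that("Balding-Nichols drift keeps the Beta mean and variance", {
  expect_identical(drift_population(c(0.2, 0.5), 0), c(0.2, 0.5))
  f <- drift_population(rep(0.5, 10000), 0.2, seed = 8)
  # Beta mean f, variance F f (1 - f)
  expect_lt(abs(mean(f) - 0.5), 3 * sqrt(0.05 / 10000))
  expect_lt(abs(var(f) - 0.05), 0.003)
  expect_identical(drift_population(c(0, 1), 0.3, seed = 1), c(0, 1))
  expect_error(drift_population(0.5, 1), "fst")
})

test_that("predictor performance degrades with ancestry drift on average", {
  fx <- make_fixture(n = 1200, p = 150, s = 10, h2 = 0.6, seed = 31,
                     maf_low = 0.1)
  # the true architecture itself is the predictor; test its correlation
  # in drifted target populations of increasing fst
  fst_levels <- c(0, 0.05, 0.2)
  reps <- 20
  mean_cor <- sapply(fst_levels, function(fs) {
    mean(sapply(seq_len(reps), function(r) {
      f2 <- drift_population(fx$geno$freqs, fs, seed = 1000 + r)
      gt <- simulate_from_freqs(fx$geno, f2, 400, seed = 2000 + r)
      ph <- simulate_phenotype(fx$arch, gt, seed = 3000 + r)
      cor(genetic_values(fx$arch, gt), ph$phenotype)
    }))
  })
  expect_true(all(diff(mean_cor) <= 0.01))
})
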