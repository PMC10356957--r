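make_predictor_fixture <- function(geno, weights, snps = seq_along(weights)) {
  structure(
    data.frame(
      snp_id = geno$snp_ids[snps], chr = geno$chr[snps],
      pos = geno$pos[snps], effect_allele = geno$effect_allele[snps],
      weight = weights, training_freq = geno$freqs[snps],
      stringsAsFactors = FALSE
    ),
    class = c("pgs_predictor", "data.frame")
  )
}

test_that("PGS computation respects weights, alleles and imputation", {
  fx <- make_fixture(n = 50, p = 10, s = 2, seed = 33)
  g <- fx$geno
  # single SNP, weight 1: score equals the dosage
  p1 <- make_predictor_fixture(g, 1, snps = 4)
  expect_equal(as.numeric(compute_pgs(g, p1)), g$dosages[, 4])
  # all-zero weights
  p0 <- make_predictor_fixture(g, c(0, 0), snps = c(1, 2))
  expect_true(all(compute_pgs(g, p0) == 0))
  # allele flip: dosage complement identity PGS' = 2 sum(beta) - PGS
  pw <- make_predictor_fixture(g, c(0.5, -1.2, 2), snps = c(1, 5, 9))
  base <- compute_pgs(g, pw)
  gflip <- g
  gflip$effect_allele <- g$other_allele
  gflip$other_allele <- g$effect_allele
  gflip$dosages <- 2 - g$dosages
  flip <- compute_pgs(gflip, pw)
  expect_equal(as.numeric(flip), as.numeric(base), tolerance = 1e-12)
  # missing dosages impute to 2 * training frequency
  gm <- g
  gm$dosages[1, 1] <- NA
  pm <- make_predictor_fixture(g, 1, snps = 1)
  expect_equal(compute_pgs(gm, pm)[1], 2 * g$freqs[1])
  # unresolvable SNPs beyond 20% error out
  pbad <- make_predictor_fixture(g, c(1, 1), snps = c(1, 2))
  pbad$snp_id <- c("nope1", "nope2")
  expect_error(compute_pgs(g, pbad), "unresolvable")
})

test_that("AUC matches exhaustive pair counting and its known cases", {
  expect_equal(metric_auc(1:4, c(0, 1, 0, 1))$value, 0.75)
  expect_equal(metric_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$value, 1)
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 2) # rounded to exercise ties
    l <- sample(0:1, n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(metric_auc(s, l)$value, oracle_auc(s, l))
  }
  expect_error(metric_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under monotone transforms and flips sign", {
  set.seed(42)
  s <- rnorm(200)
  l <- rbinom(200, 1, plogis(s))
  a <- metric_auc(s, l)$value
  expect_equal(metric_auc(exp(s), l)$value, a)
  expect_equal(metric_auc(rank(s), l)$value, a)
  expect_equal(metric_auc(-s, l)$value, 1 - a)
})

test_that("null scores give AUC 0.5 within three standard errors", {
  set.seed(43)
  s <- rnorm(2000)
  l <- rbinom(2000, 1, 0.3)
  r <- metric_auc(s, l)
  expect_lt(abs(r$value - 0.5), 3 * r$se)
})

test_that("correlation metric recovers known correlations with Fisher SE", {
  set.seed(44)
  x <- rnorm(1000)
  expect_equal(metric_correlation(x, x)$value, 1)
  y <- rnorm(1000)
  r0 <- metric_correlation(x, y)
  expect_lt(abs(r0$value), 3 / sqrt(997))
  # bivariate normal with r = 0.6
  n <- 5000
  z <- rnorm(n)
  a <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  r6 <- metric_correlation(z, a)
  expect_equal(r6$value, 0.6, tolerance = 3 * r6$se)
  expect_error(metric_correlation(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("inclusive odds ratio matches direct counting and omits empty bins", {
  # constructed counts: 30 of 100 cases and 10 of 100 controls above q
  scores <- c(seq(2, 3, length.out = 30), seq(0, 1, length.out = 70),
              seq(1.5, 1.9, length.out = 10), seq(-1, 0.9, length.out = 90))
  labels <- rep(c(1, 0), c(100, 100))
  or <- inclusive_odds_ratio(scores, labels, percentiles = c(0, 80))
  expect_equal(or$or[or$percentile == 0], 1) # inclusive set is everyone
  row80 <- or[or$percentile == 80, ]
  expect_equal(row80$or, (row80$n_cases / row80$n_controls) / 1)
  expect_equal(row80$or,
               (row80$n_cases / 100) / (row80$n_controls / 100))
  # all cases above all controls: top bins with no controls are omitted
  s2 <- c(rnorm(50, 10), rnorm(50, -10))
  l2 <- rep(c(1, 0), each = 50)
  or2 <- inclusive_odds_ratio(s2, l2)
  expect_false(any(or2$percentile > 50))
  expect_true(all(or2$n_controls > 0 & or2$n_cases > 0))
})

test_that("ASP selection rate counts qualifying pairs correctly", {
  # worked pairs: (2.0 case, 1.0 control), (0.5 case, 1.5 control)
  r <- asp_selection_rate(c(2, 0.5), c(1, 1.5), sd_cutoffs = 0)
  expect_equal(r$rate, 0.5)
  # case always higher
  r1 <- asp_selection_rate(c(3, 4, 5), c(1, 2, 3), sd_cutoffs = 0)
  expect_equal(r1$rate, 1)
  # cutoff excluding all pairs: undefined, not zero
  r2 <- asp_selection_rate(c(1.1, 1.2), c(1, 1.1), sd_cutoffs = 50)
  expect_true(is.na(r2$rate))
  expect_equal(r2$n_pairs, 0L)
})

test_that("selection rates are null-calibrated and anti-symmetric", {
  set.seed(45)
  n <- 1000
  case_s <- rnorm(n)
  ctrl_s <- rnorm(n)
  r <- asp_selection_rate(case_s, ctrl_s)
  expect_lt(abs(r$rate[1] - 0.5), 3 * r$se[1])
  # anti-predictor: qualifying sets unchanged, rates flip
  ra <- asp_selection_rate(-case_s, -ctrl_s)
  expect_equal(ra$n_pairs, r$n_pairs)
  expect_equal(ra$rate, 1 - r$rate)
  # cutoff sets are nested
  expect_true(all(diff(r$n_pairs) <= 0))

  y_a <- rnorm(n)
  y_b <- rnorm(n)
  rr <- rank_order_selection_rate(rnorm(n), rnorm(n), y_a, y_b)
  expect_lt(abs(rr$rate[1] - 0.5), 3 * rr$se[1])
  # PGS identical to phenotype: rate 1 wherever defined
  rp <- rank_order_selection_rate(y_a, y_b, y_a, y_b)
  expect_true(all(rp$rate[rp$n_pairs > 0] == 1))
  # no qualifying pairs at a large cutoff
  rq <- rank_order_selection_rate(c(1, 2), c(2, 1), c(0.1, 0.2), c(0.2, 0.1),
                                  sd_cutoffs = 60)
  expect_true(is.na(rq$rate))
})

test_that("SSV matches its closed form and the independent-SNP variance", {
  fx <- make_fixture(n = 4000, p = 500, s = 10, seed = 47, maf_low = 0.05)
  g <- fx$geno
  p1 <- make_predictor_fixture(g, 1, snps = 1)
  p1$training_freq <- 0.5
  expect_equal(ssv(p1)$total, 0.5) # 2 * 1 * 0.25
  p0 <- make_predictor_fixture(g, c(0, 0), snps = 1:2)
  expect_equal(ssv(p0)$total, 0)
  set.seed(48)
  w <- rnorm(500, sd = 0.1)
  pw <- make_predictor_fixture(g, w, snps = 1:500)
  pw$training_freq <- colMeans(g$dosages) / 2
  scores <- compute_pgs(g, pw)
  sv <- ssv(pw)
  expect_lt(abs(sv$total - var(scores)) / var(scores), 0.05)
  expect_equal(sum(sv$per_snp$share), 1)
  expect_equal(sum(sv$by_chr$share), 1)
  pbadf <- pw
  pbadf$training_freq[1] <- 1.5
  expect_error(ssv(pbadf), "freqs")
})

test_that("variance-explained estimates satisfy their identities", {
  set.seed(49)
  y <- rnorm(500)
  ve <- variance_explained(y, y)
  expect_equal(ve$triangle, 1)
  expect_equal(ve$corr2, 1)
  v0 <- variance_explained(rep(0, 500), y)
  expect_equal(v0$triangle, 0)
  expect_equal(v0$corr2, 0)
  expect_true(v0$degenerate)
  # corr(P, G)^2 estimates h2 at large n
  fx <- make_fixture(n = 5000, p = 100, s = 10, h2 = 0.5, seed = 50)
  vh <- variance_explained(fx$arch$genetic_values, fx$arch$phenotype)
  expect_equal(vh$corr2, 0.5, tolerance = 0.05)
  # the bullet estimate undoes the sex-specific z-scoring on the PGS
  sex <- rep(c(1, 2), 250)
  y_raw <- ifelse(sex == 1, 5, 9) + ifelse(sex == 1, 1, 2) * rnorm(500)
  z <- zscore_by_sex(y_raw, sex)
  vb <- variance_explained(z$y, z$y, y_raw = y_raw, sex = sex,
                           zscore_stats = z$stats)
  expect_equal(vb$bullet, 1, tolerance = 1e-10)
})

test_that("fold pooling combines spread and finite-sample error", {
  mk <- function(v, se) metric_result("auc", v, se, 100)
  single <- pool_metric(list(mk(0.6, 0.02)))
  expect_equal(single$value, 0.6)
  expect_equal(single$se, 0.02)
  same <- pool_metric(list(mk(0.6, 0.01), mk(0.6, 0.01)))
  expect_equal(same$components$cv_spread, 0)
  spread <- pool_metric(list(mk(0.60, 1e-9), mk(0.62, 1e-9), mk(0.64, 1e-9)))
  expect_equal(spread$value, 0.62)
  expect_equal(spread$se, sd(c(0.60, 0.62, 0.64)) / sqrt(3),
               tolerance = 1e-6)
})
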