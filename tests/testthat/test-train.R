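std_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  scale(X) * sqrt(n / (n - 1)) # unit mean-square columns
}

test_that("the null solution holds at and above lambda_max", {
  X <- std_design(100, 15, seed = 3)
  set.seed(4)
  y <- rnorm(100)
  lam_max <- max(abs(crossprod(X, y))) / (100 * 1)
  path <- enet_path(X, y, l1_ratio = 1, lambda = c(lam_max * 2, lam_max))
  expect_true(all(path$beta[, 1] == 0))
  expect_true(all(path$beta[, 2] == 0))
  # objective at the solution never exceeds the null objective
  path2 <- enet_path(X, y, l1_ratio = 0.5)
  null_obj <- sum(y^2) / (2 * 100)
  expect_true(all(path2$objective <= null_obj + 1e-10))
  expect_equal(path2$df[1], 0)
})

test_that("a single standardized SNP solves to the soft threshold", {
  n <- 200
  X <- std_design(n, 1, seed = 5)
  set.seed(6)
  y <- 0.7 * X[, 1] + rnorm(n)
  rho <- sum(X * y) / n
  xx <- sum(X^2) / n
  for (lam in c(0.05, 0.2, abs(rho) / xx * 2)) {
    path <- enet_path(X, y, l1_ratio = 1, lambda = c(lam * 1.5, lam))
    expected <- sign(rho) * max(abs(rho) - lam, 0) / xx
    expect_equal(as.numeric(path$beta[, 2]), expected, tolerance = 1e-6)
  }
})

test_that("path solutions match an independent coordinate-descent oracle", {
  X <- std_design(50, 20, seed = 7)
  set.seed(8)
  beta_true <- c(rep(1.5, 3), rep(0, 17))
  y <- drop(X %*% beta_true) + rnorm(50)
  for (r in c(1, 0.5)) {
    lam_max <- max(abs(crossprod(X, y))) / (50 * r)
    lams <- lam_max * c(0.5, 0.1, 0.02)
    path <- enet_path(X, y, l1_ratio = r, lambda = c(lam_max, lams),
                      thresh = 1e-12)
    for (k in seq_along(lams)) {
      bo <- oracle_enet(X, y, lams[k], r)
      expect_lt(max(abs(as.numeric(path$beta[, k + 1]) - bo)), 1e-5)
    }
  }
})

test_that("penalized logistic path shrinks to the intercept-only model", {
  fx <- make_fixture(n = 300, p = 30, s = 3, h2 = 0.8, seed = 19,
                     prevalence = 0.5)
  labels <- apply_liability_threshold(fx$arch$phenotype, 0.5)
  X <- scale(fx$geno$dosages)
  path <- l1_logistic_path(X, labels, nlambda = 30)
  expect_equal(path$df[1], 0) # lambda_max: no SNPs enter
  expect_true(max(path$df) > 0)
  expect_error(l1_logistic_path(X, rep(1, 300)), "both classes")
})

test_that("separable single-SNP logistic fits stay finite under L1", {
  set.seed(20)
  x <- matrix(c(rnorm(50, -2), rnorm(50, 2)), ncol = 1)
  lab <- rep(c(0L, 1L), each = 50)
  path <- l1_logistic_path(x, lab, nlambda = 40, lambda_min_ratio = 0.05)
  b <- as.numeric(path$beta[1, ])
  expect_true(all(is.finite(b)))
  # penalized-likelihood grid oracle at the smallest lambda on the path
  lam <- min(path$lambda)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x[, 1]
    mean(lab * eta - log(1 + exp(eta))) - lam * abs(b1)
  }
  grid <- seq(0, 10, by = 0.01)
  prof <- vapply(grid, function(b1) {
    stats::optimize(function(b0) -ll(b0, b1), c(-5, 5))$objective
  }, numeric(1))
  b1_star <- grid[which.min(prof)]
  expect_lt(abs(tail(b, 1)), 1.2 * b1_star + 1)
  expect_true(is.finite(b1_star))
})

test_that("hyperparameter selection maximizes the validation metric", {
  X <- std_design(300, 25, seed = 21)
  set.seed(22)
  y <- drop(X %*% c(rep(1, 5), rep(0, 20))) + rnorm(300)
  tr <- 1:200
  val <- 201:300
  path <- enet_path(X[tr, ], y[tr], l1_ratio = 1, nlambda = 40)
  sel <- select_hyperparameter(path, X[val, ], y[val])
  m <- sapply(seq_along(path$lambda), function(j) {
    s <- as.numeric(X[val, ] %*% path$beta[, j])
    if (sd(s) == 0) 0 else cor(s, y[val])
  })
  expect_equal(sel$value, max(m))
  expect_equal(sel$lambda, path$lambda[which.max(m)])
  expect_error(select_hyperparameter(path, X[0, , drop = FALSE], numeric(0)),
               "empty validation")
})

test_that("the one-SE rule steps back to sparser solutions", {
  X <- std_design(400, 10, seed = 23)
  set.seed(24)
  y <- drop(X %*% c(2, rep(0, 9))) + 0.2 * rnorm(400)
  path <- enet_path(X[1:300, ], y[1:300], l1_ratio = 1, nlambda = 50)
  sel0 <- select_hyperparameter(path, X[301:400, ], y[301:400])
  sel1 <- select_hyperparameter(path, X[301:400, ], y[301:400],
                                one_se_rule = TRUE, seed = 1)
  expect_lte(sel1$df, sel0$df)
  expect_gte(sel1$lambda, sel0$lambda)
})

test_that("continuous ladders are geometric and nested", {
  pool <- 1:4000
  rungs <- build_ladder(pool, NULL, n_rungs = 4, min_size = 500, seed = 2)
  sizes <- lengths(rungs)
  expect_equal(sizes, c(500, 1000, 2000, 4000))
  for (i in 1:3) expect_true(all(rungs[[i]] %in% rungs[[i + 1]]))
})

test_that("case-control ladders balance cases and add remaining controls", {
  cases <- 1:1000
  controls <- 1001:11000
  rungs <- build_ladder(cases, controls, n_rungs = 4, min_size = 100,
                        seed = 3)
  sched <- attr(rungs, "schedule")
  expect_equal(nrow(sched), 4)
  expect_equal(sched$n_cases[1:3], sched$n_controls[1:3])
  # final rung: all cases plus every remaining control
  expect_equal(sched$n_cases[4], 1000)
  expect_equal(sched$n_controls[4], 10000)
  for (i in 1:3) expect_true(all(rungs[[i]] %in% rungs[[i + 1]]))
  # case counts too close together collapse to fewer rungs with a warning
  expect_warning(build_ladder(1:105, 200:400, n_rungs = 8, min_size = 100),
                 "rungs")
  expect_error(build_ladder(1:50, 200:400, n_rungs = 4, min_size = 100),
               "fewer cases")
})

test_that("cross-validated ladder training keeps folds disjoint", {
  fx <- make_fixture(n = 700, p = 120, s = 8, h2 = 0.6, seed = 25,
                     maf_low = 0.1)
  cfg <- train_config(n_folds = 2, n_rungs = 3, ladder_min = 100,
                      validation_size = 80, top_k = 120, seed = 9)
  cv <- cv_train(fx$geno, fx$arch$phenotype, "continuous", cfg)
  expect_equal(nrow(cv$metrics), 2 * 3) # folds x rungs predictors
  expect_equal(length(cv$predictors), 2)
  expect_s3_class(cv$predictors[[1]][[3]], "pgs_predictor")
  curve <- metric_curve(cv)
  expect_equal(nrow(curve), 3)
  expect_true(all(diff(curve$N) > 0))
  # determinism
  cv2 <- cv_train(fx$geno, fx$arch$phenotype, "continuous", cfg)
  expect_equal(cv$metrics, cv2$metrics)
})

test_that("case-control training produces informative AUC ladders", {
  fx <- make_fixture(n = 1200, p = 100, s = 6, h2 = 0.8, seed = 29,
                     maf_low = 0.1, prevalence = 0.3)
  labels <- apply_liability_threshold(fx$arch$phenotype, 0.3)
  cfg <- train_config(n_folds = 2, n_rungs = 3, ladder_min = 40,
                      validation_size = 60, top_k = 100, nlambda = 40,
                      seed = 13)
  cv <- cv_train(fx$geno, labels, "binary", cfg)
  expect_equal(unique(cv$metrics$metric), "auc")
  expect_equal(nrow(cv$metrics), 6)
  # N counts cases; the final rung uses all remaining controls
  expect_true(all(cv$metrics$n_total >= cv$metrics$N))
  # a strongly heritable trait yields a clearly informative AUC at max N
  expect_gt(max(cv$metrics$value), 0.7)
  curve <- metric_curve(cv)
  expect_equal(nrow(curve), 3)
})

test_that("recovery at large N approaches the heritability ceiling", {
  # h2 = 0.5: test correlation should approach sqrt(0.5) ~ 0.707 from
  # below at the largest rung, with a finite-N shortfall
  # equal-magnitude effects so every causal SNP is recoverable at large N
  fx <- make_fixture(n = 2300, p = 400, s = 10, h2 = 0.5, seed = 27,
                     maf_low = 0.05, effect_dist = "equal")
  cfg <- train_config(n_folds = 1, n_rungs = 3, ladder_min = 300,
                      validation_size = 200, top_k = 400, seed = 5)
  cv <- cv_train(fx$geno, fx$arch$phenotype, "continuous", cfg)
  top <- cv$metrics$value[which.max(cv$metrics$N)]
  expect_gt(top, 0.5)
  expect_lt(top, 0.78)
  # support recovery: most causal SNPs present in the final predictor
  pred <- cv$predictors[[1]][[3]]
  causal_ids <- fx$geno$snp_ids[fx$arch$causal_indices]
  expect_gte(mean(causal_ids %in% pred$snp_id), 0.9)
})
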