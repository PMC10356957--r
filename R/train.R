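#' Training configuration
#'
#' @param l1_ratio vector of elastic-net mixing weights in (0, 1\]; 1 is the
#'   LASSO. Default is the LASSO; `c(0.1, 0.3, 0.5, 0.7, 0.9)` gives the
#'   usual elastic-net sweep.
#' @param nlambda number of penalty values on the log-spaced path.
#' @param lambda_min_ratio smallest penalty as a fraction of the null-model
#'   penalty `lambda_max`.
#' @param n_folds number of cross-validation folds.
#' @param validation_size samples withheld per fold for hyperparameter
#'   selection (balanced cases/controls for binary traits).
#' @param one_se_rule if `TRUE`, pick the sparsest penalty whose validation
#'   metric is within one bootstrap standard error of the maximum.
#' @param n_rungs number of training-size ladder rungs.
#' @param ladder_min smallest rung (total samples for continuous traits,
#'   cases for case-control).
#' @param top_k GWAS pre-filter size; SNP scans are run on the training
#'   subset only. Default 50000 (10000 is typical for penalized logistic
#'   regression, which is costlier).
#' @param thresh,maxit convergence tolerance and iteration cap for the
#'   path solver.
#' @param seed integer seed controlling fold splits, ladders and bootstraps.
#' @return an object of class `train_config`.
#' @export
train_config <- function(l1_ratio = 1, nlambda = 100,
                         lambda_min_ratio = 1e-3, n_folds = 5,
                         validation_size = 2500, one_se_rule = FALSE,
                         n_rungs = 11, ladder_min = 100,
                         top_k = 50000, thresh = 1e-9, maxit = 1e5,
                         seed = 1L) {
  if (any(l1_ratio <= 0 | l1_ratio > 1)) stop("l1_ratio must lie in (0, 1]")
  stopifnot(nlambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_folds >= 1, validation_size >= 1, n_rungs >= 1,
            ladder_min >= 1, top_k >= 1)
  structure(list(
    l1_ratio = l1_ratio, nlambda = as.integer(nlambda),
    lambda_min_ratio = lambda_min_ratio, n_folds = as.integer(n_folds),
    validation_size = as.integer(validation_size),
    one_se_rule = one_se_rule, n_rungs = as.integer(n_rungs),
    ladder_min = as.integer(ladder_min), top_k = as.integer(top_k),
    thresh = thresh, maxit = maxit, seed = as.integer(seed)
  ), class = "train_config")
}

#' Elastic-net regularization path
#'
#' Minimizes, for each penalty lambda on a descending log-spaced grid,
#' \deqn{\frac{1}{2N}\|y - X\beta\|_2^2 + \lambda\left(r \|\beta\|_1 +
#'   \frac{1-r}{2}\|\beta\|_2^2\right)}
#' with mixing weight `r = l1_ratio` (1 = LASSO). The path starts at
#' `lambda_max = max|X'y| / (N r)`, where the null solution `beta = 0`
#' satisfies the KKT conditions exactly. Solving is delegated to the
#' coordinate-descent engine of \pkg{glmnet} with warm starts along the
#' path; `X` is expected already column-standardized on the training
#' samples and `y` centered, and no intercept is fit.
#'
#' @param X standardized genotype matrix (training fold).
#' @param y adjusted (centered) phenotype.
#' @param l1_ratio single mixing weight in (0, 1\].
#' @param nlambda,lambda_min_ratio path grid controls.
#' @param lambda optional explicit descending penalty grid.
#' @param thresh,maxit solver convergence tolerance and iteration cap.
#' @return an object of class `enet_path`: `lambda`, sparse coefficient
#'   matrix `beta` (p x n_lambda), active-set sizes `df`, per-lambda
#'   `objective` values and `l1_ratio`.
#' @export
enet_path <- function(X, y, l1_ratio = 1, nlambda = 100,
                      lambda_min_ratio = 1e-3, lambda = NULL,
                      thresh = 1e-9, maxit = 1e5) {
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  if (l1_ratio <= 0 || l1_ratio > 1) stop("l1_ratio must lie in (0, 1]")
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(X, y))) / (n * l1_ratio)
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  # glmnet standardizes y internally, which silently rescales the ridge
  # part of the penalty by sd(y). Feed it y at exactly unit (population)
  # variance so that standardization is a no-op, with (alpha, lambda)
  # transformed so the returned solution minimizes the stated objective at
  # the requested l1_ratio and lambda grid: for b = sy * b~,
  # lambda~ alpha~ = lambda r / sy and lambda~ (1 - alpha~) = lambda (1 - r).
  sy <- sqrt(mean((y - mean(y))^2))
  if (sy > 0 && abs(sy - 1) > 1e-12) {
    y_g <- y / sy
    kap <- l1_ratio / sy + (1 - l1_ratio)
    alpha_g <- (l1_ratio / sy) / kap
    lambda_g <- lambda * kap
  } else {
    y_g <- y
    sy <- 1
    alpha_g <- l1_ratio
    lambda_g <- lambda
  }
  if (ncol(X) == 1) { # glmnet requires >= 2 columns; pad an inert one
    X <- cbind(X, 0)
    padded <- TRUE
  } else {
    padded <- FALSE
  }
  fit <- glmnet::glmnet(X, y_g, family = "gaussian", alpha = alpha_g,
                        lambda = lambda_g, standardize = FALSE,
                        intercept = FALSE, thresh = thresh, maxit = maxit)
  beta <- fit$beta * sy
  if (padded) {
    X <- X[, 1, drop = FALSE]
    beta <- beta[1, , drop = FALSE]
  }
  # Refine solutions to tight KKT residuals of the stated objective
  # (glmnet's own stopping rule leaves coefficient errors around 1e-5 on
  # elastic-net problems). Refinement is restricted to the sparse regime:
  # deep-overfit tail solutions (active sets comparable to n) converge
  # pathologically slowly under coordinate descent and are never selected
  # by validation.
  beta <- as.matrix(beta)
  beta[abs(beta) < 1e-12] <- 0 # drop numerically-zero boundary flicker
  xx <- colSums(X^2) / n
  df_cap <- min(ceiling(0.5 * n), 400)
  for (j in seq_along(lambda)) {
    if (sum(beta[, j] != 0) <= df_cap) {
      beta[, j] <- cd_refine(X, y, beta[, j], lambda[j], l1_ratio, xx)
    }
  }
  beta[abs(beta) < 1e-12] <- 0
  beta <- methods::as(beta, "CsparseMatrix")
  obj <- vapply(seq_along(lambda), function(j) {
    enet_objective(X, y, beta[, j], lambda[j], l1_ratio)
  }, numeric(1))
  structure(list(
    lambda = lambda, beta = beta,
    df = unname(Matrix::colSums(beta != 0)), objective = obj,
    l1_ratio = l1_ratio, family = "gaussian",
    converged = length(fit$lambda) == length(lambda)
  ), class = "enet_path")
}

#' Elastic-net objective value
#'
#' Evaluates the penalized least-squares objective minimized by
#' [enet_path()] at a given coefficient vector.
#'
#' @param X,y as in [enet_path()].
#' @param beta coefficient vector.
#' @param lambda,l1_ratio penalty and mixing weight.
#' @return the scalar objective value.
#' @export
enet_objective <- function(X, y, beta, lambda, l1_ratio) {
  n <- nrow(X)
  r <- y - drop(X %*% beta)
  sum(r^2) / (2 * n) +
    lambda * (l1_ratio * sum(abs(beta)) +
                (1 - l1_ratio) / 2 * sum(beta^2))
}

#' L1-penalized logistic regression path
#'
#' Maximizes the L1-penalized Bernoulli log-likelihood over a descending
#' penalty grid (with an unpenalized intercept), via \pkg{glmnet}'s binomial
#' coordinate descent.
#'
#' @param X standardized genotype matrix.
#' @param labels binary labels (0/1); both classes must be present.
#' @param nlambda,lambda_min_ratio,lambda,thresh,maxit as in [enet_path()].
#' @return an `enet_path` object with `family = "binomial"`.
#' @export
l1_logistic_path <- function(X, labels, nlambda = 100,
                             lambda_min_ratio = 1e-3, lambda = NULL,
                             thresh = 1e-9, maxit = 1e5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (ncol(X) == 1) {
    X <- cbind(X, 0)
    padded <- TRUE
  } else {
    padded <- FALSE
  }
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = 1,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE, thresh = thresh, maxit = maxit)
  beta <- fit$beta
  if (padded) beta <- beta[1, , drop = FALSE]
  structure(list(
    lambda = fit$lambda, beta = beta, intercept = fit$a0,
    df = unname(Matrix::colSums(beta != 0)), objective = NULL,
    l1_ratio = 1, family = "binomial", converged = TRUE
  ), class = "enet_path")
}

# Active-set coordinate descent started from an approximate solution:
# sweeps the active set to stationarity, then runs a full KKT pass over
# all coordinates to admit violators, until no violation remains.
# Implemented in compiled code (src/cd_refine.cpp).
cd_refine <- function(X, y, beta, lambda, l1_ratio, xx,
                      tol = 1e-10, max_outer = 10, max_sweeps = 500) {
  cd_refine_cpp(X, y, as.numeric(beta), lambda, l1_ratio, xx,
                tol, as.integer(max_outer), as.integer(max_sweeps))
}

# validation metric for every column of a path's coefficient matrix
path_validation_metric <- function(path, X_val, y_val, metric) {
  S <- as.matrix(X_val %*% path$beta)
  vapply(seq_len(ncol(S)), function(j) {
    s <- S[, j]
    if (stats::sd(s) == 0) {
      return(if (metric == "auc") 0.5 else 0)
    }
    if (metric == "auc") auc_value(s, y_val) else stats::cor(s, y_val)
  }, numeric(1))
}

#' Validation-set hyperparameter selection
#'
#' Scores every (l1_ratio, lambda) pair of one or more regularization paths
#' on a withheld validation set and picks the maximizer of the validation
#' metric (AUC for binary traits, correlation for continuous). With
#' `one_se_rule = TRUE`, a bootstrap standard error of the best metric is
#' estimated and the sparsest solution within one SE of the maximum is
#' chosen instead (stepping "back" toward fewer features).
#'
#' @param paths an `enet_path` or list of them (one per l1_ratio).
#' @param X_val validation design matrix on the same (standardized) scale
#'   as training.
#' @param y_val validation phenotype or labels; for case-control selection
#'   the validation set should hold equal cases and controls.
#' @param metric `"auto"` (by path family), `"correlation"` or `"auc"`.
#' @param one_se_rule apply the one-standard-error rule.
#' @param n_boot bootstrap replicates for the one-SE rule.
#' @param seed RNG seed for the bootstrap.
#' @return list with `path_index`, `lambda_index`, `lambda`, `l1_ratio`,
#'   `beta` (sparse vector), `df`, `metric`, `value` and `se`.
#' @export
select_hyperparameter <- function(paths, X_val, y_val,
                                  metric = c("auto", "correlation", "auc"),
                                  one_se_rule = FALSE, n_boot = 200,
                                  seed = 1L) {
  if (inherits(paths, "enet_path")) paths <- list(paths)
  if (nrow(X_val) == 0 || length(y_val) == 0) stop("empty validation set")
  metric <- match.arg(metric)
  if (metric == "auto") {
    metric <- if (paths[[1]]$family == "binomial") "auc" else "correlation"
  }
  grid <- do.call(rbind, lapply(seq_along(paths), function(i) {
    m <- path_validation_metric(paths[[i]], X_val, y_val, metric)
    data.frame(path = i, lambda_index = seq_along(m),
               lambda = paths[[i]]$lambda, df = paths[[i]]$df, value = m)
  }))
  best <- grid[order(-grid$value, grid$df, -grid$lambda), ][1, ]
  se <- 0
  if (one_se_rule) {
    set.seed(stage_seed(seed, "boot"))
    bpath <- paths[[best$path]]
    s_best <- as.numeric(X_val %*% bpath$beta[, best$lambda_index])
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(y_val), replace = TRUE)
      if (stats::sd(s_best[idx]) == 0 || length(unique(y_val[idx])) < 2) {
        return(NA_real_)
      }
      if (metric == "auc") auc_value(s_best[idx], y_val[idx]) else {
        stats::cor(s_best[idx], y_val[idx])
      }
    }, numeric(1))
    se <- stats::sd(vals, na.rm = TRUE)
    ok <- grid[grid$value >= best$value - se, ]
    best <- ok[order(ok$df, -ok$lambda, -ok$value), ][1, ]
  }
  path <- paths[[best$path]]
  list(path_index = best$path, lambda_index = best$lambda_index,
       lambda = best$lambda, l1_ratio = path$l1_ratio,
       beta = path$beta[, best$lambda_index], df = best$df,
       metric = metric, value = best$value, se = se)
}

#' Training-size ladder construction
#'
#' Builds nested training subsets of geometrically increasing size. For
#' continuous traits the rungs are total-sample counts. For case-control
#' traits the first `n_rungs - 1` rungs hold equal numbers of cases and
#' controls at geometrically increasing case counts, and the final rung
#' adds every remaining control to the maximal case set. Nesting (each rung
#' contains the previous) makes metric growth comparable across rungs.
#'
#' @param case_idx sample indices of cases (or of all training-pool samples
#'   for a continuous trait).
#' @param control_idx sample indices of controls, or `NULL` for continuous.
#' @param n_rungs requested number of rungs.
#' @param min_size smallest rung (cases for case-control, total otherwise).
#' @param seed RNG seed for the single shuffle that defines nesting.
#' @return list of index vectors, one per rung, with a `schedule` attribute
#'   (data.frame rung / n_cases / n_controls / n).
#' @export
build_ladder <- function(case_idx, control_idx = NULL, n_rungs = 11,
                         min_size = 100, seed = 1L) {
  set.seed(stage_seed(seed, "ladder"))
  if (is.null(control_idx)) {
    pool <- sample(case_idx)
    if (length(pool) < min_size) stop("training pool smaller than min_size")
    sizes <- unique(round(geom_seq(min_size, length(pool), n_rungs)))
    rungs <- lapply(sizes, function(s) sort(pool[seq_len(s)]))
    attr(rungs, "schedule") <- data.frame(
      rung = seq_along(sizes), n_cases = NA_integer_,
      n_controls = NA_integer_, n = sizes
    )
    return(rungs)
  }
  cases <- sample(case_idx)
  controls <- sample(control_idx)
  n_bal <- n_rungs - 1L
  if (length(cases) < min_size) {
    stop("fewer cases than the smallest rung")
  }
  c_sizes <- unique(round(geom_seq(min_size, length(cases), n_bal)))
  if (length(c_sizes) < n_bal) {
    warning("case count supports only ", length(c_sizes) + 1L, " rungs")
  }
  ctrl_cap <- length(controls)
  rungs <- lapply(c_sizes, function(s) {
    sort(c(cases[seq_len(s)], controls[seq_len(min(s, ctrl_cap))]))
  })
  # final rung: maximum cases plus all remaining controls
  rungs <- c(rungs, list(sort(c(cases, controls))))
  sched <- data.frame(
    rung = seq_along(rungs),
    n_cases = c(c_sizes, length(cases)),
    n_controls = c(pmin(c_sizes, ctrl_cap), length(controls))
  )
  sched$n <- sched$n_cases + sched$n_controls
  attr(rungs, "schedule") <- sched
  rungs
}

# Standardize a column subset on the training rows and freeze the
# statistics for validation/test scoring. Constant columns are dropped.
freeze_standardization <- function(D, train_rows, snp_subset) {
  Xtr <- D[train_rows, snp_subset, drop = FALSE]
  mu <- colMeans(Xtr)
  sdv <- col_sds(Xtr)
  keep <- sdv > 0
  list(snp = snp_subset[keep], mu = mu[keep], sd = sdv[keep])
}

apply_standardization <- function(D, rows, std) {
  X <- D[rows, std$snp, drop = FALSE]
  sweep(sweep(X, 2, std$mu, "-"), 2, std$sd, "/")
}

# Build a dosage-scale predictor from a standardized-scale solution.
make_predictor <- function(genotypes, std, beta_std, sel, trait_type,
                           n_train, fold = NA_integer_) {
  nz <- which(beta_std != 0)
  w <- as.numeric(beta_std[nz]) / std$sd[nz]
  idx <- std$snp[nz]
  pred <- data.frame(
    snp_id = genotypes$snp_ids[idx],
    chr = genotypes$chr[idx],
    pos = genotypes$pos[idx],
    effect_allele = genotypes$effect_allele[idx],
    weight = w,
    training_freq = std$mu[nz] / 2,
    stringsAsFactors = FALSE
  )
  structure(pred, class = c("pgs_predictor", "data.frame"),
            lambda = sel$lambda, l1_ratio = sel$l1_ratio,
            n_train = n_train, trait_type = trait_type, fold = fold,
            cols = idx)
}

#' @export
print.pgs_predictor <- function(x, ...) {
  cat(sprintf(
    "pgs_predictor: %d SNPs (lambda = %.4g, l1_ratio = %.2g, N = %s)\n",
    nrow(x), attr(x, "lambda") %||% NA, attr(x, "l1_ratio") %||% NA,
    attr(x, "n_train") %||% "?"
  ))
  invisible(x)
}

# One train/validation/test split run over a training-size ladder.
# Returns per-rung predictors and test metrics.
fit_ladder <- function(genotypes, y, rungs, val_rows, test_rows,
                       trait_type = c("continuous", "binary"),
                       config = train_config(), fold = NA_integer_) {
  trait_type <- match.arg(trait_type)
  D <- genotypes$dosages
  metrics <- NULL
  predictors <- vector("list", length(rungs))
  sched <- attr(rungs, "schedule")
  for (i in seq_along(rungs)) {
    tr <- rungs[[i]]
    gwas <- single_marker_regression(D[tr, , drop = FALSE], y[tr])
    keep <- select_top_k(gwas, config$top_k)
    std <- freeze_standardization(D, tr, keep)
    Xtr <- apply_standardization(D, tr, std)
    ytr <- y[tr]
    if (trait_type == "continuous") {
      ytr <- ytr - mean(ytr)
      paths <- lapply(config$l1_ratio, function(r) {
        enet_path(Xtr, ytr, l1_ratio = r, nlambda = config$nlambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  thresh = config$thresh, maxit = config$maxit)
      })
    } else {
      paths <- list(l1_logistic_path(Xtr, y[tr], nlambda = config$nlambda,
                                     lambda_min_ratio = config$lambda_min_ratio,
                                     thresh = config$thresh,
                                     maxit = config$maxit))
    }
    Xval <- apply_standardization(D, val_rows, std)
    sel <- select_hyperparameter(paths, Xval, y[val_rows],
                                 one_se_rule = config$one_se_rule,
                                 seed = config$seed + i)
    n_train <- if (!is.null(sched) && !is.na(sched$n_cases[i])) {
      sched$n_cases[i]
    } else {
      length(tr)
    }
    pred <- make_predictor(genotypes, std, sel$beta, sel, trait_type,
                           n_train, fold)
    predictors[[i]] <- pred
    scores <- score_rows(D, test_rows, pred)
    mr <- if (trait_type == "binary") {
      metric_auc(scores, y[test_rows])
    } else {
      if (stats::sd(scores) == 0) {
        metric_result("correlation", 0, NA_real_, length(test_rows))
      } else {
        metric_correlation(scores, y[test_rows])
      }
    }
    metrics <- rbind(metrics, data.frame(
      fold = fold, rung = i, N = n_train, n_total = length(tr),
      n_active = nrow(pred), lambda = sel$lambda, l1_ratio = sel$l1_ratio,
      metric = mr$metric, value = mr$value, se = mr$se
    ))
  }
  list(predictors = predictors, metrics = metrics)
}

# score rows of the source dosage matrix with a predictor built in-session
# (column indices cached at construction; external data goes through
# compute_pgs, which resolves SNPs by id and allele)
score_rows <- function(D, rows, pred) {
  cols <- attr(pred, "cols")
  if (is.null(cols)) {
    stop("internal: predictor lacks column resolution; use compute_pgs()")
  }
  if (nrow(pred) == 0) return(rep(0, length(rows)))
  drop(D[rows, cols, drop = FALSE] %*% pred$weight)
}

#' Cross-validated ladder training
#'
#' The full training protocol: samples are split into `n_folds` folds; for
#' each fold the fold itself is the test set, `validation_size` samples are
#' withheld from the remainder for hyperparameter selection (balanced
#' cases/controls for binary traits), and the rest form the training pool
#' from which a nested training-size ladder is drawn. At every (fold, rung)
#' the GWAS pre-filter is re-run on that training subset alone, the
#' regularization path is fit for each `l1_ratio`, the hyperparameters are
#' selected on the withheld validation set and the resulting predictor is
#' evaluated on the fold's test set. Deterministic given `config$seed`.
#'
#' @param genotypes a QC'd [genotype_matrix()] (no missing dosages).
#' @param y adjusted phenotype (continuous) or 0/1 labels (binary).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param config a [train_config()].
#' @return an object of class `cv_ladder`: `predictors` (list indexed
#'   \[fold\]\[\[rung\]\]), `metrics` (long data.frame) and `config`.
#' @export
cv_train <- function(genotypes, y, trait_type = c("continuous", "binary"),
                     config = train_config()) {
  trait_type <- match.arg(trait_type)
  n <- nrow(genotypes$dosages)
  stopifnot(length(y) == n)
  set.seed(stage_seed(config$seed, "split"))
  fold_id <- sample(rep_len(seq_len(config$n_folds), n))
  folds <- vector("list", config$n_folds)
  all_metrics <- NULL
  for (f in seq_len(config$n_folds)) {
    test_rows <- if (config$n_folds == 1) NULL else which(fold_id == f)
    rest <- if (config$n_folds == 1) seq_len(n) else which(fold_id != f)
    if (config$n_folds == 1) {
      # single split: carve a test set the size of one nominal fold (20%)
      test_rows <- sort(sample(rest, max(2, round(0.2 * n))))
      rest <- setdiff(rest, test_rows)
    }
    val_rows <- draw_validation(rest, y, trait_type, config$validation_size)
    pool <- setdiff(rest, val_rows)
    rungs <- if (trait_type == "binary") {
      build_ladder(pool[y[pool] == 1], pool[y[pool] == 0],
                   n_rungs = config$n_rungs, min_size = config$ladder_min,
                   seed = config$seed + f)
    } else {
      build_ladder(pool, NULL, n_rungs = config$n_rungs,
                   min_size = config$ladder_min, seed = config$seed + f)
    }
    res <- fit_ladder(genotypes, y, rungs, val_rows, test_rows,
                      trait_type, config, fold = f)
    folds[[f]] <- res$predictors
    all_metrics <- rbind(all_metrics, res$metrics)
  }
  structure(list(predictors = folds, metrics = all_metrics,
                 config = config, trait_type = trait_type),
            class = "cv_ladder")
}

draw_validation <- function(rest, y, trait_type, size) {
  if (trait_type == "binary") {
    cases <- rest[y[rest] == 1]
    controls <- rest[y[rest] == 0]
    k <- min(floor(size / 2), length(cases) %/% 2, length(controls))
    if (k < 1) stop("not enough cases/controls for a balanced validation set")
    sort(c(sample(cases, k), sample(controls, k)))
  } else {
    if (length(rest) <= size) stop("validation_size >= available samples")
    sort(sample(rest, size))
  }
}

#' Pooled metric curve from a cross-validated ladder
#'
#' Averages each rung's test metric over folds via [pool_metric()]
#' (cross-validation spread and finite-sample errors combined in
#' quadrature), producing the (N, value, se, n_active) trajectory consumed
#' by the sparsity and projection modules.
#'
#' @param cv a `cv_ladder` from [cv_train()], or its `metrics` data.frame.
#' @return data.frame with columns `N`, `value`, `se`, `n_active`, `n_folds`.
#' @export
metric_curve <- function(cv) {
  m <- if (inherits(cv, "cv_ladder")) cv$metrics else cv
  out <- do.call(rbind, lapply(split(m, m$rung), function(g) {
    pooled <- pool_metric(lapply(seq_len(nrow(g)), function(i) {
      metric_result(g$metric[i], g$value[i], g$se[i], g$N[i])
    }))
    data.frame(N = stats::median(g$N), value = pooled$value,
               se = pooled$se, n_active = mean(g$n_active),
               n_folds = nrow(g))
  }))
  out <- out[order(out$N), ]
  rownames(out) <- NULL
  out
}
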