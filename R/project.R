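#' Bounded four-parameter growth families
#'
#' Each family models a bounded performance metric as
#' `g(x; a, b, c, d) = a + b u(c (x + d))` with `x = log10(N)` and `u` a
#' sigmoidal kernel rising from -1 to +1: logistic (`sigmoid`), inverse
#' tangent (`atan`), error function (`erf`) or hyperbolic tangent (`tanh`).
#' The left asymptote is `a - b`, the right (infinite-data) asymptote
#' `a + b`. The tanh kernel is an exact reparameterization of the sigmoid
#' kernel (`tanh(z) = 2 logistic(2z) - 1`), which the fitting uses as a
#' cross-check against local minima.
#'
#' @return character vector of the family names.
#' @export
growth_families <- function() c("sigmoid", "atan", "erf", "tanh")

family_kernel <- function(family) {
  switch(family,
    sigmoid = list(
      u = function(z) 2 / (1 + exp(-z)) - 1,
      du = function(z) {
        s <- 1 / (1 + exp(-z))
        2 * s * (1 - s)
      }
    ),
    atan = list(
      u = function(z) (2 / pi) * atan(z),
      du = function(z) (2 / pi) / (1 + z^2)
    ),
    erf = list(
      u = function(z) 2 * stats::pnorm(z * sqrt(2)) - 1,
      du = function(z) 2 * sqrt(2) * stats::dnorm(z * sqrt(2))
    ),
    tanh = list(
      u = function(z) tanh(z),
      du = function(z) 1 - tanh(z)^2
    ),
    stop("unknown growth family: ", family)
  )
}

#' Evaluate a growth curve
#'
#' @param params numeric vector `c(a, b, c, d)`.
#' @param x evaluation points on the `log10(N)` axis.
#' @param family one of [growth_families()].
#' @return numeric vector `a + b u(c (x + d))`.
#' @export
growth_curve <- function(params, x, family) {
  k <- family_kernel(family)
  unname(params[1] + params[2] * k$u(params[3] * (x + params[4])))
}

metric_bounds <- function(metric_type) {
  switch(metric_type,
    auc = c(0.5, 1),
    correlation = c(0, 1),
    stop("metric_type must be 'auc' or 'correlation'")
  )
}

# Unconstrained reparameterization enforcing the physical constraints
#   L <= a - b, a + b <= U, b > 0, c > 0, d <= 0.
# t = (t1..t4): hi = L + (U - L) logistic(t1); b = (hi - L)/2 logistic(t2);
# a = hi - b; c = exp(t3); d = -exp(t4).
theta_to_params <- function(t, L, U) {
  hi <- L + (U - L) * stats::plogis(t[1])
  b <- (hi - L) / 2 * stats::plogis(t[2])
  c(a = hi - b, b = b, c = exp(t[3]), d = -exp(t[4]))
}

params_to_theta <- function(par, L, U) {
  hi <- par[1] + par[2]
  hi <- min(max(hi, L + 1e-9), U - 1e-9)
  frac <- min(max(par[2] / ((hi - L) / 2), 1e-9), 1 - 1e-9)
  c(stats::qlogis((hi - L) / (U - L)), stats::qlogis(frac),
    log(max(par[3], 1e-9)), log(max(-par[4], 1e-9)))
}

growth_jacobian <- function(params, x, family) {
  k <- family_kernel(family)
  z <- params[3] * (x + params[4])
  u <- k$u(z)
  du <- k$du(z)
  cbind(a = rep(1, length(x)), b = u,
        c = params[2] * du * (x + params[4]),
        d = params[2] * du * params[3])
}

#' Fit a bounded growth family to a metric curve
#'
#' Weighted least squares (weights `1 / se^2`) of the four-parameter family
#' to metric-versus-`log10(N)` points, under the physical constraints that
#' the metric stays within its bounds (AUC in \[0.5, 1\], correlation in
#' \[0, 1\]: `a - b >= lower`, `a + b <= upper`), growth is increasing in
#' training size (`b, c > 0`) and occurs at positive sample counts
#' (`d <= 0`). The constraints are imposed through a smooth
#' reparameterization and the reparameterized problem solved by BFGS from
#' multiple starts. The parameter covariance is the inverse Gauss-Newton
#' Hessian of the weighted residual sum of squares at the optimum.
#'
#' @param curve data.frame with columns `N`, `value`, `se` (positive),
#'   at least 5 points. For case-control traits `N` should count cases.
#' @param family one of [growth_families()].
#' @param metric_type `"auc"` or `"correlation"`.
#' @param starts number of extra random starts.
#' @return an object of class `projection_fit`: `params` (a, b, c, d),
#'   `cov`, `family`, `metric_type`, `bounds`, `converged`, `ssr`, plus the
#'   fitted data.
#' @export
fit_growth <- function(curve, family = "erf",
                       metric_type = c("auc", "correlation"), starts = 8) {
  metric_type <- match.arg(metric_type)
  stopifnot(all(c("N", "value", "se") %in% names(curve)))
  curve <- curve[is.finite(curve$value) & is.finite(curve$se) &
                   curve$se > 0, ]
  if (nrow(curve) < 5) stop("need at least 5 points with positive se")
  bounds <- metric_bounds(metric_type)
  L <- bounds[1]
  U <- bounds[2]
  x <- log10(curve$N)
  y <- curve$value
  w <- 1 / curve$se^2

  ssr_fn <- function(t) {
    par <- theta_to_params(t, L, U)
    r <- y - growth_curve(par, x, family)
    sum(w * r^2)
  }

  hi0 <- min(max(max(y) + 0.25 * (max(y) - min(y)), L + 1e-3), U - 1e-4)
  start_list <- list()
  for (cc in c(0.5, 1, 2, 4)) {
    for (dd in c(-stats::median(x), -min(x), -max(x))) {
      start_list[[length(start_list) + 1]] <-
        params_to_theta(c((hi0 + L) / 2 + (hi0 - L) / 4, (hi0 - L) / 4,
                          cc, min(dd, -1e-3)), L, U)
    }
  }
  set.seed(1009L)
  for (i in seq_len(starts)) {
    start_list[[length(start_list) + 1]] <- stats::rnorm(4, 0, 1.5)
  }

  best <- NULL
  for (t0 in start_list) {
    o <- tryCatch(
      stats::optim(t0, ssr_fn, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(o) || !all(is.finite(o$par))) next
    # polish
    o2 <- tryCatch(
      stats::optim(o$par, ssr_fn, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) o
    )
    if (o2$value <= o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    return(structure(list(family = family, converged = FALSE),
                     class = "projection_fit"))
  }
  params <- theta_to_params(best$par, L, U)
  # Levenberg-Marquardt polish in the original parameter space with the
  # analytic Jacobian; kept only while it stays feasible and improves.
  polish <- lm_polish(params, x, y, w, family, L, U)
  if (polish$ssr <= best$value + 1e-12) {
    params <- polish$params
    best$value <- polish$ssr
  }
  J <- growth_jacobian(params, x, family)
  C <- gauss_newton_covariance(J, w)
  structure(list(
    family = family, params = params, cov = C,
    metric_type = metric_type, bounds = bounds,
    x = x, y = y, se = curve$se, N = curve$N,
    ssr = best$value, converged = TRUE
  ), class = "projection_fit")
}

#' @export
print.projection_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("projection_fit (%s): not converged\n", x$family))
    return(invisible(x))
  }
  cat(sprintf(
    "projection_fit (%s): a=%.4f b=%.4f c=%.4f d=%.4f  asymptote=%.4f\n",
    x$family, x$params[1], x$params[2], x$params[3], x$params[4],
    x$params[1] + x$params[2]
  ))
  invisible(x)
}

lm_polish <- function(params, x, y, w, family, L, U, maxit = 100) {
  feasible <- function(p) {
    p[1] - p[2] >= L - 1e-12 && p[1] + p[2] <= U + 1e-12 &&
      p[2] >= 0 && p[3] > 0 && p[4] <= 0
  }
  ssr_of <- function(p) sum(w * (y - growth_curve(p, x, family))^2)
  cur <- params
  cur_ssr <- ssr_of(cur)
  damp <- 1e-6
  for (it in seq_len(maxit)) {
    J <- growth_jacobian(cur, x, family)
    r <- y - growth_curve(cur, x, family)
    H <- crossprod(J * sqrt(w))
    g <- crossprod(J, w * r)
    step <- tryCatch(
      solve(H + damp * diag(diag(H) + 1e-12), g),
      error = function(e) NULL
    )
    if (is.null(step)) break
    cand <- cur + drop(step)
    names(cand) <- names(cur)
    if (feasible(cand) && ssr_of(cand) < cur_ssr) {
      if (max(abs(cand - cur)) < 1e-14) {
        cur <- cand
        break
      }
      cur <- cand
      cur_ssr <- ssr_of(cand)
      damp <- max(damp / 3, 1e-12)
    } else {
      damp <- damp * 10
      if (damp > 1e8) break
    }
  }
  list(params = cur, ssr = cur_ssr)
}

gauss_newton_covariance <- function(J, w) {
  H <- crossprod(J * sqrt(w))
  H <- (H + t(H)) / 2
  kap <- tryCatch(kappa(H, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e12) {
    ridge <- max(diag(H)) * 1e-10 + 1e-12
    message(sprintf(
      "near-singular Hessian (condition number %.3g); ridge-stabilized", kap
    ))
    H <- H + diag(ridge, nrow(H))
  }
  C <- solve(H)
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0) # PSD projection
  C <- e$vectors %*% diag(ev) %*% t(e$vectors)
  dimnames(C) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  (C + t(C)) / 2
}

#' Parameter covariance of a growth fit
#'
#' Inverse of the Gauss-Newton Hessian of the weighted residual sum of
#' squares at the optimum, symmetrized and projected onto the
#' positive-semidefinite cone; near-singular Hessians are ridge-stabilized
#' with a logged condition number.
#'
#' @param fit a converged `projection_fit`.
#' @return 4 x 4 covariance matrix of (a, b, c, d).
#' @export
param_covariance <- function(fit) {
  stopifnot(inherits(fit, "projection_fit"), fit$converged)
  J <- growth_jacobian(fit$params, fit$x, fit$family)
  gauss_newton_covariance(J, 1 / fit$se^2)
}

chol_lower <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(R)) return(t(R))
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

#' Monte-Carlo confidence band via Cholesky sampling
#'
#' Draws correlated parameter sets `Y = theta_hat + L X` with
#' `C = L L'` the Cholesky factorization of the parameter covariance and
#' `X` standard normal, rejects draws violating the physical constraints,
#' and forms per-N central 68% and 95% quantile bands of the implied
#' growth curves.
#'
#' @param fit a converged `projection_fit`.
#' @param n_draws Monte-Carlo draws (before rejection).
#' @param grid evaluation grid of training sizes N; defaults to 50
#'   log-spaced points spanning the fitted range extended 100-fold.
#' @param seed RNG seed.
#' @return an object of class `band_estimate`: `grid`, `central`, `lo68`,
#'   `hi68`, `lo95`, `hi95`, the accepted parameter `draws`, asymptote
#'   draws and acceptance bookkeeping.
#' @export
mc_band <- function(fit, n_draws = 10000, grid = NULL, seed = 1L) {
  stopifnot(inherits(fit, "projection_fit"), fit$converged)
  L <- fit$bounds[1]
  U <- fit$bounds[2]
  if (is.null(grid)) {
    grid <- 10^seq(min(fit$x), max(fit$x) + 2, length.out = 50)
  }
  set.seed(stage_seed(seed, "mc"))
  Lc <- chol_lower(fit$cov)
  X <- matrix(stats::rnorm(4 * n_draws), 4, n_draws)
  TH <- fit$params + Lc %*% X
  tol <- 1e-9
  ok <- TH[1, ] - TH[2, ] >= L - tol &
    TH[1, ] + TH[2, ] <= U + tol &
    TH[2, ] >= 0 & TH[3, ] >= 0 & TH[4, ] <= tol
  rej <- 1 - mean(ok)
  if (rej > 0.9) {
    stop(sprintf(
      "MC rejection rate %.1f%%: review constraints/covariance", 100 * rej
    ))
  }
  draws <- t(TH[, ok, drop = FALSE])
  colnames(draws) <- c("a", "b", "c", "d")
  gx <- log10(grid)
  curves <- apply(draws, 1, function(p) growth_curve(p, gx, fit$family))
  qs <- apply(curves, 1, stats::quantile,
              probs = c(0.025, 0.16, 0.84, 0.975), names = FALSE)
  structure(list(
    grid = grid, central = growth_curve(fit$params, gx, fit$family),
    lo95 = qs[1, ], lo68 = qs[2, ], hi68 = qs[3, ], hi95 = qs[4, ],
    draws = draws, asym_draws = draws[, "a"] + draws[, "b"],
    n_draws = n_draws, n_accepted = nrow(draws),
    rejection_rate = rej, fit = fit
  ), class = "band_estimate")
}

#' Asymptotic (infinite-data) metric of a growth fit
#'
#' The right asymptote `a + b` of the fitted family. The interval comes
#' from the accepted Monte-Carlo draws when a [mc_band()] is supplied, and
#' from the delta-method standard error
#' `var(a) + var(b) + 2 cov(a, b)` otherwise.
#'
#' @param x a converged `projection_fit` or a `band_estimate`.
#' @param level interval coverage (default 95%).
#' @return list with `value`, `se` and `interval`.
#' @export
asymptote <- function(x, level = 0.95) {
  al <- (1 - level) / 2
  if (inherits(x, "band_estimate")) {
    fit <- x$fit
    value <- fit$params[1] + fit$params[2]
    iv <- stats::quantile(x$asym_draws, c(al, 1 - al), names = FALSE)
    return(list(value = unname(value), se = stats::sd(x$asym_draws),
                interval = iv))
  }
  stopifnot(inherits(x, "projection_fit"), x$converged)
  value <- unname(x$params[1] + x$params[2])
  v <- x$cov[1, 1] + x$cov[2, 2] + 2 * x$cov[1, 2]
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - al)
  list(value = value, se = se, interval = c(value - z * se, value + z * se))
}

#' Pool asymptotes across growth families
#'
#' Inverse-variance-weighted mean of the per-family asymptotes. Because
#' every family is fit to the same metric curve, their estimation errors
#' are treated as fully dependent: the pooled standard deviation is the
#' weight-averaged family standard deviation (pooling same-data fits
#' cannot shrink the uncertainty the way independent replicates would),
#' and the between-family dispersion is added in quadrature so that
#' disagreeing families widen the interval even when each is individually
#' precise.
#'
#' @param fits list of converged `projection_fit` / `band_estimate`
#'   objects, or a list of [asymptote()] results.
#' @param level interval coverage.
#' @return list with `value`, `se`, `interval`, per-family table and the
#'   dispersion component.
#' @export
combine_families <- function(fits, level = 0.95) {
  asys <- lapply(fits, function(f) {
    if (inherits(f, c("projection_fit", "band_estimate"))) {
      if (inherits(f, "projection_fit") && !f$converged) return(NULL)
      asymptote(f, level)
    } else {
      f
    }
  })
  asys <- asys[!vapply(asys, is.null, logical(1))]
  if (length(asys) == 0) stop("no converged family fits to pool")
  vals <- vapply(asys, function(a) a$value, numeric(1))
  ses <- vapply(asys, function(a) a$se, numeric(1))
  if (any(ses <= 0)) {
    # exact fits: plain mean, dispersion only
    pooled <- mean(vals)
    base_var <- 0
    wts <- rep(1 / length(vals), length(vals))
  } else {
    wts <- 1 / ses^2
    wts <- wts / sum(wts)
    pooled <- sum(wts * vals)
    # full dependence between same-data fits: weighted mean of sds
    base_var <- sum(wts * ses)^2
  }
  disp2 <- sum(wts * (vals - pooled)^2)
  se <- sqrt(base_var + disp2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(value = pooled, se = se,
       interval = c(pooled - z * se, pooled + z * se),
       families = data.frame(value = vals, se = ses),
       dispersion = sqrt(disp2))
}

#' Project a metric to a planned biobank
#'
#' Evaluates a fitted growth band at the effective training size a new
#' biobank would supply: `prevalence x cohort_size` cases for case-control
#' traits (the conservative assumption that the biobank recruits at
#' population prevalence), the full cohort size for continuous traits.
#'
#' @param band a `band_estimate` from [mc_band()].
#' @param cohort_size planned cohort size.
#' @param prevalence population prevalence in (0, 1) for case-control
#'   traits; `NULL` for continuous.
#' @param name optional biobank name carried through to the output.
#' @return list with `name`, `n_eff`, `value`, `lo95`, `hi95` and an
#'   `extrapolated` flag (effective size beyond 10x the largest fitted N).
#' @export
project_biobank <- function(band, cohort_size, prevalence = NULL,
                            name = NULL) {
  stopifnot(inherits(band, "band_estimate"))
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  n_eff <- if (is.null(prevalence)) cohort_size else prevalence * cohort_size
  fit <- band$fit
  n_min <- min(fit$N)
  n_max <- max(fit$N)
  if (n_eff < n_min) {
    stop(sprintf("effective size %.0f below the fitted range [%.0f, %.0f]",
                 n_eff, n_min, n_max))
  }
  xe <- log10(n_eff)
  vals <- apply(band$draws, 1, function(p) growth_curve(p, xe, fit$family))
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(name = name, n_eff = n_eff,
       value = growth_curve(fit$params, xe, fit$family),
       lo95 = qs[1], hi95 = qs[2],
       extrapolated = n_eff > 10 * n_max)
}
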