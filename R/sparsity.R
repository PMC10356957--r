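#' Four sparsity definitions over a training-size ladder
#'
#' Sparsity of a trained sparse predictor can be counted in several ways:
#' \enumerate{
#'   \item active SNPs at the maximal training size (all cases and
#'     controls);
#'   \item active SNPs at the maximal *balanced* rung (largest equal
#'     cases/controls training);
#'   \item active SNPs at the rung of maximal relative increase of the
#'     performance metric, `(y[i+1] - y[i]) / y[i]` (or the first increase
#'     above `cut`);
#'   \item active SNPs at the rung of maximal relative increase of the
#'     feature count itself.
#' }
#' Definitions 1 and 2 coincide for continuous traits. For flat or
#' non-increasing trajectories the inflection-based definitions are flagged
#' undefined rather than reported.
#'
#' @param traj data.frame with columns `N`, `n_active`, `value` (and
#'   optionally `se`), e.g. from [metric_curve()], trained with maximum
#'   controls on the final rung.
#' @param traj_balanced optional trajectory from balanced (equal
#'   cases/controls) training; defaults to `traj`.
#' @param cut optional relative-increase threshold; when supplied, the
#'   first rung exceeding it is used instead of the argmax.
#' @return an object of class `sparsity_summary`: counts `def1`..`def4`,
#'   `inflection_N` (geometric midpoints for defs 3-4) and `defined` flags.
#' @export
sparsity_definitions <- function(traj, traj_balanced = NULL, cut = NULL) {
  stopifnot(nrow(traj) >= 3, all(c("N", "n_active", "value") %in% names(traj)))
  traj <- traj[order(traj$N), ]
  if (is.null(traj_balanced)) traj_balanced <- traj
  traj_balanced <- traj_balanced[order(traj_balanced$N), ]

  pick_inflection <- function(x, N) {
    r <- diff(x) / ifelse(abs(x[-length(x)]) > 0, x[-length(x)], NA_real_)
    if (all(is.na(r)) || max(r, na.rm = TRUE) <= 0) {
      return(list(idx = NA_integer_, N = NA_real_, defined = FALSE))
    }
    j <- if (!is.null(cut)) {
      w <- which(r > cut)
      if (length(w)) w[1] else which.max(r)
    } else {
      which.max(r)
    }
    list(idx = j + 1L, N = sqrt(N[j] * N[j + 1L]), defined = TRUE)
  }

  inf3 <- pick_inflection(traj$value, traj$N)
  inf4 <- pick_inflection(traj$n_active, traj$N)
  structure(list(
    def1 = traj$n_active[nrow(traj)],
    def2 = traj_balanced$n_active[nrow(traj_balanced)],
    def3 = if (inf3$defined) traj$n_active[inf3$idx] else NA_integer_,
    def4 = if (inf4$defined) traj$n_active[inf4$idx] else NA_integer_,
    inflection_N = c(def3 = inf3$N, def4 = inf4$N),
    defined = c(def3 = inf3$defined, def4 = inf4$defined)
  ), class = "sparsity_summary")
}

#' @export
print.sparsity_summary <- function(x, ...) {
  cat(sprintf("sparsity: def1 = %s, def2 = %s, def3 = %s, def4 = %s\n",
              x$def1, x$def2, x$def3, x$def4))
  invisible(x)
}

#' Detect compressed-sensing phase-transition behavior
#'
#' Locates the training size at which the test metric jumps most sharply
#' along a geometric ladder, the empirical signature of the Donoho-Tanner
#' phase transition for L1 recovery (expected near `N = 30 s` for
#' heritability 0.5). The jump statistic is the metric increment normalized
#' by the trajectory's total span, which makes detection invariant to
#' affine rescaling of the metric; `N*` is reported as the geometric
#' midpoint of the bracketing rung interval (ladders are geometric). When
#' every increment is below twice the pooled standard error the transition
#' is undefined (no jump above noise). The diagnostics flag the
#' characteristic non-monotone active-set signature: the solver first adds
#' many SNPs, sheds most of them (a >= 30% dip) just before the metric
#' jump, then grows again.
#'
#' @param traj data.frame with columns `N`, `value` and optionally `se` and
#'   `n_active`, sorted or sortable by `N`; at least 4 rungs.
#' @return list with `N_star` (`NA` when undefined), `defined`,
#'   `jump_interval`, `rel_increase` and `diagnostics` (with the `dip`
#'   flag).
#' @export
detect_phase_transition <- function(traj) {
  stopifnot(all(c("N", "value") %in% names(traj)))
  if (nrow(traj) < 4) stop("need at least 4 ladder rungs")
  traj <- traj[order(traj$N), ]
  y <- traj$value
  dy <- diff(y)
  span <- max(y) - min(y)
  undefined <- function(reason) {
    list(N_star = NA_real_, defined = FALSE, jump_interval = c(NA, NA),
         rel_increase = rep(NA_real_, length(dy)),
         diagnostics = list(dip = NA, reason = reason))
  }
  if (span <= 0) return(undefined("flat trajectory"))
  if (!is.null(traj$se) && any(is.finite(traj$se))) {
    pooled_se <- sqrt(mean(traj$se^2, na.rm = TRUE))
    if (all(dy < 2 * pooled_se)) return(undefined("no jump above noise"))
  }
  r <- dy / span
  j <- which.max(r)
  n_star <- sqrt(traj$N[j] * traj$N[j + 1L])
  dip <- NA
  if (!is.null(traj$n_active) && j >= 2) {
    cnt <- traj$n_active[seq_len(j)]
    peaks <- cummax(cnt)
    dip <- any(cnt <= 0.7 * peaks & peaks > 0)
  }
  list(N_star = n_star, defined = TRUE,
       jump_interval = c(traj$N[j], traj$N[j + 1L]),
       rel_increase = r,
       diagnostics = list(dip = dip, jump_index = j))
}

#' Log-log sparsity-versus-training-size scaling fit
#'
#' Ordinary least squares of `log10(s)` on `log10(N)` over pooled
#' (training size, active-SNP count) points, the empirical scaling law
#' relating predictor sparsity to sample size.
#'
#' @param N training sizes (positive).
#' @param s active-SNP counts (positive).
#' @return list with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r2` and `n`.
#' @export
loglog_scaling_fit <- function(N, s) {
  stopifnot(length(N) == length(s), length(N) >= 3)
  if (any(N <= 0) || any(s <= 0)) stop("N and s must be positive")
  fit <- stats::lm(log10(s) ~ log10(N))
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co[2, 1], slope_se = co[2, 2],
       intercept = co[1, 1], intercept_se = co[1, 2],
       r2 = sm$r.squared, n = length(N))
}

#' Phase-transition simulation experiment
#'
#' End-to-end experiment tying the simulator, LASSO ladder training and
#' transition detection together: simulate independent standardized
#' genotypes with a sparse additive architecture (s causal SNPs,
#' heritability `h2`), train a LASSO with validation-selected penalty at
#' geometrically spaced training sizes, measure test correlation per rung
#' and detect the training size of the maximal metric jump.
#'
#' @param s number of causal SNPs.
#' @param p number of SNPs.
#' @param h2 narrow-sense heritability.
#' @param ladder_range range `c(min, max)` of training sizes.
#' @param n_rungs ladder rungs (geometric).
#' @param validation_size,test_size withheld sample counts.
#' @param maf allele-frequency bounds `c(low, high)`.
#' @param effect_dist causal-effect model; the default `"equal"`
#'   (equal-magnitude, random-sign effects) is the canonical
#'   compressed-sensing benchmark in which the recovery transition is
#'   sharpest. `"normal"` effects let the largest effects be recovered
#'   well below the transition and pull the detected jump to smaller N.
#' @param seed RNG seed.
#' @return list with `N_star`, `transition` (full detector output),
#'   `trajectory` (per-rung N / n_active / value / se) and `s`.
#' @export
phase_transition_sim <- function(s = 20, p = 2000, h2 = 0.5,
                                 ladder_range = c(100, 1800), n_rungs = 11,
                                 validation_size = 500, test_size = 1000,
                                 maf = c(0.05, 0.5),
                                 effect_dist = "equal", seed = 1L) {
  n <- ladder_range[2] + validation_size + test_size
  cfg <- sim_config(n_samples = n, n_snps = p, n_causal = s, h2 = h2,
                    maf_low = maf[1], maf_high = maf[2],
                    effect_dist = effect_dist, seed = seed)
  geno <- simulate_genotypes(cfg)
  arch <- simulate_architecture(geno, cfg)
  y <- arch$phenotype
  set.seed(stage_seed(seed, "split"))
  ord <- sample.int(n)
  test_rows <- ord[seq_len(test_size)]
  val_rows <- ord[test_size + seq_len(validation_size)]
  pool <- ord[-seq_len(test_size + validation_size)]
  rungs <- build_ladder(pool, NULL, n_rungs = n_rungs,
                        min_size = ladder_range[1], seed = seed)
  tcfg <- train_config(l1_ratio = 1, n_rungs = n_rungs,
                       ladder_min = ladder_range[1], top_k = p,
                       seed = seed)
  res <- fit_ladder(geno, y, rungs, val_rows, test_rows,
                    trait_type = "continuous", config = tcfg)
  traj <- res$metrics[, c("N", "n_active", "value", "se")]
  trans <- detect_phase_transition(traj)
  list(N_star = trans$N_star, transition = trans, trajectory = traj, s = s)
}
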