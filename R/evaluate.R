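#' Construct a metric result
#'
#' Container for a metric value with its finite-sample standard error,
#' effective sample size and optional error components.
#'
#' @param metric metric name.
#' @param value metric value.
#' @param se standard error (non-negative or `NA`).
#' @param n_eff effective sample size.
#' @param components optional named list of error components.
#' @return an object of class `metric_result`.
#' @export
metric_result <- function(metric, value, se, n_eff, components = list()) {
  if (!is.na(se) && se < 0) stop("se must be non-negative")
  structure(list(metric = metric, value = value, se = se,
                 n_eff = n_eff, components = components),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (se %.4f, n = %d)\n", x$metric, x$value,
              x$se, as.integer(x$n_eff)))
  invisible(x)
}

#' Score genotypes against a sparse predictor
#'
#' Computes `PGS = X . beta` over the predictor's SNPs, resolving SNPs by
#' id and reconciling effect alleles: when the target matrix counts the
#' opposite allele, the dosage is complemented (`2 - x`). Missing dosages
#' are imputed to twice the predictor's training allele frequency. More
#' than 20% unresolvable predictor SNPs is an error; fewer produce a
#' warning with the count.
#'
#' @param genotypes a [genotype_matrix()].
#' @param predictor a `pgs_predictor` (from training or [read_predictor()]).
#' @return numeric vector of polygenic scores (one per sample), with the
#'   resolution bookkeeping in attributes `n_resolved` and `n_flipped`.
#' @export
compute_pgs <- function(genotypes, predictor) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(predictor) == 0) {
    return(structure(rep(0, nrow(genotypes$dosages)),
                     n_resolved = 0L, n_flipped = 0L))
  }
  pos <- match(predictor$snp_id, genotypes$snp_ids)
  found <- !is.na(pos)
  flip <- rep(FALSE, nrow(predictor))
  same <- found & genotypes$effect_allele[pos] == predictor$effect_allele
  flp <- found & !same & genotypes$other_allele[pos] == predictor$effect_allele
  resolved <- same | flp
  n_bad <- sum(!resolved)
  if (n_bad > 0.2 * nrow(predictor)) {
    stop(n_bad, " of ", nrow(predictor), " predictor SNPs unresolvable")
  }
  if (n_bad > 0) {
    warning(n_bad, " predictor SNP(s) unresolvable; skipped")
  }
  use <- which(resolved)
  D <- genotypes$dosages[, pos[use], drop = FALSE]
  if (anyNA(D)) {
    imp <- matrix(2 * predictor$training_freq[use], nrow(D), ncol(D),
                  byrow = TRUE)
    D[is.na(D)] <- imp[is.na(D)]
  }
  fl <- flp[use]
  if (any(fl)) D[, fl] <- 2 - D[, fl]
  structure(drop(D %*% predictor$weight[use]),
            n_resolved = length(use), n_flipped = sum(fl))
}

# Mann-Whitney AUC with ties counted one half
auc_value <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve with Hanley-McNeil error
#'
#' AUC via the Mann-Whitney U statistic (ties counted one half), i.e. the
#' probability that a random case outscores a random control, with the
#' Hanley-McNeil finite-sample standard error.
#'
#' @param scores polygenic scores.
#' @param labels 0/1 case-control labels.
#' @return a [metric_result()] with `value` in \[0, 1\].
#' @export
metric_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  a <- auc_value(scores, labels)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  metric_result("auc", a, se, n1 + n0,
                components = list(n_cases = n1, n_controls = n0))
}

#' Pearson correlation with Fisher-z error
#'
#' Correlation between PGS and adjusted phenotype; the finite-sample
#' standard error comes from the Fisher z transform
#' (`se_z = 1 / sqrt(n - 3)`) mapped back to the correlation scale.
#'
#' @param scores polygenic scores.
#' @param y_adj adjusted phenotype.
#' @return a [metric_result()].
#' @export
metric_correlation <- function(scores, y_adj) {
  n <- length(scores)
  stopifnot(length(y_adj) == n, n >= 4)
  if (stats::sd(scores) == 0 || stats::sd(y_adj) == 0) {
    stop("zero variance input")
  }
  r <- stats::cor(scores, y_adj)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  sez <- 1 / sqrt(n - 3)
  se <- (tanh(z + sez) - tanh(z - sez)) / 2
  metric_result("correlation", r, se, n)
}

#' Inclusive odds ratio curve
#'
#' At each percentile q of the score distribution, the inclusive odds ratio
#' is the ratio of cases to controls among all individuals *at that score
#' or above*, normalized by the overall case/control ratio:
#' `OR(q) = (cases >= q / controls >= q) / (total cases / total controls)`.
#' At the lowest percentile the inclusive set is everyone, so the OR is 1
#' exactly. Percentile bins with no cases or no controls above threshold
#' are omitted. Uncertainty is the Katz log-scale standard error for a
#' ratio of binomial proportions.
#'
#' @param scores polygenic scores.
#' @param labels 0/1 labels.
#' @param percentiles percentile grid; default 0 then 2..98 in steps of 2.
#' @return data.frame with `percentile`, `n_cases`, `n_controls`, `or`,
#'   `log_se`, `lo`, `hi` (95% interval).
#' @export
inclusive_odds_ratio <- function(scores, labels,
                                 percentiles = c(0, seq(2, 98, by = 2))) {
  labels <- as.integer(labels)
  Ca <- sum(labels == 1)
  Co <- sum(labels == 0)
  if (Ca == 0 || Co == 0) stop("both classes must be present")
  rows <- lapply(percentiles, function(q) {
    thr <- stats::quantile(scores, q / 100, type = 1, names = FALSE)
    sel <- scores >= thr
    ca <- sum(labels[sel] == 1)
    co <- sum(labels[sel] == 0)
    if (ca == 0 || co == 0) return(NULL) # bin omitted
    or <- (ca / co) / (Ca / Co)
    lse <- sqrt(1 / ca - 1 / Ca + 1 / co - 1 / Co)
    data.frame(percentile = q, n_cases = ca, n_controls = co, or = or,
               log_se = lse, lo = or * exp(-1.96 * lse),
               hi = or * exp(1.96 * lse))
  })
  do.call(rbind, rows)
}

#' Affected-sibling-pair selection rate
#'
#' For sibling pairs with one case and one control, the fraction of pairs
#' in which the case carries the higher PGS, recomputed with the pairs
#' restricted to score differences of at least `sd_cutoffs` standard
#' deviations. The SD unit is the PGS standard deviation across all sibling
#' individuals in the cohort. Pairs with exactly tied scores are dropped
#' (and counted). A cutoff with no qualifying pairs yields `NA` with
#' `n_pairs = 0`, not a rate of 0.
#'
#' @param case_scores,control_scores PGS of the case and control sibling of
#'   each pair (aligned vectors).
#' @param sd_cutoffs score-difference cutoffs in SD units.
#' @return data.frame with `cutoff`, `n_pairs`, `rate`, `se` (binomial), and
#'   the tie count in attribute `n_ties`.
#' @export
asp_selection_rate <- function(case_scores, control_scores,
                               sd_cutoffs = c(0, 1.5, 2, 2.5)) {
  stopifnot(length(case_scores) == length(control_scores))
  sd_unit <- stats::sd(c(case_scores, control_scores))
  d <- case_scores - control_scores
  ties <- d == 0
  if (any(ties)) message(sum(ties), " tied pair(s) dropped")
  d <- d[!ties]
  out <- do.call(rbind, lapply(sd_cutoffs, function(cut) {
    qual <- abs(d) >= cut * sd_unit
    m <- sum(qual)
    if (m == 0) {
      return(data.frame(cutoff = cut, n_pairs = 0L, rate = NA_real_,
                        se = NA_real_))
    }
    r <- mean(d[qual] > 0)
    data.frame(cutoff = cut, n_pairs = m, rate = r,
               se = sqrt(r * (1 - r) / m))
  }))
  attr(out, "n_ties") <- sum(ties)
  out
}

#' Rank-order sibling selection rate (continuous traits)
#'
#' For sibling pairs with a continuous phenotype, the fraction of pairs in
#' which the higher-PGS sibling also has the higher phenotype, restricted
#' to pairs whose phenotype difference is at least `sd_cutoffs` standard
#' deviations (phenotype SD across all sibling individuals). Exact
#' phenotype or PGS ties are dropped with a logged count.
#'
#' @param pgs_a,pgs_b PGS of the two siblings of each pair.
#' @param y_a,y_b their phenotypes.
#' @param sd_cutoffs phenotype-difference cutoffs in SD units.
#' @return data.frame with `cutoff`, `n_pairs`, `rate`, `se`.
#' @export
rank_order_selection_rate <- function(pgs_a, pgs_b, y_a, y_b,
                                      sd_cutoffs = c(0, 0.5, 1, 1.5)) {
  stopifnot(length(pgs_a) == length(pgs_b),
            length(y_a) == length(y_b), length(pgs_a) == length(y_a))
  sd_unit <- stats::sd(c(y_a, y_b))
  dy <- y_a - y_b
  dp <- pgs_a - pgs_b
  ties <- dy == 0 | dp == 0
  if (any(ties)) message(sum(ties), " tied pair(s) dropped")
  dy <- dy[!ties]
  dp <- dp[!ties]
  out <- do.call(rbind, lapply(sd_cutoffs, function(cut) {
    qual <- abs(dy) >= cut * sd_unit
    m <- sum(qual)
    if (m == 0) {
      return(data.frame(cutoff = cut, n_pairs = 0L, rate = NA_real_,
                        se = NA_real_))
    }
    r <- mean(sign(dp[qual]) == sign(dy[qual]))
    data.frame(cutoff = cut, n_pairs = m, rate = r,
               se = sqrt(r * (1 - r) / m))
  }))
  attr(out, "n_ties") <- sum(ties)
  out
}

#' Single SNP variance (SSV)
#'
#' The no-covariance approximation to the variance of a polygenic score:
#' `SSV = sum_i 2 beta_i^2 f_i (1 - f_i)` over the predictor's SNPs, with
#' `beta` on the dosage scale. For (near-)independent SNPs this matches the
#' exact `var(PGS)`; correlated SNPs add covariance terms the approximation
#' drops. Per-SNP shares and per-chromosome aggregates are returned for
#' interpreting where the signal lives.
#'
#' @param predictor a `pgs_predictor`.
#' @param freqs optional per-SNP allele frequencies aligned with the
#'   predictor rows; defaults to the predictor's training frequencies.
#' @return list with `total`, `per_snp` (data.frame snp_id/ssv/share) and
#'   `by_chr` (data.frame chr/ssv/share).
#' @export
ssv <- function(predictor, freqs = NULL) {
  if (is.null(freqs)) freqs <- predictor$training_freq
  stopifnot(length(freqs) == nrow(predictor))
  if (any(freqs < 0 | freqs > 1)) stop("freqs must lie in [0, 1]")
  terms <- 2 * predictor$weight^2 * freqs * (1 - freqs)
  total <- sum(terms)
  share <- if (total > 0) terms / total else rep(0, length(terms))
  by_chr <- NULL
  if (!is.null(predictor$chr) && nrow(predictor) > 0) {
    agg <- tapply(terms, predictor$chr, sum)
    by_chr <- data.frame(chr = as.integer(names(agg)),
                         ssv = as.numeric(agg),
                         share = if (total > 0) as.numeric(agg) / total else 0)
  }
  list(total = total,
       per_snp = data.frame(snp_id = predictor$snp_id, ssv = terms,
                            share = share),
       by_chr = by_chr)
}

#' Variance-explained estimates for a polygenic score
#'
#' Three estimates of the fraction of phenotypic variance captured by the
#' predictor: `var(PGS) / var(y_adj)` (the triangle estimate);
#' `var(y*_PGS) / var(y_raw)` (the bullet estimate) where `y*_PGS` undoes
#' the sex-specific z-scoring on the PGS alone; and, for continuous traits,
#' the squared correlation between PGS and adjusted phenotype, which under
#' P = G + E with uncorrelated E estimates the heritability captured.
#'
#' @param scores polygenic scores.
#' @param y_adj adjusted phenotype.
#' @param y_raw optional raw phenotype (needed for the bullet estimate).
#' @param sex optional per-sample sex codes (needed for the bullet
#'   estimate).
#' @param zscore_stats optional `stats` data.frame from [zscore_by_sex()].
#' @return list with `triangle`, `bullet` (`NA` when the z-scoring
#'   statistics are unavailable), `corr2` and `degenerate` flag (`TRUE`
#'   when the PGS is constant and `corr2` is reported as 0).
#' @export
variance_explained <- function(scores, y_adj, y_raw = NULL, sex = NULL,
                               zscore_stats = NULL) {
  triangle <- stats::var(scores) / stats::var(y_adj)
  bullet <- NA_real_
  if (!is.null(zscore_stats) && !is.null(sex) && !is.null(y_raw)) {
    sd_map <- zscore_stats$sd[match(sex, zscore_stats$sex)]
    mean_map <- zscore_stats$mean[match(sex, zscore_stats$sex)]
    y_star <- scores * sd_map + mean_map
    bullet <- stats::var(y_star) / stats::var(y_raw)
  }
  degenerate <- stats::var(scores) == 0
  corr2 <- if (degenerate) 0 else stats::cor(scores, y_adj)^2
  list(triangle = triangle, bullet = bullet, corr2 = corr2,
       degenerate = degenerate)
}

#' Pool a metric across cross-validation folds
#'
#' The pooled value is the fold mean; its uncertainty combines the
#' cross-validation spread (`var(values) / n_folds`) and the mean squared
#' finite-sample error in quadrature.
#'
#' @param results list of [metric_result()] objects (one per fold).
#' @return a [metric_result()] with `components` holding both pieces.
#' @export
pool_metric <- function(results) {
  stopifnot(length(results) >= 1)
  vals <- vapply(results, function(r) r$value, numeric(1))
  ses <- vapply(results, function(r) r$se, numeric(1))
  k <- length(vals)
  cv_spread <- if (k > 1) stats::var(vals) / k else 0
  fin <- mean(ses^2, na.rm = TRUE)
  if (is.nan(fin)) fin <- 0
  metric_result(results[[1]]$metric, mean(vals), sqrt(cv_spread + fin),
                sum(vapply(results, function(r) r$n_eff, numeric(1))),
                components = list(cv_spread = sqrt(cv_spread),
                                  finite_sample_se = sqrt(fin)))
}
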