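#' Genotype quality control
#'
#' Applies the standard array QC filters in a fixed order: (1) remove SNPs
#' with a missing-call fraction above `snp_miss_max`; (2) remove samples with
#' a missing fraction above `sample_miss_max`; (3) recompute allele
#' frequencies on the surviving samples and remove SNPs with minor allele
#' frequency below `maf_min`. Surviving missing dosages are imputed to the
#' SNP mean. Running the filter twice is a no-op (idempotent).
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_miss_max,sample_miss_max,maf_min filter thresholds in \[0, 1\];
#'   defaults 3% missingness and MAF 0.001.
#' @return list with `genotypes` (filtered, mean-imputed, frequencies
#'   recomputed) and `report` (a `qc_report`).
#' @export
qc_filter <- function(genotypes, snp_miss_max = 0.03,
                      sample_miss_max = 0.03, maf_min = 0.001) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  stopifnot(snp_miss_max >= 0, snp_miss_max <= 1,
            sample_miss_max >= 0, sample_miss_max <= 1,
            maf_min >= 0, maf_min <= 0.5)
  D <- genotypes$dosages
  n_in <- nrow(D)
  p_in <- ncol(D)

  snp_miss <- colMeans(is.na(D))
  keep_snp1 <- snp_miss <= snp_miss_max
  n_snp_miss_removed <- sum(!keep_snp1)
  D <- D[, keep_snp1, drop = FALSE]

  samp_miss <- rowMeans(is.na(D))
  keep_samp <- samp_miss <= sample_miss_max
  n_samp_removed <- sum(!keep_samp)
  D <- D[keep_samp, , drop = FALSE]

  f <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep_snp2 <- !is.na(maf) & maf >= maf_min
  n_maf_removed <- sum(!keep_snp2)
  D <- D[, keep_snp2, drop = FALSE]
  f <- f[keep_snp2]

  if (ncol(D) == 0) stop("QC removed all SNPs")
  if (nrow(D) == 0) stop("QC removed all samples")

  # mean-impute surviving missing dosages
  if (anyNA(D)) {
    means <- matrix(2 * f, nrow(D), ncol(D), byrow = TRUE)
    D[is.na(D)] <- means[is.na(D)]
  }

  keep_snp <- which(keep_snp1)[keep_snp2]
  out <- genotype_matrix(
    D,
    genotypes$snp_ids[keep_snp], genotypes$chr[keep_snp],
    genotypes$pos[keep_snp], genotypes$effect_allele[keep_snp],
    genotypes$other_allele[keep_snp], f,
    sample_ids = genotypes$sample_ids[keep_samp],
    sex = if (!is.null(genotypes$sex)) genotypes$sex[keep_samp]
  )
  report <- structure(list(
    n_snps_in = p_in, n_snps_out = ncol(D),
    n_samples_in = n_in, n_samples_out = nrow(D),
    removed = c(snp_missingness = n_snp_miss_removed,
                sample_missingness = n_samp_removed,
                maf = n_maf_removed)
  ), class = "qc_report")
  list(genotypes = out, report = report, kept_samples = which(keep_samp))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: SNPs %d -> %d, samples %d -> %d\n",
              x$n_snps_in, x$n_snps_out, x$n_samples_in, x$n_samples_out))
  cat(sprintf("  removed: %d SNPs (missingness), %d samples (missingness), %d SNPs (MAF)\n",
              x$removed[["snp_missingness"]],
              x$removed[["sample_missingness"]], x$removed[["maf"]]))
  invisible(x)
}

#' Sex-specific z-scoring of a continuous phenotype
#'
#' Standardizes the phenotype to mean 0 and unit variance within each sex
#' separately, so both sexes can be pooled in training under the assumption
#' of shared genetic factors. Binary (two-valued) phenotypes are passed
#' through unchanged. The per-sex means and SDs are returned so the scoring
#' can be inverted later (needed by [variance_explained()]).
#'
#' @param y numeric phenotype vector.
#' @param sex vector of sex codes aligned with `y`.
#' @return list with `y` (z-scored), `stats` (data.frame sex/mean/sd) and
#'   `binary` flag.
#' @export
zscore_by_sex <- function(y, sex) {
  stopifnot(length(y) == length(sex))
  if (length(unique(y[!is.na(y)])) <= 2) {
    return(list(y = y, stats = NULL, binary = TRUE))
  }
  out <- y
  lv <- unique(sex)
  stats <- data.frame(sex = lv, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(lv)) {
    idx <- which(sex == lv[i])
    if (length(idx) < 2) stop("need >= 2 samples per sex level")
    m <- mean(y[idx])
    s <- stats::sd(y[idx])
    if (s == 0) stop("zero within-sex phenotype variance")
    out[idx] <- (y[idx] - m) / s
    stats$mean[i] <- m
    stats$sd[i] <- s
  }
  list(y = out, stats = stats, binary = FALSE)
}

#' Covariate adjustment to a residual phenotype
#'
#' Regresses the phenotype on the covariate matrix by least squares and
#' returns the residual (adjusted) phenotype `y_adj = y - H alpha`, which is
#' orthogonal to the column space of H. Rank-deficient covariate columns are
#' dropped with a warning.
#'
#' @param y numeric phenotype vector.
#' @param H covariate matrix including an intercept column; rows align with
#'   `y`.
#' @return list with `y_adj` and `alpha` (coefficients, `NA` for dropped
#'   columns).
#' @export
adjust_covariates <- function(y, H) {
  H <- as.matrix(H)
  stopifnot(nrow(H) == length(y))
  fit <- stats::lm.fit(H, y)
  if (any(is.na(fit$coefficients))) {
    warning("rank-deficient covariate matrix; dropped ",
            sum(is.na(fit$coefficients)), " column(s)")
  }
  alpha <- fit$coefficients
  list(y_adj = as.numeric(fit$residuals), alpha = alpha)
}

#' Per-SNP single-marker regression (GWAS scan)
#'
#' Simple linear regression of the adjusted phenotype on each SNP dosage,
#' used to rank SNPs for the top-k pre-filter ahead of penalized training.
#' Binary traits are handled by the same linear score test on the
#' (covariate-residualized) labels: the goal is a ranking, not inference.
#' Monomorphic SNPs get `beta = 0`, `p = 1` by convention.
#'
#' @param genotypes a [genotype_matrix()] or a plain dosage matrix (missing
#'   values are mean-imputed for the scan).
#' @param y_adj adjusted phenotype (or residualized labels) aligned with
#'   samples.
#' @return data.frame with columns `snp`, `beta`, `se`, `p`.
#' @export
single_marker_regression <- function(genotypes, y_adj) {
  D <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  stopifnot(nrow(D) == length(y_adj))
  n <- nrow(D)
  if (anyNA(D)) {
    mns <- matrix(colMeans(D, na.rm = TRUE), n, ncol(D), byrow = TRUE)
    D[is.na(D)] <- mns[is.na(D)]
  }
  yc <- y_adj - mean(y_adj)
  xm <- colMeans(D)
  sxy <- drop(crossprod(D, yc)) # sum x_j * yc = sum (x_j - xm) yc
  sxx <- colSums(D^2) - n * xm^2
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(sxx > 0, sqrt(rss / pmax(n - 2, 1) / sxx), NA_real_)
  tstat <- ifelse(sxx > 0 & !is.na(se) & se > 0, beta / se,
                  ifelse(sxx > 0 & beta != 0, Inf, 0))
  pval <- ifelse(sxx > 0, 2 * stats::pt(-abs(tstat), df = n - 2), 1)
  ids <- if (inherits(genotypes, "genotype_matrix")) genotypes$snp_ids else {
    colnames(D) %||% paste0("snp", seq_len(ncol(D)))
  }
  data.frame(snp = ids, beta = beta, se = se, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top-k SNPs from a GWAS scan
#'
#' Returns the indices of the `k` SNPs with the smallest p-values; ties are
#' broken by larger `|beta|`, then by lower SNP index, so the selection is
#' deterministic. If `k >= p` all SNPs are retained.
#'
#' @param stats data.frame from [single_marker_regression()] (needs columns
#'   `p` and `beta`).
#' @param k number of SNPs to keep.
#' @return integer vector of selected SNP indices, in increasing index order.
#' @export
select_top_k <- function(stats, k) {
  stopifnot(k >= 1)
  p <- nrow(stats)
  if (k >= p) return(seq_len(p))
  ord <- order(stats$p, -abs(stats$beta), seq_len(p))
  sort(ord[seq_len(k)])
}
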