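#' Simulation configuration for biobank-like synthetic data
#'
#' Bundles every parameter of the synthetic genotype/phenotype generator:
#' cohort and SNP-panel dimensions, the sparse causal architecture (number of
#' causal SNPs `n_causal` and narrow-sense heritability `h2`), an optional
#' liability-threshold disease prevalence, the allele-frequency spectrum,
#' block LD structure, Balding-Nichols drift, and the master seed from which
#' every stage derives its own RNG stream.
#'
#' @param n_samples number of individuals to simulate.
#' @param n_snps number of biallelic SNPs (p).
#' @param n_causal number of causal SNPs (s); must not exceed `n_snps`.
#' @param h2 narrow-sense heritability of the continuous trait, in \[0, 1\].
#' @param prevalence optional population prevalence in (0, 1\]; when supplied,
#'   case-control labels are produced by thresholding the liability.
#' @param maf_low,maf_high bounds of the uniform allele-frequency spectrum;
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param ld_block_size size of LD blocks; 1 means independent SNPs.
#' @param ld_rho within-block AR(1) latent correlation in \[0, 1).
#' @param fst Balding-Nichols drift parameter in \[0, 1) for the optional
#'   ancestry-shifted population.
#' @param effect_dist causal-effect magnitude model on the
#'   standardized-genotype scale: `"normal"` (standard normal draws, the
#'   default) or `"equal"` (equal magnitudes with random signs, the
#'   canonical compressed-sensing benchmark used by the phase-transition
#'   experiment).
#' @param seed integer master seed; all stages are deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_snps, n_causal, h2,
                       prevalence = NULL,
                       maf_low = 0.01, maf_high = 0.5,
                       ld_block_size = 1L, ld_rho = 0,
                       fst = 0, effect_dist = c("normal", "equal"),
                       seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  if (n_samples < 1 || n_snps < 1) {
    stop("n_samples and n_snps must be positive")
  }
  if (n_causal < 0 || n_causal > n_snps) {
    stop("n_causal must lie in [0, n_snps]")
  }
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence > 1)) {
    stop("prevalence must lie in (0, 1]")
  }
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_causal = as.integer(n_causal), h2 = h2, prevalence = prevalence,
    maf_low = maf_low, maf_high = maf_high,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    fst = fst, effect_dist = effect_dist, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a genotype matrix container
#'
#' Samples x SNPs dosage matrix (counts of the effect allele, 0/1/2, `NA` for
#' missing) together with SNP metadata and per-SNP effect-allele frequencies.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns.
#' @param snp_ids,chr,pos,effect_allele,other_allele per-SNP metadata vectors.
#' @param freqs per-SNP effect-allele frequency in \[0, 1\].
#' @param sample_ids,sex per-sample metadata; `sex` coded 1/2 or `NA`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_ids, chr, pos,
                            effect_allele, other_allele, freqs,
                            sample_ids = NULL, sex = NULL) {
  p <- ncol(dosages)
  stopifnot(
    length(snp_ids) == p, length(chr) == p, length(pos) == p,
    length(effect_allele) == p, length(other_allele) == p,
    length(freqs) == p
  )
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("id", seq_len(nrow(dosages)))
  }
  stopifnot(length(sample_ids) == nrow(dosages))
  if (!is.null(sex)) stopifnot(length(sex) == nrow(dosages))
  structure(list(
    dosages = dosages, snp_ids = as.character(snp_ids),
    chr = as.integer(chr), pos = as.integer(pos),
    effect_allele = as.character(effect_allele),
    other_allele = as.character(other_allele),
    freqs = as.numeric(freqs),
    sample_ids = as.character(sample_ids), sex = sex
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# assign SNPs to 22 autosomes in contiguous runs with increasing positions
snp_map <- function(p) {
  chr <- pmin(((seq_len(p) - 1L) * 22L) %/% max(p, 1L) + 1L, 22L)
  pos <- integer(p)
  for (c in unique(chr)) {
    idx <- which(chr == c)
    pos[idx] <- seq_along(idx) * 5000L
  }
  list(chr = chr, pos = pos)
}

#' Simulate biobank-like genotypes
#'
#' Draws per-SNP effect-allele frequencies uniformly on
#' `[maf_low, maf_high]` and genotype dosages under Hardy-Weinberg
#' equilibrium. With `ld_block_size > 1`, SNPs within a block are correlated
#' through an AR(1) Gaussian copula on the latent haplotype liabilities:
#' each of the two haplotypes per individual carries an AR(1)-correlated
#' standard-normal vector that is thresholded at the allele-frequency
#' quantile, so per-SNP marginals remain Hardy-Weinberg while adjacent SNPs
#' within a block share LD controlled by `ld_rho`. SNPs are laid out on the
#' 22 autosomes in contiguous runs.
#'
#' @param config a [sim_config()].
#' @param freqs optional vector of per-SNP frequencies to use instead of
#'   drawing them (e.g. frequencies drifted with [drift_population()]).
#' @return a [genotype_matrix()]. Deterministic given `config$seed`.
#' @export
simulate_genotypes <- function(config, freqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  p <- config$n_snps
  set.seed(stage_seed(config$seed, "genotypes"))
  if (is.null(freqs)) {
    freqs <- stats::runif(p, config$maf_low, config$maf_high)
  } else {
    stopifnot(length(freqs) == p)
  }
  b <- config$ld_block_size
  if (b <= 1L || config$ld_rho == 0) {
    dos <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)), n, p)
  } else {
    rho <- config$ld_rho
    thr <- matrix(stats::qnorm(freqs), n, p, byrow = TRUE)
    dos <- matrix(0L, n, p)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n * p), n, p)
      if (p > 1) {
        for (j in 2:p) {
          if ((j - 1L) %% b != 0L) {
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
          }
        }
      }
      dos <- dos + (z < thr)
    }
    storage.mode(dos) <- "integer"
  }
  m <- snp_map(p)
  genotype_matrix(
    dosages = dos, snp_ids = sprintf("snp%06d", seq_len(p)),
    chr = m$chr, pos = m$pos,
    effect_allele = rep("A", p), other_allele = rep("G", p),
    freqs = freqs,
    sample_ids = sprintf("id%06d", seq_len(n)),
    sex = rep_len(c(1L, 2L), n)
  )
}

#' Simulate genotypes under Hardy-Weinberg at given allele frequencies
#'
#' Convenience generator for a new population (e.g. an ancestry group with
#' drifted frequencies) sharing the SNP panel of an existing
#' [genotype_matrix()].
#'
#' @param template a [genotype_matrix()] supplying the SNP metadata.
#' @param freqs per-SNP effect-allele frequencies for the new population.
#' @param n_samples number of individuals to draw.
#' @param seed RNG seed.
#' @return a [genotype_matrix()].
#' @export
simulate_from_freqs <- function(template, freqs, n_samples, seed = 1L) {
  stopifnot(inherits(template, "genotype_matrix"),
            length(freqs) == ncol(template$dosages))
  set.seed(stage_seed(seed, "genotypes"))
  p <- length(freqs)
  dos <- matrix(stats::rbinom(n_samples * p, 2L, rep(freqs, each = n_samples)),
                n_samples, p)
  genotype_matrix(
    dosages = dos, snp_ids = template$snp_ids, chr = template$chr,
    pos = template$pos, effect_allele = template$effect_allele,
    other_allele = template$other_allele, freqs = freqs,
    sample_ids = sprintf("alt%06d", seq_len(n_samples)),
    sex = rep_len(c(1L, 2L), n_samples)
  )
}

#' Simulate a sparse additive genetic architecture
#'
#' Chooses `n_causal` causal SNPs without replacement, draws their effects
#' standard-normal on the standardized-genotype scale, and rescales them so
#' the realized in-sample variance of the genetic value G equals `h2`
#' exactly. The environmental component E is drawn independently with
#' variance `1 - h2` (exactly zero when `h2 = 1`), giving the phenotype
#' P = G + E with population variance 1. Because G is rescaled in-sample,
#' the identity h2 = corr(P, G)^2 holds up to the sampling noise of E alone.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config the [sim_config()] used to generate it.
#' @return an object of class `true_architecture` with elements
#'   `causal_indices`, `causal_effects` (standardized-genotype scale),
#'   `scale_mean`/`scale_sd` (the freezing of the standardization),
#'   `genetic_values`, `environmental_values`, `phenotype` and `h2`.
#' @export
simulate_architecture <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (config$h2 < 0 || config$h2 > 1) stop("h2 must lie in [0, 1]")
  p <- ncol(genotypes$dosages)
  n <- nrow(genotypes$dosages)
  s <- config$n_causal
  if (s > p) stop("n_causal exceeds n_snps")
  set.seed(stage_seed(config$seed, "architecture"))
  idx <- sort(sample.int(p, s))
  X <- genotypes$dosages[, idx, drop = FALSE]
  mu <- colMeans(X)
  sdv <- col_sds(X)
  u <- if (identical(config$effect_dist, "equal")) {
    sample(c(-1, 1), s, replace = TRUE)
  } else {
    stats::rnorm(s)
  }
  u[sdv == 0] <- 0 # monomorphic SNPs carry no signal
  sdv_safe <- ifelse(sdv > 0, sdv, 1)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv_safe, "/")
  g <- drop(Xs %*% u)
  if (config$h2 == 0 || s == 0 || stats::var(g) == 0) {
    if (config$h2 > 0 && s > 0) {
      stop("degenerate genetic value: all candidate causal SNPs monomorphic")
    }
    scale_f <- 0
  } else {
    scale_f <- sqrt(config$h2 / stats::var(g))
  }
  g <- g * scale_f
  eff <- u * scale_f
  set.seed(stage_seed(config$seed, "environment"))
  e <- if (config$h2 >= 1) rep(0, n) else stats::rnorm(n, 0, sqrt(1 - config$h2))
  structure(list(
    causal_indices = idx, causal_effects = eff,
    scale_mean = mu, scale_sd = sdv_safe,
    genetic_values = g, environmental_values = e,
    phenotype = g + e, h2 = config$h2
  ), class = "true_architecture")
}

#' Genetic values of new samples under an existing architecture
#'
#' Applies the causal effects of a `true_architecture` to a new
#' [genotype_matrix()] on the same SNP panel, using the standardization
#' frozen at architecture creation (so scores are comparable across
#' populations).
#'
#' @param arch a `true_architecture`.
#' @param genotypes a [genotype_matrix()] on the same SNP panel.
#' @return numeric vector of genetic values G.
#' @export
genetic_values <- function(arch, genotypes) {
  stopifnot(inherits(arch, "true_architecture"),
            inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosages[, arch$causal_indices, drop = FALSE]
  X[is.na(X)] <- matrix(arch$scale_mean, nrow(X), ncol(X),
                        byrow = TRUE)[is.na(X)]
  Xs <- sweep(sweep(X, 2, arch$scale_mean, "-"), 2, arch$scale_sd, "/")
  drop(Xs %*% arch$causal_effects)
}

#' Phenotypes for new samples under an existing architecture
#'
#' @param arch a `true_architecture`.
#' @param genotypes a [genotype_matrix()] on the same SNP panel.
#' @param seed RNG seed for the fresh environmental draw.
#' @return list with `phenotype`, `genetic_values`, `environmental_values`.
#' @export
simulate_phenotype <- function(arch, genotypes, seed = 1L) {
  g <- genetic_values(arch, genotypes)
  set.seed(stage_seed(seed, "environment"))
  e <- if (arch$h2 >= 1) rep(0, length(g)) else {
    stats::rnorm(length(g), 0, sqrt(1 - arch$h2))
  }
  list(phenotype = g + e, genetic_values = g, environmental_values = e)
}

#' Liability-threshold case-control labels
#'
#' Labels an individual a case when its (standardized) liability exceeds the
#' `1 - prevalence` quantile of the standard normal liability distribution,
#' so the realized case fraction converges to `prevalence` as n grows.
#'
#' @param liability numeric vector on the standard liability scale
#'   (population mean 0, variance 1), e.g. the phenotype of
#'   [simulate_architecture()].
#' @param prevalence population prevalence in (0, 1\].
#' @return integer vector of labels (1 = case, 0 = control).
#' @export
apply_liability_threshold <- function(liability, prevalence) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must lie in (0, 1]")
  if (length(liability) < 2 || stats::sd(liability) == 0) {
    stop("degenerate constant liability")
  }
  thr <- stats::qnorm(1 - prevalence)
  as.integer(liability > thr)
}

#' Simulate full-sibling pairs from a parental genotype pool
#'
#' For each pair two parents are drawn from the pool (without replacement
#' while the pool allows) and each offspring receives, independently at every
#' SNP, one allele per parent by fair transmission
#' (Bernoulli(dosage / 2)). Both siblings of a pair share the same two
#' parents, giving the classical expected additive-genotype correlation of
#' 0.5 between sibs.
#'
#' @param parents a [genotype_matrix()] parental pool (no missing dosages).
#' @param n_pairs number of sibling pairs.
#' @param config a [sim_config()] (supplies the seed).
#' @param parent_pairs optional `n_pairs x 2` matrix of parental row indices,
#'   e.g. to reuse the same two parents for every pair.
#' @return list with `genotypes` (a [genotype_matrix()] of the
#'   `2 * n_pairs` offspring, siblings adjacent in order sib-a, sib-b) and
#'   `pedigree` (data.frame pair / sib_a / sib_b / parent_a / parent_b).
#' @export
simulate_siblings <- function(parents, n_pairs, config, parent_pairs = NULL) {
  stopifnot(inherits(parents, "genotype_matrix"),
            inherits(config, "sim_config"))
  n_pairs <- as.integer(n_pairs)
  p <- ncol(parents$dosages)
  if (anyNA(parents$dosages)) stop("parental dosages must be complete")
  set.seed(stage_seed(config$seed, "siblings"))
  if (n_pairs == 0L) {
    return(list(
      genotypes = genotype_matrix(
        matrix(integer(0), 0, p), parents$snp_ids, parents$chr, parents$pos,
        parents$effect_allele, parents$other_allele, parents$freqs,
        sample_ids = character(0), sex = integer(0)
      ),
      pedigree = data.frame(pair = integer(0), sib_a = character(0),
                            sib_b = character(0), parent_a = character(0),
                            parent_b = character(0))
    ))
  }
  np <- nrow(parents$dosages)
  if (is.null(parent_pairs)) {
    if (np >= 2L * n_pairs) {
      perm <- sample.int(np, 2L * n_pairs)
      parent_pairs <- cbind(perm[seq_len(n_pairs)],
                            perm[n_pairs + seq_len(n_pairs)])
    } else {
      warning("parental pool smaller than 2 * n_pairs; reusing parents")
      parent_pairs <- t(replicate(n_pairs, sample.int(np, 2L)))
    }
  }
  parent_pairs <- matrix(as.integer(parent_pairs), ncol = 2L)
  stopifnot(nrow(parent_pairs) == n_pairs, all(parent_pairs[, 1] != parent_pairs[, 2]))
  D1 <- parents$dosages[parent_pairs[, 1], , drop = FALSE]
  D2 <- parents$dosages[parent_pairs[, 2], , drop = FALSE]
  transmit <- function(D) {
    matrix(stats::rbinom(length(D), 1L, D / 2), nrow(D), ncol(D))
  }
  off_a <- transmit(D1) + transmit(D2)
  off_b <- transmit(D1) + transmit(D2)
  dos <- matrix(0L, 2L * n_pairs, p)
  dos[seq(1L, 2L * n_pairs, by = 2L), ] <- off_a
  dos[seq(2L, 2L * n_pairs, by = 2L), ] <- off_b
  ids <- as.vector(t(outer(seq_len(n_pairs), c("a", "b"),
                           function(i, s) sprintf("sib%05d_%s", i, s))))
  ped <- data.frame(
    pair = seq_len(n_pairs),
    sib_a = ids[seq(1L, 2L * n_pairs, by = 2L)],
    sib_b = ids[seq(2L, 2L * n_pairs, by = 2L)],
    parent_a = parents$sample_ids[parent_pairs[, 1]],
    parent_b = parents$sample_ids[parent_pairs[, 2]]
  )
  list(
    genotypes = genotype_matrix(
      dos, parents$snp_ids, parents$chr, parents$pos,
      parents$effect_allele, parents$other_allele,
      freqs = colMeans(dos) / 2,
      sample_ids = ids, sex = rep_len(c(1L, 2L), 2L * n_pairs)
    ),
    pedigree = ped
  )
}

#' Balding-Nichols allele-frequency drift
#'
#' Draws drifted frequencies `f' ~ Beta(f (1 - F) / F, (1 - f)(1 - F) / F)`
#' per SNP, so that `E(f') = f` and `var(f') = F f (1 - f)`. `fst = 0`
#' returns the input unchanged; fixed alleles (f of 0 or 1) stay fixed.
#'
#' @param freqs per-SNP allele frequencies in \[0, 1\].
#' @param fst drift parameter F in \[0, 1).
#' @param seed RNG seed.
#' @return drifted frequency vector of the same length.
#' @export
drift_population <- function(freqs, fst, seed = 1L) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (any(freqs < 0 | freqs > 1)) stop("freqs must lie in [0, 1]")
  if (fst == 0) return(freqs)
  set.seed(stage_seed(seed, "drift"))
  out <- freqs
  free <- freqs > 0 & freqs < 1
  f <- freqs[free]
  out[free] <- stats::rbeta(length(f),
                            f * (1 - fst) / fst,
                            (1 - f) * (1 - fst) / fst)
  out
}
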