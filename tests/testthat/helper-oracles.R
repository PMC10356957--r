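# Independent oracles used to cross-check the implementation.

# Naive cyclic coordinate descent for the elastic-net objective
#   1/(2n) ||y - X b||^2 + lambda (r |b|_1 + (1 - r)/2 |b|_2^2),
# written from the soft-thresholding update alone (no warm starts, no
# screening) so it is independent of the path solver it checks.
oracle_enet <- function(X, y, lambda, l1_ratio = 1,
                        maxit = 50000, tol = 1e-13) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- rep(0, p)
  xx <- colSums(X^2) / n
  r <- y
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj <- beta[j]
      rho <- sum(X[, j] * r) / n + xx[j] * bj
      bn <- sign(rho) * max(abs(rho) - lambda * l1_ratio, 0) /
        (xx[j] + lambda * (1 - l1_ratio))
      if (bn != bj) {
        r <- r - X[, j] * (bn - bj)
        delta <- max(delta, abs(bn - bj))
        beta[j] <- bn
      }
    }
    if (delta < tol) break
  }
  beta
}

# Exhaustive pair-counting AUC (ties count one half).
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Expected dosage correlation of two SNPs whose haplotype indicators come
# from a bivariate normal with latent correlation rho, thresholded at the
# allele-frequency quantiles: brute-force orthant probability by
# quadrature.
oracle_ld_corr <- function(rho, f1, f2) {
  t1 <- qnorm(f1)
  t2 <- qnorm(f2)
  p11 <- integrate(function(z) {
    pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
  }, -Inf, t1, rel.tol = 1e-10)$value
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Small dense genotype fixture with a known sparse architecture.
make_fixture <- function(n = 400, p = 60, s = 5, h2 = 0.5, seed = 42,
                         ...) {
  cfg <- sim_config(n, p, s, h2, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  arch <- simulate_architecture(geno, cfg)
  list(cfg = cfg, geno = geno, arch = arch)
}
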