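# Internal helpers shared across modules.

# Deterministic per-stage seed derived from one user seed, so pipeline stages
# can be re-run independently without sharing an RNG stream. Kept < 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genotypes    = 101L,
    architecture = 211L,
    environment  = 307L,
    liability    = 401L,
    siblings     = 503L,
    drift        = 601L,
    split        = 701L,
    ladder       = 809L,
    boot         = 907L,
    mc           = 1009L
  )
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  ((as.integer(seed) %% 1000003L) * 2039L + offsets[[stage]]) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

geom_seq <- function(from, to, length.out) {
  stopifnot(from > 0, to >= from, length.out >= 1)
  if (length.out == 1) return(to)
  exp(seq(log(from), log(to), length.out = length.out))
}

# column means / sds that tolerate NA, vectorized
col_sds <- function(x) {
  n <- colSums(!is.na(x))
  m <- colMeans(x, na.rm = TRUE)
  m2 <- colMeans(x^2, na.rm = TRUE)
  v <- (m2 - m^2) * n / pmax(n - 1, 1)
  sqrt(pmax(v, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
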