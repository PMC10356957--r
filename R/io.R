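#' Write genotypes to PLINK1 .bed/.bim/.fam
#'
#' SNP-major PLINK1 binary format. The dosage counts the .bim A1 allele
#' (the effect allele), so a dosage of 2 is coded homozygous-A1.
#'
#' @param genotypes a [genotype_matrix()].
#' @param prefix path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosages
  n <- nrow(D)
  p <- ncol(D)
  if (n == 0) stop("cannot write a .fam with 0 samples")
  # 2-bit codes (counting A1): 2 -> 00, missing -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, p)
  code[D == 2] <- 0L
  code[D == 1] <- 2L
  code[is.na(D)] <- 1L
  bpr <- ceiling(n / 4)
  pad <- bpr * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  i4 <- matrix(seq_len(bpr * 4L), nrow = 4L)
  bytes <- code[i4[1, ], , drop = FALSE] +
    code[i4[2, ], , drop = FALSE] * 4L +
    code[i4[3, ], , drop = FALSE] * 16L +
    code[i4[4, ], , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  utils::write.table(
    data.frame(genotypes$chr, genotypes$snp_ids, 0L, genotypes$pos,
               genotypes$effect_allele, genotypes$other_allele),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  sex <- genotypes$sex %||% rep(0L, n)
  utils::write.table(
    data.frame(genotypes$sample_ids, genotypes$sample_ids, 0L, 0L, sex, -9L),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read genotypes from PLINK1 .bed/.bim/.fam
#'
#' Reads the SNP-major PLINK1 binary triplet into a [genotype_matrix()].
#' Dosages count the .bim A1 allele; the PLINK missing code becomes `NA`.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  p <- nrow(bim_df)
  if (n == 0) stop("empty .fam: 0 samples")
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 ||
      !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK1 .bed file (magic bytes mismatch)")
  }
  bpr <- ceiling(n / 4)
  expected <- 3 + bpr * p
  if (length(raw) != expected) {
    stop(sprintf(".bed size %d does not match expected %d bytes (%d samples x %d SNPs)",
                 length(raw), expected, n, p))
  }
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = bpr * 4L)[seq_len(n), , drop = FALSE]
  D <- matrix(NA_integer_, n, p)
  D[codes == 0L] <- 2L
  D[codes == 2L] <- 1L
  D[codes == 3L] <- 0L
  f <- colMeans(D, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  genotype_matrix(
    D, snp_ids = bim_df[[2]], chr = bim_df[[1]], pos = bim_df[[4]],
    effect_allele = bim_df[[5]], other_allele = bim_df[[6]], freqs = f,
    sample_ids = as.character(fam_df[[2]]), sex = fam_df[[5]]
  )
}

#' Write a predictor scoring file
#'
#' Tab-separated scoring format: `snp_id`, `chr`, `pos`, `effect_allele`,
#' `weight`, `training_freq`, weights serialized at full double precision.
#'
#' @param predictor a `pgs_predictor`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_predictor <- function(predictor, path) {
  if (anyDuplicated(predictor$snp_id)) {
    stop("duplicated snp_id: ",
         predictor$snp_id[duplicated(predictor$snp_id)][1])
  }
  df <- as.data.frame(predictor)
  df$weight <- sprintf("%.17g", df$weight)
  df$training_freq <- sprintf("%.17g", df$training_freq)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictor scoring file
#'
#' @param path a TSV written by [write_predictor()] (unknown extra columns
#'   are tolerated with a warning; missing required columns are an error).
#' @return a `pgs_predictor`.
#' @export
read_predictor <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("snp_id", "chr", "pos", "effect_allele", "weight",
                "training_freq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  df <- df[required]
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id: ", df$snp_id[duplicated(df$snp_id)][1])
  }
  structure(df, class = c("pgs_predictor", "data.frame"))
}

validate_run_config <- function(config) {
  need <- c("trait", "sim", "train")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing section(s): ",
                         paste(miss, collapse = ", "))
  tt <- config$trait$type %||% stop("config$trait$type required")
  if (!tt %in% c("continuous", "binary")) {
    stop("trait type must be 'continuous' or 'binary'")
  }
  if (tt == "binary" && is.null(config$trait$prevalence)) {
    stop("binary trait requires trait$prevalence")
  }
  invisible(config)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> preprocess -> train -> evaluate -> sparsity ->
#' project and writes every stage output plus a manifest (seed, parameters,
#' package version, output checksums) into a run directory. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config a nested list (or path to a YAML/JSON file) with sections
#'   `trait` (name, type, prevalence), `sim` (arguments of [sim_config()]),
#'   `train` (arguments of [train_config()]), optional `project`
#'   (`families`, `biobanks`: list of name/cohort_size/prevalence) and a
#'   global `seed`.
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the main in-memory results (`cv`,
#'   `curve`, `sparsity`, `fits`, `projection`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
    note("%s done in %.1fs", stage, proc.time()[3] - t0)
    out
  }
  seed <- config$seed %||% 1L
  trait <- config$trait

  scfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
  sim <- tick("simulate", {
    geno <- simulate_genotypes(scfg)
    arch <- simulate_architecture(geno, scfg)
    y_raw <- arch$phenotype
    labels <- NULL
    if (trait$type == "binary") {
      labels <- apply_liability_threshold(y_raw, trait$prevalence)
    }
    list(geno = geno, arch = arch, y_raw = y_raw, labels = labels)
  })
  utils::write.table(
    data.frame(sample_id = sim$geno$sample_ids, sex = sim$geno$sex,
               phenotype = sim$y_raw,
               label = sim$labels %||% NA_integer_),
    file.path(out_dir, "phenotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  prep <- tick("preprocess", {
    qc <- qc_filter(sim$geno)
    if (trait$type == "continuous") {
      z <- zscore_by_sex(sim$y_raw[qc$kept_samples],
                         sim$geno$sex[qc$kept_samples])
      adj <- adjust_covariates(z$y, cbind(1, qc$genotypes$sex))
      list(qc = qc, y = adj$y_adj, z = z)
    } else {
      list(qc = qc, y = sim$labels[qc$kept_samples], z = NULL)
    }
  })
  jsonlite::write_json(unclass(prep$qc$report),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE)

  tcfg <- do.call(train_config, c(config$train, list(seed = seed)))
  cv <- tick("train", cv_train(prep$qc$genotypes, prep$y, trait$type, tcfg))
  utils::write.table(cv$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- metric_curve(cv)
  utils::write.table(curve, file.path(out_dir, "curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # largest-rung predictor per fold
  pdir <- file.path(out_dir, "predictors")
  dir.create(pdir, showWarnings = FALSE)
  for (f in seq_along(cv$predictors)) {
    preds <- cv$predictors[[f]]
    write_predictor(preds[[length(preds)]],
                    file.path(pdir, sprintf("fold%d_max.tsv", f)))
  }

  sp <- tick("sparsity", {
    s <- sparsity_definitions(curve)
    pt <- if (nrow(curve) >= 4) detect_phase_transition(curve) else NULL
    list(summary = s, transition = pt)
  })
  jsonlite::write_json(
    list(def1 = sp$summary$def1, def2 = sp$summary$def2,
         def3 = sp$summary$def3, def4 = sp$summary$def4,
         inflection_N = as.list(sp$summary$inflection_N),
         N_star = if (!is.null(sp$transition)) sp$transition$N_star else NULL),
    file.path(out_dir, "sparsity.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )

  proj <- tick("project", {
    mt <- if (trait$type == "binary") "auc" else "correlation"
    fams <- config$project$families %||% growth_families()
    fits <- lapply(fams, function(fm) {
      tryCatch(fit_growth(curve, fm, mt), error = function(e) NULL)
    })
    names(fits) <- fams
    fits <- fits[!vapply(fits, is.null, logical(1))]
    conv <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
    pooled <- if (length(conv)) combine_families(conv) else NULL
    bands <- lapply(conv, function(f) {
      tryCatch(mc_band(f, seed = seed), error = function(e) {
        note("mc_band (%s) skipped: %s", f$family, conditionMessage(e))
        NULL
      })
    })
    bands <- bands[!vapply(bands, is.null, logical(1))]
    rows <- NULL
    for (bb in if (length(bands)) config$project$biobanks %||% list() else list()) {
      b1 <- bands[[1]]
      pr <- project_biobank(b1, bb$cohort_size,
                            prevalence = bb$prevalence, name = bb$name)
      rows <- rbind(rows, data.frame(
        biobank = bb$name, n_eff = pr$n_eff, value = pr$value,
        lo95 = pr$lo95, hi95 = pr$hi95, extrapolated = pr$extrapolated
      ))
    }
    list(fits = fits, pooled = pooled, bands = bands, biobanks = rows)
  })
  if (!is.null(proj$pooled)) {
    best <- max(curve$value)
    utils::write.table(
      data.frame(trait = trait$name %||% "trait",
                 metric = if (trait$type == "binary") "auc" else "correlation",
                 asymptote = proj$pooled$value, se = proj$pooled$se,
                 lo = proj$pooled$interval[1], hi = proj$pooled$interval[2],
                 gain_over_best = proj$pooled$value - best),
      file.path(out_dir, "projection.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(proj$biobanks)) {
    utils::write.table(proj$biobanks, file.path(out_dir, "biobanks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("run.log", "manifest.json")))
  md5 <- tools::md5sum(file.path(out_dir, outputs))
  names(md5) <- outputs
  manifest <- list(
    package = "sparsepgs",
    version = as.character(utils::packageVersion("sparsepgs")),
    seed = seed, config = config,
    files = as.list(md5)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("pipeline complete")
  invisible(list(cv = cv, curve = curve, sparsity = sp, fits = proj$fits,
                 projection = proj, manifest = manifest))
}
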