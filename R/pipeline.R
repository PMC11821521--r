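# Orchestration of the two-step analysis: step 1 (variance components,
# whole-genome fit, warm-started LOCO fits, residual files), step 2
# (calibrated score statistics, Firth fallback, weighted tests), variant
# QC, and evaluation against simulation truth.

#' Run configuration
#'
#' Collects paths and options for the two-step pipeline. All paths are
#' validated lazily by the steps that use them.
#'
#' @param bed path prefix or full `.bed` path of the PLINK fileset.
#' @param pheno phenotype table path (FID IID trait columns) or data.frame.
#' @param covar optional covariate table path or data.frame.
#' @param weights optional participation-weight table (FID IID weight).
#' @param out output prefix.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param h2_grid binary-trait heritability grid.
#' @param slab_prob prior slab probability.
#' @param control an [svi_control()]; its `holdout_frac` (default here 0.1)
#'   drives the held-out residual-variance estimate used in calibration.
#' @param calibration_ids optional data.frame/path of FID IID for the
#'   unrelated homogeneous calibration subset; autodetected otherwise.
#' @param maf_min,hwe_p_min,geno_max QC thresholds (MAF minimum,
#'   Hardy-Weinberg exact-test minimum p, maximum missingness).
#' @param calibration_frac fraction of tested variants used for
#'   calibration (min 1000).
#' @param n_rhe_vectors Hutchinson vectors for [rhe_estimate()].
#' @param seed root seed for every source of randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(bed, pheno, covar = NULL, weights = NULL, out,
                       trait_type = c("quantitative", "binary"),
                       h2_grid = c(0.01, 0.25, 0.5, 0.75), slab_prob = 0.01,
                       control = svi_control(holdout_frac = 0.1),
                       calibration_ids = NULL, maf_min = 0.01,
                       hwe_p_min = 1e-15, geno_max = 0.01,
                       calibration_frac = 0.05, n_rhe_vectors = 50L,
                       seed = 1L) {
  trait_type <- match.arg(trait_type)
  structure(as.list(environment()), class = "run_config")
}

.load_cfg_inputs <- function(cfg) {
  bed <- if (grepl("\\.bed$", cfg$bed)) cfg$bed else paste0(cfg$bed, ".bed")
  G <- read_bed(bed)
  G <- qc_filter(G, maf_min = cfg$maf_min, missingness_max = cfg$geno_max,
                 hwe_p_min = cfg$hwe_p_min)
  ph <- if (is.data.frame(cfg$pheno)) cfg$pheno else read_pheno_table(cfg$pheno)
  al <- align_samples(G, ph)
  G <- al$genotypes
  ph <- al$table
  C <- NULL
  if (!is.null(cfg$covar)) {
    cv <- if (is.data.frame(cfg$covar)) cfg$covar else read_pheno_table(cfg$covar)
    alc <- align_samples(G, cv)
    if (nrow(alc$genotypes$dosages) != nrow(G$dosages)) {
      G <- alc$genotypes
      keep <- paste(G$samples$fid, G$samples$iid) %in%
        paste(alc$table$fid, alc$table$iid)
      ph <- ph[paste(ph$fid, ph$iid) %in%
                 paste(G$samples$fid, G$samples$iid), , drop = FALSE]
    }
    C <- as.matrix(alc$table[, -(1:2), drop = FALSE])
  }
  w <- NULL
  if (!is.null(cfg$weights)) {
    wt <- if (is.data.frame(cfg$weights)) cfg$weights else read_pheno_table(cfg$weights)
    alw <- align_samples(G, wt)
    w <- alw$table[[3L]]
  }
  traits <- ph[, -(1:2), drop = FALSE]
  n_ok <- colSums(!is.na(traits))
  drop_tr <- n_ok < 100L
  if (any(drop_tr)) {
    warning("skipping trait(s) with < 100 non-missing samples: ",
            paste(names(traits)[drop_tr], collapse = ", "))
    traits <- traits[, !drop_tr, drop = FALSE]
  }
  if (ncol(traits) == 0L) stop("no analyzable traits")
  cc <- stats::complete.cases(traits)
  if (!all(cc)) {
    message(sum(!cc), " sample(s) with missing phenotypes dropped")
    G <- genotype_matrix(G$dosages[cc, , drop = FALSE],
                         G$samples[cc, , drop = FALSE], G$variants)
    traits <- traits[cc, , drop = FALSE]
    if (!is.null(C)) C <- C[cc, , drop = FALSE]
    if (!is.null(w)) w <- w[cc]
  }
  list(G = G, Y = as.matrix(traits), C = C, weights = w)
}

#' Step 1: model fitting
#'
#' Estimates variance components (randomized Haseman-Elston for
#' quantitative traits, ELBO grid search for binary), fits the whole-genome
#' spike-and-slab regression, warm-starts one leave-one-chromosome-out fit
#' per chromosome from it, and writes per-chromosome LOCO residual files
#' plus a posterior-effects file per trait under `cfg$out`.
#'
#' @param cfg a [run_config()].
#' @return list of class `step1_result` carrying the adjusted genotypes,
#'   adjusted phenotypes (or offsets for binary traits), variance
#'   components, whole-genome fit, per-chromosome fits and
#'   [loco_residuals()].
#' @export
run_step1 <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  inp <- .load_cfg_inputs(cfg)
  G <- inp$G
  X <- standardize(G, covariates = inp$C)
  m <- ncol(X$values)
  trait_names <- colnames(inp$Y)
  binary <- cfg$trait_type == "binary"
  if (binary) {
    Y <- inp$Y
    if (!all(Y %in% c(0, 1))) stop("binary traits must be coded 0/1")
    offset <- covariate_offset_logistic(Y, inp$C)
    vc <- grid_search_h2(X, Y, inp$C, grid = cfg$h2_grid,
                         slab_prob = cfg$slab_prob,
                         control = local({cl <- cfg$control; cl$holdout_frac <- 0; cl}),
                         seed = cfg$seed + 100L)
    prior <- prior_from_h2(vc$h2, m, cfg$slab_prob)
    prior$sigma_e2 <- NULL
    model <- "logistic"
    Yfit <- Y
  } else {
    Ya <- residualize_covariates(inp$Y, inp$C)
    y_scale <- apply(Ya, 2L, stats::sd)
    if (any(y_scale == 0)) stop("constant phenotype after covariate adjustment")
    Ya <- sweep(Ya, 2L, y_scale, "/")
    vc <- rhe_estimate(X, Ya, n_random_vectors = cfg$n_rhe_vectors,
                       seed = cfg$seed + 200L)
    prior <- prior_from_h2(vc$h2, m, cfg$slab_prob)
    offset <- NULL
    model <- "linear"
    Yfit <- Ya
  }
  wg <- fit_svi(X, Yfit, prior, model = model, control = cfg$control,
                offset = offset, seed = cfg$seed + 300L)
  chroms <- names(X$chromosome_index)
  loco_control <- cfg$control
  loco_control$holdout_frac <- 0
  # warm-started fits start near the optimum; allow early convergence
  loco_control$min_epochs <- min(cfg$control$min_epochs, 3L)
  fits <- list()
  for (k in seq_along(chroms)) {
    fits[[chroms[k]]] <- fit_svi(X, Yfit, prior, model = model,
                                 control = loco_control,
                                 init = wg$posterior,
                                 exclude_chromosome = chroms[k],
                                 offset = offset,
                                 seed = cfg$seed + 400L + k)
  }
  loco <- loco_residuals(X, Yfit, fits, model = model, offset = offset,
                         wg_fit = wg)
  .write_step1_files(cfg, G, X, loco, wg, trait_names)
  structure(list(G = G, X = X, Y = Yfit, offset = offset, model = model,
                 variance_components = vc, prior = prior, wg_fit = wg,
                 loco_fits = fits, loco = loco, covariates = inp$C,
                 weights = inp$weights, trait_names = trait_names),
            class = "step1_result")
}

.write_step1_files <- function(cfg, G, X, loco, wg, trait_names) {
  ids <- G$samples[, c("fid", "iid")]
  for (cc in loco$chromosomes) {
    vals <- if (loco$model == "linear") loco$ytilde[[cc]] else loco$phat[[cc]]
    d <- cbind(ids, as.data.frame(vals))
    names(d) <- c("FID", "IID", trait_names)
    data.table::fwrite(d, sprintf("%s.loco.chr%s.tsv", cfg$out, cc), sep = "\t")
  }
  post <- wg$posterior
  for (t in seq_along(trait_names)) {
    eff <- data.frame(SNP = X$variants$id[post$variant_cols],
                      SLAB_PROB = post$psi[, t], MU = post$mu[, t],
                      VAR = post$s2[, t], BETA_MEAN = post$beta_mean[, t])
    data.table::fwrite(eff, sprintf("%s.%s.effects.tsv", cfg$out,
                                    trait_names[t]), sep = "\t")
  }
}

# Weighted per-variant scan with sandwich variance; X columns = variants.
.weighted_scan <- function(X, ytilde, w) {
  den <- drop(crossprod(X^2, w))
  ok <- den > 0
  num <- drop(crossprod(X * w, ytilde))
  beta <- ifelse(ok, num / den, NA_real_)
  # sum_i (w x (y - x b))^2 = S_yy - 2 b S_xy + b^2 S_xx with w^2 weights
  s_yy <- drop(crossprod(X^2, (w * ytilde)^2))
  s_xy <- drop(crossprod(X^3, w^2 * ytilde))
  s_xx <- drop(crossprod(X^4, w^2))
  v <- (s_yy - 2 * beta * s_xy + beta^2 * s_xx) / den^2
  list(beta = beta, var = v, chisq = ifelse(ok, beta^2 / v, NA_real_), ok = ok)
}

#' Step 2: calibrated association testing
#'
#' Computes raw proportional score statistics for every QC-passing variant
#' against the LOCO residual (or null prediction) of its chromosome,
#' calibrates them per trait by matching the effective sample size of a
#' plain regression on an unrelated homogeneous subset, applies the Firth
#' fallback policy to binary traits and writes one summary-statistics file
#' per trait.
#'
#' @param cfg the [run_config()].
#' @param step1 result of [run_step1()].
#' @return named list (per trait) of `association_results` data.frames
#'   with columns CHR SNP BP A1 A2 A1FREQ N TEST BETA SE CHISQ LOG10P P;
#'   each carries attributes `calibration` and `skipped` (variant ids
#'   dropped for zero variance).
#' @export
run_step2 <- function(cfg, step1) {
  stopifnot(inherits(step1, "step1_result"))
  set.seed(cfg$seed + 900L)
  X <- step1$X
  G <- step1$G
  n <- nrow(X$values)
  m <- ncol(X$values)
  binary <- step1$model == "logistic"
  v <- X$variants
  chrom_of <- rep(names(X$chromosome_index),
                  vapply(X$chromosome_index, length, 1L))
  col_of <- unlist(X$chromosome_index, use.names = FALSE)
  chrom_by_col <- character(m)
  chrom_by_col[col_of] <- chrom_of
  missing_res <- setdiff(unique(chrom_by_col), step1$loco$chromosomes)
  if (length(missing_res)) {
    stop("no LOCO residuals for chromosome(s): ",
         paste(missing_res, collapse = ", "))
  }
  # kinship-based relatedness correction and calibration subset
  pairs <- estimate_kinship_pairs(X, seed = cfg$seed + 1L)
  pop <- if ("population" %in% names(G$samples)) G$samples$population else NULL
  subset_ids <- if (!is.null(cfg$calibration_ids)) {
    cal <- if (is.data.frame(cfg$calibration_ids)) cfg$calibration_ids
           else data.table::fread(cfg$calibration_ids, header = TRUE,
                                  colClasses = "character", data.table = FALSE)
    which(paste(G$samples$fid, G$samples$iid) %in% paste(cal[[1L]], cal[[2L]]))
  } else {
    calibration_subset(pop, pairs, n = n)
  }
  if (length(subset_ids) < 2L) stop("degenerate calibration subset")
  n_eff <- effective_sample_size(n, pairs)
  rel_adj <- n_eff / length(subset_ids)
  n_cal <- max(min(1000L, m), ceiling(cfg$calibration_frac * m))
  cal_cols <- sort(sample(m, min(n_cal, m)))
  weights <- step1$weights
  out <- list()
  for (t in seq_along(step1$trait_names)) {
    tn <- step1$trait_names[t]
    chisq_raw <- beta <- rep(NA_real_, m)
    for (cc in unique(chrom_by_col)) {
      cols <- X$chromosome_index[[cc]]
      Xc <- X$values[, cols, drop = FALSE]
      if (binary) {
        sc <- .score_scan_binary(Xc, step1$Y[, t],
                                 step1$loco$phat[[cc]][, t],
                                 step1$loco$W[[cc]][, t])
      } else if (!is.null(weights)) {
        sc <- .weighted_scan(Xc, step1$loco$ytilde[[cc]][, t], weights)
      } else {
        sc <- .score_scan_quant(Xc, step1$loco$ytilde[[cc]][, t])
      }
      chisq_raw[cols] <- sc$chisq
      beta[cols] <- sc$beta
    }
    # reference: plain regression with covariates on the unrelated subset
    Xcal <- X$values[subset_ids, cal_cols, drop = FALSE]
    Csub <- if (is.null(step1$covariates)) NULL else
      step1$covariates[subset_ids, , drop = FALSE]
    if (binary) {
      ref <- reference_chisq(Xcal, step1$Y[subset_ids, t], Csub, "logistic")
    } else if (!is.null(weights)) {
      ya <- drop(residualize_covariates(step1$Y[subset_ids, t], Csub))
      wsc <- .weighted_scan(residualize_covariates(Xcal, Csub), ya,
                            weights[subset_ids])
      ref <- list(mean_chisq = mean(wsc$chisq, na.rm = TRUE))
    } else {
      ref <- reference_chisq(Xcal, step1$Y[subset_ids, t], Csub, "linear")
    }
    ng <- if (!is.null(step1$loco$neff_gain)) step1$loco$neff_gain[t] else 1
    calib <- calibrate(chisq_raw[cal_cols], ref$mean_chisq,
                       neff_gain = ng, relatedness_adjustment = rel_adj)
    chisq_cal <- calib$gamma * chisq_raw
    log10p <- -stats::pchisq(chisq_cal, 1L, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
    res <- data.frame(
      CHR = v$chrom, SNP = v$id, BP = v$pos, A1 = v$a1, A2 = v$a2,
      A1FREQ = colMeans(G$dosages[, X$keep, drop = FALSE], na.rm = TRUE) / 2,
      N = n, TEST = "score", BETA = beta,
      SE = ifelse(chisq_cal > 0, abs(beta) / sqrt(chisq_cal), NA_real_),
      CHISQ = chisq_cal, LOG10P = log10p,
      P = stats::pchisq(chisq_cal, 1L, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
    skipped <- res$SNP[is.na(chisq_raw)]
    if (length(skipped)) {
      message(length(skipped), " zero-variance variant(s) skipped for ", tn)
      res <- res[!is.na(chisq_raw), , drop = FALSE]
    }
    if (binary) {
      prev <- mean(step1$Y[, t])
      null_offsets <- lapply(step1$loco$phat, function(p) stats::qlogis(p[, t]))
      col_by_snp <- match(res$SNP, v$id)
      res <- apply_fallback_policy(
        res, x_provider = function(i) X$values[, col_by_snp[i]],
        y = step1$Y[, t], null_offsets = null_offsets, prevalence = prev)
    }
    attr(res, "calibration") <- calib
    attr(res, "skipped") <- skipped
    class(res) <- c("association_results", "data.frame")
    data.table::fwrite(res, sprintf("%s.%s.sumstats.tsv", cfg$out, tn),
                       sep = "\t")
    out[[tn]] <- res
  }
  out
}

#' Evaluate association results against simulation truth
#'
#' Null variants are the even-chromosome variants (exact nulls under the
#' odd-chromosome-causal simulation design); causal variants come from the
#' truth flags. Reports mean chi-square in both sets, their ratio, and the
#' false-positive rate at the requested p-value thresholds.
#'
#' @param results an `association_results` data.frame (one trait).
#' @param truth data.frame with columns `id` and `causal` (0/1), e.g. one
#'   trait's columns of the simulator's truth file.
#' @param thresholds p-value thresholds for FPR (default 5e-2, 1e-3, 1e-5).
#' @return list of class `evaluation_report`: `mean_chisq_causal`,
#'   `mean_chisq_null`, `normalized_causal_chisq`, `fpr` (named vector),
#'   `n_causal`, `n_null`.
#' @export
evaluate_results <- function(results, truth,
                             thresholds = c(5e-2, 1e-3, 1e-5)) {
  extra <- setdiff(results$SNP, truth$id)
  missing <- setdiff(truth$id, results$SNP)
  # variants skipped in testing are allowed to be absent from results
  if (length(extra)) {
    stop("variants in results but not truth: ",
         paste(utils::head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) " ...")
  }
  tr <- truth[match(results$SNP, truth$id), ]
  causal <- tr$causal > 0
  even <- suppressWarnings(as.integer(as.character(results$CHR))) %% 2L == 0L
  null_set <- even & !causal
  fpr <- vapply(thresholds, function(th) {
    mean(results$P[null_set] < th, na.rm = TRUE)
  }, numeric(1))
  names(fpr) <- format(thresholds, scientific = TRUE, trim = TRUE)
  mc <- if (any(causal)) mean(results$CHISQ[causal], na.rm = TRUE) else NA_real_
  mn <- mean(results$CHISQ[null_set], na.rm = TRUE)
  structure(list(mean_chisq_causal = mc, mean_chisq_null = mn,
                 normalized_causal_chisq = if (is.na(mc)) NA_real_ else mc / mn,
                 fpr = fpr, n_causal = sum(causal), n_null = sum(null_set),
                 n_missing_from_results = length(missing)),
            class = "evaluation_report")
}

#' Hardy-Weinberg exact test
#'
#' Exact (Levene-Haldane conditional) test: the p-value sums the
#' probabilities of all heterozygote counts, conditional on the observed
#' allele counts, that are no more probable than the observed one.
#'
#' @param n_het heterozygote count.
#' @param n_hom1,n_hom2 homozygote counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  hs <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  logp <- vapply(hs, function(h) {
    a <- (rare - h) / 2
    b <- n - h - a
    h * log(2) + lgamma(n + 1) - lgamma(h + 1) - lgamma(a + 1) - lgamma(b + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  sum(p[p <= obs * (1 + 1e-9)])
}

#' Variant quality-control filter
#'
#' Removes variants failing MAF, missingness or Hardy-Weinberg exact-test
#' thresholds.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missingness_max maximum missing-call fraction (default 0.01).
#' @param hwe_p_min minimum HWE exact p (default 1e-15).
#' @return filtered [genotype_matrix()]; counts of removals are logged.
#' @export
qc_filter <- function(G, maf_min = 0.01, missingness_max = 0.01,
                      hwe_p_min = 1e-15) {
  d <- G$dosages
  maf <- G$variants$maf
  miss <- colMeans(is.na(d))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 1L, na.rm = TRUE), sum(x == 0L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- miss > missingness_max
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_miss | fail_hwe)
  message(sprintf("QC: %d variants kept (%d failed MAF, %d missingness, %d HWE)",
                  sum(keep), sum(fail_maf), sum(fail_miss), sum(fail_hwe)))
  if (!any(keep)) stop("no variants pass QC")
  genotype_matrix(d[, keep, drop = FALSE], G$samples,
                  G$variants[keep, , drop = FALSE])
}
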