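# Step-2 association testing: proportional score statistics on LOCO
# residuals, calibration of the constant of proportionality to an effective
# sample size, approximate Firth penalized-likelihood fallback for binary
# traits, and participation-weighted testing with Huber-White variance.

#' Score statistic for a quantitative trait
#'
#' Proportional chi-square `(x' ytilde)^2 / (x' x)` for one variant against
#' the LOCO residual phenotype of its chromosome, with the matching effect
#' estimate `x' ytilde / (x' x)`.
#'
#' @param x_test covariate-adjusted dosage vector.
#' @param ytilde LOCO residual phenotype for the variant's chromosome.
#' @return list: `chisq_raw`, `beta`, `xtx`; or NULL (variant skipped) when
#'   `x' x` is zero.
#' @export
score_stat_quant <- function(x_test, ytilde) {
  stopifnot(length(x_test) == length(ytilde))
  xtx <- sum(x_test^2)
  if (xtx <= 0) return(NULL)
  xty <- sum(x_test * ytilde)
  list(chisq_raw = xty^2 / xtx, beta = xty / xtx, xtx = xtx)
}

#' Score statistic for a binary trait
#'
#' Proportional statistic `T_B = x' (y - phat) / sqrt(x' W x)` with
#' `W = diag(phat (1 - phat))` from the step-1 null model; returns `T_B^2`
#' as the chi-square statistic.
#'
#' @param x_test covariate-adjusted dosage vector.
#' @param y 0/1 outcomes.
#' @param phat null-model case probabilities in (0, 1).
#' @param W optional diagonal weights (defaults to `phat * (1 - phat)`).
#' @return list: `chisq_raw`, `beta` (score effect on the logit scale,
#'   `x'(y - phat) / (x' W x)`), `xwx`; or NULL when `x' W x` is zero.
#' @export
score_stat_binary <- function(x_test, y, phat, W = phat * (1 - phat)) {
  stopifnot(length(x_test) == length(y), all(phat > 0), all(phat < 1))
  xwx <- sum(x_test^2 * W)
  if (xwx <= 0) return(NULL)
  u <- sum(x_test * (y - phat))
  list(chisq_raw = u^2 / xwx, beta = u / xwx, xwx = xwx)
}

# Vectorized raw score statistics over the columns of X (per chromosome the
# caller passes the matching ytilde / phat).
.score_scan_quant <- function(X, ytilde) {
  xty <- drop(crossprod(X, ytilde))
  xtx <- colSums(X^2)
  ok <- xtx > 0
  list(chisq = ifelse(ok, xty^2 / xtx, NA_real_),
       beta = ifelse(ok, xty / xtx, NA_real_), ok = ok)
}

.score_scan_binary <- function(X, y, phat, W = phat * (1 - phat)) {
  u <- drop(crossprod(X, y - phat))
  xwx <- drop(crossprod(X^2, W))
  ok <- xwx > 0
  list(chisq = ifelse(ok, u^2 / xwx, NA_real_),
       beta = ifelse(ok, u / xwx, NA_real_), ok = ok)
}

#' Pairwise kinship estimates from standardized genotypes
#'
#' Kinship `phi = GRM / 2` from standardized dosages; returns sample pairs
#' whose kinship falls in a detection window, by default third degree
#' (`2^-4.5`) up to duplicates.
#'
#' @param X standardized genotype matrix or `adjusted_matrix`.
#' @param min_kinship,max_kinship detection window. The default lower
#'   bound is the third-degree threshold `2^-4.5`, raised to five noise
#'   standard deviations `5 / (2 sqrt(M))` when few markers are available
#'   (the sampling noise of a GRM entry is about `1/sqrt(M)`), so unrelated
#'   pairs are not flagged en masse on small panels.
#' @param max_variants subsample of variants used (default 5000) to bound
#'   the cost of the N x N product.
#' @param seed seed for the variant subsample.
#' @return data.frame `i`, `j`, `kinship` for detected pairs.
#' @export
estimate_kinship_pairs <- function(X, min_kinship = NULL,
                                   max_kinship = 2^-0.5,
                                   max_variants = 5000L, seed = 1L) {
  if (inherits(X, "adjusted_matrix")) X <- X$values
  m <- ncol(X)
  if (m > max_variants) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    X <- X[, sort(sample(m, max_variants)), drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  if (is.null(min_kinship)) {
    min_kinship <- max(2^-4.5, 5 / (2 * sqrt(ncol(X))))
  }
  K <- tcrossprod(X) / ncol(X) / 2
  K[!upper.tri(K)] <- NA_real_
  hit <- which(K >= min_kinship & K <= max_kinship, arr.ind = TRUE)
  data.frame(i = hit[, 1L], j = hit[, 2L],
             kinship = K[hit])
}

#' Effective sample size under relatedness
#'
#' `N_eff = N - sum over detected pairs of 2 * kinship`, discounting the
#' duplicated genome share of relative pairs up to third degree.
#'
#' @param n total sample count.
#' @param pairs data.frame from [estimate_kinship_pairs()].
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(n, pairs) {
  n - if (nrow(pairs)) sum(2 * pairs$kinship) else 0
}

#' Reference mean chi-square from plain regression on a subset
#'
#' Classical linear or logistic score statistics with covariates on an
#' unrelated homogeneous calibration subset: the reference effective sample
#' size the calibrated statistics are matched to.
#'
#' @param X_cal genotypes (columns = calibration variants) for the subset
#'   samples, unstandardized or standardized.
#' @param y subset phenotype (quantitative) or 0/1 outcomes.
#' @param C subset covariates or NULL.
#' @param model `"linear"` or `"logistic"`.
#' @return list: `mean_chisq`, `chisq` per variant.
#' @export
reference_chisq <- function(X_cal, y, C = NULL, model = c("linear", "logistic")) {
  model <- match.arg(model)
  y <- as.numeric(y)
  n <- length(y)
  Xa <- residualize_covariates(X_cal, C)
  if (model == "linear") {
    ya <- drop(residualize_covariates(y, C))
    sc <- .score_scan_quant(Xa, ya)
    # classical score test N * corr^2 = (x'y)^2 / (x'x) * N / y'y
    chisq <- sc$chisq * n / pmax(sum(ya^2), 1e-12)
  } else {
    B <- .covariate_basis(C, n)
    fit <- stats::glm.fit(B, y, family = stats::binomial())
    phat <- fit$fitted.values
    sc <- .score_scan_binary(Xa, y, phat)
    chisq <- sc$chisq
  }
  list(mean_chisq = mean(chisq, na.rm = TRUE), chisq = chisq)
}

#' Calibrate proportional score statistics
#'
#' Finds the per-trait multiplier `gamma` applied to the raw proportional
#' statistics so that their mean on a genome-wide calibration variant set
#' matches the effective-sample-size target
#' `(reference_mean_chisq - 1) * neff_gain * relatedness_adjustment + 1`,
#' where the reference mean comes from plain linear/logistic regression on
#' an unrelated homogeneous subset, `neff_gain` is the held-out
#' residual-variance ratio from step 1 (the power gain of the Bayesian
#' predictor), and `relatedness_adjustment` scales the reference to the
#' full sample discounted for duplicated genome shares of relatives.
#'
#' @param raw_chisq raw statistics of the calibration variants on the full
#'   sample.
#' @param reference_mean_chisq mean chi-square from [reference_chisq()].
#' @param neff_gain held-out residual-variance ratio (default 1).
#' @param relatedness_adjustment `N_eff(full) / N(subset)` (default 1).
#' @return list of class `calibration_factor`: `gamma`,
#'   `reference_mean_chisq`, `raw_mean_chisq`, `neff_gain`,
#'   `relatedness_adjustment`.
#' @export
calibrate <- function(raw_chisq, reference_mean_chisq, neff_gain = 1,
                      relatedness_adjustment = 1) {
  raw_chisq <- raw_chisq[is.finite(raw_chisq)]
  if (!length(raw_chisq)) stop("no finite raw statistics to calibrate on")
  raw_mean <- mean(raw_chisq)
  if (raw_mean <= 0) stop("degenerate raw statistics (mean <= 0)")
  target <- (reference_mean_chisq - 1) * neff_gain * relatedness_adjustment + 1
  target <- max(target, 1e-6)
  structure(list(gamma = target / raw_mean,
                 reference_mean_chisq = reference_mean_chisq,
                 raw_mean_chisq = raw_mean,
                 neff_gain = neff_gain,
                 relatedness_adjustment = relatedness_adjustment),
            class = "calibration_factor")
}

#' Unrelated homogeneous calibration subset
#'
#' For synthetic or labelled data: the largest population with every member
#' of a detected relative pair removed.
#'
#' @param population integer/factor population labels (NULL = one
#'   population).
#' @param pairs data.frame from [estimate_kinship_pairs()].
#' @param n sample count (required when `population` is NULL).
#' @return integer vector of sample indices.
#' @export
calibration_subset <- function(population = NULL, pairs = NULL, n = NULL) {
  if (is.null(population)) {
    stopifnot(!is.null(n))
    ids <- seq_len(n)
  } else {
    tab <- table(population)
    big <- names(tab)[which.max(tab)]
    ids <- which(as.character(population) == big)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    ids <- setdiff(ids, unique(c(pairs$i, pairs$j)))
  }
  ids
}

# Penalized log-likelihood for a single-parameter Firth test:
# l(b) + 0.5 * log I(b), I(b) = sum x^2 w, w = p(1-p), p = plogis(off + x b)
.firth_pll <- function(b, x, y, off) {
  eta <- off + x * b
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
            (1 - y) * stats::plogis(-eta, log.p = TRUE))
  p <- stats::plogis(eta)
  info <- sum(x^2 * p * (1 - p))
  ll + 0.5 * log(max(info, 1e-300))
}

#' Approximate Firth penalized-likelihood test
#'
#' One-parameter Firth logistic regression for a single variant: the
#' covariate (and LOCO genetic offset) fixed effects are estimated once in
#' the null model and held fixed; the variant effect maximizes the
#' Jeffreys-penalized likelihood `l(b) + log det I(b) / 2` by damped
#' Newton. The p-value is a likelihood-ratio test on chi-square 1. Firth's
#' penalty guarantees a finite estimate even under complete separation.
#'
#' @param x_test dosage vector (raw or adjusted).
#' @param y 0/1 outcomes.
#' @param C covariates or NULL.
#' @param offset LOCO genetic prediction on the logit scale (default 0).
#' @param null_offset optional precomputed total null linear predictor
#'   (covariate fit + offset); supply to avoid refitting the null per
#'   variant.
#' @param max_iter,tol Newton controls.
#' @return list: `beta`, `se`, `lrt`, `p`, `converged`.
#' @export
firth_lrt <- function(x_test, y, C = NULL, offset = NULL, null_offset = NULL,
                      max_iter = 50L, tol = 1e-8) {
  y <- as.numeric(y)
  if (is.null(null_offset)) {
    null_offset <- firth_null_offset(y, C, offset)
  }
  x <- as.numeric(x_test)
  off <- null_offset
  b <- 0
  pll0 <- .firth_pll(0, x, y, off)
  pll <- pll0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- off + x * b
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- sum(x^2 * w)
    if (info <= 0) break
    # penalized score: U(b) = x'(y - p) + I'(b) / (2 I(b))
    dinfo <- sum(x^3 * w * (1 - 2 * p))
    u <- sum(x * (y - p)) + dinfo / (2 * info)
    step <- u / info
    step <- sign(step) * min(abs(step), 5) # cap huge first steps
    # damped: halve until the penalized likelihood does not decrease
    ok <- FALSE
    for (h in 0:10) {
      bnew <- b + step / 2^h
      pllnew <- .firth_pll(bnew, x, y, off)
      if (is.finite(pllnew) && pllnew >= pll - 1e-12) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    moved <- abs(bnew - b)
    b <- bnew
    pll <- pllnew
    if (moved < tol * (1 + abs(b))) {
      converged <- TRUE
      break
    }
  }
  if (pll < pll0) {
    b <- 0
    pll <- pll0
  }
  eta <- off + x * b
  p <- stats::plogis(eta)
  info <- sum(x^2 * p * (1 - p))
  lrt <- max(2 * (pll - pll0), 0)
  list(beta = b, se = if (info > 0) 1 / sqrt(info) else NA_real_,
       lrt = lrt, p = stats::pchisq(lrt, 1L, lower.tail = FALSE),
       converged = converged)
}

#' Null linear predictor for the approximate Firth test
#'
#' Covariate-only logistic fit with the LOCO genetic prediction as a fixed
#' offset; run once per trait (and chromosome) and shared across variants.
#'
#' @param y 0/1 outcomes.
#' @param C covariates or NULL.
#' @param offset logit-scale genetic offset (default 0).
#' @return numeric vector: fitted covariate predictor plus offset.
#' @export
firth_null_offset <- function(y, C = NULL, offset = NULL) {
  y <- as.numeric(y)
  off <- if (is.null(offset)) rep(0, length(y)) else as.numeric(offset)
  B <- .covariate_basis(C, length(y))
  fit <- stats::glm.fit(B, y, family = stats::binomial(), offset = off)
  drop(B %*% fit$coefficients) + off
}

#' Firth fallback policy for binary traits
#'
#' Re-tests with the approximate Firth likelihood-ratio test exactly those
#' variants whose score p-value is below `p_threshold` (default 0.05) and
#' that are rare (MAF below `maf_threshold`, default 5%) or belong to a
#' rare trait (prevalence below `prevalence_threshold`, default 5%), or
#' both. Other variants keep the calibrated score test.
#'
#' @param results `association_results` data.frame for one binary trait
#'   (columns `P`, `A1FREQ`, `TEST`, ...).
#' @param x_provider function(variant_row_index) returning the dosage
#'   vector for that variant (covariate adjustment is not needed; the null
#'   offset carries the covariates).
#' @param y 0/1 outcomes.
#' @param null_offsets named list chromosome -> null linear predictor from
#'   [firth_null_offset()] (LOCO offset per chromosome).
#' @param prevalence trait case fraction.
#' @param maf_threshold,prevalence_threshold,p_threshold policy gates.
#' @return `results` with Firth-retested rows updated (`TEST = "firth"`,
#'   new `BETA`, `SE`, `CHISQ`, `P`).
#' @export
apply_fallback_policy <- function(results, x_provider, y, null_offsets,
                                  prevalence, maf_threshold = 0.05,
                                  prevalence_threshold = 0.05,
                                  p_threshold = 0.05) {
  maf <- pmin(results$A1FREQ, 1 - results$A1FREQ)
  gate <- results$P < p_threshold &
    (maf < maf_threshold | prevalence < prevalence_threshold)
  gate[is.na(gate)] <- FALSE
  for (i in which(gate)) {
    off <- null_offsets[[as.character(results$CHR[i])]]
    ft <- firth_lrt(x_provider(i), y, null_offset = off)
    if (!ft$converged && ft$lrt == 0) next # keep score result, flag stays
    results$TEST[i] <- "firth"
    results$BETA[i] <- ft$beta
    results$SE[i] <- ft$se
    results$CHISQ[i] <- ft$lrt
    results$P[i] <- ft$p
    results$LOG10P[i] <- -stats::pchisq(ft$lrt, 1L, lower.tail = FALSE,
                                        log.p = TRUE) / log(10)
  }
  results
}

#' Participation-weighted score test with Huber-White variance
#'
#' Weighted least squares of the LOCO residual on one adjusted dosage with
#' a sandwich (heteroskedasticity-robust) variance:
#' `Var(beta) = (x' W x)^-2 * sum w_i^2 x_i^2 r_i^2`. With unit weights
#' this reduces to the unweighted score effect with an HC0 robust standard
#' error.
#'
#' @param x_test covariate-adjusted dosage vector.
#' @param ytilde LOCO residual phenotype.
#' @param weights positive per-sample participation weights.
#' @return list: `beta`, `se` (robust), `chisq`.
#' @export
weighted_score_test <- function(x_test, ytilde, weights) {
  stopifnot(length(weights) == length(x_test))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  xwx <- sum(weights * x_test^2)
  if (xwx <= 0) stop("zero weighted variance for the tested variant")
  beta <- sum(weights * x_test * ytilde) / xwx
  r <- ytilde - x_test * beta
  v <- sum((weights * x_test * r)^2) / xwx^2
  list(beta = beta, se = sqrt(v), chisq = beta^2 / v)
}
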