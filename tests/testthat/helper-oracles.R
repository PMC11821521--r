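# Independent oracle implementations used across the test files. These are
# deliberately written with different algorithms / primitives than the
# package code paths they check.

# Bit-level PLINK bed encoder built on packBits(), independent of the
# package's lookup-table codec. Dosages count allele1: 2 -> 00, 1 -> 10,
# 0 -> 11, NA -> 01 (two bits per genotype, low bits first).
oracle_encode_bed <- function(dosages) {
  n <- nrow(dosages); m <- ncol(dosages)
  bpv <- ceiling(n / 4)
  out <- as.raw(c(0x6C, 0x1B, 0x01))
  code_bits <- function(d) {
    if (is.na(d)) c(1L, 0L) # low bit, high bit
    else if (d == 2L) c(0L, 0L)
    else if (d == 1L) c(0L, 1L)
    else c(1L, 1L)
  }
  for (j in seq_len(m)) {
    bits <- integer(8L * bpv)
    for (i in seq_len(n)) {
      bits[(2L * (i - 1L) + 1L):(2L * i)] <- code_bits(dosages[i, j])
    }
    out <- c(out, packBits(as.integer(bits), type = "raw"))
  }
  out
}

# Exact Haseman-Elston solve with the explicitly formed GRM and exact
# traces (the randomized estimator's reference).
oracle_exact_he <- function(X, y) {
  n <- nrow(X); m <- ncol(X)
  K <- tcrossprod(X) / m
  tr_k <- sum(diag(K))
  tr_k2 <- sum(K^2)
  lhs <- matrix(c(tr_k2, tr_k, tr_k, n), 2, 2)
  rhs <- c(drop(crossprod(y, K %*% y)), sum(y^2))
  sol <- solve(lhs, rhs)
  sg <- max(sol[1], 0)
  se <- max(sol[2], 1e-12)
  c(sigma_g2 = sg, sigma_e2 = se, h2 = sg / (sg + se))
}

# Hudson F_ST, ratio-of-sums across variants with finite-sample correction.
oracle_hudson_fst <- function(dos1, dos2) {
  p1 <- colMeans(dos1, na.rm = TRUE) / 2
  p2 <- colMeans(dos2, na.rm = TRUE) / 2
  n1 <- 2 * nrow(dos1); n2 <- 2 * nrow(dos2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0 & is.finite(num)
  sum(num[keep]) / sum(den[keep])
}

# Exact posterior mean and log evidence of the spike-and-slab linear model
# by enumerating all 2^M spike/slab configurations with conjugate Gaussian
# integrals.
oracle_enum_posterior <- function(X, y, slab_prob, slab_var, sigma_e2) {
  m <- ncol(X); n <- nrow(X)
  gauss_logdens <- function(y, V) {
    ch <- chol(V)
    -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, y, transpose = TRUE)^2))
  }
  n_cfg <- 2^m
  logw <- numeric(n_cfg)
  means <- matrix(0, n_cfg, m)
  for (i in seq_len(n_cfg)) {
    S <- which(bitwAnd(i - 1L, 2^(seq_len(m) - 1L)) > 0L)
    logw[i] <- length(S) * log(slab_prob) + (m - length(S)) * log(1 - slab_prob)
    if (length(S) == 0L) {
      logw[i] <- logw[i] + sum(stats::dnorm(y, 0, sqrt(sigma_e2), log = TRUE))
    } else {
      Xs <- X[, S, drop = FALSE]
      V <- slab_var * tcrossprod(Xs) + sigma_e2 * diag(n)
      logw[i] <- logw[i] + gauss_logdens(y, V)
      Sig <- solve(crossprod(Xs) / sigma_e2 + diag(length(S)) / slab_var)
      means[i, S] <- Sig %*% crossprod(Xs, y) / sigma_e2
    }
  }
  mx <- max(logw)
  w <- exp(logw - mx)
  list(mean = drop(crossprod(means, w / sum(w))),
       log_evidence = mx + log(sum(w)))
}

# Closed-form ridge posterior mean (Gaussian-prior limit of the slab).
oracle_ridge_mean <- function(X, y, slab_var, sigma_e2) {
  drop(solve(crossprod(X) / sigma_e2 + diag(ncol(X)) / slab_var,
             crossprod(X, y) / sigma_e2))
}

# Brute-force grid maximization of the one-parameter Firth penalized
# likelihood over beta in [-5, 5].
oracle_firth_grid <- function(x, y, off, step = 1e-4) {
  bs <- seq(-5, 5, by = step)
  pll <- vapply(bs, function(b) {
    eta <- off + x * b
    p <- stats::plogis(eta)
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      0.5 * log(sum(x^2 * p * (1 - p)))
  }, numeric(1))
  bs[which.max(pll)]
}

# Standard genotype/trait fixture for unit tests.
make_toy_genotypes <- function(n = 120, m = 80, n_chrom = 4, seed = 42,
                               maf_min = 0.05, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, n_chromosomes = n_chrom,
                    maf_min = maf_min, seed = seed, ...)
  list(cfg = cfg, G = simulate_genotypes(cfg))
}
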