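# Variational machinery: KL, stochastic ELBO, gradients, fitting,
# warm-started LOCO refits and residual construction.

test_that("spike-and-slab KL is zero at the prior and hits known limits", {
  prior <- prior_spec(0.5, 0.3, 1)
  q <- svi_posterior(psi = 0.5, mu = 0, s2 = 0.3)
  expect_equal(kl_spike_slab(q, prior), 0)
  # slab probability -> eps with prior 0.5: Bernoulli term dominates, log 2
  q2 <- svi_posterior(psi = 1e-6, mu = 0, s2 = 0.3)
  expect_equal(kl_spike_slab(q2, prior), log(2), tolerance = 1e-4)
  # nonnegative over random admissible tuples
  set.seed(1)
  for (i in 1:50) {
    qr <- svi_posterior(runif(3, 0.01, 0.99), rnorm(3), runif(3, 0.01, 2))
    pr <- prior_spec(runif(1, 0.05, 0.95), runif(1, 0.05, 2))
    expect_true(all(kl_spike_slab(qr, pr) >= 0))
  }
})

test_that("KL matches Monte-Carlo integration over the mixture", {
  set.seed(2)
  n_mc <- 1e6
  for (i in 1:20) {
    psi <- runif(1, 0.05, 0.95); mu <- rnorm(1); s2 <- runif(1, 0.05, 1.5)
    p1 <- runif(1, 0.05, 0.95); s2p <- runif(1, 0.1, 2)
    analytic <- kl_spike_slab(svi_posterior(psi, mu, s2),
                              prior_spec(p1, s2p))
    # draw from the posterior mixture; log ratio of mixture densities
    # (the point mass contributes its probability ratio)
    slab <- runif(n_mc) < psi
    contrib <- numeric(n_mc)
    contrib[!slab] <- log((1 - psi) / (1 - p1))
    x <- rnorm(sum(slab), mu, sqrt(s2))
    contrib[slab] <- log(psi) + dnorm(x, mu, sqrt(s2), log = TRUE) -
      log(p1) - dnorm(x, 0, sqrt(s2p), log = TRUE)
    mc <- mean(contrib)
    se <- sd(contrib) / sqrt(n_mc)
    expect_lt(abs(mc - analytic), 3 * se + 1e-8)
  }
})

test_that("linear ELBO matches direct evaluation near the null posterior", {
  set.seed(3)
  n <- 40; m <- 6
  X <- matrix(rnorm(n * m), n, m)
  y <- rnorm(n)
  prior <- prior_spec(0.2, 0.5, 1.3)
  q <- svi_posterior(rep(1e-6, m), rep(0, m), rep(0.5, m))
  e <- elbo_linear(q, prior, X, y, exact = TRUE)
  bern_kl <- m * ((1 - 1e-6) * log((1 - 1e-6) / 0.8) + 1e-6 * log(1e-6 / 0.2))
  expect_equal(e, -sum(y^2) / (2 * 1.3) - n / 2 * log(2 * pi * 1.3) - bern_kl,
               tolerance = 1e-6)
})

test_that("stochastic ELBO is unbiased for the closed-form expectation", {
  set.seed(4)
  n <- 30; m <- 8
  X <- matrix(rnorm(n * m), n, m)
  y <- drop(X %*% rnorm(m, 0, 0.3)) + rnorm(n)
  prior <- prior_spec(0.3, 0.4, 1)
  q <- svi_posterior(runif(m, 0.2, 0.8), rnorm(m, 0, 0.3), runif(m, 0.1, 0.5))
  exact <- elbo_linear(q, prior, X, y, exact = TRUE)
  est <- replicate(400, elbo_linear(q, prior, X, y, n_mc_samples = 4L))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - exact), 3 * se + 1e-10)
  # minibatch sums are unbiased for the full ELBO too
  est_b <- replicate(400, {
    elbo_linear(q, prior, X[1:15, ], y[1:15], n_total = n) +
      elbo_linear(q, prior, X[16:30, ], y[16:30], n_total = n)
  })
  expect_lt(abs(mean(est_b) - exact), 3 * sd(est_b) / sqrt(400) + 1e-10)
})

test_that("antithetic pairing reduces the ELBO estimator variance", {
  set.seed(5)
  n <- 50; m <- 10
  X <- matrix(rnorm(n * m), n, m)
  y <- drop(X %*% rnorm(m, 0, 0.5)) + rnorm(n)
  prior <- prior_spec(0.3, 0.4, 1)
  q <- svi_posterior(runif(m, 0.3, 0.7), rnorm(m, 0, 0.5), runif(m, 0.1, 0.4))
  # same total draws: 1 antithetic pair vs 2 independent samples
  with_anti <- replicate(300, elbo_linear(q, prior, X, y, n_mc_samples = 1L,
                                          antithetic = TRUE))
  without <- replicate(300, elbo_linear(q, prior, X, y, n_mc_samples = 2L,
                                        antithetic = FALSE))
  expect_lt(var(with_anti), var(without))
})

test_that("logistic ELBO behaves at the null and rewards signal", {
  set.seed(6)
  n <- 60; m <- 4
  X <- matrix(rnorm(n * m), n, m)
  y <- rep(c(0, 1), n / 2)
  prior <- prior_spec(0.2, 0.5)
  q0 <- svi_posterior(rep(1e-6, m), rep(0, m), rep(0.5, m))
  e0 <- elbo_logistic(q0, prior, X, y, n_mc_samples = 8L, seed = 1)
  expect_equal(e0, n * log(0.5), tolerance = 0.05 * abs(n * log(0.5)))
  # all-case outcome with positive dosage variant: positive mu beats zero
  xpos <- matrix(abs(rnorm(n)), n, 1)
  y1 <- rep(1, n)
  pr <- prior_spec(0.5, 4)
  q_sig <- svi_posterior(1 - 1e-6, 2, 0.01)
  q_nul <- svi_posterior(1 - 1e-6, 0, 0.01)
  expect_gt(elbo_logistic(q_sig, pr, xpos, y1, n_mc_samples = 16L, seed = 2),
            elbo_logistic(q_nul, pr, xpos, y1, n_mc_samples = 16L, seed = 2))
})

test_that("stochastic gradients match central differences of the averaged ELBO", {
  set.seed(7)
  n <- 50; m <- 5
  X <- matrix(rnorm(n * m), n, m)
  ylin <- drop(X %*% rnorm(m, 0, 0.4)) + rnorm(n)
  ybin <- rbinom(n, 1, plogis(drop(X %*% rnorm(m, 0, 0.4))))
  prior <- prior_spec(0.3, 0.25, 1)
  q <- svi_posterior(runif(m, 0.2, 0.8), rnorm(m, 0, 0.3),
                     runif(m, 0.05, 0.3))
  reps <- 500L
  h <- 1e-4
  for (model in c("linear", "logistic")) {
    y <- if (model == "linear") ylin else ybin
    f <- if (model == "linear") elbo_linear else elbo_logistic
    gs <- sapply(seq_len(reps), function(r) {
      slabgwas:::.svi_gradient(q, prior, X, y, model = model, seed = r)$dmu
    })
    gbar <- rowMeans(gs)
    gse <- apply(gs, 1, sd) / sqrt(reps)
    for (j in seq_len(m)) {
      fd <- mean(sapply(seq_len(reps), function(r) {
        qp <- svi_posterior(q$psi, replace(q$mu, j, q$mu[j] + h), q$s2)
        qm <- svi_posterior(q$psi, replace(q$mu, j, q$mu[j] - h), q$s2)
        (f(qp, prior, X, y, seed = r) - f(qm, prior, X, y, seed = r)) / (2 * h)
      }))
      expect_lt(abs(gbar[j] - fd), 3 * gse[j] + 1e-6)
    }
  }
})

test_that("fit_svi is bit-reproducible under a fixed seed", {
  set.seed(8)
  n <- 80; m <- 30
  X <- matrix(rnorm(n * m), n, m)
  y <- drop(X %*% rnorm(m, 0, 0.2)) + rnorm(n)
  prior <- prior_spec(0.1, 0.1, 1)
  ctrl <- svi_control(max_epochs = 15, batch_size = 32)
  f1 <- fit_svi(X, y, prior, control = ctrl, seed = 99)
  f2 <- fit_svi(X, y, prior, control = ctrl, seed = 99)
  expect_identical(f1$posterior$beta_mean, f2$posterior$beta_mean)
  expect_identical(f1$report$elbo_trace, f2$report$elbo_trace)
})

test_that("posterior slab probabilities are enriched on causal variants", {
  cfg <- sim_config(n_samples = 2000, n_variants = 2000, n_chromosomes = 2,
                    maf_min = 0.05, polygenicity = 0.01, h2 = 0.4,
                    causal_odd_chrom_only = FALSE, seed = 9)
  G <- simulate_genotypes(cfg)
  set.seed(10)
  eff <- sample_effects(cfg, G$variants)
  tr <- simulate_quantitative(G, eff, cfg)
  X <- standardize(G)
  prior <- prior_from_h2(0.4, ncol(X$values), 0.01)
  fit <- fit_svi(X, tr$y, prior, control = svi_control(max_epochs = 30),
                 seed = 11)
  causal <- eff$causal_mask[X$keep]
  expect_gt(mean(fit$posterior$psi[causal, 1]),
            2 * mean(fit$posterior$psi[!causal, 1]))
})

test_that("warm-started LOCO fits reach the cold-start ELBO in far fewer epochs", {
  cfg <- sim_config(n_samples = 1000, n_variants = 2000, n_chromosomes = 2,
                    maf_min = 0.05, polygenicity = 0.02, h2 = 0.4,
                    causal_odd_chrom_only = FALSE, seed = 12)
  G <- simulate_genotypes(cfg)
  set.seed(13)
  tr <- simulate_quantitative(G, sample_effects(cfg, G$variants), cfg)
  X <- standardize(G)
  prior <- prior_from_h2(0.4, ncol(X$values), 0.01)
  wg <- fit_svi(X, tr$y, prior, control = svi_control(max_epochs = 40),
                seed = 14)
  cold_ctrl <- svi_control(max_epochs = 40, tol = 1e-7, min_epochs = 40)
  cold <- fit_svi(X, tr$y, prior, control = cold_ctrl,
                  exclude_chromosome = "1", seed = 15)
  n_cold <- cold$report$epochs
  warm_ctrl <- svi_control(max_epochs = ceiling(0.25 * n_cold), tol = 1e-9,
                           min_epochs = 1)
  warm <- fit_svi(X, tr$y, prior, control = warm_ctrl, init = wg$posterior,
                  exclude_chromosome = "1", seed = 16)
  cold_elbo <- tail(cold$report$elbo_trace, 1)
  warm_elbo <- tail(warm$report$elbo_trace, 1)
  expect_lte(warm$report$epochs, ceiling(0.25 * n_cold))
  expect_gte(warm_elbo, cold_elbo - 0.001 * abs(cold_elbo))
})

test_that("LOCO residuals handle null predictors and degenerate genomes", {
  toy <- make_toy_genotypes(n = 100, m = 60, n_chrom = 2, seed = 17)
  X <- standardize(toy$G)
  y <- rnorm(100)
  mcols <- ncol(X$values)
  null_post <- svi_posterior(rep(1e-6, mcols), rep(0, mcols), rep(0.1, mcols))
  null_post$variant_cols <- seq_len(mcols)
  lr <- loco_residuals(X, y, list(`1` = null_post, `2` = null_post), "linear")
  expect_equal(drop(lr$ytilde[["1"]]), y)
  expect_equal(drop(lr$ytilde[["2"]]), y)
  # single-chromosome genome: the LOCO fit is empty, residual equals y
  toy1 <- make_toy_genotypes(n = 80, m = 30, n_chrom = 1, seed = 18)
  X1 <- standardize(toy1$G)
  prior <- prior_spec(0.1, 0.05, 1)
  f1 <- fit_svi(X1, rnorm(80), prior, control = svi_control(max_epochs = 5),
                exclude_chromosome = "1", seed = 19)
  expect_identical(length(f1$posterior$variant_cols), 0L)
  lr1 <- loco_residuals(X1, y[1:80], list(`1` = f1), "linear")
  expect_equal(drop(lr1$ytilde[["1"]]), y[1:80])
  expect_error(loco_residuals(X, y, list(`1` = null_post), "linear"),
               "missing LOCO")
})

test_that("LOCO residual variance drops only where signal is retained", {
  # all causal variants on chromosome 1: leaving chr1 out keeps residual
  # variance near var(y); leaving chr2 out removes the chr1 signal
  cfg <- sim_config(n_samples = 1200, n_variants = 600, n_chromosomes = 2,
                    maf_min = 0.05, polygenicity = 0.05, h2 = 0.5, seed = 20)
  G <- simulate_genotypes(cfg)
  set.seed(21)
  eff <- sample_effects(cfg, G$variants) # odd-only: all causal on chr1
  tr <- simulate_quantitative(G, eff, cfg)
  X <- standardize(G)
  prior <- prior_from_h2(0.5, ncol(X$values), 0.05)
  ctrl <- svi_control(max_epochs = 30)
  fits <- list(
    `1` = fit_svi(X, tr$y, prior, control = ctrl, exclude_chromosome = "1",
                  seed = 22),
    `2` = fit_svi(X, tr$y, prior, control = ctrl, exclude_chromosome = "2",
                  seed = 23)
  )
  lr <- loco_residuals(X, tr$y, fits, "linear")
  v1 <- var(drop(lr$ytilde[["1"]]))
  v2 <- var(drop(lr$ytilde[["2"]]))
  vy <- var(tr$y)
  d <- attr(tr, "decomposition")
  expect_gt(v1, vy - 0.1)            # no proximal signal removed
  expect_lt(v2, vy - 0.5 * d["genetic"]) # chr1 signal removed from ytilde
})
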