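# Genotype and trait simulator: allele-frequency behaviour, relatedness,
# stratification, effect architectures, variance bookkeeping and the
# liability threshold.

test_that("HWE sampling tracks the drawn frequencies without structure", {
  cfg <- sim_config(n_samples = 800, n_variants = 200, n_chromosomes = 2,
                    maf_min = 0.05, seed = 1)
  G <- simulate_genotypes(cfg)
  f_hat <- colMeans(G$dosages) / 2
  # each realized frequency within a generous binomial CI of something in
  # (0, 1); pooled check: mean |f - round trip through maf| small
  expect_true(all(f_hat >= 0 & f_hat <= 1))
  # no population or relatives: genotype correlation between disjoint
  # sample halves should be null on average
  x1 <- colMeans(G$dosages[1:400, ])
  x2 <- colMeans(G$dosages[401:800, ])
  expect_lt(abs(cor(x1, x2) - 1), 0.2) # frequencies agree across halves
  expect_equal(unname(G$variants$maf), pmin(f_hat, 1 - f_hat),
               tolerance = 1e-12)
})

test_that("full-sib pairs show ~0.5 genomic relatedness, unrelated ~0", {
  cfg <- sim_config(n_samples = 600, n_variants = 2000, n_chromosomes = 2,
                    maf_min = 0.05,
                    relative_pairs = c(first_degree = 100L), seed = 2)
  G <- simulate_genotypes(cfg)
  X <- standardize(G)$values
  K <- tcrossprod(X) / ncol(X) # genomic relatedness (2 * kinship)
  pair_rel <- vapply(1:100, function(q) K[2 * q - 1, 2 * q], numeric(1))
  expect_equal(mean(pair_rel), 0.5, tolerance = 0.03)
  off <- K[301:400, 501:600]
  expect_lt(abs(mean(off)), 0.02)
  # half sibs: ~0.25
  cfg2 <- sim_config(n_samples = 400, n_variants = 2000, n_chromosomes = 2,
                     maf_min = 0.05,
                     relative_pairs = c(second_degree = 80L), seed = 3)
  X2 <- standardize(simulate_genotypes(cfg2))$values
  K2 <- tcrossprod(X2) / ncol(X2)
  pair2 <- vapply(1:80, function(q) K2[2 * q - 1, 2 * q], numeric(1))
  expect_equal(mean(pair2), 0.25, tolerance = 0.03)
  expect_error(sim_config(n_samples = 10, n_variants = 5,
                          relative_pairs = c(first_degree = 6L)),
               "relative pairs")
})

test_that("Balding-Nichols drift reproduces the target Hudson F_ST", {
  cfg <- sim_config(n_samples = 1000, n_variants = 3000, n_chromosomes = 2,
                    maf_min = 0.05, n_populations = 2, fst = 0.1, seed = 4)
  G <- simulate_genotypes(cfg)
  pop <- G$samples$population
  fst <- oracle_hudson_fst(G$dosages[pop == 1, ], G$dosages[pop == 2, ])
  expect_equal(fst, 0.1, tolerance = 0.015)
})

test_that("effect variances follow the MAF-dependence exponent", {
  variants <- data.frame(chrom = c(1L, 1L), id = c("a", "b"), pos = 1:2,
                         a1 = "A", a2 = "G", maf = c(0.01, 0.5))
  cfg <- sim_config(n_samples = 100, n_variants = 2, n_chromosomes = 1,
                    polygenicity = 1, effect_dist = "gaussian",
                    maf_alpha = -0.3, causal_odd_chrom_only = FALSE)
  # expected per-variant variance ratio (2f(1-f))^alpha evaluated directly
  expected_ratio <- (2 * 0.01 * 0.99)^-0.3 / (2 * 0.5 * 0.5)^-0.3
  set.seed(10)
  draws <- replicate(4000, sample_effects(cfg, variants)$beta)
  expect_equal(var(draws[1, ]) / var(draws[2, ]), expected_ratio,
               tolerance = 0.1)
  # alpha = 0: equal variances
  cfg0 <- cfg; cfg0$maf_alpha <- 0
  draws0 <- replicate(4000, sample_effects(cfg0, variants)$beta)
  expect_equal(var(draws0[1, ]) / var(draws0[2, ]), 1, tolerance = 0.1)
})

test_that("architectures honor polygenicity and the odd-chromosome rule", {
  toy <- make_toy_genotypes(n = 100, m = 200, n_chrom = 4, seed = 6,
                            polygenicity = 0.1)
  set.seed(7)
  eff <- sample_effects(toy$cfg, toy$G$variants)
  expect_identical(sum(eff$causal_mask), 20L)
  expect_true(all(eff$beta[!eff$causal_mask] == 0))
  odd <- as.integer(toy$G$variants$chrom) %% 2L == 1L
  expect_true(all(odd[eff$causal_mask]))
  # gaussian/laplace force polygenicity 1: every odd-chromosome variant causal
  for (dist in c("gaussian", "laplace")) {
    cfgd <- sim_config(n_samples = 100, n_variants = 200, n_chromosomes = 4,
                       maf_min = 0.05, effect_dist = dist, polygenicity = 0.5)
    expect_identical(cfgd$polygenicity, 1)
    effd <- sample_effects(cfgd, toy$G$variants)
    expect_identical(effd$causal_mask, odd & toy$G$variants$maf > 0)
  }
  # laplace draws have Laplace kurtosis (excess ~ 3)
  cfgl <- sim_config(n_samples = 100, n_variants = 2000, n_chromosomes = 1,
                     effect_dist = "laplace", maf_alpha = 0,
                     causal_odd_chrom_only = FALSE)
  vl <- data.frame(chrom = 1L, id = paste0("v", 1:2000), pos = 1:2000,
                   a1 = "A", a2 = "G", maf = 0.25)
  set.seed(8)
  bl <- sample_effects(cfgl, vl)$beta
  expect_equal(mean(bl^4) / mean(bl^2)^2, 6, tolerance = 0.8)
})

test_that("trait variance decomposition is exact and budgets are honored", {
  cfg <- sim_config(n_samples = 1500, n_variants = 400, n_chromosomes = 4,
                    maf_min = 0.05, polygenicity = 0.05, h2 = 0.4,
                    n_populations = 2, fst = 0.05, strat_var = 0.05,
                    relative_pairs = c(first_degree = 50L,
                                       second_degree = 50L), seed = 9)
  G <- simulate_genotypes(cfg)
  set.seed(19)
  eff <- sample_effects(cfg, G$variants)
  tr <- simulate_quantitative(G, eff, cfg)
  d <- attr(tr, "decomposition")
  expect_equal(sum(d[c("genetic", "stratification", "shared_env",
                       "residual", "cross_cov")]),
               unname(d["total"]), tolerance = 1e-6)
  expect_equal(unname(d["genetic"] / d["total"]), 0.4, tolerance = 0.05)
  expect_equal(var(tr$y), 1, tolerance = 1e-12)
  expect_equal(mean(tr$y), 0, tolerance = 1e-12)
  # stratification explains ~5% of variance: between-population share
  pop <- G$samples$population
  between <- var(ave(tr$y, pop)) / var(tr$y)
  expect_equal(unname(d["stratification"] / d["total"]), 0.05,
               tolerance = 0.02)
  expect_gt(between, 0.02)
})

test_that("null configuration produces pure noise", {
  cfg <- sim_config(n_samples = 2000, n_variants = 100, n_chromosomes = 2,
                    maf_min = 0.1, polygenicity = 0.1, h2 = 0, seed = 12)
  G <- simulate_genotypes(cfg)
  set.seed(13)
  eff <- sample_effects(cfg, G$variants)
  tr <- simulate_quantitative(G, eff, cfg)
  expect_gt(shapiro.test(sample(tr$y, 1000))$p.value, 1e-3)
  X <- standardize(G)$values
  r <- abs(drop(crossprod(X, tr$y)) / nrow(X))
  expect_lt(max(r), 5 / sqrt(nrow(X))) # no genetic correlation
  d <- attr(tr, "decomposition")
  expect_equal(unname(d["genetic"]), 0)
})

test_that("realized heritability is centered on the target across traits", {
  cfg <- sim_config(n_samples = 500, n_variants = 300, n_chromosomes = 2,
                    maf_min = 0.05, polygenicity = 0.1, h2 = 0.4, seed = 14)
  G <- simulate_genotypes(cfg)
  set.seed(15)
  shares <- replicate(50, {
    tr <- simulate_quantitative(G, sample_effects(cfg, G$variants), cfg)
    d <- attr(tr, "decomposition")
    unname(d["genetic"] / d["total"])
  })
  expect_equal(mean(shares), 0.4, tolerance = 3 * sd(shares) / sqrt(50) + 0.01)
})

test_that("liability threshold yields exact case counts and flags ties", {
  liab <- structure(data.frame(fid = 1:50000, iid = 1:50000,
                               y = rnorm(50000)),
                    class = c("trait_table", "data.frame"))
  b <- simulate_binary(liab, 0.3)
  expect_identical(sum(b$status), 15000L)
  b2 <- simulate_binary(liab, 0.01)
  expect_identical(sum(b2$status), 500L)
  # cases are the top liabilities
  expect_true(min(liab$y[b$status == 1]) >= max(liab$y[b$status == 0]) - 1e-12)
  const <- structure(data.frame(fid = 1:100, iid = 1:100, y = rep(1, 100)),
                     class = c("trait_table", "data.frame"))
  expect_error(simulate_binary(const, 0.3), "constant")
  small <- structure(data.frame(fid = 1:20, iid = 1:20, y = rnorm(20)),
                     class = c("trait_table", "data.frame"))
  expect_error(simulate_binary(small, 0.05), "degenerate")
})

test_that("simulation is reproducible under a fixed seed and writes a study", {
  cfg <- sim_config(n_samples = 60, n_variants = 40, n_chromosomes = 2,
                    maf_min = 0.1, polygenicity = 0.2, prevalence = 0.3,
                    seed = 77)
  s1 <- simulate_study(cfg, n_traits = 2)
  s2 <- simulate_study(cfg, n_traits = 2)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$status, s2$status)
  dir <- tempfile(); dir.create(dir)
  prefix <- file.path(dir, "study")
  write_study(s1, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".bed", ".bim", ".fam",
                                               ".pheno.tsv", ".status.tsv",
                                               ".truth.variants.tsv",
                                               ".truth.traits.tsv")))))
  G <- read_bed(paste0(prefix, ".bed"))
  expect_identical(unname(G$dosages), unname(s1$genotypes$dosages))
  tv <- read.delim(paste0(prefix, ".truth.variants.tsv"))
  expect_identical(nrow(tv), 40L)
  expect_identical(tv$causal1, as.integer(s1$truth[[1]]$causal_mask))
})

test_that("cross-population effects honor the configured correlation", {
  cfg <- sim_config(n_samples = 200, n_variants = 4000, n_chromosomes = 1,
                    n_populations = 2, fst = 0.05, polygenicity = 1,
                    effect_dist = "gaussian", maf_alpha = 0,
                    effect_corr = 0.4, causal_odd_chrom_only = FALSE)
  v <- data.frame(chrom = 1L, id = paste0("v", 1:4000), pos = 1:4000,
                  a1 = "A", a2 = "G", maf = 0.25)
  set.seed(33)
  eff <- sample_effects(cfg, v)
  B <- eff$beta_by_population
  expect_identical(dim(B), c(4000L, 2L))
  expect_equal(cor(B[, 1], B[, 2]), 0.4, tolerance = 0.05)
  # uncorrelated limit and perfectly shared limit
  for (rho in c(0, 1)) {
    cfg$effect_corr <- rho
    Br <- sample_effects(cfg, v)$beta_by_population
    expect_equal(cor(Br[, 1], Br[, 2]), rho, tolerance = 0.05)
  }
})
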