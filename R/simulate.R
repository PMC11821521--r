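# Genotype and trait simulator: Balding-Nichols discrete populations,
# gene-dropped close relatives, and traits built from standardized dosages
# with MAF-dependent effect variances, a discrete-ancestry stratification
# shift, a shared-environment draw per relative cluster, and i.i.d. Gaussian
# residual noise. Binary traits by an empirical liability threshold.

#' Simulation configuration
#'
#' Defaults are the study conditions used throughout the package's tests:
#' heritability 0.4, MAF-dependence exponent -0.3, 1% polygenicity with
#' causal variants restricted to odd chromosomes (even chromosomes are exact
#' nulls), stratification worth 5% of trait variance when more than one
#' population is simulated, and shared environment worth 20% / 10% of trait
#' variance in first- / second-degree relatives.
#'
#' @param n_samples,n_variants problem size.
#' @param n_chromosomes chromosomes variants are spread over (default 22).
#' @param maf_min,maf_max founder minor-allele-frequency range; the spectrum
#'   has density proportional to 1/f (log-uniform), so rare variants down to
#'   `maf_min` (default 1e-4) are included.
#' @param n_populations,fst discrete populations and the Balding-Nichols
#'   drift parameter between them.
#' @param relative_pairs named counts `c(first_degree = , second_degree = )`
#'   of full-sib and half-sib pairs.
#' @param h2 narrow-sense heritability of the quantitative liability.
#' @param polygenicity fraction of variants causal (spike-and-slab /
#'   Gaussian-mixture architectures; forced to 1 for Laplace and Gaussian).
#' @param effect_dist one of `"spike_slab"`, `"gaussian_mixture"`,
#'   `"laplace"`, `"gaussian"`.
#' @param mixture_f for `gaussian_mixture`: fraction of genetic variance
#'   explained by the smaller-variance Gaussian (0.05 or 0.5 in the study
#'   design).
#' @param maf_alpha exponent of the `(2f(1-f))^alpha` per-variant effect
#'   variance weight on standardized dosages (default -0.3).
#' @param strat_var trait-variance fraction from population stratification
#'   (default 0.05 when `n_populations > 1`, else 0).
#' @param env_first,env_second trait-variance fractions of the shared
#'   environmental draw in first- and second-degree relatives.
#' @param prevalence case fraction for liability-threshold binary traits
#'   (NULL for quantitative-only configs).
#' @param effect_corr optional cross-population effect correlation in
#'   [0, 1]: causal effects are drawn per population from an
#'   equi-correlated multivariate Gaussian (off, i.e. shared effects, by
#'   default).
#' @param causal_odd_chrom_only restrict causal variants to odd chromosomes.
#' @param seed RNG seed for reproducibility.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_variants, n_chromosomes = 22L,
                       maf_min = 1e-4, maf_max = 0.5,
                       n_populations = 1L, fst = 0,
                       relative_pairs = c(first_degree = 0L, second_degree = 0L),
                       h2 = 0.4, polygenicity = 0.01,
                       effect_dist = c("spike_slab", "gaussian_mixture",
                                       "laplace", "gaussian"),
                       mixture_f = 0.5, maf_alpha = -0.3,
                       strat_var = if (n_populations > 1L) 0.05 else 0,
                       env_first = 0.2, env_second = 0.1,
                       prevalence = NULL, effect_corr = NULL,
                       causal_odd_chrom_only = TRUE, seed = NULL) {
  effect_dist <- match.arg(effect_dist)
  if (effect_dist %in% c("laplace", "gaussian")) polygenicity <- 1
  stopifnot(n_samples >= 2, n_variants >= 1, n_chromosomes >= 1,
            maf_min > 0, maf_min < maf_max, maf_max <= 0.5,
            fst >= 0, fst < 1, h2 >= 0, h2 <= 1,
            polygenicity > 0, polygenicity <= 1,
            strat_var >= 0, env_first >= 0, env_second >= 0)
  rp <- c(first_degree = 0L, second_degree = 0L)
  rp[names(relative_pairs)] <- as.integer(relative_pairs)
  if (2L * sum(rp) > n_samples) stop("relative pairs exceed n_samples / 2")
  max_env <- if (rp["first_degree"] > 0L) env_first
             else if (rp["second_degree"] > 0L) env_second else 0
  if (h2 + strat_var + max_env > 1) {
    stop("variance budget exceeds 1: h2 + strat_var + max env share = ",
         h2 + strat_var + max_env)
  }
  if (!is.null(prevalence)) {
    stopifnot(prevalence > 0, prevalence <= 0.5)
  }
  if (!is.null(effect_corr)) {
    stopifnot(effect_corr >= 0, effect_corr <= 1, n_populations > 1L)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_chromosomes = as.integer(n_chromosomes),
    maf_min = maf_min, maf_max = maf_max,
    n_populations = as.integer(n_populations), fst = fst,
    relative_pairs = rp, h2 = h2, polygenicity = polygenicity,
    effect_dist = effect_dist, mixture_f = mixture_f, maf_alpha = maf_alpha,
    strat_var = strat_var, env_first = env_first, env_second = env_second,
    prevalence = prevalence, effect_corr = effect_corr,
    causal_odd_chrom_only = causal_odd_chrom_only, seed = seed
  ), class = "sim_config")
}

.draw_maf <- function(n, cfg) {
  exp(stats::runif(n, log(cfg$maf_min), log(cfg$maf_max)))
}

#' Simulate genotypes with population structure and relatives
#'
#' Founder allele frequencies are drawn from the configured spectrum;
#' population-specific frequencies follow a Balding-Nichols Beta drift with
#' parameter `fst`; unrelated individuals are Hardy-Weinberg binomial draws
#' within their population; first-degree pairs are full sibs and
#' second-degree pairs are half sibs produced by gene-dropping from
#' simulated parental haplotypes.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] whose `samples` table carries `population`,
#'   `cluster` (relative-cluster id, NA if unrelated) and `degree` columns.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_variants; K <- cfg$n_populations
  f0 <- .draw_maf(m, cfg)
  # population frequencies (m x K)
  P <- if (K > 1L && cfg$fst > 0) {
    c_ <- cfg$fst
    vapply(seq_len(K), function(k) {
      pk <- stats::rbeta(m, f0 * (1 - c_) / c_, (1 - f0) * (1 - c_) / c_)
      pmin(pmax(pk, 0), 1)
    }, numeric(m))
  } else {
    matrix(f0, m, K)
  }
  pop <- sort(rep_len(seq_len(K), n))
  dos <- matrix(0L, n, m)
  rp <- cfg$relative_pairs
  n_rel <- 2L * sum(rp)
  # relatives occupy the first rows (pairs laid out consecutively)
  cluster <- rep(NA_integer_, n)
  degree <- rep(NA_integer_, n)
  pair_deg <- rep(c(1L, 2L), rp)
  if (n_rel > 0L) {
    for (q in seq_along(pair_deg)) {
      i1 <- 2L * q - 1L; i2 <- 2L * q
      pk <- P[, pop[i1]]
      mom <- cbind(stats::rbinom(m, 1L, pk), stats::rbinom(m, 1L, pk))
      dad1 <- cbind(stats::rbinom(m, 1L, pk), stats::rbinom(m, 1L, pk))
      dad2 <- if (pair_deg[q] == 1L) dad1 else
        cbind(stats::rbinom(m, 1L, pk), stats::rbinom(m, 1L, pk))
      pick <- function(h) h[cbind(seq_len(m), stats::rbinom(m, 1L, 0.5) + 1L)]
      dos[i1, ] <- pick(mom) + pick(dad1)
      dos[i2, ] <- pick(mom) + pick(dad2)
      cluster[c(i1, i2)] <- q
      degree[c(i1, i2)] <- pair_deg[q]
    }
  }
  # unrelated remainder, chunked over variants to bound memory
  unrel <- seq(n_rel + 1L, length.out = n - n_rel)
  if (length(unrel)) {
    chunk <- 4000L
    for (k in seq_len(K)) {
      rows <- unrel[pop[unrel] == k]
      if (!length(rows)) next
      for (j0 in seq(1L, m, by = chunk)) {
        jj <- seq(j0, min(j0 + chunk - 1L, m))
        pr <- rep(P[jj, k], each = length(rows))
        dos[rows, jj] <- matrix(stats::rbinom(length(rows) * length(jj), 2L, pr),
                                length(rows), length(jj))
      }
    }
  }
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  variants <- data.frame(chrom = chrom, id = sprintf("snp%06d", seq_len(m)),
                         pos = pos, a1 = "A", a2 = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                        iid = sprintf("I%05d", seq_len(n)),
                        population = pop, cluster = cluster, degree = degree,
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, samples, variants)
}

#' Sample per-variant causal effects
#'
#' Selects `round(M * polygenicity)` causal variants (all polymorphic
#' variants for Laplace/Gaussian architectures, where polygenicity is 1),
#' restricted to odd chromosomes when configured, and draws their effects on
#' the standardized-dosage scale with per-variant variance proportional to
#' `(2 f (1 - f))^alpha`. The overall scale is nominal: the trait generator
#' rescales the realized genetic component to explain exactly `h2` of trait
#' variance.
#'
#' @param cfg a [sim_config()].
#' @param variants variant metadata data.frame with `chrom` and `maf`.
#' @return list of class `effect_vector` with `beta` (length M) and
#'   `causal_mask` (logical, length M).
#' @export
sample_effects <- function(cfg, variants) {
  m <- nrow(variants)
  maf <- variants$maf
  candidates <- which(!is.na(maf) & maf > 0)
  if (cfg$causal_odd_chrom_only) {
    odd <- as.integer(as.character(variants$chrom)) %% 2L == 1L
    candidates <- candidates[odd[candidates]]
  }
  n_causal <- round(m * cfg$polygenicity)
  if (n_causal < 1) stop("polygenicity * n_variants < 1: no causal variants")
  if (cfg$polygenicity == 1) {
    causal <- candidates
  } else {
    if (n_causal > length(candidates)) {
      stop("requested ", n_causal, " causal variants but only ",
           length(candidates), " candidates")
    }
    causal <- sort(sample(candidates, n_causal))
  }
  f <- maf[causal]
  cf <- (2 * f * (1 - f))^cfg$maf_alpha
  v <- cfg$h2 * cf / (m * cfg$polygenicity)
  nc <- length(causal)
  eff <- switch(cfg$effect_dist,
    spike_slab = ,
    gaussian = stats::rnorm(nc, 0, sqrt(v)),
    laplace = {
      # Laplace(0, b) has variance 2 b^2
      u <- stats::runif(nc, -0.5, 0.5)
      b <- sqrt(v / 2)
      -b * sign(u) * log(1 - 2 * abs(u))
    },
    gaussian_mixture = {
      # half the causal variants from each component; the small-variance
      # component carries fraction mixture_f of the genetic variance
      small <- seq_len(nc) %% 2L == 0L
      vs <- 2 * cfg$mixture_f * v
      vl <- 2 * (1 - cfg$mixture_f) * v
      ifelse(small, stats::rnorm(nc, 0, sqrt(vs)), stats::rnorm(nc, 0, sqrt(vl)))
    }
  )
  mask <- logical(m)
  mask[causal] <- TRUE
  if (!is.null(cfg$effect_corr)) {
    # equi-correlated per-population effects sharing the per-variant scale
    rho <- cfg$effect_corr
    K <- cfg$n_populations
    z0 <- stats::rnorm(nc)
    B <- matrix(0, m, K)
    for (k in seq_len(K)) {
      zk <- stats::rnorm(nc)
      B[causal, k] <- sqrt(v) * (sqrt(rho) * z0 + sqrt(1 - rho) * zk)
    }
    return(structure(list(beta = B[, 1L], beta_by_population = B,
                          causal_mask = mask), class = "effect_vector"))
  }
  beta <- numeric(m)
  beta[causal] <- eff
  structure(list(beta = beta, causal_mask = mask), class = "effect_vector")
}

.standardize_cols <- function(d, cols) {
  X <- matrix(as.double(d[, cols, drop = FALSE]), nrow(d))
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X))
  if (length(nas)) X[nas] <- mu[((nas - 1L) %/% nrow(X)) + 1L]
  X <- sweep(X, 2L, mu, "-")
  s <- sqrt(colMeans(X^2))
  s[s == 0] <- 1
  sweep(X, 2L, s, "/")
}

#' Simulate a quantitative trait
#'
#' Builds the trait as genetic effect + stratification shift + shared
#' environment + residual noise. Each realized component is rescaled to
#' explain exactly its configured trait-variance share (so `h2` is the
#' realized, not just expected, genetic fraction), and the trait is finally
#' standardized to zero mean and unit variance.
#'
#' @param G a [genotype_matrix()] from [simulate_genotypes()].
#' @param effects an `effect_vector` from [sample_effects()].
#' @param cfg the [sim_config()].
#' @return An object of class `trait_table`: data.frame columns `fid`,
#'   `iid`, `y`, with attributes `decomposition` (realized variance shares,
#'   summing to the total trait variance) and `beta_realized` (the effect
#'   sizes after rescaling, on the standardized-dosage scale of the final
#'   trait).
#' @export
simulate_quantitative <- function(G, effects, cfg) {
  n <- nrow(G$dosages)
  s <- G$samples
  causal <- which(effects$causal_mask)
  g <- if (cfg$h2 > 0 && length(causal)) {
    Xc <- .standardize_cols(G$dosages, causal)
    if (!is.null(effects$beta_by_population)) {
      gk <- Xc %*% effects$beta_by_population[causal, , drop = FALSE]
      gk[cbind(seq_len(n), s$population)]
    } else {
      drop(Xc %*% effects$beta[causal])
    }
  } else numeric(n)
  scale_comp <- function(x, target_var) {
    v <- stats::var(x)
    if (v <= 0) {
      if (target_var > 0) stop("degenerate component with positive variance target")
      return(list(x = x, k = 0))
    }
    k <- sqrt(target_var / v)
    list(x = x * k, k = k)
  }
  gs <- scale_comp(g, cfg$h2)
  strat <- numeric(n)
  if (cfg$strat_var > 0) {
    if (cfg$n_populations < 2L) stop("strat_var > 0 requires >= 2 populations")
    delta <- stats::rnorm(cfg$n_populations)
    strat <- scale_comp(delta[s$population], cfg$strat_var)$x
  }
  tau <- numeric(n)
  if (any(!is.na(s$cluster))) {
    cl <- unique(s$cluster[!is.na(s$cluster)])
    draw <- stats::rnorm(length(cl))
    names(draw) <- cl
    idx <- !is.na(s$cluster)
    share <- ifelse(s$degree[idx] == 1L, cfg$env_first, cfg$env_second)
    tau[idx] <- draw[as.character(s$cluster[idx])] * sqrt(share)
  }
  env_share_i <- ifelse(is.na(s$degree), 0,
                        ifelse(s$degree == 1L, cfg$env_first, cfg$env_second))
  resid_var <- 1 - cfg$h2 - cfg$strat_var - env_share_i
  if (any(resid_var < 0)) stop("negative residual variance; check the variance budget")
  eps <- stats::rnorm(n, 0, sqrt(resid_var))
  y <- gs$x + strat + tau + eps
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (sd_y == 0) stop("degenerate trait (zero variance)")
  y_std <- (y - mu_y) / sd_y
  comp <- cbind(genetic = gs$x, stratification = strat, shared_env = tau,
                residual = eps) / sd_y
  vars <- apply(comp, 2L, stats::var)
  cross <- stats::var(rowSums(comp)) - sum(vars)
  decomp <- c(vars, cross_cov = cross, total = stats::var(y_std))
  beta_real <- effects$beta * gs$k / sd_y
  structure(data.frame(fid = s$fid, iid = s$iid, y = y_std,
                       stringsAsFactors = FALSE),
            decomposition = decomp, beta_realized = beta_real,
            class = c("trait_table", "data.frame"))
}

#' Dichotomize a liability into cases and controls
#'
#' Liability-threshold model with empirical quantiles: the `round(N *
#' prevalence)` samples with the highest liability become cases, so the case
#' fraction equals the prevalence to within 1/N. Ties are broken by sample
#' order (deterministic); a constant liability is rejected.
#'
#' @param trait a `trait_table` with quantitative liabilities in `y`.
#' @param prevalence target case fraction in (0, 0.5].
#' @return the trait table with an added binary column `status` and
#'   attribute `prevalence`.
#' @export
simulate_binary <- function(trait, prevalence) {
  y <- trait$y
  n <- length(y)
  stopifnot(prevalence > 0, prevalence <= 0.5)
  n_cases <- round(prevalence * n)
  if (n_cases < 2) stop("prevalence * N < 2: degenerate case count")
  if (stats::sd(y) == 0) stop("constant liability; cannot threshold")
  ord <- order(y, seq_along(y), decreasing = TRUE)
  status <- integer(n)
  status[ord[seq_len(n_cases)]] <- 1L
  trait$status <- status
  attr(trait, "prevalence") <- n_cases / n
  trait
}

#' Simulate a complete study
#'
#' Genotypes plus `n_traits` replicate traits from one architecture, with
#' the per-variant truth (causal flags and realized effects) and per-trait
#' variance decompositions.
#'
#' @param cfg a [sim_config()]; if `cfg$prevalence` is set every trait also
#'   gets a liability-threshold binary version.
#' @param n_traits number of replicate traits.
#' @return list with `genotypes`, `phenotypes` (data.frame fid, iid, y1..),
#'   `status` (binary matrix or NULL), `truth` (list of per-trait
#'   `effect_vector`s, realized betas and decompositions).
#' @export
simulate_study <- function(cfg, n_traits = 1L) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  G <- local({cfg2 <- cfg; cfg2$seed <- NULL; simulate_genotypes(cfg2)})
  phen <- G$samples[, c("fid", "iid")]
  status <- NULL
  truth <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    eff <- sample_effects(cfg, G$variants)
    tr <- simulate_quantitative(G, eff, cfg)
    phen[[paste0("trait", t)]] <- tr$y
    if (!is.null(cfg$prevalence)) {
      tr <- simulate_binary(tr, cfg$prevalence)
      if (is.null(status)) status <- matrix(0L, nrow(phen), 0L)
      status <- cbind(status, tr$status)
      colnames(status)[t] <- paste0("trait", t)
    }
    truth[[t]] <- list(causal_mask = eff$causal_mask,
                       beta_realized = attr(tr, "beta_realized"),
                       decomposition = attr(tr, "decomposition"))
  }
  list(genotypes = G, phenotypes = phen, status = status, truth = truth,
       config = cfg)
}

#' Write a simulated study to disk
#'
#' PLINK bed/bim/fam plus whitespace-delimited phenotype (and, for binary
#' configs, case/control status) files, a covariate file carrying population
#' indicator columns, and tab-separated truth files: per-variant causal
#' flags and realized effects, and per-trait variance decompositions.
#'
#' @param study result of [simulate_study()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_study <- function(study, prefix) {
  G <- study$genotypes
  write_bed(G, prefix)
  data.table::fwrite(study$phenotypes, paste0(prefix, ".pheno.tsv"), sep = "\t")
  if (!is.null(study$status)) {
    st <- cbind(study$phenotypes[, c("fid", "iid")], as.data.frame(study$status))
    data.table::fwrite(st, paste0(prefix, ".status.tsv"), sep = "\t")
  }
  K <- study$config$n_populations
  if (K > 1L) {
    covar <- study$phenotypes[, c("fid", "iid")]
    for (k in seq(2L, K)) {
      covar[[paste0("pop", k)]] <- as.integer(G$samples$population == k)
    }
    data.table::fwrite(covar, paste0(prefix, ".covar.tsv"), sep = "\t")
  }
  tv <- data.frame(id = G$variants$id, chrom = G$variants$chrom)
  for (t in seq_along(study$truth)) {
    tv[[paste0("causal", t)]] <- as.integer(study$truth[[t]]$causal_mask)
    tv[[paste0("beta", t)]] <- study$truth[[t]]$beta_realized
  }
  data.table::fwrite(tv, paste0(prefix, ".truth.variants.tsv"), sep = "\t")
  td <- do.call(rbind, lapply(study$truth, function(x) x$decomposition))
  td <- data.frame(trait = paste0("trait", seq_along(study$truth)), td)
  data.table::fwrite(td, paste0(prefix, ".truth.traits.tsv"), sep = "\t")
  invisible(prefix)
}
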