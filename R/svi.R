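# Spike-and-slab Bayesian whole-genome regression fitted by stochastic
# variational inference. The approximate posterior is fully factorized:
# q(beta_j) = (1 - psi_j) delta(0) + psi_j N(mu_j, s2_j), with psi_j the
# slab (nonzero-effect) probability. The stochastic ELBO uses the local
# reparameterization trick -- the per-sample linear predictor is sampled
# from its implied Gaussian N(X a, X^2 s) with a_j = psi_j mu_j and
# s_j = psi_j s2_j + psi_j (1 - psi_j) mu_j^2 -- and antithetic +/-z pairs.
# Parameters are optimized on unconstrained scales (logit psi, mu, log s2)
# with Adam. Multiple traits are fitted jointly as parameter-matrix columns
# sharing every genotype pass.

.PSI_EPS <- 1e-6

#' Prior specification for the spike-and-slab regression
#'
#' @param slab_prob prior probability that a variant has a nonzero effect.
#' @param slab_var prior effect variance of the slab component.
#' @param sigma_e2 residual variance (linear model only); may be a vector
#'   with one entry per trait.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(slab_prob, slab_var, sigma_e2 = NULL) {
  stopifnot(all(slab_prob > 0), all(slab_prob < 1), all(slab_var > 0))
  if (!is.null(sigma_e2)) stopifnot(all(sigma_e2 > 0))
  structure(list(slab_prob = slab_prob, slab_var = slab_var,
                 sigma_e2 = sigma_e2), class = "prior_spec")
}

#' Derive the prior from variance components
#'
#' For a standardized trait and standardized genotypes the prior satisfies
#' `M * slab_prob * slab_var = h2`, so `slab_var = h2 / (M * slab_prob)` and
#' `sigma_e2 = 1 - h2`. The heritability is clamped to `[0.01, 0.95]` to
#' keep the prior proper.
#'
#' @param h2 heritability estimate (scalar or per-trait vector).
#' @param n_variants number of model-fitting variants M.
#' @param slab_prob prior slab probability (default 0.01).
#' @return a [prior_spec()].
#' @export
prior_from_h2 <- function(h2, n_variants, slab_prob = 0.01) {
  h2 <- pmin(pmax(h2, 0.01), 0.95)
  prior_spec(slab_prob = slab_prob, slab_var = h2 / (n_variants * slab_prob),
             sigma_e2 = 1 - h2)
}

.as_param_matrix <- function(x, m, t) {
  if (is.null(dim(x))) matrix(x, m, t) else {
    stopifnot(nrow(x) == m)
    if (ncol(x) == t) x else matrix(x, m, t)
  }
}

#' Construct a variational posterior object
#'
#' @param psi per-variant slab probabilities (length M or M x T matrix).
#' @param mu slab means.
#' @param s2 slab variances.
#' @return list of class `svi_posterior` with matrix fields `psi`, `mu`,
#'   `s2` and `beta_mean = psi * mu`.
#' @export
svi_posterior <- function(psi, mu, s2) {
  m <- if (is.null(dim(psi))) length(psi) else nrow(psi)
  t <- if (is.null(dim(psi))) 1L else ncol(psi)
  psi <- pmin(pmax(.as_param_matrix(psi, m, t), .PSI_EPS), 1 - .PSI_EPS)
  mu <- .as_param_matrix(mu, m, t)
  s2 <- .as_param_matrix(s2, m, t)
  stopifnot(all(s2 > 0))
  structure(list(psi = psi, mu = mu, s2 = s2, beta_mean = psi * mu),
            class = "svi_posterior")
}

.prior_cols <- function(prior, t) {
  list(p1 = rep_len(prior$slab_prob, t),
       s2p = rep_len(prior$slab_var, t),
       se2 = if (is.null(prior$sigma_e2)) NULL else rep_len(prior$sigma_e2, t))
}

#' Per-variant KL divergence between posterior and prior
#'
#' `KL(Bern(psi_j) || Bern(p1)) + psi_j * KL(N(mu_j, s2_j) || N(0, s2p))`,
#' the penalty of the spike-and-slab ELBO. Always nonnegative and exactly
#' zero when the posterior equals the prior.
#'
#' @param q an [svi_posterior()].
#' @param prior a [prior_spec()].
#' @return M x T matrix (dropped to a vector for one trait) of KL values.
#' @export
kl_spike_slab <- function(q, prior) {
  t <- ncol(q$psi)
  pc <- .prior_cols(prior, t)
  psi <- q$psi
  p1 <- matrix(pc$p1, nrow(psi), t, byrow = TRUE)
  s2p <- matrix(pc$s2p, nrow(psi), t, byrow = TRUE)
  bern <- (1 - psi) * log((1 - psi) / (1 - p1)) + psi * log(psi / p1)
  gauss <- 0.5 * (-1 + (q$mu^2 + q$s2) / s2p - log(q$s2 / s2p))
  kl <- bern + psi * gauss
  if (t == 1L) drop(kl) else kl
}

.kl_grads <- function(psi, mu, s2, p1, s2p) {
  gauss <- 0.5 * (-1 + (mu^2 + s2) / s2p - log(s2 / s2p))
  list(dpsi = log(psi / (1 - psi)) - log(p1 / (1 - p1)) + gauss,
       dmu = psi * mu / s2p,
       ds2 = psi * 0.5 * (1 / s2p - 1 / s2))
}

.kl_total <- function(psi, mu, s2, p1, s2p) {
  bern <- (1 - psi) * log((1 - psi) / (1 - p1)) + psi * log(psi / p1)
  gauss <- 0.5 * (-1 + (mu^2 + s2) / s2p - log(s2 / s2p))
  colSums(bern + psi * gauss)
}

# One stochastic evaluation of the batch ELBO contribution and (optionally)
# its gradient w.r.t. the natural parameters (psi, mu, s2). Shared by
# elbo_linear/elbo_logistic and the fit loop. `scale_kl` is |batch|/N.
# p1m/s2pm are prior matrices precomputed once per fit; the training path
# sets want_elbo = FALSE to skip the parts the optimizer never reads.
.svi_batch2 <- function(Xb, X2b, Yb, psi, mu, s2, p1m, s2pm, se2, model,
                        scale_kl, n_mc_samples, antithetic,
                        want_grad, want_elbo, OFFb = NULL, tX = FALSE) {
  # tX: Xb/X2b are stored transposed (variants x samples), the layout the
  # fit loop uses so that minibatch extraction is a contiguous column gather
  nb <- nrow(Yb); t <- ncol(Yb)
  a <- psi * mu
  pm2 <- psi * mu^2
  s <- psi * s2 + pm2 - psi * pm2 # psi s2 + psi (1 - psi) mu^2
  m_lin <- if (tX) crossprod(Xb, a) else Xb %*% a
  if (!is.null(OFFb)) m_lin <- m_lin + OFFb
  v_lin <- if (tX) crossprod(X2b, s) else X2b %*% s
  sd_lin <- sqrt(pmax(v_lin, 1e-12))
  signs <- if (antithetic) c(1, -1) else 1
  n_draws <- n_mc_samples * length(signs)
  gm <- gv <- if (want_grad) 0 else NULL
  data_sum <- 0
  inv_se2 <- if (model == "linear") {
    matrix(1 / se2, nb, t, byrow = TRUE)
  } else NULL
  for (sdx in seq_len(n_mc_samples)) {
    Z <- matrix(stats::rnorm(nb * t), nb, t)
    for (sgn in signs) {
      eta <- m_lin + (sgn) * sd_lin * Z
      if (model == "linear") {
        r <- (Yb - eta) * inv_se2
        if (want_elbo) data_sum <- data_sum - colSums((Yb - eta)^2 * inv_se2) / 2
      } else {
        r <- Yb - stats::plogis(eta)
        if (want_elbo) {
          data_sum <- data_sum +
            colSums(Yb * stats::plogis(eta, log.p = TRUE) +
                    (1 - Yb) * stats::plogis(-eta, log.p = TRUE))
        }
      }
      if (want_grad) {
        gm <- gm + r
        gv <- gv + r * (sgn * Z) / (2 * sd_lin)
      }
    }
  }
  out <- list()
  if (want_elbo) {
    data_sum <- data_sum / n_draws
    if (model == "linear") data_sum <- data_sum - nb / 2 * log(2 * pi * se2)
    gauss <- 0.5 * (-1 + (mu^2 + s2) / s2pm - log(s2 / s2pm))
    bern <- (1 - psi) * log((1 - psi) / (1 - p1m)) + psi * log(psi / p1m)
    out$elbo <- data_sum - scale_kl * colSums(bern + psi * gauss)
  }
  if (want_grad) {
    gA <- (if (tX) Xb %*% gm else crossprod(Xb, gm)) / n_draws
    gS <- (if (tX) X2b %*% gv else crossprod(X2b, gv)) / n_draws
    gauss <- 0.5 * (-1 + (mu^2 + s2) / s2pm - log(s2 / s2pm))
    mu1p <- mu - psi * mu # mu (1 - psi)
    out$dpsi <- gA * mu + gS * (s2 + mu * mu1p - pm2) -
      scale_kl * (log(psi / (1 - psi)) - log(p1m / (1 - p1m)) + gauss)
    out$dmu <- gA * psi + gS * (2 * psi * mu1p) - scale_kl * (psi * mu / s2pm)
    out$ds2 <- gS * psi - scale_kl * (psi * 0.5 * (1 / s2pm - 1 / s2))
  }
  out
}

# Compatibility wrapper used by the exported ELBO/gradient entry points.
.svi_batch <- function(Xb, X2b, Yb, psi, mu, s2, pc, model, scale_kl,
                       n_mc_samples, antithetic, want_grad, OFFb = NULL) {
  t <- ncol(Yb)
  p1m <- matrix(pc$p1, nrow(psi), t, byrow = TRUE)
  s2pm <- matrix(pc$s2p, nrow(psi), t, byrow = TRUE)
  .svi_batch2(Xb, X2b, Yb, psi, mu, s2, p1m, s2pm, pc$se2, model, scale_kl,
              n_mc_samples, antithetic, want_grad, want_elbo = TRUE, OFFb)
}

.elbo_stochastic <- function(q, prior, X_batch, y_batch, n_mc_samples,
                             antithetic, n_total, model, seed, exact = FALSE,
                             offset = NULL) {
  X_batch <- as.matrix(X_batch)
  Yb <- as.matrix(y_batch)
  t <- ncol(Yb)
  stopifnot(nrow(Yb) == nrow(X_batch), nrow(q$psi) == ncol(X_batch))
  pc <- .prior_cols(prior, t)
  scale_kl <- nrow(X_batch) / n_total
  OFFb <- if (is.null(offset)) NULL else {
    o <- as.matrix(offset)
    if (ncol(o) == 1L && t > 1L) o <- o[, rep(1L, t), drop = FALSE]
    o
  }
  if (exact && model == "linear") {
    a <- q$psi * q$mu
    s <- q$psi * q$s2 + q$psi * (1 - q$psi) * q$mu^2
    resid <- Yb - X_batch %*% a
    quad <- colSums(resid^2) + colSums((X_batch^2) %*% s)
    p1 <- matrix(pc$p1, nrow(q$psi), t, byrow = TRUE)
    s2p <- matrix(pc$s2p, nrow(q$psi), t, byrow = TRUE)
    elbo <- -quad / (2 * pc$se2) - nrow(X_batch) / 2 * log(2 * pi * pc$se2) -
      scale_kl * .kl_total(q$psi, q$mu, q$s2, p1, s2p)
    return(if (t == 1L) drop(elbo) else elbo)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- .svi_batch(X_batch, X_batch^2, Yb, q$psi, q$mu, q$s2, pc, model,
                    scale_kl, n_mc_samples, antithetic, want_grad = FALSE,
                    OFFb = OFFb)
  if (!all(is.finite(res$elbo))) stop("non-finite ELBO estimate")
  if (t == 1L) drop(res$elbo) else res$elbo
}

#' Stochastic ELBO estimate for the linear spike-and-slab model
#'
#' Gaussian log-likelihood of linear predictors sampled by local
#' reparameterization (antithetic pairs share one standard-normal draw),
#' minus the KL penalty scaled by `|batch| / n_total`. With
#' `exact = TRUE` the expectation of the quadratic is evaluated in closed
#' form instead of sampled (the linear-model expected ELBO has one).
#'
#' @param q an [svi_posterior()].
#' @param prior a [prior_spec()] with `sigma_e2` set.
#' @param X_batch batch genotype matrix (covariate-adjusted, standardized).
#' @param y_batch batch phenotype vector/matrix (covariate-adjusted).
#' @param n_mc_samples Monte-Carlo draws (antithetic pairs count once).
#' @param antithetic use paired +/-z draws (default TRUE).
#' @param n_total full-data sample count for KL scaling (defaults to the
#'   batch size, i.e. the batch is the full data).
#' @param exact closed-form expected ELBO instead of a stochastic estimate.
#' @param seed optional seed for the Monte-Carlo draws (RNG state restored).
#' @return scalar ELBO estimate (vector for multi-trait input), including
#'   the Gaussian normalizing constant so that full-data values lower-bound
#'   the log evidence.
#' @export
elbo_linear <- function(q, prior, X_batch, y_batch, n_mc_samples = 1L,
                        antithetic = TRUE, n_total = NROW(X_batch),
                        exact = FALSE, seed = NULL) {
  stopifnot(!is.null(prior$sigma_e2), n_mc_samples >= 1L, NROW(X_batch) >= 1L)
  .elbo_stochastic(q, prior, X_batch, y_batch, n_mc_samples, antithetic,
                   n_total, "linear", seed, exact = exact)
}

#' Stochastic ELBO estimate for the logistic spike-and-slab model
#'
#' Bernoulli log-likelihood of sampled linear predictors plus the scaled KL
#' penalty; local reparameterization and antithetic pairing as in
#' [elbo_linear()].
#'
#' @inheritParams elbo_linear
#' @param y_batch binary 0/1 outcomes (vector or matrix).
#' @param offset fixed linear-predictor offset (covariate fixed effects).
#' @return scalar ELBO estimate (vector for multi-trait input).
#' @export
elbo_logistic <- function(q, prior, X_batch, y_batch, n_mc_samples = 1L,
                          antithetic = TRUE, n_total = NROW(X_batch),
                          seed = NULL, offset = NULL) {
  yb <- as.matrix(y_batch)
  stopifnot(all(yb %in% c(0, 1)), n_mc_samples >= 1L)
  .elbo_stochastic(q, prior, X_batch, y_batch, n_mc_samples, antithetic,
                   n_total, "logistic", seed, offset = offset)
}

# Stochastic gradient of the batch ELBO w.r.t. the natural parameters; used
# by the finite-difference correctness tests.
.svi_gradient <- function(q, prior, X_batch, y_batch, model = "linear",
                          n_mc_samples = 1L, antithetic = TRUE,
                          n_total = NROW(X_batch), seed = NULL) {
  Xb <- as.matrix(X_batch); Yb <- as.matrix(y_batch)
  pc <- .prior_cols(prior, ncol(Yb))
  if (!is.null(seed)) set.seed(seed)
  .svi_batch(Xb, Xb^2, Yb, q$psi, q$mu, q$s2, pc, model,
             nrow(Xb) / n_total, n_mc_samples, antithetic, want_grad = TRUE)
}

#' Optimizer and schedule settings for [fit_svi()]
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size samples per minibatch (default 128).
#' @param max_epochs maximum passes over the data (default 100).
#' @param n_mc_samples Monte-Carlo draws per batch; with antithetic pairing
#'   the default 1 gives two effective samples.
#' @param antithetic use antithetic +/-z pairs (default TRUE).
#' @param tol relative ELBO change declaring convergence (default 1e-4).
#' @param patience epochs the smoothed ELBO must be stable (default 5).
#' @param holdout_frac fraction of samples excluded from training and used
#'   to estimate the held-out residual variance (default 0).
#' @param min_epochs minimum epochs before convergence can be declared.
#' @param eval_every evaluate the full-data ELBO every this many epochs
#'   (the convergence check runs on evaluated epochs only).
#' @return list of class `svi_control`.
#' @export
svi_control <- function(learning_rate = 0.01, batch_size = 128L,
                        max_epochs = 100L, n_mc_samples = 1L,
                        antithetic = TRUE, tol = 1e-4, patience = 5L,
                        holdout_frac = 0, min_epochs = 10L,
                        eval_every = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            n_mc_samples >= 1, tol > 0, patience >= 1,
            holdout_frac >= 0, holdout_frac < 0.5, eval_every >= 1)
  structure(as.list(environment()), class = "svi_control")
}

#' Fit the spike-and-slab regression by stochastic variational inference
#'
#' Maximizes the ELBO by minibatch Adam updates on unconstrained
#' reparameterizations (logit slab probability, slab mean, log slab
#' variance). Multiple traits (columns of `y`) are fitted jointly with
#' independent parameters, sharing every pass over the genotypes. For
#' leave-one-chromosome-out fits, pass `exclude_chromosome` and the
#' whole-genome posterior as `init`: the excluded chromosome's columns are
#' dropped and all remaining parameters are warm-started.
#'
#' @param X standardized, covariate-adjusted genotypes: an
#'   `adjusted_matrix` from [standardize()] or a plain matrix (then supply
#'   `chromosome_index` if `exclude_chromosome` is used).
#' @param y covariate-adjusted phenotype (linear) or raw 0/1 outcomes
#'   (logistic); vector or N x T matrix.
#' @param prior a [prior_spec()]; `sigma_e2` required for the linear model.
#' @param model `"linear"` or `"logistic"`.
#' @param control an [svi_control()].
#' @param init optional [svi_posterior()] over all M columns (or the kept
#'   columns) used to warm-start.
#' @param exclude_chromosome optional chromosome label to leave out.
#' @param chromosome_index named list chromosome -> column indices (taken
#'   from `X` when it is an `adjusted_matrix`).
#' @param offset fixed linear-predictor offset, N x T or vector (logistic
#'   model: the covariate fixed effects enter here).
#' @param seed RNG seed; fixed seed makes the fit bit-reproducible.
#' @return list with `posterior` (an [svi_posterior()] plus
#'   `variant_cols`, the global column indices it covers) and `report`
#'   (class `svi_report`: `elbo_trace`, `epochs`, `converged`, `seed`,
#'   `holdout` row indices, `elapsed` seconds).
#' @export
fit_svi <- function(X, y, prior, model = c("linear", "logistic"),
                    control = svi_control(), init = NULL,
                    exclude_chromosome = NULL, chromosome_index = NULL,
                    offset = NULL, seed = NULL) {
  model <- match.arg(model)
  t0 <- proc.time()[["elapsed"]]
  if (inherits(X, "adjusted_matrix")) {
    chromosome_index <- X$chromosome_index
    X <- X$values
  }
  X <- as.matrix(X)
  Y <- as.matrix(y)
  storage.mode(Y) <- "double"
  n <- nrow(X); t <- ncol(Y)
  stopifnot(nrow(Y) == n)
  if (model == "logistic") {
    stopifnot(all(Y %in% c(0, 1)))
  } else if (is.null(prior$sigma_e2)) {
    stop("linear model requires prior$sigma_e2")
  }
  cols <- seq_len(ncol(X))
  if (!is.null(exclude_chromosome)) {
    if (is.null(chromosome_index)) stop("exclude_chromosome needs chromosome_index")
    drop_cols <- unlist(chromosome_index[as.character(exclude_chromosome)],
                        use.names = FALSE)
    if (is.null(drop_cols)) stop("unknown chromosome: ", exclude_chromosome)
    cols <- setdiff(cols, drop_cols)
  }
  m <- length(cols)
  if (!is.null(seed)) set.seed(seed)
  pc <- .prior_cols(prior, t)
  OFF <- if (is.null(offset)) NULL else {
    o <- as.matrix(offset)
    if (ncol(o) == 1L && t > 1L) o <- o[, rep(1L, t), drop = FALSE]
    stopifnot(nrow(o) == n, ncol(o) == t)
    o
  }
  if (m == 0L) {
    post <- structure(list(psi = matrix(numeric(0), 0, t),
                           mu = matrix(numeric(0), 0, t),
                           s2 = matrix(numeric(0), 0, t),
                           beta_mean = matrix(numeric(0), 0, t),
                           variant_cols = integer(0)),
                      class = "svi_posterior")
    report <- structure(list(elbo_trace = numeric(0), epochs = 0L,
                             converged = TRUE, seed = seed,
                             holdout = integer(0),
                             elapsed = proc.time()[["elapsed"]] - t0),
                        class = "svi_report")
    return(list(posterior = post, report = report))
  }
  Xs <- X[, cols, drop = FALSE]
  # unconstrained parameters
  if (!is.null(init)) {
    ii <- if (nrow(init$psi) == m) seq_len(m) else cols
    tpsi <- stats::qlogis(pmin(pmax(.as_param_matrix(init$psi, nrow(init$psi), t)[ii, , drop = FALSE],
                                    .PSI_EPS), 1 - .PSI_EPS))
    mu <- .as_param_matrix(init$mu, nrow(init$mu), t)[ii, , drop = FALSE]
    tsig <- log(.as_param_matrix(init$s2, nrow(init$s2), t)[ii, , drop = FALSE])
  } else {
    tpsi <- matrix(stats::qlogis(rep(pc$p1, each = m)), m, t)
    mu <- matrix(0, m, t)
    tsig <- matrix(log(rep(pc$s2p, each = m)), m, t)
  }
  holdout <- integer(0)
  if (control$holdout_frac > 0) {
    holdout <- sort(sample(n, max(1L, floor(control$holdout_frac * n))))
  }
  train <- setdiff(seq_len(n), holdout)
  n_train <- length(train)
  bs <- min(control$batch_size, n_train)
  # hoist the training matrices once, stored transposed (variants x
  # samples): minibatch extraction then gathers contiguous columns
  XtT <- t(if (n_train == n) Xs else Xs[train, , drop = FALSE])
  X2tT <- XtT^2
  Yt <- if (n_train == n) Y else Y[train, , drop = FALSE]
  OFFt <- if (is.null(OFF)) NULL else if (n_train == n) OFF else
    OFF[train, , drop = FALSE]
  p1m <- matrix(pc$p1, m, t, byrow = TRUE)
  s2pm <- matrix(pc$s2p, m, t, byrow = TRUE)
  # Adam state (first and second moments per parameter block)
  am1 <- av1 <- am2 <- av2 <- am3 <- av3 <- matrix(0, m, t)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  lr <- control$learning_rate
  trace <- numeric(0)
  n_bad <- 0L
  epochs_run <- 0L
  converged <- FALSE
  eval_seed <- if (is.null(seed)) 0L else seed
  full_elbo <- function(psi, mu_, s2) {
    if (model == "linear") {
      a <- psi * mu_
      s <- psi * s2 + psi * (1 - psi) * mu_^2
      quad <- colSums((Yt - crossprod(XtT, a))^2) + colSums(crossprod(X2tT, s))
      sum(-quad / (2 * pc$se2) - n_train / 2 * log(2 * pi * pc$se2) -
            .kl_total(psi, mu_, s2, p1m, s2pm))
    } else {
      old <- get(".Random.seed", globalenv())
      set.seed(eval_seed + 777L)
      v <- .svi_batch2(XtT, X2tT, Yt, psi, mu_, s2, p1m, s2pm, pc$se2,
                       model, 1, 4L, TRUE, want_grad = FALSE,
                       want_elbo = TRUE, OFFb = OFFt, tX = TRUE)$elbo
      assign(".Random.seed", old, globalenv())
      sum(v)
    }
  }
  for (epoch in seq_len(control$max_epochs)) {
    perm <- if (n_train > bs) sample.int(n_train) else seq_len(n_train)
    starts <- seq(1L, n_train, by = bs)
    for (st in starts) {
      rows <- perm[st:min(st + bs - 1L, n_train)]
      psi <- stats::plogis(tpsi)
      psi <- pmin(pmax(psi, .PSI_EPS), 1 - .PSI_EPS)
      s2 <- exp(tsig)
      g <- .svi_batch2(XtT[, rows, drop = FALSE], X2tT[, rows, drop = FALSE],
                       Yt[rows, , drop = FALSE], psi, mu, s2, p1m, s2pm,
                       pc$se2, model, length(rows) / n_train,
                       control$n_mc_samples, control$antithetic,
                       want_grad = TRUE, want_elbo = FALSE,
                       if (is.null(OFFt)) NULL else OFFt[rows, , drop = FALSE],
                       tX = TRUE)
      # chain rule to unconstrained scales; Adam ascent
      dtpsi <- g$dpsi * psi * (1 - psi)
      dtsig <- g$ds2 * s2
      step <- step + 1L
      c1 <- lr / (1 - b1^step); c2 <- 1 / (1 - b2^step)
      am1 <- b1 * am1 + (1 - b1) * dtpsi
      av1 <- b2 * av1 + (1 - b2) * dtpsi^2
      tpsi <- tpsi + c1 * am1 / (sqrt(c2 * av1) + eps)
      am2 <- b1 * am2 + (1 - b1) * g$dmu
      av2 <- b2 * av2 + (1 - b2) * g$dmu^2
      mu <- mu + c1 * am2 / (sqrt(c2 * av2) + eps)
      am3 <- b1 * am3 + (1 - b1) * dtsig
      av3 <- b2 * av3 + (1 - b2) * dtsig^2
      tsig <- tsig + c1 * am3 / (sqrt(c2 * av3) + eps)
      tpsi <- pmin(pmax(tpsi, stats::qlogis(.PSI_EPS)), stats::qlogis(1 - .PSI_EPS))
      tsig <- pmin(pmax(tsig, -30), 30)
    }
    epochs_run <- epoch
    if (epoch %% control$eval_every != 0L && epoch != control$max_epochs) {
      next
    }
    psi <- pmin(pmax(stats::plogis(tpsi), .PSI_EPS), 1 - .PSI_EPS)
    e <- full_elbo(psi, mu, exp(tsig))
    if (!is.finite(e)) {
      n_bad <- n_bad + 1L
      if (n_bad >= 2L) {
        stop("SVI diverged (non-finite ELBO at epoch ", epoch,
             "); try a smaller learning_rate")
      }
      trace <- c(trace, NA_real_)
      next
    }
    trace <- c(trace, e)
    w <- min(control$patience, length(trace))
    if (epoch >= control$min_epochs && length(trace) > w) {
      recent <- mean(trace[seq(length(trace) - w + 1L, length(trace))])
      prev <- mean(trace[seq(length(trace) - w, length(trace) - 1L)])
      if (abs(recent - prev) < control$tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  psi <- pmin(pmax(stats::plogis(tpsi), .PSI_EPS), 1 - .PSI_EPS)
  post <- svi_posterior(psi, mu, exp(tsig))
  post$variant_cols <- cols
  report <- structure(list(elbo_trace = trace, epochs = epochs_run,
                           converged = converged, seed = seed,
                           holdout = holdout,
                           elapsed = proc.time()[["elapsed"]] - t0),
                      class = "svi_report")
  list(posterior = post, report = report)
}

#' Leave-one-chromosome-out residual phenotypes / null predictions
#'
#' Quantitative model: for each chromosome `c`, `ytilde_c = y - X_{-c}
#' E[beta_{-c}]` using the posterior fitted without chromosome `c`. Binary
#' model: `phat_c = sigmoid(offset + X_{-c} E[beta_{-c}])` with the
#' covariate fixed effects in `offset`, and `W_c = phat_c (1 - phat_c)`.
#' When a whole-genome fit with held-out samples is supplied, the held-out
#' residual-variance ratio (the effective-sample-size gain used in
#' calibration) is estimated per trait.
#'
#' @param X `adjusted_matrix` or matrix of standardized, covariate-adjusted
#'   genotypes over all chromosomes.
#' @param y adjusted phenotype (linear) or 0/1 outcomes (logistic), N x T.
#' @param fits named list: chromosome label -> result of [fit_svi()] run
#'   with that chromosome excluded (or its `posterior`).
#' @param model `"linear"` or `"logistic"`.
#' @param offset logistic covariate offset (N x T or vector).
#' @param wg_fit optional whole-genome [fit_svi()] result whose report
#'   carries held-out rows; used for the residual-variance ratio.
#' @return object of class `loco_residuals`: per-chromosome `ytilde` (or
#'   `phat` and `W`) matrices, `neff_gain` per trait (NULL without a
#'   held-out whole-genome fit), `model`, `chromosomes`.
#' @export
loco_residuals <- function(X, y, fits, model = c("linear", "logistic"),
                           offset = NULL, wg_fit = NULL) {
  model <- match.arg(model)
  chrom_index <- NULL
  if (inherits(X, "adjusted_matrix")) {
    chrom_index <- X$chromosome_index
    X <- X$values
  }
  Y <- as.matrix(y)
  t <- ncol(Y)
  if (!is.null(chrom_index)) {
    missing_fit <- setdiff(names(chrom_index), names(fits))
    if (length(missing_fit)) {
      stop("missing LOCO posterior for chromosome(s): ",
           paste(missing_fit, collapse = ", "))
    }
  }
  OFF <- if (is.null(offset)) matrix(0, nrow(Y), t) else {
    o <- as.matrix(offset)
    if (ncol(o) == 1L && t > 1L) o <- o[, rep(1L, t), drop = FALSE]
    o
  }
  out <- list(model = model, chromosomes = names(fits),
              ytilde = list(), phat = list(), W = list(), neff_gain = NULL)
  for (cc in names(fits)) {
    f <- fits[[cc]]
    post <- if (!is.null(f$posterior)) f$posterior else f
    pred <- if (length(post$variant_cols)) {
      X[, post$variant_cols, drop = FALSE] %*% post$beta_mean
    } else matrix(0, nrow(Y), t)
    if (model == "linear") {
      out$ytilde[[cc]] <- Y - pred
    } else {
      p <- stats::plogis(OFF + pred)
      out$phat[[cc]] <- p
      out$W[[cc]] <- p * (1 - p)
    }
  }
  if (!is.null(wg_fit) && length(wg_fit$report$holdout)) {
    ho <- wg_fit$report$holdout
    post <- wg_fit$posterior
    pred <- X[ho, post$variant_cols, drop = FALSE] %*% post$beta_mean
    if (model == "linear") {
      vy <- apply(Y[ho, , drop = FALSE], 2L, stats::var)
      vr <- apply(Y[ho, , drop = FALSE] - pred, 2L, stats::var)
    } else {
      p0 <- stats::plogis(OFF[ho, , drop = FALSE])
      p1 <- stats::plogis(OFF[ho, , drop = FALSE] + pred)
      vy <- apply(Y[ho, , drop = FALSE] - p0, 2L, stats::var)
      vr <- apply(Y[ho, , drop = FALSE] - p1, 2L, stats::var)
    }
    out$neff_gain <- pmax(vy / vr, 1)
  }
  class(out) <- "loco_residuals"
  out
}
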