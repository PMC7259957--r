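#' Model specification for the spike-and-slab Poisson count model
#'
#' The model for spectral counts y_gct (protein g, block c, condition t):
#'
#'   (y_gct + pseudo_count) ~ Poisson(lambda_gct)
#'   log(lambda_gct) = log(mu_c) + alpha_gc + t * beta_g
#'   alpha_gc ~ N(0, sigma_c^2)
#'   beta_g  ~ pi0 * delta_0 + (1 - pi0) * N(0, tau^2)
#'   pi0 ~ Beta(a, b),  sigma_c^-2, tau^-2 ~ Gamma(shape, rate)
#'
#' with mu_c a fixed plug-in (see [compute_mu_plugin()]). The pseudo count
#' guards against log(0) and makes inference conservative: it shrinks
#' fold-changes toward 1. Default hyperparameters are Beta(0.5, 0.5) on the
#' spike weight and Gamma(1, 1) on both precisions.
#'
#' @param pseudo_count non-negative integer offset added to each count in
#'   the likelihood. Use 0 when fitting counts generated on the shifted
#'   scale (see [simulate_counts()]).
#' @param prior_pi0 length-2 positive vector, Beta(a, b) prior on pi0.
#' @param prior_precision length-2 positive vector, Gamma(shape, rate)
#'   prior on each precision sigma_c^-2 and tau^-2.
#' @param mu per-block plug-in scale; if `NULL`, computed from the data at
#'   fit time.
#' @return object of class `count_model_spec`.
#' @export
count_model_spec <- function(pseudo_count = 1,
                             prior_pi0 = c(0.5, 0.5),
                             prior_precision = c(1, 1),
                             mu = NULL) {
  stopifnot(length(pseudo_count) == 1L, pseudo_count >= 0,
            pseudo_count == round(pseudo_count),
            length(prior_pi0) == 2L, all(prior_pi0 > 0),
            length(prior_precision) == 2L, all(prior_precision > 0))
  if (!is.null(mu) && any(mu <= 0)) stop("mu_c must be strictly positive")
  structure(list(pseudo_count = as.integer(pseudo_count),
                 prior_pi0 = as.numeric(prior_pi0),
                 prior_precision = as.numeric(prior_precision),
                 mu = mu),
            class = "count_model_spec")
}

# log-rates are clamped to this window before exponentiation
LOG_RATE_CLAMP <- 30

clamp_exp <- function(x) exp(pmin(pmax(x, -LOG_RATE_CLAMP), LOG_RATE_CLAMP))

#' Joint Poisson log-likelihood of a model state
#'
#' Sum over all cells of the Poisson log-mass of (y + pseudo_count) at rate
#' lambda_gct = mu_c * exp(alpha_gc + t * beta_g).
#'
#' @param state list with elements `beta` (length p), `alpha` (p x C
#'   matrix); protein/block order must match the sorted order of `table`.
#' @param table a `count_table`.
#' @param spec a `count_model_spec`; its `mu` must be set.
#' @return finite scalar log-likelihood.
#' @export
count_log_likelihood <- function(state, table, spec) {
  a <- count_arrays(table)
  mu <- spec$mu
  if (is.null(mu)) mu <- compute_mu_plugin(table, spec$pseudo_count)
  p <- nrow(a$y0); C <- ncol(a$y0)
  stopifnot(length(state$beta) == p, all(dim(state$alpha) == c(p, C)))
  logmu <- matrix(log(mu), p, C, byrow = TRUE)
  eta0 <- logmu + state$alpha
  eta1 <- eta0 + state$beta
  ll <- sum(stats::dpois(a$y0 + spec$pseudo_count, clamp_exp(eta0), log = TRUE)) +
        sum(stats::dpois(a$y1 + spec$pseudo_count, clamp_exp(eta1), log = TRUE))
  if (!is.finite(ll)) stop("non-finite log-likelihood; check rates")
  ll
}

# --- conjugate updates -------------------------------------------------------

# pi0 | z ~ Beta(a + #spike, b + #slab); tau^-2 | beta ~ Gamma(shape + n_slab/2,
# rate + sum beta^2 / 2); sigma_c^-2 | alpha ~ Gamma(shape + p/2,
# rate + sum_g alpha_gc^2 / 2). Exact closed forms.
gibbs_update_conjugates <- function(z, beta, alpha, spec) {
  n_slab <- sum(z)
  n_spike <- length(z) - n_slab
  pi0 <- stats::rbeta(1, spec$prior_pi0[1] + n_spike, spec$prior_pi0[2] + n_slab)
  sh <- spec$prior_precision[1]; ra <- spec$prior_precision[2]
  tau2 <- 1 / stats::rgamma(1, sh + n_slab / 2,
                            ra + sum(beta[z == 1L]^2) / 2)
  p <- nrow(alpha)
  sigma2 <- 1 / stats::rgamma(ncol(alpha), sh + p / 2,
                              ra + colSums(alpha^2) / 2)
  list(pi0 = pi0, tau2 = tau2, sigma2 = sigma2)
}

# --- beta / z update via deterministic 1-D quadrature ------------------------

# The beta-conditional for protein g depends on the data only through
#   A_g = sum_c (y_gc1 + pseudo),  B_g = sum_c mu_c exp(alpha_gc),
# giving log L(beta) = A_g beta - B_g exp(beta) + const. The slab marginal
# int L(beta) N(beta; 0, tau2) dbeta is computed on a per-protein grid
# spanning +/- half_width * max(tau, 1) around 0 and the likelihood mode
# log(A/B); beta | z = 1 is drawn from the gridded conditional by
# inverse CDF with within-bin jitter.
update_beta_and_z <- function(A, B, tau2, pi0, n_grid = 401L, half_width = 8) {
  p <- length(A)
  tau <- sqrt(tau2)
  s <- half_width * max(tau, 1)
  mode <- log(pmax(A, 0.5) / B)          # likelihood mode; A=0 handled by floor
  lo <- pmin(0, mode) - s
  hi <- pmax(0, mode) + s
  step <- (hi - lo) / (n_grid - 1L)
  grid <- lo + outer(step, 0:(n_grid - 1L))         # p x n_grid
  for (attempt in 1:2) {
    logint <- A * grid - B * clamp_exp(grid) - grid^2 / (2 * tau2)
    m <- logint[cbind(seq_len(p), max.col(logint, ties.method = "first"))]
    w <- exp(logint - m)
    sw <- rowSums(w)
    # mass at the grid edges must be negligible or the grid is widened once
    edge_bad <- (w[, 1L] + w[, n_grid]) / sw > 1e-6
    if (!any(edge_bad) || attempt == 2L) break
    lo[edge_bad] <- lo[edge_bad] - 2 * s
    hi[edge_bad] <- hi[edge_bad] + 2 * s
    step <- (hi - lo) / (n_grid - 1L)
    grid <- lo + outer(step, 0:(n_grid - 1L))
  }
  if (any(edge_bad)) {
    stop("slab quadrature failed to bracket the integrand for protein(s) ",
         paste(utils::head(which(edge_bad), 5L), collapse = ", "))
  }
  log_slab_marg <- m + log(sw) + log(step) - 0.5 * log(2 * pi * tau2)
  log_spike <- -B                          # log L(0) up to the shared constant
  logit_slab <- log1p(-pi0) - log(pi0) + log_slab_marg - log_spike
  prob_slab <- stats::plogis(logit_slab)
  z <- as.integer(stats::runif(p) < prob_slab)
  beta <- numeric(p)
  idx <- which(z == 1L)
  if (length(idx) > 0L) {
    u <- stats::runif(length(idx))
    jit <- (stats::runif(length(idx)) - 0.5) * step[idx]
    for (k in seq_along(idx)) {
      i <- idx[k]
      cdf <- cumsum(w[i, ])
      j <- findInterval(u[k] * cdf[n_grid], cdf) + 1L
      beta[i] <- grid[i, min(j, n_grid)] + jit[k]
    }
  }
  list(z = z, beta = beta, prob_slab = prob_slab)
}

# Brute-force oracle for the slab probability of a single protein: very fine
# trapezoid integration over a wide window. Used only by tests.
slab_prob_bruteforce <- function(A, B, tau2, pi0, n = 200001L, width = 60) {
  f <- function(b) A * b - B * exp(b) - b^2 / (2 * tau2)
  mode <- log(max(A, 0.5) / B)
  g <- seq(min(0, mode) - width, max(0, mode) + width, length.out = n)
  lf <- f(g)
  m <- max(lf)
  marg <- (sum(exp(lf - m)) - 0.5 * (exp(lf[1] - m) + exp(lf[n] - m))) *
    (g[2] - g[1])
  log_slab <- m + log(marg) - 0.5 * log(2 * pi * tau2)
  stats::plogis(log(1 - pi0) - log(pi0) + log_slab - (-B))
}

# --- alpha update: adaptive random-walk Metropolis ---------------------------

# Targets, for each cell (g, c):
#   (y0 + y1 + 2 pseudo) * alpha - mu_c (1 + exp(beta_g)) exp(alpha)
#   - alpha^2 / (2 sigma_c^2).
# One simultaneous vectorized proposal per sweep; per-block step sizes are
# adapted toward ~40% acceptance during burn-in only.
update_alpha <- function(alpha, S, Bfac, sigma2, step) {
  p <- nrow(alpha); C <- ncol(alpha)
  stepm <- matrix(step, p, C, byrow = TRUE)
  prop <- alpha + stepm * matrix(stats::rnorm(p * C), p, C)
  s2 <- matrix(sigma2, p, C, byrow = TRUE)
  dlog <- S * (prop - alpha) - Bfac * (clamp_exp(prop) - clamp_exp(alpha)) -
    (prop^2 - alpha^2) / (2 * s2)
  acc <- matrix(log(stats::runif(p * C)), p, C) < dlog
  alpha[acc] <- prop[acc]
  list(alpha = alpha, acc_rate = colMeans(acc))
}

#' Fit the spike-and-slab count model by MCMC
#'
#' Metropolis-within-Gibbs sampler: exact conjugate draws for (pi0, tau^2,
#' sigma_c^2), exact gridded Gibbs for each (z_g, beta_g) via deterministic
#' 1-D quadrature of the slab marginal, and adaptive random-walk Metropolis
#' for the alpha_gc random effects (step adapted during burn-in only, then
#' frozen).
#'
#' @param table a `count_table`.
#' @param spec a `count_model_spec`.
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded (must be < n_iter).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; the run is deterministic given the seed.
#' @param n_grid,half_width quadrature grid for the beta update: `n_grid`
#'   nodes spanning `half_width * max(tau, 1)` beyond 0 and the likelihood
#'   mode.
#' @return object of class `count_posterior`: matrices `beta`, `z`
#'   (draws x p), `sigma2` (draws x C), vectors `pi0`, `tau2`, acceptance
#'   rates, and run metadata.
#' @export
fit_count_model <- function(table, spec = count_model_spec(),
                            n_iter = 4000, burn_in = 2000, thin = 1,
                            seed = 1L, n_grid = 401L, half_width = 8) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  set.seed(seed)
  a <- count_arrays(table)
  p <- nrow(a$y0); C <- ncol(a$y0)
  mu <- spec$mu
  if (is.null(mu)) mu <- compute_mu_plugin(table, spec$pseudo_count)
  if (length(mu) == 1L) mu <- rep(mu, C)
  stopifnot(length(mu) == C)

  ps <- spec$pseudo_count
  S <- a$y0 + a$y1 + 2 * ps                       # alpha sufficient stat
  A_base <- rowSums(a$y1 + ps)                    # beta sufficient stat

  # initial state
  alpha <- matrix(0, p, C)
  beta <- numeric(p); z <- integer(p)
  pi0 <- 0.5; tau2 <- 1; sigma2 <- rep(1, C)
  step <- rep(0.5, C)

  n_keep <- floor((n_iter - burn_in) / thin)
  draws_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, a$proteins))
  draws_z <- matrix(NA_integer_, n_keep, p, dimnames = list(NULL, a$proteins))
  draws_pi0 <- numeric(n_keep); draws_tau2 <- numeric(n_keep)
  draws_sigma2 <- matrix(NA_real_, n_keep, C, dimnames = list(NULL, a$blocks))
  acc_sum <- rep(0, C)
  mum <- matrix(mu, p, C, byrow = TRUE)
  kept <- 0L

  for (it in seq_len(n_iter)) {
    Bfac <- mum * (1 + clamp_exp(beta))           # p x C factor on exp(alpha)
    au <- update_alpha(alpha, S, Bfac, sigma2, step)
    alpha <- au$alpha
    if (it <= burn_in) {
      step <- step * exp(0.05 * (au$acc_rate - 0.4))
      step <- pmin(pmax(step, 1e-3), 10)
    } else {
      acc_sum <- acc_sum + au$acc_rate
    }

    B <- rowSums(mum * clamp_exp(alpha))          # bait-side rate at beta = 0
    bz <- update_beta_and_z(A_base, B, tau2, pi0, n_grid, half_width)
    z <- bz$z; beta <- bz$beta

    cj <- gibbs_update_conjugates(z, beta, alpha, spec)
    pi0 <- cj$pi0; tau2 <- cj$tau2; sigma2 <- cj$sigma2
    if (!all(is.finite(c(beta, alpha, pi0, tau2, sigma2)))) {
      stop("non-finite sampler state at iteration ", it)
    }

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws_beta[kept, ] <- beta
      draws_z[kept, ] <- z
      draws_pi0[kept] <- pi0
      draws_tau2[kept] <- tau2
      draws_sigma2[kept, ] <- sigma2
    }
  }

  structure(list(beta = draws_beta, z = draws_z, pi0 = draws_pi0,
                 tau2 = draws_tau2, sigma2 = draws_sigma2,
                 mu = mu, alpha_acc_rate = acc_sum / (n_iter - burn_in),
                 alpha_step = step,
                 seed = seed, n_iter = n_iter, burn_in = burn_in, thin = thin,
                 proteins = a$proteins, blocks = a$blocks),
            class = "count_posterior")
}

#' Local false sign rates and enrichment selection
#'
#' For each protein, lfsr_g = P(beta_g <= 0 | data), estimated as the
#' fraction of posterior draws with beta_g <= 0 (spike draws, beta_g = 0,
#' count toward the event). Proteins with lfsr at or below the threshold
#' are selected as enriched; the global false sign rate of the selected set
#' is estimated by the mean lfsr among selections.
#'
#' @param draws a `count_posterior`.
#' @param threshold selection cutoff on lfsr (default 0.2).
#' @return object of class `enrichment_result`: data.frame with
#'   `protein_id`, `post_mean_beta`, `post_prob_slab`, `lfsr`, `selected`,
#'   plus attribute `global_fsr`.
#' @export
compute_lfsr <- function(draws, threshold = 0.2) {
  stopifnot(inherits(draws, "count_posterior"))
  if (nrow(draws$beta) < 1L) stop("no posterior draws")
  lfsr <- colMeans(draws$beta <= 0)
  res <- data.frame(protein_id = draws$proteins,
                    post_mean_beta = colMeans(draws$beta),
                    post_prob_slab = colMeans(draws$z),
                    lfsr = lfsr,
                    selected = lfsr <= threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  global <- if (any(res$selected)) mean(res$lfsr[res$selected]) else NA_real_
  structure(res, class = c("enrichment_result", "data.frame"),
            threshold = threshold, global_fsr = global)
}

#' Write enrichment results and a run summary
#'
#' Writes `enrichment.tsv` (fixed column order) and `run_summary.json`
#' (seed, iterations, acceptance rates, estimated global false sign rate)
#' into `out_dir`. Deterministic: identical inputs give byte-identical
#' files.
#'
#' @param result an `enrichment_result`.
#' @param draws the `count_posterior` it came from.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_enrichment <- function(result, draws, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(out_dir, "enrichment.tsv")
  out <- as.data.frame(result)
  out$post_mean_beta <- formatC(out$post_mean_beta, format = "g", digits = 8)
  out$lfsr <- formatC(out$lfsr, format = "g", digits = 8)
  out$post_prob_slab <- formatC(out$post_prob_slab, format = "g", digits = 8)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("ercal")),
    seed = draws$seed, n_iter = draws$n_iter, burn_in = draws$burn_in,
    thin = draws$thin, lfsr_threshold = attr(result, "threshold"),
    n_selected = sum(result$selected),
    global_false_sign_rate = attr(result, "global_fsr"),
    alpha_acceptance = as.list(stats::setNames(round(draws$alpha_acc_rate, 4),
                                               draws$blocks))),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
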