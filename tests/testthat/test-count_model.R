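test_that("log-likelihood matches a brute-force Poisson evaluation", {
  set.seed(41)
  y0 <- matrix(rpois(8, 4), 4, 2)
  y1 <- matrix(rpois(8, 6), 4, 2)
  tab <- make_count_table(y0, y1)
  mu <- compute_mu_plugin(tab)
  state <- list(beta = rnorm(4, 0, 0.5),
                alpha = matrix(rnorm(8, 0, 0.3), 4, 2))
  spec <- count_model_spec(mu = mu)
  expect_equal(count_log_likelihood(state, tab, spec),
               loglik_bruteforce(y0, y1, mu, state$alpha, state$beta, 1),
               tolerance = 1e-12)

  # single cell with y = 0, lambda = 1: Poisson mass at 0+1 is exp(-1)
  tab1 <- make_count_table(y0 = cbind(c(0, 0)), y1 = cbind(c(0, 0)))
  spec1 <- count_model_spec(mu = 1)
  st0 <- list(beta = c(0, 0), alpha = matrix(0, 2, 1))
  expect_equal(count_log_likelihood(st0, tab1, spec1), 4 * (-1))

  # with all beta = 0 the likelihood is invariant to swapping conditions
  tab_sw <- make_count_table(y1, y0)
  expect_equal(count_log_likelihood(st0wrap <- list(beta = rep(0, 4),
                                                    alpha = state$alpha),
                                    tab, spec),
               count_log_likelihood(st0wrap, tab_sw, spec))
})

test_that("conjugate updates reproduce their closed-form moments", {
  set.seed(42)
  p <- 12; C <- 2
  z <- c(rep(1L, 4), rep(0L, 8))
  beta <- c(rnorm(4, 0, 1.5), rep(0, 8))
  alpha <- matrix(rnorm(p * C, 0, 0.7), p, C)
  spec <- count_model_spec()
  n <- 2e4
  draws <- replicate(n, ercal:::gibbs_update_conjugates(z, beta, alpha, spec),
                     simplify = FALSE)
  pi0s <- vapply(draws, `[[`, 0, "pi0")
  prec_tau <- 1 / vapply(draws, `[[`, 0, "tau2")
  prec_sig <- t(vapply(draws, function(d) 1 / d$sigma2, numeric(C)))

  # pi0 | z ~ Beta(0.5 + 8, 0.5 + 4)
  m_pi0 <- (0.5 + 8) / (0.5 + 8 + 0.5 + 4)
  expect_lt(abs(mean(pi0s) - m_pi0), 3 * sd(pi0s) / sqrt(n))

  # tau^-2 ~ Gamma(1 + 2, 1 + sum(beta_slab^2)/2)
  sh <- 1 + sum(z) / 2; ra <- 1 + sum(beta[z == 1]^2) / 2
  expect_lt(abs(mean(prec_tau) - sh / ra), 3 * sd(prec_tau) / sqrt(n))

  # sigma_c^-2 ~ Gamma(1 + p/2, 1 + sum_g alpha_gc^2/2), per block
  for (c in 1:C) {
    shc <- 1 + p / 2; rac <- 1 + sum(alpha[, c]^2) / 2
    expect_lt(abs(mean(prec_sig[, c]) - shc / rac),
              3 * sd(prec_sig[, c]) / sqrt(n))
  }

  # single slab protein with beta = 2: tau^-2 | . = Gamma(1.5, 3), mean 0.5
  d2 <- replicate(n, 1 / ercal:::gibbs_update_conjugates(
    1L, 2, matrix(0, 1, 1), spec)$tau2)
  expect_lt(abs(mean(d2) - 0.5), 3 * sd(d2) / sqrt(n))

  # empty slab: pi0 ~ Beta(0.5 + p, 0.5)
  d0 <- replicate(n, ercal:::gibbs_update_conjugates(
    rep(0L, p), rep(0, p), alpha, spec)$pi0)
  expect_lt(abs(mean(d0) - (0.5 + p) / (1 + p)), 3 * sd(d0) / sqrt(n))
})

test_that("slab probability from the gridded update matches fine-grid integration", {
  set.seed(7)
  worst <- 0
  for (i in 1:50) {
    A <- rpois(1, 25)
    B <- runif(1, 0.5, 50)
    tau2 <- runif(1, 0.05, 6)
    pi0 <- runif(1, 0.05, 0.95)
    grid_p <- ercal:::update_beta_and_z(A, B, tau2, pi0)$prob_slab
    oracle <- ercal:::slab_prob_bruteforce(A, B, tau2, pi0)
    worst <- max(worst, abs(grid_p - oracle))
  }
  expect_lt(worst, 1e-4)
})

test_that("spike dominates for balanced counts and collapses the slab as tau -> 0", {
  # identical counts in both conditions, pi0 near 1: slab probability -> 0
  p1 <- ercal:::update_beta_and_z(A = 20, B = 20, tau2 = 1, pi0 = 0.999)
  expect_lt(p1$prob_slab, 0.05)
  # degenerate slab: sampled beta pinned near 0 whatever z is
  set.seed(1)
  bz <- ercal:::update_beta_and_z(A = 40, B = 10, tau2 = 1e-8, pi0 = 0.5)
  expect_lt(abs(bz$beta), 1e-3)
})

test_that("alpha Metropolis kernel targets the exact conditional density", {
  # scalar cell: y0 = 7, y1 = 9, mu = 3, beta = 0.4, sigma2 = 0.5, pseudo 1
  y0 <- 7; y1 <- 9; mu <- 3; beta <- 0.4; sigma2 <- 0.5; ps <- 1
  S <- matrix(y0 + y1 + 2 * ps, 1, 1)
  Bfac <- matrix(mu * (1 + exp(beta)), 1, 1)
  set.seed(5)
  n_sweep <- 1e5; thin <- 10; burn <- 2000
  alpha <- matrix(0, 1, 1)
  kept <- numeric((n_sweep - burn) / thin)
  k <- 0
  for (i in seq_len(n_sweep)) {
    alpha <- ercal:::update_alpha(alpha, S, Bfac, sigma2, step = 0.6)$alpha
    if (i > burn && (i - burn) %% thin == 0) {
      k <- k + 1; kept[k] <- alpha[1, 1]
    }
  }
  # gridded conditional CDF as oracle
  g <- seq(-3, 3, length.out = 4001)
  logd <- S[1] * g - Bfac[1] * exp(g) - g^2 / (2 * sigma2)
  d <- exp(logd - max(logd)); cdf <- cumsum(d) / sum(d)
  ks <- max(abs(ecdf(kept)(g) - cdf))
  expect_lt(ks, 0.02)

  # prior domination: sigma2 -> 0 pins alpha at 0
  set.seed(6)
  a2 <- matrix(0.3, 1, 1)
  for (i in 1:2000) {
    a2 <- ercal:::update_alpha(a2, S, Bfac, sigma2 = 1e-6, step = 0.01)$alpha
  }
  expect_lt(abs(a2[1, 1]), 0.01)

  # large balanced counts, beta = 0: alpha concentrates at log((y+1)/mu)
  yb <- 2000
  Sb <- matrix(2 * (yb + 1), 1, 1); Bb <- matrix(2 * mu, 1, 1)
  set.seed(8)
  ab <- matrix(0, 1, 1)
  vals <- numeric(4000)
  for (i in 1:4000) {
    ab <- ercal:::update_alpha(ab, Sb, Bb, sigma2 = 10, step = 0.05)$alpha
    vals[i] <- ab[1, 1]
  }
  expect_equal(mean(vals[-(1:1000)]), log((yb + 1) / mu), tolerance = 0.02)
})

test_that("MCMC is deterministic given the seed and recovers simulated effects", {
  sim <- simulate_counts(count_sim_config(p = 100, C = 3, pi0 = 0.7,
                                          tau = 1.2, sigma = 0.5,
                                          mu = c(3, 3, 3)), seed = 11)
  spec <- count_model_spec(pseudo_count = 0)
  f1 <- fit_count_model(sim$table, spec, n_iter = 800, burn_in = 300,
                        seed = 2)
  f2 <- fit_count_model(sim$table, spec, n_iter = 800, burn_in = 300,
                        seed = 2)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$pi0, f2$pi0)
  expect_equal(nrow(f1$beta), 500)

  res <- compute_lfsr(f1)
  expect_gt(cor(res$post_mean_beta, sim$truth$beta), 0.8)
  # acceptance rate adapted into the targeted band
  expect_true(all(f1$alpha_acc_rate > 0.2 & f1$alpha_acc_rate < 0.6))
})

test_that("null data pull the posterior spike weight above one half", {
  sim <- simulate_counts(count_sim_config(p = 80, C = 3, pi0 = 1,
                                          tau = 1, sigma = 0.5,
                                          mu = c(3, 3, 3)), seed = 21)
  expect_true(all(sim$truth$beta == 0))
  fit <- fit_count_model(sim$table, count_model_spec(pseudo_count = 0),
                         n_iter = 800, burn_in = 300, seed = 3)
  expect_gt(mean(fit$pi0), 0.5)
})

test_that("lfsr counts non-positive draws and selects at the threshold", {
  fake <- structure(list(beta = cbind(g1 = c(-1, 0, 2, 3),
                                      g2 = c(1, 2, 3, 4),
                                      g3 = c(0, 0, 0, 0)),
                         z = cbind(g1 = c(0L, 0L, 1L, 1L),
                                   g2 = c(1L, 1L, 1L, 1L),
                                   g3 = c(0L, 0L, 0L, 0L)),
                         proteins = c("g1", "g2", "g3")),
                    class = "count_posterior")
  res <- compute_lfsr(fake, threshold = 0.5)
  expect_equal(res$lfsr, c(0.5, 0, 1))
  # lfsr equal to the threshold is selected (<=)
  expect_equal(res$selected, c(TRUE, TRUE, FALSE))
  expect_equal(attr(res, "global_fsr"), mean(c(0.5, 0)))
  expect_error(compute_lfsr(structure(list(beta = matrix(0, 0, 1),
                                           proteins = "g"),
                                      class = "count_posterior")),
               "no posterior draws")
})

test_that("mean lfsr decreases with true enrichment strength", {
  # five-protein tables; the target protein's bait counts are scaled
  base <- 6
  scales <- c(1, 2, 4)
  n_rep <- 60
  mean_lfsr <- sapply(seq_along(scales), function(si) {
    lf <- numeric(n_rep)
    for (r in 1:n_rep) {
      set.seed(9000 + 100 * si + r)
      y0 <- matrix(rpois(5, base), 5, 1)
      y1 <- matrix(rpois(5, base), 5, 1)
      y1[1, 1] <- rpois(1, base * scales[si])
      tab <- make_count_table(y0, y1)
      fit <- fit_count_model(tab, count_model_spec(), n_iter = 500,
                             burn_in = 200, seed = 10 + r)
      lf[r] <- compute_lfsr(fit)$lfsr[1]
    }
    mean(lf)
  })
  expect_true(all(diff(mean_lfsr) <= 0))
})

test_that("relabeling blocks leaves per-protein lfsr unchanged up to MC error", {
  sim <- simulate_counts(count_sim_config(p = 30, C = 3, pi0 = 0.6,
                                          tau = 1.2, sigma = 0.5,
                                          mu = c(2.5, 3, 3.5)), seed = 31)
  tab <- sim$table
  spec <- count_model_spec(pseudo_count = 0)
  f_orig <- fit_count_model(tab, spec, n_iter = 3000, burn_in = 1000,
                            seed = 4)
  swapped <- as.data.frame(tab)
  swapped$block_id <- c(cow1 = "cow3", cow2 = "cow2",
                        cow3 = "cow1")[swapped$block_id]
  f_swap <- fit_count_model(count_table(swapped), spec, n_iter = 3000,
                            burn_in = 1000, seed = 4)
  lf1 <- compute_lfsr(f_orig)$lfsr
  lf2 <- compute_lfsr(f_swap)$lfsr
  expect_lt(max(abs(lf1 - lf2)), 0.08)
  # and the swapped blocks carry their variances with them
  expect_equal(unname(colMeans(f_orig$sigma2)),
               unname(rev(colMeans(f_swap$sigma2))), tolerance = 0.25)
})

test_that("enrichment output files are deterministic and complete", {
  sim <- simulate_counts(count_sim_config(p = 20, C = 2, pi0 = 0.8, tau = 1,
                                          sigma = 0.5, mu = c(3, 3)),
                         seed = 51)
  fit <- fit_count_model(sim$table, count_model_spec(pseudo_count = 0),
                         n_iter = 300, burn_in = 100, seed = 5)
  res <- compute_lfsr(fit)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_enrichment(res, fit, d1)
  write_enrichment(res, fit, d2)
  f1 <- file.path(d1, "enrichment.tsv"); f2 <- file.path(d2, "enrichment.tsv")
  expect_identical(readLines(f1), readLines(f2))
  out <- read.delim(f1)
  expect_equal(names(out), c("protein_id", "post_mean_beta",
                             "post_prob_slab", "lfsr", "selected"))
  expect_equal(nrow(out), 20)
  js <- jsonlite::read_json(file.path(d1, "run_summary.json"))
  expect_equal(js$seed, 5)
})
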