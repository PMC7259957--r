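test_that("noise-free records are idealized exactly", {
  fs <- 5000
  # alternating square wave: 10 ms open / 30 ms closed, 10 cycles
  one_cycle <- c(rep(5, 0.010 * fs), rep(0, 0.030 * fs))
  tr <- current_trace(rep(one_cycle, 10), fs, 1000,
                      closed_level_pA = 0, open_increment_pA = 5)
  id <- idealize(tr)
  expect_equal(id$events$level, rep(c(1L, 0L), 10))
  expect_equal(id$events$duration_s, rep(c(0.010, 0.030), 10))
  expect_equal(sum(id$events$duration_s), length(tr$current_pA) / fs)
  dw <- dwell_times(id)
  expect_equal(dw$mean_open_s, 0.010)
  expect_equal(dw$mean_closed_s, 0.030)

  # constant closed trace: one level-0 event spanning the record
  tr0 <- current_trace(rep(0, fs), fs, 1000, closed_level_pA = 0,
                       open_increment_pA = 5)
  id0 <- idealize(tr0)
  expect_equal(nrow(id0$events), 1L)
  expect_equal(id0$events$level, 0L)
  expect_equal(id0$events$duration_s, 1)
  expect_equal(open_probability(id0, 1), 0)
})

test_that("idealization refuses traces without level separation", {
  set.seed(2)
  tr <- current_trace(rnorm(5000, 0, 2), 5000, 1000,
                      closed_level_pA = 0, open_increment_pA = 5)
  expect_error(idealize(tr), "insufficient separation")
})

test_that("idealization recovers super-dead-time events from noisy traces", {
  cfg <- gating_sim_config(duration_s = 30)
  tr <- simulate_trace(cfg, seed = 14)
  id <- idealize(tr)
  lev <- ideal_levels(id)
  ev <- tr$true_events[[1]]
  dur <- ev$t_end - ev$t_start
  keep <- dur > 3 * id$dead_time_s
  mid <- (ev$t_start + ev$t_end)[keep] / 2
  idx <- pmin(floor(mid * tr$sampling_rate_hz) + 1, length(lev))
  recovered <- mean(lev[idx] == ev$state[keep])
  expect_gte(recovered, 0.99)
})

test_that("open probability follows the occupancy-time definition", {
  # single channel open 65% of the time
  id <- make_ideal(c(1, 0), c(6.5, 3.5))
  expect_equal(open_probability(id, 1), 0.65)
  # multichannel normalization
  id2 <- make_ideal(c(2, 1, 0), c(1, 2, 7))
  expect_equal(open_probability(id2, 2), (2 * 1 + 1 * 2) / (2 * 10))
  expect_error(open_probability(id2, 1), "below the maximum observed level")
  # two simulated channels at true P_o 0.3
  tr <- simulate_trace(gating_sim_config(n_channels = 2, p_open = 0.3,
                                         duration_s = 60), seed = 9)
  expect_equal(open_probability(idealize(tr), 2), 0.3, tolerance = 0.05)
})

test_that("P_o error shrinks with record length at the MC rate", {
  est_err <- function(dur, seeds) {
    sapply(seeds, function(s) {
      tr <- simulate_trace(gating_sim_config(duration_s = dur), seed = s)
      open_probability(idealize(tr), 1) - 0.65
    })
  }
  e_short <- est_err(10, 1:12)
  e_long <- est_err(40, 1:12)
  # quadrupling the duration should roughly halve the RMS error
  ratio <- sqrt(mean(e_long^2)) / sqrt(mean(e_short^2))
  expect_lt(ratio, 0.85)
})

test_that("dwell-time means match exponential sojourn theory away from the dead time", {
  cfg <- gating_sim_config(p_open = 0.5, mean_open_s = 0.020,
                           duration_s = 60)
  tr <- simulate_trace(cfg, seed = 33)
  dw <- dwell_times(idealize(tr))
  se_open <- 0.020 / sqrt(dw$n_open)
  se_closed <- 0.020 / sqrt(dw$n_closed)
  expect_lt(abs(dw$mean_open_s - 0.020), 3 * se_open)
  expect_lt(abs(dw$mean_closed_s - 0.020), 3 * se_closed)

  # a dead time longer than every closed gap merges the record into one opening
  id <- idealize(tr, dead_time_s = 10)
  expect_lte(nrow(id$events), 3L)
  expect_error(dwell_times(make_ideal(1, 1)), "no complete sojourns")
})

test_that("channel-count confidence behaves at its extremes", {
  expect_equal(channel_count_confidence(make_ideal(0, 10)), 0)
  # near-saturated single channel: a second channel would be seen at once
  id_hi <- make_ideal(rep(c(1, 0), 50), rep(c(0.098, 0.002), 50))
  expect_gt(channel_count_confidence(id_hi, 1), 0.999)
  # few openings, low P_o: no confidence in the count
  id_lo <- make_ideal(c(0, 1, 0), c(5, 0.01, 5))
  expect_lt(channel_count_confidence(id_lo, 1), 0.5)
})

test_that("accepted traces undercount the channel number in under 1% of cases", {
  # records long enough for the confidence rule to resolve N+1 vs N
  for (N in 1:3) {
    accepted <- 0; undercount <- 0
    for (s in 1:40) {
      tr <- simulate_trace(gating_sim_config(n_channels = N, p_open = 0.4,
                                             duration_s = 8),
                           seed = 400 * N + s)
      id <- idealize(tr)
      if (max(id$events$level) == 0) next
      conf <- channel_count_confidence(id)
      if (conf > 0.99) {
        accepted <- accepted + 1
        if (max(id$events$level) < N) undercount <- undercount + 1
      }
    }
    expect_gt(accepted, 0)
    expect_lte(undercount / max(accepted, 1), 0.01)
  }
  # a too-short multichannel record is rejected, not misclassified
  tr_short <- simulate_trace(gating_sim_config(n_channels = 3, p_open = 0.25,
                                               duration_s = 2), seed = 77)
  expect_lt(channel_count_confidence(idealize(tr_short)), 0.99)
})

test_that("level occupancy of multichannel patches is binomial", {
  for (N in 2:3) {
    tr <- simulate_trace(gating_sim_config(n_channels = N, p_open = 0.3,
                                           duration_s = 120),
                         seed = 70 + N)
    id <- idealize(tr)
    ev <- id$events
    obs <- vapply(0:N, function(k) {
      sum(ev$duration_s[ev$level == k])
    }, 0) / sum(ev$duration_s)
    po_hat <- open_probability(id, N)
    expected <- dbinom(0:N, N, po_hat)
    # effective looks: one per gating cycle
    n_eff <- nrow(ev) / 2
    X2 <- n_eff * sum((obs - expected)^2 / expected)
    expect_lt(X2, qchisq(0.99, df = N))
  }
})

test_that("ramp fits recover conductance and match the normal equations", {
  fs <- 5000
  n <- 2 * fs   # 2 s ramp, -50 to 50 mV
  v <- seq(-50, 50, length.out = n)
  gamma <- 0.5  # nS, so i = 0.5 pA/mV * V
  level <- rep(rep(c(0L, 1L), each = 250), length.out = n)
  i_pA <- level * gamma * v + 0.02 * v + 1   # ohmic channel + linear leak
  tr <- current_trace(i_pA, fs, 1000, ramp = list(start_mV = -50,
                                                  end_mV = 50,
                                                  duration_s = 2))
  fit <- iv_ramp_fit(tr, order = 1, level = level)
  expect_equal(fit$conductance_nS, gamma, tolerance = 1e-8)

  # 4th-order fit agrees with a direct normal-equations solve
  i_nl <- level * (gamma * v + 2e-5 * v^3 - 3e-8 * v^4)
  tr2 <- current_trace(i_nl, fs, 1000, ramp = tr$ramp)
  fit4 <- iv_ramp_fit(tr2, order = 4, level = level)
  open <- level >= 1
  X <- outer(v[open], 0:4, `^`)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% i_nl[open])
  expect_equal(fit4$coefficients, as.numeric(beta_oracle), tolerance = 1e-6)
  expect_equal(fit4$conductance_nS, gamma, tolerance = 1e-6)

  # zero current: all coefficients vanish
  tr0 <- current_trace(rep(0, n), fs, 1000, ramp = tr$ramp)
  fit0 <- iv_ramp_fit(tr0, order = 1, level = level)
  expect_equal(fit0$coefficients, c(0, 0), tolerance = 1e-12)

  expect_error(iv_ramp_fit(current_trace(i_pA, fs, 1000), order = 1,
                           level = level), "no ramp")
  expect_error(iv_ramp_fit(tr, order = 4, level = rep(c(0L, 1L, 0L, 0L),
                                                      c(1, 3, n - 8, 4))),
               "fewer open-channel points")
})

test_that("normalized P_o and percent reduction follow the definitions", {
  po <- c(0.6, 0.6, 0.6, 0.06, 0.06, 0.06)
  grp <- rep(c("ctrl", "treated"), each = 3)
  out <- normalize_po(po, grp, "ctrl")
  sm <- out$summary
  expect_equal(sm$normalized_mean[sm$group == "ctrl"], 1)
  expect_equal(sm$percent_reduction[sm$group == "ctrl"], 0)
  expect_equal(sm$normalized_mean[sm$group == "treated"], 0.1)
  expect_equal(sm$percent_reduction[sm$group == "treated"], 90)
  expect_error(normalize_po(po, grp, "absent"), "empty")
  expect_error(normalize_po(rep(0, 3), rep("a", 3), "a"), "positive")
})

test_that("gating statistics bundle is consistent", {
  tr <- simulate_trace(gating_sim_config(duration_s = 20), seed = 3)
  gs <- gating_stats(idealize(tr))
  expect_equal(gs$n_a, 1L)
  expect_gt(gs$confidence, 0.99)
  expect_equal(gs$p_o, 0.65, tolerance = 0.05)
  expect_gt(gs$mean_open_s, 0)
})
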