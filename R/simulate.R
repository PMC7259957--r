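#' Configuration for the spectral-count generator
#'
#' Defaults follow the scale of the affinity-enrichment experiment the
#' count model was built for: p = 486 proteins pulled down from bovine
#' hepatocyte ER-luminal extract in C = 3 blocks (individual animals),
#' with sparse positive binding effects. Effect and nuisance magnitudes
#' (pi0 = 0.95, tau = 1, sigma_c = 0.6, lognormal mu_c around 3) are the
#' package's documented choices for a realistic sparse-enrichment regime.
#'
#' @param p number of proteins (>= 2).
#' @param C number of blocks (>= 1).
#' @param pi0 spike weight: probability a protein has no binding effect.
#' @param tau slab standard deviation of the log fold-change beta_g.
#' @param sigma per-block standard deviation(s) of the alpha_gc random
#'   effects; recycled to length C.
#' @param mu per-block baseline scale(s); `NULL` draws them from a
#'   lognormal centered at 3 (sdlog 0.2).
#' @return list of class `count_sim_config`.
#' @export
count_sim_config <- function(p = 486, C = 3, pi0 = 0.95, tau = 1.0,
                             sigma = 0.6, mu = NULL) {
  stopifnot(p >= 2, C >= 1, pi0 >= 0, pi0 <= 1, tau > 0, all(sigma > 0))
  structure(list(p = as.integer(p), C = as.integer(C), pi0 = pi0, tau = tau,
                 sigma = rep_len(sigma, C), mu = mu),
            class = "count_sim_config")
}

#' Simulate spectral-count tables from the generative model
#'
#' Draws z_g ~ Bernoulli(1 - pi0), beta_g = z_g * N(0, tau^2),
#' alpha_gc ~ N(0, sigma_c^2), then rates
#' lambda_gct = mu_c * exp(alpha_gc + t * beta_g). In `shifted` mode the
#' emitted counts are u ~ Poisson(lambda) directly — exactly the law the
#' count model assumes for (y + 1) — so a fit with `pseudo_count = 0`
#' treats the generative model and the fitted model as identical (required
#' for calibration studies). Otherwise raw counts are emulated as
#' y = max(Poisson(lambda) - 1, 0).
#'
#' @param config a `count_sim_config`.
#' @param seed integer seed.
#' @param shifted emit shifted-scale counts (default `TRUE`).
#' @return list with `table` (a [count_table()]) and `truth` (z, beta,
#'   alpha, mu, config, seed).
#' @export
simulate_counts <- function(config = count_sim_config(), seed = 1L,
                            shifted = TRUE) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(seed)
  p <- config$p; C <- config$C
  mu <- config$mu
  if (is.null(mu)) mu <- stats::rlnorm(C, log(3), 0.2)
  mu <- rep_len(mu, C)
  z <- as.integer(stats::runif(p) < 1 - config$pi0)
  beta <- z * stats::rnorm(p, 0, config$tau)
  alpha <- matrix(stats::rnorm(p * C, 0, rep(config$sigma, each = p)), p, C)
  proteins <- sprintf("P%04d", seq_len(p))
  blocks <- sprintf("cow%d", seq_len(C))
  mum <- matrix(mu, p, C, byrow = TRUE)
  # same +/-30 log-rate clamp as the fitted likelihood, so the generative
  # and fitted models agree even for extreme prior draws
  lam0 <- clamp_exp(log(mum) + alpha)
  lam1 <- clamp_exp(log(mum) + alpha + beta)
  u0 <- matrix(rpois_safe(p * C, lam0), p, C)
  u1 <- matrix(rpois_safe(p * C, lam1), p, C)
  if (!shifted) {
    u0 <- pmax(u0 - 1L, 0L)
    u1 <- pmax(u1 - 1L, 0L)
  }
  tab <- data.frame(
    protein_id = rep(proteins, times = 2 * C),
    block_id = rep(rep(blocks, each = p), times = 2),
    condition = rep(c(0L, 1L), each = p * C),
    count = c(as.vector(u0), as.vector(u1)))
  list(table = count_table(tab),
       truth = list(z = z, beta = beta, alpha = alpha, mu = mu,
                    proteins = proteins, blocks = blocks,
                    shifted = shifted, config = config, seed = seed))
}

#' Configuration for the single-channel gating simulator
#'
#' Two-state (closed/open) Markov channels. The default preset matches the
#' uninhibited InsP3R regime used throughout the gating analyses: open
#' probability 0.65 with mean open time 10 ms (so k_oc = 100 / s and
#' k_co = k_oc * Po / (1 - Po)), a 5 pA unitary current on a 0 pA closed
#' level, 5 kHz sampling with a 1 kHz anti-aliasing filter, and 0.8 pA rms
#' instrument noise before filtering.
#'
#' If `ca_er_uM` is given, the target open probability is set from the
#' inhibitory Hill relation at that luminal calcium concentration using
#' `hill` (defaults P_max = 0.65, K_inh = 260 uM, H_inh = 2.3), keeping
#' the mean open time fixed.
#'
#' @param n_channels number of independent channels in the patch.
#' @param p_open target per-channel open probability.
#' @param mean_open_s mean open sojourn (s).
#' @param ca_er_uM optional luminal calcium concentration (uM) that sets
#'   `p_open` through the Hill relation.
#' @param hill parameters used when `ca_er_uM` is given; a list/HillFit
#'   with `p_max`, `k_inh`, `h_inh`.
#' @param closed_level_pA,open_increment_pA current levels.
#' @param noise_sd_pA Gaussian noise s.d. added before filtering.
#' @param sampling_rate_hz,filter_cutoff_hz acquisition settings.
#' @param duration_s trace length (>= 1 s).
#' @return list of class `gating_sim_config` including derived rate
#'   constants `k_co` (closed to open) and `k_oc` (open to closed), per s.
#' @export
gating_sim_config <- function(n_channels = 1, p_open = 0.65,
                              mean_open_s = 0.010, ca_er_uM = NULL,
                              hill = list(p_max = 0.65, k_inh = 260,
                                          h_inh = 2.3),
                              closed_level_pA = 0, open_increment_pA = 5,
                              noise_sd_pA = 0.8, sampling_rate_hz = 5000,
                              filter_cutoff_hz = 1000, duration_s = 60) {
  if (!is.null(ca_er_uM)) {
    p_open <- hill_po(ca_er_uM, hill$p_max, hill$k_inh, hill$h_inh)
  }
  stopifnot(n_channels >= 1, p_open > 0, p_open < 1, mean_open_s > 0,
            duration_s >= 1, sampling_rate_hz > 2 * filter_cutoff_hz,
            open_increment_pA > 0, noise_sd_pA >= 0)
  k_oc <- 1 / mean_open_s
  k_co <- k_oc * p_open / (1 - p_open)
  structure(list(n_channels = as.integer(n_channels), p_open = p_open,
                 k_co = k_co, k_oc = k_oc,
                 closed_level_pA = closed_level_pA,
                 open_increment_pA = open_increment_pA,
                 noise_sd_pA = noise_sd_pA,
                 sampling_rate_hz = sampling_rate_hz,
                 filter_cutoff_hz = filter_cutoff_hz,
                 duration_s = duration_s),
            class = "gating_sim_config")
}

# Exact event-level path of one two-state channel: exponential sojourns,
# initial state from the stationary law. Returns transition times and the
# state (0/1) entered at each time, covering [0, duration].
simulate_channel_events <- function(k_co, k_oc, duration) {
  p_open <- k_co / (k_co + k_oc)
  state <- as.integer(stats::runif(1) < p_open)
  # generous preallocation; expected events = duration * 2 k_co k_oc/(k_co+k_oc)
  n_guess <- max(64L, ceiling(duration * (k_co + k_oc)))
  times <- numeric(n_guess); states <- integer(n_guess)
  t <- 0; n <- 0L
  while (t < duration) {
    n <- n + 1L
    if (n > length(times)) {
      times <- c(times, numeric(length(times)))
      states <- c(states, integer(length(states)))
    }
    times[n] <- t; states[n] <- state
    rate <- if (state == 1L) k_oc else k_co
    t <- t + stats::rexp(1, rate)
    state <- 1L - state
  }
  list(t_start = times[seq_len(n)], state = states[seq_len(n)],
       t_end = c(times[seq_len(n)][-1], duration))
}

# Occupied fraction of [0, duration] for one simulated channel.
simulate_open_fraction <- function(k_co, k_oc, duration) {
  ev <- simulate_channel_events(k_co, k_oc, duration)
  sum((ev$t_end - ev$t_start)[ev$state == 1L]) / duration
}

# Gaussian FIR low-pass kernel with -3 dB amplitude at `cutoff`:
# sigma_t = sqrt(ln 2) / (2 pi fc) ~ 0.1325 / fc.
gaussian_fir <- function(cutoff_hz, sampling_rate_hz) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_hz) * sampling_rate_hz  # samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

filter_trace <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, kernel, sides = 2))[(half + 1L):(half + length(x))]
}

#' Simulate a single-channel current trace
#'
#' N independent two-state Markov channels are sampled exactly
#' (exponential sojourns), summed into an occupancy-level path, scaled to
#' current, Gaussian noise is added, and the record is low-pass filtered
#' with a Gaussian FIR kernel (-3 dB at the configured cutoff) to emulate
#' the anti-aliasing filter of the acquisition chain.
#'
#' @param config a `gating_sim_config`.
#' @param seed integer seed.
#' @return object of class `current_trace`: `current_pA`, `time_s`,
#'   acquisition metadata, plus the true per-sample level path
#'   (`true_level`) and per-channel event lists (`true_events`).
#' @export
simulate_trace <- function(config = gating_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "gating_sim_config"))
  set.seed(seed)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  level <- integer(n)
  events <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    ev <- simulate_channel_events(config$k_co, config$k_oc, config$duration_s)
    events[[ch]] <- ev
    idx <- findInterval(tt, ev$t_start)
    level <- level + ev$state[idx]
  }
  current <- config$closed_level_pA + level * config$open_increment_pA
  if (config$noise_sd_pA > 0) {
    current <- current + stats::rnorm(n, 0, config$noise_sd_pA)
  }
  kernel <- gaussian_fir(config$filter_cutoff_hz, fs)
  current <- filter_trace(current, kernel)
  structure(list(current_pA = current, time_s = tt,
                 sampling_rate_hz = fs,
                 filter_cutoff_hz = config$filter_cutoff_hz,
                 closed_level_pA = config$closed_level_pA,
                 open_increment_pA = config$open_increment_pA,
                 v_app_mV = NULL, ramp = NULL,
                 true_level = level, true_events = events,
                 config = config, seed = seed),
            class = "current_trace")
}

#' Simulate an open-probability dose-inhibition dataset
#'
#' For each luminal calcium concentration, the true per-channel open
#' probability is set by the inhibitory Hill relation and `n_traces`
#' independent gating records of `trace_duration_s` are simulated at the
#' event level (exact exponential sojourns, mean open time fixed); each
#' trace contributes its occupied-time fraction as one open-probability
#' estimate. Rows carry the across-trace mean, s.e.m. and n, the format
#' consumed by [fit_hill()].
#'
#' @param p_max,k_inh,h_inh true Hill parameters (defaults 0.65, 260 uM,
#'   2.3).
#' @param concentrations_uM luminal calcium levels; the default 8 points
#'   are log-spaced over 0.07-600 uM, spanning the plateau and descent.
#' @param n_traces traces per concentration.
#' @param trace_duration_s duration of each simulated record.
#' @param mean_open_s mean open sojourn (s).
#' @param seed integer seed.
#' @return list with `data` (data.frame `ca_er_uM, mean_po, sem, n`) and
#'   `truth` (parameters, per-trace values).
#' @export
simulate_po_dataset <- function(p_max = 0.65, k_inh = 260, h_inh = 2.3,
                                concentrations_uM =
                                  10^seq(log10(0.07), log10(600), length.out = 8),
                                n_traces = 10, trace_duration_s = 30,
                                mean_open_s = 0.010, seed = 1L) {
  set.seed(seed)
  k_oc <- 1 / mean_open_s
  per_trace <- matrix(NA_real_, length(concentrations_uM), n_traces)
  for (i in seq_along(concentrations_uM)) {
    po <- hill_po(concentrations_uM[i], p_max, k_inh, h_inh)
    k_co <- k_oc * po / (1 - po)
    for (j in seq_len(n_traces)) {
      per_trace[i, j] <- simulate_open_fraction(k_co, k_oc, trace_duration_s)
    }
  }
  data <- data.frame(ca_er_uM = concentrations_uM,
                     mean_po = rowMeans(per_trace),
                     sem = apply(per_trace, 1, stats::sd) / sqrt(n_traces),
                     n = n_traces)
  list(data = data,
       truth = list(p_max = p_max, k_inh = k_inh, h_inh = h_inh,
                    per_trace = per_trace, seed = seed))
}

#' Configuration for the single-cell calcium-trace generator
#'
#' Emulates ratiometric (Fura-2) imaging of histamine-stimulated cells:
#' frames every 2 s, a pre-stimulus baseline, a stimulation window, and a
#' washout. Cells are drawn from four archetypes with known ground truth:
#' non-responders (baseline noise only), smooth single-transient
#' responders, periodic oscillators (regular spike train), and random
#' spikers (Poisson-timed spikes).
#'
#' @param n_cells number of cells.
#' @param frac_nonresponder,frac_smooth,frac_periodic,frac_random archetype
#'   fractions; must sum to 1.
#' @param frame_interval_s frame spacing (default 2 s).
#' @param baseline_s,stim_end_s,washout_s timing: stimulus starts at
#'   `baseline_s`, ends at `stim_end_s`; trace ends after `washout_s` more.
#' @param baseline_cv multiplicative baseline noise CV (default 0.03).
#' @param peak_ratio peak R/R0 of the response archetypes (default 3).
#' @return list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_cells = 40, frac_nonresponder = 0.25,
                            frac_smooth = 0.25, frac_periodic = 0.25,
                            frac_random = 0.25,
                            frame_interval_s = 2, baseline_s = 30,
                            stim_end_s = 390, washout_s = 90,
                            baseline_cv = 0.03, peak_ratio = 3) {
  fr <- c(frac_nonresponder, frac_smooth, frac_periodic, frac_random)
  stopifnot(abs(sum(fr) - 1) < 1e-8, all(fr >= 0), frame_interval_s > 0,
            n_cells >= 1, baseline_cv >= 0, peak_ratio > 2)
  structure(list(n_cells = as.integer(n_cells), fractions = fr,
                 frame_interval_s = frame_interval_s,
                 baseline_s = baseline_s, stim_end_s = stim_end_s,
                 washout_s = washout_s, baseline_cv = baseline_cv,
                 peak_ratio = peak_ratio),
            class = "cell_sim_config")
}

#' Simulate single-cell ratio traces with ground-truth labels
#'
#' @param config a `cell_sim_config`.
#' @param seed integer seed.
#' @return list with `time_s`, `ratio` (frames x cells matrix of raw
#'   ratios; per-cell gain applied so only R/R0 is meaningful),
#'   `stim_window` (start, end in s), `truth` (archetype per cell).
#' @export
simulate_cells <- function(config = cell_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "cell_sim_config"))
  set.seed(seed)
  dt <- config$frame_interval_s
  total <- config$stim_end_s + config$washout_s
  tt <- seq(0, total, by = dt)
  n_t <- length(tt)
  archetypes <- c("nonresponder", "smooth", "periodic", "random")
  labels <- sample(rep(archetypes,
                       times = round_fractions(config$fractions,
                                               config$n_cells)))
  ratio <- matrix(NA_real_, n_t, config$n_cells)
  t0 <- config$baseline_s
  for (j in seq_len(config$n_cells)) {
    base <- rep(1, n_t)
    resp <- switch(labels[j],
      nonresponder = rep(0, n_t),
      smooth = smooth_transient(tt, t0, peak = config$peak_ratio - 1,
                                rise_s = 5, decay_s = 8),
      periodic = spike_train(tt, t0, config$stim_end_s,
                             period_s = 40, jitter_s = 0,
                             amp = config$peak_ratio - 1, width_s = 8),
      random = spike_train(tt, t0, config$stim_end_s,
                           period_s = 40, jitter_s = 18,
                           amp = config$peak_ratio - 1, width_s = 8))
    rr <- (base + resp) *
      (1 + stats::rnorm(n_t, 0, config$baseline_cv))
    gain <- stats::runif(1, 0.5, 2)          # raw-ratio gain; cancels in R/R0
    ratio[, j] <- rr * gain
  }
  colnames(ratio) <- sprintf("cell%03d", seq_len(config$n_cells))
  list(time_s = tt, ratio = ratio,
       stim_window = c(start = t0, end = config$stim_end_s),
       truth = data.frame(cell_id = colnames(ratio), archetype = labels,
                          stringsAsFactors = FALSE),
       config = config, seed = seed)
}

# Poisson draw with a Gaussian approximation above 1e7 (where rpois would
# overflow its integer range and the approximation error is negligible)
rpois_safe <- function(n, lambda) {
  lambda <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  big <- lambda > 1e7
  out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  }
  out
}

round_fractions <- function(fr, n) {
  k <- floor(fr * n)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(fr * n - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  k
}

# single smooth transient: fast exponential rise, slow decay, returning
# to baseline well before washout
smooth_transient <- function(tt, t0, peak, rise_s, decay_s) {
  s <- pmax(tt - t0, 0)
  peak * (1 - exp(-s / rise_s)) * exp(-s / decay_s) /
    max((1 - exp(-seq(0, 1000) / rise_s)) * exp(-seq(0, 1000) / decay_s))
}

# train of brief transients during the stimulation window; jitter_s = 0
# gives a strictly periodic train, larger jitter gives random spiking.
# Jittered centers are kept clear of the baseline window and trace end so
# spike tails cannot defeat the inclusion tests.
spike_train <- function(tt, t0, t_end, period_s, jitter_s, amp, width_s) {
  centers <- seq(t0 + period_s / 2, t_end - period_s / 2, by = period_s)
  if (jitter_s > 0) {
    centers <- centers + stats::runif(length(centers), -jitter_s, jitter_s)
    centers <- pmin(pmax(centers, t0 + 3 * width_s), t_end - 2 * width_s)
  }
  out <- rep(0, length(tt))
  for (ct in centers) {
    out <- out + amp * exp(-(tt - ct)^2 / (2 * (width_s / 2.355)^2))
  }
  pmin(out, 1.5 * amp)
}
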