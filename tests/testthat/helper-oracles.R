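# Shared fixtures and independent oracles used across the suite.

# small complete count table built by hand
make_count_table <- function(y0, y1, blocks = NULL) {
  p <- nrow(y0); C <- ncol(y0)
  proteins <- sprintf("P%02d", seq_len(p))
  if (is.null(blocks)) blocks <- sprintf("b%d", seq_len(C))
  df <- expand.grid(protein_id = proteins, block_id = blocks,
                    condition = c(0L, 1L), stringsAsFactors = FALSE)
  df$count <- ifelse(df$condition == 0L,
                     y0[cbind(match(df$protein_id, proteins),
                              match(df$block_id, blocks))],
                     y1[cbind(match(df$protein_id, proteins),
                              match(df$block_id, blocks))])
  count_table(df)
}

# brute-force Poisson log-likelihood: plain double loop over cells
loglik_bruteforce <- function(y0, y1, mu, alpha, beta, pseudo) {
  total <- 0
  for (g in seq_len(nrow(y0))) {
    for (c in seq_len(ncol(y0))) {
      lam0 <- mu[c] * exp(alpha[g, c])
      lam1 <- mu[c] * exp(alpha[g, c] + beta[g])
      total <- total + dpois(y0[g, c] + pseudo, lam0, log = TRUE) +
        dpois(y1[g, c] + pseudo, lam1, log = TRUE)
    }
  }
  total
}

# idealized_trace built directly from an event list (level, duration_s)
make_ideal <- function(levels, durations_s, fs = 5000, dead_time_s = 0) {
  structure(list(events = data.frame(level = as.integer(levels),
                                     duration_s = durations_s),
                 dead_time_s = dead_time_s, sampling_rate_hz = fs,
                 closed_level_pA = 0, open_increment_pA = 5,
                 noise_sd_pA = 0, duration_s = sum(durations_s)),
            class = "idealized_trace")
}

# expand idealized events back to a per-sample level path
ideal_levels <- function(ideal) {
  rep(ideal$events$level,
      round(ideal$events$duration_s * ideal$sampling_rate_hz))
}

# Welch two-sample t statistic from the textbook formula
welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}
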