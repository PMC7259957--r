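#' Construct a single-channel current trace
#'
#' Container for a patch-clamp record: uniformly sampled current, the
#' acquisition settings, and either a constant applied potential or a
#' voltage-ramp description.
#'
#' @param current_pA numeric current samples.
#' @param sampling_rate_hz sampling rate (must exceed twice the filter
#'   cutoff).
#' @param filter_cutoff_hz anti-aliasing filter cutoff.
#' @param v_app_mV constant applied potential, or `NULL` for a ramp.
#' @param ramp `NULL`, or list with `start_mV`, `end_mV`, `duration_s`.
#' @param closed_level_pA,open_increment_pA current levels, if known.
#' @param time_s optional explicit time base.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(current_pA, sampling_rate_hz,
                          filter_cutoff_hz = sampling_rate_hz / 5,
                          v_app_mV = NULL, ramp = NULL,
                          closed_level_pA = NULL, open_increment_pA = NULL,
                          time_s = NULL) {
  stopifnot(is.numeric(current_pA), length(current_pA) > 1,
            sampling_rate_hz > 2 * filter_cutoff_hz)
  if (is.null(time_s)) {
    time_s <- (seq_along(current_pA) - 1L) / sampling_rate_hz
  }
  structure(list(current_pA = as.numeric(current_pA), time_s = time_s,
                 sampling_rate_hz = sampling_rate_hz,
                 filter_cutoff_hz = filter_cutoff_hz,
                 v_app_mV = v_app_mV, ramp = ramp,
                 closed_level_pA = closed_level_pA,
                 open_increment_pA = open_increment_pA),
            class = "current_trace")
}

#' Read a current trace from CSV plus a JSON metadata sidecar
#'
#' The CSV must have columns `time_s,current_pA`; the sidecar must name at
#' least `sampling_rate_hz` and `filter_cutoff_hz`. Sampling uniformity is
#' verified (maximum jitter below 10% of the nominal interval).
#'
#' @param path CSV path.
#' @param metadata_path JSON sidecar path.
#' @return a `current_trace`.
#' @export
read_trace <- function(path, metadata_path) {
  x <- data.table::fread(path, data.table = FALSE)
  if (!all(c("time_s", "current_pA") %in% names(x))) {
    stop("trace file must have columns time_s, current_pA")
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in c("sampling_rate_hz", "filter_cutoff_hz")) {
    if (is.null(meta[[key]])) stop("trace metadata missing key: ", key)
  }
  dt <- diff(x$time_s)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  nominal <- 1 / meta$sampling_rate_hz
  if (max(abs(dt - nominal)) > 0.1 * nominal) {
    stop("non-uniform sampling: jitter exceeds 10% of the sampling interval")
  }
  current_trace(x$current_pA, meta$sampling_rate_hz, meta$filter_cutoff_hz,
                v_app_mV = meta$v_app_mV, ramp = meta$ramp,
                closed_level_pA = meta$closed_level_pA,
                open_increment_pA = meta$open_increment_pA,
                time_s = x$time_s)
}

#' Write a current trace and its metadata sidecar
#'
#' @param trace a `current_trace`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return invisibly, the paths written.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              current_pA = trace$current_pA),
                   path, row.names = FALSE, quote = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- trace[c("sampling_rate_hz", "filter_cutoff_hz", "v_app_mV",
                  "ramp", "closed_level_pA", "open_increment_pA")]
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], meta_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, meta_path))
}

#' Default dead time for an idealized record
#'
#' Gaussian-filter rise-time convention: events briefer than
#' 0.179 / f_c (about 179 us at a 1 kHz cutoff) are unresolvable and are
#' merged into their neighbors during idealization.
#'
#' @param filter_cutoff_hz filter cutoff (Hz).
#' @return dead time in seconds.
#' @export
default_dead_time <- function(filter_cutoff_hz) 0.179 / filter_cutoff_hz

#' Estimate closed level and unitary increment from the amplitude histogram
#'
#' Fits a Gaussian mixture to (a subsample of) the current amplitudes; the
#' lowest component mean is taken as the closed level and the median
#' spacing of consecutive component means as the open-channel increment.
#' Requires the `mclust` package; pass explicit levels otherwise.
#'
#' @param current_pA current samples.
#' @param max_components maximum number of mixture components.
#' @param subsample cap on the number of samples used for fitting.
#' @return list with `closed_level_pA`, `open_increment_pA`, component
#'   means.
#' @export
estimate_levels <- function(current_pA, max_components = 4,
                            subsample = 20000) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stop("estimate_levels requires the 'mclust' package; ",
         "supply closed_level_pA and open_increment_pA explicitly")
  }
  x <- current_pA
  if (length(x) > subsample) {
    x <- x[round(seq(1, length(x), length.out = subsample))]
  }
  fit <- mclust::Mclust(x, G = 1:max_components, modelNames = "V",
                        verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  if (length(mu) < 2) {
    stop("amplitude histogram shows a single level; cannot estimate increment")
  }
  list(closed_level_pA = mu[1],
       open_increment_pA = stats::median(diff(mu)),
       component_means = mu)
}

#' Idealize a current trace into discrete occupancy levels
#'
#' Half-amplitude multi-level scheme: each sample is assigned the level
#' nearest to (i - closed) / increment (clamped at zero, i.e. thresholds
#' sit halfway between adjacent levels), the level path is run-length
#' encoded, and events briefer than the dead time are merged into their
#' neighbors (shortest first; an absorbed event joins the longer adjacent
#' event, and equal-level neighbors coalesce).
#'
#' @param trace a `current_trace`; `closed_level_pA` and
#'   `open_increment_pA` must be set on the trace or passed here.
#' @param closed_level_pA,open_increment_pA overrides.
#' @param dead_time_s minimum resolvable event duration; default
#'   [default_dead_time()] of the trace's filter cutoff.
#' @param hysteresis fraction of the increment by which a run of samples
#'   must overshoot the half-amplitude boundary before a level transition
#'   is committed (default 0.1); suppresses noise chatter at thresholds.
#' @return object of class `idealized_trace`: data.frame of events
#'   (`level`, `duration_s`) plus metadata. Total event duration equals
#'   the trace duration.
#' @export
idealize <- function(trace, closed_level_pA = NULL, open_increment_pA = NULL,
                     dead_time_s = NULL, hysteresis = 0.1) {
  stopifnot(inherits(trace, "current_trace"), hysteresis >= 0,
            hysteresis < 0.5)
  closed <- closed_level_pA %||% trace$closed_level_pA
  inc <- open_increment_pA %||% trace$open_increment_pA
  if (is.null(closed) || is.null(inc)) {
    est <- estimate_levels(trace$current_pA)
    closed <- closed %||% est$closed_level_pA
    inc <- inc %||% est$open_increment_pA
  }
  if (is.null(dead_time_s)) {
    dead_time_s <- default_dead_time(trace$filter_cutoff_hz)
  }
  level <- pmax(0L, as.integer(round((trace$current_pA - closed) / inc)))
  noise_sd <- stats::sd(trace$current_pA - (closed + level * inc))
  if (inc <= 4 * noise_sd) {
    stop("insufficient separation: open increment (", signif(inc, 3),
         " pA) must exceed 4x the residual noise s.d. (",
         signif(noise_sd, 3), " pA)")
  }
  r <- apply_hysteresis(trace$current_pA, level, closed, inc, hysteresis)
  # resolution floor: a single-sample run has no measurable duration, so
  # the merge threshold is at least 1.5 samples even when the filter dead
  # time is shorter than a sampling interval
  min_len <- max(dead_time_s * trace$sampling_rate_hz, 1.5)
  ev <- merge_brief_events(r$values, r$lengths, min_len = min_len)
  events <- data.frame(level = ev$values,
                       duration_s = ev$lengths / trace$sampling_rate_hz)
  structure(list(events = events, dead_time_s = dead_time_s,
                 sampling_rate_hz = trace$sampling_rate_hz,
                 closed_level_pA = closed, open_increment_pA = inc,
                 noise_sd_pA = noise_sd,
                 duration_s = length(trace$current_pA) /
                   trace$sampling_rate_hz),
            class = "idealized_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Schmitt-trigger confirmation of level transitions, run by run: a run of
# samples rounded to level v only commits a transition from the current
# level L if its extreme sample overshoots the half-amplitude boundary on
# the v side by `hysteresis` * increment; unconfirmed runs stay at L.
# Returns confirmed run-length encoding (values, lengths).
apply_hysteresis <- function(current, level, closed, inc, hysteresis) {
  r <- rle(level)
  n_runs <- length(r$values)
  if (n_runs <= 1L || hysteresis == 0) {
    return(list(values = r$values, lengths = as.numeric(r$lengths)))
  }
  run_id <- rep.int(seq_len(n_runs), r$lengths)
  run_max <- vapply(split(current, run_id), max, 0)
  run_min <- vapply(split(current, run_id), min, 0)
  vals <- integer(n_runs); lens <- numeric(n_runs)
  L <- r$values[1L]
  vals[1L] <- L; lens[1L] <- r$lengths[1L]
  k <- 1L
  for (i in 2:n_runs) {
    v <- r$values[i]
    commit <- if (v > L) {
      run_max[i] >= closed + (v - 0.5 + hysteresis) * inc
    } else {
      run_min[i] <= closed + (v + 0.5 - hysteresis) * inc
    }
    if (commit && v != L) {
      L <- v
      k <- k + 1L
      vals[k] <- v; lens[k] <- r$lengths[i]
    } else {
      lens[k] <- lens[k] + r$lengths[i]
    }
  }
  list(values = vals[seq_len(k)], lengths = lens[seq_len(k)])
}

# Merge run-length-encoded events shorter than min_len (in samples) into
# their neighbors, shortest first. Durations are conserved exactly.
merge_brief_events <- function(values, lengths, min_len) {
  repeat {
    if (length(values) <= 1L) break
    short <- which(lengths < min_len)
    if (length(short) == 0L) break
    i <- short[which.min(lengths[short])]
    if (i == 1L) {
      j <- 2L
    } else if (i == length(values)) {
      j <- i - 1L
    } else if (values[i - 1L] == values[i + 1L]) {
      # equal-level neighbors: coalesce all three
      lengths[i - 1L] <- lengths[i - 1L] + lengths[i] + lengths[i + 1L]
      values <- values[-c(i, i + 1L)]
      lengths <- lengths[-c(i, i + 1L)]
      next
    } else {
      j <- if (lengths[i - 1L] >= lengths[i + 1L]) i - 1L else i + 1L
    }
    lengths[j] <- lengths[j] + lengths[i]
    values <- values[-i]
    lengths <- lengths[-i]
    # coalesce newly adjacent equal levels
    r <- rle(values)
    if (length(r$values) < length(values)) {
      grp <- rep(seq_along(r$values), r$lengths)
      lengths <- as.numeric(tapply(lengths, grp, sum))
      values <- r$values
    }
  }
  list(values = values, lengths = lengths)
}

#' Per-channel open probability from an idealized trace
#'
#' P_o = sum_k (k * time at level k) / (n_channels * total duration): the
#' occupied fraction of channel-time, the multichannel-patch convention.
#'
#' @param ideal an `idealized_trace`.
#' @param n_channels number of channels assumed in the patch; must be at
#'   least the maximum observed level.
#' @return scalar in [0, 1].
#' @export
open_probability <- function(ideal, n_channels = max(ideal$events$level)) {
  stopifnot(inherits(ideal, "idealized_trace"))
  max_lev <- max(ideal$events$level)
  if (max_lev == 0L) return(0)
  if (n_channels < max_lev) {
    stop("n_channels (", n_channels, ") is below the maximum observed level (",
         max_lev, ")")
  }
  sum(ideal$events$level * ideal$events$duration_s) /
    (n_channels * sum(ideal$events$duration_s))
}

#' Confidence that the active-channel count is not an undercount
#'
#' Let candidate_N be the maximum occupancy level observed and P_o the
#' per-channel open probability estimated under candidate_N channels. If
#' the patch actually held candidate_N + 1 independent identical channels,
#' the chance that a random instant shows occupancy <= candidate_N is
#' q = 1 - P_o^(candidate_N + 1). Treating the record as
#' m = duration / (mean open + mean closed sojourn) independent looks, the
#' confidence that candidate_N is not an undercount is 1 - q^m. A trace is
#' conventionally accepted for analysis when this exceeds 0.99.
#'
#' @param ideal an `idealized_trace`.
#' @param candidate_N channel count being tested; defaults to the maximum
#'   observed level.
#' @return confidence in [0, 1]; 0 when the trace shows no openings.
#' @export
channel_count_confidence <- function(ideal,
                                     candidate_N = max(ideal$events$level)) {
  stopifnot(inherits(ideal, "idealized_trace"))
  ev <- ideal$events
  if (max(ev$level) == 0L || candidate_N < 1) return(0)
  po <- open_probability(ideal, candidate_N)
  open_d <- ev$duration_s[ev$level > 0]
  closed_d <- ev$duration_s[ev$level == 0]
  if (length(open_d) == 0L || length(closed_d) == 0L) {
    # a single sustained opening (or no closures): one effective look per
    # mean cycle is undefined; fall back to the whole record as one look
    m <- 1
  } else {
    m <- sum(ev$duration_s) / (mean(open_d) + mean(closed_d))
  }
  q <- 1 - po^(candidate_N + 1)
  1 - q^m
}

#' Mean open and closed dwell times
#'
#' Arithmetic means of open and closed sojourn durations from
#' single-channel segments (maximum level 1). The first and last events
#' are censored (their start/end was not observed) and excluded; all
#' retained events already exceed the dead time by construction.
#'
#' @param ideal an `idealized_trace` with maximum level <= 1.
#' @return list with `mean_open_s`, `mean_closed_s`, `n_open`, `n_closed`.
#' @export
dwell_times <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  ev <- ideal$events
  if (max(ev$level) > 1L) {
    stop("dwell_times requires single-channel segments (max level 1); ",
         "got maximum level ", max(ev$level))
  }
  if (nrow(ev) <= 2L) {
    stop("no complete sojourns to analyze: every event is censored ",
         "at the record boundary")
  }
  ev <- ev[-c(1L, nrow(ev)), , drop = FALSE]
  open_d <- ev$duration_s[ev$level == 1L]
  closed_d <- ev$duration_s[ev$level == 0L]
  list(mean_open_s = if (length(open_d)) mean(open_d) else NA_real_,
       mean_closed_s = if (length(closed_d)) mean(closed_d) else NA_real_,
       n_open = length(open_d), n_closed = length(closed_d))
}

#' Gating statistics for one trace
#'
#' Bundles the event-level reduction of a record: active-channel count
#' (maximum observed level) with its undercount confidence, per-channel
#' open probability, mean dwell times (single-channel records only), and
#' event counts.
#'
#' @param ideal an `idealized_trace`.
#' @param n_channels channel count to normalize P_o by; defaults to the
#'   observed maximum level.
#' @return object of class `gating_stats`.
#' @export
gating_stats <- function(ideal, n_channels = NULL) {
  stopifnot(inherits(ideal, "idealized_trace"))
  n_a <- max(ideal$events$level)
  if (is.null(n_channels)) n_channels <- max(n_a, 1L)
  dw <- if (n_a <= 1L && nrow(ideal$events) > 2L) {
    tryCatch(dwell_times(ideal), error = function(e) NULL)
  } else NULL
  structure(list(
    n_a = n_a,
    confidence = channel_count_confidence(ideal, max(n_a, 1L)),
    p_o = open_probability(ideal, n_channels),
    mean_open_s = dw$mean_open_s %||% NA_real_,
    mean_closed_s = dw$mean_closed_s %||% NA_real_,
    n_events = nrow(ideal$events)), class = "gating_stats")
}

#' Polynomial fit to open-channel ramp currents
#'
#' For a voltage-ramp record, closed-channel (leak) current is estimated
#' by a linear fit over level-0 samples and subtracted; open-channel
#' samples (level >= 1, scaled to one channel) are fitted with a
#' least-squares polynomial of order 1 (ohmic) or 4 (permeant-ion block
#' regime). The slope conductance at 0 mV is the derivative there, i.e.
#' the linear coefficient (pA/mV = nS... reported in nS).
#'
#' @param trace a `current_trace` whose `ramp` field gives `start_mV`,
#'   `end_mV`, `duration_s`.
#' @param order polynomial order, 1 or 4.
#' @param level per-sample occupancy level; defaults to the simulator's
#'   true path when present, otherwise the trace is idealized.
#' @return list with `coefficients` (increasing powers of V),
#'   `conductance_nS` (slope at 0 mV), `n_open_points`, and `fitted`
#'   data.frame (`v_mV`, `i_open_pA`, `i_fit_pA`).
#' @export
iv_ramp_fit <- function(trace, order = 1, level = NULL) {
  stopifnot(inherits(trace, "current_trace"), order %in% c(1, 4))
  if (is.null(trace$ramp)) stop("trace has no ramp description")
  if (is.null(level)) {
    level <- trace$true_level
    if (is.null(level)) {
      ideal <- idealize(trace)
      level <- rep(ideal$events$level,
                   round(ideal$events$duration_s * ideal$sampling_rate_hz))
    }
  }
  n <- length(trace$current_pA)
  v <- seq(trace$ramp$start_mV, trace$ramp$end_mV, length.out = n)
  closed <- level == 0L
  if (sum(closed) < 2L) stop("no closed-channel samples to estimate baseline")
  base_fit <- stats::lm(i ~ v, data = data.frame(i = trace$current_pA[closed],
                                                 v = v[closed]))
  baseline <- stats::predict(base_fit, newdata = data.frame(v = v))
  open <- level >= 1L
  if (sum(open) < order + 1) {
    stop("fewer open-channel points (", sum(open), ") than coefficients (",
         order + 1, ")")
  }
  vi <- v[open]
  io <- (trace$current_pA[open] - baseline[open]) / level[open]
  X <- outer(vi, 0:order, `^`)
  coef <- as.numeric(stats::lm.fit(X, io)$coefficients)
  coef[is.na(coef)] <- 0
  list(coefficients = coef,
       conductance_nS = coef[2],
       n_open_points = sum(open),
       fitted = data.frame(v_mV = vi, i_open_pA = io,
                           i_fit_pA = as.numeric(X %*% coef)))
}

#' Normalize open probabilities to a reference group
#'
#' Each P_o is divided by the reference-group mean; per-group means,
#' standard errors (with the reference-mean uncertainty propagated), and
#' the percent reduction relative to the reference are reported.
#'
#' @param po numeric open probabilities.
#' @param group group label per value.
#' @param reference label of the reference group.
#' @return list with `values` (data.frame of normalized P_o) and `summary`
#'   (per group: n, mean, sem, normalized mean, propagated se, percent
#'   reduction).
#' @export
normalize_po <- function(po, group, reference) {
  stopifnot(length(po) == length(group))
  group <- as.character(group)
  if (!reference %in% group) stop("reference group '", reference, "' is empty")
  ref <- po[group == reference]
  ref_mean <- mean(ref)
  if (ref_mean <= 0) stop("reference-group mean must be positive")
  ref_se <- stats::sd(ref) / sqrt(length(ref))
  values <- data.frame(group = group, p_o = po, normalized = po / ref_mean)
  sm <- do.call(rbind, lapply(split(values, values$group), function(d) {
    n <- nrow(d)
    m <- mean(d$p_o)
    se <- stats::sd(d$p_o) / sqrt(n)
    nm <- m / ref_mean
    prop_se <- if (n > 1 && length(ref) > 1) {
      abs(nm) * sqrt((se / m)^2 + (ref_se / ref_mean)^2)
    } else NA_real_
    data.frame(group = d$group[1], n = n, mean_po = m, sem_po = se,
               normalized_mean = nm, normalized_se = prop_se,
               percent_reduction = 100 * (1 - nm))
  }))
  rownames(sm) <- NULL
  list(values = values, summary = sm)
}
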