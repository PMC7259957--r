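#' Baseline-normalize a fluorescence-ratio trace
#'
#' Divides the 340/380 ratio at every time point by its mean over the
#' baseline window (by default the first 30 s), giving R/R0 with mean 1
#' over the baseline. Scale-invariant: multiplying the raw trace by any
#' gain leaves R/R0 unchanged.
#'
#' @param time_s time points (s), strictly increasing, uniform spacing.
#' @param ratio raw fluorescence ratio, positive.
#' @param baseline_window_s length of the baseline window starting at
#'   time 0 (default 30 s); must cover at least 3 frames.
#' @return numeric R/R0 series.
#' @export
normalize_ratio <- function(time_s, ratio, baseline_window_s = 30) {
  stopifnot(length(time_s) == length(ratio))
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (any(ratio <= 0)) stop("raw ratios must be positive")
  base <- ratio[time_s <= time_s[1] + baseline_window_s]
  if (length(base) < 3L) stop("baseline window must cover at least 3 frames")
  r0 <- mean(base)
  if (r0 <= 0) stop("baseline mean must be positive")
  ratio / r0
}

#' Classify a single-cell calcium trace
#'
#' Applies the logic tests used for histamine-stimulated Fura-2 imaging:
#' a cell is included only if every baseline frame (first 30 s) has
#' R/R0 within [0.75, 1.25] and every frame of the final 30 s of washout
#' has R/R0 < 1.5; an included cell is a responder if its post-stimulus
#' maximum R/R0 is >= 2.0; a responder is oscillating if the coefficient
#' of variation of R/R0 over the analysis window — from the end of the
#' initial calcium signal to the end of stimulation — exceeds 15%.
#'
#' The end of the initial signal is the first time after the first
#' post-stimulus peak at which R/R0 falls below
#' baseline + 0.5 * (peak - baseline); if it never does, the window starts
#' 20 s after the peak. Oscillating cells are further labelled "periodic"
#' when the dominant positive-lag autocorrelation peak of the window
#' exceeds 0.4, else "random spiking".
#'
#' @param time_s,ratio the raw trace (uniform sampling).
#' @param stim_start_s,stim_end_s stimulation window (s).
#' @param baseline_window_s baseline test window (default 30 s).
#' @param washout_window_s washout test window at the trace end (default
#'   30 s).
#' @param washout_all_frames if `TRUE` (default) every washout frame must
#'   be < 1.5; if `FALSE` only the window mean is tested.
#' @param responder_threshold,washout_threshold,cv_threshold_pct classifier
#'   constants; defaults 2.0, 1.5 and 15.
#' @param baseline_range inclusion band for baseline frames, default
#'   c(0.75, 1.25).
#' @return object of class `classified_cell`: flags `included`,
#'   `responder`, `oscillating`, labels `pattern` ("periodic oscillation",
#'   "random spiking" or "none"), `cv_pct`, the normalized trace and the
#'   analysis window used.
#' @export
classify_cell <- function(time_s, ratio, stim_start_s, stim_end_s,
                          baseline_window_s = 30, washout_window_s = 30,
                          washout_all_frames = TRUE,
                          responder_threshold = 2.0,
                          washout_threshold = 1.5,
                          cv_threshold_pct = 15,
                          baseline_range = c(0.75, 1.25)) {
  if (stim_start_s < time_s[1] || stim_end_s > time_s[length(time_s)]) {
    stop("stimulus window must lie within the trace")
  }
  total <- time_s[length(time_s)] - time_s[1]
  if (total < baseline_window_s + washout_window_s) {
    stop("trace shorter than the required baseline + washout windows")
  }
  rr <- normalize_ratio(time_s, ratio, baseline_window_s)

  base_idx <- time_s <= time_s[1] + baseline_window_s
  wash_idx <- time_s >= time_s[length(time_s)] - washout_window_s
  baseline_ok <- all(rr[base_idx] >= baseline_range[1] &
                     rr[base_idx] <= baseline_range[2])
  wash_vals <- rr[wash_idx]
  washout_ok <- if (washout_all_frames) all(wash_vals < washout_threshold)
                else mean(wash_vals) < washout_threshold
  included <- baseline_ok && washout_ok

  post <- which(time_s >= stim_start_s)
  responder <- included && max(rr[post]) >= responder_threshold

  oscillating <- NA
  pattern <- "none"
  cv_pct <- NA_real_
  window <- c(NA_real_, NA_real_)
  if (isTRUE(responder)) {
    base_mean <- mean(rr[base_idx])
    pk <- first_peak(time_s, rr, stim_start_s, responder_threshold)
    half_return <- base_mean + 0.5 * (rr[pk] - base_mean)
    after_pk <- which(time_s > time_s[pk] & time_s <= stim_end_s)
    drop_idx <- after_pk[rr[after_pk] < half_return]
    win_start <- if (length(drop_idx)) time_s[drop_idx[1]] else
      time_s[pk] + 20
    win_start <- min(win_start, stim_end_s)
    win_idx <- which(time_s >= win_start & time_s <= stim_end_s)
    if (length(win_idx) >= 3L) {
      seg <- rr[win_idx]
      cv_pct <- 100 * stats::sd(seg) / mean(seg)
      oscillating <- cv_pct > cv_threshold_pct
      window <- c(win_start, stim_end_s)
      pattern <- if (oscillating) {
        if (dominant_acf_peak(seg) > 0.4) "periodic oscillation"
        else "random spiking"
      } else "none"
    } else {
      oscillating <- FALSE
    }
  } else if (isTRUE(included)) {
    oscillating <- FALSE
  }

  structure(list(included = included, baseline_ok = baseline_ok,
                 washout_ok = washout_ok, responder = isTRUE(responder),
                 oscillating = oscillating, pattern = pattern,
                 cv_pct = cv_pct, analysis_window_s = window,
                 r_r0 = rr), class = "classified_cell")
}

# first local maximum at or above `threshold` after the stimulus; falls
# back to the post-stimulus global maximum
first_peak <- function(time_s, rr, stim_start_s, threshold) {
  post <- which(time_s >= stim_start_s)
  n <- length(rr)
  for (i in post) {
    if (rr[i] >= threshold &&
        (i == 1L || rr[i] >= rr[i - 1L]) &&
        (i == n || rr[i] >= rr[i + 1L])) {
      return(i)
    }
  }
  post[which.max(rr[post])]
}

# height of the dominant autocorrelation peak at positive lag: a local
# maximum of the ACF that exceeds both neighbours
dominant_acf_peak <- function(x, max_lag = floor(length(x) / 2)) {
  if (length(x) < 8L || stats::sd(x) == 0) return(0)
  a <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)[-1]
  if (length(a) < 3L) return(max(a, 0))
  peaks <- which(diff(sign(diff(a))) == -2) + 1L
  if (length(peaks) == 0L) return(0)
  max(a[peaks])
}

#' Classify every cell of an imaging field
#'
#' @param time_s shared time base.
#' @param ratio frames x cells matrix of raw ratios (column names used as
#'   cell ids).
#' @param stim_start_s,stim_end_s stimulation window.
#' @param ... further arguments to [classify_cell()].
#' @return data.frame with one row per cell: `cell_id`, `included`,
#'   `responder`, `oscillating`, `pattern`, `cv_pct`.
#' @export
classify_cells <- function(time_s, ratio, stim_start_s, stim_end_s, ...) {
  stopifnot(is.matrix(ratio), nrow(ratio) == length(time_s))
  ids <- colnames(ratio) %||% sprintf("cell%03d", seq_len(ncol(ratio)))
  rows <- lapply(seq_len(ncol(ratio)), function(j) {
    cl <- classify_cell(time_s, ratio[, j], stim_start_s, stim_end_s, ...)
    data.frame(cell_id = ids[j], included = cl$included,
               responder = cl$responder,
               oscillating = cl$oscillating, pattern = cl$pattern,
               cv_pct = cl$cv_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a single-exponential rise to a population calcium response
#'
#' For a population fluorescence-ratio record, the baseline is the mean R
#' over the pre-agonist window (by default the 90 s before the stimulus),
#' dR(t) = R(t) - baseline, and the rising phase runs from the stimulus to
#' the first maximum of dR. The fit is
#' dR(t) = dR_max * (1 - exp(-(t - t0) / tau)) with t0 fixed at the
#' stimulus time; at t = t0 + tau the fitted curve equals
#' (1 - 1/e) * dR_max.
#'
#' @param time_s,r the record (raw ratio).
#' @param stim_time_s stimulus time (s).
#' @param baseline_window_s pre-stimulus baseline span (default 90 s).
#' @return object of class `rise_fit`: `dr_max`, `tau_s`, their standard
#'   errors, baseline, and the fitted rising-phase data.
#' @export
fit_rise <- function(time_s, r, stim_time_s, baseline_window_s = 90) {
  stopifnot(length(time_s) == length(r))
  pre <- which(time_s < stim_time_s &
               time_s >= stim_time_s - baseline_window_s)
  if (length(pre) < 3L) stop("too few pre-stimulus frames for a baseline")
  baseline <- mean(r[pre])
  dr <- r - baseline
  post <- which(time_s >= stim_time_s)
  if (length(post) < 4L) stop("too few post-stimulus frames")
  pk_rel <- which.max(dr[post])
  if (dr[post][pk_rel] <= 0) stop("no rise after stimulus")
  rise_idx <- post[seq_len(pk_rel)]
  if (length(rise_idx) < 3L) stop("rising phase too short to fit")
  d <- data.frame(t = time_s[rise_idx] - stim_time_s, y = dr[rise_idx])
  peak <- max(d$y)
  tau0 <- max(d$t[which(d$y >= (1 - exp(-1)) * peak)[1]], d$t[2] / 2,
              na.rm = TRUE)
  fit <- minpack.lm::nlsLM(y ~ dr_max * (1 - exp(-t / tau)), data = d,
                           start = list(dr_max = peak, tau = tau0),
                           lower = c(dr_max = 1e-12, tau = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(dr_max = unname(cf["dr_max"]), tau_s = unname(cf["tau"]),
                 se = se, baseline = baseline,
                 rising = cbind(d, fit = stats::fitted(fit))),
            class = "rise_fit")
}

#' Normalize per-group measurements to a control group
#'
#' Each value is divided by the control-group mean. Group means, standard
#' errors and the unpaired two-sample t-test p-value (treated vs control,
#' Welch) are reported.
#'
#' @param values numeric measurements (e.g. dR_max or 1/tau per trace).
#' @param group group label per value.
#' @param control label of the control group.
#' @return list with `values` (data.frame of normalized values) and
#'   `summary` (per group: n, mean, sem, normalized mean and sem, and the
#'   t-test p-value against control).
#' @export
normalize_to_control <- function(values, group, control) {
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' is empty")
  ctl <- values[group == control]
  ctl_mean <- mean(ctl)
  if (ctl_mean <= 0) stop("control-group mean must be positive")
  norm <- values / ctl_mean
  sm <- do.call(rbind, lapply(split(seq_along(values), group), function(ix) {
    g <- group[ix[1]]
    v <- values[ix]
    p <- if (g == control || length(v) < 2L || length(ctl) < 2L) NA_real_
         else tryCatch(stats::t.test(v, ctl)$p.value,
                       error = function(e) NA_real_)
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               normalized_mean = mean(v) / ctl_mean,
               normalized_sem = stats::sd(v / ctl_mean) / sqrt(length(v)),
               p_value_vs_control = p, stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  list(values = data.frame(group = group, value = values, normalized = norm),
       summary = sm)
}

#' Read single-cell ratio traces from CSV
#'
#' Accepts wide format (a `time_s` column plus one column per cell) or
#' long format (`cell_id, time_s, ratio`).
#'
#' @param path file path.
#' @return list with `time_s` and a frames x cells `ratio` matrix.
#' @export
read_cell_traces <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  if (all(c("cell_id", "time_s", "ratio") %in% names(x))) {
    cells <- sort(unique(x$cell_id))
    tt <- sort(unique(x$time_s))
    m <- matrix(NA_real_, length(tt), length(cells),
                dimnames = list(NULL, cells))
    m[cbind(match(x$time_s, tt), match(x$cell_id, cells))] <- x$ratio
    if (anyNA(m)) stop("long-format traces do not share a common time base")
    return(list(time_s = tt, ratio = m))
  }
  if (!"time_s" %in% names(x)) {
    stop("cell-trace file must be wide (time_s + cell columns) or long ",
         "(cell_id, time_s, ratio)")
  }
  tt <- x$time_s
  m <- as.matrix(x[, setdiff(names(x), "time_s"), drop = FALSE])
  list(time_s = tt, ratio = m)
}
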