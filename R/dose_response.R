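#' Inhibitory Hill relation for luminal-calcium suppression of P_o
#'
#' P_o = P_max * [1 + ([Ca]_ER / K_inh)^H_inh]^-1: a sigmoid descent from
#' the P_max plateau with half-maximal inhibition at K_inh and steepness
#' H_inh. Monotone non-increasing in concentration; equals P_max at zero
#' and exactly P_max / 2 at K_inh.
#'
#' @param ca_er_uM luminal calcium concentration(s), uM, >= 0.
#' @param p_max plateau open probability, in (0, 1].
#' @param k_inh half-maximal inhibitory concentration, uM, > 0.
#' @param h_inh Hill coefficient, > 0.
#' @return open probability value(s).
#' @export
hill_po <- function(ca_er_uM, p_max, k_inh, h_inh) {
  if (any(ca_er_uM < 0)) stop("concentration must be non-negative")
  stopifnot(p_max > 0, p_max <= 1, k_inh > 0, h_inh > 0)
  p_max / (1 + (ca_er_uM / k_inh)^h_inh)
}

#' Validate an open-probability dose dataset
#'
#' @param data data.frame with columns `ca_er_uM`, `mean_po`, and
#'   optionally `sem`, `n`.
#' @return the data sorted by concentration.
#' @keywords internal
validate_po_dataset <- function(data) {
  need <- c("ca_er_uM", "mean_po")
  if (!all(need %in% names(data))) {
    stop("dose dataset needs columns: ", paste(need, collapse = ", "))
  }
  if (any(data$ca_er_uM <= 0)) stop("concentrations must be positive")
  if (any(data$mean_po < 0 | data$mean_po > 1)) {
    stop("mean_po must lie in [0, 1]")
  }
  data <- data[order(data$ca_er_uM), , drop = FALSE]
  if (any(diff(data$ca_er_uM) == 0)) stop("duplicate concentrations")
  data
}

#' Fit the inhibitory Hill equation to mean open-probability data
#'
#' Nonlinear least squares (Levenberg-Marquardt) over a small
#' deterministic multi-start grid: P_max starts at the maximum observed
#' P_o, K_inh at the first concentration where P_o falls below half the
#' maximum, and H_inh at each of 1, 2 and 4. Optionally 1/sem^2-weighted.
#' Parameter standard errors come from the local curvature at the optimum.
#'
#' @param data data.frame with `ca_er_uM`, `mean_po`, and (for weighting)
#'   `sem`; at least 4 points spanning plateau and descent.
#' @param weights `"none"` (default; fit to the averages) or `"sem"`.
#' @param fix_p_max optional fixed plateau; if given, only K_inh and H_inh
#'   are estimated.
#' @return object of class `hill_fit`: `p_max`, `k_inh`, `h_inh`, their
#'   standard errors, `rss`, `descent_sampled` flag, and the `nls` object.
#' @export
fit_hill <- function(data, weights = c("none", "sem"), fix_p_max = NULL) {
  weights <- match.arg(weights)
  data <- validate_po_dataset(data)
  if (nrow(data) < 4L) stop("at least 4 dose points are required")
  pmax_obs <- max(data$mean_po)
  if (pmax_obs <= 0) stop("all open probabilities are zero; nothing to fit")
  if (diff(range(data$mean_po)) < 0.02 * pmax_obs) {
    stop("open probability is flat across the sampled concentrations; ",
         "K_inh and H_inh are unidentifiable")
  }
  descent_sampled <- min(data$mean_po) < 0.5 * pmax_obs
  if (!descent_sampled) {
    warning("descent below half-maximum not sampled; ",
            "K_inh is poorly constrained")
  }
  below <- which(data$mean_po < pmax_obs / 2)
  k_start <- if (length(below)) data$ca_er_uM[below[1]] else
    max(data$ca_er_uM)
  w <- if (weights == "sem") {
    if (is.null(data$sem) || any(data$sem <= 0)) {
      stop("sem weighting requested but sem column missing or non-positive")
    }
    1 / data$sem^2
  } else rep(1, nrow(data))

  best <- NULL
  for (h_start in c(1, 2, 4)) {
    fit <- tryCatch({
      if (is.null(fix_p_max)) {
        minpack.lm::nlsLM(
          mean_po ~ p_max / (1 + (ca_er_uM / k_inh)^h_inh), data = data,
          start = list(p_max = pmax_obs, k_inh = k_start, h_inh = h_start),
          weights = w,
          lower = c(p_max = 1e-6, k_inh = min(data$ca_er_uM) * 1e-2,
                    h_inh = 0.05),
          upper = c(p_max = 1, k_inh = max(data$ca_er_uM) * 1e2,
                    h_inh = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          mean_po ~ fix_p_max / (1 + (ca_er_uM / k_inh)^h_inh), data = data,
          start = list(k_inh = k_start, h_inh = h_start), weights = w,
          lower = c(k_inh = min(data$ca_er_uM) * 1e-2, h_inh = 0.05),
          upper = c(k_inh = max(data$ca_er_uM) * 1e2, h_inh = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop("Hill fit did not converge from any start (K_inh starts at ",
         signif(k_start, 4), " uM, H_inh in {1, 2, 4})")
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  out <- list(p_max = unname(if (is.null(fix_p_max)) cf["p_max"] else
                             fix_p_max),
              k_inh = unname(cf["k_inh"]),
              h_inh = unname(cf["h_inh"]),
              se = se, rss = best$rss,
              descent_sampled = descent_sampled,
              weights = weights, nls = best$fit)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Inhibitory Hill fit\n")
  cat(sprintf("  P_max = %.3f\n", x$p_max))
  cat(sprintf("  K_inh = %.1f uM\n", x$k_inh))
  cat(sprintf("  H_inh = %.2f\n", x$h_inh))
  cat(sprintf("  RSS   = %.3g\n", x$rss))
  invisible(x)
}

#' Read an open-probability dose dataset from TSV/CSV
#'
#' Columns `ca_er_uM, mean_po, sem, n` (sem/n optional). An alternative
#' concentration column `ca_er_nM` is accepted and converted to uM.
#'
#' @param path file path.
#' @return validated data.frame sorted by concentration.
#' @export
read_po_dataset <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  if (!"ca_er_uM" %in% names(x) && "ca_er_nM" %in% names(x)) {
    x$ca_er_uM <- x$ca_er_nM / 1000
    x$ca_er_nM <- NULL
  }
  validate_po_dataset(x)
}
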