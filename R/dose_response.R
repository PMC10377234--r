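# Junctional conductance from dual patch-clamp voltage ramps, time-course
# normalization, and three-parameter Hill dose-response fitting.

#' Junctional conductance from a voltage-ramp measurement
#'
#' In the dual whole-cell configuration both cells sit at the same holding
#' potential; a voltage step \eqn{\Delta V_1} (the transjunctional voltage
#' \eqn{V_j}, typically -10 mV for 20 ms) is applied to Cell-1 and the
#' junctional current is read in Cell-2 (\eqn{I_j = \Delta I_2}).
#' Conductance is \eqn{g_j = -I_j/\Delta V_1}; the sign reflects that the
#' current measured in Cell-2 is oppositely oriented to Cell-1's. With
#' \eqn{I_j} in nA and \eqn{\Delta V_1} in mV the ratio is in uS and is
#' returned in nS. A negative result flags a non-junctional artifact.
#'
#' @param i_j junctional current in nA (vectorized).
#' @param delta_v1 voltage step in mV, non-zero.
#' @return conductance in nS: \code{-i_j/delta_v1 * 1000}.
#' @examples
#' compute_gj(0.2, -10)  # 20 nS
#' @export
compute_gj <- function(i_j, delta_v1) {
  stopifnot(is.numeric(i_j), is.numeric(delta_v1))
  if (any(delta_v1 == 0)) stop("delta_v1 must be non-zero")
  -i_j / delta_v1 * 1000
}

#' Read a voltage-ramp time series
#'
#' @param path CSV with columns \code{timestamp} (s), \code{i_j} (nA),
#'   \code{delta_v1} (mV).
#' @return data.frame with those columns plus \code{gj} (nS).
#' @export
read_ramp_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "i_j", "delta_v1")
  if (!all(need %in% names(df)))
    stop("ramp table must have columns ", paste(need, collapse = ", "))
  df$gj <- compute_gj(df$i_j, df$delta_v1)
  df
}

#' Normalize a conductance time course to its baseline
#'
#' The response to one inhibitor concentration is the plateau conductance
#' after drug application divided by the mean baseline conductance before
#' it. The plateau is estimated as the mean over the final stationary
#' segment of the recording.
#'
#' @param timestamp numeric vector of sample times, s, increasing.
#' @param gj conductance samples, nS.
#' @param baseline_window length of the initial baseline period, s; must
#'   contain at least 3 samples and precede drug application.
#' @param plateau_window length of the final segment averaged as the
#'   plateau, s (default: same as the baseline window).
#' @return list: \code{response} (plateau/baseline, dimensionless, 1 = no
#'   block), \code{baseline_gj}, \code{plateau_gj} (nS).
#' @export
normalize_timecourse <- function(timestamp, gj, baseline_window,
                                 plateau_window = baseline_window) {
  stopifnot(length(timestamp) == length(gj), baseline_window > 0)
  t0 <- timestamp[1]
  base <- gj[timestamp <= t0 + baseline_window]
  if (length(base) < 3)
    stop("baseline window contains ", length(base), " sample(s); need >= 3")
  t_end <- timestamp[length(timestamp)]
  plat <- gj[timestamp >= t_end - plateau_window]
  b <- mean(base)
  if (b <= 0) stop("baseline mean conductance must be > 0 (got ", b, " nS)")
  list(response = mean(plat) / b, baseline_gj = b, plateau_gj = mean(plat))
}

#' Three-parameter Hill inhibition curve
#'
#' \deqn{y(C) = y_{max} / (1 + (C/IC_{50})^h)}
#' At \eqn{C = 0} the response is \eqn{y_{max}} (the unblocked baseline);
#' at \eqn{C = IC_{50}} it is \eqn{y_{max}/2} for any Hill coefficient
#' \eqn{h}.
#'
#' @param conc concentration, uM (vectorized, >= 0).
#' @param y_max maximal (baseline) response.
#' @param ic50 half-maximal inhibitory concentration, uM.
#' @param h Hill coefficient.
#' @return response values.
#' @export
hill_response <- function(conc, y_max, ic50, h) {
  stopifnot(ic50 > 0, h > 0, all(conc >= 0))
  y_max / (1 + (conc / ic50)^h)
}

#' Fit a three-parameter Hill curve to dose-response points
#'
#' Least-squares fit of \code{\link{hill_response}} by multistart bounded
#' quasi-Newton (L-BFGS-B on \eqn{(y_{max}, \log IC_{50}, \log h)})
#' followed by a Nelder-Mead polish; the best sum of squares wins. IC50 is
#' started from the concentration bracketing half-maximal response and
#' from the geometric mean of the positive doses; the Hill coefficient
#' from {1, 2, 4}; \eqn{y_{max}} from the largest observed response.
#' Bounds: \eqn{y_{max} \in (0, 1.5]}, \eqn{h \in [10^{-3}, 50]}.
#'
#' @param conc concentrations in uM; must include a zero-dose baseline and
#'   at least 4 points in total.
#' @param response normalized responses (1 = no block).
#' @return a \code{hill_fit}: \code{ic50} (uM), \code{hill_h},
#'   \code{y_max}, \code{converged}, \code{residual_sse}.
#' @export
fit_hill <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc >= 0),
            all(response >= 0))
  if (length(conc) < 4)
    stop("need at least 4 dose-response points (got ", length(conc), ")")
  if (!any(conc == 0))
    stop("a zero-dose baseline point is required")
  sse <- function(p) {
    y <- p[1] / (1 + (conc / exp(p[2]))^exp(p[3]))
    sum((response - y)^2)
  }
  pos <- sort(unique(conc[conc > 0]))
  y0 <- max(response)
  half <- y0 / 2
  below <- which(response < half & conc > 0)
  ic_starts <- exp(mean(log(pos)))
  if (length(below) > 0) ic_starts <- c(conc[below[1]], ic_starts)
  best <- NULL
  for (ic0 in unique(ic_starts)) {
    for (h0 in c(1, 2, 4)) {
      p0 <- c(min(max(y0, 1e-3), 1.5), log(ic0), log(h0))
      f <- tryCatch(
        stats::optim(p0, sse, method = "L-BFGS-B",
                     lower = c(1e-6, log(1e-6), log(1e-3)),
                     upper = c(1.5, log(1e9), log(50)),
                     control = list(factr = 1e1, maxit = 1000)),
        error = function(e) NULL)
      if (is.null(f)) next
      g <- stats::optim(f$par, sse, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      cand <- if (g$value <= f$value) g else f
      # the polish hitting maxit at reltol 1e-14 is not a failure if the
      # bounded stage itself converged
      cand$convergence <- min(cand$convergence, f$convergence)
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  }
  if (is.null(best)) {
    warning("fit_hill: no start converged; returning NA parameters")
    return(structure(list(ic50 = NA_real_, hill_h = NA_real_,
                          y_max = NA_real_, converged = FALSE,
                          residual_sse = NA_real_), class = "hill_fit"))
  }
  converged <- best$convergence == 0
  if (!converged)
    warning("fit_hill: optimizer did not report convergence; ",
            "best-effort parameters returned")
  structure(list(ic50 = exp(best$par[2]), hill_h = exp(best$par[3]),
                 y_max = best$par[1], converged = converged,
                 residual_sse = best$value),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: IC50 = %.3g uM, h = %.3g, y_max = %.3g (SSE %.3g%s)\n",
              x$ic50, x$hill_h, x$y_max, x$residual_sse,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}
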