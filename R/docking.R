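# Affine calibration mapping docking minimized affinity (DMA, kcal/mol;
# more negative = stronger binding) to potency on the -log10 molar scale:
#   -log(pIC50) = m * DMA + n

new_docking_calibration <- function(slope_m, intercept_n) {
  stopifnot(is.finite(slope_m), is.finite(intercept_n))
  structure(list(slope_m = slope_m, intercept_n = intercept_n),
            class = "docking_calibration")
}

#' @export
print.docking_calibration <- function(x, ...) {
  cat(sprintf("docking calibration: -log(pIC50) = %.4g * DMA %+.4g\n",
              x$slope_m, x$intercept_n))
  invisible(x)
}

#' The published Cx43 docking calibration preset
#'
#' Slope and intercept fitted against the Cx43 inhibitor panel:
#' m = -0.18, n = 0.75. The intercept is the predicted potency of a ligand
#' with zero docking affinity; the negative slope means stronger (more
#' negative) affinities map to higher potency.
#'
#' @return a \code{docking_calibration}.
#' @export
paper_docking_calibration <- function() new_docking_calibration(-0.18, 0.75)

#' Fit the affinity-to-potency calibration line
#'
#' Simple least squares of measured \eqn{-\log_{10}}(eIC50) on docking
#' minimized affinity.
#'
#' @param dma numeric vector of docking minimized affinities (kcal/mol).
#' @param neg_log_e_ic50 numeric vector of measured potencies, same length.
#' @return list with \code{calibration} (a \code{docking_calibration}) and
#'   \code{stats} (a \code{fit_stats}).
#' @export
fit_calibration <- function(dma, neg_log_e_ic50) {
  stopifnot(length(dma) == length(neg_log_e_ic50))
  if (length(dma) < 3) stop("need at least 3 (dma, potency) pairs")
  if (stats::sd(dma) == 0) stop("zero variance in DMA values")
  fit <- fit_ols(matrix(dma, ncol = 1, dimnames = list(NULL, "dma")),
                 neg_log_e_ic50)
  list(calibration = new_docking_calibration(fit$model$coefficients[["dma"]],
                                             fit$model$intercept),
       stats = fit$stats, fitted = fit$fitted)
}

#' Predict potency from a docking minimized affinity
#'
#' @param cal a \code{docking_calibration}.
#' @param dma docking minimized affinity (kcal/mol), finite; vectorized.
#' @return predicted \eqn{-\log_{10}} molar potency \code{m * dma + n}.
#' @examples
#' predict_from_dma(paper_docking_calibration(), -19.06)  # ~4.18
#' @export
predict_from_dma <- function(cal, dma) {
  stopifnot(inherits(cal, "docking_calibration"), all(is.finite(dma)))
  cal$slope_m * dma + cal$intercept_n
}

#' Read a docking score table
#'
#' @param path CSV with columns \code{cid} and \code{dma} (kcal/mol).
#' @return data.frame with those two columns.
#' @export
read_dma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cid", "dma") %in% names(df)))
    stop("score table must have columns cid, dma")
  if (any(!is.finite(df$dma))) stop("non-finite DMA value in score table")
  df[c("cid", "dma")]
}
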