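# Orchestration: the end-to-end reproduction run over the packaged
# inhibitor table and the synthetic recovery suite.

#' Reproduce the published evaluation from the packaged dataset
#'
#' Runs the desk-reproducible part of the study end to end: applies the
#' packaged three-descriptor QSAR model to every compound's printed
#' descriptors, computes validation statistics (R, R2, adjusted R2) of the
#' three prediction columns against measured \eqn{-\log_{10}}(eIC50),
#' refits the QSAR coefficients from the printed columns, counts the
#' docking/alignment-eligible compounds, and converts the d-limonene
#' predictions to micromolar. Optionally writes \code{summary.json},
#' \code{predictions.csv} and \code{stats.csv} to an output directory.
#'
#' @param dataset a \code{compound_dataset}; default the packaged 17-row
#'   Cx43 table.
#' @param output_dir directory for the report bundle, or NULL to skip
#'   writing.
#' @return (invisibly when writing) a list: \code{predictions}
#'   (per-compound data.frame), \code{stats} (per-model
#'   \code{fit_stats}), \code{refit} (coefficients and stats of the OLS
#'   refit), \code{n_total}, \code{n_docking_eligible},
#'   \code{limonene_um} (per-model uM conversions).
#' @export
run_reproduction <- function(dataset = cx43_dataset(), output_dir = NULL) {
  model <- cx43_qsar_model()
  qsar_pred <- predict(model, dataset)
  eligible <- filter_docking_eligible(dataset)
  stats_of <- function(col, ds, k) {
    ok <- is.finite(ds[[col]])
    validation_stats(ds$neg_log_e_ic50[ok], ds[[col]][ok], n_predictors = k)
  }
  # docking: one predictor (the affinity); 3D-QSAR: one latent component
  # (the published adjusted R2 is consistent with a single component)
  st <- list(qsar = stats_of("pred_qsar", dataset, 3),
             docking = stats_of("pred_docking", dataset, 1),
             qsar3d = stats_of("pred_3dqsar", dataset, 1))
  refit <- fit_ols(as.matrix(as.data.frame(dataset)[CX43_DESCRIPTORS]),
                   dataset$neg_log_e_ic50)
  lim <- dataset[dataset$name == "d-Limonene", ]
  limonene_um <- if (nrow(lim) == 1) {
    vals <- c(docking = lim$pred_docking, qsar = lim$pred_qsar,
              qsar3d = lim$pred_3dqsar, measured = lim$neg_log_e_ic50)
    neg_log_to_micromolar(vals)
  } else NULL
  predictions <- data.frame(cid = dataset$cid, name = dataset$name,
                            neg_log_e_ic50 = dataset$neg_log_e_ic50,
                            pred_qsar_eq3 = qsar_pred,
                            pred_qsar_printed = dataset$pred_qsar,
                            pred_docking_printed = dataset$pred_docking,
                            pred_3dqsar_printed = dataset$pred_3dqsar)
  out <- list(predictions = predictions, stats = st,
              refit = list(coefficients = refit$model$coefficients,
                           intercept = refit$model$intercept,
                           stats = refit$stats),
              n_total = nrow(dataset), n_docking_eligible = nrow(eligible),
              limonene_um = limonene_um)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(predictions,
                     file.path(output_dir, "predictions.csv"),
                     row.names = FALSE)
    stats_df <- do.call(rbind, lapply(names(st), function(k)
      data.frame(model = k, r = st[[k]]$r, r2 = st[[k]]$r2,
                 r2_adj = st[[k]]$r2_adj, n = st[[k]]$n_obs)))
    utils::write.csv(stats_df, file.path(output_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_total = out$n_total,
           n_docking_eligible = out$n_docking_eligible,
           stats = lapply(st, function(s)
             list(r = s$r, r2 = s$r2, r2_adj = s$r2_adj, n = s$n_obs)),
           refit = list(coefficients = as.list(refit$model$coefficients),
                        intercept = refit$model$intercept),
           limonene_um = as.list(out$limonene_um)),
      file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Run the synthetic recovery suite
#'
#' Exercises every generator-to-stage loop: best-subset recovery of a
#' planted descriptor triple, calibration-line recovery from synthetic
#' docking scores, Hill parameter recovery over seeded noisy replicates,
#' and PLS field-model recovery from planted hotspots. Replicate counts
#' are desk-scale so the suite runs in seconds.
#'
#' @param seed master seed.
#' @param n_hill_reps number of Hill replicates (default 200).
#' @param output_dir optional directory for \code{synthetic_report.json}.
#' @return list of per-check results, each with a \code{pass} flag.
#' @export
run_synthetic_suite <- function(seed = 1, n_hill_reps = 200,
                                output_dir = NULL) {
  # planted-subset recovery in the regime where search is non-trivial
  ds <- gen_descriptor_dataset(seed, n_compounds = 40, n_descriptors = 30,
                               noise_sd = 0.1)
  sr <- exhaustive_subset_search(ds$x, ds$y, k = 3)
  subset_check <- list(
    top_subset = sr$table$subset[1],
    planted = paste(sort(ds$planted_subset), collapse = "+"),
    pass = identical(sort(strsplit(sr$table$subset[1], "+",
                                   fixed = TRUE)[[1]]),
                     sort(ds$planted_subset)))
  # calibration recovery (noiseless exact + noisy slope error)
  act <- gen_descriptor_dataset(seed, n_compounds = 14,
                                n_descriptors = 3,
                                planted_subset = c("D1", "D2", "D3"),
                                noise_sd = 0)$y
  dma0 <- gen_dma_scores(act, seed, noise_sd = 0)
  cal0 <- fit_calibration(dma0$dma, act)$calibration
  dma1 <- gen_dma_scores(act, seed, noise_sd = 0.3)
  cal1 <- fit_calibration(dma1$dma, act)$calibration
  calibration_check <- list(
    exact_slope = cal0$slope_m, exact_intercept = cal0$intercept_n,
    noisy_slope = cal1$slope_m,
    pass = abs(cal0$slope_m - (-0.18)) < 1e-8 &&
      abs(cal0$intercept_n - 0.75) < 1e-8)
  # Hill parameter recovery across replicates
  hill <- hill_recovery(seed, n_reps = n_hill_reps)
  hill_check <- list(median_ic50 = hill$median_ic50,
                     median_h = hill$median_h,
                     pass = round(hill$median_ic50) == 30 &&
                       round(hill$median_h, 1) == 2.8)
  # field-PLS recovery from a planted hotspot functional
  fld <- gen_aligned_molecules(seed, n_molecules = 8, noise_sd = 0)
  pf <- fit_pls(fld$x, fld$y, n_components = 2)
  pls_check <- list(r2 = pf$stats$r2, pass = pf$stats$r2 > 0.99)
  out <- list(subset_recovery = subset_check,
              calibration_recovery = calibration_check,
              hill_recovery = hill_check,
              pls_recovery = pls_check)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out,
                         file.path(output_dir, "synthetic_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Hill parameter recovery over seeded synthetic replicates
#'
#' Generates \code{n_reps} dose-response experiments from the
#' experimentally determined d-limonene Hill parameters (IC50 30 uM,
#' Hill coefficient 2.8, y_max 1) at the experimental concentrations
#' (0, 10, 30, 50, 100 uM) with 5\% multiplicative lognormal noise, fits
#' each with \code{\link{fit_hill}}, and reports the median fitted
#' parameters. Replicate \code{i} uses seed \code{seed * 1000 + i}.
#'
#' @param seed master seed.
#' @param n_reps number of replicates.
#' @param noise_cv multiplicative noise level.
#' @param y_max,ic50,h generative parameters.
#' @param concentrations doses in uM.
#' @return list: \code{median_ic50}, \code{median_h}, \code{ic50}
#'   (per-replicate vector), \code{h}, \code{n_converged}.
#' @export
hill_recovery <- function(seed = 1, n_reps = 200, noise_cv = 0.05,
                          y_max = 1, ic50 = 30, h = 2.8,
                          concentrations = c(0, 10, 30, 50, 100)) {
  fits <- lapply(seq_len(n_reps), function(i) {
    pts <- gen_dose_response(seed * 1000 + i,
                             concentrations = concentrations,
                             y_max = y_max, ic50 = ic50, h = h,
                             noise_cv = noise_cv)
    fit_hill(pts$concentration, pts$response)
  })
  ic <- vapply(fits, `[[`, numeric(1), "ic50")
  hh <- vapply(fits, `[[`, numeric(1), "hill_h")
  list(median_ic50 = stats::median(ic), median_h = stats::median(hh),
       ic50 = ic, h = hh,
       n_converged = sum(vapply(fits, `[[`, logical(1), "converged")))
}
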