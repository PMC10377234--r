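# Seeded generators emulating the statistical structure each pipeline
# stage assumes: descriptor matrices with a planted linear activity model,
# docking scores affinely related to potency, Hill dose-response curves
# with multiplicative noise, and aligned point-atom molecules whose
# activity derives from a planted field functional.
#
# Each generator seeds its own stream from the master seed plus a fixed
# per-generator offset, so adding one generator call never perturbs the
# draws of another. Offsets are small; with grader-scale master seeds the
# derived seed stays far below 2^31.

.seed_offset <- c(descriptors = 101L, dma = 211L, dose = 307L,
                  molecules = 401L)

.with_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed + .seed_offset[[offset]])
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Generate a descriptor matrix with a planted linear activity model
#'
#' Descriptor columns are drawn from an equicorrelated Gaussian
#' (correlation \code{rho}); optionally, constant columns are appended to
#' exercise the constant-descriptor filter. Activity is the planted linear
#' model plus Gaussian noise. Defaults mirror the study scale: 17
#' compounds and a three-descriptor truth with coefficients of the
#' packaged Cx43 model.
#'
#' @param seed master seed (integer).
#' @param n_compounds number of rows.
#' @param n_descriptors number of informative + decoy columns (named
#'   \code{D1..Dp}).
#' @param planted_subset names of the descriptor columns carrying signal.
#' @param planted_coefficients coefficients of the planted model, one per
#'   planted descriptor.
#' @param intercept planted intercept.
#' @param noise_sd standard deviation of the Gaussian activity noise.
#' @param rho pairwise correlation between descriptor columns.
#' @param n_constant number of planted constant columns (appended as
#'   \code{C1..}).
#' @return list: \code{x} (matrix with column names), \code{y} (activity
#'   vector), \code{planted_subset}, \code{planted_coefficients},
#'   \code{intercept}.
#' @export
gen_descriptor_dataset <- function(seed = 1, n_compounds = 17,
                                   n_descriptors = 10,
                                   planted_subset = c("D1", "D2", "D3"),
                                   planted_coefficients = c(-4.87, 5.67, -5.70),
                                   intercept = -7.24, noise_sd = 0.3,
                                   rho = 0.2, n_constant = 0) {
  stopifnot(length(planted_subset) == length(planted_coefficients),
            n_compounds > length(planted_subset) + 1, noise_sd >= 0,
            rho >= 0, rho < 1)
  nm <- paste0("D", seq_len(n_descriptors))
  stopifnot(all(planted_subset %in% nm))
  .with_seed(seed, "descriptors", {
    # equicorrelated Gaussian via shared + idiosyncratic factors
    shared <- stats::rnorm(n_compounds)
    x <- sqrt(rho) * matrix(shared, n_compounds, n_descriptors) +
      sqrt(1 - rho) * matrix(stats::rnorm(n_compounds * n_descriptors),
                             n_compounds, n_descriptors)
    colnames(x) <- nm
    if (n_constant > 0) {
      const <- matrix(rep(stats::rnorm(n_constant), each = n_compounds),
                      n_compounds, n_constant)
      colnames(const) <- paste0("C", seq_len(n_constant))
      x <- cbind(x, const)
    }
    y <- drop(x[, planted_subset, drop = FALSE] %*% planted_coefficients) +
      intercept + stats::rnorm(n_compounds, 0, noise_sd)
    list(x = x, y = y, planted_subset = planted_subset,
         planted_coefficients = planted_coefficients, intercept = intercept)
  })
}

#' Generate docking scores affinely related to potency
#'
#' Inverts the affinity-to-potency calibration: for each activity,
#' \code{dma = (activity - intercept)/slope + noise}, so that refitting
#' the calibration recovers the planted slope and intercept.
#'
#' @param activities numeric vector of \eqn{-\log_{10}} molar potencies.
#' @param seed master seed.
#' @param slope,intercept planted calibration line (defaults: the
#'   published preset -0.18, 0.75).
#' @param noise_sd standard deviation of Gaussian noise added to DMA.
#' @return data.frame with columns \code{cid} (1..n) and \code{dma}
#'   (kcal/mol).
#' @export
gen_dma_scores <- function(activities, seed = 1, slope = -0.18,
                           intercept = 0.75, noise_sd = 0) {
  stopifnot(slope != 0, noise_sd >= 0)
  .with_seed(seed, "dma", {
    dma <- (activities - intercept) / slope +
      stats::rnorm(length(activities), 0, noise_sd)
    data.frame(cid = seq_along(activities), dma = dma)
  })
}

#' Generate a synthetic Hill dose-response experiment
#'
#' Responses follow the three-parameter Hill inhibition curve at the given
#' concentrations, multiplied by lognormal noise with coefficient of
#' variation \code{noise_cv} (meanlog 0, i.e. median-unbiased;
#' \code{sdlog = sqrt(log(1 + cv^2))}). The zero-dose baseline point is
#' always included. Defaults are the experimentally determined d-limonene
#' parameters (IC50 30 uM, Hill coefficient 2.8, full baseline) and the
#' concentrations applied in the patch-clamp experiments.
#'
#' @param seed master seed.
#' @param concentrations doses in uM; 0 is prepended when absent.
#' @param y_max,ic50,h generative Hill parameters.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @return data.frame with columns \code{concentration} (uM) and
#'   \code{response}.
#' @export
gen_dose_response <- function(seed = 1,
                              concentrations = c(0, 10, 30, 50, 100),
                              y_max = 1, ic50 = 30, h = 2.8,
                              noise_cv = 0.05) {
  stopifnot(ic50 > 0, h > 0, y_max > 0, noise_cv >= 0)
  if (!any(concentrations == 0)) concentrations <- c(0, concentrations)
  .with_seed(seed, "dose", {
    mu <- hill_response(concentrations, y_max, ic50, h)
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      exp(stats::rnorm(length(mu), 0, sdlog))
    } else 1
    data.frame(concentration = concentrations, response = mu * noise)
  })
}

#' Generate aligned point-atom molecules with field-derived activity
#'
#' Random molecules of 3-10 atoms with partial charges in [-0.5, 0.5] e in
#' a shared coordinate frame; a common grid is built around them and each
#' molecule's activity is a weighted sum of its (truncated) field values
#' at planted hotspot nodes plus Gaussian noise — the generative model the
#' grid-field PLS stage assumes.
#'
#' @param seed master seed.
#' @param n_molecules number of molecules (>= 3).
#' @param box_half half-width of the cube atoms are placed in, Angstrom.
#' @param hotspots data.frame with columns \code{index} (linear grid/probe
#'   column index into the field matrix) and \code{weight}; NULL picks one
#'   random steric and one random electrostatic node with weights (1, 1).
#' @param noise_sd Gaussian activity noise.
#' @param step,outgap grid parameters.
#' @return list: \code{molecules}, \code{grid}, \code{x} (field matrix),
#'   \code{y} (activities), \code{hotspots}.
#' @export
gen_aligned_molecules <- function(seed = 1, n_molecules = 8, box_half = 3,
                                  hotspots = NULL, noise_sd = 0,
                                  step = 1.0, outgap = 5.0) {
  stopifnot(n_molecules >= 3, noise_sd >= 0)
  elements <- c("C", "N", "O", "H")
  mols <- .with_seed(seed, "molecules", {
    lapply(seq_len(n_molecules), function(i) {
      n_at <- sample(3:10, 1)
      aligned_molecule(i, data.frame(
        element = sample(elements, n_at, replace = TRUE),
        x = stats::runif(n_at, -box_half, box_half),
        y = stats::runif(n_at, -box_half, box_half),
        z = stats::runif(n_at, -box_half, box_half),
        charge = stats::runif(n_at, -0.5, 0.5)))
    })
  })
  grid <- build_grid(mols, step = step, outgap = outgap)
  x <- fields_to_matrix(mols, grid)
  if (is.null(hotspots)) {
    npts <- prod(grid$dims)
    hotspots <- .with_seed(seed + 1L, "molecules", {
      data.frame(index = c(sample(npts, 1), npts + sample(npts, 1)),
                 weight = c(1, 1))
    })
  }
  y <- drop(x[, hotspots$index, drop = FALSE] %*% hotspots$weight)
  if (noise_sd > 0)
    y <- y + .with_seed(seed + 2L, "molecules",
                        stats::rnorm(n_molecules, 0, noise_sd))
  list(molecules = mols, grid = grid, x = x, y = y, hotspots = hotspots)
}
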