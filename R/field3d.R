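# Grid-based 3D-QSAR: molecular interaction fields (MIFs) evaluated on a
# regular lattice around pre-aligned molecules, extreme-value truncation,
# PLS regression of the field matrix on activity, and coefficient-map
# export in OpenDX format.

#' Construct an aligned molecule
#'
#' A point-atom representation of a molecule in the shared alignment frame:
#' element, Cartesian coordinates (Angstrom), partial charge (e) and
#' per-atom Lennard-Jones parameters (minimum-energy distance in Angstrom,
#' well depth in kcal/mol). Alignment itself is out of scope; inputs are
#' assumed pre-aligned to a common frame.
#'
#' @param cid integer compound identifier.
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge}; optional \code{lj_rmin}, \code{lj_eps}
#'   (filled from \code{lj_parameters} when absent).
#' @return an \code{aligned_molecule}.
#' @export
aligned_molecule <- function(cid, atoms) {
  atoms <- as.data.frame(atoms)
  stopifnot(nrow(atoms) >= 1,
            all(c("element", "x", "y", "z", "charge") %in% names(atoms)),
            all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(is.finite(atoms$charge)))
  if (is.null(atoms$lj_rmin) || is.null(atoms$lj_eps)) {
    lj <- lj_parameters(atoms$element)
    if (is.null(atoms$lj_rmin)) atoms$lj_rmin <- lj$rmin
    if (is.null(atoms$lj_eps)) atoms$lj_eps <- lj$eps
  }
  structure(list(cid = cid, atoms = atoms), class = "aligned_molecule")
}

#' @export
print.aligned_molecule <- function(x, ...) {
  cat("aligned_molecule cid", x$cid, "-", nrow(x$atoms), "atom(s)\n")
  invisible(x)
}

#' Element-based Lennard-Jones parameter lookup
#'
#' Generic per-element minimum-energy distances (Angstrom) and well depths
#' (kcal/mol) in the style of classical force fields; used when the input
#' carries no per-atom parameters. Unknown elements fall back to a
#' carbon-like default.
#'
#' @param element character vector of element symbols.
#' @return list with numeric vectors \code{rmin} and \code{eps}.
#' @export
lj_parameters <- function(element) {
  tab <- list(H = c(2.40, 0.030), C = c(3.80, 0.107), N = c(3.65, 0.095),
              O = c(3.35, 0.122), F = c(3.20, 0.080), S = c(4.00, 0.250),
              Cl = c(3.90, 0.300), P = c(4.20, 0.200), B = c(3.60, 0.095))
  default <- c(3.80, 0.107)
  par <- t(vapply(element, function(e) {
    p <- tab[[e]]
    if (is.null(p)) default else p
  }, numeric(2)))
  list(rmin = unname(par[, 1]), eps = unname(par[, 2]))
}

#' Parameters of the interaction probe
#'
#' The steric probe is sp3-carbon-like; combination rules are arithmetic
#' mean for the minimum-energy distance and geometric mean for the well
#' depth. The electrostatic probe is a unit positive charge in vacuum
#' (dielectric constant 1); energies in kcal/mol use the Coulomb constant
#' 332.0637 kcal*Angstrom/(mol*e^2).
#'
#' @param probe_rmin probe LJ minimum-energy distance, Angstrom.
#' @param probe_eps probe LJ well depth, kcal/mol.
#' @param probe_charge probe charge, elementary charge units.
#' @param coulomb_k Coulomb constant in kcal*Angstrom/(mol*e^2).
#' @param clash_value energy (kcal/mol) assigned when a grid point
#'   coincides with an atom center (the positive truncation bound).
#' @return list of probe parameters.
#' @export
probe_params <- function(probe_rmin = 4.0, probe_eps = 0.107,
                         probe_charge = 1.0, coulomb_k = 332.0637,
                         clash_value = 30) {
  list(probe_rmin = probe_rmin, probe_eps = probe_eps,
       probe_charge = probe_charge, coulomb_k = coulomb_k,
       clash_value = clash_value)
}

#' Build the common grid box around a set of aligned molecules
#'
#' The axis-aligned joint bounding box of all atoms, expanded by
#' \code{outgap} on every side, discretized at \code{step}; the number of
#' nodes per axis is \code{floor(extent/step) + 1}.
#'
#' @param molecules list of \code{aligned_molecule}.
#' @param step grid spacing in Angstrom (default 1.0).
#' @param outgap padding beyond the bounding box in Angstrom (default 5.0).
#' @return a \code{grid_spec}: \code{origin}, \code{step}, \code{dims},
#'   \code{outgap}.
#' @export
build_grid <- function(molecules, step = 1.0, outgap = 5.0) {
  stopifnot(length(molecules) >= 1, step > 0, outgap >= 0)
  xyz <- do.call(rbind, lapply(molecules, function(m)
    as.matrix(m$atoms[c("x", "y", "z")])))
  lo <- apply(xyz, 2, min) - outgap
  hi <- apply(xyz, 2, max) + outgap
  dims <- pmax(1L, as.integer(floor((hi - lo) / step + 1e-9)) + 1L)
  structure(list(origin = unname(lo), step = step, dims = dims,
                 outgap = outgap),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, step %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$step,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Cartesian coordinates of all grid nodes
#'
#' Nodes are ordered x-fastest, then y, then z (linear index
#' \code{ix + nx*(iy + ny*iz)}, zero-based).
#'
#' @param grid a \code{grid_spec}.
#' @return numeric matrix (n_nodes x 3) of coordinates in Angstrom.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(i)
    grid$origin[i] + grid$step * (seq_len(grid$dims[i]) - 1))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

#' Compute a molecular interaction field on a grid
#'
#' For the steric probe, the 12-6 Lennard-Jones energy summed over atoms,
#' \eqn{\sum_i \epsilon_i [(r_{min,i}/r)^{12} - 2 (r_{min,i}/r)^6]}, with
#' probe/atom parameters combined by arithmetic mean (distance) and
#' geometric mean (depth); the minimum of each pair term is
#' \eqn{-\epsilon_i} at \eqn{r = r_{min,i}}. For the electrostatic probe,
#' the Coulomb energy of a unit positive charge in vacuum,
#' \eqn{k \sum_i q_i / r_i}, in kcal/mol. A grid node coinciding with an
#' atom center receives \code{params$clash_value} with a warning, except
#' for a zero-charge atom under the electrostatic probe, whose
#' contribution is zero everywhere.
#'
#' @param mol an \code{aligned_molecule}.
#' @param grid a \code{grid_spec} covering the molecule.
#' @param probe \code{"steric_vdw"} or \code{"electrostatic"}.
#' @param params probe parameters, see \code{\link{probe_params}}.
#' @return a \code{mif_field}: \code{grid}, \code{probe}, \code{values}
#'   (kcal/mol, x-fastest), \code{truncated_mask} (all FALSE until
#'   \code{\link{truncate_extremes}}).
#' @export
compute_mif <- function(mol, grid, probe = c("steric_vdw", "electrostatic"),
                        params = probe_params()) {
  probe <- match.arg(probe)
  pts <- unname(grid_points(grid))
  at <- mol$atoms
  n_pts <- nrow(pts)
  values <- numeric(n_pts)
  clash <- logical(n_pts)
  for (i in seq_len(nrow(at))) {
    d2 <- (pts[, 1] - at$x[i])^2 + (pts[, 2] - at$y[i])^2 +
          (pts[, 3] - at$z[i])^2
    r <- sqrt(d2)
    hit <- r < 1e-6
    r[hit] <- NA_real_
    if (probe == "steric_vdw") {
      rmin <- (params$probe_rmin + at$lj_rmin[i]) / 2
      eps <- sqrt(params$probe_eps * at$lj_eps[i])
      s6 <- (rmin / r)^6
      contrib <- eps * (s6^2 - 2 * s6)
      clash <- clash | hit
    } else {
      contrib <- params$coulomb_k * params$probe_charge * at$charge[i] / r
      # a zero-charge atom contributes nothing, even at zero distance
      clash <- clash | (hit & at$charge[i] != 0)
    }
    contrib[hit] <- 0
    values <- values + contrib
  }
  if (any(clash)) {
    warning("compute_mif: ", sum(clash), " grid node(s) coincide with an ",
            "atom center of cid ", mol$cid, "; set to clash value ",
            params$clash_value)
    values[clash] <- params$clash_value
  }
  structure(list(grid = grid, probe = probe, values = values,
                 truncated_mask = rep(FALSE, n_pts)),
            class = "mif_field")
}

#' Clamp extreme field values
#'
#' Steric fields are clamped from above only (the LJ well is shallow and
#' physically meaningful; the repulsive wall is not), electrostatic fields
#' symmetrically. Clamping rather than deleting keeps field vectors the
#' same length across molecules. Default bounds (steric +30 kcal/mol,
#' electrostatic +/-10 kcal/mol) follow common CoMFA practice.
#'
#' @param field a \code{mif_field}.
#' @param steric_max upper clamp for steric fields, kcal/mol.
#' @param elec_abs_max symmetric clamp for electrostatic fields, kcal/mol.
#' @return the field with \code{values} clamped and \code{truncated_mask}
#'   marking exactly the altered nodes.
#' @export
truncate_extremes <- function(field, steric_max = 30, elec_abs_max = 10) {
  stopifnot(inherits(field, "mif_field"), steric_max > 0, elec_abs_max > 0)
  v <- field$values
  if (field$probe == "steric_vdw") {
    mask <- v > steric_max
    v[mask] <- steric_max
  } else {
    mask <- abs(v) > elec_abs_max
    v <- pmin(pmax(v, -elec_abs_max), elec_abs_max)
  }
  field$values <- v
  field$truncated_mask <- field$truncated_mask | mask
  field
}

#' Assemble the PLS predictor matrix from molecule fields
#'
#' Computes (and by default truncates) the requested MIFs for every
#' molecule on a shared grid and concatenates them into one row per
#' molecule, probe blocks side by side. Column metadata (probe label and
#' grid) is attached so that fitted PLS coefficients can be mapped back
#' onto the grid.
#'
#' @param molecules list of \code{aligned_molecule}.
#' @param grid shared \code{grid_spec}; built from the molecules with
#'   default step/outgap when NULL.
#' @param probes character vector of probes to include.
#' @param truncate clamp extremes per \code{\link{truncate_extremes}}.
#' @param params probe parameters.
#' @param steric_max,elec_abs_max truncation bounds.
#' @return numeric matrix (molecules x grid nodes * probes) with
#'   attributes \code{probe} (per-column label) and \code{grid}.
#' @export
fields_to_matrix <- function(molecules, grid = NULL,
                             probes = c("steric_vdw", "electrostatic"),
                             truncate = TRUE, params = probe_params(),
                             steric_max = 30, elec_abs_max = 10) {
  stopifnot(length(molecules) >= 1)
  if (is.null(grid)) grid <- build_grid(molecules)
  rows <- lapply(molecules, function(m) {
    unlist(lapply(probes, function(p) {
      f <- compute_mif(m, grid, p, params)
      if (truncate) f <- truncate_extremes(f, steric_max, elec_abs_max)
      f$values
    }))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(molecules, function(m) as.character(m$cid),
                        character(1))
  attr(x, "probe") <- rep(probes, each = prod(grid$dims))
  attr(x, "grid") <- grid
  x
}

#' Fit a PLS regression of activity on field values
#'
#' Mean-centered PLS1 by NIPALS: successive score/loading pairs maximize
#' the covariance between predictor scores and the (deflated) response.
#' With as many components as the predictor rank on a full-rank problem,
#' the fit coincides with OLS. Component extraction stops early if the
#' residual covariance vanishes.
#'
#' @param x numeric predictor matrix (molecules x grid values), e.g. from
#'   \code{\link{fields_to_matrix}}.
#' @param y numeric activity vector (\eqn{-\log_{10}} molar).
#' @param n_components number of latent components; must be less than the
#'   number of molecules.
#' @return list with \code{model} (a \code{pls_model}: coefficients on the
#'   original predictor scale, centering terms, component count actually
#'   used, column metadata) and \code{stats} (\code{fit_stats} of fitted vs
#'   observed).
#' @export
fit_pls <- function(x, y, n_components) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, n >= 3)
  if (n_components >= n)
    stop("n_components (", n_components, ") must be < number of molecules (",
         n, ")")
  stopifnot(n_components >= 1)
  x_means <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_means)
  yc <- y - y_mean
  p_dim <- ncol(x)
  w_mat <- p_mat <- matrix(0, p_dim, n_components)
  q_vec <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_sc <- drop(xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p <- drop(crossprod(xc, t_sc)) / tt
    q <- sum(yc * t_sc) / tt
    xc <- xc - tcrossprod(t_sc, p)
    yc <- yc - q * t_sc
    w_mat[, a] <- w; p_mat[, a] <- p; q_vec[a] <- q
    used <- a
  }
  if (used == 0L) stop("response has no covariance with predictors")
  w_mat <- w_mat[, seq_len(used), drop = FALSE]
  p_mat <- p_mat[, seq_len(used), drop = FALSE]
  q_vec <- q_vec[seq_len(used)]
  # B = W (P'W)^-1 q maps centered predictors to centered response
  coef <- drop(w_mat %*% solve(crossprod(p_mat, w_mat), q_vec))
  model <- structure(list(n_components = used,
                          coefficients = coef,
                          x_means = x_means, y_mean = y_mean,
                          column_probe = attr(x, "probe"),
                          grid = attr(x, "grid")),
                     class = "pls_model")
  fitted <- pls_predict(model, x)
  list(model = model, stats = validation_stats(y, fitted, used),
       fitted = fitted)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$n_components, "component(s),",
      length(x$coefficients), "grid predictor(s)\n")
  invisible(x)
}

#' Predict activity from a field vector with a fitted PLS model
#'
#' @param model a \code{pls_model}.
#' @param x numeric vector (one molecule) or matrix (molecules in rows)
#'   of field values; length must match the training matrix.
#' @return numeric predictions on the \eqn{-\log_{10}} molar scale.
#' @export
pls_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$coefficients))
    stop("field vector length ", ncol(x), " does not match training length ",
         length(model$coefficients))
  drop(sweep(x, 2, model$x_means) %*% model$coefficients) + model$y_mean
}

#' Choose the PLS component count by leave-one-out q2
#'
#' Computes leave-one-out cross-validated q2 for each candidate component
#' count and returns the smallest count attaining the maximum.
#'
#' @param x predictor matrix.
#' @param y activity vector.
#' @param max_components largest count to consider (default 5, capped at
#'   n - 2).
#' @return list: \code{n_components}, \code{q2} (vector per candidate).
#' @export
select_pls_components <- function(x, y, max_components = 5) {
  n <- nrow(x)
  cand <- seq_len(min(max_components, n - 2))
  ss <- sum((y - mean(y))^2)
  q2 <- vapply(cand, function(a) {
    press <- sum(vapply(seq_len(n), function(i) {
      fit <- fit_pls(x[-i, , drop = FALSE], y[-i], a)
      (y[i] - pls_predict(fit$model, x[i, ]))^2
    }, numeric(1)))
    1 - press / ss
  }, numeric(1))
  list(n_components = cand[which.max(q2)], q2 = stats::setNames(q2, cand))
}

#' Extract a thresholded coefficient map for one probe
#'
#' Grid coefficients with absolute value below the cutoff are zeroed; what
#' remains corresponds to the isosurface-rendered "clouds" of beneficial
#' (positive) and detrimental (negative) field contributions. The default
#' cutoff is 0.0002 for the positive and -0.0002 for the negative
#' contribution.
#'
#' @param model a \code{pls_model} fitted on a matrix carrying column
#'   metadata (see \code{\link{fields_to_matrix}}).
#' @param probe which probe block to extract.
#' @param cutoff absolute coefficient threshold (default 0.0002).
#' @return a \code{coefficient_map}: \code{grid}, \code{probe},
#'   \code{values} (thresholded), \code{positive_cutoff},
#'   \code{negative_cutoff}.
#' @export
coefficient_map <- function(model, probe, cutoff = 2e-4) {
  stopifnot(inherits(model, "pls_model"), abs(cutoff) > 0)
  if (is.null(model$column_probe) || is.null(model$grid))
    stop("model carries no grid metadata; fit via fields_to_matrix()")
  sel <- model$column_probe == probe
  if (!any(sel)) stop("no columns for probe ", probe)
  v <- model$coefficients[sel]
  v[abs(v) < abs(cutoff)] <- 0
  structure(list(grid = model$grid, probe = probe, values = v,
                 positive_cutoff = abs(cutoff),
                 negative_cutoff = -abs(cutoff)),
            class = "coefficient_map")
}

#' Write a scalar grid in OpenDX format
#'
#' Minimal OpenDX scalar-field writer readable by the common molecular
#' viewers. Internal storage is x-fastest; the DX data block is emitted
#' z-fastest as the format requires.
#'
#' @param values numeric vector over grid nodes, x-fastest.
#' @param grid a \code{grid_spec}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dx <- function(values, grid, path) {
  d <- grid$dims
  stopifnot(length(values) == prod(d))
  arr <- array(values, dim = d)                 # [ix, iy, iz], x-fastest
  zfast <- as.vector(aperm(arr, c(3, 2, 1)))    # emit z-fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gjqsar coefficient map (OpenDX scalar grid)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$step),
    sprintf("delta 0.000000 %.6f 0.000000", grid$step),
    sprintf("delta 0.000000 0.000000 %.6f", grid$step),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  n <- length(zfast)
  idx <- seq(1, n, by = 3)
  lines <- vapply(idx, function(i)
    paste(formatC(zfast[i:min(i + 2, n)], format = "e", digits = 6),
          collapse = " "), character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Export thresholded PLS coefficient maps as OpenDX files
#'
#' One file per probe and sign: positive contributions (coefficients above
#' the cutoff) and negative contributions (below its negation) separately,
#' so viewers can color them independently.
#'
#' @param model a \code{pls_model} with grid metadata.
#' @param dir output directory (created if needed).
#' @param cutoff absolute coefficient threshold (default 0.0002).
#' @param prefix filename prefix.
#' @return character vector of the files written, named
#'   \code{<probe>_<positive|negative>}.
#' @export
export_coefficient_map <- function(model, dir, cutoff = 2e-4,
                                   prefix = "pls_coef") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probes <- unique(model$column_probe)
  out <- character(0)
  for (p in probes) {
    cm <- coefficient_map(model, p, cutoff)
    for (sgn in c("positive", "negative")) {
      v <- cm$values
      if (sgn == "positive") v[v < 0] <- 0 else v[v > 0] <- 0
      path <- file.path(dir, sprintf("%s_%s_%s.dx", prefix, p, sgn))
      write_dx(v, cm$grid, path)
      out[paste(p, sgn, sep = "_")] <- path
    }
  }
  out
}

#' Read pre-aligned molecules from an SDF (V2000) file
#'
#' Parses element symbols and coordinates from the atom block of each
#' molecule record. Partial charges must be supplied either as an SDF data
#' item (default tag \code{PARTIAL_CHARGES}: whitespace-separated values,
#' one per atom, in atom order) or via a sidecar CSV with columns
#' \code{cid}, \code{atom} (1-based index), \code{charge}; no charge model
#' is computed internally. Compound identifiers are taken from a
#' \code{PUBCHEM_CID}-style data item when present, otherwise from the
#' record order.
#'
#' @param path SDF file, V2000 connection tables.
#' @param charge_tag SDF data-item tag holding per-atom charges.
#' @param sidecar optional path to a charge sidecar CSV.
#' @param cid_tag SDF data-item tag holding the compound id.
#' @return list of \code{aligned_molecule}.
#' @export
read_sdf_v2000 <- function(path, charge_tag = "PARTIAL_CHARGES",
                           sidecar = NULL, cid_tag = "PUBCHEM_CID") {
  lines <- readLines(path)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) stop("no molecule records ($$$$) in ", path)
  starts <- c(1, utils::head(ends, -1) + 1)
  side <- NULL
  if (!is.null(sidecar)) {
    side <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    stopifnot(all(c("cid", "atom", "charge") %in% names(side)))
  }
  mols <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[starts[m]:ends[m]]
    counts <- blk[4]
    natoms <- as.integer(substr(counts, 1, 3))
    if (is.na(natoms) || natoms < 1)
      stop("bad counts line in record ", m, " of ", path)
    at_lines <- blk[5:(4 + natoms)]
    atoms <- data.frame(
      x = as.numeric(substr(at_lines, 1, 10)),
      y = as.numeric(substr(at_lines, 11, 20)),
      z = as.numeric(substr(at_lines, 21, 30)),
      element = trimws(substr(at_lines, 32, 34)),
      stringsAsFactors = FALSE)
    get_item <- function(tag) {
      hdr <- grep(paste0("^>.*<", tag, ">"), blk)
      if (length(hdr) == 0) return(NULL)
      body <- character(0)
      i <- hdr[1] + 1
      while (i <= length(blk) && nzchar(trimws(blk[i])) &&
             !startsWith(blk[i], ">")) {
        body <- c(body, blk[i]); i <- i + 1
      }
      body
    }
    cid_item <- get_item(cid_tag)
    cid <- if (!is.null(cid_item)) as.integer(trimws(cid_item[1])) else m
    chg <- get_item(charge_tag)
    if (!is.null(chg)) {
      charge <- as.numeric(strsplit(trimws(paste(chg, collapse = " ")),
                                    "\\s+")[[1]])
      if (length(charge) != natoms)
        stop("record ", m, ": ", length(charge), " charges for ",
             natoms, " atoms")
    } else if (!is.null(side)) {
      sel <- side[side$cid == cid, ]
      if (nrow(sel) != natoms)
        stop("sidecar has ", nrow(sel), " charges for cid ", cid,
             " (expected ", natoms, ")")
      charge <- sel$charge[order(sel$atom)]
    } else {
      stop("record ", m, " (cid ", cid, "): no '", charge_tag,
           "' data item and no sidecar CSV; partial charges are required")
    }
    atoms$charge <- charge
    mols[[m]] <- aligned_molecule(cid, atoms)
  }
  mols
}
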