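grid1 <- function(at, step = 1, outgap = 5)
  build_grid(list(one_atom_molecule(at = at)), step, outgap)

# a grid consisting of a single explicit probe position
point_grid <- function(p)
  structure(list(origin = p, step = 1, dims = c(1L, 1L, 1L), outgap = 0),
            class = "grid_spec")

test_that("grid construction: bounding box + outgap discretized at step", {
  g <- grid1(c(0, 0, 0))
  expect_equal(g$dims, c(11L, 11L, 11L))
  expect_equal(g$origin, c(-5, -5, -5))
  g0 <- grid1(c(0, 0, 0), outgap = 0)
  expect_equal(g0$dims, c(1L, 1L, 1L))
  two <- list(one_atom_molecule(at = c(0, 0, 0)),
              one_atom_molecule(at = c(4, 0, 0)))
  g2 <- build_grid(two, step = 1, outgap = 5)
  expect_equal(g2$dims, c(15L, 11L, 11L))
  # node coordinates are x-fastest
  pts <- grid_points(g0)
  expect_equal(dim(pts), c(1L, 3L))
  pts11 <- grid_points(grid1(c(0, 0, 0), outgap = 5))
  expect_equal(unname(pts11[2, ]), c(-4, -5, -5))
})

test_that("electrostatic probe: zero charges give a zero field, linearity", {
  mol0 <- one_atom_molecule(charge = 0)
  # off-lattice origin so no node coincides with the atom
  g <- structure(list(origin = c(-2.75, -2.75, -2.75), step = 1,
                      dims = c(6L, 6L, 6L), outgap = 0),
                 class = "grid_spec")
  f0 <- compute_mif(mol0, g, "electrostatic")
  expect_true(all(f0$values == 0))
  # Coulomb value at 2 A for q = +0.5 with unit positive probe
  molq <- one_atom_molecule(charge = 0.5)
  fq <- compute_mif(molq, point_grid(c(2, 0, 0)), "electrostatic")
  expect_equal(fq$values, 332.0637 * 0.5 / 2, tolerance = 1e-12)
  # doubling all charges doubles the field everywhere
  mol2q <- one_atom_molecule(charge = 1.0)
  f1 <- compute_mif(molq, g, "electrostatic")
  f2 <- compute_mif(mol2q, g, "electrostatic")
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
})

test_that("steric probe: Lennard-Jones identities", {
  mol <- one_atom_molecule(lj_rmin = 4.0, lj_eps = 0.4)
  rmin_c <- (4.0 + 4.0) / 2
  eps_c <- sqrt(0.107 * 0.4)
  # at the combined minimum-energy distance the energy is -(well depth)
  f <- compute_mif(mol, point_grid(c(rmin_c, 0, 0)), "steric_vdw")
  expect_equal(f$values, -eps_c, tolerance = 1e-12)
  # at twice that distance: eps * (2^-12 - 2 * 2^-6)
  f2 <- compute_mif(mol, point_grid(c(2 * rmin_c, 0, 0)), "steric_vdw")
  expect_equal(f2$values, eps_c * (2^-12 - 2 * 2^-6), tolerance = 1e-12)
  expect_equal(f2$values / eps_c, -0.0310, tolerance = 1e-3)
})

test_that("fields decay with distance from the molecule", {
  # steric field at far padded corners of a centered neutral pair
  mol <- aligned_molecule(1L, data.frame(
    element = "C", x = c(-0.5, 0.5), y = 0, z = 0,
    charge = c(-0.1, 0.1), lj_rmin = 4.0, lj_eps = 0.107))
  # steps chosen so no lattice node falls on an atom center
  g <- build_grid(list(mol), step = 3, outgap = 10)
  st <- compute_mif(mol, g, "steric_vdw")
  corner <- c(1, prod(g$dims))  # first and last node are box corners
  expect_lt(max(abs(st$values[corner])), 1e-3)
  # electrostatic: 1/r monopole terms cancel to a dipole tail; the field
  # at a 20 A-padded corner is small and smaller than at a 5 A one
  g20 <- build_grid(list(mol), step = 7, outgap = 20)
  e20 <- compute_mif(mol, g20, "electrostatic")
  g5 <- build_grid(list(mol), step = 1.7, outgap = 5)
  e5 <- compute_mif(mol, g5, "electrostatic")
  expect_lt(max(abs(e20$values[c(1, prod(g20$dims))])), 0.05)
  expect_lt(max(abs(e20$values[c(1, prod(g20$dims))])),
            max(abs(e5$values[c(1, prod(g5$dims))])))
})

test_that("a grid node on an atom center gets the clash value, with warning", {
  mol <- one_atom_molecule()
  expect_warning(f <- compute_mif(mol, point_grid(c(0, 0, 0)), "steric_vdw"),
                 "coincide")
  expect_equal(f$values, probe_params()$clash_value)
})

test_that("extreme-value truncation clamps and marks exactly those nodes", {
  mol <- one_atom_molecule()
  g <- structure(list(origin = c(-2.75, -2.75, -2.75), step = 1,
                      dims = c(6L, 6L, 6L), outgap = 0),
                 class = "grid_spec")
  f <- compute_mif(mol, g, "steric_vdw")
  f_in <- f
  f_in$values <- pmin(f_in$values, 5)
  t1 <- truncate_extremes(f_in)
  expect_equal(t1$values, f_in$values)
  expect_false(any(t1$truncated_mask))
  # one planted extreme point
  f$values[10] <- 1e6
  t2 <- truncate_extremes(f, steric_max = 30)
  expect_equal(t2$values[10], 30)
  expect_equal(which(t2$truncated_mask), which(f$values > 30))
  # electrostatic clamp is symmetric
  fe <- compute_mif(one_atom_molecule(charge = 0), g, "electrostatic")
  fe$values[3] <- -25
  te <- truncate_extremes(fe, elec_abs_max = 10)
  expect_equal(te$values[3], -10)
  expect_true(te$truncated_mask[3])
})

test_that("PLS with one component is exact on rank-1 predictors", {
  set.seed(21)
  x <- outer(rnorm(6), rnorm(10))
  y <- 3 * x[, 4]
  fit <- fit_pls(x, y, 1)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-10)
  expect_equal(unname(pls_predict(fit$model, x)), y, tolerance = 1e-8)
})

test_that("PLS with full components reproduces OLS on full-rank toys", {
  set.seed(12)
  for (rep in 1:3) {
    x <- matrix(rnorm(5 * 4), 5, 4)
    y <- rnorm(5)
    pls <- fit_pls(x, y, 4)
    ols <- stats::lm(y ~ x)
    expect_equal(unname(pls_predict(pls$model, x)), unname(fitted(ols)),
                 tolerance = 1e-8)
  }
})

test_that("PLS fitted values are invariant to a common column permutation", {
  set.seed(30)
  x <- matrix(rnorm(8 * 12), 8, 12)
  y <- rnorm(8)
  perm <- sample(ncol(x))
  f1 <- fit_pls(x, y, 3)
  f2 <- fit_pls(x[, perm], y, 3)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-10)
})

test_that("pls_predict centering identity, errors, and component cap", {
  set.seed(31)
  x <- matrix(rnorm(6 * 9), 6, 9)
  y <- rnorm(6)
  fit <- fit_pls(x, y, 2)
  # mean training field predicts the mean training activity
  expect_equal(unname(pls_predict(fit$model, colMeans(x))), mean(y),
               tolerance = 1e-10)
  expect_equal(unname(pls_predict(fit$model, x)), unname(fit$fitted))
  expect_error(pls_predict(fit$model, rnorm(4)), "does not match")
  expect_error(fit_pls(x, y, 6), "must be <")
})

test_that("leave-one-out component selection returns a sane count", {
  set.seed(33)
  g <- gen_aligned_molecules(5, n_molecules = 8, noise_sd = 0.05)
  sel <- select_pls_components(g$x, g$y, max_components = 4)
  expect_true(sel$n_components %in% 1:4)
  expect_equal(length(sel$q2), 4)
  expect_equal(sel$n_components,
               as.integer(names(sel$q2)[which.max(sel$q2)]))
})

test_that("coefficient maps threshold at the cutoff; default is 0.0002", {
  grid <- structure(list(origin = c(0, 0, 0), step = 1,
                         dims = c(2L, 2L, 1L), outgap = 0),
                    class = "grid_spec")
  model <- structure(list(
    n_components = 1L,
    coefficients = c(5e-4, -5e-4, 1e-4, -1e-4, 3e-4, 0, 0, 0),
    x_means = rep(0, 8), y_mean = 0,
    column_probe = rep(c("steric_vdw", "electrostatic"), each = 4),
    grid = grid), class = "pls_model")
  cm <- coefficient_map(model, "steric_vdw")
  expect_equal(cm$values, c(5e-4, -5e-4, 0, 0))
  expect_equal(cm$positive_cutoff, 2e-4)
  expect_equal(cm$negative_cutoff, -2e-4)
  expect_equal(eval(formals(coefficient_map)$cutoff), 2e-4)
  # a cutoff above the largest coefficient empties the map
  cm2 <- coefficient_map(model, "steric_vdw", cutoff = 1e-3)
  expect_true(all(cm2$values == 0))
  # export writes one file per probe and sign
  d <- withr::local_tempdir()
  files <- export_coefficient_map(model, d)
  expect_length(files, 4)
  expect_true(all(file.exists(files)))
})

test_that("OpenDX writer emits a well-formed z-fastest scalar grid", {
  grid <- structure(list(origin = c(1, 2, 3), step = 0.5,
                         dims = c(2L, 2L, 2L), outgap = 0),
                    class = "grid_spec")
  values <- 1:8  # x-fastest: v[ix + 2*(iy + 2*iz)], zero-based
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(values, grid, f)
  lines <- readLines(f)
  expect_true(any(grepl("gridpositions counts 2 2 2", lines)))
  expect_true(any(grepl("origin 1.000000 2.000000 3.000000", lines)))
  i0 <- grep("data follows", lines)
  i1 <- grep('attribute "dep"', lines)
  nums <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(i1 - 1)]),
                                     "\\s+")))
  # z-fastest output: (0,0,0), (0,0,1), (0,1,0), (0,1,1), (1,0,0), ...
  expect_equal(nums, c(1, 5, 3, 7, 2, 6, 4, 8))
})

test_that("SDF V2000 reader parses atoms, charges, and ids", {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, -0.3))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_test_sdf(f, coords, c("C", "O", "H"), c(0.1, -0.4, 0.3), cid = 22311L)
  mols <- read_sdf_v2000(f)
  expect_length(mols, 1)
  m <- mols[[1]]
  expect_equal(m$cid, 22311L)
  expect_equal(m$atoms$element, c("C", "O", "H"))
  expect_equal(as.matrix(m$atoms[c("x", "y", "z")]), coords,
               ignore_attr = TRUE)
  expect_equal(m$atoms$charge, c(0.1, -0.4, 0.3))
  # LJ parameters filled from the element table
  expect_equal(m$atoms$lj_rmin, lj_parameters(c("C", "O", "H"))$rmin)
  # missing charges: error without sidecar, resolved with one
  write_test_sdf(f, coords, c("C", "O", "H"), NULL, cid = 7L,
                 with_charges = FALSE)
  expect_error(read_sdf_v2000(f), "partial charges are required")
  side <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cid,atom,charge", "7,1,0.2", "7,2,-0.2", "7,3,0.0"), side)
  m2 <- read_sdf_v2000(f, sidecar = side)[[1]]
  expect_equal(m2$atoms$charge, c(0.2, -0.2, 0.0))
})
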