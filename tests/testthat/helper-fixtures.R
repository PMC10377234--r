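# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no binary files.

# A molecule with fully specified LJ parameters so probe energies have
# closed-form values: combined rmin = (4.0 + lj_rmin)/2, combined
# eps = sqrt(0.107 * lj_eps) under the default probe.
one_atom_molecule <- function(charge = 0, lj_rmin = 4.0, lj_eps = 0.4,
                              at = c(0, 0, 0)) {
  aligned_molecule(1L, data.frame(element = "C", x = at[1], y = at[2],
                                  z = at[3], charge = charge,
                                  lj_rmin = lj_rmin, lj_eps = lj_eps))
}

# Brute-force best-subset oracle, independent of the package's search
# path: plain lm() over every combination, R^2 from summary.lm.
oracle_subset_search <- function(x, y, k) {
  subsets <- utils::combn(colnames(x), k, simplify = FALSE)
  r2 <- vapply(subsets, function(s) {
    df <- data.frame(y = y, x[, s, drop = FALSE])
    summary(stats::lm(y ~ ., data = df))$r.squared
  }, numeric(1))
  key <- vapply(subsets, paste, character(1), collapse = "\r")
  ord <- order(-r2, key)
  list(subset = vapply(subsets, paste, character(1), collapse = "+")[ord],
       r2 = r2[ord])
}

# Write a minimal single-record V2000 SDF with a charge data item.
write_test_sdf <- function(path, coords, elements, charges, cid = 99L,
                           with_charges = TRUE) {
  n <- nrow(coords)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L)
  atom_lines <- vapply(seq_len(n), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], elements[i]),
    character(1))
  lines <- c("test molecule", "  gjqsar", "", counts, atom_lines,
             "M  END",
             "> <PUBCHEM_CID>", as.character(cid), "")
  if (with_charges)
    lines <- c(lines, "> <PARTIAL_CHARGES>",
               paste(format(charges), collapse = " "), "")
  writeLines(c(lines, "$$$$"), path)
  path
}
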