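# Descriptor columns used by the packaged Cx43 QSAR model, in model order.
CX43_DESCRIPTORS <- c("SpMin5_Bhm", "SpMax3_Bhi", "minHBd")

# Columns every compound table must carry. Prediction columns and the
# alignment score are optional per record (stored as NA when absent).
.required_columns <- c("cid", "name", "species", "assay", "neg_log_e_ic50")
.optional_columns <- c("pred_docking", "pred_qsar", "pred_3dqsar",
                       "o3a_score", "exclusion_flags")
.known_flags <- c("no_clear_3d_structure", "organoboron")

#' Load a compound dataset from CSV
#'
#' Reads a table of gap-junction inhibitors: one row per compound with its
#' PubChem CID, measured potency as \eqn{-\log_{10}} molar IC50, molecular
#' descriptor values, optional model predictions, and docking/alignment
#' exclusion flags.
#'
#' The CSV dialect is comma-separated, UTF-8, \code{.} decimal separator,
#' with a header row. Required columns: \code{cid}, \code{name},
#' \code{species} (\code{human}/\code{rat}), \code{assay}
#' (\code{patch_clamp}/\code{metabolic_communication}),
#' \code{neg_log_e_ic50}. Any further numeric columns not in the optional
#' set are treated as molecular descriptors. \code{exclusion_flags} holds
#' semicolon-separated flags from
#' \code{no_clear_3d_structure}/\code{organoboron}; empty means eligible
#' for docking-dependent and 3D stages.
#'
#' @param path path to a CSV file.
#' @return a \code{compound_dataset}: a \code{data.frame} with attribute
#'   \code{descriptor_names} giving the descriptor columns in order.
#' @examples
#' ds <- cx43_dataset()
#' nrow(ds)            # 17
#' descriptor_names(ds)
#' @export
load_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(exclusion_flags = "character"))
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$cid))
    stop("duplicate cid(s): ",
         paste(unique(df$cid[duplicated(df$cid)]), collapse = ", "))
  if (nrow(df) > 0) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$neg_log_e_ic50))))
    if (length(bad) > 0)
      stop("non-numeric potency (neg_log_e_ic50) in row(s): ",
           paste(bad, collapse = ", "), " (cid ",
           paste(df$cid[bad], collapse = ", "), ")")
    df$neg_log_e_ic50 <- as.numeric(df$neg_log_e_ic50)
  }
  if (is.null(df$exclusion_flags)) df$exclusion_flags <- rep("", nrow(df))
  df$exclusion_flags[is.na(df$exclusion_flags)] <- ""
  flags <- unlist(strsplit(df$exclusion_flags, ";", fixed = TRUE))
  unknown <- setdiff(flags, c(.known_flags, ""))
  if (length(unknown) > 0)
    stop("unknown exclusion flag(s): ", paste(unknown, collapse = ", "))
  desc <- setdiff(names(df), c(.required_columns, .optional_columns))
  desc <- desc[vapply(df[desc], is.numeric, logical(1)) | nrow(df) == 0]
  new_compound_dataset(df, descriptor_names = desc)
}

new_compound_dataset <- function(df, descriptor_names) {
  structure(df, descriptor_names = descriptor_names,
            class = c("compound_dataset", "data.frame"))
}

#' The packaged Cx43 inhibitor dataset
#'
#' Returns the curated 17-compound evaluation dataset: 16 literature Cx43
#' gap-junction inhibitors plus d-limonene, with measured
#' \eqn{-\log_{10}}(eIC50), the three Burden-matrix/E-state descriptors
#' used by the packaged QSAR model, per-compound predictions of the three
#' published models, alignment scores, and docking-eligibility flags
#' (digoxin and DGBA lack reliable 3D structures; 2-APB is an organoboron
#' compound with no docking parameters for boron).
#'
#' @return a \code{compound_dataset} with 17 records.
#' @export
cx43_dataset <- function() {
  load_dataset(system.file("extdata", "cx43_inhibitors.csv",
                           package = "gjqsar", mustWork = TRUE))
}

#' @export
print.compound_dataset <- function(x, ...) {
  cat("compound_dataset:", nrow(x), "record(s),",
      length(attr(x, "descriptor_names")), "descriptor(s)\n")
  NextMethod()
}

#' Descriptor column names of a compound dataset
#' @param ds a \code{compound_dataset}.
#' @return character vector of descriptor column names, in order.
#' @export
descriptor_names <- function(ds) attr(ds, "descriptor_names")

#' Keep only compounds eligible for docking and 3D alignment
#'
#' Drops every record carrying an exclusion flag (no reliable 3D structure,
#' or organoboron chemistry unsupported by the docking force field). On the
#' packaged dataset this removes digoxin, DGBA and 2-APB, leaving the 14
#' compounds used for docking and field-based modeling. Order is preserved
#' and the operation is idempotent.
#'
#' @param ds a \code{compound_dataset}.
#' @return the filtered \code{compound_dataset}.
#' @export
filter_docking_eligible <- function(ds) {
  flags <- ds$exclusion_flags
  if (is.null(flags)) flags <- rep("", nrow(ds))
  flags[is.na(flags)] <- ""
  keep <- !nzchar(flags)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_compound_dataset(out, descriptor_names = descriptor_names(ds))
}

#' Convert \eqn{-\log_{10}} molar potency to micromolar concentration
#'
#' @param x potency on the \eqn{-\log_{10}} molar scale (finite).
#' @return concentration in uM: \code{10^(-x) * 1e6}.
#' @examples
#' neg_log_to_micromolar(4.18)  # ~66 uM
#' @export
neg_log_to_micromolar <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  10^(-x) * 1e6
}

#' Convert micromolar concentration to \eqn{-\log_{10}} molar potency
#'
#' @param conc_um concentration in uM, strictly positive.
#' @return \eqn{-\log_{10}}(conc_um * 1e-6).
#' @examples
#' micromolar_to_neg_log(30)  # 4.52
#' @export
micromolar_to_neg_log <- function(conc_um) {
  stopifnot(is.numeric(conc_um))
  if (any(!is.finite(conc_um)) || any(conc_um <= 0))
    stop("concentration must be finite and > 0")
  -log10(conc_um * 1e-6)
}
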