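# Monoisotopic atomic masses (IUPAC/CODATA), hard-coded to 6 d.p. so that the
# derived deltas are exact and testable without a runtime chemistry dependency.
.atomic_mass <- c(
  H   = 1.007825,
  C12 = 12.000000,
  C13 = 13.003355,
  N14 = 14.003074,
  N15 = 15.000109,
  O16 = 15.994915
)

.delta_labels <- c("citrullination", "deamidation", "c13_isotope",
                   "n15_isotope", "isocyanic_acid_loss")

#' Monoisotopic mass delta of a modification or isotope substitution
#'
#' Citrullination converts the arginine side-chain imine (=NH) to a carbonyl
#' (=O), a net gain of O and loss of NH; deamidation of Asn/Gln produces the
#' identical elemental change, which is why the two cannot be separated by
#' precursor mass alone. The natural heavy-isotope substitutions (13C, 15N)
#' produce nearby but distinct shifts, and MS/MS of citrullinated peptides
#' shows a diagnostic neutral loss of isocyanic acid (HNCO).
#'
#' @param name one of `"citrullination"`, `"deamidation"`, `"c13_isotope"`,
#'   `"n15_isotope"`, `"isocyanic_acid_loss"`.
#' @return list with `name` and `delta` (Da). The isocyanic-acid loss is
#'   reported as a positive magnitude.
#' @examples
#' modification_delta("citrullination")$delta  # ~0.9840 Da
#' @export
modification_delta <- function(name) {
  if (length(name) != 1L || !is.character(name) || !(name %in% .delta_labels)) {
    stop("unknown modification label '", paste(name, collapse = ","),
         "'; supported: ", paste(.delta_labels, collapse = ", "))
  }
  m <- .atomic_mass
  delta <- switch(name,
    citrullination      = m[["O16"]] - m[["N14"]] - m[["H"]],
    deamidation         = m[["O16"]] - m[["N14"]] - m[["H"]],
    c13_isotope         = m[["C13"]] - m[["C12"]],
    n15_isotope         = m[["N15"]] - m[["N14"]],
    isocyanic_acid_loss = m[["H"]] + m[["C12"]] + m[["N14"]] + m[["O16"]]
  )
  list(name = name, delta = unname(delta))
}

#' Table of all supported mass deltas
#'
#' @return data.frame with columns `name` and `delta_da`.
#' @export
mass_delta_table <- function() {
  data.frame(
    name = .delta_labels,
    delta_da = vapply(.delta_labels, function(x) modification_delta(x)$delta,
                      numeric(1)),
    row.names = NULL
  )
}

#' Classify a small observed precursor-mass shift
#'
#' Decides whether an observed ~1 Da shift is consistent with the
#' citrullination/deamidation modification mass, a 13C substitution, or a 15N
#' substitution, at a stated mass tolerance (default 0.002 Da, the precursor
#' accuracy the discrimination argument rests on). If more than one reference
#' delta lies within tolerance, or none does, the shift is reported as
#' `"ambiguous"` rather than silently assigned to the nearest reference.
#'
#' @param observed observed mass difference in Da (finite scalar).
#' @param tolerance tolerance in Da, > 0. Default 0.002.
#' @return list with `label` (`"modification"`, `"isotope_c13"`,
#'   `"isotope_n15"` or `"ambiguous"`), `observed_delta`, `tolerance` and
#'   `matches` (labels within tolerance).
#' @export
classify_shift <- function(observed, tolerance = 0.002) {
  if (length(observed) != 1L || !is.numeric(observed) || !is.finite(observed))
    stop("observed mass shift must be a single finite number")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be a single positive number (Da)")
  refs <- c(
    modification = modification_delta("citrullination")$delta,
    isotope_c13  = modification_delta("c13_isotope")$delta,
    isotope_n15  = modification_delta("n15_isotope")$delta
  )
  within <- names(refs)[abs(observed - refs) <= tolerance]
  label <- if (length(within) == 1L) within else "ambiguous"
  list(label = label, observed_delta = observed, tolerance = tolerance,
       matches = within)
}

#' Write the mass-delta constants to a TSV file
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mass_delta_table <- function(path) {
  utils::write.table(mass_delta_table(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
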