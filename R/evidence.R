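# MaxQuant-style evidence table IO.

.evidence_columns <- c(
  peptide_sequence = "peptide_sequence",
  protein_id       = "protein_id",
  residue          = "residue",
  position         = "position",
  mod_label        = "mod_label",
  localization_prob = "localization_prob",
  intensity        = "intensity",
  condition        = "condition",
  replicate        = "replicate",
  fraction         = "fraction",
  mass_error       = "mass_error",
  neutral_loss     = "neutral_loss"
)

#' Read a MaxQuant-style evidence table of peptide-spectrum matches
#'
#' Parses a tab-separated evidence table (one row per modified-peptide
#' observation) into a PSM data frame. Column names follow the package's
#' evidence dialect by default; a named `column_map` can translate other
#' dialects (names = internal names, values = file column names). Malformed
#' rows are kept with repaired fields and counted, not silently dropped:
#' an empty/unparsable localization probability becomes 0 and is counted in
#' the parse log.
#'
#' @param path path to a tab-separated evidence file with a header row.
#' @param column_map optional named character vector mapping internal column
#'   names to the file's column names.
#' @return data.frame of PSM records with attribute `"parse_log"` (list with
#'   `n_rows`, `n_bad_localization`, `n_bad_intensity`).
#' @export
read_evidence <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("evidence file is empty: ", path)
  cols <- .evidence_columns
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  missing_cols <- cols[!(cols %in% names(raw))]
  if (length(missing_cols))
    stop("evidence file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  num <- function(x) suppressWarnings(as.numeric(x))
  loc <- num(raw[[cols["localization_prob"]]])
  n_bad_loc <- sum(is.na(loc))
  loc[is.na(loc)] <- 0
  inten <- num(raw[[cols["intensity"]]])
  n_bad_int <- sum(is.na(inten))

  psm <- data.frame(
    peptide_sequence  = raw[[cols["peptide_sequence"]]],
    protein_id        = raw[[cols["protein_id"]]],
    residue           = raw[[cols["residue"]]],
    position          = as.integer(num(raw[[cols["position"]]])),
    mod_label         = raw[[cols["mod_label"]]],
    localization_prob = loc,
    intensity         = inten,
    condition         = raw[[cols["condition"]]],
    replicate         = as.integer(num(raw[[cols["replicate"]]])),
    fraction          = as.integer(num(raw[[cols["fraction"]]])),
    mass_error        = num(raw[[cols["mass_error"]]]),
    neutral_loss      = raw[[cols["neutral_loss"]]] %in% c("1", "TRUE", "true", "T"),
    stringsAsFactors  = FALSE
  )
  bad <- psm$localization_prob < 0 | psm$localization_prob > 1
  if (any(bad)) stop("localization probabilities outside [0,1] in rows: ",
                     paste(utils::head(which(bad)), collapse = ", "))
  attr(psm, "parse_log") <- list(n_rows = nrow(psm),
                                 n_bad_localization = n_bad_loc,
                                 n_bad_intensity = n_bad_int)
  psm
}

#' Write a PSM data frame as an evidence TSV
#'
#' @param psm PSM data frame as produced by [read_evidence()] or the
#'   synthetic generator.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_evidence <- function(psm, path) {
  out <- psm
  out$neutral_loss <- as.integer(out$neutral_loss)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
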