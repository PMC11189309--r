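# Parsing of published RA-autoantigen citrullination-site tables
# (gene, printed site count, UniProt accession, semicolon-separated
# positions) and internal consistency checks.

#' Read an RA-autoantigen citrullination-site table
#'
#' Expects a TSV with columns `gene`, `n_sites` (printed site count),
#' `uniprot`, `positions` (semicolon-separated R-prefixed positions, e.g.
#' `"R10;R14"`).
#'
#' @param path TSV path; defaults to the bundled transcription of the
#'   published RA-autoantigen table.
#' @return data.frame with an added `n_listed` column (number of positions
#'   actually listed) and `consistent` (`n_listed == n_sites`).
#' @export
read_autoantigen_table <- function(path = system.file("extdata",
                                                      "ra_autoantigen_sites.tsv",
                                                      package = "citscape")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "n_sites", "uniprot", "positions") %in% names(tab)))
  pos_list <- parse_site_positions(tab$positions)
  tab$n_listed <- lengths(pos_list)
  tab$consistent <- tab$n_listed == tab$n_sites
  attr(tab, "positions_parsed") <- pos_list
  tab
}

#' Parse semicolon-separated R-position strings
#'
#' @param x character vector like `"R10;R14;R51"` (whitespace tolerated).
#' @return list of integer position vectors.
#' @export
parse_site_positions <- function(x) {
  lapply(strsplit(x, ";"), function(parts) {
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    as.integer(sub("^R", "", parts))
  })
}

#' Unique-site and protein counts of a site table
#'
#' @param sites data.frame with `protein_id` and `position`.
#' @return list with `n_sites` (unique protein/position pairs) and
#'   `n_proteins`.
#' @export
count_sites_proteins <- function(sites) {
  keys <- unique(site_key(sites$protein_id, sites$position))
  list(n_sites = length(keys), n_proteins = length(unique(sites$protein_id)))
}
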