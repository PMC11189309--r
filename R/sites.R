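# Localization-probability filtering of PSMs into quantified citrullination
# sites, site-matrix assembly, normalization/imputation and core-set calls.
#
# Threshold semantics are strict ">" throughout: a site is identified only if
# at least one supporting PSM has localization probability > id_threshold
# (default 0.90), and intensities aggregate only PSMs with localization
# > quant_threshold (default 0.75).

#' Canonical site key
#' @param protein_id,position protein accession(s) and 1-based position(s).
#' @return character vector `"protein:position"`.
#' @export
site_key <- function(protein_id, position) paste(protein_id, position, sep = ":")

#' Build citrullination sites from PSM records
#'
#' Applies the two-tier localization filter: identification requires at least
#' one PSM above `id_threshold`; quantification pools all PSMs above
#' `quant_threshold` at the same protein/position. Citrullination PSMs whose
#' stated residue is not arginine are excluded and counted as inconsistent
#' (deamidation of Asn/Gln has the same precursor mass shift, so residue
#' identity plus localization is the only thing separating the two).
#'
#' @param psm PSM data frame (see [read_evidence()]).
#' @param id_threshold localization probability required for site
#'   identification (exclusive). Default 0.90.
#' @param quant_threshold localization probability required for a PSM to
#'   contribute intensity (exclusive). Default 0.75.
#' @return data.frame of sites (`protein_id`, `position`, `site`,
#'   `best_localization`, `n_psms`, `neutral_loss_fraction`) with attributes
#'   `"quant"` (long data.frame site x condition x replicate -> intensity)
#'   and `"n_inconsistent"` (citrullination PSMs not on R).
#' @export
build_sites <- function(psm, id_threshold = 0.90, quant_threshold = 0.75) {
  stopifnot(id_threshold >= quant_threshold)
  cit <- psm[psm$mod_label == "citrullination", , drop = FALSE]
  inconsistent <- cit$residue != "R"
  n_inconsistent <- sum(inconsistent)
  cit <- cit[!inconsistent, , drop = FALSE]

  cit$site <- site_key(cit$protein_id, cit$position)
  id_ok <- tapply(cit$localization_prob, cit$site, max)
  keep_sites <- names(id_ok)[id_ok > id_threshold]
  cit <- cit[cit$site %in% keep_sites, , drop = FALSE]

  if (nrow(cit) == 0L) {
    sites <- data.frame(protein_id = character(), position = integer(),
                        site = character(), best_localization = numeric(),
                        n_psms = integer(), neutral_loss_fraction = numeric())
    attr(sites, "quant") <- data.frame(site = character(),
                                       condition = character(),
                                       replicate = integer(),
                                       intensity = numeric())
    attr(sites, "n_inconsistent") <- n_inconsistent
    return(sites)
  }

  ord <- order(cit$site)
  cit <- cit[ord, , drop = FALSE]
  sites <- do.call(rbind, lapply(split(cit, cit$site), function(d) {
    data.frame(protein_id = d$protein_id[1], position = d$position[1],
               site = d$site[1],
               best_localization = max(d$localization_prob),
               n_psms = nrow(d),
               neutral_loss_fraction = mean(d$neutral_loss),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  quant_psm <- cit[cit$localization_prob > quant_threshold, , drop = FALSE]
  quant <- aggregate_intensity(quant_psm)
  attr(sites, "quant") <- quant
  attr(sites, "n_inconsistent") <- n_inconsistent
  sites
}

#' Aggregate PSM intensities per site, condition and replicate
#'
#' Replicate intensity is the sum of all contributing PSM intensities (the
#' sites-table convention); a replicate with no PSM simply has no row, i.e.
#' it is missing, never zero.
#'
#' @param psm PSM data frame restricted to quantification-grade PSMs; must
#'   carry a `site` column or `protein_id`/`position` to derive one.
#' @return long data.frame `site`, `condition`, `replicate`, `intensity`.
#' @export
aggregate_intensity <- function(psm) {
  if (is.null(psm$site)) psm$site <- site_key(psm$protein_id, psm$position)
  if (any(psm$intensity < 0, na.rm = TRUE)) stop("negative PSM intensity")
  if (nrow(psm) == 0L)
    return(data.frame(site = character(), condition = character(),
                      replicate = integer(), intensity = numeric()))
  agg <- stats::aggregate(intensity ~ site + condition + replicate,
                          data = psm, FUN = sum)
  agg[order(agg$site, agg$condition, agg$replicate), , drop = FALSE]
}

#' Assemble the site x (condition, replicate) intensity matrix
#'
#' @param quant long quantification data.frame from [build_sites()]'s
#'   `"quant"` attribute.
#' @param log2_transform log2-transform intensities (default TRUE).
#' @return list of class `"site_matrix"`: `values` (matrix, NA = missing),
#'   `observed` (logical matrix, TRUE where an observed PSM supports the
#'   value), `condition` (character vector, one per column).
#' @export
site_matrix <- function(quant, log2_transform = TRUE) {
  cols <- unique(quant[c("condition", "replicate")])
  cols <- cols[order(cols$condition, cols$replicate), , drop = FALSE]
  col_id <- paste(cols$condition, cols$replicate, sep = ".")
  sites <- sort(unique(quant$site))
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(col_id),
              dimnames = list(sites, col_id))
  idx <- cbind(match(quant$site, sites),
               match(paste(quant$condition, quant$replicate, sep = "."), col_id))
  m[idx] <- if (log2_transform) log2(quant$intensity) else quant$intensity
  structure(list(values = m, observed = !is.na(m), condition = cols$condition),
            class = "site_matrix")
}

#' Median-center and impute a site matrix
#'
#' Each column is median-centered (normalization within condition); missing
#' values are then drawn from a down-shifted normal distribution per column
#' (mean = observed column mean - `downshift` x column s.d., s.d. =
#' `width` x column s.d.), the standard left-censored imputation for
#' label-free proteomics. The observed mask is preserved so imputed values
#' can always be distinguished from measurements.
#'
#' @param sm a `"site_matrix"` object.
#' @param seed integer seed for the imputation draws.
#' @param width imputation width as a fraction of the column s.d. (default 0.3).
#' @param downshift imputation down-shift in column s.d. units (default 1.8).
#' @return a `"site_matrix"` with no NA values and unchanged `observed` mask.
#' @export
normalize_impute <- function(sm, seed, width = 0.3, downshift = 1.8) {
  stopifnot(inherits(sm, "site_matrix"))
  m <- sm$values
  obs <- sm$observed
  if (any(colSums(obs) == 0L))
    stop("column(s) with zero observed values: ",
         paste(colnames(m)[colSums(obs) == 0L], collapse = ", "))
  for (j in seq_len(ncol(m)))
    m[, j] <- m[, j] - stats::median(m[obs[, j], j])
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(m))) {
    miss <- !obs[, j]
    if (!any(miss)) next
    mu <- mean(m[obs[, j], j])
    s <- stats::sd(m[obs[, j], j])
    if (!is.finite(s) || s == 0) s <- 1e-6
    m[miss, j] <- stats::rnorm(sum(miss), mean = mu - downshift * s,
                               sd = width * s)
  }
  structure(list(values = m, observed = obs, condition = sm$condition),
            class = "site_matrix")
}

#' Sites observed in every listed condition (core citrullinome)
#'
#' @param sm a `"site_matrix"` object (imputed or not; only the observed
#'   mask is used).
#' @param conditions condition labels that must each carry at least one
#'   observed (non-imputed) value; at least 2.
#' @return character vector of site keys.
#' @export
core_sites <- function(sm, conditions) {
  stopifnot(inherits(sm, "site_matrix"), length(conditions) >= 2L)
  unknown <- setdiff(conditions, unique(sm$condition))
  if (length(unknown)) stop("unknown condition(s): ",
                            paste(unknown, collapse = ", "))
  ok <- vapply(conditions, function(cond) {
    rowSums(sm$observed[, sm$condition == cond, drop = FALSE]) >= 1L
  }, logical(nrow(sm$values)))
  rownames(sm$values)[rowSums(ok) == length(conditions)]
}

#' Neutral-loss summary across citrullination PSMs
#'
#' Share of supporting PSMs exhibiting the diagnostic isocyanic-acid neutral
#' loss, by spectrum count and by intensity, overall and per site.
#'
#' @param psm PSM data frame restricted to citrullination PSMs supporting
#'   built sites (must have `neutral_loss` and `intensity`).
#' @return list with `count_share`, `intensity_share` and `per_site`
#'   (data.frame `site`, `count_share`, `intensity_share`).
#' @export
neutral_loss_summary <- function(psm) {
  if (nrow(psm) == 0L) stop("no PSMs supplied")
  if (is.null(psm$site)) psm$site <- site_key(psm$protein_id, psm$position)
  per_site <- do.call(rbind, lapply(split(psm, psm$site), function(d) {
    data.frame(site = d$site[1],
               count_share = mean(d$neutral_loss),
               intensity_share = sum(d$intensity[d$neutral_loss]) /
                 sum(d$intensity),
               stringsAsFactors = FALSE)
  }))
  rownames(per_site) <- NULL
  list(count_share = mean(psm$neutral_loss),
       intensity_share = sum(psm$intensity[psm$neutral_loss]) / sum(psm$intensity),
       per_site = per_site)
}

#' Write a sites table and site matrix to TSV
#'
#' @param sites sites data.frame from [build_sites()].
#' @param sm optional `"site_matrix"`.
#' @param sites_path,matrix_path output paths (`matrix_path` ignored when
#'   `sm` is NULL).
#' @return invisibly, the paths written.
#' @export
write_sites <- function(sites, sites_path, sm = NULL, matrix_path = NULL) {
  utils::write.table(sites, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sm) && !is.null(matrix_path)) {
    out <- data.frame(site = rownames(sm$values), sm$values,
                      check.names = FALSE)
    utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(sites_path, matrix_path))
}
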