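# Peptide-microarray reactivity pipeline: replicate collapse, log2, chip-pair
# normalization, citrullinated-vs-baseline ratios, z-scores, citrulline
# spacing and abundance-stratified reactivity enrichment.
#
# Citrulline is encoded as lowercase "r" inside otherwise uppercase peptide
# sequences; the baseline counterpart reverts every "r" to "R".

CIT_CHAR <- "r"

#' Baseline (unmodified) counterpart of a citrullinated peptide
#' @param sequence peptide sequence(s) with citrulline as lowercase "r".
#' @return sequence(s) with citrullines reverted to arginine.
#' @export
baseline_sequence <- function(sequence) gsub(CIT_CHAR, "R", sequence, fixed = TRUE)

#' 0-based citrulline offsets within a peptide
#' @param sequence peptide sequence(s).
#' @return list of integer vectors of 0-based offsets from the N terminus.
#' @export
citrulline_offsets <- function(sequence) {
  lapply(gregexpr(CIT_CHAR, sequence, fixed = TRUE), function(m) {
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  })
}

#' Collapse replicate spots to one value per sequence per chip
#'
#' Median of the raw mean intensities across replicate prints of the same
#' sequence on the same chip, then log2. Raw intensities must be positive
#' (the raw-mean readout guarantees no zero reads). Collapsing is
#' idempotent: applying it to already collapsed values is the identity.
#'
#' @param spots data.frame with `chip_id`, `fluid`, `sequence`, `raw_mean`.
#' @return data.frame: `chip_id`, `fluid`, `sequence`, `log2_intensity`.
#' @export
collapse_spots <- function(spots) {
  stopifnot(all(c("chip_id", "fluid", "sequence", "raw_mean") %in% names(spots)))
  if (any(spots$raw_mean <= 0)) stop("non-positive raw_mean intensities")
  agg <- stats::aggregate(raw_mean ~ chip_id + fluid + sequence, data = spots,
                          FUN = stats::median)
  agg$log2_intensity <- log2(agg$raw_mean)
  agg$raw_mean <- NULL
  agg[order(agg$fluid, agg$chip_id, agg$sequence), , drop = FALSE]
}

#' Normalize a pair of chips treated with the same fluid
#'
#' Additive shift in log2 space bringing both chips' global medians to their
#' common mean-of-medians (symmetric centering); within-chip differences are
#' preserved exactly.
#'
#' @param a,b numeric log2-intensity vectors of the two chips (non-empty).
#' @return list: `a`, `b` (shifted values), `shift_a`, `shift_b`.
#' @export
normalize_chip_pair <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty chip")
  target <- (stats::median(a) + stats::median(b)) / 2
  list(a = a + (target - stats::median(a)),
       b = b + (target - stats::median(b)),
       shift_a = target - stats::median(a),
       shift_b = target - stats::median(b))
}

.normalize_collapsed <- function(collapsed) {
  out <- collapsed
  for (fl in unique(collapsed$fluid)) {
    chips <- sort(unique(collapsed$chip_id[collapsed$fluid == fl]))
    if (length(chips) != 2L)
      stop("fluid '", fl, "' must have exactly two chips, found ",
           length(chips))
    ia <- out$fluid == fl & out$chip_id == chips[1]
    ib <- out$fluid == fl & out$chip_id == chips[2]
    nrm <- normalize_chip_pair(out$log2_intensity[ia], out$log2_intensity[ib])
    out$log2_intensity[ia] <- nrm$a
    out$log2_intensity[ib] <- nrm$b
  }
  out
}

#' Per-pair, per-fluid reactivity ratios and z-scores
#'
#' After chip-pair normalization, every citrullinated peptide is matched to
#' its baseline counterpart on the same chip; the pair ratio is cit log2 -
#' baseline log2. Pairs present on both chips of a fluid (the controls) take
#' the median ratio across chips. Finally each fluid's ratios are
#' standardized to z-scores (mean 0, s.d. 1 across all pairs of that fluid).
#' Citrullinated peptides without a baseline counterpart on the same chip
#' are dropped and counted.
#'
#' @param spots raw spot data.frame (see [collapse_spots()]).
#' @return data.frame `cit_sequence`, `baseline`, `fluid`, `ratio`, `z` with
#'   attribute `"n_unmatched"`.
#' @export
pair_statistics <- function(spots) {
  collapsed <- .normalize_collapsed(collapse_spots(spots))
  is_cit <- grepl(CIT_CHAR, collapsed$sequence, fixed = TRUE)
  cit <- collapsed[is_cit, , drop = FALSE]
  base <- collapsed[!is_cit, , drop = FALSE]
  base_key <- paste(base$chip_id, base$sequence, sep = "\r")
  idx <- match(paste(cit$chip_id, baseline_sequence(cit$sequence), sep = "\r"),
               base_key)
  n_unmatched <- sum(is.na(idx))
  cit <- cit[!is.na(idx), , drop = FALSE]
  cit$ratio <- cit$log2_intensity - base$log2_intensity[idx[!is.na(idx)]]
  # median across the chips of a fluid for pairs present on both
  agg <- stats::aggregate(ratio ~ fluid + sequence, data = cit,
                          FUN = stats::median)
  agg$z <- stats::ave(agg$ratio, agg$fluid,
                      FUN = function(x) (x - mean(x)) / stats::sd(x))
  out <- data.frame(cit_sequence = agg$sequence,
                    baseline = baseline_sequence(agg$sequence),
                    fluid = agg$fluid, ratio = agg$ratio, z = agg$z,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fluid, out$cit_sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Spacing between citrullines in multi-citrullinated peptides
#'
#' For peptides carrying >= 2 citrullines, the gaps are the numbers of
#' residues between consecutive citrullines (offsets 4 and 6 -> gap 1).
#' Returns the gap histogram for the `top_n` most reactive pairs (highest z
#' within the given fluid, ties broken by sequence) against all
#' multi-citrullinated pairs.
#'
#' @param pairs pair-statistics data.frame for one fluid (see
#'   [pair_statistics()]).
#' @param top_n number of most-reactive pairs in the foreground set.
#' @return list: `top` and `all` (integer gap count tables), `n_multi`.
#' @export
spacing_profile <- function(pairs, top_n) {
  offs <- citrulline_offsets(pairs$cit_sequence)
  multi <- lengths(offs) >= 2L
  pairs <- pairs[multi, , drop = FALSE]
  offs <- offs[multi]
  if (nrow(pairs) == 0L) stop("no multi-citrullinated pairs")
  if (top_n > nrow(pairs)) {
    warning("top_n exceeds available multi-citrullinated pairs; clipped")
    top_n <- nrow(pairs)
  }
  gaps <- function(o) unlist(lapply(o, function(x) diff(x) - 1L))
  ord <- order(-pairs$z, pairs$cit_sequence)
  top_idx <- ord[seq_len(top_n)]
  list(top = table(gaps(offs[top_idx])), all = table(gaps(offs)),
       n_multi = nrow(pairs))
}

#' Reactivity enrichment across MS-abundance strata
#'
#' Tests, for each abundance stratum (e.g. the top 1,000 / 2,000 / 3,000
#' most abundant citrullination sites in the MS screen), whether stratum
#' membership is enriched among the most reactive microarray pairs. The
#' top-reactivity set is the highest-z fraction of pairs within the fluid
#' (default top quartile). The relative score is the signed -log10 Fisher p,
#' positive when the stratum is over-represented among reactive pairs.
#'
#' @param pairs pair-statistics data.frame for one fluid, with a
#'   `cit_sequence` column mapping 1:1 to MS sites via `site_of`.
#' @param site_of named character vector mapping cit_sequence -> site key.
#' @param abundance named numeric vector of MS abundances per site key.
#' @param strata integer vector of stratum sizes (top-N by abundance).
#' @param reactive_fraction fraction of pairs forming the top-reactivity set
#'   (default 0.25).
#' @return data.frame: `stratum`, `overlap`, `odds_ratio`, `p`, `score`.
#' @export
reactivity_by_abundance <- function(pairs, site_of, abundance,
                                    strata = c(1000L, 2000L, 3000L),
                                    reactive_fraction = 0.25) {
  sites <- unname(site_of[pairs$cit_sequence])
  ab <- abundance[sites]
  ok <- !is.na(sites) & !is.na(ab)
  pairs <- pairs[ok, , drop = FALSE]
  sites <- sites[ok]; ab <- ab[ok]
  n <- nrow(pairs)
  if (any(strata > n)) stop("stratum size exceeds the joined pair population")
  n_react <- max(1L, floor(reactive_fraction * n))
  reactive <- logical(n)
  reactive[order(-pairs$z, pairs$cit_sequence)[seq_len(n_react)]] <- TRUE
  ab_rank <- order(-ab, sites) # most abundant first, deterministic ties
  do.call(rbind, lapply(strata, function(k) {
    in_stratum <- logical(n)
    in_stratum[ab_rank[seq_len(k)]] <- TRUE
    a <- sum(reactive & in_stratum); b <- sum(reactive & !in_stratum)
    c_ <- sum(!reactive & in_stratum); d <- sum(!reactive & !in_stratum)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    sign <- if (is.finite(ft$estimate) && ft$estimate < 1) -1 else 1
    data.frame(stratum = k, overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               score = sign * -log10(ft$p.value))
  }))
}
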