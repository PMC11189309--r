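# PTM co-occurrence testing and iceLogo-style position-specific motif
# enrichment around modified residues.

#' Hypergeometric co-occurrence test for two site sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two site sets drawn from a common universe of candidate
#' arginines (used e.g. for citrullination x arginine mono-methylation
#' crosstalk).
#'
#' @param setA,setB character vectors of site keys, subsets of the universe.
#' @param universe_size number of candidate sites in the universe.
#' @return list: `overlap`, `p`.
#' @export
overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  k <- length(intersect(setA, setB))
  if (universe_size < length(setA) || universe_size < length(setB))
    stop("universe smaller than one of the sets")
  if (universe_size < length(setA) + length(setB) - k)
    stop("universe cannot hold both sets with the observed overlap")
  p <- stats::phyper(k - 1, length(setA), universe_size - length(setA),
                     length(setB), lower.tail = FALSE)
  list(overlap = k, p = p)
}

GAP_CHAR <- "-"

#' Extract fixed-width sequence windows around modified positions
#'
#' Returns strings of length 2f+1 centered on each stated position, padded
#' with the gap character where the window extends past a protein terminus.
#'
#' @param sequences named character vector (or Biostrings AAStringSet) of
#'   protein sequences.
#' @param positions data.frame with `protein_id`, `position` (1-based).
#' @param flank number of flanking residues f on each side (default 7).
#' @return data.frame: `protein_id`, `position`, `center` (residue at the
#'   central position), `window`.
#' @export
extract_windows <- function(sequences, positions, flank = 7L) {
  if (inherits(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  seqs <- sequences[positions$protein_id]
  if (any(is.na(names(seqs)) | is.na(seqs)))
    stop("protein(s) absent from the sequence set: ",
         paste(unique(positions$protein_id[is.na(seqs)]), collapse = ", "))
  n <- nchar(seqs)
  beyond <- positions$position < 1L | positions$position > n
  if (any(beyond))
    stop("position beyond sequence length for protein(s): ",
         paste(unique(positions$protein_id[beyond]), collapse = ", "))
  pad <- strrep(GAP_CHAR, flank)
  padded <- paste0(pad, seqs, pad)
  window <- substr(padded, positions$position, positions$position + 2L * flank)
  data.frame(protein_id = positions$protein_id, position = positions$position,
             center = substr(seqs, positions$position, positions$position),
             window = window, stringsAsFactors = FALSE)
}

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], GAP_CHAR)

.window_freq <- function(windows, flank) {
  mat <- do.call(rbind, strsplit(windows, ""))
  offsets <- seq.int(-flank, flank)
  keep <- offsets != 0L
  sapply(which(keep), function(j) {
    col <- factor(mat[, j], levels = .aa_alphabet)
    as.numeric(table(col)) / nrow(mat)
  }) -> freq
  dimnames(freq) <- list(.aa_alphabet, offsets[keep])
  freq
}

#' Position-specific motif enrichment (iceLogo-style)
#'
#' Compares amino-acid frequencies at each position around the modified
#' residue (offsets -f..+f, excluding 0) between foreground and background
#' window sets. For each position/letter the difference fg% - bg% is scored
#' as z = diff / sqrt(bg(1-bg)/n_fg) (the s.d.-unit height used for logo
#' display), with a two-tailed normal p; letters observed in the foreground
#' with zero background frequency are flagged rather than given an infinite
#' z.
#'
#' @param fg,bg character vectors of equal-width windows (length 2f+1).
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame: `offset`, `aa`, `fg_freq`, `bg_freq`, `diff`, `z`,
#'   `p`, `significant`, `zero_background`.
#' @export
motif_enrichment <- function(fg, bg, alpha = 0.05) {
  if (length(bg) == 0L) stop("empty background window set")
  if (length(fg) < 30L)
    warning("fewer than 30 foreground windows; motif statistics are weak")
  width <- unique(nchar(c(fg, bg)))
  if (length(width) != 1L || width %% 2L != 1L)
    stop("all windows must share one odd width")
  flank <- (width - 1L) %/% 2L
  f_fg <- .window_freq(fg, flank)
  f_bg <- .window_freq(bg, flank)
  n_fg <- length(fg)
  rows <- expand.grid(aa = .aa_alphabet, offset = as.integer(colnames(f_fg)),
                      stringsAsFactors = FALSE)
  rows$fg_freq <- f_fg[cbind(rows$aa, as.character(rows$offset))]
  rows$bg_freq <- f_bg[cbind(rows$aa, as.character(rows$offset))]
  rows$diff <- rows$fg_freq - rows$bg_freq
  se <- sqrt(rows$bg_freq * (1 - rows$bg_freq) / n_fg)
  rows$z <- ifelse(se > 0, rows$diff / se, NA_real_)
  rows$p <- ifelse(is.finite(rows$z), 2 * stats::pnorm(-abs(rows$z)),
                   NA_real_)
  rows$zero_background <- rows$bg_freq == 0 & rows$fg_freq > 0
  rows$significant <- (is.finite(rows$p) & rows$p < alpha) |
    rows$zero_background
  rows[order(rows$offset, rows$aa), c("offset", "aa", "fg_freq", "bg_freq",
                                      "diff", "z", "p", "significant",
                                      "zero_background")]
}
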