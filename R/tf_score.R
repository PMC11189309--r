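# Scoring target genes by the balance of citrullinated vs non-citrullinated
# transcription factors regulating them.

#' Score target genes by citrullinated-TF regulation balance
#'
#' For each target gene, computes the fraction of all citrullinated TFs and
#' of all non-citrullinated TFs that regulate it, and scores the gene as
#' log2((frac_cit + eps_c) / (frac_noncit + eps_n)) with per-group
#' pseudofractions eps = pseudocount / group size (half a TF by default).
#' The score is negative when proportionally more non-citrullinated TFs
#' regulate the target. Targets with no regulating TF are excluded and
#' counted. Output is sorted by descending score with a deterministic
#' lexicographic tie-break on the gene label.
#'
#' @param edges data.frame with columns `target` and `tf` (one edge per row).
#' @param tf_flags data.frame with columns `tf` and `citrullinated`
#'   (logical); every TF in `edges` must be flagged, and both groups must be
#'   non-empty.
#' @param pseudocount pseudo-TF count added to each group's fraction
#'   (default 0.5; set 0 for the raw ratio).
#' @return data.frame: `target`, `n_cit`, `n_noncit`, `frac_cit`,
#'   `frac_noncit`, `score`; attribute `"n_excluded"` counts targets
#'   dropped for having no regulating TF.
#' @export
score_targets <- function(edges, tf_flags, pseudocount = 0.5) {
  stopifnot(all(c("target", "tf") %in% names(edges)),
            all(c("tf", "citrullinated") %in% names(tf_flags)))
  unflagged <- setdiff(unique(edges$tf), tf_flags$tf)
  if (length(unflagged))
    stop("TF(s) without citrullination flag: ",
         paste(utils::head(unflagged), collapse = ", "))
  cit_tfs <- unique(tf_flags$tf[tf_flags$citrullinated])
  non_tfs <- unique(tf_flags$tf[!tf_flags$citrullinated])
  if (length(cit_tfs) == 0L || length(non_tfs) == 0L)
    stop("both TF groups must be non-empty")

  edges <- unique(edges[c("target", "tf")])
  n_excluded <- sum(!nzchar(edges$target)) # malformed targets
  edges <- edges[nzchar(edges$target), , drop = FALSE]
  is_cit <- edges$tf %in% cit_tfs
  n_cit <- tapply(is_cit, edges$target, sum)
  n_non <- tapply(!is_cit, edges$target, sum)
  targets <- names(n_cit)
  keep <- (n_cit + n_non) > 0
  n_excluded <- n_excluded + sum(!keep)

  frac_cit <- as.numeric(n_cit[keep]) / length(cit_tfs)
  frac_non <- as.numeric(n_non[keep]) / length(non_tfs)
  eps_c <- pseudocount / length(cit_tfs)
  eps_n <- pseudocount / length(non_tfs)
  score <- log2((frac_cit + eps_c) / (frac_non + eps_n))
  out <- data.frame(target = targets[keep],
                    n_cit = as.integer(n_cit[keep]),
                    n_noncit = as.integer(n_non[keep]),
                    frac_cit = frac_cit, frac_noncit = frac_non,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read TF->target edges and TF citrullination flags from TSV files
#'
#' @param edges_path two-column TSV (`target`, `tf`).
#' @param flags_path two-column TSV (`tf`, `citrullinated` 0/1).
#' @return list with `edges` and `tf_flags` data.frames.
#' @export
read_tf_tables <- function(edges_path, flags_path) {
  edges <- utils::read.delim(edges_path, sep = "\t", stringsAsFactors = FALSE)
  flags <- utils::read.delim(flags_path, sep = "\t", stringsAsFactors = FALSE)
  flags$citrullinated <- as.logical(flags$citrullinated) |
    flags$citrullinated == 1
  list(edges = edges, tf_flags = flags)
}
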