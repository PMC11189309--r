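# Structural and sequence-feature context of citrullination sites: disorder
# regions, fold-enrichment + Fisher tests, coordination number, RSA profiles,
# pLDDT summaries and secondary-structure enrichment.

#' Assemble disorder regions from per-residue scores
#'
#' Maximal runs of consecutive residues with disorder score >= `cutoff`.
#' Long mode keeps runs of length >= 31; short mode keeps runs of length
#' 2-30 (the two modes partition all runs of length >= 2).
#'
#' @param scores numeric vector of per-residue disorder scores in [0,1],
#'   covering contiguous positions 1..length of one protein.
#' @param mode `"long"` or `"short"`.
#' @param cutoff disorder score cutoff (default 0.5, inclusive).
#' @return data.frame with `start`, `end` (1-based inclusive), `length`.
#' @export
assemble_disorder_regions <- function(scores, mode = c("long", "short"),
                                      cutoff = 0.5) {
  mode <- match.arg(mode)
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("disorder scores must lie in [0,1]")
  r <- rle(!is.na(scores) & scores >= cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & if (mode == "long") r$lengths >= 31L
                     else r$lengths >= 2L & r$lengths <= 30L
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep], row.names = NULL)
}

.positions_inside <- function(positions, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(positions)))
  vapply(positions, function(p)
    any(p >= intervals$start & p <= intervals$end), logical(1))
}

#' Fold enrichment of citrullination inside feature intervals
#'
#' FE = (Cit_i / R_i) * (R_o / Cit_o), where Cit_i/Cit_o are citrullinated
#' arginines inside/outside the features and R_i/R_o are all arginines
#' inside/outside. Significance is a two-sided Fisher exact test on the 2x2
#' table of citrullinated vs unmodified arginines, inside vs outside.
#'
#' @param cit_positions positions of citrullinated arginines (must be a
#'   subset of `arg_positions`).
#' @param arg_positions positions of all arginines in the same coordinate
#'   system.
#' @param intervals data.frame with `start`, `end` (1-based inclusive); may
#'   span several proteins if positions are globally unique (e.g. keyed).
#' @return one-row data.frame: `cit_in`, `cit_out`, `arg_in`, `arg_out`,
#'   `fe` (NA with `zero_cell = TRUE` when undefined), `p`, `zero_cell`.
#' @export
feature_enrichment <- function(cit_positions, arg_positions, intervals) {
  if (!all(cit_positions %in% arg_positions))
    stop("cit_positions must be a subset of arg_positions")
  cit_in <- sum(.positions_inside(cit_positions, intervals))
  cit_out <- length(cit_positions) - cit_in
  arg_in <- sum(.positions_inside(arg_positions, intervals))
  arg_out <- length(arg_positions) - arg_in
  zero_cell <- cit_out == 0L || arg_in == 0L
  fe <- if (zero_cell) NA_real_ else (cit_in / arg_in) * (arg_out / cit_out)
  tab <- matrix(c(cit_in, cit_out, arg_in - cit_in, arg_out - cit_out),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  data.frame(cit_in = cit_in, cit_out = cit_out, arg_in = arg_in,
             arg_out = arg_out, fe = fe, p = p, zero_cell = zero_cell)
}

#' Coordination number of residues from C-alpha coordinates
#'
#' The coordination number (CN) of a residue is the number of other
#' residues' C-alpha atoms within a closed ball of `radius` angstroms around
#' its own C-alpha (self excluded); a burial proxy. Residues with missing
#' coordinates are skipped and reported, never treated as distance 0.
#'
#' @param ca_xyz numeric matrix (n x 3) of C-alpha coordinates; rows with any
#'   NA are treated as missing.
#' @param radius ball radius in angstroms (default 13).
#' @return list: `cn` (integer vector, NA for missing-coordinate residues),
#'   `n_missing`.
#' @export
coordination_number <- function(ca_xyz, radius = 13) {
  stopifnot(is.matrix(ca_xyz), ncol(ca_xyz) == 3, radius > 0)
  ok <- stats::complete.cases(ca_xyz)
  cn <- rep(NA_integer_, nrow(ca_xyz))
  if (sum(ok) >= 1L) {
    d <- as.matrix(stats::dist(ca_xyz[ok, , drop = FALSE]))
    cn[ok] <- as.integer(rowSums(d <= radius) - 1L)
  }
  list(cn = cn, n_missing = sum(!ok))
}

#' Compare RSA profiles of citrullinated vs background arginines
#'
#' Bins relative solvent accessibility into 50 half-open bins of width 0.02
#' ([x, x+0.02), last bin closed at 1.0), and compares the paired 50-bin
#' frequency profiles with a two-tailed Spearman rank test.
#'
#' @param fg_rsa RSA values (0-1) of citrullinated arginines (non-empty).
#' @param bg_rsa RSA values (0-1) of background arginines.
#' @return list: `bins` (data.frame `lower`, `upper`, `fg`, `bg` frequency),
#'   `rho`, `p`.
#' @export
rsa_comparison <- function(fg_rsa, bg_rsa) {
  if (length(fg_rsa) == 0L) stop("empty foreground RSA vector")
  if (any(c(fg_rsa, bg_rsa) < 0 | c(fg_rsa, bg_rsa) > 1))
    stop("RSA values must lie in [0,1]")
  bin_of <- function(x) pmin(floor(x / 0.02), 49) + 1L
  fg_counts <- tabulate(bin_of(fg_rsa), nbins = 50L)
  bg_counts <- tabulate(bin_of(bg_rsa), nbins = 50L)
  fg_freq <- fg_counts / sum(fg_counts)
  bg_freq <- if (sum(bg_counts) > 0) bg_counts / sum(bg_counts) else bg_counts
  ct <- suppressWarnings(
    stats::cor.test(fg_freq, bg_freq, method = "spearman",
                    alternative = "two.sided"))
  list(bins = data.frame(lower = seq(0, 0.98, by = 0.02),
                         upper = seq(0.02, 1, by = 0.02),
                         fg = fg_freq, bg = bg_freq),
       rho = unname(ct$estimate), p = ct$p.value)
}

#' Collapse per-segment predictions for one residue
#'
#' Large proteins are predicted in overlapping segments; a residue covered by
#' several segments takes the median pLDDT across segments, and the
#' secondary-structure label of the most confidently predicted segment
#' (highest pLDDT; first on ties).
#'
#' @param plddt numeric vector of per-segment pLDDT values for one residue.
#' @param ss character vector of per-segment secondary-structure labels.
#' @return list with `plddt` (median) and `ss`.
#' @export
collapse_segments <- function(plddt, ss) {
  stopifnot(length(plddt) == length(ss), length(plddt) >= 1L)
  list(plddt = stats::median(plddt), ss = ss[which.max(plddt)])
}

#' Distribution summaries of pLDDT for arginine selections
#'
#' Summarizes pLDDT (quartiles, median, 5th/95th percentile whiskers) for
#' named selections of residues, e.g. all arginines, all citrullination
#' sites, and the top-N most abundant sites. Sites mapping to a
#' non-arginine residue are excluded and counted as mismatched.
#'
#' @param residues data.frame with `protein_id`, `position`, `residue`,
#'   `plddt`.
#' @param selections named list of data.frames with `protein_id`, `position`.
#' @return list: `summary` (data.frame selection x n, p5, q1, median, q3,
#'   p95, mean), `values` (named list of pLDDT vectors), `n_mismatched`.
#' @export
plddt_site_summary <- function(residues, selections) {
  rk <- site_key(residues$protein_id, residues$position)
  n_mismatched <- 0L
  values <- lapply(selections, function(sel) {
    k <- site_key(sel$protein_id, sel$position)
    idx <- match(k, rk)
    found <- !is.na(idx)
    is_arg <- found & residues$residue[idx] == "R"
    n_mismatched <<- n_mismatched + sum(found & !is_arg)
    residues$plddt[idx[is_arg]]
  })
  summ <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(selection = nm, n = length(v), p5 = q[1], q1 = q[2],
               median = q[3], q3 = q[4], p95 = q[5], mean = mean(v),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, values = values, n_mismatched = n_mismatched)
}

.ss8_states <- c("H", "G", "I", "E", "B", "T", "S", "-")

# coarse classes used when reporting: turns, left-handed/3-10-type helices,
# bends; the 8-state labels themselves are tested individually.
ss8_class_map <- function() {
  data.frame(ss8 = .ss8_states,
             class = c("Helix", "Helix left-handed", "Helix", "Strand",
                       "Strand", "Turn", "Bend", "Coil"),
             stringsAsFactors = FALSE)
}

#' Secondary-structure enrichment of citrullination-site groups
#'
#' For every 8-state secondary-structure label and every site group, a
#' two-sided Fisher exact test of group membership vs structure class
#' against the chosen arginine background, with Benjamini-Hochberg
#' adjustment across all tests performed in the family.
#'
#' @param residues data.frame with `protein_id`, `position`, `residue`, `ss`
#'   (8-state label).
#' @param groups named list of data.frames with `protein_id`, `position`
#'   (site selections, e.g. all sites / top-1000 / top-250).
#' @param background data.frame with `protein_id`, `position` giving the
#'   arginine background (all arginines or arginines of citrullinated
#'   proteins).
#' @return data.frame: `group`, `ss`, `in_group`, `in_bg`, `fe`, `p`, `q`.
#' @export
secondary_structure_enrichment <- function(residues, groups, background) {
  bad <- !(residues$ss %in% .ss8_states)
  if (any(bad)) stop("unknown secondary-structure label(s): ",
                     paste(unique(residues$ss[bad]), collapse = ", "))
  rk <- site_key(residues$protein_id, residues$position)
  ss_of <- function(sel) {
    idx <- match(site_key(sel$protein_id, sel$position), rk)
    residues$ss[idx[!is.na(idx)]]
  }
  bg_ss <- ss_of(background)
  rows <- list()
  for (g in names(groups)) {
    grp_ss <- ss_of(groups[[g]])
    for (s in .ss8_states) {
      a <- sum(grp_ss == s); b <- length(grp_ss) - a
      c_ <- sum(bg_ss == s); d <- length(bg_ss) - c_
      fe <- if (c_ == 0L || b == 0L || length(bg_ss) == 0L) NA_real_
            else (a / length(grp_ss)) / (c_ / length(bg_ss))
      p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                     byrow = TRUE))$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, ss = s, in_group = a, in_bg = c_,
                   fe = fe, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read a per-residue context TSV
#'
#' Columns: `protein_id`, `position`, `residue`, `disorder`, `rsa`, `plddt`,
#' `ss`, `ca_x`, `ca_y`, `ca_z`.
#'
#' @param path input TSV path.
#' @return data.frame of residue contexts.
#' @export
read_residue_context <- function(path) {
  ctx <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "disorder", "rsa", "plddt",
            "ss", "ca_x", "ca_y", "ca_z")
  miss <- setdiff(need, names(ctx))
  if (length(miss)) stop("residue-context file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ctx$plddt < 0 | ctx$plddt > 100, na.rm = TRUE))
    stop("pLDDT values must lie in [0,100]")
  ctx
}

#' Read feature intervals from a GFF3 file (UniProt protein dialect)
#'
#' 1-based inclusive intervals on protein coordinates; the GFF `type` column
#' is mapped to the feature kind (e.g. domain, NLS).
#'
#' @param path GFF3 path.
#' @return data.frame: `protein_id`, `start`, `end`, `kind`.
#' @export
read_feature_gff <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    data.frame(protein_id = as.character(gr$seqnames), start = gr$start,
               end = gr$end, kind = as.character(gr$type),
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(protein_id = f[, 1], start = as.integer(f[, 4]),
               end = as.integer(f[, 5]), kind = f[, 3],
               stringsAsFactors = FALSE)
  }
}
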