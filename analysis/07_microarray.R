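#!/usr/bin/env Rscript
# Stage 7: peptide-microarray reactivity.
#
# Replicate collapse, chip-pair normalization, citrullinated-vs-baseline
# ratios and per-fluid z-scores; then the three downstream reads: the
# Cit-Gly recognition motif of the most reactive peptides per fluid, the
# spacing of citrullines in the most reactive multi-citrullinated peptides,
# and reactivity enrichment across MS-abundance strata.

suppressPackageStartupMessages(library(citscape))

spots <- read.delim("results/data/array_spots.tsv")
quant <- read.delim("results/site_matrix.tsv", check.names = FALSE)

pairs <- pair_statistics(spots)
write.table(pairs, "results/array_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# motif of the most reactive peptides, per fluid
for (fl in c("ccp_positive", "ccp_negative")) {
  d <- pairs[pairs$fluid == fl, ]
  ord <- order(-d$z, d$cit_sequence)
  m <- motif_enrichment(toupper(d$cit_sequence[ord[1:60]]),
                        toupper(d$cit_sequence[ord[-(1:60)]]))
  g1 <- m[m$offset == 1 & m$aa == "G", ]
  cat(sprintf("%s: Cit-Gly (+1 G) flagged = %s (fg %.0f%%, bg %.0f%%)\n",
              fl, g1$significant && (g1$zero_background || g1$z > 0),
              100 * g1$fg_freq, 100 * g1$bg_freq))
  write.table(m, sprintf("results/motif_array_%s.tsv", fl), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

# spacing of citrullines among the most reactive multi-cit peptides
pos_pairs <- pairs[pairs$fluid == "ccp_positive", ]
prof <- spacing_profile(pos_pairs, top_n = 10)
cat("gap histogram, top reactive multi-cit peptides:\n")
print(prof$top)

# reactivity by MS-abundance strata (scaled-down analog of top-1000/2000/3000)
abund <- setNames(rowMeans(as.matrix(quant[-1])), quant$site)
# map each cit peptide back to its MS site via the proteome windows: the
# baseline form of a peptide equals the 17-mer window around its site
seqs <- read_proteome_fasta("results/data/proteome.fasta")
sites <- read.delim("results/sites.tsv")
win <- extract_windows(seqs, sites[c("protein_id", "position")], flank = 8)
joined <- setNames(
  sites$site[match(baseline_sequence(pos_pairs$cit_sequence), win$window)],
  pos_pairs$cit_sequence)
strata <- c(60L, 120L, 200L)
res <- reactivity_by_abundance(pos_pairs, joined, abund, strata = strata)
write.table(res, "results/reactivity_by_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("reactivity enrichment by abundance stratum (signed -log10 p):\n")
print(res, row.names = FALSE)
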