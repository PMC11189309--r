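#!/usr/bin/env Rscript
# Stage 5: PTM crosstalk and sequence-motif enrichment.
#
# Hypergeometric co-occurrence of citrullination with a simulated arginine
# mono-methylation site set, and iceLogo-style motif enrichment of the
# identified sites against non-citrullinated arginines from the same
# proteins.

suppressPackageStartupMessages(library(citscape))

seqs <- read_proteome_fasta("results/data/proteome.fasta")
sites <- read.delim("results/sites.tsv")

# arginine universe: all arginines in citrullinated proteins
registry <- do.call(rbind, lapply(names(seqs), function(p) {
  pos <- which(strsplit(seqs[[p]], "")[[1]] == "R")
  data.frame(protein_id = p, position = pos)
}))
universe <- registry[registry$protein_id %in% unique(sites$protein_id), ]
universe_keys <- site_key(universe$protein_id, universe$position)

# a methylation site set overlapping the citrullinome more than chance:
# half drawn from citrullination sites, half from other arginines
set.seed(1)
meth <- c(sample(sites$site, 60),
          sample(setdiff(universe_keys, sites$site), 60))
ov <- overlap_test(sites$site, meth, length(universe_keys))

fg <- extract_windows(seqs, sites[c("protein_id", "position")], flank = 7)
bg_pos <- universe[!(universe_keys %in% sites$site), ]
bg <- extract_windows(seqs, bg_pos, flank = 7)
motif <- motif_enrichment(fg$window, bg$window, alpha = 0.05)
write.table(motif, "results/motif_ms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("methylation overlap: %d of %d sites, hypergeometric p = %.3g\n",
            ov$overlap, nrow(sites), ov$p))
sig <- motif[motif$significant & motif$diff > 0, ]
cat(sprintf("%d position/letter motif enrichments at alpha 0.05\n",
            nrow(sig)))
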