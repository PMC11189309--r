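#!/usr/bin/env Rscript
# Stage 6: transcription-factor target scoring.
#
# Every target gene is scored by log2 of the ratio between the fraction of
# citrullinated TFs and the fraction of non-citrullinated TFs regulating it;
# the ranked list is the input contract for downstream gene-set enrichment.

suppressPackageStartupMessages(library(citscape))

tf <- read_tf_tables("results/data/tf_edges.tsv", "results/data/tf_flags.tsv")
scores <- score_targets(tf$edges, tf$tf_flags)
write.table(scores, "results/tf_target_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("scored %d targets from %d citrullinated / %d other TFs\n",
            nrow(scores), sum(tf$tf_flags$citrullinated),
            sum(!tf$tf_flags$citrullinated)))
cat("top 5 citrullination-driven targets:\n")
print(head(scores, 5), row.names = FALSE)
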