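#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth.
#
# Emulates the full input set of a citrullinome screen: a proteome FASTA, a
# MaxQuant-style evidence table over five cell conditions (HL60 / NLC with
# calcium treatments) plus an inhibitor arm, per-residue structural context,
# feature intervals, TF-target edges and a peptide microarray. All planted
# truths are kept in a JSON ledger for the later stages to check against.

suppressPackageStartupMessages(library(citscape))

seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

config <- synth_config(seed)
proteome <- synth_proteome(config)
structures <- synth_structures(config, proteome)
features <- synth_features(config, structures)
evidence <- synth_evidence(config, proteome, structures, features)
array <- synth_array(config, proteome, evidence)
tf <- synth_tf_edges(config)

write_proteome_fasta(proteome$sequences, "results/data/proteome.fasta")
write_evidence(evidence$psm, "results/data/evidence.tsv")
write.table(structures$context, "results/data/residue_context.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(features, "results/data/features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(evidence$counterpart, "results/data/counterparts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(evidence$dose, "results/data/dose_response.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(array$spots, "results/data/array_spots.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tf$edges, "results/data/tf_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tf$tf_flags, "results/data/tf_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       n_cit_sites = nrow(evidence$ledger$cit_sites),
       id_pass_sites = evidence$ledger$id_pass_sites,
       core_sites = evidence$ledger$core_sites,
       occupancy_truth = as.list(evidence$ledger$occupancy_truth),
       dose_truth = evidence$ledger$dose_truth,
       chip_offset = array$ledger$chip_offset),
  "results/data/truth_ledger.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d proteins, %d PSMs, %d planted sites (%d core)\n",
            length(proteome$sequences), nrow(evidence$psm),
            nrow(evidence$ledger$cit_sites),
            length(evidence$ledger$core_sites)))
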