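#!/usr/bin/env Rscript
# Stage 4: structural and feature context of citrullination.
#
# Fold enrichment (FE = (Cit_i/R_i)(R_o/Cit_o)) with Fisher tests for
# domains, NLS and long/short disorder regions; coordination number at 13 A
# as a burial proxy; RSA profile comparison in 0.02 bins; pLDDT summaries of
# abundance-ranked site selections; secondary-structure enrichment with BH
# adjustment.

suppressPackageStartupMessages(library(citscape))

ctx <- read_residue_context("results/data/residue_context.tsv")
features <- read.delim("results/data/features.tsv")
sites <- read.delim("results/sites.tsv")

# disorder regions assembled from the per-residue scores
disorder <- do.call(rbind, lapply(split(ctx, ctx$protein_id), function(d) {
  d <- d[order(d$position), ]
  rbind(
    if (nrow(lr <- assemble_disorder_regions(d$disorder, "long")))
      data.frame(protein_id = d$protein_id[1], start = lr$start,
                 end = lr$end, kind = "long_disorder"),
    if (nrow(sr <- assemble_disorder_regions(d$disorder, "short")))
      data.frame(protein_id = d$protein_id[1], start = sr$start,
                 end = sr$end, kind = "short_disorder"))
}))
all_features <- rbind(features, disorder)

# global coordinates so one enrichment call spans all proteins
prot_len <- tapply(ctx$position, ctx$protein_id, max)
offset <- setNames(c(0, cumsum(prot_len))[seq_along(prot_len)],
                   names(prot_len))
glob <- function(protein_id, pos) pos + offset[protein_id]

args <- ctx[ctx$residue == "R", ]
is_cit <- site_key(args$protein_id, args$position) %in% sites$site
enr <- do.call(rbind, lapply(unique(all_features$kind), function(k) {
  f <- all_features[all_features$kind == k, ]
  cbind(kind = k, feature_enrichment(
    glob(args$protein_id[is_cit], args$position[is_cit]),
    glob(args$protein_id, args$position),
    data.frame(start = glob(f$protein_id, f$start),
               end = glob(f$protein_id, f$end))))
}))
enr$q <- p.adjust(enr$p, method = "BH")
write.table(enr, "results/feature_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# burial: coordination number of citrullinated vs background arginines
cn_by_protein <- lapply(split(ctx, ctx$protein_id), function(d) {
  d <- d[order(d$position), ]
  data.frame(protein_id = d$protein_id, position = d$position,
             cn = coordination_number(
               as.matrix(d[c("ca_x", "ca_y", "ca_z")]), 13)$cn)
})
cn <- do.call(rbind, cn_by_protein)
cn_key <- site_key(cn$protein_id, cn$position)
cn_cit <- cn$cn[cn_key %in% sites$site]
cn_bg <- cn$cn[cn_key %in% site_key(args$protein_id, args$position)]

# exposure: RSA profiles
rsa <- rsa_comparison(args$rsa[is_cit], args$rsa[!is_cit])

# order: pLDDT for all arginines / all sites / top selections by abundance
quant <- read.delim("results/site_matrix.tsv", check.names = FALSE)
abund <- rowMeans(as.matrix(quant[-1]))
top_sites <- function(n) {
  keys <- quant$site[order(-abund)][seq_len(n)]
  data.frame(protein_id = sub(":.*", "", keys),
             position = as.integer(sub(".*:", "", keys)))
}
site_df <- data.frame(protein_id = sites$protein_id,
                      position = sites$position)
pl <- plddt_site_summary(ctx, list(
  all_arginines = args[c("protein_id", "position")],
  all_sites = site_df, top_100 = top_sites(100), top_50 = top_sites(50)))
write.table(pl$summary, "results/plddt_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ss <- secondary_structure_enrichment(
  ctx, list(all_sites = site_df, top_100 = top_sites(100),
            top_50 = top_sites(50)),
  args[c("protein_id", "position")])
write.table(ss, "results/secondary_structure_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("feature enrichment (FE, Fisher q):\n")
print(enr[c("kind", "cit_in", "arg_in", "fe", "q")], row.names = FALSE)
cat(sprintf("mean CN: citrullinated %.1f vs all arginines %.1f\n",
            mean(cn_cit, na.rm = TRUE), mean(cn_bg, na.rm = TRUE)))
cat(sprintf("RSA Spearman on binned profiles: rho %.2f, p %.3g\n",
            rsa$rho, rsa$p))
cat("median pLDDT by selection:\n")
print(pl$summary[c("selection", "n", "median")], row.names = FALSE)
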