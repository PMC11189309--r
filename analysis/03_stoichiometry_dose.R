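#!/usr/bin/env Rscript
# Stage 3: modification stoichiometry and PADI4-inhibitor dose-response.
#
# Occupancy per condition from matched modified/unmodified counterpart
# intensities, then the inhibitor arm: model-free half-inhibition and a 4PL
# fit of the global citrullination response (truth: IC50 = 2 uM).

suppressPackageStartupMessages(library(citscape))

cp <- read.delim("results/data/counterparts.tsv")
dose <- read.delim("results/data/dose_response.tsv")
truth <- jsonlite::read_json("results/data/truth_ledger.json",
                             simplifyVector = TRUE)

occ <- do.call(rbind, lapply(split(cp, cp$condition), function(d) {
  o <- occupancy(d$modified, d$unmodified)
  data.frame(condition = d$condition[1], median_occupancy =
               median(o$occupancy, na.rm = TRUE))
}))
write.table(occ, "results/occupancy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dmean <- aggregate(response ~ concentration, data = dose, FUN = mean)
dmean <- dmean[order(dmean$concentration), ]
fit <- fit_ic50(dmean$concentration, dmean$response)
write.table(data.frame(ic50_uM = fit$ic50, hill_slope = fit$hill_slope,
                       bottom = fit$bottom, converged = fit$converged,
                       half_inhibition_uM = fit$ci50_interpolated),
            "results/ic50.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("median occupancy per condition:\n")
print(occ, row.names = FALSE)
cat(sprintf("IC50 fit: %.2f uM (truth %.1f); half-inhibition %.2f uM\n",
            fit$ic50, truth$dose_truth$ic50, fit$ci50_interpolated))
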