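# Peptide-microarray reactivity pipeline.

spot_row <- function(chip, fluid, seqs, raw, rep_i = 1L) {
  data.frame(chip_id = chip, fluid = fluid, sequence = seqs,
             replicate = rep_i, raw_mean = raw, stringsAsFactors = FALSE)
}

test_that("replicate spots collapse to the median before log2", {
  spots <- rbind(spot_row("c1", "f", "ArG", 100, 1L),
                 spot_row("c1", "f", "ArG", 300, 2L))
  out <- collapse_spots(spots)
  expect_equal(out$log2_intensity, log2(200), tolerance = 1e-9)
  # n = 4 printing: median of 4
  four <- do.call(rbind, lapply(1:4, function(i)
    spot_row("c1", "f", "ArG", c(80, 100, 120, 400)[i], i)))
  expect_equal(collapse_spots(four)$log2_intensity, log2(110))
  expect_error(collapse_spots(spot_row("c1", "f", "ArG", 0)), "positive")
})

test_that("collapsing already collapsed values is the identity", {
  spots <- rbind(spot_row("c1", "f", c("ArG", "AAA"), c(150, 250)))
  once <- collapse_spots(spots)
  again <- collapse_spots(data.frame(chip_id = once$chip_id,
                                     fluid = once$fluid,
                                     sequence = once$sequence,
                                     raw_mean = 2^once$log2_intensity))
  expect_equal(once$log2_intensity, again$log2_intensity)
})

test_that("chip-pair normalization centers medians symmetrically, preserving differences", {
  a <- c(9, 10, 11); b <- c(11, 12, 13)
  out <- normalize_chip_pair(a, b)
  expect_equal(median(out$a), 11)
  expect_equal(median(out$b), 11)
  expect_equal(diff(out$a), diff(a))
  expect_equal(diff(out$b), diff(b))
  same <- normalize_chip_pair(a, a)
  expect_equal(same$shift_a, 0)
  expect_equal(same$shift_b, 0)
  expect_error(normalize_chip_pair(numeric(), a), "empty")
})

test_that("a planted chip offset is recovered within 0.05 log2", {
  config <- synth_config(12)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  arr <- synth_array(config, proteome, ev)
  spots <- arr$spots[arr$spots$fluid == "ccp_negative", ]
  coll <- collapse_spots(spots)
  chips <- sort(unique(coll$chip_id))
  est <- median(coll$log2_intensity[coll$chip_id == chips[2]]) -
    median(coll$log2_intensity[coll$chip_id == chips[1]])
  expect_lt(abs(est - arr$ledger$chip_offset), 0.05)
})

test_that("pair ratios are zero for identical intensities and z-scores standardize", {
  seqs <- c("AArGA", "GGrGG", "CCrCC", "DDrDD")
  base <- baseline_sequence(seqs)
  spots <- rbind(spot_row("c1", "f", c(seqs, base), rep(2^10, 8)),
                 spot_row("c2", "f", c(seqs, base), rep(2^10, 8)))
  pp <- pair_statistics(spots)
  expect_equal(pp$ratio, rep(0, 4))

  set.seed(31)
  spots2 <- rbind(spot_row("c1", "f", c(seqs, base), 2^rnorm(8, 10)),
                  spot_row("c2", "f", c(seqs, base), 2^rnorm(8, 10)))
  pp2 <- pair_statistics(spots2)
  expect_equal(mean(pp2$z), 0, tolerance = 1e-9)
  expect_equal(sd(pp2$z), 1, tolerance = 1e-9)
})

test_that("citrullinated peptides without a baseline are dropped and counted", {
  spots <- rbind(spot_row("c1", "f", c("AArGA", "AARGA", "GGrGG"),
                          c(1000, 900, 800)),
                 spot_row("c2", "f", c("AArGA", "AARGA", "GGrGG"),
                          c(1000, 900, 800)))
  pp <- pair_statistics(spots)
  expect_equal(pp$cit_sequence, "AArGA")
  expect_equal(attr(pp, "n_unmatched"), 2L)  # GGrGG unmatched on both chips
})

test_that("the pipeline is deterministic given the spot table", {
  config <- synth_config(13)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  arr <- synth_array(config, proteome, ev)
  expect_identical(pair_statistics(arr$spots), pair_statistics(arr$spots))
})

test_that("planted CCP-positive reactivity puts Cit-Gly pairs in the top z decile", {
  config <- synth_config(1)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  arr <- synth_array(config, proteome, ev)
  pp <- pair_statistics(arr$spots)
  pos <- pp[pp$fluid == "ccp_positive", ]
  planted <- arr$ledger$reactive_g_plus1
  cut90 <- quantile(pos$z, 0.9)
  expect_gt(mean(pos$z[pos$cit_sequence %in% planted] >= cut90), 0.8)
  # no such enrichment in the disease-control fluid
  ctrl <- pp[pp$fluid == "disease_control", ]
  expect_lt(mean(ctrl$z[ctrl$cit_sequence %in% planted] >= quantile(ctrl$z, 0.9)),
            0.4)
})

test_that("citrulline spacing gaps follow the offset definition", {
  expect_equal(citrulline_offsets("AAAArArAA")[[1]], c(4L, 6L))
  pairs <- data.frame(cit_sequence = c("AAAArArAA", "rAAAAAAAr", "AArAAAAAA"),
                      z = c(3, 1, 2), stringsAsFactors = FALSE)
  prof <- spacing_profile(pairs, top_n = 1)
  expect_equal(prof$n_multi, 2L)             # single-cit pair excluded
  expect_equal(as.integer(names(prof$top)), 1L)  # offsets 4,6 -> gap 1
  expect_warning(spacing_profile(pairs, top_n = 10), "clipped")
})

test_that("planted gap-1 spacing dominates the most reactive multi-cit pairs", {
  config <- synth_config(1)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  arr <- synth_array(config, proteome, ev)
  pp <- pair_statistics(arr$spots)
  pos <- pp[pp$fluid == "ccp_positive", ]
  offs <- citrulline_offsets(pos$cit_sequence)
  n_multi <- sum(lengths(offs) >= 2)
  expect_gt(n_multi, 8)
  prof <- spacing_profile(pos, top_n = max(3L, n_multi %/% 4L))
  top_gaps <- rep(as.integer(names(prof$top)), prof$top)
  expect_equal(sort(table(top_gaps), decreasing = TRUE)[[1]],
               sum(top_gaps == 1))
})

test_that("reactivity enrichment is monotone in planted abundance strata and null at random", {
  config <- synth_config(1)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  arr <- synth_array(config, proteome, ev)
  pp <- pair_statistics(arr$spots)
  pos <- pp[pp$fluid == "ccp_positive", ]
  strata <- c(60L, 120L, 200L)
  res <- reactivity_by_abundance(pos, arr$ledger$site_of, arr$ledger$abundance,
                                 strata = strata)
  expect_true(all(diff(res$score) < 0))  # tightest stratum scores highest
  expect_gt(res$score[1], 2)

  # with permuted abundances the association collapses
  set.seed(33)
  shuf <- sample(arr$ledger$abundance)
  names(shuf) <- names(arr$ledger$abundance)
  null_res <- reactivity_by_abundance(pos, arr$ledger$site_of, shuf,
                                      strata = strata)
  expect_lt(max(abs(null_res$score)), 2)
  expect_error(reactivity_by_abundance(pos, arr$ledger$site_of,
                                       arr$ledger$abundance, strata = 10000L),
               "exceeds")
})
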