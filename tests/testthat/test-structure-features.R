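# Disorder regions, feature enrichment, coordination number, RSA profiles,
# pLDDT summaries and secondary-structure enrichment.

test_that("disorder-region assembly respects the 31 / 2-30 length boundaries", {
  sc <- rep(0.6, 40)
  long <- assemble_disorder_regions(sc, "long")
  expect_equal(nrow(long), 1L)
  expect_equal(long$length, 40L)
  expect_equal(nrow(assemble_disorder_regions(sc, "short")), 0L)

  sc31 <- c(rep(0, 5), rep(0.7, 31), rep(0, 5))
  expect_equal(nrow(assemble_disorder_regions(sc31, "long")), 1L)
  sc30 <- c(rep(0, 5), rep(0.7, 30), rep(0, 5))
  expect_equal(nrow(assemble_disorder_regions(sc30, "long")), 0L)
  expect_equal(nrow(assemble_disorder_regions(sc30, "short")), 1L)
  expect_error(assemble_disorder_regions(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("region assembly matches a brute-force run scanner on random scores", {
  set.seed(14)
  for (i in 1:20) {
    sc <- round(runif(200), 2)
    long <- assemble_disorder_regions(sc, "long")
    short <- assemble_disorder_regions(sc, "short")
    ref_long <- brute_regions(sc, 0.5, 31)
    ref_short <- brute_regions(sc, 0.5, 2, 30)
    expect_equal(long[c("start", "end")], ref_long, ignore_attr = TRUE)
    expect_equal(short[c("start", "end")], ref_short, ignore_attr = TRUE)
    # partition property: long and short never overlap
    cover <- function(df) unlist(mapply(seq, df$start, df$end,
                                        SIMPLIFY = FALSE))
    expect_length(intersect(cover(long), cover(short)), 0L)
  }
})

test_that("fold enrichment follows the FE formula and Fisher consistency", {
  iv <- data.frame(start = 1, end = 100)
  res <- feature_enrichment(c(1:10, 150:154), c(1:100, 101:300), iv)
  expect_equal(res$cit_in, 10); expect_equal(res$cit_out, 5)
  expect_equal(res$arg_in, 100); expect_equal(res$arg_out, 200)
  expect_equal(res$fe, 4.0)    # (10/100) * (200/5)

  zero_in <- feature_enrichment(c(150, 151), c(1:100, 150:200), iv)
  expect_equal(zero_in$fe, 0)  # Cit_i = 0 => fe = 0
  expect_error(feature_enrichment(c(150), c(1:100), iv), "subset")
})

test_that("fe > 1 iff the 2x2 sample odds ratio exceeds 1", {
  set.seed(15)
  iv <- data.frame(start = 1, end = 50)
  for (i in 1:25) {
    args <- sort(sample(1:200, 80))
    cit <- sort(sample(args, 20))
    res <- feature_enrichment(cit, args, iv)
    if (res$zero_cell || res$cit_in == 0) next
    or_hat <- (res$cit_in / (res$arg_in - res$cit_in)) /
      (res$cit_out / (res$arg_out - res$cit_out))
    if (is.finite(or_hat) && or_hat != 1)
      expect_equal(res$fe > 1, or_hat > 1)
  }
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(feature_enrichment(c(1:3, 60:66), c(1:5, 60:84), # (3,7,2,18)
                                  data.frame(start = 1, end = 5))$p,
               enum_fisher_p(3, 2, 7, 18), tolerance = 1e-12)
  # exhaustive over all small tables, plus random larger tables up to 60
  for (tot in c(8, 12)) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (c_ in 0:(tot - a - b)) {
      d <- tot - a - b - c_
      p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, enum_fisher_p(a, b, c_, d), tolerance = 1e-9)
    }
  }
  set.seed(16)
  for (i in 1:300) {
    cell <- as.vector(rmultinom(1, sample(20:60, 1), runif(4)))
    p_pkg <- fisher.test(matrix(cell, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, enum_fisher_p(cell[1], cell[2], cell[3], cell[4]),
                 tolerance = 1e-9)
  }
})

test_that("coordination number matches brute force and is symmetric", {
  expect_equal(coordination_number(matrix(c(0, 0, 0), 1))$cn, 0L)
  two <- matrix(c(0, 0, 0, 12, 0, 0), 2, byrow = TRUE)
  expect_equal(coordination_number(two, 13)$cn, c(1L, 1L))
  two[2, 1] <- 14
  expect_equal(coordination_number(two, 13)$cn, c(0L, 0L))

  set.seed(17)
  cloud <- matrix(runif(150, 0, 40), 50, 3)
  got <- coordination_number(cloud, 13)$cn
  expect_equal(got, brute_cn(cloud, 13))
  # pair symmetry on the distance matrix
  d <- as.matrix(dist(cloud))
  expect_true(isSymmetric(d <= 13))
})

test_that("missing coordinates are skipped, not treated as distance zero", {
  xyz <- matrix(c(0, 0, 0, NA, NA, NA, 5, 0, 0), 3, byrow = TRUE)
  res <- coordination_number(xyz, 13)
  expect_equal(res$n_missing, 1L)
  expect_true(is.na(res$cn[2]))
  expect_equal(res$cn[c(1, 3)], c(1L, 1L))
})

test_that("RSA binning uses half-open 0.02 bins with a closed last bin", {
  res <- rsa_comparison(c(0, 0.019, 0.02, 1.0), c(0, 0.5, 1.0))
  expect_equal(sum(res$bins$fg), 1)
  expect_equal(res$bins$fg[1], 0.5)      # 0 and 0.019 in [0, 0.02)
  expect_equal(res$bins$fg[2], 0.25)     # 0.02 in [0.02, 0.04)
  expect_equal(res$bins$fg[50], 0.25)    # 1.0 in the closed last bin
  identical_samples <- rsa_comparison(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(identical_samples$bins$fg, identical_samples$bins$bg)
  expect_error(rsa_comparison(numeric(), c(0.5)), "empty")
})

test_that("an RSA shift between exposed foreground and buried background is detected", {
  set.seed(18)
  fg <- pmin(1, rbeta(400, 5, 5) + 0.2)
  bg <- rbeta(4000, 5, 5)
  res <- rsa_comparison(fg, bg)
  upper <- res$bins$lower >= 0.6
  expect_gt(sum(res$bins$fg[upper]), sum(res$bins$bg[upper]))
  expect_gt(mean(fg), mean(bg))
})

test_that("segment collapse takes median pLDDT and the most confident label", {
  got <- collapse_segments(c(60, 70), c("H", "T"))
  expect_equal(got$plddt, 65)
  expect_identical(got$ss, "T")
  expect_equal(collapse_segments(80, "E")$plddt, 80)
})

test_that("pLDDT summaries exclude non-arginine mappings and rank selections", {
  config <- synth_config(3)
  proteome <- synth_proteome(config)
  structures <- synth_structures(config, proteome)
  ev <- synth_evidence(config, proteome, structures)
  ctx <- structures$context
  sites <- ev$ledger$cit_sites
  args <- ctx[ctx$residue == "R", c("protein_id", "position")]
  top <- sites[order(-sites$base_intensity), ][1:75, ]
  res <- plddt_site_summary(ctx, list(all_args = args,
                                      sites = sites,
                                      top = top))
  # planted abundance-order correlation: top sites have higher median pLDDT
  expect_gt(res$summary$median[res$summary$selection == "top"],
            res$summary$median[res$summary$selection == "sites"])
  # a site pointing at a non-arginine is counted as mismatched
  bad <- data.frame(protein_id = ctx$protein_id[ctx$residue != "R"][1],
                    position = ctx$position[ctx$residue != "R"][1])
  res2 <- plddt_site_summary(ctx, list(bad = bad, ok = args[1, ]))
  expect_equal(res2$n_mismatched, 1L)
})

test_that("secondary-structure enrichment is null on identical groups and BH-adjusted", {
  config <- synth_config(4)
  proteome <- synth_proteome(config)
  structures <- synth_structures(config, proteome)
  ctx <- structures$context
  args <- ctx[ctx$residue == "R", c("protein_id", "position")]
  res <- secondary_structure_enrichment(ctx, list(same = args), args)
  expect_true(all(abs(res$fe[!is.na(res$fe)] - 1) < 1e-9))
  expect_true(all(res$q[!is.na(res$q)] >= 0.05))
  expect_error(secondary_structure_enrichment(
    within(ctx, ss[1] <- "X"), list(a = args), args), "unknown")
})

test_that("planted turn enrichment grows from all sites to the top selection", {
  config <- synth_config(5)
  proteome <- synth_proteome(config)
  structures <- synth_structures(config, proteome)
  ev <- synth_evidence(config, proteome, structures)
  ctx <- structures$context
  sites <- ev$ledger$cit_sites
  args <- ctx[ctx$residue == "R", c("protein_id", "position")]
  ord <- sites[order(-sites$base_intensity), ]
  res <- secondary_structure_enrichment(
    ctx, list(all_sites = sites, top = ord[1:60, ]), args)
  fe_turn <- setNames(res$fe[res$ss == "T"], res$group[res$ss == "T"])
  expect_gt(fe_turn[["top"]], fe_turn[["all_sites"]])
})
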