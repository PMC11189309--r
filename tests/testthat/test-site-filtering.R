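# Evidence parsing and the two-tier localization filter into quantified
# citrullination sites.

make_psm <- function(loc, protein = "P1", pos = 10L, mod = "citrullination",
                     residue = "R", condition = "A", replicate = 1L,
                     intensity = 100, nl = FALSE) {
  data.frame(peptide_sequence = "PEPTIDEK", protein_id = protein,
             residue = residue, position = pos, mod_label = mod,
             localization_prob = loc, intensity = intensity,
             condition = condition, replicate = replicate, fraction = 1L,
             mass_error = 0, neutral_loss = nl, stringsAsFactors = FALSE)
}

test_that("evidence round-trips through TSV with mod labels intact", {
  psm <- rbind(make_psm(0.95), make_psm(0.8, mod = "deamidation", residue = "N"),
               make_psm(0.0, mod = "none"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(psm, path)
  back <- read_evidence(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$mod_label, psm$mod_label)
  expect_equal(back$localization_prob, psm$localization_prob)
})

test_that("empty localization fields become 0 and are counted, not dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  psm <- make_psm(0.95)
  write_evidence(psm, path)
  txt <- readLines(path)
  txt[2] <- sub("0.95", "", txt[2])
  writeLines(txt, path)
  back <- read_evidence(path)
  expect_equal(back$localization_prob, 0)
  expect_equal(attr(back, "parse_log")$n_bad_localization, 1L)
})

test_that("missing columns and empty files are rejected by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), path)
  expect_error(read_evidence(path), "peptide_sequence")
  writeLines("peptide_sequence", path)
  expect_error(read_evidence(path), "empty|missing")
})

test_that("identification needs one PSM above 0.90; quantification pools above 0.75", {
  psm <- rbind(make_psm(0.95, replicate = 1L, intensity = 100),
               make_psm(0.80, replicate = 1L, intensity = 50),
               make_psm(0.60, replicate = 1L, intensity = 1000))
  sites <- build_sites(psm)
  expect_equal(nrow(sites), 1L)
  quant <- attr(sites, "quant")
  expect_equal(quant$intensity, 150)  # 0.60 PSM excluded from quantification

  # a lone 0.85 PSM fails the identification threshold
  expect_equal(nrow(build_sites(make_psm(0.85))), 0L)
  # strict ">": exactly 0.90 does not identify
  expect_equal(nrow(build_sites(make_psm(0.90))), 0L)
})

test_that("citrullination PSMs not on arginine are excluded and counted", {
  psm <- rbind(make_psm(0.99), make_psm(0.99, residue = "K", pos = 20L))
  sites <- build_sites(psm)
  expect_equal(nrow(sites), 1L)
  expect_equal(attr(sites, "n_inconsistent"), 1L)
})

test_that("filtering is monotone in the identification threshold", {
  set.seed(11)
  psm <- do.call(rbind, lapply(1:200, function(i)
    make_psm(runif(1), protein = sample(c("P1", "P2", "P3"), 1),
             pos = sample(1:30, 1))))
  thresholds <- c(0.5, 0.7, 0.9, 0.95, 0.99)
  site_sets <- lapply(thresholds, function(th)
    build_sites(psm, id_threshold = th, quant_threshold = 0.5)$site)
  for (i in seq_len(length(thresholds) - 1))
    expect_true(all(site_sets[[i + 1]] %in% site_sets[[i]]))
})

test_that("aggregation matches an independent group-by-sum and conserves totals", {
  set.seed(3)
  psm <- do.call(rbind, lapply(1:120, function(i)
    make_psm(1, protein = sample(c("P1", "P2"), 1), pos = sample(1:5, 1),
             condition = sample(c("A", "B"), 1), replicate = sample(1:3, 1),
             intensity = runif(1, 1, 100))))
  agg <- aggregate_intensity(psm)
  # oracle: tapply over a pasted key
  key <- paste(site_key(psm$protein_id, psm$position), psm$condition,
               psm$replicate)
  oracle <- tapply(psm$intensity, key, sum)
  got <- setNames(agg$intensity, paste(agg$site, agg$condition, agg$replicate))
  expect_setequal(names(got), names(oracle))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle))
  expect_equal(sum(agg$intensity), sum(psm$intensity))
  expect_error(aggregate_intensity(make_psm(1, intensity = -5)), "negative")
})

test_that("missing replicates stay missing (not zero) in the site matrix", {
  psm <- rbind(make_psm(0.95, replicate = 1L, intensity = 100),
               make_psm(0.95, replicate = 2L, intensity = 200),
               make_psm(0.95, pos = 11L, replicate = 1L, intensity = 50))
  sites <- build_sites(psm)
  sm <- site_matrix(attr(sites, "quant"))
  expect_true(is.na(sm$values["P1:11", "A.2"]))
  expect_false(sm$observed["P1:11", "A.2"])
})

test_that("normalization centers column medians at zero and preserves ranks", {
  set.seed(5)
  m <- matrix(rnorm(60, mean = 20), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("A.", 1:6)))
  m[sample(60, 10)] <- NA
  sm <- structure(list(values = m, observed = !is.na(m),
                       condition = rep("A", 6)), class = "site_matrix")
  out <- normalize_impute(sm, seed = 42)
  for (j in 1:6) {
    obs <- sm$observed[, j]
    expect_equal(median(out$values[obs, j]), 0, tolerance = 1e-9)
    expect_equal(order(out$values[obs, j]), order(m[obs, j]))
  }
  expect_false(anyNA(out$values))
})

test_that("imputation is seeded and deterministic; fully observed is a no-op", {
  set.seed(6)
  m <- matrix(rnorm(40, 20), 10, 4, dimnames = list(paste0("s", 1:10),
                                                    paste0("A.", 1:4)))
  m2 <- m; m2[c(3, 17, 25)] <- NA
  sm <- structure(list(values = m2, observed = !is.na(m2),
                       condition = rep("A", 4)), class = "site_matrix")
  a <- normalize_impute(sm, seed = 9)
  b <- normalize_impute(sm, seed = 9)
  expect_identical(a$values, b$values)
  # imputed values are drawn below the observed bulk
  expect_lt(max(a$values[!sm$observed]), median(a$values[sm$observed]))

  full <- structure(list(values = m, observed = !is.na(m),
                         condition = rep("A", 4)), class = "site_matrix")
  out <- normalize_impute(full, seed = 1)
  centered <- sweep(m, 2, apply(m, 2, median))
  expect_equal(out$values, centered)
})

test_that("core sites require an observed value in every condition", {
  obs <- rbind(s1 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
               s2 = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- matrix(0, 2, 5, dimnames = list(rownames(obs), paste0("c", 1:5, ".1")))
  sm <- structure(list(values = m, observed = obs,
                       condition = paste0("c", 1:5)), class = "site_matrix")
  expect_identical(core_sites(sm, paste0("c", 1:5)), "s1")
  expect_setequal(core_sites(sm, paste0("c", 1:4)), c("s1", "s2"))
  expect_error(core_sites(sm, c("c1", "nope")), "unknown")
})

test_that("neutral-loss shares by count and intensity behave as defined", {
  psm <- rbind(make_psm(1, nl = TRUE), make_psm(1, nl = TRUE),
               make_psm(1, nl = TRUE), make_psm(1, nl = FALSE))
  s <- neutral_loss_summary(psm)
  expect_equal(s$count_share, 0.75)
  expect_equal(s$intensity_share, 0.75)
  all_on <- neutral_loss_summary(rbind(make_psm(1, nl = TRUE)))
  expect_equal(all_on$count_share, 1)
  expect_equal(all_on$intensity_share, 1)
  expect_error(neutral_loss_summary(make_psm(1)[0, ]), "no PSMs")
})

test_that("deamidation decoys on N/Q never enter the citrullination site list", {
  config <- synth_config(21)
  proteome <- synth_proteome(config)
  ev <- synth_evidence(config, proteome)
  sites <- build_sites(ev$psm)
  expect_length(intersect(sites$site, ev$ledger$deamid_sites), 0L)
})
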