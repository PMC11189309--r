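# End-to-end orchestration of the synthetic study: generation, filtering,
# quantification, stoichiometry, dose-response, structural context, motif and
# microarray analysis, with a consolidated deterministic summary.

#' Default run configuration
#'
#' Houses the pipeline's named constants: localization thresholds (0.90 for
#' identification, 0.75 for quantification), mass tolerance 0.002 Da,
#' coordination-number radius 13 A, disorder cutoff 0.5 with region lengths
#' >= 31 (long) and 2-30 (short), RSA bin width 0.02, and motif alpha 0.05.
#'
#' @param seed master seed (also drives the synthetic generators).
#' @return named list.
#' @export
run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    id_threshold = 0.90,
    quant_threshold = 0.75,
    mass_tolerance = 0.002,
    cn_radius = 13,
    disorder_cutoff = 0.5,
    long_disorder_min = 31L,
    short_disorder_range = c(2L, 30L),
    rsa_bin = 0.02,
    motif_alpha = 0.05,
    impute_width = 0.3,
    impute_downshift = 1.8,
    synth = synth_config(seed)
  )
}

.required_run_fields <- c("seed", "id_threshold", "quant_threshold",
                          "mass_tolerance", "cn_radius", "disorder_cutoff",
                          "long_disorder_min", "short_disorder_range",
                          "rsa_bin", "motif_alpha", "impute_width",
                          "impute_downshift")

#' Validate a run configuration
#'
#' @param config list as from [run_config()] (possibly read from YAML).
#' @return the config, invisibly; errors name the first missing field.
#' @export
validate_run_config <- function(config) {
  miss <- setdiff(.required_run_fields, names(config))
  if (length(miss)) stop("run configuration is missing field(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(config$id_threshold >= config$quant_threshold,
            config$mass_tolerance > 0, config$cn_radius > 0)
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list (for writing).
#' @return for `read_run_config`, the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic proteome, structures, features, evidence, TF edges
#' and microarray; runs site filtering, normalization/imputation, core-set
#' calling, neutral-loss accounting, occupancy, dose-response fitting,
#' feature/structure enrichment, motif analysis, TF scoring and the
#' microarray pipeline; writes per-stage TSVs and a summary JSON to
#' `out_dir`. The run is a pure function of the configuration seed: the
#' same config yields a byte-identical summary JSON.
#'
#' @param config run configuration from [run_config()].
#' @param out_dir output directory (created if needed); NULL to skip file
#'   output.
#' @return list with all stage results and `summary` (the list serialized to
#'   `summary.json`).
#' @export
run_citrullinome <- function(config = run_config(), out_dir = NULL) {
  validate_run_config(config)
  sc <- config$synth

  proteome <- synth_proteome(sc)
  structures <- synth_structures(sc, proteome)
  features <- synth_features(sc, structures)
  evidence <- synth_evidence(sc, proteome, structures, features)
  array <- synth_array(sc, proteome, evidence)
  tf <- synth_tf_edges(sc)

  sites <- build_sites(evidence$psm, config$id_threshold,
                       config$quant_threshold)
  quant <- attr(sites, "quant")
  sm <- site_matrix(quant)
  smn <- normalize_impute(sm, seed = config$seed,
                          width = config$impute_width,
                          downshift = config$impute_downshift)
  core <- core_sites(sm, sc$conditions)
  cit_psm <- evidence$psm[evidence$psm$mod_label == "citrullination" &
                            site_key(evidence$psm$protein_id,
                                     evidence$psm$position) %in% sites$site, ]
  nl <- neutral_loss_summary(cit_psm)

  # occupancy from matched counterparts, per condition
  occ_med <- vapply(sc$conditions, function(cond) {
    d <- evidence$counterpart[evidence$counterpart$condition == cond, ]
    stats::median(occupancy(d$modified, d$unmodified)$occupancy, na.rm = TRUE)
  }, numeric(1))

  # dose-response on mean responses across replicates
  dmean <- stats::aggregate(response ~ concentration, data = evidence$dose,
                            FUN = mean)
  dmean <- dmean[order(dmean$concentration), ]
  ic50 <- fit_ic50(dmean$concentration, dmean$response)

  # feature enrichment (global coordinates via per-protein offsets)
  ctx <- structures$context
  offset_of <- c(0, cumsum(vapply(split(ctx$position, ctx$protein_id), max,
                                  numeric(1))))
  prot_levels <- names(split(ctx$position, ctx$protein_id))
  glob <- function(df) df$position +
    offset_of[match(df$protein_id, prot_levels)]
  arg_ctx <- ctx[ctx$residue == "R", ]
  cit_set <- sites$site
  arg_is_cit <- site_key(arg_ctx$protein_id, arg_ctx$position) %in% cit_set
  feat_glob <- data.frame(start = glob(data.frame(protein_id = features$protein_id,
                                                  position = features$start)),
                          end = glob(data.frame(protein_id = features$protein_id,
                                                position = features$end)),
                          kind = features$kind)
  enr <- do.call(rbind, lapply(unique(features$kind), function(k) {
    res <- feature_enrichment(glob(arg_ctx[arg_is_cit, ]),
                              glob(arg_ctx),
                              feat_glob[feat_glob$kind == k, ])
    cbind(kind = k, res)
  }))

  # motif around identified sites vs all arginines in citrullinated proteins
  cit_prot <- unique(sites$protein_id)
  bg_pos <- proteome$registry[proteome$registry$protein_id %in% cit_prot, ]
  bg_key <- site_key(bg_pos$protein_id, bg_pos$position)
  fg_pos <- sites[c("protein_id", "position")]
  bg_only <- bg_pos[!(bg_key %in% cit_set), ]
  motif <- motif_enrichment(
    extract_windows(proteome$sequences, fg_pos, flank = 7L)$window,
    extract_windows(proteome$sequences, bg_only, flank = 7L)$window,
    alpha = config$motif_alpha)

  tf_scores <- score_targets(tf$edges, tf$tf_flags)
  pairs <- pair_statistics(array$spots)

  summary <- list(
    seed = config$seed,
    n_psm = nrow(evidence$psm),
    n_sites = nrow(sites),
    n_proteins = length(unique(sites$protein_id)),
    n_core_sites = length(core),
    mean_best_localization = round(mean(sites$best_localization), 6),
    neutral_loss_count_share = round(nl$count_share, 6),
    neutral_loss_intensity_share = round(nl$intensity_share, 6),
    occupancy_median = as.list(round(occ_med, 6)),
    ic50_uM = round(ic50$ic50, 6),
    ic50_converged = ic50$converged,
    feature_fe = stats::setNames(as.list(round(enr$fe, 6)), enr$kind),
    n_significant_motif_letters = sum(motif$significant &
                                        is.finite(motif$z) & motif$z > 0),
    top_tf_target = tf_scores$target[1],
    n_array_pairs = nrow(pairs) / length(unique(pairs$fluid))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sites(sites, file.path(out_dir, "sites.tsv"), smn,
                file.path(out_dir, "site_matrix.tsv"))
    utils::write.table(enr, file.path(out_dir, "feature_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(motif, file.path(out_dir, "motif.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tf_scores, file.path(out_dir, "tf_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(out_dir, "array_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(proteome = proteome, structures = structures,
                 features = features, evidence = evidence, array = array,
                 sites = sites, matrix = smn, core = core,
                 neutral_loss = nl, occupancy_median = occ_med, ic50 = ic50,
                 enrichment = enr, motif = motif, tf_scores = tf_scores,
                 pairs = pairs, summary = summary))
}
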