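# End-to-end orchestration: simulate -> preprocess -> align -> enrich ->
# sitecall -> aggregate, driven by a single config with a master seed, with
# manifest logging and a parameter-recovery report against the emitted
# ground truth.

#' Preset parameter sets
#'
#' Named bundles of stage parameters: `toy` (the package's standard study
#' conditions: 200 miRNA-sized loci, 30 modified, 5e4 molecules, 3
#' replicate pairs), `plant_flower` (20-25 nt, no quality filter),
#' `plant_pollen` (18-30 nt, TE-rich reference), `mouse_testis` (14-44 nt,
#' Q20 over 90%, up to 3 mismatches).
#'
#' @param name preset name.
#' @return list of stage parameters.
#' @export
pipeline_preset <- function(name = c("toy", "plant_flower", "plant_pollen",
                                     "mouse_testis")) {
  name <- match.arg(name)
  base <- list(
    reference = list(n_mirna = 200L, n_te_families = 0L, rrna_len = 0L,
                     n_trna = 0L, n_genes = 0L),
    truth = list(n_modified = 30L, stoich_range = c(0.5, 1),
                 five_prime_bias = 0),
    sim = list(),
    min_len = 15L, max_len = 30L, apply_quality = FALSE,
    max_mismatch = 1L, min_mean = 10, alpha = 0.01,
    min_reads = 5, min_fold = 1.5)
  switch(name,
    toy = base,
    plant_flower = utils::modifyList(base, list(min_len = 20L,
                                                max_len = 25L)),
    plant_pollen = utils::modifyList(base, list(
      min_len = 18L, max_len = 30L,
      reference = list(n_mirna = 60L, n_te_families = 6L, rrna_len = 1500L,
                       n_trna = 4L, n_genes = 0L))),
    mouse_testis = utils::modifyList(base, list(
      min_len = 14L, max_len = 44L, apply_quality = TRUE,
      max_mismatch = 3L)))
}

enrichment_by_feature <- function(res, seq2feat) {
  res$feature_id_seq <- res$feature_id
  res$feature_id <- seq2feat[res$feature_id_seq]
  res <- res[!is.na(res$feature_id), , drop = FALSE]
  # representative-sequence rule: a feature is summarized by its member
  # sequence with the smallest p-value
  o <- order(res$pvalue, res$feature_id_seq)
  res <- res[o, , drop = FALSE]
  res <- res[!duplicated(res$feature_id), , drop = FALSE]
  res[order_radix(res$feature_id), , drop = FALSE]
}

#' Run the full pipeline on a config
#'
#' Executes every stage under a single master seed fanned out through named
#' substreams, writes all result tables, a YAML manifest and a JSON report
#' into `outdir`, and returns the in-memory results. Re-running the same
#' config yields byte-identical tables.
#'
#' @param config list with elements `preset` (see [pipeline_preset()]),
#'   `master_seed`, and optional overrides for `reference`, `truth`, `sim`
#'   and stage parameters; or a path to a YAML file with those fields.
#' @param outdir output directory.
#' @param verbose log stage progress.
#' @return list of class `PipelineResult` with reference, truth, collapsed
#'   counts, alignments, enrichment tables, site calls, consensus and the
#'   report.
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  preset <- pipeline_preset(config$preset %||% "toy")
  cfg <- utils::modifyList(preset, config[setdiff(names(config),
                                                  c("preset"))])
  seed <- as.integer(cfg$master_seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  log_msg("simulate", "INFO", "building reference and libraries", verbose)
  ref_spec <- do.call(reference_spec, cfg$reference)
  ref <- build_toy_reference(ref_spec, seed = seed)
  truth <- do.call(assign_psi_sites,
                   c(list(ref = ref, seed = seed), cfg$truth))
  sim_cfg <- do.call(sim_config, c(list(master_seed = seed), cfg$sim))
  sim <- simulate_libraries(ref, truth, sim_cfg)
  write_reference(ref, file.path(outdir, "reference.fasta"),
                  file.path(outdir, "features.bed"))
  write_tsv(sim$truth$sites, file.path(outdir, "truth_sites.tsv"))
  write_tsv(sim$metadata, file.path(outdir, "sample_sheet.tsv"))

  log_msg("preprocess", "INFO", "trim/filter/collapse", verbose)
  reads_list <- lapply(sim$libraries, `[[`, "reads")
  collapsed <- preprocess_reads(
    reads_list,
    adapter = if (sim_cfg$raw_mode) sim_cfg$adapter3 else NULL,
    random_ends = if (sim_cfg$raw_mode) sim_cfg$random_ends else 0L,
    min_len = cfg$min_len, max_len = cfg$max_len,
    apply_quality = cfg$apply_quality)
  collapsed_q <- collapse_reads(reads_list, keep_quality = TRUE)
  write_tsv(collapsed, file.path(outdir, "collapsed_counts.tsv"))

  log_msg("align", "INFO", "aligning collapsed sequences", verbose)
  aln <- align_reads(collapsed, ref, max_mismatch = cfg$max_mismatch,
                     policy = "all_best")
  aln <- annotate_alignments(aln, ref)
  seq2feat <- setNames(aln$feature_id[!duplicated(aln$sequence)],
                       aln$sequence[!duplicated(aln$sequence)])

  meta <- sim$metadata
  results <- list()
  for (contrast in list(c("ip_bound", "ip_unbound"),
                        c("cmc_plus", "cmc_mock"))) {
    libs <- meta$library[meta$condition %in% contrast]
    if (!length(libs)) next
    sub <- collapsed[, c("sequence", libs)]
    class(sub) <- class(collapsed)
    cm <- build_count_matrix(sub, meta, min_mean = cfg$min_mean)
    if (!nrow(cm$counts)) next
    sf <- tryCatch(compute_size_factors(cm), error = function(e) {
      log_msg("enrich", "WARN",
              "falling back to pseudo-reference size factors", verbose)
      compute_size_factors(cm, pseudo_reference = TRUE)
    })
    disp <- estimate_dispersion(cm, sf)
    res <- test_enrichment(cm, sf, disp, contrast)
    nm <- if (contrast[1] == "ip_bound") "ip" else "cmc"
    results[[nm]] <- res
    write_tsv(res, file.path(outdir, paste0(nm, "_results.tsv")))
  }

  mn_calls <- NULL; site_calls <- NULL
  mn_libs <- meta$library[meta$condition == "mn_plus"]
  mock_libs <- meta$library[meta$condition == "mn_mock"]
  if (length(mn_libs)) {
    log_msg("sitecall", "INFO", "Mn2+ pileups and site calls", verbose)
    aln_del <- align_with_deletions(collapsed_q, ref,
                                    max_mismatch = cfg$max_mismatch,
                                    policy = "single_hit")
    quals <- attr(collapsed_q, "qual")
    pool_counts <- function(libs) {
      m <- as.matrix(collapsed_q[, libs, drop = FALSE])
      setNames(rowSums(m), collapsed_q$sequence)
    }
    pu_t <- build_pileup(aln_del, pool_counts(mn_libs), ref, quals = quals)
    pu_m <- build_pileup(aln_del, pool_counts(mock_libs), ref,
                         quals = quals)
    site_calls <- call_psi_sites(pu_t, pu_m, min_reads = cfg$min_reads,
                                 min_fold = cfg$min_fold)
    mn_calls <- call_psi_features(pu_t, pu_m, ref,
                                  min_reads = cfg$min_reads,
                                  min_fold = cfg$min_fold)
    write_tsv(site_calls[site_calls$called, , drop = FALSE],
              file.path(outdir, "mn_site_calls.tsv"))
    write_tsv(mn_calls, file.path(outdir, "mn_feature_calls.tsv"))
  }

  consensus <- NULL
  if (!is.null(results$ip) && !is.null(results$cmc) &&
      !is.null(mn_calls)) {
    ipf <- enrichment_by_feature(results$ip, seq2feat)
    cmcf <- enrichment_by_feature(results$cmc, seq2feat)
    consensus <- consensus_calls(ipf, cmcf, mn_calls, alpha = cfg$alpha)
    write_tsv(consensus, file.path(outdir, "consensus.tsv"))
  }

  report <- list(n_features = nrow(ref$features),
                 n_truth_sites = nrow(truth),
                 n_sequences_collapsed = nrow(collapsed))
  if (!is.null(consensus)) {
    report$venn <- as.list(attr(consensus, "venn"))
    if (nrow(truth)) {
      report$recovery <- recovery_metrics(consensus, truth)
    }
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), c("reference", "truth",
                                                      "sim"))],
                   master_seed = seed,
                   stages = c("simulate", "preprocess", "align", "enrich",
                              "sitecall", "consensus", "report"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  structure(list(ref = ref, truth = truth, sim_metadata = meta,
                 collapsed = collapsed, alignments = aln,
                 enrichment = results, site_calls = site_calls,
                 mn_feature_calls = mn_calls, consensus = consensus,
                 report = report, outdir = outdir),
            class = "PipelineResult")
}

#' Recovery metrics of consensus calls against ground truth
#'
#' Sensitivity (fraction of truly modified features, at or above a
#' stoichiometry floor, recovered by each assay and by the high-confidence
#' intersection) and false discovery fraction (called features that carry
#' no site at all).
#'
#' @param consensus output of [consensus_calls()].
#' @param truth a `PsiGroundTruth`.
#' @param stoich_min stoichiometry floor defining the recoverable set.
#' @return list of per-assay sensitivity and FDR values.
#' @export
recovery_metrics <- function(consensus, truth, stoich_min = 0.5) {
  modified <- unique(truth$feature_id[truth$stoich >= stoich_min])
  any_mod <- unique(truth$feature_id)
  out <- list()
  for (col in c("ip", "cmc", "mn", "high_confidence")) {
    called <- consensus$feature_id[consensus[[col]]]
    sens <- if (length(modified))
      mean(modified %in% called) else NA_real_
    fdr <- if (length(called))
      mean(!(called %in% any_mod)) else 0
    out[[paste0(col, "_sensitivity")]] <- sens
    out[[paste0(col, "_fdr")]] <- fdr
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
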