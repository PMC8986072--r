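#' Run the full analysis pipeline on a simulated study
#'
#' End-to-end driver: simulate a trio study, write its inputs, run
#' differential expression for the proband and parent contrasts, derive the
#' trio-shared / proband-unique partition, select markers and compute
#' composition scores, compare scores between groups, associate them with
#' clinical covariates, cluster samples on the trio-shared genes, and run
#' overlap enrichment of the DEG set against a collection built from the
#' simulation's own marker panels. All outputs are tab-delimited text with
#' 6-significant-digit floats, so a fixed seed yields byte-identical runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed passed to the simulation config.
#' @param config Optional [sim_config()]; its seed is overridden by `seed`
#'   when both are given.
#' @param gmt Optional `gene_set_collection` for the enrichment stage; by
#'   default a collection of the simulation's subset marker panels is used.
#' @param verbose Log stage dimensions and counts via `message()`.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_study <- function(out_dir, seed = 1L, config = NULL, gmt = NULL,
                      verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  cfg <- config %||% sim_config(seed = seed)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg <- validate_sim_config(cfg)

  # simulate
  study <- simulate_study(cfg)
  log_msg("simulate: %d genes x %d samples", nrow(study$expression$values),
    ncol(study$expression$values))
  write_expression(study$expression, file.path(out_dir, "expression.tsv"))
  write_table(study$metadata, file.path(out_dir, "metadata.tsv"))
  write_table(as_tibble(study$candidates), file.path(out_dir, "markers.tsv"))
  truth_report(study, out_dir)

  # differential expression
  de_prob <- fit_moderated(study$expression, study$metadata,
    contrast("proband", "HC"))
  de_moth <- fit_moderated(study$expression, study$metadata,
    contrast("mother", "HC"))
  log_msg("de: proband_vs_HC %d DEGs; mother_vs_HC %d DEGs",
    sum(de_prob$is_deg), sum(de_moth$is_deg))
  write_table(tidy(de_prob), file.path(out_dir, "de_proband_vs_HC.tsv"))
  write_table(tidy(de_moth), file.path(out_dir, "de_mother_vs_HC.tsv"))
  write_table(deg_summary(de_prob), file.path(out_dir, "deg_summary.tsv"))

  # set logic
  venn <- venn_partition(de_prob, de_moth, labels = c("proband", "mother"))
  log_msg("sets: %d shared, %d proband-unique, %d mother-unique",
    length(venn$shared), length(venn$a_unique), length(venn$b_unique))
  write_table(venn$counts, file.path(out_dir, "venn_counts.tsv"))
  readr::write_lines(sort(venn$shared), file.path(out_dir, "trio_shared.txt"))
  readr::write_lines(sort(venn$a_unique), file.path(out_dir, "proband_unique.txt"))

  # deconvolution
  panel <- select_markers(study$expression, study$candidates)
  scores <- composition_scores(study$expression, panel)
  log_msg("deconv: %d/%d candidates kept", nrow(panel), nrow(study$candidates))
  write_table(attr(panel, "selection_record"),
    file.path(out_dir, "selection_record.tsv"))
  write_table(tidy(scores), file.path(out_dir, "scores.tsv"))
  write_table(score_recovery_report(scores, study),
    file.path(out_dir, "score_recovery.tsv"))

  # group comparisons
  cmp <- compare_scores(scores, study$metadata)
  log_msg("compare: %d comparisons, %d significant after Holm-Sidak",
    nrow(cmp), sum(cmp$p_adjusted < 0.05))
  write_table(tidy(cmp), file.path(out_dir, "comparisons.tsv"))

  # clinical association
  assoc <- correlate_clinical(scores, study$metadata)
  strat <- subgroup_compare(scores, study$metadata, "cftr_class")
  log_msg("assoc: %d correlations, %d subgroup comparisons",
    nrow(assoc), nrow(strat))
  write_table(tidy(assoc), file.path(out_dir, "associations.tsv"))
  write_table(tidy(strat), file.path(out_dir, "subgroups.tsv"))

  # structure: cluster on the familial (trio-shared-like) gene set when the
  # DEG-derived shared set is small
  clust_genes <- venn$shared
  if (length(clust_genes) < 10) {
    clust_genes <- study$truth$genes$gene_id[
      study$truth$genes$role == "family_background"]
  }
  emb <- pca_embed(study$expression, clust_genes, study$metadata)
  cl <- hier_cluster(study$expression, clust_genes, study$metadata)
  adj <- family_adjacency(cl, study$metadata)
  log_msg("cluster: %d genes, family adjacency %.3f (chance %.3f)",
    length(clust_genes), adj$fraction, adj$chance_level)
  write_table(emb$coordinates[, 1:4], file.path(out_dir, "embedding.tsv"))
  write_table(tidy(cl), file.path(out_dir, "linkage.tsv"))
  write_table(tibble(fraction = adj$fraction, chance_level = adj$chance_level,
    n_samples = adj$n_samples), file.path(out_dir, "family_adjacency.tsv"))

  # enrichment: default collection = the simulation's subset marker panels
  if (is.null(gmt)) {
    truth_g <- study$truth$genes
    sets <- split(truth_g$gene_id[truth_g$role == "marker"],
      truth_g$subset[truth_g$role == "marker"])
    gmt <- gene_set_collection(sets, name = "subset_markers")
  }
  input_set <- de_prob$gene_id[de_prob$is_deg]
  enr <- NULL
  if (length(input_set) > 0) {
    enr <- enrich(input_set, gmt, gene_ids(study$expression))
    write_table(tidy(enr), file.path(out_dir, "enrichment.tsv"))
    log_msg("enrich: top set '%s' (q = %.3g)", enr$set_name[1], enr$fdr_q[1])
  } else {
    log_msg("enrich: skipped (no DEGs)")
  }

  invisible(list(study = study, de_proband = de_prob, de_mother = de_moth,
    venn = venn, panel = panel, scores = scores, comparisons = cmp,
    associations = assoc, subgroups = strat, embedding = emb,
    clustering = cl, adjacency = adj, enrichment = enr))
}
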