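#' Run the full synthetic-cohort pipeline end to end
#'
#' Chains every stage on data from the synthetic generators: taxonomic
#' reports -> five-step decontamination -> rare-taxon filter -> CLR ->
#' batch assessment/removal -> diversity, PERMANOVA and differential
#' abundance -> variance filter, VST and moderated differential expression
#' (per disease stage vs control) -> per-stage Lasso interaction networks ->
#' sparse CCA clusters (with pathway enrichment when gene sets are given) ->
#' single-cell microbe-carrying / active-cell analysis. All outputs are
#' written as TSV/JSON under `out_dir` and a manifest with parameter
#' snapshot, per-stage summary counts and file checksums is returned (and
#' written as `manifest.json`).
#'
#' @param config a [sim_config()]; its `seed` drives every stage
#' @param out_dir output directory
#' @param gene_sets optional named list of gene sets for GSEA / cluster
#'   enrichment
#' @param stages stages to build interaction networks for (default: all
#'   disease stages plus control)
#' @param skip character vector of stage names to skip, from
#'   `c("interact", "cca", "sc")`
#' @param n_splits,n_iter interaction-chain effort knobs (defaults 50, 100)
#' @param cca_K number of sparse CCA components
#' @return the manifest (invisibly written to `manifest.json`)
#' @export
run_all <- function(config, out_dir, gene_sets = NULL, stages = NULL,
                    skip = character(0), n_splits = 50L, n_iter = 100L,
                    cca_K = 5L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hepanet")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "stages")],
                   stages_run = list())
  note <- function(stage, ...) {
    manifest$stages_run[[stage]] <<- list(...)
  }

  ## decontamination on simulated classification reports
  rep_sim <- simulate_taxon_reports(config)
  ds_map <- stats::setNames(rep_sim$metadata$dataset,
                            rep_sim$metadata$sample_id)
  dec <- run_decontam(rep_sim$records,
                      read_length = config$read_length,
                      kmer_length = config$kmer_length,
                      datasets = ds_map)
  utils::write.table(dec$report$removed,
                     file.path(out_dir, "decontam_removed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("decontam",
       taxa_in = length(unique(rep_sim$records$name)),
       taxa_retained = length(dec$report$retained),
       removed_per_step = as.list(table(dec$report$removed$step)))

  ## bulk profile + expression with planted truth
  sim <- simulate_expression_and_profile(config)
  prof <- rare_taxon_filter(sim$profile)
  clr <- clr_transform(prof)
  meta <- sim$metadata

  bat <- permanova(aitchison_distance(clr), meta$dataset,
                   n_perm = 199L, seed = config$seed)
  clr_bc <- clr
  clr_bc$abundance <- t(remove_batch(t(clr$abundance), meta$dataset,
                                     preserve = meta[, "stage", drop = FALSE]))
  h <- shannon_index(prof)
  kw <- kruskal_wallis(split(h, meta$stage))
  da <- lapply(setdiff(levels(meta$stage), "control"), function(st) {
    differential_abundance(clr_bc, as.character(meta$stage), "control", st)
  })
  names(da) <- setdiff(levels(meta$stage), "control")
  write_matrix(clr_bc$abundance, file.path(out_dir, "clr_batchcorrected.tsv"))
  note("profile", taxa_after_rare_filter = ncol(prof$abundance),
       batch_permanova_p = bat$p, shannon_kruskal_p = kw$p_value,
       diff_taxa = lapply(da, function(d) sum(d$significant)))

  ## host expression
  expr <- variance_filter(sim$expression)
  lexpr <- remove_batch(vst(expr), meta$dataset,
                        preserve = meta[, "stage", drop = FALSE])
  de <- lapply(names(da), function(st) {
    moderated_de(lexpr, as.character(meta$stage), "control", st)
  })
  names(de) <- names(da)
  gsea <- NULL
  if (!is.null(gene_sets)) {
    ranks <- stats::setNames(de[[length(de)]]$t_mod, de[[length(de)]]$gene)
    gsea <- preranked_gsea(ranks, gene_sets, n_perm = 500L,
                           seed = config$seed)
    utils::write.table(gsea, file.path(out_dir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  note("deg", genes_tested = nrow(lexpr),
       degs = lapply(de, function(d) sum(d$is_deg)))

  ## per-stage interaction networks
  if (!"interact" %in% skip) {
    taxa_mat <- build_taxa_matrix(list(species = clr_bc$abundance))
    if (is.null(stages)) stages <- levels(meta$stage)
    nets <- lapply(stages, function(st) {
      sel <- meta$stage == st
      interaction_network(lexpr[, sel, drop = FALSE],
                          scale(taxa_mat[sel, , drop = FALSE]),
                          stage = st,
                          covariates = meta[sel, c("age", "sex"),
                                            drop = FALSE],
                          n_splits = n_splits, n_iter = n_iter,
                          seed = config$seed)
    })
    names(nets) <- stages
    summ <- build_stage_networks(nets)
    edges <- do.call(rbind, nets)
    utils::write.table(edges, file.path(out_dir, "interaction_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("interact", edges_per_stage = as.list(stats::setNames(
      summ$per_stage$n_edges, summ$per_stage$stage)))
  }

  ## sparse CCA functional clusters
  if (!"cca" %in% skip) {
    Xg <- scale(t(lexpr))
    keep <- apply(Xg, 2, function(v) all(is.finite(v)))
    Zt <- scale(clr_bc$abundance)
    comps <- sparse_cca(Xg[, keep, drop = FALSE], Zt, K = cca_K)
    clusters <- extract_clusters(comps)
    if (!is.null(gene_sets) && length(clusters)) {
      clusters <- enrich_clusters(clusters, gene_sets,
                                  universe = colnames(Xg)[keep])
    }
    jsonlite::write_json(
      lapply(clusters, function(cl) list(
        component = cl$component,
        genes = as.list(cl$genes), taxa = as.list(cl$taxa),
        canonical_correlation = cl$canonical_correlation)),
      file.path(out_dir, "cca_clusters.json"), auto_unbox = TRUE,
      digits = NA)
    note("cca", n_components = length(clusters),
         correlations = vapply(clusters, `[[`, numeric(1),
                               "canonical_correlation"))
  }

  ## single-cell co-localization
  if (!"sc" %in% skip) {
    sc <- simulate_single_cell(config)
    cells <- flag_microbe_carrying(sc$cells, sc$taxa_reads)
    enr <- celltype_enrichment(cells)
    cells <- active_interaction_cells(cells, sc$umi, sc$taxa_reads,
                                      sc$cluster)
    act <- summarize_active_by_type(cells)
    utils::write.table(enr, file.path(out_dir, "sc_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(act, file.path(out_dir, "sc_active_by_type.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("sc", carrying = sum(cells$microbe_carrying),
         active = sum(cells$active), cells = nrow(cells))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
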