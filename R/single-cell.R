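#' Flag microbe-carrying cells
#'
#' A cell carrying at least one filtered microbial read is "microbe-carrying";
#' a cell with none is "microbe-free". Idempotent.
#'
#' @param cells data.frame with one row per cell (barcode, cell_type,
#'   condition, ...)
#' @param taxa_reads cells x taxa non-negative read-count matrix, rows
#'   aligned to `cells$barcode`
#' @return `cells` with a logical `microbe_carrying` column
#' @export
flag_microbe_carrying <- function(cells, taxa_reads) {
  if (any(taxa_reads < 0)) stop("negative microbial read counts")
  stopifnot(nrow(taxa_reads) == nrow(cells))
  cells$microbe_carrying <- rowSums(taxa_reads) >= 1
  cells
}

#' Cell-type enrichment of microbe-carrying cells
#'
#' Within each condition, a Fisher exact test per cell type of
#' (carrying vs not) x (this type vs all others), with BH correction across
#' cell types. Reports the one-sided (enrichment) p alongside the two-sided.
#'
#' @param cells output of [flag_microbe_carrying()] with `cell_type` and
#'   `condition` columns (>= 2 cell types)
#' @return data.frame: condition, cell_type, carrying, total, odds_ratio,
#'   p_one_sided, p, fdr
#' @export
celltype_enrichment <- function(cells) {
  stopifnot("microbe_carrying" %in% names(cells))
  if (length(unique(cells$cell_type)) < 2L) stop("need >= 2 cell types")
  out <- lapply(split(cells, cells$condition), function(cc) {
    types <- unique(cc$cell_type)
    rows <- lapply(types, function(ty) {
      this <- cc$cell_type == ty
      if (!any(this)) return(NULL)
      tab <- matrix(c(sum(cc$microbe_carrying & this),
                      sum(cc$microbe_carrying & !this),
                      sum(!cc$microbe_carrying & this),
                      sum(!cc$microbe_carrying & !this)), 2, byrow = TRUE)
      ft <- fisher_exact(tab)
      data.frame(condition = cc$condition[1], cell_type = ty,
                 carrying = sum(cc$microbe_carrying & this),
                 total = sum(this), odds_ratio = ft$statistic,
                 p_one_sided = ft$p_one_sided, p = ft$p_value,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- adjust_pvalues(tab$p, "BH")$adjusted
    tab
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag active-interaction cells for one cluster
#'
#' A cell is "active" for an interaction cluster if it expresses at least one
#' cluster gene strictly above that gene's q-quantile across cells AND
#' carries at least one cluster taxon strictly above that taxon's q-quantile.
#' Quantiles (linear-interpolation type 7) are computed within condition.
#' Since quantiles of read counts are >= 0, activity implies
#' microbe-carrying.
#'
#' @param cells cell data.frame with `barcode` and `condition`
#' @param umi cells x genes UMI matrix, rows aligned to cells
#' @param taxa_reads cells x taxa read matrix, rows aligned to cells
#' @param cluster list with `genes` and `taxa` name vectors (weight names
#'   from [extract_clusters()] also work)
#' @param q quantile threshold, default 0.75
#' @param by_condition compute quantiles within condition (default TRUE)
#' @return `cells` with a logical `active` column
#' @export
active_interaction_cells <- function(cells, umi, taxa_reads, cluster,
                                     q = 0.75, by_condition = TRUE) {
  genes <- intersect(if (is.null(names(cluster$genes))) cluster$genes
                     else names(cluster$genes), colnames(umi))
  taxa <- intersect(if (is.null(names(cluster$taxa))) cluster$taxa
                    else names(cluster$taxa), colnames(taxa_reads))
  if (!length(genes) || !length(taxa)) {
    stop("cluster features missing from the cell data: need >= 1 of genes [",
         paste(setdiff(cluster$genes, colnames(umi)), collapse = ","),
         "] and taxa [",
         paste(setdiff(cluster$taxa, colnames(taxa_reads)), collapse = ","),
         "]")
  }
  groups <- if (by_condition) cells$condition else rep("all", nrow(cells))
  active <- logical(nrow(cells))
  for (g in unique(groups)) {
    sel <- groups == g
    eg <- umi[sel, genes, drop = FALSE]
    tg <- taxa_reads[sel, taxa, drop = FALSE]
    gq <- apply(eg, 2, stats::quantile, probs = q, type = 7)
    tq <- apply(tg, 2, stats::quantile, probs = q, type = 7)
    gene_hit <- rowSums(sweep(eg, 2, gq, ">")) > 0
    taxon_hit <- rowSums(sweep(tg, 2, tq, ">")) > 0
    active[sel] <- gene_hit & taxon_hit
  }
  cells$active <- active
  cells
}

#' Summarize active cells by cell type and condition
#'
#' @param cells output of [active_interaction_cells()] with `cell_type`,
#'   `condition`, `active`
#' @return data.frame: condition, cell_type, n_active, n_cells, fraction (of
#'   the condition's active cells; sums to 1 within condition when any cell
#'   is active)
#' @export
summarize_active_by_type <- function(cells) {
  stopifnot(all(c("active", "cell_type", "condition") %in% names(cells)))
  out <- lapply(split(cells, cells$condition), function(cc) {
    tot_active <- sum(cc$active)
    tab <- lapply(unique(cc$cell_type), function(ty) {
      this <- cc$cell_type == ty
      data.frame(condition = cc$condition[1], cell_type = ty,
                 n_active = sum(cc$active & this), n_cells = sum(this),
                 fraction = if (tot_active > 0)
                   sum(cc$active & this) / tot_active else 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, tab)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
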