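#' Simulation configuration for the synthetic NAFLD cohort
#'
#' Builds the configuration object consumed by the three generators
#' ([simulate_taxon_reports()], [simulate_expression_and_profile()],
#' [simulate_single_cell()]). Defaults emulate a multi-dataset liver RNA-seq
#' cohort spanning the four histological stages (control, NAFL, Borderline,
#' NASH): several batches ("datasets"), short 150 bp reads classified with
#' 31-mers, planted differential genes and taxa, and planted linear
#' gene-by-taxon couplings on the log2-expression / CLR-abundance scale.
#'
#' @param seed integer master seed; every generator call is deterministic
#'   given (config, seed)
#' @param n_datasets number of datasets (batches)
#' @param samples_per_stage named integer vector of samples per stage,
#'   names control/NAFL/Borderline/NASH
#' @param n_genes number of host genes in the bulk expression matrix
#' @param n_taxa total taxa in the classification reports (genuine +
#'   contaminant)
#' @param n_contaminants planted contaminant taxa, split evenly over the four
#'   signature classes: low unique k-mers, low total k-mers, decorrelated
#'   statistics, blacklisted name
#' @param read_length,kmer_length sequencing read and classifier k-mer length
#'   (bp); the unique-k-mer decontamination threshold is
#'   `read_length - kmer_length + 1`
#' @param n_de_genes,de_log2fc planted differentially expressed genes and the
#'   magnitude of their stage shift (log2 scale, random sign per gene)
#' @param n_diff_taxa,da_log2fc planted differentially abundant taxa and the
#'   magnitude of their compositional stage shift (log2 scale)
#' @param n_interactions,interaction_beta,noise_sd planted gene-taxon
#'   couplings: gene log2-expression = baseline + beta * CLR(taxon) + noise
#' @param batch_sd standard deviation of per-(gene, dataset) additive batch
#'   shifts on the log2 scale (and of the per-dataset taxa batch factors)
#' @param n_cells,n_cell_types,n_sc_genes,n_sc_taxa single-cell matrix sizes
#' @param fraction_carrying expected fraction of cells carrying >= 1 microbial
#'   read; enrichment is concentrated in the first cell type
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_datasets = 3L,
                       samples_per_stage = c(control = 80L, NAFL = 80L,
                                             Borderline = 80L, NASH = 80L),
                       n_genes = 2000L,
                       n_taxa = 150L,
                       n_contaminants = 40L,
                       read_length = 150L,
                       kmer_length = 31L,
                       n_de_genes = 50L,
                       de_log2fc = 2,
                       n_diff_taxa = 10L,
                       da_log2fc = 2.5,
                       n_interactions = 10L,
                       interaction_beta = 0.8,
                       noise_sd = 0.3,
                       batch_sd = 0.5,
                       n_cells = 600L,
                       n_cell_types = 5L,
                       n_sc_genes = 200L,
                       n_sc_taxa = 8L,
                       fraction_carrying = 0.3) {
  stages <- c("control", "NAFL", "Borderline", "NASH")
  if (is.null(names(samples_per_stage))) names(samples_per_stage) <- stages
  stopifnot(kmer_length <= read_length, kmer_length >= 1,
            n_contaminants <= n_taxa, n_de_genes <= n_genes,
            n_diff_taxa + n_interactions <= n_taxa - n_contaminants,
            all(samples_per_stage >= 0), n_datasets >= 1,
            n_cells >= n_cell_types, n_cell_types >= 1,
            fraction_carrying >= 0, fraction_carrying <= 1)
  cfg <- as.list(environment())
  cfg$stages <- stages
  class(cfg) <- "sim_config"
  cfg
}

# Stage/dataset layout shared by the bulk generators: samples are assigned to
# datasets round-robin within stage so stage is never confounded with batch.
sim_metadata <- function(config) {
  stage <- rep(names(config$samples_per_stage), config$samples_per_stage)
  n <- length(stage)
  dataset <- integer(n)
  for (s in unique(stage)) {
    idx <- which(stage == s)
    dataset[idx] <- ((seq_along(idx) - 1L) %% config$n_datasets) + 1L
  }
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    stage = factor(stage, levels = config$stages),
    dataset = paste0("DS", dataset),
    age = round(stats::rnorm(n, 45, 12)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    platform = paste0("PL", dataset),  # platform tracks dataset, as in pooled cohorts
    stringsAsFactors = FALSE
  )
}

# Names for a small synthetic taxonomy; each taxon is a species with a full
# lineage so rank aggregation and blacklist lineage matching are exercised.
sim_lineage <- function(i, genus = sprintf("Genus%02d", ((i - 1) %% 25) + 1)) {
  phylum <- sprintf("Phylum%02d", ((i - 1) %% 6) + 1)
  paste("Bacteria", phylum, sprintf("Class%02d", ((i - 1) %% 10) + 1),
        sprintf("Order%02d", ((i - 1) %% 15) + 1),
        sprintf("Family%02d", ((i - 1) %% 20) + 1),
        genus, sprintf("%s species%03d", genus, i), sep = "|")
}

#' Simulate per-sample taxonomic classification reports with planted
#' contaminants
#'
#' Emulates KrakenUniq-style per-sample reports: for each (sample, taxon)
#' record, a read count plus total and unique k-mer counts. Genuine taxa have
#' the signature of real organisms — unique k-mers scale with reads times the
#' number of k-mers per read (up to a genome-size cap and a per-taxon k-mer
#' uniformity factor), total k-mers well above five times the reads, and the
#' three statistics co-monotone across samples. Contaminants fall in four
#' signature classes, each designed to trip exactly one decontamination rule:
#' \describe{
#'   \item{low_unique}{unique k-mers below `read_length - kmer_length + 1`}
#'   \item{low_total}{total k-mers at most five times the read count}
#'   \item{decorrelated}{reads / unique / total statistically independent
#'     across samples}
#'   \item{blacklist}{named after a reagent-contaminant genus from the
#'     bundled blacklist}
#' }
#'
#' @param config a [sim_config()]
#' @param blacklist character vector of contaminant genus names used to name
#'   class-`blacklist` taxa; defaults to the bundled reagent list
#' @return list with `records` (a long data.frame of TaxonRecord rows:
#'   sample_id, taxon_id, name, rank, lineage, reads, total_kmers,
#'   unique_kmers), `metadata` (sample table), and `truth` (per-class
#'   contaminant names and the genuine taxon names)
#' @export
simulate_taxon_reports <- function(config, blacklist = default_blacklist()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  meta <- sim_metadata(config)
  n_samp <- nrow(meta)
  thr <- unique_kmer_threshold(config$read_length, config$kmer_length)
  kmers_per_read <- config$read_length - config$kmer_length + 1

  n_cont <- config$n_contaminants
  per_class <- n_cont %/% 4L
  classes <- rep(c("low_unique", "low_total", "decorrelated", "blacklist"),
                 c(per_class, per_class, per_class, n_cont - 3L * per_class))
  n_gen <- config$n_taxa - n_cont

  gen_names <- vapply(seq_len(n_gen), function(i) {
    sub(".*\\|", "", sim_lineage(i))
  }, character(1))
  bl_genera <- rep_len(blacklist, sum(classes == "blacklist"))
  cont_names <- character(n_cont)
  gi <- n_gen
  for (j in seq_len(n_cont)) {
    gi <- gi + 1L
    cont_names[j] <- if (classes[j] == "blacklist") {
      sprintf("%s species%03d", bl_genera[sum(classes[seq_len(j)] == "blacklist")], gi)
    } else {
      sub(".*\\|", "", sim_lineage(gi))
    }
  }

  make_block <- function(name, idx, class) {
    # per-taxon latent scale; per-sample reads vary log-normally around it
    mu <- stats::rlnorm(1, log(60), 0.6)
    reads <- pmax(5L, round(stats::rlnorm(n_samp, log(mu), 0.5)))
    u_t <- stats::runif(1, 0.3, 0.8)     # k-mer uniformity (genome coverage)
    m_t <- stats::runif(1, 1.8, 3)       # total-to-unique k-mer multiplicity
    if (is.na(class) || class == "blacklist") {
      unique_k <- pmax(thr, round(reads * kmers_per_read * u_t))
      total_k <- round(unique_k * m_t)
    } else if (class == "low_unique") {
      # few distinct k-mers despite many reads: repetitive / artifact signal
      unique_k <- pmin(thr - 1L, pmax(1L, round(reads * 0.15)))
      total_k <- round(6 * reads) + unique_k
    } else if (class == "low_total") {
      # sparse random hits: k-mer yield barely above one per read
      reads <- pmax(40L, reads)
      total_k <- round(4 * reads)
      unique_k <- pmax(thr, round(0.8 * total_k))
    } else { # decorrelated: the three statistics drawn independently
      unique_k <- pmax(thr, round(stats::rlnorm(n_samp, log(mu * kmers_per_read * u_t), 0.5)))
      total_k <- round(6 * pmax(5, stats::rlnorm(n_samp, log(mu), 0.5))) +
        pmax(unique_k, round(unique_k * stats::runif(n_samp, 1, 1.5)))
      reads <- sample(reads)  # break the reads link too
      total_k <- pmax(total_k, round(5 * reads) + 1L, unique_k)
    }
    lineage <- if (!is.na(class) && class == "blacklist") {
      sim_lineage(idx, genus = sub(" species.*", "", name))
    } else sim_lineage(idx)
    data.frame(
      sample_id = meta$sample_id,
      taxon_id = sprintf("T%04d", idx),
      name = name, rank = "species", lineage = lineage,
      reads = as.integer(reads),
      total_kmers = as.integer(pmax(total_k, unique_k)),
      unique_kmers = as.integer(unique_k),
      stringsAsFactors = FALSE
    )
  }

  blocks <- vector("list", config$n_taxa)
  for (i in seq_len(n_gen)) blocks[[i]] <- make_block(gen_names[i], i, NA)
  for (j in seq_len(n_cont)) {
    blocks[[n_gen + j]] <- make_block(cont_names[j], n_gen + j, classes[j])
  }
  records <- do.call(rbind, blocks)

  truth <- list(
    genuine_taxa = gen_names,
    contaminant_taxa = stats::setNames(classes, cont_names)
  )
  list(records = records, metadata = meta, truth = truth)
}

# CLR helper on a plain count matrix (rows = samples), pseudocount 0.5 on
# counts; used internally by the generator to plant couplings.
.clr_counts <- function(counts, pseudo = 0.5) {
  lx <- log(counts + pseudo)
  sweep(lx, 1, rowMeans(lx))
}

#' Simulate bulk expression and a microbial profile with planted signal
#'
#' Host genes are negative-binomial counts whose log2 means carry a planted
#' stage shift (`de_log2fc`, random sign) for the differential genes and an
#' additive per-(gene, dataset) batch shift. Taxa are Dirichlet-multinomial
#' compositions with a planted stage shift for the differential taxa.
#' For each planted interaction edge the gene's log2 expression is
#' `baseline + interaction_beta * CLR(taxon) + Normal(0, noise_sd)` (plus its
#' batch shift), so the coupling lives on the scale the downstream Lasso
#' models operate on.
#'
#' @param config a [sim_config()]
#' @return list with `expression` (genes x samples integer matrix),
#'   `profile` (a `microbial_profile`: samples x taxa counts + metadata),
#'   `metadata`, and `truth` (`de_genes` named signed log2FC vector,
#'   `diff_taxa` named signed log2FC vector, `interaction_edges` data.frame
#'   gene/taxon/beta)
#' @export
simulate_expression_and_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  meta <- sim_metadata(config)
  n <- nrow(meta)
  disease <- meta$stage != "control"

  taxa_names <- vapply(seq_len(config$n_taxa - config$n_contaminants),
                       function(i) sub(".*\\|", "", sim_lineage(i)),
                       character(1))
  n_tax <- length(taxa_names)
  gene_names <- sprintf("Gene%04d", seq_len(config$n_genes))

  ## ---- microbial profile: Dirichlet-multinomial with stage shifts ----
  base_alpha <- stats::rlnorm(n_tax, 0, 1)
  diff_idx <- sample.int(n_tax, config$n_diff_taxa)
  # balanced up/down shifts so the planted signal does not move the
  # geometric mean (which would leak into every taxon's CLR value)
  diff_sign <- sample(rep(c(-1, 1), length.out = config$n_diff_taxa))
  conc <- 30  # Dirichlet concentration: overdispersed composition
  batch_tax <- matrix(stats::rnorm(config$n_datasets * n_tax, 0,
                                   config$batch_sd / 2),
                      config$n_datasets, n_tax)
  depth <- pmax(2e4, round(stats::rlnorm(n, log(1e5), 0.3)))
  counts_tax <- matrix(0L, n, n_tax,
                       dimnames = list(meta$sample_id, taxa_names))
  ds_num <- as.integer(factor(meta$dataset))
  alpha0 <- conc * base_alpha / sum(base_alpha)  # fixed per-taxon shapes
  for (i in seq_len(n)) {
    a <- alpha0
    if (disease[i]) a[diff_idx] <- a[diff_idx] * 2^(diff_sign * config$da_log2fc)
    a <- a * exp(batch_tax[ds_num[i], ])
    g <- stats::rgamma(n_tax, shape = a, rate = 1)
    if (sum(g) <= 0) g[which.max(a)] <- 1
    counts_tax[i, ] <- as.integer(stats::rmultinom(1, depth[i], g / sum(g)))
  }
  clr_tax <- .clr_counts(counts_tax)

  ## ---- host expression: NB counts with DE, batch, and planted couplings ----
  n_de <- config$n_de_genes
  de_idx <- sample.int(config$n_genes, n_de)
  remaining <- setdiff(seq_len(config$n_genes), de_idx)
  int_gene_idx <- sample(remaining, config$n_interactions)
  int_taxa_idx <- sample(setdiff(seq_len(n_tax), diff_idx),
                         config$n_interactions)
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)

  baseline <- stats::runif(config$n_genes, 3, 9)
  baseline[int_gene_idx] <- stats::runif(config$n_interactions, 7, 9)
  batch_gene <- matrix(stats::rnorm(config$n_datasets * config$n_genes, 0,
                                    config$batch_sd),
                       config$n_datasets, config$n_genes)
  size <- 20  # NB size: moderate biological overdispersion

  log2mu <- matrix(baseline, config$n_genes, n)
  log2mu[de_idx, disease] <- log2mu[de_idx, disease] +
    de_sign * config$de_log2fc
  log2mu <- log2mu + t(batch_gene[ds_num, , drop = FALSE])
  expr <- matrix(stats::rnbinom(length(log2mu), mu = 2^log2mu, size = size),
                 config$n_genes, n,
                 dimnames = list(gene_names, meta$sample_id))

  if (config$n_interactions > 0 && config$interaction_beta != 0) {
    for (k in seq_len(config$n_interactions)) {
      g <- int_gene_idx[k]; tx <- int_taxa_idx[k]
      y <- baseline[g] + config$interaction_beta * clr_tax[, tx] +
        stats::rnorm(n, 0, config$noise_sd) + batch_gene[ds_num, g]
      expr[g, ] <- as.integer(round(2^y))
    }
    edges <- data.frame(gene = gene_names[int_gene_idx],
                        taxon = taxa_names[int_taxa_idx],
                        beta = config$interaction_beta,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene = character(0), taxon = character(0),
                        beta = numeric(0))
  }

  truth <- list(
    de_genes = stats::setNames(de_sign * config$de_log2fc, gene_names[de_idx]),
    diff_taxa = stats::setNames(diff_sign * config$da_log2fc,
                                taxa_names[diff_idx]),
    interaction_edges = edges
  )
  prof <- microbial_profile(counts_tax, samples = meta, form = "counts")
  list(expression = expr, profile = prof, metadata = meta, truth = truth)
}

#' Simulate a single-cell cohort with microbe-carrying and active cells
#'
#' UMI counts are Poisson draws around cell-type signature means. A configured
#' fraction of cells receives at least one microbial read, concentrated in the
#' first cell type. A planted interaction cluster (two genes, two taxa) gets a
#' set of planted "active" cells per condition whose cluster-gene expression
#' and cluster-taxon reads are pushed above the 75th percentile.
#'
#' @param config a [sim_config()]
#' @return list with `umi` (cells x genes), `cells` (barcode, cell_type,
#'   condition), `taxa_reads` (cells x taxa), `cluster` (planted cluster:
#'   genes, taxa), `truth` (`active_cells` barcodes, `enriched_type`)
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_cells <- config$n_cells; n_types <- config$n_cell_types
  n_g <- config$n_sc_genes; n_t <- config$n_sc_taxa
  types <- paste0("CT", seq_len(n_types))
  cell_type <- sample(types, n_cells, replace = TRUE)
  condition <- rep(c("control", "NAFLD"), length.out = n_cells)
  barcode <- sprintf("BC%05d", seq_len(n_cells))
  genes <- sprintf("scGene%03d", seq_len(n_g))
  taxa <- sprintf("scTaxon%02d", seq_len(n_t))

  # signature blocks: each type over-expresses its own slice of genes
  mu <- matrix(0.1, n_types, n_g)
  slice <- split(seq_len(n_g), rep(seq_len(n_types), length.out = n_g))
  for (k in seq_len(n_types)) mu[k, slice[[k]]] <- 3
  umi <- matrix(stats::rpois(n_cells * n_g,
                             mu[match(cell_type, types), ]),
                n_cells, n_g, dimnames = list(barcode, genes))

  # microbial reads: carrying probability boosted in the first cell type
  p_carry <- rep(config$fraction_carrying, n_cells)
  if (config$fraction_carrying > 0 && config$fraction_carrying < 1) {
    p_carry[cell_type == types[1]] <- min(1, 3 * config$fraction_carrying)
  }
  carrying <- stats::runif(n_cells) < p_carry
  taxa_reads <- matrix(0L, n_cells, n_t, dimnames = list(barcode, taxa))
  for (i in which(carrying)) {
    k <- sample.int(n_t, sample(1:2, 1))
    taxa_reads[i, k] <- 1L + stats::rpois(length(k), 0.7)
  }

  # planted cluster and active cells
  cluster <- list(genes = genes[1:2], taxa = taxa[1:2])
  active <- character(0)
  if (config$fraction_carrying > 0) {
    for (cond in c("control", "NAFLD")) {
      pool <- which(condition == cond)
      act <- sample(pool, min(15L, length(pool)))
      hi_g <- max(umi[, cluster$genes[1]]) + 5L
      hi_t <- max(taxa_reads[, cluster$taxa[1]]) + 5L
      umi[act, cluster$genes[1]] <- hi_g + stats::rpois(length(act), 2)
      taxa_reads[act, cluster$taxa[1]] <- hi_t + stats::rpois(length(act), 2)
      active <- c(active, barcode[act])
    }
  }

  cells <- data.frame(barcode = barcode, cell_type = cell_type,
                      condition = condition, stringsAsFactors = FALSE)
  list(umi = umi, cells = cells, taxa_reads = taxa_reads, cluster = cluster,
       truth = list(active_cells = active, enriched_type = types[1]))
}

#' Bundled reagent-contaminant genus blacklist
#'
#' Genera widely reported as DNA-extraction-kit and laboratory reagent
#' contaminants in low-biomass sequencing studies. Shipped as a plain-text
#' default for the blacklist decontamination step; users should substitute
#' their own laboratory-specific list where available.
#'
#' @return character vector of genus names
#' @export
default_blacklist <- function() {
  path <- system.file("extdata", "reagent_blacklist.txt", package = "hepanet")
  if (!nzchar(path)) stop("bundled blacklist not found")
  readLines(path, warn = FALSE) |> trimws() |> Filter(f = nzchar, x = _)
}
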