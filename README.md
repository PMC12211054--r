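# hepanet

Hepatic microbiota profiling and host–microbe interaction networks from
liver RNA-seq.

Liver biopsies sequenced for host transcriptomics also capture transcripts
from tissue-resident microbes. Extracting a credible microbial community
from that signal — and relating it to host gene expression across the
nonalcoholic fatty liver disease (NAFLD) spectrum (control → NAFL →
Borderline → NASH) — requires aggressive decontamination, compositional
statistics, and sparse high-dimensional regression. `hepanet` implements
that full chain for analysts working with taxonomic classification reports
(KrakenUniq-style read/k-mer statistics) and expression count matrices:

* **Decontamination** (`run_decontam()`): a five-step protocol on
  per-taxon k-mer statistics — unique-k-mer floor `L − k + 1`, fivefold
  total-k-mer excess, cross-sample Spearman coherence of the three
  statistics, an optional inverse-depth contaminant-distribution screen,
  and a reagent-genus blacklist — with a full per-taxon audit trail.
* **Compositional profiling** (`rare_taxon_filter()`, `clr_transform()`,
  `shannon_index()`, `aitchison_distance()`, `pcoa()`, `permanova()`,
  `remove_batch()`, `differential_abundance()`): CLR-based community
  analysis with Wilcoxon differential abundance (FDR < 0.05,
  |log2FC| > 1).
* **Host expression** (`variance_filter()`, `vst()`, `moderated_de()`,
  `preranked_gsea()`): empirical-Bayes moderated t differential expression
  (FDR < 0.05, |log2FC| > 1.2) and preranked gene-set enrichment.
* **Interaction networks** (`interaction_network()` and its parts): per
  stage, each gene is Lasso-regressed on the merged phylum-to-species CLR
  taxa matrix

  $$\hat\beta = \arg\min_\beta \tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1,$$

  with λ by leave-one-out CV, significance by multi sample-splitting
  (FDR < 0.01), stability by 100 perturbed-λ subsample refits (retention
  at ≥ 60%), Spearman interaction strength, and confounder-adjusted
  p-values.
* **Functional clusters** (`sparse_cca()`, `extract_clusters()`,
  `enrich_clusters()`): sparse canonical correlation via penalized matrix
  decomposition with L1 budgets, plus hypergeometric pathway enrichment
  (FDR < 0.05).
* **Single-cell co-localization** (`flag_microbe_carrying()`,
  `celltype_enrichment()`, `active_interaction_cells()`): the ≥ 1-read
  microbe-carrying rule, Fisher cell-type enrichment, and active
  interaction cells above the 75th-percentile threshold for a cluster gene
  and taxon.
* **Synthetic cohorts** (`sim_config()`, `simulate_taxon_reports()`,
  `simulate_expression_and_profile()`, `simulate_single_cell()`):
  generators with planted contaminants, differential genes/taxa, linear
  gene–taxon couplings and active cells, so the whole pipeline is testable
  offline. `run_all()` chains every stage and writes a reproducible
  manifest.

## Worked example

Simulate a one-stage cohort with ten planted gene–taxon couplings and run
the interaction chain:

```r
library(hepanet)

cfg <- sim_config(seed = 11,
                  samples_per_stage = c(control = 0, NAFL = 80,
                                        Borderline = 0, NASH = 0),
                  n_genes = 100, n_taxa = 60, n_contaminants = 0,
                  n_de_genes = 0, n_diff_taxa = 0,
                  n_interactions = 10, interaction_beta = 0.8,
                  noise_sd = 0.3, n_datasets = 2)
sim  <- simulate_expression_and_profile(cfg)
taxa <- build_taxa_matrix(list(species = clr_transform(sim$profile)$abundance))
net  <- interaction_network(vst(sim$expression), taxa,
                            stage = "NAFL", seed = 42)

truth <- paste(sim$truth$interaction_edges$gene,
               paste0("species|", sim$truth$interaction_edges$taxon))
found <- paste(net$gene, net$taxon)
cat("edges retained:", nrow(net),
    "\nrecall:", mean(truth %in% found),
    "\nfalse-discovery proportion:",
    length(setdiff(found, truth)) / max(1, length(found)), "\n")
```

```
edges retained: 9 
recall: 0.9 
false-discovery proportion: 0 
```

Nine of the ten planted couplings survive the full
λ-selection → split-significance (FDR < 0.01) → stability (≥ 0.6 of 100
refits) chain with no false edges; each retained row carries the Lasso
coefficient, aggregated p-value, FDR, stability frequency and Spearman
strength. The tenth edge fails the stability cut at this noise level —
expected behavior for a conservative retention rule.

For decontamination, the analogous check (30 samples, 200 taxa, 40 planted
contaminants — 10 per signature class) removes every planted contaminant
and retains all genuine taxa; see `tests/testthat/test-decontam.R`.

## Vignette

`vignettes/hepanet-methods.Rmd` documents the statistical model of every
stage, the conventions adopted where published protocols are silent
(boundary inclusivity, pseudocounts, CLR effect sizes, quantile types,
penalty scalings), the generator's design, and known limitations.
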