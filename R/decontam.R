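#' Unique k-mer decontamination threshold
#'
#' A single read of length L contributes at most `L - k + 1` distinct k-mers,
#' so a taxon supported by genuine reads must accumulate at least that many
#' unique k-mers. Taxa below this floor are classification artifacts.
#'
#' @param read_length read length in bp
#' @param kmer_length classifier k-mer length in bp
#' @return integer threshold `read_length - kmer_length + 1`
#' @export
unique_kmer_threshold <- function(read_length, kmer_length) {
  if (kmer_length < 1 || kmer_length > read_length) {
    stop("need 1 <= kmer_length <= read_length")
  }
  as.integer(read_length - kmer_length + 1)
}

.empty_removed <- function() {
  data.frame(taxon = character(0), step = character(0),
             reason = character(0), values = character(0),
             stringsAsFactors = FALSE)
}

.taxon_removed <- function(records, keep, step, reason_fun) {
  # taxa whose records are entirely gone after a per-record filter
  before <- unique(records$name)
  after <- unique(records$name[keep])
  lost <- setdiff(before, after)
  if (!length(lost)) return(.empty_removed())
  data.frame(taxon = lost, step = step,
             reason = vapply(lost, reason_fun, character(1)),
             values = vapply(lost, function(tx) {
               r <- records[records$name == tx, ][1L, ]
               sprintf("reads=%d total_kmers=%d unique_kmers=%d",
                       r$reads, r$total_kmers, r$unique_kmers)
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Step (i): remove records with too few unique k-mers
#'
#' Records with `unique_kmers` strictly below [unique_kmer_threshold()] are
#' removed; records exactly at the threshold are retained.
#'
#' @param records TaxonRecord data.frame (see [simulate_taxon_reports()])
#' @param read_length,kmer_length bp
#' @return list `records` (surviving rows), `removed` (taxon-level entries
#'   for taxa that lost all records)
#' @export
filter_low_unique_kmers <- function(records, read_length, kmer_length) {
  thr <- unique_kmer_threshold(read_length, kmer_length)
  keep <- records$unique_kmers >= thr
  removed <- .taxon_removed(records, keep, "1", function(tx) {
    sprintf("unique_kmers below threshold %d", thr)
  })
  list(records = records[keep, , drop = FALSE], removed = removed,
       threshold = thr)
}

#' Step (ii): remove records whose total k-mers do not exceed reads fivefold
#'
#' Genuine classifications yield many k-mers per read; records with
#' `total_kmers <= fold * reads` are treated as random occurrences. Retention
#' requires strict excess (`total_kmers > fold * reads`).
#'
#' @param records TaxonRecord data.frame
#' @param fold multiplier, default 5
#' @return list `records`, `removed`
#' @export
filter_low_total_kmers <- function(records, fold = 5) {
  if (fold <= 0) stop("fold must be positive")
  keep <- records$total_kmers > fold * records$reads
  removed <- .taxon_removed(records, keep, "2", function(tx) {
    sprintf("total_kmers not exceeding %g x reads", fold)
  })
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Step (iii): remove taxa with decorrelated classification statistics
#'
#' For a genuine taxon the read count, unique k-mer count and total k-mer
#' count rise and fall together across samples. Per taxon (and per dataset,
#' when dataset labels are given) the three pairwise Spearman correlations
#' are computed across the samples where the taxon appears; the taxon is
#' removed if any correlation is non-significant (p >= alpha), undefined
#' (constant statistic), or if the taxon appears in fewer than `min_samples`
#' samples in every dataset (reason "insufficiency"). When dataset labels are
#' supplied a taxon must pass in every dataset where it is testable.
#'
#' @param records TaxonRecord data.frame
#' @param alpha significance level for each Spearman test, default 0.05
#' @param min_samples minimum samples for a testable correlation, default 5
#' @param datasets optional named character vector mapping sample_id to
#'   dataset; NULL treats the cohort as one dataset
#' @return list `records`, `removed`
#' @export
filter_decorrelated <- function(records, alpha = 0.05, min_samples = 5L,
                                datasets = NULL) {
  out_removed <- .empty_removed()
  drop <- character(0)
  for (tx in unique(records$name)) {
    sub <- records[records$name == tx, , drop = FALSE]
    ds <- if (is.null(datasets)) rep("all", nrow(sub)) else
      unname(datasets[sub$sample_id])
    testable <- FALSE; fail <- NULL
    for (d in unique(ds)) {
      s <- sub[ds == d, , drop = FALSE]
      if (nrow(s) < min_samples) next
      testable <- TRUE
      pairs <- list(c("reads", "unique_kmers"), c("reads", "total_kmers"),
                    c("unique_kmers", "total_kmers"))
      for (pr in pairs) {
        ts <- spearman(s[[pr[1]]], s[[pr[2]]])
        if (ts$undefined || is.na(ts$p_value) || ts$p_value >= alpha) {
          fail <- sprintf("%s~%s %s in %s", pr[1], pr[2],
                          if (ts$undefined) "undefined" else
                            sprintf("p=%.3g", ts$p_value), d)
          break
        }
      }
      if (!is.null(fail)) break
    }
    if (!testable) {
      out_removed <- rbind(out_removed, data.frame(
        taxon = tx, step = "insufficiency",
        reason = sprintf("present in < %d samples in every dataset",
                         min_samples),
        values = sprintf("n=%d", nrow(sub)), stringsAsFactors = FALSE))
      drop <- c(drop, tx)
    } else if (!is.null(fail)) {
      out_removed <- rbind(out_removed, data.frame(
        taxon = tx, step = "3",
        reason = "non-significant or undefined Spearman among statistics",
        values = fail, stringsAsFactors = FALSE))
      drop <- c(drop, tx)
    }
  }
  list(records = records[!(records$name %in% drop), , drop = FALSE],
       removed = out_removed)
}

#' Step (iv): remove taxa resembling an experimental-contaminant distribution
#'
#' Reagent contamination contributes a roughly fixed number of reads per
#' library, so a contaminant's relative abundance falls as total sample depth
#' rises. With `depth_test = TRUE` a taxon is removed when its relative
#' abundance is significantly negatively Spearman-correlated with sample
#' depth. A supplied reference (named list of per-sample abundance profiles)
#' removes taxa whose profile correlates with any reference profile at or
#' above `similarity_threshold`. With no reference and the depth test off
#' (the default) this step is a pass-through.
#'
#' @param records TaxonRecord data.frame
#' @param reference optional named list of numeric per-sample abundance
#'   vectors (aligned to the cohort's samples) of known contaminants
#' @param depth_test logical, run the inverse-depth signature test
#' @param alpha significance level for the depth test
#' @param similarity_threshold Spearman similarity above which a taxon
#'   matches a reference profile
#' @return list `records`, `removed`
#' @export
filter_contaminant_like <- function(records, reference = NULL,
                                    depth_test = FALSE, alpha = 0.05,
                                    similarity_threshold = 0.9) {
  if (is.null(reference) && !depth_test) {
    return(list(records = records, removed = .empty_removed()))
  }
  depth <- tapply(records$reads, records$sample_id, sum)
  drop <- character(0); rows <- .empty_removed()
  for (tx in unique(records$name)) {
    sub <- records[records$name == tx, , drop = FALSE]
    rel <- sub$reads / as.numeric(depth[sub$sample_id])
    why <- NULL
    if (depth_test && nrow(sub) >= 5L) {
      ts <- spearman(rel, as.numeric(depth[sub$sample_id]))
      if (!ts$undefined && !is.na(ts$estimate) && ts$estimate < 0 &&
          ts$p_value < alpha) {
        why <- sprintf("abundance inversely tracks depth (rho=%.2f, p=%.3g)",
                       ts$estimate, ts$p_value)
      }
    }
    if (is.null(why) && length(reference)) {
      full <- stats::setNames(rep(0, length(depth)), names(depth))
      full[sub$sample_id] <- rel
      for (rn in names(reference)) {
        rv <- reference[[rn]]
        if (length(rv) != length(full)) next
        rho <- suppressWarnings(stats::cor(full, rv, method = "spearman"))
        if (!is.na(rho) && rho >= similarity_threshold) {
          why <- sprintf("matches reference profile %s (rho=%.2f)", rn, rho)
          break
        }
      }
    }
    if (!is.null(why)) {
      drop <- c(drop, tx)
      rows <- rbind(rows, data.frame(taxon = tx, step = "4", reason = why,
                                     values = "", stringsAsFactors = FALSE))
    }
  }
  list(records = records[!(records$name %in% drop), , drop = FALSE],
       removed = rows)
}

#' Step (v): remove taxa on a reagent-contaminant blacklist
#'
#' Case-insensitive exact-name matching of the taxon name, its leading
#' (genus) token, or any lineage ancestor against the blacklist, so listing a
#' genus removes the genus and all its species records.
#'
#' @param records TaxonRecord data.frame
#' @param blacklist character vector of names; see [default_blacklist()]
#' @return list `records`, `removed`
#' @export
filter_blacklist <- function(records, blacklist = default_blacklist()) {
  bl <- tolower(trimws(blacklist))
  if (!length(bl)) return(list(records = records, removed = .empty_removed()))
  hit <- function(name, lineage) {
    parts <- tolower(c(name, strsplit(name, "[ _]")[[1]][1],
                       strsplit(lineage, "|", fixed = TRUE)[[1]]))
    any(parts %in% bl)
  }
  tx_tab <- unique(records[, c("name", "lineage")])
  if (nrow(tx_tab) == 0L) {
    return(list(records = records, removed = .empty_removed()))
  }
  bad <- tx_tab$name[vapply(seq_len(nrow(tx_tab)), function(i) {
    hit(tx_tab$name[i], tx_tab$lineage[i])
  }, logical(1))]
  rows <- if (length(bad)) {
    data.frame(taxon = bad, step = "5",
               reason = "name or lineage ancestor on the reagent blacklist",
               values = "", stringsAsFactors = FALSE)
  } else .empty_removed()
  list(records = records[!(records$name %in% bad), , drop = FALSE],
       removed = rows)
}

#' Run the full five-step decontamination protocol
#'
#' Applies, in order: (i) the unique-k-mer floor and (ii) the fivefold
#' total-k-mer rule per (taxon, sample) record, then cohort-wide (iii) the
#' statistic-correlation screen, (iv) the contaminant-distribution screen and
#' (v) the blacklist. Surviving read counts are assembled into a sample x
#' taxon count matrix (and per-rank aggregates from the lineage).
#'
#' @param records TaxonRecord data.frame covering >= 1 sample (e.g. from
#'   [simulate_taxon_reports()] or [read_taxon_reports()])
#' @param read_length,kmer_length bp, for the step (i) threshold
#' @param fold step (ii) multiplier
#' @param alpha,min_samples step (iii) parameters
#' @param datasets optional sample_id -> dataset map for step (iii)
#' @param reference,depth_test step (iv) inputs (default: pass-through)
#' @param blacklist step (v) name list
#' @return list with `profile` (species-level `microbial_profile`; flagged
#'   empty when nothing survives), `by_rank` (named list of sample x taxon
#'   count matrices at phylum..species), and `report` (list: `removed`
#'   data.frame, `retained` names, `parameters`)
#' @export
run_decontam <- function(records, read_length = 150L, kmer_length = 31L,
                         fold = 5, alpha = 0.05, min_samples = 5L,
                         datasets = NULL, reference = NULL,
                         depth_test = FALSE,
                         blacklist = default_blacklist()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("need a non-empty TaxonRecord table")
  }
  if (any(records$unique_kmers > records$total_kmers)) {
    stop("unique_kmers must not exceed total_kmers")
  }
  input_taxa <- unique(records$name)
  s1 <- filter_low_unique_kmers(records, read_length, kmer_length)
  s2 <- filter_low_total_kmers(s1$records, fold)
  s3 <- filter_decorrelated(s2$records, alpha, min_samples, datasets)
  s4 <- filter_contaminant_like(s3$records, reference, depth_test, alpha)
  s5 <- filter_blacklist(s4$records, blacklist)
  removed <- rbind(s1$removed, s2$removed, s3$removed, s4$removed, s5$removed)
  retained <- unique(s5$records$name)
  report <- list(
    removed = removed, retained = retained,
    parameters = list(read_length = read_length, kmer_length = kmer_length,
                      unique_kmer_threshold = s1$threshold, fold = fold,
                      alpha = alpha, min_samples = min_samples,
                      depth_test = depth_test,
                      blacklist_size = length(blacklist))
  )
  stopifnot(setequal(c(removed$taxon, retained), input_taxa))

  samples <- sort(unique(records$sample_id))
  if (!length(retained)) {
    prof <- microbial_profile(
      matrix(0, length(samples), 0, dimnames = list(samples, NULL)),
      form = "counts")
    prof$empty <- TRUE
    return(list(profile = prof, by_rank = list(), report = report))
  }
  counts <- .records_to_matrix(s5$records, samples, retained)
  by_rank <- .aggregate_ranks(s5$records, samples)
  list(profile = microbial_profile(counts, form = "counts"),
       by_rank = by_rank, report = report)
}

.records_to_matrix <- function(records, samples, taxa) {
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  i <- cbind(match(records$sample_id, samples), match(records$name, taxa))
  m[i] <- m[i] + records$reads
  m
}

# Aggregate surviving species records up the lineage into per-rank matrices.
# Lineages are kingdom|phylum|class|order|family|genus|species.
.aggregate_ranks <- function(records, samples) {
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  parts <- strsplit(records$lineage, "|", fixed = TRUE)
  depth <- lengths(parts)
  out <- list()
  for (k in seq_along(ranks)) {
    pos <- k + 1L  # skip kingdom
    lab <- vapply(seq_along(parts), function(i) {
      if (depth[i] >= pos) parts[[i]][pos] else NA_character_
    }, character(1))
    ok <- !is.na(lab)
    if (!any(ok)) next
    taxa <- sort(unique(lab[ok]))
    m <- matrix(0, length(samples), length(taxa),
                dimnames = list(samples, taxa))
    agg <- rowsum(records$reads[ok],
                  paste(records$sample_id[ok], lab[ok], sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r"))
    m[cbind(match(key[, 1], samples), match(key[, 2], taxa))] <- agg[, 1]
    out[[ranks[k]]] <- m
  }
  out
}

#' Read KrakenUniq-style per-sample report files
#'
#' Reads tab-separated classification reports, one file per sample, keeping
#' the columns the decontamination protocol consumes. The default mapping
#' expects the package's canonical columns; `col_map` renames dialect columns
#' (e.g. `c(reads = "reads", unique_kmers = "kmers", name = "taxName")`).
#'
#' @param paths character vector of file paths; the sample_id is the file
#'   name without extension
#' @param col_map named character vector mapping canonical names
#'   (taxon_id, name, rank, lineage, reads, total_kmers, unique_kmers) to the
#'   file's column names
#' @return TaxonRecord data.frame
#' @export
read_taxon_reports <- function(paths, col_map = NULL) {
  canonical <- c("taxon_id", "name", "rank", "lineage", "reads",
                 "total_kmers", "unique_kmers")
  out <- lapply(paths, function(p) {
    tab <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(col_map)) {
      for (cn in names(col_map)) {
        if (!col_map[[cn]] %in% names(tab)) {
          stop(sprintf("%s: mapped column '%s' not found", p, col_map[[cn]]))
        }
        names(tab)[names(tab) == col_map[[cn]]] <- cn
      }
    }
    missing <- setdiff(canonical, names(tab))
    if (length(missing)) {
      stop(sprintf("%s: missing columns %s", p,
                   paste(missing, collapse = ", ")))
    }
    tab <- tab[, canonical]
    tab$sample_id <- sub("(\\.report)?\\.[^.]+$", "", basename(p))
    tab
  })
  do.call(rbind, out)
}

#' Write per-sample report files from a TaxonRecord table
#'
#' @param records TaxonRecord data.frame
#' @param dir output directory (created if needed); one
#'   `<sample_id>.report.tsv` per sample
#' @return invisibly, the written paths
#' @export
write_taxon_reports <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(records, records$sample_id), function(s) {
    p <- file.path(dir, paste0(s$sample_id[1], ".report.tsv"))
    utils::write.table(
      s[, c("taxon_id", "name", "rank", "lineage", "reads", "total_kmers",
            "unique_kmers")],
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}
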