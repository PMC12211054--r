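# A minimal hand-built record set used by the boundary tests.
make_rec <- function(name, sample, reads, total, uniq,
                     lineage = paste("Bacteria|P1|C1|O1|F1|G1", name,
                                     sep = "|")) {
  data.frame(sample_id = sample, taxon_id = name, name = name,
             rank = "species", lineage = lineage, reads = reads,
             total_kmers = total, unique_kmers = uniq,
             stringsAsFactors = FALSE)
}

test_that("unique k-mer threshold follows the read/k-mer arithmetic", {
  expect_equal(unique_kmer_threshold(100, 31), 70)
  expect_equal(unique_kmer_threshold(150, 35), 116)
  expect_equal(unique_kmer_threshold(50, 50), 1)
  expect_error(unique_kmer_threshold(50, 51), "kmer_length")
})

test_that("step boundaries: strictly-below unique k-mers removed, strict
           fivefold excess required for total k-mers", {
  rec <- rbind(make_rec("A", "s1", 10, 1000, 69),
               make_rec("B", "s1", 10, 1000, 70))
  r1 <- filter_low_unique_kmers(rec, 100, 31)  # threshold 70
  expect_setequal(r1$records$name, "B")
  expect_equal(r1$removed$taxon, "A")

  rec2 <- rbind(make_rec("C", "s1", 10, 51, 40),
                make_rec("D", "s1", 10, 50, 40),
                make_rec("E", "s1", 10, 49, 40),
                make_rec("F", "s1", 0, 0, 0))
  r2 <- filter_low_total_kmers(rec2)
  expect_setequal(r2$records$name, "C")
  expect_setequal(r2$removed$taxon, c("D", "E", "F"))
})

test_that("decorrelation screen retains co-monotone taxa and removes
           undefined or under-sampled ones", {
  # perfectly co-monotone over 5 samples: each exact Spearman p = 1/60
  reads <- c(10, 20, 30, 40, 50)
  rec <- do.call(rbind, lapply(1:5, function(i) {
    make_rec("good", paste0("s", i), reads[i], reads[i] * 12, reads[i] * 5)
  }))
  expect_equal(nrow(filter_decorrelated(rec)$removed), 0)

  # constant unique k-mers: undefined correlation -> removed
  rec2 <- do.call(rbind, lapply(1:5, function(i) {
    make_rec("flat", paste0("s", i), reads[i], reads[i] * 12, 100)
  }))
  r2 <- filter_decorrelated(rec2)
  expect_equal(r2$removed$taxon, "flat")
  expect_equal(r2$removed$step, "3")

  # three samples < min_samples -> insufficiency
  rec3 <- do.call(rbind, lapply(1:3, function(i) {
    make_rec("rare", paste0("s", i), reads[i], reads[i] * 12, reads[i] * 5)
  }))
  r3 <- filter_decorrelated(rec3)
  expect_equal(r3$removed$step, "insufficiency")
})

test_that("contaminant-distribution screen is a pass-through by default and
           flags inverse-depth taxa when enabled", {
  set.seed(21)
  n <- 20
  depth_driver <- round(stats::rlnorm(n, log(5000), 0.5))
  recs <- list()
  for (i in seq_len(n)) {
    s <- paste0("s", i)
    # anchor taxon carrying the depth variation
    recs[[length(recs) + 1]] <- make_rec("anchor", s, depth_driver[i],
                                         depth_driver[i] * 12,
                                         depth_driver[i] * 5)
    # contaminant: constant reads -> relative abundance ~ 1/depth
    recs[[length(recs) + 1]] <- make_rec("kitbug", s, 50, 600, 250)
    # genuine taxon: reads proportional to depth
    recs[[length(recs) + 1]] <- make_rec("real", s,
                                         round(depth_driver[i] / 10) + i %% 3,
                                         round(depth_driver[i] * 1.2) + 10,
                                         round(depth_driver[i] / 2) + 5)
  }
  rec <- do.call(rbind, recs)
  off <- filter_contaminant_like(rec)
  expect_identical(off$records, rec)
  on <- filter_contaminant_like(rec, depth_test = TRUE)
  expect_true("kitbug" %in% on$removed$taxon)
  expect_false("real" %in% on$removed$taxon)
})

test_that("blacklist removes matching genera and their species via the
           lineage", {
  rec <- rbind(
    make_rec("Bradyrhizobium", "s1", 100, 2000, 500,
             lineage = "Bacteria|P|C|O|F|Bradyrhizobium|Bradyrhizobium"),
    make_rec("Bradyrhizobium japonicum", "s1", 100, 2000, 500,
             lineage = "Bacteria|P|C|O|F|Bradyrhizobium|Bradyrhizobium japonicum"),
    make_rec("Escherichia coli", "s1", 100, 2000, 500,
             lineage = "Bacteria|P|C|O|F|Escherichia|Escherichia coli"))
  r <- filter_blacklist(rec, "bradyrhizobium")  # case-insensitive
  expect_setequal(r$records$name, "Escherichia coli")
  expect_equal(nrow(filter_blacklist(rec, character(0))$removed), 0)
})

test_that("the full protocol recovers planted contaminants and keeps
           genuine taxa", {
  cfg <- sim_config(seed = 31,
                    samples_per_stage = c(control = 8, NAFL = 8,
                                          Borderline = 7, NASH = 7),
                    n_taxa = 80, n_contaminants = 20, n_genes = 10,
                    n_de_genes = 0, n_interactions = 0, n_diff_taxa = 0)
  rs <- simulate_taxon_reports(cfg)
  ds <- stats::setNames(rs$metadata$dataset, rs$metadata$sample_id)
  dec <- run_decontam(rs$records, datasets = ds)
  cls <- rs$truth$contaminant_taxa
  rem <- dec$report$removed
  for (cl in unique(cls)) {
    planted <- names(cls)[cls == cl]
    expect_gte(mean(planted %in% rem$taxon), 0.9)
  }
  expect_gte(mean(rs$truth$genuine_taxa %in% dec$report$retained), 0.9)
  # the report partitions the input exactly
  expect_setequal(c(rem$taxon, dec$report$retained),
                  unique(rs$records$name))
  expect_length(intersect(rem$taxon, dec$report$retained), 0)
  # per-rank aggregation preserves total retained reads
  expect_equal(sum(dec$by_rank$species), sum(dec$profile$abundance))
  expect_equal(sum(dec$by_rank$phylum), sum(dec$profile$abundance))
})

test_that("filters are idempotent and order-stable on disjoint
           signatures", {
  cfg <- sim_config(seed = 33,
                    samples_per_stage = c(control = 8, NAFL = 8,
                                          Borderline = 7, NASH = 7),
                    n_taxa = 60, n_contaminants = 16, n_genes = 10,
                    n_de_genes = 0, n_interactions = 0, n_diff_taxa = 0)
  rs <- simulate_taxon_reports(cfg)
  dec <- run_decontam(rs$records)
  # idempotence: rerunning on survivors removes nothing planted
  surv <- rs$records[rs$records$name %in% dec$report$retained, ]
  dec2 <- run_decontam(surv)
  expect_setequal(dec2$report$retained, dec$report$retained)

  # order stability: per-record steps applied in either order
  a <- filter_low_total_kmers(filter_low_unique_kmers(rs$records, 150, 31)$records)$records
  b <- filter_low_unique_kmers(filter_low_total_kmers(rs$records)$records, 150, 31)$records
  expect_setequal(unique(a$name), unique(b$name))
  # cohort steps in either order
  c1 <- filter_blacklist(filter_decorrelated(a)$records)$records
  c2 <- filter_decorrelated(filter_blacklist(a)$records)$records
  expect_setequal(unique(c1$name), unique(c2$name))
})

test_that("degenerate inputs: empty report errors, zero survivors yield a
           flagged-empty profile", {
  expect_error(run_decontam(data.frame()), "non-empty")
  rec <- make_rec("A", "s1", 10, 1000, 5)  # fails step (i)
  dec <- run_decontam(rec, read_length = 100, kmer_length = 31)
  expect_true(dec$profile$empty)
  expect_equal(dec$report$removed$taxon, "A")
})

test_that("report files round-trip through write and read", {
  cfg <- sim_config(seed = 35,
                    samples_per_stage = c(control = 2, NAFL = 2,
                                          Borderline = 1, NASH = 1),
                    n_taxa = 10, n_contaminants = 0, n_genes = 5,
                    n_de_genes = 0, n_interactions = 0, n_diff_taxa = 0)
  rs <- simulate_taxon_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_taxon_reports(rs$records, dir)
  back <- read_taxon_reports(paths)
  ord <- order(back$sample_id, back$taxon_id)
  ord0 <- order(rs$records$sample_id, rs$records$taxon_id)
  expect_equal(back[ord, c("name", "reads", "total_kmers", "unique_kmers")],
               rs$records[ord0, c("name", "reads", "total_kmers",
                                  "unique_kmers")],
               ignore_attr = TRUE)
  expect_error(read_taxon_reports(paths, col_map = c(reads = "nope")),
               "not found")
})
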