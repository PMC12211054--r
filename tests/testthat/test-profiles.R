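mk_profile <- function(m, ds = NULL, form = "counts") {
  rn <- rownames(m)
  if (is.null(rn)) rn <- paste0("s", seq_len(nrow(m)))
  rownames(m) <- rn
  if (is.null(colnames(m)) && ncol(m) > 0) {
    colnames(m) <- paste0("t", seq_len(ncol(m)))
  }
  samples <- data.frame(sample_id = rn,
                        dataset = if (is.null(ds)) rep("d1", nrow(m)) else ds,
                        stringsAsFactors = FALSE)
  microbial_profile(m, samples = samples, form = form)
}

test_that("clr transform matches the closed form and rows sum to zero", {
  p1 <- mk_profile(matrix(1, 3, 4))
  expect_equal(unname(clr_transform(p1)$abundance),
               matrix(0, 3, 4), tolerance = 1e-12)
  p2 <- mk_profile(matrix(c(1, 2, 4), 1, 3))
  got <- clr_transform(p2, pseudocount = 1e-15)$abundance
  expect_equal(unname(got)[1, ], c(-log(2), 0, log(2)), tolerance = 1e-6)
  set.seed(3)
  p3 <- mk_profile(matrix(rpois(60, 40) + 1, 6, 10))
  expect_lt(max(abs(rowSums(clr_transform(p3)$abundance))), 1e-9)
  expect_error(clr_transform(mk_profile(matrix(c(0, 1, 2, 3), 2, 2)),
                             pseudocount = 0), "pseudocount")
})

test_that("rare-taxon filter applies the within-dataset prevalence and
           multi-dataset detection rules", {
  # 20 samples over two datasets; taxon X only in dataset 1, abundant there
  set.seed(4)
  m <- matrix(rpois(20 * 4, 20000) + 100, 20, 4)
  colnames(m) <- c("A", "B", "X", "Y")
  ds <- rep(c("d1", "d2"), each = 10)
  m[ds == "d2", "X"] <- 0                       # single-dataset taxon
  # rare everywhere: a single read is ~2e-5 relative, below the 0.01% floor
  m[, "Y"] <- ifelse(seq_len(20) %% 10 == 0, 1, 0)
  pr <- rare_taxon_filter(mk_profile(m, ds))
  expect_setequal(colnames(pr$abundance), c("A", "B"))
  # single dataset: rule relaxed with a warning
  expect_warning(r1 <- rare_taxon_filter(mk_profile(m[ds == "d1", ])),
                 "relaxed")
  expect_true("X" %in% colnames(r1$abundance))
  # empty profile passes through
  e <- mk_profile(matrix(0, 3, 0))
  expect_equal(ncol(rare_taxon_filter(e)$abundance), 0)
})

test_that("shannon index reproduces closed-form diversities", {
  p <- mk_profile(rbind(c(1, 1, 1, 1), c(4, 0, 0, 0), c(2, 2, 0, 0)))
  h <- shannon_index(p)
  expect_equal(unname(h), c(log(4), 0, log(2)), tolerance = 1e-12)
  p0 <- mk_profile(rbind(c(1, 1), c(0, 0)))
  expect_true(is.na(shannon_index(p0)[2]))
  # strict CLR variant is computable and finite for non-uniform compositions
  set.seed(6)
  pr <- mk_profile(matrix(rpois(40, 30) + 1, 4, 10))
  expect_true(all(is.finite(shannon_index(pr, on_clr = TRUE))))
})

test_that("aitchison distance is scale-invariant and equals the
           euclidean-on-CLR oracle", {
  set.seed(9)
  m <- matrix(rpois(5 * 8, 100) + 1, 5, 8)
  m[2, ] <- 2 * m[1, ]  # same composition, doubled scale
  p <- mk_profile(m)
  d <- as.matrix(aitchison_distance(p, pseudocount = 1e-9))
  expect_equal(d[1, 2], 0, tolerance = 1e-6)
  # oracle: explicit CLR then euclidean
  rel <- m / rowSums(m)
  lx <- log(rel + 1e-9)
  clr <- lx - rowMeans(lx)
  expect_equal(unname(d), unname(as.matrix(dist(clr))), tolerance = 1e-10)
  # metric property on random triples
  for (i in 1:20) {
    tri <- sample(nrow(m), 3)
    expect_lte(d[tri[1], tri[2]],
               d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("pcoa reproduces euclidean configurations and handles degenerate
           input", {
  set.seed(12)
  pts <- matrix(rnorm(10 * 3), 10, 3)
  d <- dist(pts)
  fit <- pcoa(d, k = 3)
  expect_lt(max(abs(as.matrix(dist(fit$coordinates)) - as.matrix(d))), 1e-8)
  # collinear points: first axis recovers the line
  line <- cbind(seq(0, 9), 0)
  fl <- pcoa(dist(line), k = 2)
  expect_lt(max(abs(as.matrix(dist(fl$coordinates[, 1])) -
                      as.matrix(dist(line)))), 1e-8)
  z <- pcoa(matrix(0, 4, 4), k = 2)
  expect_true(all(z$coordinates == 0))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permanova separates planted clusters and rejects degenerate
           calls", {
  set.seed(13)
  x <- rbind(matrix(rnorm(10 * 4), 10, 4),
             matrix(rnorm(10 * 4, mean = 3), 10, 4))
  r <- permanova(dist(x), rep(c("a", "b"), each = 10), n_perm = 999,
                 seed = 3)
  expect_lte(r$p, 0.01)
  expect_gt(r$pseudo_F, 1)
  expect_error(permanova(dist(x), rep("a", 20)), "2 groups")
  expect_error(permanova(dist(x), rep(c("a", "b"), each = 10), n_perm = 0),
               "n_perm")
  # determinism under a seed
  r2 <- permanova(dist(x), rep(c("a", "b"), each = 10), n_perm = 999,
                  seed = 3)
  expect_identical(r, r2)
})

test_that("batch removal strips an additive shift but preserves the stage
           signal", {
  set.seed(14)
  n <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  stage <- rep(rep(c("ctrl", "dis"), each = n / 4), 2)
  x <- matrix(rnorm(30 * n), 30, n)
  x[, batch == "b2"] <- x[, batch == "b2"] + 2       # pure batch shift
  x[1:5, stage == "dis"] <- x[1:5, stage == "dis"] + 3  # real signal
  xc <- remove_batch(x, batch, preserve = data.frame(stage = stage))
  pb <- permanova(dist(t(xc)), batch, n_perm = 199, seed = 1)
  expect_gt(pb$p, 0.05)
  ps <- permanova(dist(t(xc)), stage, n_perm = 199, seed = 1)
  expect_lte(ps$p, 0.01)
  # single batch: identity
  expect_equal(remove_batch(x, rep("b1", n)), x)
  # exact confounding errors out
  expect_error(remove_batch(x, stage, preserve = data.frame(stage = stage)),
               "confounded")
})

test_that("differential abundance recovers planted taxa with matching
           signs and calls nothing on identical groups", {
  set.seed(15)
  m <- matrix(rpois(40 * 12, 200) + 1, 40, 12)
  p <- clr_transform(mk_profile(m))
  groups <- rep(c("control", "NASH"), each = 20)
  da0 <- differential_abundance(p, sample(groups), "control", "NASH")
  expect_equal(sum(da0$significant), 0)
  expect_error(differential_abundance(p, groups, "healthy", "NASH"),
               "control")

  cfg <- sim_config(seed = 5,
                    samples_per_stage = c(control = 30, NAFL = 30,
                                          Borderline = 0, NASH = 0),
                    n_genes = 20, n_de_genes = 0, n_taxa = 120, n_contaminants = 0,
                    n_diff_taxa = 10, n_interactions = 0)
  sim <- simulate_expression_and_profile(cfg)
  clr <- clr_transform(rare_taxon_filter(sim$profile))
  da <- differential_abundance(clr, as.character(sim$metadata$stage),
                               "control", "NAFL")
  planted <- sim$truth$diff_taxa
  hit <- da[da$significant & da$taxon %in% names(planted), ]
  expect_gte(nrow(hit) / length(planted), 0.8)
  # recovered direction matches the planted sign
  expect_true(all(sign(hit$log2fc) == sign(planted[hit$taxon])))
  fp <- sum(da$significant) - nrow(hit)
  expect_lte(fp / max(1, sum(da$significant)), 0.1)
})
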