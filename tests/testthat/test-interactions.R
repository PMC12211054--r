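test_that("merged taxa matrix concatenates ranks with recoverable prefixes
           and standardized columns", {
  set.seed(31)
  mats <- lapply(1:5, function(i) {
    m <- matrix(rnorm(20 * 10), 20, 10)
    colnames(m) <- paste0("tax", i, "_", 1:10)
    m
  })
  names(mats) <- c("phylum", "class", "order", "family", "genus")
  X <- build_taxa_matrix(mats)
  expect_equal(ncol(X), 50)
  expect_lt(max(abs(colMeans(X))), 1e-9)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(sub("\\|.*", "", colnames(X)) %in% names(mats)))
  mats$genus[, 1] <- 7  # constant column
  expect_warning(X2 <- build_taxa_matrix(mats), "constant")
  expect_equal(ncol(X2), 49)
})

test_that("lasso solutions satisfy closed-form oracles", {
  set.seed(32)
  n <- 50; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("t", 1:p)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.5)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  expect_true(all(lasso_fit(y, X, lmax * 1.0001)$beta == 0))
  expect_true(any(lasso_fit(y, X, lmax * 0.5)$beta != 0))
  # lambda = 0, n > p: ordinary least squares
  f0 <- lasso_fit(y, X, 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(f0$beta - ols[-1])), 1e-6)
  # orthonormal columns: coordinate-wise soft threshold of the OLS solution
  Q <- qr.Q(qr(scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)))
  Q <- scale(Q, center = TRUE, scale = FALSE) * sqrt(40)  # x_j'x_j = n
  Q <- qr.Q(qr(Q)) * sqrt(40)
  colnames(Q) <- paste0("q", 1:5)
  y2 <- rnorm(40)
  bols <- crossprod(Q, y2 - mean(y2)) / 40
  lam <- 0.05
  want <- sign(bols) * pmax(abs(bols) - lam, 0)
  got <- lasso_fit(y2, Q, lam)$beta
  expect_equal(unname(got), as.numeric(want), tolerance = 1e-6)
  expect_error(lasso_fit(c(y, NA), rbind(X, 1), 0.1), "non-finite")
})

test_that("coordinate descent agrees with glmnet on its shared objective", {
  set.seed(33)
  n <- 60; p <- 25
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("t", 1:p)
  y <- X[, 1:3] %*% c(1, -0.7, 0.4) + rnorm(n, 0, 0.4)
  for (lam in c(0.3, 0.1, 0.02)) {
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        thresh = 1e-12)
    f <- lasso_fit(y, X, lam)
    expect_lt(max(abs(f$beta - as.numeric(g$beta))), 1e-5)
  }
})

test_that("leave-one-out penalty selection is deterministic and finds
           planted predictors", {
  st <- make_planted_stage(60, 20, beta = 1, sigma = 0.1, seed = 34)
  s1 <- select_lambda_loocv(st$y, st$X)
  s2 <- select_lambda_loocv(st$y, st$X)
  expect_identical(s1, s2)
  hits <- 0
  for (i in 1:10) {
    st <- make_planted_stage(60, 20, beta = 1, sigma = 0.1, seed = 400 + i)
    f <- lasso_fit(st$y, st$X, select_lambda_loocv(st$y, st$X)$lambda)
    hits <- hits + (abs(f$beta[st$signal]) > 0)
  }
  expect_gte(hits, 9)
  # pure noise: near-empty models dominate
  empt <- 0
  for (i in 1:10) {
    set.seed(500 + i)
    Xn <- scale(matrix(rnorm(60 * 20), 60, 20))
    colnames(Xn) <- paste0("t", 1:20)
    yn <- rnorm(60)
    f <- lasso_fit(yn, Xn, select_lambda_loocv(yn, Xn)$lambda)
    empt <- empt + (sum(abs(f$beta) > 0) <= 2)
  }
  expect_gte(empt, 9)
})

test_that("multi sample-splitting p-values are reproducible, sensitive to
           planted signal and conservative on noise", {
  st <- make_planted_stage(100, 20, beta = 1, sigma = 0.1, seed = 36)
  p1 <- interaction_pvalues(st$y, st$X, seed = 9)
  p2 <- interaction_pvalues(st$y, st$X, seed = 9)
  expect_identical(p1, p2)
  fdr <- adjust_pvalues(p1, "BH")$adjusted
  expect_lt(fdr[st$signal], 0.01)
  # null predictors: aggregated p-values sit high (conservative)
  expect_gte(median(p1[setdiff(names(p1), st$signal)]), 0.9)
  expect_error(interaction_pvalues(rnorm(10), matrix(rnorm(100), 10)),
               "n >= 20")
})

test_that("stability selection separates planted from null predictors and
           respects its seed", {
  st <- make_planted_stage(80, 20, beta = 0.8, sigma = 0.3, seed = 37)
  lam <- select_lambda_loocv(st$y, st$X)$lambda_1se
  f1 <- stability_selection(st$y, st$X, lam, seed = 4)
  f2 <- stability_selection(st$y, st$X, lam, seed = 4)
  expect_identical(f1, f2)
  expect_gte(f1[st$signal], 0.9)
  nulls <- f1[setdiff(names(f1), st$signal)]
  expect_gte(mean(nulls <= 0.2), 0.9)
})

test_that("confounder adjustment matches simple regression without
           covariates and absorbs mediated associations", {
  set.seed(38)
  n <- 100
  tax <- rnorm(n)
  gene <- 0.8 * tax + rnorm(n, 0, 0.3)
  p0 <- confounder_adjust(gene, tax)
  p_lm <- coef(summary(lm(gene ~ tax)))["tax", 4]
  expect_equal(p0, p_lm, tolerance = 1e-12)
  # association wholly mediated by a covariate
  absorbed <- 0
  for (i in 1:10) {
    set.seed(600 + i)
    z <- rnorm(n)
    tax_m <- z + rnorm(n, 0, 0.1)
    gene_m <- z + rnorm(n, 0, 0.1)
    pm <- confounder_adjust(gene_m, tax_m, data.frame(z = z))
    absorbed <- absorbed + (pm > 0.05)
  }
  expect_gte(absorbed, 9)
  expect_error(confounder_adjust(gene, tax,
                                 data.frame(a = tax, b = tax)),
               "collinear")
})

test_that("stage network summaries count edges, degrees and intersections
           exactly", {
  e1 <- data.frame(stage = "control", gene = c("g1", "g1", "g2"),
                   taxon = c("t1", "t2", "t1"))
  e2 <- data.frame(stage = "NASH", gene = c("g1", "g3"),
                   taxon = c("t1", "t3"))
  s <- build_stage_networks(list(control = e1, NASH = e2))
  expect_equal(s$per_stage$n_edges, c(3, 2))
  expect_equal(s$per_stage$n_genes, c(2, 2))
  # handshake: degree sums equal edge counts on each side
  expect_equal(sum(s$degrees$control$gene), 3)
  expect_equal(sum(s$degrees$control$taxon), 3)
  expect_equal(s$intersections[["control&NASH"]],
               data.frame(gene = "g1", taxon = "t1"))
  d1 <- data.frame(stage = "a", gene = "g9", taxon = "t9")
  d2 <- data.frame(stage = "b", gene = "g8", taxon = "t8")
  s2 <- build_stage_networks(list(a = d1, b = d2))
  expect_equal(nrow(s2$intersections[["a&b"]]), 0)
})

test_that("the retained edge set shrinks as the stability cutoff rises", {
  st <- make_planted_stage(60, 15, beta = 0.8, sigma = 0.3, seed = 39,
                           n_signal = 3L)
  lam <- select_lambda_loocv(st$y, st$X)$lambda_1se
  freq <- stability_selection(st$y, st$X, lam, seed = 2)
  sizes <- vapply(seq(0, 1, by = 0.1), function(cut) sum(freq >= cut),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
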