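# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# BH step-up: q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(1, q)[order(o)]
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties assumed).
wilcox_exact_bruteforce <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(v)[seq_len(n1)])
  combs <- utils::combn(length(v), n1)
  rks <- rank(v)
  stats <- apply(combs, 2, function(idx) sum(rks[idx]))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-12)
}

# Kruskal-Wallis H from the textbook rank formula (with tie correction).
kruskal_bruteforce <- function(groups) {
  v <- unlist(groups)
  n <- length(v)
  r <- rank(v)
  sizes <- lengths(groups)
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))) -
    3 * (n + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Unweighted / weighted GSEA running-sum enrichment score, written
# independently from the package implementation.
es_bruteforce <- function(scores_sorted, set_genes, weight) {
  genes <- names(scores_sorted)
  hit <- genes %in% set_genes
  w <- abs(scores_sorted)^weight
  nr <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) w[i] / nr else -1 / (length(genes) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Shared small synthetic stage for interaction tests: standardized predictor
# matrix with one planted coupling.
make_planted_stage <- function(n, p, beta, sigma, seed, n_signal = 1L) {
  set.seed(seed)
  X <- scale(matrix(stats::rnorm(n * p), n, p))
  colnames(X) <- paste0("taxon", seq_len(p))
  y <- X[, seq_len(n_signal), drop = FALSE] %*% rep(beta, n_signal) +
    stats::rnorm(n, 0, sigma)
  list(X = X, y = as.numeric(y), signal = colnames(X)[seq_len(n_signal)])
}
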