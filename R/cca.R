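# Soft-threshold then L2-normalize, with the threshold chosen by binary
# search so the L1 norm of the unit-L2 vector meets the budget c.
.sparse_unit <- function(a, c1) {
  l2 <- sqrt(sum(a^2))
  if (l2 == 0) return(a)
  u <- a / l2
  if (sum(abs(u)) <= c1) return(u)
  soft <- function(x, d) sign(x) * pmax(abs(x) - d, 0)
  lo <- 0; hi <- max(abs(a))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    su <- soft(a, mid)
    n2 <- sqrt(sum(su^2))
    l1 <- if (n2 > 0) sum(abs(su)) / n2 else 0
    if (l1 > c1) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, max(abs(a)))) break
  }
  su <- soft(a, hi)
  su / sqrt(sum(su^2))
}

#' Sparse canonical correlation analysis (penalized matrix decomposition)
#'
#' Finds K pairs of sparse weight vectors (u over taxa, v over genes)
#' maximizing `u' (Z'X) v` subject to unit L2 norms and L1 budgets, by
#' alternating soft-thresholded updates (the threshold located by binary
#' search to meet the L1 budget) initialized from the leading singular
#' vectors. After each component the cross-product matrix is deflated by the
#' fitted rank-1 term. The sign indeterminacy is resolved by forcing the
#' largest-magnitude entry of u positive.
#'
#' @param X samples x genes matrix, column-standardized
#' @param Z samples x taxa matrix, column-standardized
#' @param penalty_u,penalty_v L1 budgets for the taxa and gene sides, as
#'   fractions of `sqrt(ncol(.))`; defaults 0.3 (1 = unpenalized)
#' @param K number of components, default 10
#' @param max_iter,tol alternation controls
#' @param drop_below components with |canonical correlation| below this are
#'   flagged degenerate and dropped (default 0.1); set 0 to keep all
#' @return list of components, each with `index`, `u`, `v` (named),
#'   `canonical_correlation`, `objective` (trace of u'Cv per iteration), and
#'   `degenerate` flag
#' @export
sparse_cca <- function(X, Z, penalty_u = 0.3, penalty_v = 0.3, K = 10L,
                       max_iter = 100L, tol = 1e-6, drop_below = 0.1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z)) stop("X and Z need the same samples")
  if (max(abs(colMeans(X))) > 1e-6 || max(abs(colMeans(Z))) > 1e-6) {
    stop("X and Z must be column-standardized (zero means)")
  }
  c_u <- max(1, penalty_u * sqrt(ncol(Z)))
  c_v <- max(1, penalty_v * sqrt(ncol(X)))
  C <- crossprod(Z, X)  # taxa x genes cross-product
  comps <- list()
  for (k in seq_len(K)) {
    if (max(abs(C)) < 1e-12) break  # zero cross-covariance left
    sv <- svd(C, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      u_new <- .sparse_unit(C %*% v, c_u)
      v_new <- .sparse_unit(crossprod(C, u_new), c_v)
      obj <- c(obj, as.numeric(t(u_new) %*% C %*% v_new))
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- as.numeric(u_new); v <- as.numeric(v_new)
      if (delta < tol) break
    }
    if (sum(abs(u)) == 0 || sum(abs(v)) == 0) break
    i_max <- which.max(abs(u))
    if (u[i_max] < 0) { u <- -u; v <- -v }
    zu <- Z %*% u; xv <- X %*% v
    rho <- if (stats::sd(zu) > 0 && stats::sd(xv) > 0)
      as.numeric(stats::cor(zu, xv)) else 0
    d <- as.numeric(t(u) %*% C %*% v)
    comps[[length(comps) + 1L]] <- list(
      index = k,
      u = stats::setNames(u, colnames(Z)),
      v = stats::setNames(v, colnames(X)),
      canonical_correlation = rho, objective = obj,
      degenerate = abs(rho) < drop_below)
    C <- C - d * tcrossprod(u, v)
  }
  Filter(function(cm) !cm$degenerate, comps)
}

#' Extract gene/taxa member clusters from fitted components
#'
#' @param components output of [sparse_cca()]
#' @param weight_floor members need |weight| strictly above this (default 0,
#'   i.e. any nonzero weight)
#' @return list of clusters, each with `component`, `genes`, `taxa` (named
#'   weight vectors) and `canonical_correlation`
#' @export
extract_clusters <- function(components, weight_floor = 0) {
  lapply(components, function(cm) {
    list(component = cm$index,
         genes = cm$v[abs(cm$v) > weight_floor],
         taxa = cm$u[abs(cm$u) > weight_floor],
         canonical_correlation = cm$canonical_correlation)
  })
}

#' Hypergeometric pathway enrichment of cluster genes
#'
#' For each (cluster, gene set) pair, the upper-tail hypergeometric
#' over-representation p-value against the supplied universe, BH-corrected
#' across sets within each cluster; pathways with `fdr < fdr_cut` are
#' retained.
#'
#' @param clusters output of [extract_clusters()]
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @param universe character vector of all testable genes; sets are
#'   intersected with it
#' @param fdr_cut retention threshold, default 0.05
#' @return the clusters, each gaining an `enriched_pathways` data.frame
#'   (set_name, hits, size, p, fdr)
#' @export
enrich_clusters <- function(clusters, gene_sets, universe, fdr_cut = 0.05) {
  sets <- lapply(gene_sets, intersect, y = universe)
  lapply(clusters, function(cl) {
    members <- intersect(names(cl$genes), universe)
    if (!length(members)) {
      warning("cluster ", cl$component, " has no genes in the universe")
      cl$enriched_pathways <- data.frame(set_name = character(0),
                                         hits = integer(0), size = integer(0),
                                         p = numeric(0), fdr = numeric(0))
      return(cl)
    }
    rows <- lapply(names(sets), function(nm) {
      set <- sets[[nm]]
      if (!length(set)) return(NULL)
      hits <- length(intersect(members, set))
      p <- hypergeometric_enrichment(hits, length(members), length(set),
                                     length(universe))
      data.frame(set_name = nm, hits = hits, size = length(set), p = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) {
      cl$enriched_pathways <- data.frame(set_name = character(0),
                                         hits = integer(0), size = integer(0),
                                         p = numeric(0), fdr = numeric(0))
      return(cl)
    }
    tab$fdr <- adjust_pvalues(tab$p, "BH")$adjusted
    cl$enriched_pathways <- tab[tab$fdr < fdr_cut, , drop = FALSE]
    cl
  })
}
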