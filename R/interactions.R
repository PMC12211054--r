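#' Merge per-rank taxa profiles into one standardized predictor matrix
#'
#' Column-concatenates CLR (batch-corrected) profiles from phylum to species
#' into a single sample x taxa matrix with rank-prefixed column names
#' (`rank|taxon`), then standardizes every column to zero mean and unit
#' variance. Constant columns cannot be standardized and are dropped with a
#' warning.
#'
#' @param profiles named list of sample x taxon numeric matrices, one per
#'   rank, identical row order
#' @return standardized samples x merged-taxa matrix
#' @export
build_taxa_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  mats <- lapply(names(profiles), function(rk) {
    m <- as.matrix(profiles[[rk]])
    colnames(m) <- paste(rk, colnames(m), sep = "|")
    m
  })
  X <- do.call(cbind, mats)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant taxa column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  scale(X)
}

# Descending log-spaced lambda grid from lambda_max down to
# lambda_max * min_ratio; lambda_max is the smallest penalty at which every
# coefficient is zero for standardized X.
lambda_grid <- function(y, X, n_lambda = 50L, min_ratio = 1e-3) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Lasso fit at a single penalty
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` by coordinate
#' descent (convergence tolerance 1e-7, warm-started along a short
#' decreasing path ending at the requested penalty) on a pre-standardized
#' predictor matrix.
#'
#' @param y response vector
#' @param X standardized samples x predictors matrix
#' @param lambda penalty >= 0
#' @param tol convergence tolerance (maximum coefficient update, scaled by
#'   the response variance)
#' @return list with `lambda`, `beta` (named coefficient vector) and
#'   `intercept`
#' @export
lasso_fit <- function(y, X, lambda, tol = 1e-9) {
  if (!all(is.finite(y)) || !all(is.finite(X))) stop("non-finite input")
  path <- unique(c(lambda * c(16, 8, 4, 2), lambda))
  fit <- .cd_lasso_path(X, y, path, tol = tol)
  beta <- fit$beta[, length(path)]
  names(beta) <- colnames(X)
  list(lambda = lambda, beta = beta,
       intercept = fit$intercept[length(path)])
}

#' Select the Lasso penalty by leave-one-out cross-validation
#'
#' Minimizes the mean leave-one-out squared prediction error over a
#' descending log-spaced grid from lambda_max down to lambda_max/1000; ties
#' resolve to the larger (sparser) penalty. Deterministic: LOO involves no
#' randomness. Also reports the one-standard-error penalty (the largest
#' lambda whose CV error is within one standard error of the minimum), the
#' conventional sparser choice for support-recovery tasks such as stability
#' selection.
#'
#' @param y response vector (n >= 3)
#' @param X standardized samples x predictors matrix
#' @param grid optional descending lambda grid; default [lambda_grid()]
#' @return list with `lambda` (CV-minimum), `lambda_1se`, `grid`, `cv_mse`
#' @export
select_lambda_loocv <- function(y, X, grid = NULL) {
  n <- length(y)
  if (n < 3L) stop("need n >= 3")
  if (is.null(grid)) grid <- lambda_grid(y, X)
  # selection-grade tolerance: CV prediction errors are insensitive to the
  # last digits of the coefficients
  err <- .cd_lasso_cv_err(X, y, grid, seq_len(n), tol = 1e-5)
  mse <- colMeans(err)
  best <- which(mse <= min(mse) + 1e-12)[1]  # grid descends: first = largest
  se_best <- stats::sd(err[, best]) / sqrt(n)
  i1se <- which(mse <= mse[best] + se_best)[1]
  list(lambda = grid[best], lambda_1se = grid[i1se], grid = grid,
       cv_mse = mse)
}

# OLS p-values for the selected support on the held-out half,
# Bonferroni-scaled by the support size (multi sample-splitting ingredient).
.split_ols_p <- function(y2, X2, support) {
  p <- stats::setNames(rep(1, ncol(X2)), colnames(X2))
  if (!length(support)) return(p)
  Xs <- cbind(1, X2[, support, drop = FALSE])
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) return(p)  # degenerate half-sample: uninformative
  cf <- qr.coef(qx, y2)
  resid <- y2 - Xs %*% cf
  d <- length(y2) - ncol(Xs)
  if (d < 1) return(p)
  s2 <- sum(resid^2) / d
  se <- sqrt(diag(chol2inv(qr.R(qx))) * s2)
  tt <- cf / se
  praw <- 2 * stats::pt(abs(tt[-1]), df = d, lower.tail = FALSE)
  p[support] <- pmin(1, praw * length(support))
  p
}

#' Multi sample-splitting p-values for Lasso-selected predictors
#'
#' High-dimensional inference by repeated sample splitting: in each of
#' `n_splits` random halvings, the Lasso (penalty by seeded 5-fold CV)
#' selects a support on one half and ordinary least squares on the other
#' half supplies p-values for the selected predictors, Bonferroni-scaled by
#' the support size (unselected predictors get p = 1). If a split selects
#' more variables than the testing half can estimate, the penalty is
#' tightened along the path until the support fits. Per-predictor p-values
#' are aggregated over splits by the scaled-median rule
#' `p_j = min(1, 2 * median_b p_j^(b))`.
#'
#' @param y response vector (n >= 20)
#' @param X standardized samples x predictors matrix
#' @param n_splits number of random splits, default 50
#' @param seed integer seed
#' @return named vector of aggregated per-predictor p-values
#' @export
interaction_pvalues <- function(y, X, n_splits = 50L, seed = 1L) {
  n <- length(y)
  if (n < 20L) stop("need n >= 20 for sample splitting")
  set.seed(seed)
  pmat <- matrix(1, n_splits, ncol(X),
                 dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_splits)) {
    idx1 <- sample.int(n, floor(n / 2))
    idx2 <- setdiff(seq_len(n), idx1)
    X1 <- X[idx1, , drop = FALSE]; y1 <- y[idx1]
    # half-samples have p > n: the near-saturated foot of the path is never
    # a sensible support, so the selection grid stops at lambda_max / 20
    grid <- lambda_grid(y1, X1, n_lambda = 30L, min_ratio = 0.05)
    foldid <- sample(rep_len(1:5, length(idx1)))
    mse <- colMeans(.cd_lasso_cv_err(X1, y1, grid, foldid, tol = 1e-5))
    li <- which(mse <= min(mse) + 1e-12)[1]
    fit <- .cd_lasso_path(X1, y1, grid, tol = 1e-5)
    max_support <- length(idx2) - 2L
    repeat {
      support <- colnames(X)[abs(fit$beta[, li]) > 0]
      if (length(support) <= max_support || li == 1L) break
      li <- li - 1L  # tighten: move toward lambda_max
    }
    pmat[b, ] <- .split_ols_p(y[idx2], X[idx2, , drop = FALSE], support)
  }
  apply(pmat, 2, function(pv) min(1, 2 * stats::median(pv)))
}

#' Stability selection frequencies under subsampling and penalty perturbation
#'
#' Refits the Lasso `n_iter` times on random subsamples of fraction
#' `subsample`, each time multiplying the penalty by
#' `exp(Uniform(-perturb, perturb))`, and reports the fraction of refits in
#' which each predictor has a nonzero coefficient. The base penalty is
#' rescaled by `sqrt(n / m)` on a subsample of size m so its effective
#' strength (which scales as `sqrt(log p / n)`) is preserved; without this
#' the half-sample refits are systematically under-penalized and noise
#' predictors enter too often.
#'
#' @param y response vector
#' @param X standardized samples x predictors matrix
#' @param lambda base penalty (e.g. from [select_lambda_loocv()])
#' @param n_iter refits, default 100
#' @param subsample subsample fraction, default 0.5
#' @param perturb half-width of the log-uniform penalty perturbation,
#'   default 0.2
#' @param seed integer seed
#' @return named vector of selection frequencies in [0, 1]
#' @export
stability_selection <- function(y, X, lambda, n_iter = 100L,
                                subsample = 0.5, perturb = 0.2, seed = 1L) {
  n <- length(y)
  m <- floor(n * subsample)
  if (m < 10L) stop("subsample too small: need n * subsample >= 10")
  set.seed(seed)
  hits <- stats::setNames(numeric(ncol(X)), colnames(X))
  lambda_m <- lambda * sqrt(n / m)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, m)
    lam <- lambda_m * exp(stats::runif(1, -perturb, perturb))
    fit <- lasso_fit(y[idx], X[idx, , drop = FALSE], lam)
    hits <- hits + (abs(fit$beta) > 0)
  }
  hits / n_iter
}

#' Spearman interaction strength for one gene-taxon pair
#'
#' @param gene,taxon paired per-sample vectors (length >= 3)
#' @return rho (NA when undefined)
#' @export
edge_strength <- function(gene, taxon) {
  spearman(gene, taxon)$estimate
}

#' Confounder-adjusted association p-value
#'
#' Multivariate linear regression `gene ~ taxon + covariates` (age, sex,
#' platform, ...); reports the t-test p-value of the taxon coefficient.
#'
#' @param gene,taxon paired per-sample vectors
#' @param covariates optional data.frame of per-sample confounders
#' @return p-value of the taxon term
#' @export
confounder_adjust <- function(gene, taxon, covariates = NULL) {
  df <- data.frame(gene = gene, taxon = taxon)
  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ taxon + ., data = cbind(df["taxon"], covariates))
    if (qr(X)$rank < ncol(X)) {
      bad <- colnames(X)[qr(X)$pivot[(qr(X)$rank + 1):ncol(X)]]
      stop("collinear covariates: ", paste(bad, collapse = ", "))
    }
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(gene ~ ., data = df)
  stats::coef(summary(fit))["taxon", "Pr(>|t|)"]
}

#' Per-stage host-gene by taxa interaction network
#'
#' The full inference chain for one disease stage: per gene, (1) Lasso with
#' leave-one-out-CV penalty on the merged standardized taxa matrix, (2)
#' multi sample-splitting p-values with BH FDR across the gene's taxa, (3)
#' stability-selection frequencies from `n_iter` subsample refits with
#' perturbed penalty (perturbing the one-standard-error CV penalty, the
#' sparser conventional choice for support recovery), (4) retention of
#' edges with `fdr < fdr_cut` and
#' frequency >= `stability_cut`, annotated with Spearman strength and, when
#' covariates are given, a confounder-adjusted p-value.
#'
#' @param expr genes x samples log-scale expression matrix (this stage's
#'   samples only)
#' @param taxa standardized samples x merged-taxa matrix
#'   (see [build_taxa_matrix()])
#' @param stage stage label stored on the edges
#' @param covariates optional per-sample confounder data.frame
#' @param n_splits,n_iter,subsample,perturb chain parameters (defaults 50,
#'   100, 0.5, 0.2)
#' @param fdr_cut,stability_cut retention thresholds (defaults 0.01, 0.6)
#' @param seed master seed; per-gene child seeds are derived from it
#' @return data.frame of retained edges: stage, gene, taxon, beta, p, fdr,
#'   stability_freq, rho, adj_p; all candidate edges (pre-threshold) are
#'   attached as attribute "candidates"
#' @export
interaction_network <- function(expr, taxa, stage = "all",
                                covariates = NULL, n_splits = 50L,
                                n_iter = 100L, subsample = 0.5,
                                perturb = 0.2, fdr_cut = 0.01,
                                stability_cut = 0.6, seed = 1L) {
  stopifnot(ncol(expr) == nrow(taxa))
  genes <- rownames(expr)
  all_rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    y <- as.numeric(expr[g, ])
    gseed <- (seed * 1000L + g) %% .Machine$integer.max
    sel <- select_lambda_loocv(y, taxa)
    pv <- interaction_pvalues(y, taxa, n_splits = n_splits, seed = gseed)
    fdr <- adjust_pvalues(pv, "BH")$adjusted
    freq <- stability_selection(y, taxa, sel$lambda_1se, n_iter = n_iter,
                                subsample = subsample, perturb = perturb,
                                seed = gseed + 1L)
    fit <- lasso_fit(y, taxa, sel$lambda)
    cand <- which(fdr < fdr_cut | freq >= stability_cut | abs(fit$beta) > 0)
    if (!length(cand)) next
    all_rows[[g]] <- data.frame(
      stage = stage, gene = genes[g], taxon = colnames(taxa)[cand],
      beta = unname(fit$beta[cand]), p = unname(pv[cand]),
      fdr = unname(fdr[cand]), stability_freq = unname(freq[cand]),
      rho = vapply(cand, function(j) edge_strength(y, taxa[, j]), numeric(1)),
      adj_p = vapply(cand, function(j) {
        if (is.null(covariates)) NA_real_ else
          confounder_adjust(y, taxa[, j], covariates)
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  cand_tab <- do.call(rbind, all_rows)
  if (is.null(cand_tab)) {
    cand_tab <- data.frame(stage = character(0), gene = character(0),
                           taxon = character(0), beta = numeric(0),
                           p = numeric(0), fdr = numeric(0),
                           stability_freq = numeric(0), rho = numeric(0),
                           adj_p = numeric(0))
  }
  edges <- cand_tab[cand_tab$fdr < fdr_cut &
                      cand_tab$stability_freq >= stability_cut, ,
                    drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "candidates") <- cand_tab
  edges
}

#' Summarize per-stage interaction networks
#'
#' Per stage: edge / gene / taxon counts, per-node degree and top-degree
#' taxa; across stages: exact edge-set intersections keyed on
#' (gene, taxon).
#'
#' @param edges_by_stage named list of edge data.frames
#'   (from [interaction_network()])
#' @param top number of top-degree taxa to report
#' @return list with `per_stage` (data.frame), `degrees` (per stage, named
#'   list of gene/taxon degree vectors), `top_taxa`, and `intersections`
#'   (named list keyed by stage combinations)
#' @export
build_stage_networks <- function(edges_by_stage, top = 5L) {
  key <- function(e) paste(e$gene, e$taxon, sep = "\r")
  per_stage <- data.frame(
    stage = names(edges_by_stage),
    n_edges = vapply(edges_by_stage, nrow, integer(1)),
    n_genes = vapply(edges_by_stage, function(e) length(unique(e$gene)),
                     integer(1)),
    n_taxa = vapply(edges_by_stage, function(e) length(unique(e$taxon)),
                    integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  degrees <- lapply(edges_by_stage, function(e) {
    list(gene = sort(table(e$gene), decreasing = TRUE),
         taxon = sort(table(e$taxon), decreasing = TRUE))
  })
  top_taxa <- lapply(degrees, function(d) utils::head(d$taxon, top))
  stages <- names(edges_by_stage)
  intersections <- list()
  if (length(stages) >= 2L) {
    for (m in 2:length(stages)) {
      for (cmb in utils::combn(stages, m, simplify = FALSE)) {
        shared <- Reduce(intersect, lapply(edges_by_stage[cmb], key))
        intersections[[paste(cmb, collapse = "&")]] <-
          if (length(shared)) {
            do.call(rbind, lapply(strsplit(shared, "\r"), function(p) {
              data.frame(gene = p[1], taxon = p[2], stringsAsFactors = FALSE)
            }))
          } else data.frame(gene = character(0), taxon = character(0))
      }
    }
  }
  list(per_stage = per_stage, degrees = degrees, top_taxa = top_taxa,
       intersections = intersections)
}
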