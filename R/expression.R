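#' Filter low-variance genes
#'
#' Removes genes whose expression variance falls strictly below the given
#' quantile of all gene variances; genes tied with the quantile value are
#' retained.
#'
#' @param expr genes x samples numeric matrix (>= 2 samples)
#' @param quantile variance quantile in [0, 1), default 0.25
#' @return filtered matrix
#' @export
variance_filter <- function(expr, quantile = 0.25) {
  if (quantile < 0 || quantile >= 1) stop("quantile must lie in [0, 1)")
  if (ncol(expr) < 2L) stop("need >= 2 samples to compute variances")
  v <- apply(expr, 1, stats::var)
  expr[v >= stats::quantile(v, quantile), , drop = FALSE]
}

#' Variance-stabilizing transform (log2 counts-per-million)
#'
#' `log2(CPM + 0.5)` per library: a monotone, library-size-normalized
#' transform that flattens the count-variance trend. The offset keeps zero
#' counts finite at `log2(0.5)`.
#'
#' @param counts genes x samples non-negative count matrix
#' @return real matrix of the same dimensions
#' @export
vst <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in column(s): ",
                          paste(which(lib == 0), collapse = ", "))
  log2(sweep(counts, 2, lib, "/") * 1e6 + 0.5)
}

# Newton solve of trigamma(y) = x, vectorized; used by the EB moment fit.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Fit empirical-Bayes variance-moderation hyperparameters
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior (d0, s0^2) to a
#' set of per-gene residual variances with known residual degrees of freedom,
#' via the first two moments of log s^2. When the spread of log s^2 does not
#' exceed its pure-sampling expectation, the prior is degenerate: d0 =
#' infinity and every posterior variance equals s0^2.
#'
#' @param s2 numeric vector of residual variances (>= 2 genes)
#' @param d residual degrees of freedom (scalar or per-gene, all >= 1)
#' @return list with `d0` (possibly `Inf`) and `s0_sq`
#' @export
fit_eb_params <- function(s2, d) {
  if (length(s2) < 2L) stop("need >= 2 genes")
  d <- rep_len(d, length(s2))
  if (any(d < 1)) stop("residual df must be >= 1")
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L || stats::var(log(s2[ok])) == 0) {
    return(list(d0 = Inf, s0_sq = stats::median(s2)))
  }
  z <- log(s2[ok]); dk <- d[ok]
  e <- z - digamma(dk / 2) + log(dk / 2)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok) - mean(trigamma(dk / 2))
  if (evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated differential expression (disease stage vs control)
#'
#' Per-gene linear model of (log-scale) expression on a two-group contrast
#' plus optional covariates, with empirical-Bayes variance moderation: the
#' posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated t
#' has `d0 + d` degrees of freedom. With `eb_params = list(d0 = 0)` this is
#' the ordinary t-test. Stages are never pooled: exactly one case group is
#' compared to control.
#'
#' @param expr genes x samples log2-scale matrix (e.g. [vst()] output after
#'   batch removal)
#' @param groups per-sample labels
#' @param control,case labels of the baseline and disease groups
#' @param covariates optional data.frame of per-sample adjustment covariates
#' @param eb_params NULL to fit via [fit_eb_params()], or a list
#'   `list(d0 =, s0_sq =)` (d0 = 0 gives the unmoderated t)
#' @param fdr_cut,lfc_cut DEG thresholds, defaults 0.05 and 1.2
#' @return data.frame: gene, log2fc, t_mod, p, fdr, is_deg; the fitted
#'   hyperparameters are attached as attribute "eb_params"
#' @export
moderated_de <- function(expr, groups, control, case, covariates = NULL,
                         eb_params = NULL, fdr_cut = 0.05, lfc_cut = 1.2) {
  sel <- groups %in% c(control, case)
  if (!any(groups == control)) stop("control label absent")
  if (!any(groups == case)) stop("case label absent")
  y <- expr[, sel, drop = FALSE]
  grp <- factor(groups[sel], levels = c(control, case))
  df <- data.frame(grp = grp)
  if (!is.null(covariates)) df <- cbind(df, covariates[sel, , drop = FALSE])
  df <- droplevels(as.data.frame(lapply(df, function(v) {
    if (is.character(v)) factor(v) else v
  }), stringsAsFactors = FALSE))
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design is rank deficient; aliased columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  }
  n <- ncol(y); p <- ncol(X)
  fit <- stats::lm.fit(X, t(y))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  d <- n - p
  if (d < 1) stop("no residual degrees of freedom")
  s2 <- rowSums(res^2) / d
  xtxinv <- chol2inv(qr.R(qx))
  j <- which(colnames(X) == paste0("grp", case))
  cjj <- xtxinv[j, j]
  beta <- coefs[, j]
  if (is.null(eb_params)) eb_params <- fit_eb_params(s2, d)
  d0 <- eb_params$d0
  post_var <- if (is.infinite(d0)) {
    rep(eb_params$s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * eb_params$s0_sq + d * s2) / (d0 + d)
  }
  tmod <- beta / sqrt(post_var * cjj)
  dft <- if (is.infinite(d0)) Inf else d0 + d
  pval <- 2 * stats::pt(abs(tmod), df = dft, lower.tail = FALSE)
  fdr <- adjust_pvalues(pval, "BH")$adjusted
  out <- data.frame(gene = rownames(expr), log2fc = beta, t_mod = tmod,
                    p = pval, fdr = fdr,
                    is_deg = fdr < fdr_cut & abs(beta) > lfc_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "eb_params") <- eb_params
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for one set.
.gsea_es <- function(ordered_scores, in_set, weight) {
  n <- length(ordered_scores); nh <- sum(in_set)
  w <- abs(ordered_scores)^weight
  nr <- sum(w[in_set])
  inc <- ifelse(in_set, if (nr > 0) w / nr else 0, 0)
  dec <- ifelse(in_set, 0, 1 / (n - nh))
  running <- cumsum(inc - dec)
  i <- which.max(abs(running))
  list(es = running[i], peak = i, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score over a ranked
#' gene list, with a gene-label permutation null: for each set, `n_perm`
#' random gene sets of the same size are scored, the p-value is the
#' same-signed tail fraction and NES is the ES divided by the mean |ES| of
#' the same-signed null. BH FDR across sets.
#'
#' @param scores named numeric vector of per-gene ranking scores (no NAs);
#'   sorted internally in decreasing order
#' @param gene_sets named list of character vectors; sets are intersected
#'   with the ranked universe, empty intersections are skipped with a warning
#' @param weight running-sum weight (0 = classic KS), default 1
#' @param n_perm permutations, default 1000
#' @param seed integer seed
#' @return data.frame: set_name, size, es, nes, p, fdr, leading_edge
#'   (comma-separated)
#' @export
preranked_gsea <- function(scores, gene_sets, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  if (anyNA(scores)) stop("scores must not contain NA")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    if (!length(members)) {
      warning("gene set '", nm, "' has no overlap with the ranking; skipped")
      return(NULL)
    }
    in_set <- genes %in% members
    obs <- .gsea_es(s, in_set, weight)
    nh <- length(members)
    null_es <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(genes), nh)
      flag <- logical(length(genes)); flag[idx] <- TRUE
      .gsea_es(s, flag, weight)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    le <- if (obs$es >= 0) genes[seq_len(obs$peak)][in_set[seq_len(obs$peak)]]
          else genes[obs$peak:length(genes)][in_set[obs$peak:length(genes)]]
    data.frame(set_name = nm, size = nh, es = obs$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      fdr = numeric(0), leading_edge = character(0)))
  }
  rows$fdr <- adjust_pvalues(rows$p, "BH")$adjusted
  rows[, c("set_name", "size", "es", "nes", "p", "fdr", "leading_edge")]
}
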