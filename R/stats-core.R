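#' Statistical test result
#'
#' Light container returned by the rank/exact test wrappers in this package.
#' All wrappers enforce the same degenerate-input contracts: empty groups are
#' errors, fully tied data yield p = 1 rather than NaN, and undefined
#' correlations are flagged rather than silently set to zero.
#'
#' @param statistic test statistic (may be NA for flagged-undefined results)
#' @param p_value two-sided p-value in [0, 1] (NA when undefined)
#' @param n integer vector of per-group sample sizes
#' @param method test name
#' @param estimate optional effect estimate (e.g. Spearman rho)
#' @param undefined TRUE when the statistic is undefined (e.g. constant input)
#' @return an object of class `hm_test`
#' @keywords internal
hm_test <- function(statistic, p_value, n, method, estimate = NA_real_,
                    undefined = FALSE) {
  structure(
    list(statistic = statistic, p_value = p_value, n = as.integer(n),
         method = method, estimate = estimate, undefined = undefined),
    class = "hm_test"
  )
}

#' @export
print.hm_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format(x$p_value), " n =", paste(x$n, collapse = "/"),
      if (x$undefined) " [undefined]" else "", "\n")
  invisible(x)
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration when both groups have at most 8 observations and no ties
#' are present; otherwise the tie-corrected normal approximation with
#' continuity correction. Fully tied data (zero rank variance) return p = 1.
#'
#' @param x,y numeric vectors, each non-empty
#' @return [hm_test()] with the Mann-Whitney U statistic
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    return(hm_test(length(x) * length(y) / 2, 1, c(length(x), length(y)),
                   "wilcoxon_rank_sum"))
  }
  use_exact <- !has_ties && length(x) <= 8L && length(y) <= 8L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1  # zero tie-corrected variance
  hm_test(unname(ht$statistic), min(1, p), c(length(x), length(y)),
          "wilcoxon_rank_sum")
}

#' Kruskal-Wallis rank test across k groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom. Groups that are all identical (zero rank variance) return H = 0,
#' p = 1.
#'
#' @param groups list of numeric vectors, at least two, each non-empty
#' @return [hm_test()] with the H statistic
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 1L)) stop("all groups must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(hm_test(0, 1, lengths(groups), "kruskal_wallis"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(vals, g)
  hm_test(unname(ht$statistic), ht$p.value, lengths(groups), "kruskal_wallis")
}

#' Fisher's exact test on a 2x2 table
#'
#' Reports both the two-sided p-value and the one-sided (upper-tail,
#' enrichment) p-value; the latter equals the hypergeometric tail used by
#' [hypergeometric_enrichment()].
#'
#' @param table 2x2 matrix of non-negative integers
#' @return [hm_test()]; `statistic` is the odds ratio estimate, `p_value` the
#'   two-sided p; the one-sided p is attached as `$p_one_sided`
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative cell counts are not allowed")
  if (sum(table) < 1) stop("table total must be at least 1")
  two <- stats::fisher.test(table, alternative = "two.sided")
  one <- stats::fisher.test(table, alternative = "greater")
  out <- hm_test(unname(two$estimate), two$p.value, rowSums(table),
                 "fisher_exact")
  out$p_one_sided <- one$p.value
  out
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability P(X >= hits) where X counts members of a gene set of
#' size `set_size` among `cluster_size` draws without replacement from a
#' universe of `universe` genes. This is the standard over-representation test
#' used for pathway enrichment.
#'
#' @param hits observed overlap
#' @param cluster_size number of genes drawn (the cluster)
#' @param set_size size of the annotated set within the universe
#' @param universe universe size
#' @return upper-tail p-value
#' @export
hypergeometric_enrichment <- function(hits, cluster_size, set_size, universe) {
  if (any(c(hits, cluster_size, set_size, universe) < 0)) {
    stop("all counts must be non-negative")
  }
  if (hits > min(cluster_size, set_size)) {
    stop("hits cannot exceed min(cluster_size, set_size)")
  }
  if (set_size > universe || cluster_size > universe) {
    stop("set and cluster must fit inside the universe")
  }
  stats::phyper(hits - 1, set_size, universe - set_size, cluster_size,
                lower.tail = FALSE)
}

#' Spearman rank correlation with p-value
#'
#' Tie-adjusted (midrank) rho. Exact permutation p when n <= 7 and no ties;
#' t-approximation otherwise. Constant input yields a flagged-undefined
#' result (`undefined = TRUE`, rho and p are NA) rather than a silent zero —
#' downstream significance filters must treat undefined as non-significant.
#'
#' @param x,y paired numeric vectors of equal length >= 3
#' @return [hm_test()] with `estimate` = rho
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(hm_test(NA_real_, NA_real_, length(x), "spearman",
                   estimate = NA_real_, undefined = TRUE))
  }
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- !has_ties && length(x) <= 7L
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact)
  )
  hm_test(unname(ht$statistic), min(1, ht$p.value), length(x), "spearman",
          estimate = unname(ht$estimate))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni family-wise control.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NAs pass through as NA)
#' @param method "BH" or "bonferroni"
#' @return list with `raw`, `adjusted`, `method`
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  list(raw = p, adjusted = stats::p.adjust(p, method = method),
       method = method)
}
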