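#' Construct a microbial profile
#'
#' A sample x taxon abundance matrix with optional sample metadata and a tag
#' recording which form the values are in: raw `counts`, `relative`
#' (rows sum to 1) or `clr` (rows sum to 0).
#'
#' @param abundance numeric matrix, rows = samples, columns = taxa
#' @param samples optional data.frame of sample metadata with a `sample_id`
#'   column matching the row names (stage, dataset, age, sex, platform, ...)
#' @param taxa optional data.frame of taxon annotation (rank, lineage)
#' @param form one of "counts", "relative", "clr"
#' @return object of class `microbial_profile`
#' @export
microbial_profile <- function(abundance, samples = NULL, taxa = NULL,
                              form = c("counts", "relative", "clr")) {
  form <- match.arg(form)
  abundance <- as.matrix(abundance)
  if (form == "counts" && any(abundance < 0)) stop("counts must be >= 0")
  if (form == "relative" && ncol(abundance) > 0 &&
      any(abs(rowSums(abundance) - 1) > 1e-9)) {
    stop("relative abundances must sum to 1 per sample")
  }
  if (!is.null(samples)) {
    if (!"sample_id" %in% names(samples)) stop("samples needs sample_id")
    samples <- samples[match(rownames(abundance), samples$sample_id), ,
                       drop = FALSE]
  }
  structure(list(abundance = abundance, samples = samples, taxa = taxa,
                 form = form, empty = ncol(abundance) == 0L),
            class = "microbial_profile")
}

#' @export
print.microbial_profile <- function(x, ...) {
  cat(sprintf("microbial_profile: %d samples x %d taxa [%s]%s\n",
              nrow(x$abundance), ncol(x$abundance), x$form,
              if (isTRUE(x$empty)) " (empty)" else ""))
  invisible(x)
}

#' Remove rare taxa before compositional analysis
#'
#' Retains a taxon only if (a) within at least one dataset it reaches a
#' relative abundance of at least `min_rel` in at least `min_prev` of that
#' dataset's samples, and (b) it is detected (non-zero) in at least
#' `min_datasets` datasets. With a single dataset the multi-dataset rule is
#' relaxed with a warning.
#'
#' @param profile `microbial_profile` in counts form, with a `dataset`
#'   column in its sample metadata (or `datasets` supplied)
#' @param min_rel minimum relative abundance, default 1e-4 (0.01%)
#' @param min_prev minimum within-dataset prevalence, default 0.10
#' @param min_datasets minimum number of datasets of detection, default 2
#' @param datasets optional character vector of per-sample dataset labels
#' @return filtered `microbial_profile` (counts form)
#' @export
rare_taxon_filter <- function(profile, min_rel = 1e-4, min_prev = 0.10,
                              min_datasets = 2L, datasets = NULL) {
  stopifnot(inherits(profile, "microbial_profile"), profile$form == "counts")
  x <- profile$abundance
  if (ncol(x) == 0L) return(profile)
  if (is.null(datasets)) {
    datasets <- if (!is.null(profile$samples$dataset))
      profile$samples$dataset else rep("all", nrow(x))
  }
  uds <- unique(datasets)
  if (length(uds) < min_datasets) {
    warning("fewer datasets than min_datasets; multi-dataset rule relaxed")
    min_datasets <- length(uds)
  }
  rs <- rowSums(x)
  rel <- x / ifelse(rs == 0, 1, rs)
  keep_ab <- rep(FALSE, ncol(x))
  detected <- matrix(FALSE, length(uds), ncol(x))
  for (i in seq_along(uds)) {
    sel <- datasets == uds[i]
    prev <- colMeans(rel[sel, , drop = FALSE] >= min_rel)
    keep_ab <- keep_ab | (prev >= min_prev)
    detected[i, ] <- colSums(x[sel, , drop = FALSE]) > 0
  }
  keep <- keep_ab & (colSums(detected) >= min_datasets)
  microbial_profile(x[, keep, drop = FALSE], samples = profile$samples,
                    taxa = profile$taxa[keep, , drop = FALSE],
                    form = "counts")
}

#' Centered log-ratio transform
#'
#' Per sample, `x -> log((x + pseudocount) / g)` with `g` the geometric mean
#' of `x + pseudocount`, mapping compositions into unconstrained space where
#' rows sum to zero. By default the pseudocount is half the smallest nonzero
#' relative abundance, computed per dataset when dataset labels are present.
#'
#' @param profile `microbial_profile` in counts or relative form
#' @param pseudocount positive offset applied to relative abundances; NULL
#'   (default) uses half the smallest nonzero relative abundance per dataset
#' @return `microbial_profile` in CLR form
#' @export
clr_transform <- function(profile, pseudocount = NULL) {
  stopifnot(inherits(profile, "microbial_profile"),
            profile$form %in% c("counts", "relative"))
  x <- profile$abundance
  if (ncol(x) == 0L) {
    out <- profile; out$form <- "clr"; return(out)
  }
  if (profile$form == "counts") {
    rs <- rowSums(x)
    if (any(rs == 0)) stop("all-zero sample: cannot form a composition")
    x <- x / rs
  }
  datasets <- if (!is.null(profile$samples$dataset))
    profile$samples$dataset else rep("all", nrow(x))
  clr <- x
  for (d in unique(datasets)) {
    sel <- datasets == d
    xd <- x[sel, , drop = FALSE]
    pc <- pseudocount
    if (is.null(pc)) {
      nz <- xd[xd > 0]
      pc <- if (length(nz)) min(nz) / 2 else 1e-6
    }
    if (pc <= 0 && any(xd == 0)) {
      stop("pseudocount must be positive when zeros are present")
    }
    lx <- log(xd + pc)
    clr[sel, ] <- lx - rowMeans(lx)
  }
  microbial_profile(clr, samples = profile$samples, taxa = profile$taxa,
                    form = "clr")
}

#' Shannon diversity index per sample
#'
#' `H = -sum(p_i * log(p_i))` in nats, computed on relative abundances.
#' Although diversity is often quoted alongside CLR-processed profiles, the
#' index itself requires a probability vector: CLR values are negative and
#' sum to zero, so `on_clr = TRUE` provides a strict variant that min-shifts
#' the CLR row to non-negative values and renormalizes before applying the
#' formula.
#'
#' @param profile `microbial_profile` (counts or relative; clr only with
#'   `on_clr = TRUE`)
#' @param on_clr compute the min-shifted CLR variant
#' @return named numeric vector of per-sample H (NA for all-zero samples)
#' @export
shannon_index <- function(profile, on_clr = FALSE) {
  stopifnot(inherits(profile, "microbial_profile"))
  x <- profile$abundance
  if (on_clr) {
    if (profile$form != "clr") profile <- clr_transform(profile)
    x <- profile$abundance
    x <- x - apply(x, 1, min)
  } else if (profile$form == "clr") {
    stop("Shannon needs counts or relative abundances; see on_clr")
  }
  rs <- rowSums(x)
  h <- rep(NA_real_, nrow(x))
  ok <- rs > 0
  h[ok] <- vegan::diversity(x[ok, , drop = FALSE], index = "shannon")
  stats::setNames(h, rownames(x))
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed compositions, the natural
#' metric on compositional data (scale-invariant: a sample and any positive
#' multiple of it are at distance zero).
#'
#' @param profile `microbial_profile`; converted to CLR if needed
#' @param pseudocount passed to [clr_transform()] when converting
#' @return a `dist` object over samples
#' @export
aitchison_distance <- function(profile, pseudocount = NULL) {
  stopifnot(inherits(profile, "microbial_profile"))
  if (profile$form != "clr") profile <- clr_transform(profile, pseudocount)
  stats::dist(profile$abundance, method = "euclidean")
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it;
#' coordinates are ordered by decreasing eigenvalue, axes with negative
#' eigenvalues are dropped but the eigenvalues are reported.
#'
#' @param d `dist` or symmetric zero-diagonal matrix
#' @param k number of axes to return
#' @return list with `coordinates` (samples x k) and `eigenvalues`
#' @export
pcoa <- function(d, k = 2L) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (all(m == 0)) {
    return(list(coordinates = matrix(0, nrow(m), k,
                                     dimnames = list(rownames(m), NULL)),
                eigenvalues = rep(0, nrow(m) - 1L)))
  }
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = min(k, nrow(m) - 1L), eig = TRUE)
  )
  coords <- fit$points
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  }
  list(coordinates = coords, eigenvalues = fit$eig)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: a pseudo-F from
#' among/within sums of squared distances, with a permutation p-value
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param d `dist` or symmetric matrix
#' @param labels grouping vector (>= 2 groups, each >= 2 samples)
#' @param n_perm number of label permutations, default 999
#' @param seed integer seed for the permutations
#' @return list with `pseudo_F` and `p`
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 groups")
  if (any(table(labels) < 2L)) stop("each group needs >= 2 samples")
  df <- data.frame(g = labels)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ g, data = df,
                        permutations = n_perm)
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' Remove additive batch effects from a feature matrix
#'
#' Fits, per feature, a linear model containing batch indicators plus any
#' covariates whose effects must be preserved, and subtracts only the fitted
#' batch terms (sum-to-zero coded, so feature means are preserved).
#'
#' @param x features x samples numeric matrix
#' @param batch per-sample batch labels (>= 2 batches)
#' @param preserve optional design matrix or data.frame of covariates whose
#'   signal must survive (e.g. stage)
#' @return corrected matrix, same dimensions
#' @export
remove_batch <- function(x, batch, preserve = NULL) {
  batch <- as.factor(batch)
  if (nlevels(droplevels(batch)) < 2L) return(x)
  design <- NULL
  if (!is.null(preserve)) {
    design <- if (is.data.frame(preserve)) {
      pf <- droplevels(as.data.frame(lapply(preserve, function(v) {
        if (is.character(v)) factor(v) else v
      }), stringsAsFactors = FALSE))
      stats::model.matrix(~ ., data = pf)
    } else as.matrix(preserve)
    bd <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
    r_design <- qr(design)$rank
    if (qr(cbind(design, bd))$rank < r_design + ncol(bd)) {
      stop("batch is confounded with preserved covariates: ",
           paste(colnames(design), collapse = ", "))
    }
  }
  limma::removeBatchEffect(x, batch = batch, design = if (is.null(design))
    matrix(1, ncol(x), 1) else design)
}

#' Wilcoxon differential abundance on CLR profiles
#'
#' Per taxon, a two-sided Wilcoxon-Mann-Whitney test of CLR abundance in a
#' disease group versus control, BH FDR across taxa, and the compositional
#' effect size `log2FC = (mean CLR_disease - mean CLR_control) / ln 2`.
#' Significance is `fdr < fdr_cut` and `|log2fc| > lfc_cut`.
#'
#' @param profile CLR-form `microbial_profile`
#' @param groups per-sample group labels
#' @param control label of the baseline group
#' @param case label of the disease group to compare against control
#' @param fdr_cut,lfc_cut significance thresholds (defaults 0.05 and 1)
#' @return data.frame: taxon, log2fc, p, fdr, significant
#' @export
differential_abundance <- function(profile, groups, control, case,
                                   fdr_cut = 0.05, lfc_cut = 1) {
  stopifnot(inherits(profile, "microbial_profile"), profile$form == "clr")
  if (!control %in% groups) stop("control label not present in groups")
  if (!case %in% groups) stop("case label not present in groups")
  x <- profile$abundance
  a <- x[groups == case, , drop = FALSE]
  b <- x[groups == control, , drop = FALSE]
  res <- lapply(seq_len(ncol(x)), function(j) {
    ts <- wilcoxon_rank_sum(a[, j], b[, j])
    c(log2fc = (mean(a[, j]) - mean(b[, j])) / log(2), p = ts$p_value)
  })
  res <- as.data.frame(do.call(rbind, res))
  res$taxon <- colnames(x)
  res$fdr <- adjust_pvalues(res$p, "BH")$adjusted
  res$significant <- res$fdr < fdr_cut & abs(res$log2fc) > lfc_cut
  res[, c("taxon", "log2fc", "p", "fdr", "significant")]
}
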