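#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples, the workhorse test for every
#' cohort-level burden and fraction comparison in the pipeline. The p-value
#' is exact (by enumeration of the null rank distribution) when the pooled
#' sample size is at most `exact_max` and there are no ties; otherwise the
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric vectors, both non-empty. By pipeline convention `x`
#'   holds the metastatic cohort, so a large U favours metastatic enrichment.
#' @param exact_max Largest pooled size for which the exact null
#'   distribution is enumerated (default 12).
#' @return A list with `statistic` (the U statistic for `x`), `p_value`,
#'   and `exact` (logical, which path was taken).
#' @export
mann_whitney_two_sided <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney_two_sided: both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("mann_whitney_two_sided: NA values not allowed")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && (length(x) + length(y)) <= exact_max
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  p <- ht$p.value
  if (is.nan(p)) p <- 1 # zero-variance degenerate case (all values tied)
  list(statistic = unname(ht$statistic), p_value = min(p, 1), exact = use_exact)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact independence test by hypergeometric enumeration: the two-sided
#' p-value is the total probability of tables at least as unlikely as the
#' observed one. The reported odds ratio is the sample (cross-product)
#' estimate `(a*d)/(b*c)`, which is `Inf` when `b*c == 0` (and `a*d > 0`),
#' not the conditional MLE.
#'
#' @param tab A 2x2 matrix of non-negative integers. By pipeline convention
#'   rows are (metastatic, primary) and columns (feature-true,
#'   feature-false), so an odds ratio above 1 means metastatic enrichment.
#' @return A list with `p_value` and `odds_ratio`.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact_two_sided: table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact_two_sided: cells must be non-negative integers")
  }
  if (sum(tab) == 0) stop("fisher_exact_two_sided: empty table")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Multiple-testing correction
#'
#' Thin, validated front end over the standard step-up/step-down
#' procedures. Output preserves input length and order; values are clipped
#' to 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs are propagated).
#' @param method `"bh"` (Benjamini-Hochberg FDR), `"holm"`, or
#'   `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "holm", "bonferroni")) {
  method <- match.arg(method)
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("adjust_pvalues: p-values must lie in [0, 1]")
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = switch(method, bh = "BH", holm = "holm",
                              bonferroni = "bonferroni"))
}

#' Cliff's delta effect size
#'
#' Probability-based effect size for ordinal comparisons:
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| * |y|)`, in `[-1, 1]`.
#' Positive values mean enrichment in `x` (metastatic, by pipeline
#' convention).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A scalar in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("cliffs_delta: both samples must be non-empty")
  }
  mean(sign(outer(x, y, "-")))
}

#' Signed Cramer's V for a 2x2 table
#'
#' Association strength `sqrt(chi^2 / n)` (chi-squared without continuity
#' correction) signed by the direction of the odds ratio, so the value
#' ranges over `[-1, 1]` with +1 meaning complete enrichment in row 1
#' (metastatic, by pipeline convention).
#'
#' @param tab A 2x2 matrix of non-negative counts, rows (metastatic,
#'   primary), columns (feature-true, feature-false).
#' @return A scalar in `[-1, 1]`; 0 with a warning when a margin is
#'   degenerate.
#' @export
signed_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("signed_cramers_v: table must be 2x2")
  if (any(tab < 0)) stop("signed_cramers_v: cells must be non-negative")
  n <- sum(tab)
  if (n == 0) stop("signed_cramers_v: empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("signed_cramers_v: degenerate margin; returning 0")
    return(0)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  chi2 <- n * (a * d - b * c_)^2 / prod(rs, cs)
  v <- sqrt(chi2 / n)
  s <- sign(a * d - b * c_) # sign(log OR), robust to zero cells
  s * v
}

#' Cosine similarity between two non-negative vectors
#'
#' @param u,v Non-negative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return `dot(u, v) / (|u| |v|)`, in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("cosine_similarity: length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine_similarity: zero vector")
  sum(u * v) / (nu * nv)
}

#' Mean silhouette width of a clustering
#'
#' Average over all points of `(b - a) / max(a, b)` where `a` is the mean
#' within-cluster distance and `b` the mean distance to the nearest other
#' cluster; singleton clusters contribute 0. Used to select the number of
#' signature clusters.
#'
#' @param points Numeric matrix, one row per point.
#' @param labels Cluster assignment, one per row; at least two distinct
#'   clusters required.
#' @param metric `"cosine"` (1 - cosine similarity) or `"euclidean"`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(points)) stop("silhouette_mean: label/point mismatch")
  if (length(unique(labels)) < 2) stop("silhouette_mean: need at least 2 clusters")
  d <- if (metric == "euclidean") {
    dist(points)
  } else {
    cosine_dist(points)
  }
  sil <- cluster::silhouette(labels, d)
  widths <- sil[, "sil_width"]
  widths[is.nan(widths)] <- 0
  mean(widths)
}

# Pairwise cosine distance (1 - cosine similarity) as a `dist` object.
cosine_dist <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cosine_dist: zero row")
  s <- tcrossprod(m / nrm)
  s <- pmin(pmax(s, -1), 1)
  stats::as.dist(1 - s)
}

#' Non-negative least-squares signature refit
#'
#' Finds non-negative per-signature exposures minimising the Euclidean
#' distance between the observed context-count vector and the
#' exposure-weighted sum of signature profiles.
#'
#' @param profiles Matrix of signature profiles, one row per signature,
#'   columns are context channels; each row sums to 1.
#' @param counts Non-negative numeric vector of observed channel counts.
#' @return Named non-negative exposure vector, one entry per profile row.
#' @export
nnls_fit <- function(profiles, counts) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0) stop("nnls_fit: empty profile set")
  if (ncol(profiles) != length(counts)) stop("nnls_fit: channel mismatch")
  if (any(counts < 0)) stop("nnls_fit: counts must be non-negative")
  rs <- rowSums(profiles)
  if (any(abs(rs - 1) > 1e-6)) stop("nnls_fit: profiles must each sum to 1")
  if (all(counts == 0)) {
    return(setNames(numeric(nrow(profiles)),
                    rownames(profiles) %||% paste0("sig", seq_len(nrow(profiles)))))
  }
  fit <- pracma::lsqnonneg(t(profiles), as.numeric(counts))
  setNames(fit$x,
           rownames(profiles) %||% paste0("sig", seq_len(nrow(profiles))))
}
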