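#' Classify a mutation as clonal or subclonal
#'
#' A mutation is subclonal when its subclonal likelihood is at or above the
#' threshold (default 0.8), clonal otherwise.
#'
#' @param likelihood Numeric vector of subclonal likelihoods in `[0, 1]`.
#' @param threshold Subclonal cut-off (default 0.8).
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(likelihood, threshold = 0.8) {
  if (any(is.na(likelihood)) || any(likelihood < 0 | likelihood > 1)) {
    stop("classify_clonality: likelihood must lie in [0, 1]")
  }
  ifelse(likelihood >= threshold, "subclonal", "clonal")
}

#' Per-sample clonal fraction
#'
#' Fraction of a sample's mutations (SBS, MNV and ID classes) classified as
#' clonal. Samples with no qualifying mutations get an `NA` fraction and
#' are excluded from downstream comparisons: a fraction of an empty set is
#' undefined, not 0 or 1.
#'
#' @param mutations Mutation tibble (columns `sample_id`, `variant_class`,
#'   `subclonal_likelihood`); may hold one or many samples.
#' @param threshold Subclonal likelihood cut-off (default 0.8).
#' @return A tibble with `sample_id`, `n_clonal`, `n_total`,
#'   `clonal_fraction`.
#' @export
sample_clonal_fraction <- function(mutations, threshold = 0.8) {
  keep <- mutations$variant_class %in% c("SBS", "MNV", "ID")
  m <- mutations[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble(sample_id = character(0), n_clonal = integer(0),
                  n_total = integer(0), clonal_fraction = numeric(0)))
  }
  cl <- classify_clonality(m$subclonal_likelihood, threshold) == "clonal"
  out <- dplyr::summarise(dplyr::group_by(tibble(sample_id = m$sample_id, cl = cl),
                                          .data$sample_id),
                          n_clonal = sum(.data$cl), n_total = dplyr::n(),
                          .groups = "drop")
  out$clonal_fraction <- ifelse(out$n_total > 0, out$n_clonal / out$n_total, NA_real_)
  out
}

#' Compare clonality between cohorts per cancer type
#'
#' Two-sided Mann-Whitney test on per-sample clonal fractions, metastatic
#' versus primary, per cancer type, with Benjamini-Hochberg correction
#' across cancer types. Also reports the log2 ratio of the cohort mean
#' clonal fractions (metastatic / primary).
#'
#' @param summaries Per-sample clonality tibble from
#'   [sample_clonal_fraction()].
#' @param samples Sample metadata tibble (`sample_id`, `cohort`,
#'   `cancer_type`).
#' @param q_threshold Significance threshold on the adjusted p
#'   (default 0.05).
#' @param min_per_cohort Minimum samples per cohort for a cancer type to be
#'   tested (default 2).
#' @return A tibble with one row per tested cancer type: `cancer_type`,
#'   `n_primary`, `n_metastatic`, `statistic`, `p_value`, `q_value`,
#'   `log2_ratio`, `significant`, `direction`.
#' @export
compare_clonality <- function(summaries, samples, q_threshold = 0.05,
                              min_per_cohort = 2) {
  df <- dplyr::inner_join(summaries, samples[, c("sample_id", "cohort", "cancer_type")],
                          by = "sample_id")
  df <- df[!is.na(df$clonal_fraction), , drop = FALSE]
  rows <- list()
  for (ct in sort(unique(df$cancer_type))) {
    met <- df$clonal_fraction[df$cancer_type == ct & df$cohort == "metastatic"]
    pri <- df$clonal_fraction[df$cancer_type == ct & df$cohort == "primary"]
    if (length(met) < min_per_cohort || length(pri) < min_per_cohort) {
      log_warn("compare_clonality: skipping '", ct,
               "' (not represented in both cohorts)")
      next
    }
    tr <- mann_whitney_two_sided(met, pri)
    rows[[ct]] <- tibble(cancer_type = ct, n_primary = length(pri),
                         n_metastatic = length(met),
                         statistic = tr$statistic, p_value = tr$p_value,
                         log2_ratio = log2(mean(met) / mean(pri)))
  }
  if (length(rows) == 0) {
    return(tibble(cancer_type = character(0), n_primary = integer(0),
                  n_metastatic = integer(0), statistic = numeric(0),
                  p_value = numeric(0), q_value = numeric(0),
                  log2_ratio = numeric(0), significant = logical(0),
                  direction = character(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$q_value <- adjust_pvalues(out$p_value, "bh")
  out$significant <- out$q_value < q_threshold
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$log2_ratio > 0, "metastatic_enriched",
                                 "primary_enriched"))
  out[, c("cancer_type", "n_primary", "n_metastatic", "statistic", "p_value",
          "q_value", "log2_ratio", "significant", "direction")]
}

#' Compare metastatic clonality across biopsy-site classes
#'
#' Pairwise two-sided Mann-Whitney tests on clonal fractions among biopsy
#' site classes (`local`, `lymph`, `distant`), restricted to classes with
#' at least `min_per_group` samples. Pairwise p-values are reported
#' unadjusted by default; set `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param summaries Per-sample clonality tibble.
#' @param samples Sample metadata (`sample_id`, `cohort`,
#'   `biopsy_site_class`); only metastatic samples are used.
#' @param min_per_group Minimum group size (default 5).
#' @param adjust Apply BH across the pairwise tests (default `FALSE`).
#' @return A tibble with one row per tested pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p_value` (and `q_value` if `adjust`).
#' @export
compare_biopsy_sites <- function(summaries, samples, min_per_group = 5,
                                 adjust = FALSE) {
  met <- samples[samples$cohort == "metastatic", , drop = FALSE]
  df <- dplyr::inner_join(summaries, met[, c("sample_id", "biopsy_site_class")],
                          by = "sample_id")
  df <- df[!is.na(df$clonal_fraction) &
             df$biopsy_site_class %in% c("local", "lymph", "distant"), ,
           drop = FALSE]
  sizes <- table(df$biopsy_site_class)
  groups <- names(sizes)[sizes >= min_per_group]
  rows <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(sort(groups), 2)
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1, j]; gb <- pairs[2, j]
      va <- df$clonal_fraction[df$biopsy_site_class == ga]
      vb <- df$clonal_fraction[df$biopsy_site_class == gb]
      tr <- mann_whitney_two_sided(va, vb)
      rows[[j]] <- tibble(group_a = ga, group_b = gb, n_a = length(va),
                          n_b = length(vb), statistic = tr$statistic,
                          p_value = tr$p_value)
    }
  }
  out <- if (length(rows) == 0) {
    tibble(group_a = character(0), group_b = character(0), n_a = integer(0),
           n_b = integer(0), statistic = numeric(0), p_value = numeric(0))
  } else {
    dplyr::bind_rows(rows)
  }
  if (adjust) out$q_value <- adjust_pvalues(out$p_value, "bh")
  out
}
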