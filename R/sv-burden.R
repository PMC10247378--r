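.sv_complex_tokens <- c("COMPLEX", "INV", "FB_INV_PAIR", "RECIP_INV",
                        "RECIP_INV_DEL_DUP", "RECIP_INV_DUPS", "RECIP_TRANS",
                        "RECIP_TRANS_DEL_DUP", "RECIP_TRANS_DUPS",
                        "UNBAL_TRANS", "UNBAL_TRANS_TI")

.sv_types <- c("del_small", "del_large", "dup_small", "dup_large",
               "complex_small", "complex_large", "line")

#' Classify an SV cluster into the seven-type taxonomy
#'
#' Intrachromosomal DEL/DUP clusters are deletions/duplications, small
#' when their span is strictly below 10 kb; COMPLEX and any inversion or
#' translocation resolved type are complex, large when the cluster chains
#' 20 or more SVs; `LINE` clusters are LINE insertions. Anything else
#' (including interchromosomal DEL/DUP) is `unclassified` and excluded
#' from the seven counts and the total.
#'
#' @param resolved_type,chrom_start,chrom_end,length_bp,n_sv Vectors of
#'   cluster attributes (recycled to common length).
#' @param small_max_bp DEL/DUP small/large boundary (default 10,000;
#'   "small" is strictly below).
#' @param complex_large_min Complex small/large boundary (default 20;
#'   "large" is at or above).
#' @return Character vector of SV-type labels.
#' @export
classify_sv_cluster <- function(resolved_type, chrom_start, chrom_end,
                                length_bp, n_sv, small_max_bp = 10000,
                                complex_large_min = 20) {
  n <- length(resolved_type)
  out <- rep("unclassified", n)
  intra <- !is.na(chrom_start) & !is.na(chrom_end) & chrom_start == chrom_end
  deldup <- resolved_type %in% c("DEL", "DUP") & intra
  small <- !is.na(length_bp) & length_bp < small_max_bp
  out[deldup & resolved_type == "DEL" & small] <- "del_small"
  out[deldup & resolved_type == "DEL" & !small] <- "del_large"
  out[deldup & resolved_type == "DUP" & small] <- "dup_small"
  out[deldup & resolved_type == "DUP" & !small] <- "dup_large"
  cx <- resolved_type %in% .sv_complex_tokens
  out[cx & n_sv < complex_large_min] <- "complex_small"
  out[cx & n_sv >= complex_large_min] <- "complex_large"
  out[resolved_type == "LINE"] <- "line"
  out
}

#' Per-sample SV-type burden counts
#'
#' Counts each of the seven SV types per sample (zero rows included for
#' samples without SV clusters) plus the total over classified clusters.
#'
#' @param sv_clusters SV cluster tibble.
#' @param samples Sample metadata (supplies the full sample list).
#' @param small_max_bp,complex_large_min Classification thresholds.
#' @return A tibble: `sample_id`, one column per SV type, `total`.
#' @export
sv_type_counts <- function(sv_clusters, samples, small_max_bp = 10000,
                           complex_large_min = 20) {
  cls <- classify_sv_cluster(sv_clusters$resolved_type,
                             sv_clusters$chrom_start, sv_clusters$chrom_end,
                             sv_clusters$length_bp, sv_clusters$n_sv,
                             small_max_bp, complex_large_min)
  out <- tibble(sample_id = samples$sample_id)
  for (tp in .sv_types) {
    cnt <- table(factor(sv_clusters$sample_id[cls == tp],
                        levels = samples$sample_id))
    out[[tp]] <- as.integer(cnt)
  }
  out$total <- as.integer(rowSums(as.matrix(out[, .sv_types])))
  out
}

#' Compare SV-type burden between cohorts
#'
#' Per cancer type and SV type: two-sided Mann-Whitney, Bonferroni
#' correction across all tests, relative enrichment
#' `log10(median_met + 1) - log10(median_pri + 1)` and fold change
#' `(median_met + 1) / (median_pri + 1)` (pseudocount 1 in both).
#' `gt_flag` marks fold changes whose primary median is 0 (displayed with
#' ">"); significance requires q < `q_threshold` and fold change at or
#' above `fc_high` or at or below `fc_low`.
#'
#' @param counts Output of [sv_type_counts()].
#' @param samples Sample metadata (`sample_id`, `cohort`, `cancer_type`).
#' @param q_threshold,fc_high,fc_low Decision thresholds (0.05, 1.2, 0.8).
#' @return A tibble, one row per cancer type x SV type.
#' @export
compare_sv_burden <- function(counts, samples, q_threshold = 0.05,
                              fc_high = 1.2, fc_low = 0.8) {
  df <- dplyr::inner_join(counts, samples[, c("sample_id", "cohort",
                                              "cancer_type")],
                          by = "sample_id")
  rows <- list()
  for (ct in sort(unique(df$cancer_type))) {
    sub <- df[df$cancer_type == ct, , drop = FALSE]
    met <- sub[sub$cohort == "metastatic", , drop = FALSE]
    pri <- sub[sub$cohort == "primary", , drop = FALSE]
    if (nrow(met) == 0 || nrow(pri) == 0) next
    for (tp in .sv_types) {
      tr <- mann_whitney_two_sided(met[[tp]], pri[[tp]])
      mm <- median(met[[tp]]); mp <- median(pri[[tp]])
      rows[[paste(ct, tp)]] <- tibble(
        cancer_type = ct, sv_type = tp,
        median_metastatic = mm, median_primary = mp,
        statistic = tr$statistic, p_value = tr$p_value,
        relative_enrichment = log10(mm + 1) - log10(mp + 1),
        fold_change = (mm + 1) / (mp + 1),
        gt_flag = mp == 0)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q_value <- adjust_pvalues(out$p_value, "bonferroni")
  out$significant <- out$q_value < q_threshold &
    (out$fold_change >= fc_high | out$fold_change <= fc_low)
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$fold_change > 1, "metastatic_enriched",
                                 "primary_enriched"))
  out
}

#' Build the SV-regression feature matrix
#'
#' Assembles the per-sample features correlated with SV burden: genome
#' ploidy and number of treatment mechanisms (numeric); HRD, MSI,
#' radiotherapy, one boolean per treatment mechanism, and one boolean per
#' gene in `gene_list` (driver presence, "gene status"). All primary
#' samples and metastatic samples without treatment records are treated as
#' untreated.
#'
#' @param samples,treatments,drivers Cohort tables (`treatments` and
#'   `drivers` may be `NULL`).
#' @param gene_list Genes to encode as gene-status features (default: all
#'   genes seen in `drivers`); fragile-site genes should be excluded from
#'   this list by the caller.
#' @param driver_likelihood_min Driver retention threshold.
#' @return A tibble of features, one row per sample, with attribute
#'   `feature_kind` naming each column's kind (`numeric`, `boolean` or
#'   `gene`).
#' @export
build_feature_matrix <- function(samples, treatments = NULL, drivers = NULL,
                                 gene_list = NULL,
                                 driver_likelihood_min = 0.5) {
  out <- tibble(sample_id = samples$sample_id,
                genome_ploidy = samples$genome_ploidy,
                hrd = as.integer(samples$hrd),
                msi = as.integer(samples$msi))
  kind <- c(genome_ploidy = "numeric", hrd = "boolean", msi = "boolean")
  trt <- treatments
  if (!is.null(trt)) {
    # primaries are untreated by definition of the treatment annotation
    pri_ids <- samples$sample_id[samples$cohort == "primary"]
    trt <- trt[!trt$sample_id %in% pri_ids, , drop = FALSE]
  }
  mechs <- if (is.null(trt)) character(0) else
    sort(unique(trt$mechanism_group))
  n_trt <- integer(nrow(samples))
  for (mech in mechs) {
    ids <- unique(trt$sample_id[trt$mechanism_group == mech])
    colname <- paste0("treat_", gsub("[^A-Za-z0-9]+", "_", mech))
    out[[colname]] <- as.integer(samples$sample_id %in% ids)
    kind[colname] <- "boolean"
    n_trt <- n_trt + out[[colname]]
  }
  out$n_treatments <- n_trt
  kind["n_treatments"] <- "numeric"
  if (!is.null(drivers)) {
    drv <- drivers[drivers$driver_likelihood > driver_likelihood_min, ,
                   drop = FALSE]
    if (is.null(gene_list)) gene_list <- sort(unique(drv$gene))
    for (g in gene_list) {
      colname <- paste0("gene_", g)
      out[[colname]] <- as.integer(samples$sample_id %in%
                                     drv$sample_id[drv$gene == g])
      kind[colname] <- "gene"
    }
  }
  attr(out, "feature_kind") <- kind
  out
}

filter_lm_features <- function(features, kind, gene_min, bool_min_frac) {
  keep <- character(0)
  n <- nrow(features)
  for (f in names(kind)) {
    v <- features[[f]]
    if (kind[[f]] == "numeric") {
      if (sd(v) > 0) keep <- c(keep, f)
    } else {
      nt <- sum(v)
      min_needed <- if (kind[[f]] == "gene") gene_min else 0
      if (nt >= min_needed && nt >= bool_min_frac * n && nt < n) {
        keep <- c(keep, f)
      }
    }
  }
  keep
}

run_one_lm <- function(y, X) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  # aliased (rank-deficient) features are dropped from the coefficient table
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased) > 0) {
    warning(sprintf("dropping aliased feature(s): %s",
                    paste(aliased, collapse = ", ")))
  }
  list(coefficients = co, overall_p = overall_p)
}

coef_row <- function(fit, feature) {
  co <- fit$coefficients
  rn <- rownames(co)
  # lm mangles names through the formula interface; match syntactic form
  target <- make.names(feature)
  i <- match(target, rn)
  if (is.na(i)) return(NULL)
  c(estimate = co[i, 1], p = co[i, 4])
}

#' Three-linear-model screen for features explaining SV burden
#'
#' For each requested (cancer type, SV type) pair — in the pipeline, only
#' pairs whose burden comparison showed a significant metastatic increase
#' — fits three OLS models of `log10(burden + 1)` on the features:
#' combined (both cohorts), metastatic-only and primary-only. Boolean
#' prevalence filters are applied per fit (gene-status features need >= 15
#' TRUE samples combined, >= 10 cohort-specific; remaining booleans >= 5%
#' TRUE). A feature passes the combined model when the overall regression
#' F-test p and its coefficient p are both below 0.01 with a positive
#' coefficient; it passes cohort-specific when either single-cohort model
#' shows coefficient p < 0.01 with a positive coefficient. Features
#' passing both, with a metastatic-leaning effect size (Cliff's delta for
#' numeric, signed Cramer's V for boolean), explain the metastatic burden
#' increase.
#'
#' @param burden Numeric vector of SV counts, one per sample.
#' @param features Feature tibble from [build_feature_matrix()] (same
#'   sample order).
#' @param cohort Character vector, `"primary"`/`"metastatic"`, per sample.
#' @param config Configuration list for the filter thresholds.
#' @return A tibble, one row per feature retained in the combined fit.
#' @export
fit_three_lms <- function(burden, features, cohort,
                          config = default_config()) {
  if (length(burden) < 30) stop("fit_three_lms: need at least 30 samples")
  kind <- attr(features, "feature_kind")
  fm <- features[, names(kind), drop = FALSE]
  y <- log10(burden + 1)
  met <- cohort == "metastatic"
  pri <- cohort == "primary"

  keep_comb <- filter_lm_features(fm, kind, config$lm_gene_min_combined,
                                  config$lm_bool_min_frac)
  if (length(keep_comb) == 0) return(empty_lm_result())
  fit_comb <- run_one_lm(y, fm[, keep_comb, drop = FALSE])
  fit_cohort <- list()
  for (side in c("metastatic", "primary")) {
    idx <- if (side == "metastatic") met else pri
    if (sum(idx) < 3) next
    sub <- fm[idx, , drop = FALSE]
    keep <- filter_lm_features(sub, kind[keep_comb],
                               config$lm_gene_min_cohort,
                               config$lm_bool_min_frac)
    if (length(keep) == 0) next
    fit_cohort[[side]] <- run_one_lm(y[idx], sub[, keep, drop = FALSE])
  }

  rows <- list()
  for (f in keep_comb) {
    cr <- coef_row(fit_comb, f)
    if (is.null(cr)) next
    passed_combined <- !is.na(fit_comb$overall_p) &&
      fit_comb$overall_p < config$lm_regression_p &&
      cr[["p"]] < config$lm_coef_p && cr[["estimate"]] > 0
    passed_cohort <- FALSE
    for (side in names(fit_cohort)) {
      sr <- coef_row(fit_cohort[[side]], f)
      if (!is.null(sr) && sr[["p"]] < config$lm_coef_p && sr[["estimate"]] > 0) {
        passed_cohort <- TRUE
      }
    }
    eff <- feature_effect_direction(fm[[f]], cohort,
                                    numeric_feature = kind[[f]] == "numeric")
    rows[[f]] <- tibble(feature = f, kind = kind[[f]],
                        coefficient = unname(cr[["estimate"]]),
                        coefficient_p = unname(cr[["p"]]),
                        regression_p = fit_comb$overall_p,
                        passed_combined = passed_combined,
                        passed_cohort_specific = passed_cohort,
                        effect_size = eff,
                        explains_met_increase = passed_combined &&
                          passed_cohort && eff > 0)
  }
  if (length(rows) == 0) return(empty_lm_result())
  dplyr::bind_rows(rows)
}

empty_lm_result <- function() {
  tibble(feature = character(0), kind = character(0),
         coefficient = numeric(0), coefficient_p = numeric(0),
         regression_p = numeric(0), passed_combined = logical(0),
         passed_cohort_specific = logical(0), effect_size = numeric(0),
         explains_met_increase = logical(0))
}

#' Cohort-enrichment direction of a feature
#'
#' Cliff's delta for numeric features, signed Cramer's V for boolean
#' features; positive values mean metastatic enrichment.
#'
#' @param values Feature values, one per sample.
#' @param cohort `"primary"`/`"metastatic"` per sample.
#' @param numeric_feature Treat as numeric (Cliff's delta) rather than
#'   boolean.
#' @return Effect size in `[-1, 1]`.
#' @export
feature_effect_direction <- function(values, cohort, numeric_feature = TRUE) {
  met <- values[cohort == "metastatic"]
  pri <- values[cohort == "primary"]
  if (length(met) == 0 || length(pri) == 0) {
    stop("feature_effect_direction: feature must be present in both cohorts")
  }
  if (numeric_feature) {
    cliffs_delta(met, pri)
  } else {
    tab <- matrix(c(sum(met == 1), sum(met == 0),
                    sum(pri == 1), sum(pri == 0)), nrow = 2, byrow = TRUE)
    suppressWarnings(signed_cramers_v(tab))
  }
}

#' Full SV feature-association screen
#'
#' Pipeline driver: runs [compare_sv_burden()], then [fit_three_lms()]
#' only for (cancer type, SV type) pairs with a significant metastatic
#' burden increase.
#'
#' @param counts Output of [sv_type_counts()].
#' @param features Output of [build_feature_matrix()].
#' @param samples Sample metadata.
#' @param config Configuration list.
#' @return A list with `burden_comparison` and `associations` (tibble with
#'   `cancer_type`, `sv_type` prepended).
#' @export
sv_association_screen <- function(counts, features, samples,
                                  config = default_config()) {
  cmp <- compare_sv_burden(counts, samples, config$sv_q, config$sv_fc_high,
                           config$sv_fc_low)
  assoc <- list()
  hits <- cmp[cmp$significant & cmp$fold_change > 1, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    ct <- hits$cancer_type[i]; tp <- hits$sv_type[i]
    ids <- samples$sample_id[samples$cancer_type == ct]
    idx <- match(ids, counts$sample_id)
    fidx <- match(ids, features$sample_id)
    sub_feat <- features[fidx, , drop = FALSE]
    attr(sub_feat, "feature_kind") <- attr(features, "feature_kind")
    res <- tryCatch(
      fit_three_lms(counts[[tp]][idx], sub_feat,
                    samples$cohort[match(ids, samples$sample_id)], config),
      error = function(e) empty_lm_result())
    if (nrow(res) > 0) {
      res <- dplyr::bind_cols(tibble(cancer_type = ct, sv_type = tp), res)
      assoc[[paste(ct, tp)]] <- res
    }
  }
  list(burden_comparison = cmp,
       associations = if (length(assoc) > 0) dplyr::bind_rows(assoc) else
         dplyr::bind_cols(tibble(cancer_type = character(0),
                                 sv_type = character(0)), empty_lm_result()))
}
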