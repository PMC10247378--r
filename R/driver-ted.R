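#' Driver events per patient
#'
#' Retains events with driver likelihood strictly above
#' `likelihood_min` (0.5), de-duplicates by gene (a mutation and a
#' deletion of the same gene count once), and returns the count.
#'
#' @param events Driver-event tibble for one sample/patient.
#' @param likelihood_min Retention threshold (strictly above).
#' @return Integer driver count.
#' @export
driver_count_per_patient <- function(events, likelihood_min = 0.5) {
  keep <- events$driver_likelihood > likelihood_min
  length(unique(events$gene[keep]))
}

#' Compare per-sample driver counts between cohorts
#'
#' Per cancer type: two-sided Mann-Whitney on per-sample driver counts,
#' BH-corrected across cancer types; significant when q < `q_threshold`
#' (0.01). Reports the difference of cohort means.
#'
#' @param drivers Driver-event tibble for the whole cohort.
#' @param samples Sample metadata.
#' @param q_threshold Adjusted-p threshold.
#' @param likelihood_min Driver retention threshold.
#' @return A tibble, one row per cancer type.
#' @export
compare_driver_counts <- function(drivers, samples, q_threshold = 0.01,
                                  likelihood_min = 0.5) {
  cnt <- vapply(samples$sample_id, function(s) {
    driver_count_per_patient(drivers[drivers$sample_id == s, , drop = FALSE],
                             likelihood_min)
  }, numeric(1))
  df <- tibble(sample_id = samples$sample_id, cohort = samples$cohort,
               cancer_type = samples$cancer_type, n_drivers = cnt)
  rows <- list()
  for (ct in sort(unique(df$cancer_type))) {
    met <- df$n_drivers[df$cancer_type == ct & df$cohort == "metastatic"]
    pri <- df$n_drivers[df$cancer_type == ct & df$cohort == "primary"]
    if (length(met) == 0 || length(pri) == 0) next
    tr <- mann_whitney_two_sided(met, pri)
    rows[[ct]] <- tibble(cancer_type = ct, mean_metastatic = mean(met),
                         mean_primary = mean(pri),
                         mean_diff = mean(met) - mean(pri),
                         statistic = tr$statistic, p_value = tr$p_value)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q_value <- adjust_pvalues(out$p_value, "bh")
  out$significant <- out$q_value < q_threshold
  out
}

# Collapse alteration types to test categories: partial amplifications are
# amplifications; homozygous disruptions are deletions.
driver_category <- function(alteration_type) {
  ifelse(alteration_type %in% c("amplification"), "amplification",
         ifelse(alteration_type %in% c("deletion", "homozygous_disruption"),
                "deletion",
                ifelse(alteration_type == "noncoding", "noncoding", "mutation")))
}

#' Per-gene driver-frequency enrichment between cohorts
#'
#' For each gene, alteration category and cancer type: a 2x2 Fisher's
#' exact test of mutated versus not mutated by cohort, restricted to
#' genes mutated in at least `min_mutated` (5) samples in either cohort,
#' BH-corrected within cancer type; significant when q < `q_threshold`
#' (0.01). Effect sizes are the sample odds ratio and signed Cramer's V.
#'
#' @param drivers Driver-event tibble.
#' @param samples Sample metadata.
#' @param q_threshold,min_mutated,likelihood_min Decision thresholds.
#' @return A tibble, one row per tested gene x category x cancer type.
#' @export
driver_frequency_enrichment <- function(drivers, samples, q_threshold = 0.01,
                                        min_mutated = 5,
                                        likelihood_min = 0.5) {
  drv <- drivers[drivers$driver_likelihood > likelihood_min, , drop = FALSE]
  drv$category <- driver_category(drv$alteration_type)
  rows <- list()
  for (ct in sort(unique(samples$cancer_type))) {
    sub_s <- samples[samples$cancer_type == ct, , drop = FALSE]
    met_ids <- sub_s$sample_id[sub_s$cohort == "metastatic"]
    pri_ids <- sub_s$sample_id[sub_s$cohort == "primary"]
    if (length(met_ids) == 0 || length(pri_ids) == 0) next
    sub_d <- drv[drv$sample_id %in% sub_s$sample_id, , drop = FALSE]
    fam <- list()
    combos <- unique(sub_d[, c("gene", "category")])
    for (i in seq_len(nrow(combos))) {
      g <- combos$gene[i]; cat_ <- combos$category[i]
      hit_ids <- unique(sub_d$sample_id[sub_d$gene == g &
                                          sub_d$category == cat_])
      a <- sum(met_ids %in% hit_ids); b <- length(met_ids) - a
      c_ <- sum(pri_ids %in% hit_ids); d <- length(pri_ids) - c_
      if (max(a, c_) < min_mutated) next
      tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
      fr <- fisher_exact_two_sided(tab)
      fam[[paste(g, cat_)]] <- tibble(
        cancer_type = ct, gene = g, category = cat_,
        n_metastatic = a, n_primary = c_,
        odds_ratio = fr$odds_ratio, p_value = fr$p_value,
        effect_size = suppressWarnings(signed_cramers_v(tab)))
    }
    if (length(fam) == 0) next
    fam <- dplyr::bind_rows(fam)
    fam$q_value <- adjust_pvalues(fam$p_value, "bh")
    rows[[ct]] <- fam
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$significant <- out$q_value < q_threshold
  out
}

#' Group patients by cancer type and treatment mechanism
#'
#' Maps drug names to mechanism groups, assembles one group per (cancer
#' type x mechanism), and keeps groups with at least `min_patients` (10)
#' patients. A patient with several therapy lines appears in several
#' groups. Drug names missing from the mechanism map are assigned to
#' `"other"` with a warning.
#'
#' @param treatments Treatment tibble (`sample_id`, `drug_name`,
#'   `mechanism_group` may be empty when a mechanism map is supplied).
#' @param samples Sample metadata (`sample_id`, `patient_id`,
#'   `cancer_type`).
#' @param mechanism_map Optional tibble (`drug_name`, `mechanism_group`)
#'   overriding the treatments' own mechanism column.
#' @param min_patients Group size gate.
#' @return A tibble: `cancer_type`, `mechanism_group`, `n_patients`,
#'   `patients` (list column of patient ids).
#' @export
build_treatment_groups <- function(treatments, samples, mechanism_map = NULL,
                                   min_patients = 10) {
  trt <- treatments
  if (!is.null(mechanism_map)) {
    idx <- match(trt$drug_name, mechanism_map$drug_name)
    unknown <- unique(trt$drug_name[is.na(idx)])
    if (length(unknown) > 0) {
      warning(sprintf("build_treatment_groups: unmapped drug(s) assigned to 'other': %s",
                      paste(unknown, collapse = ", ")))
    }
    trt$mechanism_group <- ifelse(is.na(idx), "other",
                                  mechanism_map$mechanism_group[idx])
  }
  trt <- dplyr::inner_join(trt, samples[, c("sample_id", "patient_id",
                                            "cancer_type")],
                           by = "sample_id")
  grp <- dplyr::summarise(
    dplyr::group_by(trt, .data$cancer_type, .data$mechanism_group),
    patients = list(sort(unique(.data$patient_id))), .groups = "drop")
  grp$n_patients <- vapply(grp$patients, length, integer(1))
  grp[grp$n_patients >= min_patients,
      c("cancer_type", "mechanism_group", "n_patients", "patients")]
}

#' Focal copy-number status of a gene
#'
#' A gene is amplified when its ploidy is strictly more than
#' `amp_diff` (2.5) above the sample's genome-wide mean ploidy, deleted
#' (deep deletion) when its ploidy is strictly below `del_ploidy` (0.3),
#' neutral otherwise.
#'
#' @param gene_ploidy,sample_mean_ploidy Non-negative ploidies
#'   (vectorised).
#' @param amp_diff,del_ploidy Decision thresholds.
#' @return Character vector: `"amplified"`, `"deleted"` or `"neutral"`.
#' @export
gene_cn_status <- function(gene_ploidy, sample_mean_ploidy, amp_diff = 2.5,
                           del_ploidy = 0.3) {
  if (any(gene_ploidy < 0) || any(sample_mean_ploidy < 0)) {
    stop("gene_cn_status: ploidies must be >= 0")
  }
  ifelse(gene_ploidy < del_ploidy, "deleted",
         ifelse(gene_ploidy - sample_mean_ploidy > amp_diff, "amplified",
                "neutral"))
}

#' Treatment-enriched driver (TED) test
#'
#' For each candidate element: a two-sided Fisher's exact test of
#' alteration frequency in the treated group versus the untreated
#' comparison group of the same cancer type, with the sample odds ratio.
#' P-values are BH-adjusted within each alteration category; the
#' significance threshold is 0.05 for coding and CN candidates and 0.1
#' for non-coding candidates (which additionally require at least 3
#' mutated treated samples). Significant elements are labelled
#' `treatment_exclusive` when the untreated frequency is strictly below
#' 5%, `treatment_enriched` otherwise.
#'
#' @param candidates Tibble with `element` (gene or element id),
#'   `category` (`coding`, `noncoding`, `amplification`, `deletion`),
#'   `n_treated_mut`, `n_treated`, `n_untreated_mut`, `n_untreated`.
#' @param q_coding,q_noncoding BH thresholds per category class.
#' @param noncoding_min_mutated Minimum mutated treated samples for
#'   non-coding candidates.
#' @param exclusive_max_freq Untreated-frequency bound for the exclusivity
#'   label.
#' @param known_resistance Optional character vector of elements curated
#'   as literature-reported resistance drivers.
#' @return A tibble of tested candidates with `odds_ratio`, `p_value`,
#'   `q_value`, `significant`, `label`, `known_resistance`.
#' @export
ted_test <- function(candidates, q_coding = 0.05, q_noncoding = 0.1,
                     noncoding_min_mutated = 3, exclusive_max_freq = 0.05,
                     known_resistance = character(0)) {
  cand <- candidates
  drop <- cand$category == "noncoding" &
    cand$n_treated_mut < noncoding_min_mutated
  cand <- cand[!drop, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_ted_result())
  res <- lapply(seq_len(nrow(cand)), function(i) {
    tab <- matrix(c(cand$n_treated_mut[i],
                    cand$n_treated[i] - cand$n_treated_mut[i],
                    cand$n_untreated_mut[i],
                    cand$n_untreated[i] - cand$n_untreated_mut[i]),
                  nrow = 2, byrow = TRUE)
    fr <- fisher_exact_two_sided(tab)
    tibble(odds_ratio = fr$odds_ratio, p_value = fr$p_value)
  })
  out <- dplyr::bind_cols(cand, dplyr::bind_rows(res))
  out <- dplyr::group_by(out, .data$category)
  out <- dplyr::mutate(out, q_value = adjust_pvalues(.data$p_value, "bh"))
  out <- dplyr::ungroup(out)
  thr <- ifelse(out$category == "noncoding", q_noncoding, q_coding)
  untreated_freq <- out$n_untreated_mut / out$n_untreated
  out$significant <- out$q_value < thr & out$odds_ratio > 1
  out$untreated_freq <- untreated_freq
  out$label <- ifelse(untreated_freq < exclusive_max_freq,
                      "treatment_exclusive", "treatment_enriched")
  out$known_resistance <- out$element %in% known_resistance
  out
}

empty_ted_result <- function() {
  tibble(element = character(0), category = character(0),
         n_treated_mut = integer(0), n_treated = integer(0),
         n_untreated_mut = integer(0), n_untreated = integer(0),
         odds_ratio = numeric(0), p_value = numeric(0), q_value = numeric(0),
         significant = logical(0), untreated_freq = numeric(0),
         label = character(0), known_resistance = logical(0))
}

#' Candidate elements for the TED test
#'
#' Frequency-based discovery stand-in: candidate genes are those altered
#' in at least `min_altered` (3) treated-group samples. A plug-in
#' interface: pass `external_candidates` (a character vector of element
#' ids) to use an externally produced discovery list instead.
#'
#' @param drivers Driver-event tibble.
#' @param treated_ids,untreated_ids Sample ids of the treated group and
#'   the untreated comparison group.
#' @param category Alteration category to count (`"coding"` counts
#'   mutation events).
#' @param min_altered Minimum altered treated samples.
#' @param external_candidates Optional externally supplied element list.
#' @param likelihood_min Driver retention threshold.
#' @return A candidates tibble suitable for [ted_test()].
#' @export
ted_candidates <- function(drivers, treated_ids, untreated_ids,
                           category = "coding", min_altered = 3,
                           external_candidates = NULL,
                           likelihood_min = 0.5) {
  drv <- drivers[drivers$driver_likelihood > likelihood_min, , drop = FALSE]
  drv$cat <- driver_category(drv$alteration_type)
  want <- switch(category, coding = "mutation", noncoding = "noncoding",
                 amplification = "amplification", deletion = "deletion",
                 stop(sprintf("unknown category '%s'", category)))
  drv <- drv[drv$cat == want, , drop = FALSE]
  count_in <- function(g, ids) {
    length(unique(drv$sample_id[drv$gene == g & drv$sample_id %in% ids]))
  }
  genes <- if (is.null(external_candidates)) {
    g <- sort(unique(drv$gene[drv$sample_id %in% treated_ids]))
    g[vapply(g, count_in, numeric(1), ids = treated_ids) >= min_altered]
  } else {
    sort(external_candidates)
  }
  if (length(genes) == 0) {
    return(tibble(element = character(0), category = character(0),
                  n_treated_mut = integer(0), n_treated = integer(0),
                  n_untreated_mut = integer(0), n_untreated = integer(0)))
  }
  tibble(element = genes, category = category,
         n_treated_mut = vapply(genes, count_in, numeric(1),
                                ids = treated_ids),
         n_treated = length(treated_ids),
         n_untreated_mut = vapply(genes, count_in, numeric(1),
                                  ids = untreated_ids),
         n_untreated = length(untreated_ids))
}

#' Merge overlapping copy-number peaks
#'
#' Within each cancer type and direction (amplification and deletion
#' peaks processed separately), overlapping peak intervals are unioned
#' into a single peak; the representative gene and treatment are taken
#' from the member peak with the lowest q-value (the gene nearest that
#' peak's summit).
#'
#' @param peaks Tibble: `cancer_type`, `direction`, `start`, `end`,
#'   `summit`, `gene`, `treatment`, `q_value`.
#' @return Merged peaks with representative annotations.
#' @export
merge_cn_peaks <- function(peaks) {
  rows <- list()
  for (key in unique(paste(peaks$cancer_type, peaks$direction, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- peaks[peaks$cancer_type == parts[1] & peaks$direction == parts[2], ,
                 drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    members <- list(cur)
    flush <- function(members) {
      m <- dplyr::bind_rows(members)
      best <- which.min(m$q_value)
      tibble(cancer_type = m$cancer_type[1], direction = m$direction[1],
             start = min(m$start), end = max(m$end),
             gene = m$gene[best], treatment = m$treatment[best],
             q_value = m$q_value[best], n_merged = nrow(m))
    }
    if (nrow(sub) > 1) {
      cur_end <- sub$end[1]
      acc <- list(sub[1, ])
      for (i in 2:nrow(sub)) {
        if (sub$start[i] < cur_end) { # overlap (half-open intervals)
          acc[[length(acc) + 1]] <- sub[i, ]
          cur_end <- max(cur_end, sub$end[i])
        } else {
          rows[[length(rows) + 1]] <- flush(acc)
          acc <- list(sub[i, ])
          cur_end <- sub$end[i]
        }
      }
      rows[[length(rows) + 1]] <- flush(acc)
    } else {
      rows[[length(rows) + 1]] <- flush(list(sub))
    }
  }
  dplyr::bind_rows(rows)
}

#' Prioritise one treatment association per gene and cancer type
#'
#' When a gene is significantly associated with several treatment groups
#' in one cancer type, keep the most significant (lowest q) association,
#' unless a curated literature pairing pins a specific treatment.
#'
#' @param ted_results Tibble with `cancer_type`, `element`,
#'   `mechanism_group`, `q_value` (typically the significant rows of
#'   [ted_test()] runs across groups).
#' @param curation Optional tibble (`cancer_type`, `element`,
#'   `mechanism_group`) of literature-pinned pairings.
#' @return The prioritised catalogue, one row per (cancer type, element).
#' @export
prioritize_teds <- function(ted_results, curation = NULL) {
  rows <- list()
  keys <- unique(ted_results[, c("cancer_type", "element")])
  for (i in seq_len(nrow(keys))) {
    ct <- keys$cancer_type[i]; el <- keys$element[i]
    sub <- ted_results[ted_results$cancer_type == ct &
                         ted_results$element == el, , drop = FALSE]
    pick <- NULL
    if (!is.null(curation)) {
      pin <- curation[curation$cancer_type == ct & curation$element == el, ,
                      drop = FALSE]
      if (nrow(pin) > 0) {
        pick <- sub[sub$mechanism_group %in% pin$mechanism_group, ,
                    drop = FALSE]
      }
    }
    if (is.null(pick) || nrow(pick) == 0) pick <- sub
    rows[[i]] <- pick[which.min(pick$q_value), , drop = FALSE]
  }
  dplyr::bind_rows(rows)
}

#' Driver counts before and after TED exclusion
#'
#' Removes catalogued TEDs from the driver events in a cancer-type-,
#' gene- and category-specific manner, then recomputes the per-cohort
#' mean drivers per sample.
#'
#' @param drivers Driver-event tibble.
#' @param samples Sample metadata.
#' @param ted_catalogue Tibble with `cancer_type`, `element` (gene) and
#'   `category`.
#' @param likelihood_min Driver retention threshold.
#' @return A tibble per cohort: mean drivers per sample before and after
#'   exclusion.
#' @export
recount_excluding_teds <- function(drivers, samples, ted_catalogue,
                                   likelihood_min = 0.5) {
  drv <- drivers
  drv$category <- driver_category(drv$alteration_type)
  drv$cancer_type <- samples$cancer_type[match(drv$sample_id,
                                               samples$sample_id)]
  # accept the TED test's category naming for small-variant drivers
  ted_catalogue$category[ted_catalogue$category == "coding"] <- "mutation"
  is_ted <- rep(FALSE, nrow(drv))
  for (i in seq_len(nrow(ted_catalogue))) {
    is_ted <- is_ted | (drv$cancer_type == ted_catalogue$cancer_type[i] &
                          drv$gene == ted_catalogue$element[i] &
                          drv$category == ted_catalogue$category[i])
  }
  count_means <- function(events) {
    vapply(split(samples$sample_id, samples$cohort), function(ids) {
      mean(vapply(ids, function(s) {
        driver_count_per_patient(events[events$sample_id == s, , drop = FALSE],
                                 likelihood_min)
      }, numeric(1)))
    }, numeric(1))
  }
  before <- count_means(drv)
  after <- count_means(drv[!is_ted, , drop = FALSE])
  tibble(cohort = names(before), mean_drivers_before = unname(before),
         mean_drivers_after = unname(after[names(before)]))
}
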