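is_skin_melanoma <- function(cancer_type) {
  grepl("skin.?melanoma|^melanoma$", tolower(cancer_type))
}

#' Count clock-like SBS1 mutations in a sample
#'
#' SBS1 mutations are C>T substitutions at a CpG site (NpCpG context,
#' pyrimidine strand), counted at contexts ACG, CCG and GCG. The TpCpG
#' context is always excluded because it is also a characteristic APOBEC
#' channel; for skin melanoma CpCpG is additionally excluded because it
#' overlaps the UV signature.
#'
#' @param mutations Mutation tibble for one sample (columns
#'   `variant_class`, `ref`, `alt`, `context`).
#' @param cancer_type Cancer-type label; anything matching "skin melanoma"
#'   triggers the additional exclusion.
#' @return Integer count of SBS1 mutations.
#' @export
count_sbs1 <- function(mutations, cancer_type = "") {
  ctx <- if (is_skin_melanoma(cancer_type)) c("ACG", "GCG") else
    c("ACG", "CCG", "GCG")
  sum(mutations$variant_class == "SBS" & mutations$ref == "C" &
        mutations$alt == "T" & mutations$context %in% ctx)
}

#' Logical SBS1 flag per mutation row
#'
#' Same rule as [count_sbs1()] but returning the per-row indicator, used
#' by the clonality-ratio computation.
#'
#' @inheritParams count_sbs1
#' @return Logical vector along the rows of `mutations`.
#' @export
is_sbs1 <- function(mutations, cancer_type = "") {
  ctx <- if (is_skin_melanoma(cancer_type)) c("ACG", "GCG") else
    c("ACG", "CCG", "GCG")
  mutations$variant_class == "SBS" & mutations$ref == "C" &
    mutations$alt == "T" & mutations$context %in% ctx
}

#' Exclude hypermutated samples from the clock regression
#'
#' Drops samples whose total mutation burden is strictly above
#' `tmb_max` (30,000) or whose SBS1 burden is strictly above `sbs1_max`
#' (5,000).
#'
#' @param df Tibble with columns `tmb` and `sbs1` (one row per sample).
#' @param tmb_max,sbs1_max Exclusion thresholds.
#' @return The retained rows of `df`.
#' @export
filter_clock_samples <- function(df, tmb_max = 30000, sbs1_max = 5000) {
  df[df$tmb <= tmb_max & df$sbs1 <= sbs1_max, , drop = FALSE]
}

ols_fit <- function(age, count) {
  mx <- mean(age); my <- mean(count)
  sxx <- sum((age - mx)^2)
  slope <- sum((age - mx) * (count - my)) / sxx
  c(slope = slope, intercept = my - slope * mx)
}

#' Subsampled age-regression of clock-like mutation burden
#'
#' Fits `n_boot` (100) ordinary-least-squares regressions of mutation
#' count on age, each on a random 75% subsample drawn without
#' replacement, and returns the fit with the median slope (the lower
#' median for even `n_boot`) as the representative regression, so the
#' representative line is always an actually fitted one. Confidence bands
#' come from the fits at the 1st and 99th slope percentiles. Deterministic
#' given `seed`.
#'
#' @param age,count Numeric vectors (years; mutations), one entry per
#'   sample.
#' @param n_boot Number of subsampled regressions.
#' @param frac Subsample fraction.
#' @param seed Integer seed for the subsampling.
#' @param min_points Minimum number of samples required.
#' @return An object of class `clock_fit`: list with `slope`, `intercept`,
#'   `pearson_r` (on the representative subsample), `slope_lo`,
#'   `intercept_lo`, `slope_hi`, `intercept_hi`, `n_samples`.
#' @export
bootstrap_regression <- function(age, count, n_boot = 100, frac = 0.75,
                                 seed = 1, min_points = 20) {
  n <- length(age)
  if (length(count) != n) stop("bootstrap_regression: length mismatch")
  if (n < min_points) {
    stop(sprintf("bootstrap_regression: %d points, need at least %d", n,
                 min_points))
  }
  m <- max(2L, round(frac * n))
  fits <- with_local_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, m, replace = FALSE)
      f <- ols_fit(age[idx], count[idx])
      r <- suppressWarnings(cor(age[idx], count[idx]))
      c(f, r = if (is.na(r)) 0 else r)
    }, numeric(3)))
  })
  ord <- order(fits[, "slope"])
  med_i <- ord[ceiling(n_boot / 2)]           # lower median for even counts
  lo_i <- ord[max(1L, ceiling(0.01 * n_boot))]
  hi_i <- ord[min(n_boot, ceiling(0.99 * n_boot))]
  structure(list(slope = unname(fits[med_i, "slope"]),
                 intercept = unname(fits[med_i, "intercept"]),
                 pearson_r = unname(fits[med_i, "r"]),
                 slope_lo = unname(fits[lo_i, "slope"]),
                 intercept_lo = unname(fits[lo_i, "intercept"]),
                 slope_hi = unname(fits[hi_i, "slope"]),
                 intercept_hi = unname(fits[hi_i, "intercept"]),
                 n_samples = n),
            class = "clock_fit")
}

#' Predict mutation burden from a clock fit
#'
#' @param object A `clock_fit`.
#' @param age Ages at which to predict.
#' @param ... Unused.
#' @return Predicted mutation counts.
#' @export
predict.clock_fit <- function(object, age, ...) {
  object$slope * age + object$intercept
}

#' Mean fold change of predicted burden over ages 40-80
#'
#' Arithmetic mean over integer ages 40..80 of the ratio of metastatic to
#' primary predicted burden. The default divisor is the number of terms
#' (41); `literal_divisor = TRUE` divides by 40 instead, reproducing the
#' printed coefficient of the defining equation.
#'
#' @param met_fit,pri_fit `clock_fit` objects (or any object supported by
#'   `predict(fit, age)`).
#' @param age_min,age_max Integer age range (inclusive).
#' @param literal_divisor Use `age_max - age_min` as divisor instead of
#'   the term count.
#' @return The mean fold change.
#' @export
mean_fold_change <- function(met_fit, pri_fit, age_min = 40, age_max = 80,
                             literal_divisor = FALSE) {
  ages <- seq(age_min, age_max)
  p <- predict(pri_fit, ages)
  if (any(p <= 0)) {
    stop("mean_fold_change: primary prediction non-positive in the age range")
  }
  m <- predict(met_fit, ages)
  div <- if (literal_divisor) (age_max - age_min) else length(ages)
  sum(m / p) / div
}

#' Mean difference of predicted burden over ages 40-80
#'
#' Arithmetic mean over integer ages 40..80 of metastatic minus primary
#' predicted burden; same divisor convention as [mean_fold_change()].
#'
#' @inheritParams mean_fold_change
#' @return The mean burden difference, in mutations.
#' @export
mean_burden_diff <- function(met_fit, pri_fit, age_min = 40, age_max = 80,
                             literal_divisor = FALSE) {
  ages <- seq(age_min, age_max)
  div <- if (literal_divisor) (age_max - age_min) else length(ages)
  sum(predict(met_fit, ages) - predict(pri_fit, ages)) / div
}

#' Test for an accelerated clock-mutation rate in metastatic tumours
#'
#' The comparison is gated on both cohorts showing a positive age trend
#' (Pearson r strictly above `r_gate`, default 0.1). Residuals of both
#' cohorts' counts are computed against the *primary* representative
#' regression and compared with a two-sided Mann-Whitney test. A cancer
#' type is significant when the gate passes, p < `p_threshold` (0.01) and
#' the metastatic intercept is above the primary intercept (which ensures
#' the shift is uniform across ages rather than driven by one extreme age
#' range).
#'
#' @param pri_fit,met_fit Representative `clock_fit`s.
#' @param pri_age,pri_count,met_age,met_count Per-sample data of the two
#'   cohorts.
#' @param r_gate Pearson-r gate.
#' @param p_threshold Mann-Whitney significance threshold.
#' @param age_min,age_max,literal_divisor Passed to the fold-change and
#'   burden-difference summaries.
#' @return A list: `gate_passed`, `mw_p`, `significant`,
#'   `mean_fold_change`, `mean_burden_diff`, intercepts.
#' @export
compare_rates <- function(pri_fit, met_fit, pri_age, pri_count, met_age,
                          met_count, r_gate = 0.1, p_threshold = 0.01,
                          age_min = 40, age_max = 80,
                          literal_divisor = FALSE) {
  gate <- (pri_fit$pearson_r > r_gate) && (met_fit$pearson_r > r_gate)
  res_pri <- pri_count - predict(pri_fit, pri_age)
  res_met <- met_count - predict(pri_fit, met_age)
  tr <- mann_whitney_two_sided(res_met, res_pri)
  fc <- tryCatch(mean_fold_change(met_fit, pri_fit, age_min, age_max,
                                  literal_divisor),
                 error = function(e) NA_real_)
  bd <- mean_burden_diff(met_fit, pri_fit, age_min, age_max, literal_divisor)
  list(gate_passed = gate, mw_p = tr$p_value,
       significant = gate && tr$p_value < p_threshold &&
         met_fit$intercept > pri_fit$intercept,
       mean_fold_change = fc, mean_burden_diff = bd,
       intercept_primary = pri_fit$intercept,
       intercept_metastatic = met_fit$intercept)
}

#' Maximum-likelihood assignment of a mutation to a signature
#'
#' Assigns a mutation (identified by its context channel) to the signature
#' maximising exposure x channel probability; ties break lexicographically
#' by signature name. Used to label individual SBS5/SBS40 (clock-like)
#' mutations.
#'
#' @param channel The mutation's context channel (e.g. `"A[C>T]G"`).
#' @param exposures Named numeric vector of the sample's signature
#'   exposures.
#' @param profiles Matrix of signature profiles (rows named by signature,
#'   columns by channel).
#' @return The winning signature name, or `NA` if all likelihoods are 0.
#' @export
assign_clocklike_ml <- function(channel, exposures, profiles) {
  sigs <- intersect(names(exposures), rownames(profiles))
  if (length(sigs) == 0) stop("assign_clocklike_ml: no common signatures")
  if (!channel %in% colnames(profiles)) {
    stop(sprintf("assign_clocklike_ml: unknown channel '%s'", channel))
  }
  lik <- exposures[sigs] * profiles[sigs, channel]
  if (all(lik == 0)) return(NA_character_)
  sigs <- sigs[lik == max(lik)]
  sort(sigs)[1]
}

#' SBS1 clonality ratio of a sample
#'
#' Ratio of the clonal proportion among SBS1 mutations to the clonal
#' proportion among all mutations. Requires at least one SBS1 mutation;
#' returns `NA` (sample excluded) otherwise.
#'
#' @param mutations Mutation tibble for one sample.
#' @param cancer_type Passed to the SBS1 rule.
#' @param threshold Subclonal likelihood threshold (default 0.8).
#' @return The clonality ratio, or `NA`.
#' @export
sbs1_clonality_ratio <- function(mutations, cancer_type = "",
                                 threshold = 0.8) {
  if (nrow(mutations) == 0) return(NA_real_)
  clonal <- classify_clonality(mutations$subclonal_likelihood, threshold) == "clonal"
  s1 <- is_sbs1(mutations, cancer_type)
  if (sum(s1) == 0) return(NA_real_)
  overall <- mean(clonal)
  if (overall == 0) return(NA_real_)
  mean(clonal[s1]) / overall
}

#' Correlate primary SBS1 rate with metastatic fold change
#'
#' Per cancer type, the primary SBS1 rate is the mean over primary samples
#' of SBS1 count divided by age at biopsy; this is correlated (Spearman)
#' with the estimated metastatic mean fold change across cancer types.
#'
#' @param rates Tibble with `cancer_type` and `sbs1_per_year` (primary
#'   rate).
#' @param fold_changes Tibble with `cancer_type` and `mean_fold_change`.
#' @param min_types Minimum number of matched cancer types (default 4).
#' @return A list with `rho` and `p_value` (`NA` with a warning when the
#'   correlation is undefined).
#' @export
rate_vs_foldchange <- function(rates, fold_changes, min_types = 4) {
  df <- dplyr::inner_join(rates, fold_changes, by = "cancer_type")
  if (nrow(df) < min_types) {
    stop(sprintf("rate_vs_foldchange: %d matched cancer types, need >= %d",
                 nrow(df), min_types))
  }
  if (sd(df$sbs1_per_year) == 0 || sd(df$mean_fold_change) == 0) {
    warning("rate_vs_foldchange: constant input; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(df)))
  }
  ct <- suppressWarnings(cor.test(df$sbs1_per_year, df$mean_fold_change,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(df))
}

#' Per-cancer-type clock-rate pipeline
#'
#' Convenience driver: per cancer type, computes per-sample SBS1 counts,
#' applies the hypermutator exclusions, fits the primary and metastatic
#' subsampled regressions (optionally on ploidy-corrected counts) and runs
#' the rate comparison.
#'
#' @param mutations,samples Cohort tables.
#' @param config Configuration list (see [default_config()]).
#' @param seed Seed for the subsampled fits.
#' @param ploidy_correct Divide counts by the sample's genome ploidy.
#' @return A tibble, one row per cancer type that could be fitted.
#' @export
clock_rate_analysis <- function(mutations, samples, config = default_config(),
                                seed = 1, ploidy_correct = FALSE) {
  per_sample <- dplyr::summarise(
    dplyr::group_by(mutations, .data$sample_id),
    tmb = dplyr::n(), .groups = "drop")
  rows <- list()
  for (ct in sort(unique(samples$cancer_type))) {
    sub <- samples[samples$cancer_type == ct, , drop = FALSE]
    sbs1 <- vapply(sub$sample_id, function(s) {
      count_sbs1(mutations[mutations$sample_id == s, , drop = FALSE], ct)
    }, numeric(1))
    df <- tibble(sample_id = sub$sample_id, cohort = sub$cohort,
                 age = sub$age_at_biopsy, ploidy = sub$genome_ploidy,
                 sbs1 = sbs1)
    df <- dplyr::left_join(df, per_sample, by = "sample_id")
    df$tmb[is.na(df$tmb)] <- 0
    df <- filter_clock_samples(df, config$tmb_exclude_above,
                               config$sbs1_exclude_above)
    if (ploidy_correct) df$sbs1 <- df$sbs1 / df$ploidy
    pri <- df[df$cohort == "primary", ]
    met <- df[df$cohort == "metastatic", ]
    if (nrow(pri) < config$clock_min_points ||
        nrow(met) < config$clock_min_points) next
    pf <- bootstrap_regression(pri$age, pri$sbs1, config$clock_n_boot,
                               config$clock_subsample_frac, seed = seed,
                               min_points = config$clock_min_points)
    mf <- bootstrap_regression(met$age, met$sbs1, config$clock_n_boot,
                               config$clock_subsample_frac, seed = seed + 1,
                               min_points = config$clock_min_points)
    cmp <- compare_rates(pf, mf, pri$age, pri$sbs1, met$age, met$sbs1,
                         config$clock_r_gate, config$clock_p_threshold,
                         config$fc_age_min, config$fc_age_max,
                         config$fc_literal_divisor)
    rows[[ct]] <- tibble(cancer_type = ct, n_primary = nrow(pri),
                         n_metastatic = nrow(met),
                         slope_primary = pf$slope, slope_metastatic = mf$slope,
                         intercept_primary = pf$intercept,
                         intercept_metastatic = mf$intercept,
                         gate_passed = cmp$gate_passed, mw_p = cmp$mw_p,
                         significant = cmp$significant,
                         mean_fold_change = cmp$mean_fold_change,
                         mean_burden_diff = cmp$mean_burden_diff)
  }
  dplyr::bind_rows(rows)
}
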