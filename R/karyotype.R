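#' Modal (highest-coverage) integer copy number of a chromosome arm
#'
#' Each purity/ploidy-adjusted segment's total copy number is rounded to
#' the nearest integer (half away from zero), coverage of each integer CN
#' is the fraction of arm bases it spans, and the arm-level ploidy is the
#' integer CN with maximal coverage. A coverage tie is broken toward the
#' lower CN by default (conservative against calling gains).
#'
#' @param segments Segment tibble for one sample (columns `chrom`, `start`,
#'   `end`, `cn_total`); coordinates 0-based half-open.
#' @param arm One arm definition row (`chrom`, `arm`, `start`, `end`).
#' @param tie_break `"lower"` or `"higher"`.
#' @return The arm-level integer copy number.
#' @export
arm_modal_ploidy <- function(segments, arm, tie_break = c("lower", "higher")) {
  tie_break <- match.arg(tie_break)
  seg <- segments[segments$chrom == arm$chrom, , drop = FALSE]
  ov_start <- pmax(seg$start, arm$start)
  ov_end <- pmin(seg$end, arm$end)
  w <- ov_end - ov_start
  keep <- w > 0
  if (!any(keep)) {
    stop(sprintf("arm_modal_ploidy: no segment overlaps arm %s%s",
                 arm$chrom, arm$arm))
  }
  cn <- round_half_away(seg$cn_total[keep])
  cov <- tapply(w[keep], cn, sum)
  best <- as.numeric(names(cov)[cov == max(cov)])
  if (tie_break == "lower") min(best) else max(best)
}

#' Expected genome ploidy under whole-genome duplication
#'
#' Without WGD the expected genome ploidy is 2; with WGD it is 4 when the
#' observed genome ploidy is below 6 and 8 when it is 6 or more. Observed
#' ploidies above 8 are rejected.
#'
#' @param wgd Logical, WGD status.
#' @param observed Observed genome ploidy (non-negative integer: the most
#'   recurrent arm-level ploidy across arms).
#' @return 2, 4 or 8.
#' @export
expected_genome_ploidy <- function(wgd, observed) {
  if (any(observed < 0)) stop("expected_genome_ploidy: observed must be >= 0")
  if (any(observed > 8)) stop("expected_genome_ploidy: observed ploidy above 8 is unsupported")
  ifelse(!wgd, 2L, ifelse(observed < 6, 4L, 8L))
}

#' Normalised arm-ploidy class
#'
#' Sign-thresholded difference between arm-level ploidy and the expected
#' genome ploidy: +1 for differences >= 1 (gain), -1 for differences <= -1
#' (loss), 0 otherwise.
#'
#' @param arm_ploidy,expected Non-negative integers (vectorised).
#' @return Integer in \{-1, 0, 1\}.
#' @export
normalized_arm_class <- function(arm_ploidy, expected) {
  if (any(arm_ploidy < 0) || any(expected < 0)) {
    stop("normalized_arm_class: inputs must be >= 0")
  }
  d <- arm_ploidy - expected
  as.integer(ifelse(d >= 1, 1L, ifelse(d <= -1, -1L, 0L)))
}

#' Arm-level karyotype profiles for a cohort
#'
#' For every sample: arm-level modal ploidies over the arm table, the
#' observed genome ploidy (most recurrent arm ploidy; ties broken toward
#' the value nearest the segment-length-weighted mean ploidy), the
#' WGD-normalised expected genome ploidy, and the per-arm gain/loss class.
#'
#' @param segments Segment tibble for the whole cohort.
#' @param samples Sample metadata with `sample_id` and `wgd`.
#' @param arms Arm definitions (default: shipped GRCh37 table).
#' @param tie_break Coverage tie rule for [arm_modal_ploidy()].
#' @return A tibble with one row per sample x arm: `sample_id`,
#'   `arm_label`, `arm_ploidy`, `observed_genome_ploidy`,
#'   `expected_genome_ploidy`, `normalized_class`.
#' @export
arm_ploidy_profiles <- function(segments, samples, arms = arm_definitions(),
                                tie_break = "lower") {
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    ap <- vapply(seq_len(nrow(arms)), function(j) {
      arm_modal_ploidy(seg, arms[j, ], tie_break = tie_break)
    }, numeric(1))
    tab <- table(ap)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    if (length(cand) > 1) {
      wmean <- sum((seg$end - seg$start) * seg$cn_total) / sum(seg$end - seg$start)
      cand <- cand[order(abs(cand - wmean), cand)][1]
    }
    observed <- cand
    expected <- expected_genome_ploidy(samples$wgd[i], observed)
    rows[[i]] <- tibble(
      sample_id = sid,
      arm_label = paste0(arms$chrom, arms$arm),
      arm_ploidy = as.integer(ap),
      observed_genome_ploidy = as.integer(observed),
      expected_genome_ploidy = as.integer(expected),
      normalized_class = normalized_arm_class(ap, expected)
    )
  }
  dplyr::bind_rows(rows)
}

#' Per-arm cohort comparison of normalised arm ploidy
#'
#' Per chromosome arm: two-sided Mann-Whitney on the per-sample gain/loss
#' classes (or raw arm ploidies with `raw_arm_ploidy = TRUE`), metastatic
#' versus primary, BH-corrected across arms; an arm is significant when
#' q is below `q_threshold` and the absolute difference of cohort mean
#' normalised ploidies strictly exceeds `diff_threshold`.
#'
#' @param profiles Output of [arm_ploidy_profiles()].
#' @param samples Sample metadata with `sample_id` and `cohort`.
#' @param q_threshold Adjusted-p threshold (default 0.01).
#' @param diff_threshold Mean-difference threshold (default 0.25, strict).
#' @param raw_arm_ploidy Test raw arm ploidies instead of classes.
#' @return A tibble per arm: means, test results, `significant`.
#' @export
compare_arm_profiles <- function(profiles, samples, q_threshold = 0.01,
                                 diff_threshold = 0.25,
                                 raw_arm_ploidy = FALSE) {
  df <- dplyr::inner_join(profiles, samples[, c("sample_id", "cohort")],
                          by = "sample_id")
  value <- if (raw_arm_ploidy) df$arm_ploidy else df$normalized_class
  df$value <- as.numeric(value)
  rows <- list()
  for (al in unique(df$arm_label)) {
    met <- df$value[df$arm_label == al & df$cohort == "metastatic"]
    pri <- df$value[df$arm_label == al & df$cohort == "primary"]
    if (length(met) == 0 || length(pri) == 0) next
    tr <- mann_whitney_two_sided(met, pri)
    mm <- mean(df$normalized_class[df$arm_label == al & df$cohort == "metastatic"])
    mp <- mean(df$normalized_class[df$arm_label == al & df$cohort == "primary"])
    rows[[al]] <- tibble(arm_label = al, mean_metastatic = mm,
                         mean_primary = mp, mean_diff = mm - mp,
                         statistic = tr$statistic, p_value = tr$p_value)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q_value <- adjust_pvalues(out$p_value, "bh")
  out$significant <- out$q_value < q_threshold & abs(out$mean_diff) > diff_threshold
  out
}

#' Aneuploidy score
#'
#' Number of chromosome arms whose arm-level ploidy deviates from the
#' sample's expected genome ploidy.
#'
#' @param profile One sample's rows from [arm_ploidy_profiles()].
#' @return Integer count of deviating arms.
#' @export
aneuploidy_score <- function(profile) {
  sum(profile$arm_ploidy != profile$expected_genome_ploidy)
}

#' Fraction of the genome under loss of heterozygosity
#'
#' A segment is LOH when its minor allele CN is strictly below
#' `minor_max` (0.25) and its major allele CN is at or above `major_min`
#' (0.8); the LOH fraction is the summed length of LOH segments divided by
#' the genome length.
#'
#' @param segments Segment tibble for one sample.
#' @param genome_len Genome length in bp (default: implied by the shipped
#'   arm table).
#' @param minor_max,major_min LOH thresholds.
#' @return LOH fraction in `[0, 1]`.
#' @export
loh_fraction <- function(segments, genome_len = genome_length(),
                         minor_max = 0.25, major_min = 0.8) {
  if (genome_len <= 0) stop("loh_fraction: genome length must be positive")
  loh <- segments$cn_minor < minor_max & segments$cn_major >= major_min
  sum((segments$end - segments$start)[loh]) / genome_len
}

#' Length-weighted chromosome copy number
#'
#' @param segments Segment tibble for one sample.
#' @param field Copy-number column to average: `"cn_major"` (default; the
#'   major-allele ploidy is what the 1.5 WGD threshold refers to — on
#'   total CN a normal diploid would trivially exceed it) or `"cn_total"`.
#' @return Named numeric vector of length-weighted mean CN per chromosome.
#' @export
chromosome_cn <- function(segments, field = c("cn_major", "cn_total")) {
  field <- match.arg(field)
  w <- segments$end - segments$start
  num <- tapply(w * segments[[field]], segments$chrom, sum)
  den <- tapply(w, segments$chrom, sum)
  cn <- num / den
  cn[order(suppressWarnings(as.numeric(names(cn))), names(cn))]
}

#' Call whole-genome duplication from chromosome copy numbers
#'
#' WGD is present when strictly more than `min_autosomes` (10) autosomes
#' have an estimated chromosome CN strictly above `cn_threshold` (1.5).
#'
#' @param chrom_cn Numeric vector of chromosome-level CN for the 22
#'   autosomes.
#' @param min_autosomes,cn_threshold Decision thresholds.
#' @return Logical.
#' @export
call_wgd <- function(chrom_cn, min_autosomes = 10, cn_threshold = 1.5) {
  if (length(chrom_cn) != 22) {
    stop("call_wgd: expected chromosome CN for the 22 autosomes")
  }
  sum(chrom_cn > cn_threshold) > min_autosomes
}

#' Per-sample genomic-instability indicators
#'
#' The four indicators: aneuploidy score, LOH fraction, WGD call (from
#' chromosome-level CN), and TP53 driver status (any retained driver event
#' in TP53, multiple events counted once).
#'
#' @param profiles Output of [arm_ploidy_profiles()].
#' @param segments Cohort segment tibble.
#' @param drivers Driver-event tibble (may be `NULL`).
#' @param samples Sample metadata.
#' @param genome_len Genome length for the LOH denominator.
#' @param driver_likelihood_min Driver retention threshold (strictly
#'   above; default 0.5).
#' @return A tibble per sample: `aneuploidy_score`, `loh_fraction`, `wgd`,
#'   `tp53_altered`.
#' @export
instability_indicators <- function(profiles, segments, drivers, samples,
                                   genome_len = genome_length(),
                                   driver_likelihood_min = 0.5) {
  ids <- samples$sample_id
  an <- vapply(ids, function(s) {
    aneuploidy_score(profiles[profiles$sample_id == s, , drop = FALSE])
  }, numeric(1), USE.NAMES = FALSE)
  loh <- vapply(ids, function(s) {
    loh_fraction(segments[segments$sample_id == s, , drop = FALSE], genome_len)
  }, numeric(1), USE.NAMES = FALSE)
  wgd <- vapply(ids, function(s) {
    call_wgd(chromosome_cn(segments[segments$sample_id == s, , drop = FALSE]))
  }, logical(1), USE.NAMES = FALSE)
  tp53 <- if (is.null(drivers)) rep(FALSE, length(ids)) else {
    keep <- drivers$gene == "TP53" & drivers$driver_likelihood > driver_likelihood_min
    ids %in% drivers$sample_id[keep]
  }
  tibble(sample_id = ids, aneuploidy_score = as.integer(an),
         loh_fraction = loh, wgd = wgd, tp53_altered = tp53)
}

#' Cohort comparison of the four instability indicators
#'
#' Per cancer type: Mann-Whitney for aneuploidy score and LOH fraction;
#' Fisher's exact test for the WGD and TP53-altered sample fractions
#' (cohort x status tables). P-values are BH-corrected across cancer types
#' separately per indicator; significance requires q below `q_threshold`
#' (default 0.01).
#'
#' @param indicators Output of [instability_indicators()].
#' @param samples Sample metadata (`sample_id`, `cohort`, `cancer_type`).
#' @param q_threshold Adjusted-p threshold.
#' @return A tibble with one row per cancer type x indicator.
#' @export
compare_instability <- function(indicators, samples, q_threshold = 0.01) {
  df <- dplyr::inner_join(indicators,
                          samples[, c("sample_id", "cohort", "cancer_type")],
                          by = "sample_id")
  rows <- list()
  for (ct in sort(unique(df$cancer_type))) {
    sub <- df[df$cancer_type == ct, , drop = FALSE]
    met <- sub[sub$cohort == "metastatic", , drop = FALSE]
    pri <- sub[sub$cohort == "primary", , drop = FALSE]
    if (nrow(met) == 0 || nrow(pri) == 0) next
    for (ind in c("aneuploidy_score", "loh_fraction")) {
      tr <- mann_whitney_two_sided(met[[ind]], pri[[ind]])
      eff <- cliffs_delta(met[[ind]], pri[[ind]])
      rows[[length(rows) + 1]] <- tibble(cancer_type = ct, indicator = ind,
                                         statistic = tr$statistic,
                                         p_value = tr$p_value,
                                         effect_size = eff)
    }
    for (ind in c("wgd", "tp53_altered")) {
      tab <- matrix(c(sum(met[[ind]]), sum(!met[[ind]]),
                      sum(pri[[ind]]), sum(!pri[[ind]])),
                    nrow = 2, byrow = TRUE)
      fr <- fisher_exact_two_sided(tab)
      eff <- suppressWarnings(signed_cramers_v(tab))
      rows[[length(rows) + 1]] <- tibble(cancer_type = ct, indicator = ind,
                                         statistic = fr$odds_ratio,
                                         p_value = fr$p_value,
                                         effect_size = eff)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out <- dplyr::group_by(out, .data$indicator)
  out <- dplyr::mutate(out, q_value = adjust_pvalues(.data$p_value, "bh"))
  out <- dplyr::ungroup(out)
  out$significant <- out$q_value < q_threshold
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$effect_size > 0, "metastatic_enriched",
                                 "primary_enriched"))
  out
}
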