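# Small in-code fixtures shared across test files.

fixture_arm <- function(len = 1000) {
  tibble::tibble(chrom = "5", arm = "p", start = 0, end = len)
}

# Segment set covering 60% / 30% / 10% of a single arm at CN 2 / 1 / 3.
fixture_60_30_10 <- function(sample_id = "S1", len = 1000) {
  tibble::tibble(sample_id = sample_id, chrom = "5",
                 start = c(0, 0.6, 0.9) * len, end = c(0.6, 0.9, 1) * len,
                 cn_total = c(2, 1, 3), cn_minor = c(1, 0.4, 1),
                 cn_major = c(1, 0.6, 2))
}

fixture_mutations <- function(sample_id = "S1", likelihoods,
                              variant_class = "SBS", context = "ACG",
                              ref = "C", alt = "T") {
  n <- length(likelihoods)
  tibble::tibble(sample_id = sample_id, chrom = "1", pos = seq_len(n),
                 ref = ref, alt = alt, variant_class = variant_class,
                 context = ifelse(variant_class == "SBS", context,
                                  NA_character_),
                 subclonal_likelihood = likelihoods)
}

fixture_samples <- function(n_primary, n_metastatic, cancer_type = "Breast") {
  n <- n_primary + n_metastatic
  tibble::tibble(
    sample_id = sprintf("%s_%03d", cancer_type, seq_len(n)),
    patient_id = sprintf("PT_%s_%03d", cancer_type, seq_len(n)),
    cohort = rep(c("primary", "metastatic"), c(n_primary, n_metastatic)),
    cancer_type = cancer_type, cancer_subtype = NA_character_,
    age_at_biopsy = 60, sex = "female", biopsy_site_class = "unknown",
    tumor_purity = 0.8, genome_ploidy = 2, wgd = FALSE, msi = FALSE,
    hrd = FALSE)
}

# Uniform-CN segments for a whole sample across the shipped arm table.
fixture_flat_segments <- function(sample_id, cn_total = 2, cn_minor = NULL,
                                  arms = metprime::arm_definitions()) {
  if (is.null(cn_minor)) cn_minor <- cn_total / 2
  tibble::tibble(sample_id = sample_id, chrom = arms$chrom,
                 start = arms$start, end = arms$end, cn_total = cn_total,
                 cn_minor = cn_minor, cn_major = cn_total - cn_minor)
}
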