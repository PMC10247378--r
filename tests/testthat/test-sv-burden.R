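test_that("SV classification follows the seven-type boundaries", {
  cls <- classify_sv_cluster(
    resolved_type = c("DEL", "DEL", "DUP", "DUP", "COMPLEX", "COMPLEX",
                      "LINE", "DEL", "SGL", "RECIP_TRANS"),
    chrom_start = c("1", "1", "2", "2", "3", "3", "4", "1", "5", "5"),
    chrom_end = c("1", "1", "2", "2", "3", "3", "4", "2", "5", "7"),
    length_bp = c(9999, 10000, 500, 20000, 1e5, 1e5, 3000, 5000, 100, NA),
    n_sv = c(1, 1, 1, 1, 19, 20, 1, 1, 1, 25))
  expect_equal(cls, c("del_small", "del_large", "dup_small", "dup_large",
                      "complex_small", "complex_large", "line",
                      "unclassified", # interchromosomal DEL
                      "unclassified", # unknown token
                      "complex_large"))
})

test_that("counts are total and order-independent with unclassified excluded", {
  set.seed(55)
  samples <- fixture_samples(2, 2)
  n <- 60
  sv <- tibble::tibble(
    sample_id = sample(samples$sample_id, n, replace = TRUE),
    resolved_type = sample(c("DEL", "DUP", "COMPLEX", "LINE", "SGL"), n, TRUE),
    n_sv = sample(1:30, n, TRUE),
    chrom_start = "1", chrom_end = "1",
    length_bp = sample(c(5000, 20000), n, TRUE))
  cnt <- sv_type_counts(sv, samples)
  cls <- classify_sv_cluster(sv$resolved_type, sv$chrom_start, sv$chrom_end,
                             sv$length_bp, sv$n_sv)
  expect_equal(sum(cnt$total) + sum(cls == "unclassified"), n)
  cnt2 <- sv_type_counts(sv[sample(n), ], samples)
  expect_equal(cnt, cnt2)
})

test_that("burden comparison computes enrichment, fold change and gates", {
  # medians 9 vs 0: enrichment 1, fold change 10, '>' flag
  samples <- fixture_samples(11, 11, "T")
  cnt <- tibble::tibble(sample_id = samples$sample_id)
  for (tp in c("del_small", "del_large", "dup_small", "dup_large",
               "complex_small", "complex_large", "line")) cnt[[tp]] <- 0L
  cnt$del_small <- c(rep(0L, 11), rep(9L, 11))
  cnt$total <- cnt$del_small
  out <- compare_sv_burden(cnt, samples)
  hit <- out[out$sv_type == "del_small", ]
  expect_equal(hit$relative_enrichment, 1)
  expect_equal(hit$fold_change, 10)
  expect_true(hit$gt_flag)
  expect_true(hit$significant)
  # identical cohorts: enrichment 0, fold change 1, nothing significant
  same <- out[out$sv_type == "dup_small", ]
  expect_equal(same$fold_change, 1)
  expect_equal(same$relative_enrichment, 0)
  expect_false(same$significant)
  # fold change below 1.2 cannot be significant however small q is
  expect_false(any(out$significant[out$fold_change < 1.2 &
                                     out$fold_change > 0.8]))
  # pseudocount fold change is monotone in the metastatic median
  fc <- vapply(0:10, function(m) (m + 1) / (0 + 1), numeric(1))
  expect_true(all(diff(fc) > 0))
})

test_that("feature matrix encodes treatments, genes and the untreated rule", {
  samples <- fixture_samples(2, 2)
  trt <- tibble::tibble(
    sample_id = c(samples$sample_id[1], samples$sample_id[3],
                  samples$sample_id[3], samples$sample_id[4]),
    drug_name = c("cisplatin", "cisplatin", "paclitaxel", "5-FU"),
    mechanism_group = c("platinum", "platinum", "taxane", "antimetabolite"),
    pre_biopsy = TRUE)
  drv <- tibble::tibble(sample_id = samples$sample_id[c(1, 3)],
                        gene = c("TP53", "TP53"),
                        alteration_type = "mutation",
                        driver_likelihood = c(0.9, 0.4))
  fm <- build_feature_matrix(samples, trt, drv)
  # the primary sample's treatment record is coerced to untreated
  expect_equal(fm$treat_platinum, c(0L, 0L, 1L, 0L))
  expect_equal(fm$n_treatments, c(0L, 0L, 2L, 1L))
  # driver likelihood 0.4 does not count as gene status
  expect_equal(fm$gene_TP53, c(1L, 0L, 0L, 0L))
  kind <- attr(fm, "feature_kind")
  expect_equal(unname(kind[c("genome_ploidy", "n_treatments", "hrd",
                             "gene_TP53")]),
               c("numeric", "numeric", "boolean", "gene"))
})

test_that("three-LM screen recovers effects and rejects confounders", {
  sim <- simulate_sv_lm_cohort(effect_size = 0.3, seed = 8)
  res <- fit_three_lms(sim$burden, sim$features, sim$cohort)
  hit <- res[res$feature == "gene_EFFECT", ]
  expect_true(hit$passed_combined)
  expect_true(hit$passed_cohort_specific)
  expect_gt(hit$coefficient, 0)
  expect_true(hit$explains_met_increase)

  # cohort-confounded null feature passes combined but not cohort-specific
  sim2 <- simulate_sv_lm_cohort(confounded = TRUE, cohort_shift = 0.25,
                                seed = 9)
  res2 <- fit_three_lms(sim2$burden, sim2$features, sim2$cohort)
  conf <- res2[res2$feature == "gene_CONFOUND", ]
  expect_false(conf$explains_met_increase)

  # prevalence filter: a gene feature with 14 TRUE samples is removed
  sim3 <- simulate_sv_lm_cohort(seed = 10)
  f3 <- sim3$features
  f3$gene_RARE <- c(rep(1L, 14), rep(0L, nrow(f3) - 14))
  attr(f3, "feature_kind") <- c(attr(sim3$features, "feature_kind"),
                                gene_RARE = "gene")
  res3 <- fit_three_lms(sim3$burden, f3, sim3$cohort)
  expect_false("gene_RARE" %in% res3$feature)
  expect_error(fit_three_lms(sim3$burden[1:10], f3[1:10, ],
                             sim3$cohort[1:10]), "at least 30")
})

test_that("effect direction uses Cliff's delta or signed Cramer's V", {
  cohort <- rep(c("metastatic", "primary"), each = 10)
  # ploidy uniformly higher in metastatic
  expect_equal(feature_effect_direction(c(rep(4, 10), rep(2, 10)), cohort), 1)
  # boolean with identical prevalence
  expect_equal(feature_effect_direction(rep(c(1, 0), 10), cohort,
                                        numeric_feature = FALSE), 0)
  # the 8/2 vs 2/8 table gives +0.6
  expect_equal(feature_effect_direction(c(rep(1, 8), rep(0, 2),
                                          rep(1, 2), rep(0, 8)), cohort,
                                        numeric_feature = FALSE), 0.6)
})

test_that("the screen only fits models where burden increase is significant", {
  sim <- simulate_sv_lm_cohort(effect_size = 0.3, seed = 12)
  scr <- sv_association_screen(sim$counts, sim$features, sim$samples)
  expect_true(all(scr$associations$sv_type %in%
                    scr$burden_comparison$sv_type[
                      scr$burden_comparison$significant]))
  # with no effect anywhere, the gate almost surely yields no models
  simn <- simulate_sv_lm_cohort(seed = 13)
  scrn <- sv_association_screen(simn$counts, simn$features, simn$samples)
  expect_equal(nrow(scrn$associations), 0)
})
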