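test_that("driver counting filters, de-duplicates and is idempotent", {
  ev <- tibble::tibble(sample_id = "S",
                       gene = c("TP53", "TP53", "KRAS", "EGFR"),
                       alteration_type = c("mutation", "deletion",
                                           "mutation", "mutation"),
                       driver_likelihood = c(0.9, 0.8, 0.5, 0.7))
  # TP53 mutation + deletion count once; KRAS at exactly 0.5 is excluded
  expect_equal(driver_count_per_patient(ev), 2)
  expect_equal(driver_count_per_patient(ev[0, ]), 0)
  expect_equal(driver_count_per_patient(dplyr::bind_rows(ev, ev)),
               driver_count_per_patient(ev))
})

test_that("driver-count comparison detects a cohort shift", {
  set.seed(19)
  samples <- fixture_samples(100, 100)
  mk_events <- function(ids, lambda) {
    dplyr::bind_rows(lapply(ids, function(s) {
      k <- rpois(1, lambda)
      if (k == 0) return(NULL)
      tibble::tibble(sample_id = s, gene = sprintf("G%02d", sample(50, k)),
                     alteration_type = "mutation", driver_likelihood = 0.9)
    }))
  }
  drv <- dplyr::bind_rows(
    mk_events(samples$sample_id[samples$cohort == "primary"], 4.5),
    mk_events(samples$sample_id[samples$cohort == "metastatic"], 6.5))
  out <- compare_driver_counts(drv, samples)
  expect_true(out$significant)
  expect_gt(out$mean_diff, 0)
  # identical cohorts are not significant
  drv0 <- mk_events(samples$sample_id, 5)
  expect_false(any(compare_driver_counts(drv0, samples)$significant))
})

test_that("per-gene enrichment applies the min-5 filter and category folding", {
  samples <- fixture_samples(100, 100)
  met_ids <- samples$sample_id[samples$cohort == "metastatic"]
  pri_ids <- samples$sample_id[samples$cohort == "primary"]
  drv <- dplyr::bind_rows(
    tibble::tibble(sample_id = met_ids[1:30], gene = "GENE_A",
                   alteration_type = "mutation", driver_likelihood = 0.9),
    tibble::tibble(sample_id = pri_ids[1:5], gene = "GENE_A",
                   alteration_type = "mutation", driver_likelihood = 0.9),
    tibble::tibble(sample_id = met_ids[1:4], gene = "GENE_B",
                   alteration_type = "mutation", driver_likelihood = 0.9),
    tibble::tibble(sample_id = pri_ids[1:4], gene = "GENE_B",
                   alteration_type = "mutation", driver_likelihood = 0.9),
    tibble::tibble(sample_id = met_ids[1:8], gene = "GENE_C",
                   alteration_type = "homozygous_disruption",
                   driver_likelihood = 0.9))
  out <- driver_frequency_enrichment(drv, samples)
  a <- out[out$gene == "GENE_A", ]
  expect_equal(a$odds_ratio, (30 * 95) / (70 * 5), tolerance = 1e-12)
  expect_true(a$significant)
  expect_false("GENE_B" %in% out$gene) # below min-5 in both cohorts
  expect_equal(out$category[out$gene == "GENE_C"], "deletion")
})

test_that("treatment groups enforce the >=10 patient gate and multiplicity", {
  samples <- fixture_samples(0, 30, "Colorectum")
  trt <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples$sample_id[1:12],
                   drug_name = c(rep("cisplatin", 6), rep("oxaliplatin", 6)),
                   mechanism_group = "", pre_biopsy = TRUE),
    tibble::tibble(sample_id = samples$sample_id[1:9],
                   drug_name = "paclitaxel", mechanism_group = "",
                   pre_biopsy = TRUE))
  map <- tibble::tibble(drug_name = c("cisplatin", "oxaliplatin",
                                      "paclitaxel"),
                        mechanism_group = c("platinum", "platinum", "taxane"))
  grp <- build_treatment_groups(trt, samples, map)
  expect_equal(nrow(grp), 1) # taxane group has 9 patients -> dropped
  expect_equal(grp$mechanism_group, "platinum")
  expect_equal(grp$n_patients, 12)
  # patients under two mechanisms appear in both groups when both pass
  trt2 <- dplyr::bind_rows(trt[1:12, ],
                           tibble::tibble(sample_id = samples$sample_id[1:10],
                                          drug_name = "paclitaxel",
                                          mechanism_group = "",
                                          pre_biopsy = TRUE))
  grp2 <- build_treatment_groups(trt2, samples, map)
  expect_setequal(grp2$mechanism_group, c("platinum", "taxane"))
  both <- intersect(grp2$patients[[1]], grp2$patients[[2]])
  expect_equal(length(both), 10)
  expect_warning(build_treatment_groups(
    tibble::tibble(sample_id = samples$sample_id[1:10], drug_name = "novel",
                   mechanism_group = "", pre_biopsy = TRUE),
    samples, map), "other")
})

test_that("gene CN status applies the strict amplification/deletion rules", {
  expect_equal(gene_cn_status(5.6, 3.0), "amplified")
  expect_equal(gene_cn_status(5.5, 3.0), "neutral") # exactly +2.5 is not enough
  expect_equal(gene_cn_status(0.29, 3.0), "deleted")
  expect_equal(gene_cn_status(0.30, 3.0), "neutral")
  expect_error(gene_cn_status(-1, 2), ">= 0")
})

test_that("the TED test computes odds ratios, thresholds and labels", {
  cand <- tibble::tibble(element = c("A", "B", "C"), category = "coding",
                         n_treated_mut = c(10, 2, 1),
                         n_treated = 20,
                         n_untreated_mut = c(1, 2, 1),
                         n_untreated = 40)
  out <- ted_test(cand)
  expect_equal(out$odds_ratio[out$element == "A"], (10 * 39) / (10 * 1))
  # exclusivity: 1/40 = 2.5% exclusive; 2/40 = 5% enriched (strict <5%)
  expect_equal(out$label[out$element == "A"], "treatment_exclusive")
  expect_equal(out$label[out$element == "B"], "treatment_enriched")
  # noncoding candidates below 3 mutated treated samples are dropped
  nc <- cand
  nc$category <- "noncoding"
  out2 <- ted_test(nc)
  expect_setequal(out2$element, c("A"))
  # known-resistance annotation is carried through
  out3 <- ted_test(cand, known_resistance = "A")
  expect_true(out3$known_resistance[out3$element == "A"])
  expect_false(any(out3$known_resistance[out3$element != "A"]))
})

test_that("injected odds ratios are detected through the candidate pipeline", {
  sim <- simulate_ted_cohort(odds_ratio = 8, seed = 27)
  cand <- ted_candidates(sim$drivers, sim$treated_ids, sim$untreated_ids)
  out <- ted_test(cand)
  expect_true(out$significant[out$element == sim$target_gene])
  # external candidate lists plug in directly
  cand2 <- ted_candidates(sim$drivers, sim$treated_ids, sim$untreated_ids,
                          external_candidates = c("G001", "G002"))
  expect_setequal(cand2$element, c("G001", "G002"))
})

test_that("CN peak merging unions overlaps and keeps the lowest-q member", {
  peaks <- tibble::tibble(
    cancer_type = "Breast", direction = "amplification",
    start = c(1, 50, 200), end = c(100, 150, 300),
    summit = c(40, 90, 250), gene = c("G1", "G2", "G3"),
    treatment = c("platinum", "taxane", "hormonal"),
    q_value = c(0.01, 0.001, 0.02))
  out <- merge_cn_peaks(peaks)
  expect_equal(nrow(out), 2)
  merged <- out[out$start == 1, ]
  expect_equal(merged$end, 150)
  expect_equal(merged$treatment, "taxane") # q = 0.001 wins
  expect_equal(merged$gene, "G2")
  # amplification and deletion peaks are processed separately
  peaks2 <- dplyr::bind_rows(peaks[1, ],
                             dplyr::mutate(peaks[2, ],
                                           direction = "deletion"))
  expect_equal(nrow(merge_cn_peaks(peaks2)), 2)
})

test_that("TED prioritisation keeps minimum q unless curation pins a pair", {
  res <- tibble::tibble(cancer_type = "Breast", element = "G1",
                        mechanism_group = c("platinum", "taxane"),
                        q_value = c(0.01, 0.001))
  expect_equal(prioritize_teds(res)$mechanism_group, "taxane")
  cur <- tibble::tibble(cancer_type = "Breast", element = "G1",
                        mechanism_group = "platinum")
  expect_equal(prioritize_teds(res, cur)$mechanism_group, "platinum")
  single <- res[1, ]
  expect_equal(prioritize_teds(single), single)
})

test_that("TED exclusion shrinks the cohort driver-count difference", {
  set.seed(33)
  samples <- fixture_samples(50, 50)
  base <- dplyr::bind_rows(lapply(samples$sample_id, function(s) {
    tibble::tibble(sample_id = s, gene = sprintf("BASE%d", sample(5, 2)),
                   alteration_type = "mutation", driver_likelihood = 0.9)
  }))
  ted_drv <- tibble::tibble(
    sample_id = samples$sample_id[samples$cohort == "metastatic"][1:30],
    gene = "RESIST", alteration_type = "mutation", driver_likelihood = 0.9)
  drv <- dplyr::bind_rows(base, ted_drv)
  catalogue <- tibble::tibble(cancer_type = "Breast", element = "RESIST",
                              category = "mutation")
  out <- recount_excluding_teds(drv, samples, catalogue)
  gap_before <- diff(range(out$mean_drivers_before))
  met <- out[out$cohort == "metastatic", ]
  pri <- out[out$cohort == "primary", ]
  expect_lt(met$mean_drivers_after - pri$mean_drivers_after,
            met$mean_drivers_before - pri$mean_drivers_before)
  # empty catalogue leaves counts unchanged
  out0 <- recount_excluding_teds(drv, samples, catalogue[0, ])
  expect_equal(out0$mean_drivers_after, out0$mean_drivers_before)
})
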