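test_that("arm modal ploidy follows the highest-coverage rule", {
  expect_equal(arm_modal_ploidy(fixture_60_30_10(), fixture_arm()), 2)
  seg <- tibble::tibble(sample_id = "S", chrom = "5", start = 0, end = 1000,
                        cn_total = 3.4, cn_minor = 1, cn_major = 2.4)
  expect_equal(arm_modal_ploidy(seg, fixture_arm()), 3)
  # 50/50 coverage tie breaks to the lower CN (configurable)
  seg <- tibble::tibble(sample_id = "S", chrom = "5",
                        start = c(0, 500), end = c(500, 1000),
                        cn_total = c(2, 3), cn_minor = 1, cn_major = 1.5)
  expect_equal(arm_modal_ploidy(seg, fixture_arm()), 2)
  expect_equal(arm_modal_ploidy(seg, fixture_arm(), tie_break = "higher"), 3)
  # rounding is half-away-from-zero: 2.5 -> 3
  seg$cn_total <- c(2.5, 1)
  expect_equal(arm_modal_ploidy(seg, fixture_arm(), tie_break = "lower"), 1)
  seg2 <- seg[1, ]
  expect_equal(arm_modal_ploidy(seg2, fixture_arm()), 3)
  expect_error(arm_modal_ploidy(seg[0, ], fixture_arm()), "no segment overlaps")
})

test_that("expected genome ploidy implements the 2/4/8 rule", {
  expect_equal(expected_genome_ploidy(FALSE, 3), 2)
  expect_equal(expected_genome_ploidy(TRUE, 5), 4)
  expect_equal(expected_genome_ploidy(TRUE, 6), 8)
  expect_error(expected_genome_ploidy(TRUE, 9), "above 8")
})

test_that("normalised arm class thresholds at +/-1", {
  expect_equal(normalized_arm_class(c(3, 2, 1), c(2, 2, 4)), c(1L, 0L, -1L))
})

test_that("WGD normalisation leaves arm classes invariant", {
  set.seed(5)
  arms <- arm_definitions()
  for (i in 1:100) {
    # random profile around diploid with scattered gains/losses
    seg <- fixture_flat_segments("S", cn_total = 2)
    shift <- sample(c(-1, 0, 1), nrow(seg), replace = TRUE,
                    prob = c(0.15, 0.7, 0.15))
    seg$cn_total <- pmax(0, seg$cn_total + shift)
    seg$cn_minor <- seg$cn_total / 2
    seg$cn_major <- seg$cn_total - seg$cn_minor
    smp <- fixture_samples(1, 0)[1, ]
    smp$sample_id <- "S"; smp$wgd <- FALSE
    p1 <- arm_ploidy_profiles(seg, smp, arms)
    seg2 <- seg; seg2$cn_total <- 2 * seg$cn_total
    seg2$cn_minor <- seg2$cn_total / 2
    seg2$cn_major <- seg2$cn_total - seg2$cn_minor
    smp2 <- smp; smp2$wgd <- TRUE
    p2 <- arm_ploidy_profiles(seg2, smp2, arms)
    expect_equal(p2$normalized_class, p1$normalized_class)
  }
})

test_that("aneuploidy score counts deviating arms", {
  smp <- fixture_samples(1, 0)[1, ]; smp$sample_id <- "S"
  seg <- fixture_flat_segments("S", cn_total = 2)
  prof <- arm_ploidy_profiles(seg, smp)
  expect_equal(aneuploidy_score(prof), 0)
  # 5 gains and 3 losses on whole arms -> score 8
  arms <- arm_definitions()
  idx_gain <- 1:5; idx_loss <- 6:8
  seg2 <- seg
  for (i in idx_gain) {
    hit <- seg2$chrom == arms$chrom[i] & seg2$start == arms$start[i]
    seg2$cn_total[hit] <- 3
  }
  for (i in idx_loss) {
    hit <- seg2$chrom == arms$chrom[i] & seg2$start == arms$start[i]
    seg2$cn_total[hit] <- 1
  }
  seg2$cn_minor <- seg2$cn_total / 2
  seg2$cn_major <- seg2$cn_total - seg2$cn_minor
  prof2 <- arm_ploidy_profiles(seg2, smp)
  expect_equal(aneuploidy_score(prof2), 8)
  # identity: score equals sum over arms of |sign(arm - expected)|
  expect_equal(aneuploidy_score(prof2),
               sum(abs(sign(prof2$arm_ploidy - prof2$expected_genome_ploidy))))
})

test_that("LOH fraction respects both allele thresholds and segment splits", {
  gl <- 1000
  seg <- tibble::tibble(sample_id = "S", chrom = "1", start = 0, end = 100,
                        cn_total = 1.1, cn_minor = 0.1, cn_major = 1.0)
  expect_equal(loh_fraction(seg, gl), 0.1)
  seg$cn_minor <- 0.25 # boundary: not LOH
  expect_equal(loh_fraction(seg, gl), 0)
  seg$cn_minor <- 0.1; seg$cn_major <- 0.79 # major below floor
  expect_equal(loh_fraction(seg, gl), 0)
  seg$cn_major <- 0.8 # inclusive boundary
  expect_equal(loh_fraction(seg, gl), 0.1)
  # splitting a segment into abutting halves changes nothing
  split <- dplyr::bind_rows(seg, seg)
  split$start <- c(0, 50); split$end <- c(50, 100)
  expect_equal(loh_fraction(split, gl), loh_fraction(seg, gl))
})

test_that("WGD calling uses the strict >10 autosome rule", {
  expect_true(call_wgd(c(rep(1.6, 11), rep(1.0, 11))))
  expect_false(call_wgd(c(rep(1.6, 10), rep(1.0, 12))))
  expect_false(call_wgd(rep(1.0, 22)))
  expect_error(call_wgd(rep(2, 21)), "22 autosomes")
})

test_that("per-arm comparison applies the q and mean-difference gates", {
  set.seed(61)
  arms <- arm_definitions()
  n <- 80
  samples <- fixture_samples(n, n)
  seg <- list()
  for (i in seq_len(2 * n)) {
    s <- fixture_flat_segments(samples$sample_id[i], cn_total = 2)
    # 5q loss with probability 0.6 metastatic vs 0.1 primary
    p <- if (samples$cohort[i] == "metastatic") 0.6 else 0.1
    if (runif(1) < p) {
      hit <- s$chrom == "5" & s$start == arms$start[arms$chrom == "5" &
                                                      arms$arm == "q"]
      s$cn_total[hit] <- 1
    }
    s$cn_minor <- s$cn_total / 2
    s$cn_major <- s$cn_total - s$cn_minor
    seg[[i]] <- s
  }
  prof <- arm_ploidy_profiles(dplyr::bind_rows(seg), samples)
  cmp <- compare_arm_profiles(prof, samples)
  expect_true(cmp$significant[cmp$arm_label == "5q"])
  expect_false(any(cmp$significant[cmp$arm_label != "5q"]))
  # a mean difference of exactly 0.25 is not significant (strict rule)
  cmp$mean_diff[cmp$arm_label == "5q"] <- -0.25
  gate <- cmp$q_value < 0.01 & abs(cmp$mean_diff) > 0.25
  expect_false(gate[cmp$arm_label == "5q"])
})

test_that("instability comparison agrees with its primitive tests", {
  set.seed(71)
  n <- 40
  samples <- fixture_samples(n, n)
  samples$wgd <- c(runif(n) < 0.2, runif(n) < 0.6)
  seg <- dplyr::bind_rows(lapply(seq_len(2 * n), function(i) {
    cn <- if (samples$wgd[i]) 4 else 2
    fixture_flat_segments(samples$sample_id[i], cn_total = cn,
                          cn_minor = cn / 2)
  }))
  drivers <- tibble::tibble(
    sample_id = samples$sample_id[c(rep(FALSE, n), runif(n) < 0.5)],
    gene = "TP53", alteration_type = "mutation", driver_likelihood = 0.9)
  prof <- arm_ploidy_profiles(seg, samples)
  ind <- instability_indicators(prof, seg, drivers, samples)
  expect_equal(ind$wgd, samples$wgd) # major-allele CN recovers the flag
  cmp <- compare_instability(ind, samples)
  # the TP53 Fisher table matches a direct computation
  tp <- cmp[cmp$indicator == "tp53_altered", ]
  tab <- matrix(c(sum(ind$tp53_altered[samples$cohort == "metastatic"]),
                  sum(!ind$tp53_altered[samples$cohort == "metastatic"]),
                  sum(ind$tp53_altered[samples$cohort == "primary"]),
                  sum(!ind$tp53_altered[samples$cohort == "primary"])),
                2, byrow = TRUE)
  expect_equal(tp$p_value, fisher_exact_two_sided(tab)$p_value)
  expect_equal(tp$p_value, oracle_fisher(tab), tolerance = 1e-12)
  # WGD 60% vs 20% at n=40/arm is significant
  expect_true(cmp$significant[cmp$indicator == "wgd"])
})
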