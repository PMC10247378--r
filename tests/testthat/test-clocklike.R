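test_that("SBS1 counting uses the NpCpG rule with its exclusions", {
  m <- fixture_mutations("S", rep(0.1, 4), context = "ACG")
  m$context <- c("ACG", "TCG", "CCG", "GCG")
  expect_equal(count_sbs1(m, "Breast"), 3)        # TCG always excluded
  expect_equal(count_sbs1(m, "Skin melanoma"), 2) # CCG also excluded
  # non-C>T or non-SBS records never count
  m2 <- m
  m2$alt <- "G"
  expect_equal(count_sbs1(m2, "Breast"), 0)
  m3 <- m
  m3$variant_class <- "ID"
  expect_equal(count_sbs1(m3, "Breast"), 0)
})

test_that("hypermutator exclusions are strict-greater on both criteria", {
  df <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                       tmb = c(30001, 30000, 100, 100),
                       sbs1 = c(10, 5000, 5001, 10))
  out <- filter_clock_samples(df)
  expect_setequal(out$sample_id, c("b", "d"))
})

test_that("subsampled regression is exact on collinear data and deterministic", {
  age <- seq(30, 79, length.out = 50)
  y <- 3 * age + 10
  f <- bootstrap_regression(age, y, seed = 99)
  expect_equal(f$slope, 3, tolerance = 1e-9)
  expect_equal(f$intercept, 10, tolerance = 1e-9)
  expect_equal(f$slope_lo, f$slope_hi, tolerance = 1e-9) # zero-width CI
  expect_equal(predict(f, 50), 160, tolerance = 1e-7)
  # determinism and seed sensitivity on noisy data
  set.seed(1); yn <- y + rnorm(50, 0, 30)
  f1 <- bootstrap_regression(age, yn, seed = 5)
  f2 <- bootstrap_regression(age, yn, seed = 5)
  f3 <- bootstrap_regression(age, yn, seed = 6)
  expect_identical(f1, f2)
  expect_false(isTRUE(all.equal(f1$slope, f3$slope)))
  expect_error(bootstrap_regression(1:10, 1:10), "at least 20")
})

test_that("subsampled regression recovers a known slope", {
  hits <- vapply(1:10, function(s) {
    d <- simulate_clock_cohort(n_primary = 200, n_metastatic = 0,
                               fold_change = 1, slope = 4, intercept = 50,
                               noise_sd = 30, seed = s)
    f <- bootstrap_regression(d$age, d$sbs1, seed = s)
    f$slope
  }, numeric(1))
  expect_true(all(hits > 3.6 & hits < 4.4))
})

test_that("fold change and burden difference follow the printed equations", {
  lin <- function(s, i) structure(list(slope = s, intercept = i),
                                  class = "clock_fit")
  # constant ratio 2 -> 2.0 with the true-mean divisor, 2.05 literal
  expect_equal(mean_fold_change(lin(4, 0), lin(2, 0)), 2)
  expect_equal(mean_fold_change(lin(4, 0), lin(2, 0), literal_divisor = TRUE),
               2 * 41 / 40)
  expect_equal(mean_fold_change(lin(3, 7), lin(3, 7)), 1)
  # P: y=2a, M: y=2a+40 -> mean of (2a+40)/(2a) over 40..80
  want <- mean((2 * (40:80) + 40) / (2 * (40:80)))
  expect_equal(mean_fold_change(lin(2, 40), lin(2, 0)), want)
  expect_equal(round(want, 4), 1.3473)
  expect_equal(mean_burden_diff(lin(2, 40), lin(2, 0)), 40)
  expect_equal(mean_burden_diff(lin(3, 0), lin(3, 0)), 0)
  # P: y=2a, M: y=3a -> mean of a over 40..80 = 60
  expect_equal(mean_burden_diff(lin(3, 0), lin(2, 0)), 60)
  expect_error(mean_fold_change(lin(2, 0), lin(-2, 0)), "non-positive")
  # scale invariance / scaling
  expect_equal(mean_fold_change(lin(8, 20), lin(4, 10)),
               mean_fold_change(lin(2, 5), lin(1, 2.5)))
  expect_equal(mean_burden_diff(lin(8, 20), lin(4, 10)),
               4 * mean_burden_diff(lin(2, 5), lin(1, 2.5)))
})

test_that("rate comparison gates on Pearson r and intercept ordering", {
  d <- simulate_clock_cohort(fold_change = 1.5, seed = 17)
  pri <- d[d$cohort == "primary", ]; met <- d[d$cohort == "metastatic", ]
  pf <- bootstrap_regression(pri$age, pri$sbs1, seed = 1)
  mf <- bootstrap_regression(met$age, met$sbs1, seed = 2)
  cmp <- compare_rates(pf, mf, pri$age, pri$sbs1, met$age, met$sbs1)
  expect_true(cmp$gate_passed)
  expect_true(cmp$significant)
  expect_equal(cmp$mean_fold_change, 1.5, tolerance = 0.1)
  # an r at or below the gate blocks significance regardless of shift
  pf_low <- pf; pf_low$pearson_r <- 0.05
  cmp2 <- compare_rates(pf_low, mf, pri$age, pri$sbs1, met$age, met$sbs1)
  expect_false(cmp2$gate_passed)
  expect_false(cmp2$significant)
})

test_that("ploidy correction commutes with regression", {
  d <- simulate_clock_cohort(n_primary = 100, n_metastatic = 0, seed = 23)
  ploidy <- 2.7
  f1 <- bootstrap_regression(d$age, d$sbs1 / ploidy, seed = 4)
  f2 <- bootstrap_regression(d$age, d$sbs1, seed = 4)
  expect_equal(f1$slope, f2$slope / ploidy, tolerance = 1e-9)
  expect_equal(f1$intercept, f2$intercept / ploidy, tolerance = 1e-9)
})

test_that("maximum-likelihood assignment picks exposure x probability", {
  prof <- rbind(SBS1 = c(0.01, 0.99), SBS5 = c(0.02, 0.98))
  colnames(prof) <- c("A[C>T]G", "T[C>T]A")
  expos <- c(SBS5 = 100, SBS1 = 300)
  expect_equal(assign_clocklike_ml("A[C>T]G", expos, prof), "SBS1") # 3 > 2
  expect_equal(assign_clocklike_ml("A[C>T]G", c(SBS5 = 100, SBS1 = 0), prof),
               "SBS5")
  # zero-probability channel loses even with equal exposure
  prof2 <- rbind(A = c(0, 1), B = c(0.5, 0.5))
  colnames(prof2) <- c("ch1", "ch2")
  expect_equal(assign_clocklike_ml("ch1", c(A = 10, B = 10), prof2), "B")
  # ties break lexicographically; all-zero is unassigned
  expect_equal(assign_clocklike_ml("ch2", c(B = 10, A = 5), prof2), "A")
  expect_true(is.na(assign_clocklike_ml("ch1", c(A = 0, B = 0), prof2)))
})

test_that("SBS1 clonality ratio follows its definition", {
  # 10 SBS1 (6 clonal), 10 other (clonal), overall clonal 16/20 = 0.8
  m <- dplyr::bind_rows(
    fixture_mutations("S", c(rep(0.1, 6), rep(0.9, 4)), context = "ACG"),
    fixture_mutations("S", rep(0.1, 10), context = "ACA", alt = "G"))
  expect_equal(sbs1_clonality_ratio(m), (6 / 10) / (16 / 20))
  # equal proportions give 1
  m2 <- dplyr::bind_rows(
    fixture_mutations("S", c(0.1, 0.9), context = "ACG"),
    fixture_mutations("S", c(0.1, 0.9), context = "ACA", alt = "G"))
  expect_equal(sbs1_clonality_ratio(m2), 1)
  # no SBS1 mutations -> NA (excluded)
  m3 <- fixture_mutations("S", rep(0.1, 5), context = "ACA", alt = "G")
  expect_true(is.na(sbs1_clonality_ratio(m3)))
})

test_that("rate-versus-fold-change correlation handles the degenerate case", {
  rates <- tibble::tibble(cancer_type = letters[1:5],
                          sbs1_per_year = c(5, 4, 3, 2, 1))
  fcs <- tibble::tibble(cancer_type = letters[1:5],
                        mean_fold_change = c(1.1, 1.2, 1.3, 1.4, 1.5))
  out <- rate_vs_foldchange(rates, fcs)
  expect_equal(out$rho, -1)
  fcs$mean_fold_change <- 1.2
  expect_warning(out2 <- rate_vs_foldchange(rates, fcs), "constant")
  expect_true(is.na(out2$rho))
  expect_error(rate_vs_foldchange(rates[1:3, ], fcs[1:3, ]), "need >= 4")
  # random pairing has small average |rho|
  set.seed(15)
  rhos <- replicate(100, {
    r <- tibble::tibble(cancer_type = letters[1:8], sbs1_per_year = rnorm(8))
    f <- tibble::tibble(cancer_type = letters[1:8],
                        mean_fold_change = rnorm(8))
    rate_vs_foldchange(r, f)$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
})
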