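test_that("channel builders produce the canonical channel counts", {
  expect_length(sbs_channels(), 96)
  expect_length(dbs_channels(), 78)
  expect_length(id_channels(), 83)
  expect_false(anyDuplicated(sbs_channels()) > 0)
  expect_false(anyDuplicated(dbs_channels()) > 0)
  expect_false(anyDuplicated(id_channels()) > 0)
  # every shipped synthetic profile is a probability vector
  cat <- synthetic_reference_catalog()
  sums <- tapply(cat$prob, cat$name, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("reference matching applies the 0.85 floor and the argmax", {
  ref <- synthetic_reference_catalog()
  denovo <- ref[ref$name == "synSBS.apobec", ]
  denovo$name <- "denovo_1"
  m <- match_to_reference(denovo, ref)
  expect_equal(m$matched_reference, "synSBS.apobec")
  expect_equal(m$similarity, 1)
  # perturb just below the floor: construct a profile at similarity < 0.85
  far <- denovo
  far$prob <- rep(1 / 96, 96)
  far$name <- "denovo_flat"
  sims <- vapply(unique(ref$name[ref$mutation_type == "SBS"]), function(r) {
    cosine_similarity(far$prob, ref$prob[ref$name == r])
  }, numeric(1))
  m2 <- match_to_reference(far, ref)
  if (max(sims) < 0.85) {
    expect_true(is.na(m2$matched_reference))
    expect_equal(m2$provenance, "unassigned")
  }
  # argmax between two candidates
  two_ref <- ref[ref$name %in% c("synSBS.apobec", "synSBS.uv"), ]
  mix <- denovo
  mix$prob <- 0.9 * ref$prob[ref$name == "synSBS.apobec"] +
    0.1 * ref$prob[ref$name == "synSBS.uv"]
  mix$prob <- mix$prob / sum(mix$prob)
  m3 <- match_to_reference(mix, two_ref)
  expect_equal(m3$matched_reference, "synSBS.apobec")
})

test_that("clustering recovers tight groups and is order-invariant", {
  set.seed(91)
  ref <- synthetic_reference_catalog()
  centers <- c("synSBS.apobec", "synSBS.uv", "synSBS.platinum")
  prof <- list()
  for (cn in centers) {
    base <- ref$prob[ref$name == cn]
    for (j in 1:4) {
      p <- base + runif(96, 0, 0.002) # tight perturbation
      p <- p / sum(p)
      prof[[paste(cn, j)]] <- tibble::tibble(
        name = paste0(cn, "_pert", j), mutation_type = "SBS",
        channel = sbs_channels(), prob = p)
    }
  }
  prof <- dplyr::bind_rows(prof)
  labs <- cluster_unmatched(prof)
  expect_equal(length(unique(labs)), 3)
  truth <- rep(seq_along(centers), each = 4)
  # same partition as the ground truth (up to relabelling)
  expect_equal(length(unique(paste(labs, truth))), 3)
  # permutation of input order gives the same partition
  perm <- sample(nrow(prof) / 96 * 96)
  prof_perm <- dplyr::bind_rows(split(prof, prof$name)[unique(prof$name)[sample(12)]])
  labs2 <- cluster_unmatched(prof_perm)
  labs2 <- labs2[names(labs)]
  expect_equal(length(unique(paste(labs, labs2))), 3)
  # two profiles: singleton clusters
  expect_equal(unname(cluster_unmatched(prof[prof$name %in%
    unique(prof$name)[1:2], ])), c(1L, 2L))
  # identical profiles: fall back to one cluster with a warning
  same <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(name = paste0("dup", i), mutation_type = "SBS",
                   channel = sbs_channels(), prob = 1 / 96)
  }))
  expect_warning(l1 <- cluster_unmatched(same), "identical")
  expect_equal(unique(l1), 1L)
})

test_that("aetiology aggregation sums exactly and rejects unmapped input", {
  exp <- tibble::tibble(sample_id = "S1",
                        signature = c("SBS2", "SBS13", "SBS5"),
                        mutation_type = "SBS",
                        exposure = c(100, 50, 300))
  map <- tibble::tibble(signature = c("SBS2", "SBS13", "SBS5"),
                        aetiology = c("APOBEC", "APOBEC", "clock-like"))
  out <- aggregate_aetiology(exp, map)
  expect_equal(out$contribution[out$aetiology == "APOBEC"], 150)
  expect_equal(out$contribution[out$aetiology == "clock-like"], 300)
  expect_error(aggregate_aetiology(exp, map[1:2, ]), "unmapped")
  # aggregation then comparison equals comparison on pre-summed data
  samples <- fixture_samples(1, 1)
  exp2 <- tidyr::expand_grid(sample_id = samples$sample_id,
                             signature = c("SBS2", "SBS13"))
  exp2$mutation_type <- "SBS"
  exp2$exposure <- c(10, 20, 30, 40)
  agg <- aggregate_aetiology(exp2, map)
  expect_equal(agg$contribution, c(30, 70))
})

test_that("absolute comparison applies the pseudocount log2fc rule", {
  sim <- simulate_exposure_cohort(n_per_cohort = 40, log2fc = 1,
                                  cancer_types = "TypeA", seed = 3)
  out <- compare_absolute(sim$contrib, sim$samples)
  hit <- out[out$aetiology == "aetiology_01", ]
  expect_true(hit$significant)
  expect_gt(hit$log2fc, 0.4)
  expect_equal(hit$direction, "metastatic_enriched")
  # frozen arithmetic: medians 139 vs 69 give log2(140/70) = 1
  expect_equal(log2((139 + 1) / (69 + 1)), 1)
  # |log2fc| below 0.4 is not significant regardless of q
  expect_false(any(out$significant[abs(out$log2fc) < 0.4]))
})

test_that("relative comparison bounds values and applies the 0.01 gate", {
  sim <- simulate_exposure_cohort(n_per_cohort = 40, log2fc = 1.5,
                                  cancer_types = "TypeA", seed = 4)
  out <- compare_relative(sim$contrib, sim$samples)
  expect_true(all(abs(out$median_diff) <= 1))
  expect_true(out$significant[out$aetiology == "aetiology_01"])
  expect_false(any(out$significant[abs(out$median_diff) < 0.01]))
  # identical cohorts: no hits
  null <- simulate_exposure_cohort(n_per_cohort = 40, log2fc = 0, seed = 5)
  expect_false(any(compare_relative(null$contrib, null$samples)$significant))
})

test_that("hypermutator flags use per-type thresholds and the >=5 gate", {
  samples <- fixture_samples(10, 10, "T")
  mk <- function(values, mt) {
    tibble::tibble(sample_id = samples$sample_id, mutation_type = mt,
                   aetiology = paste0("ae_", mt), contribution = values)
  }
  # SBS: exactly at 10,000 counts as hypermutator; 9,999 does not
  contrib <- mk(c(rep(9999, 10), rep(10000, 10)), "SBS")
  out <- hypermutator_enrichment(contrib, samples)
  expect_equal(out$n_hyper_metastatic, 10)
  expect_equal(out$n_hyper_primary, 0)
  # DBS 499 is below the 500 threshold -> no test is run (0 hypermutators)
  out2 <- hypermutator_enrichment(mk(rep(499, 20), "DBS"), samples)
  expect_equal(nrow(out2), 0)
  # 4 hypermutators in both cohorts -> below the gate, skipped
  contrib3 <- mk(c(rep(10000, 4), rep(0, 6), rep(10000, 4), rep(0, 6)), "SBS")
  expect_equal(nrow(hypermutator_enrichment(contrib3, samples)), 0)
  # 5 in one cohort -> tested
  contrib4 <- mk(c(rep(0, 10), rep(10000, 5), rep(0, 5)), "SBS")
  expect_equal(nrow(hypermutator_enrichment(contrib4, samples)), 1)
})
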