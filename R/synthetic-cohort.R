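#' Simulation configuration
#'
#' Assembles (and validates) the configuration of the synthetic two-cohort
#' generator. Defaults emulate the statistical structure of a
#' primary-versus-metastatic pan-cancer comparison: metastatic tumours are
#' more clonal, carry more whole-genome duplications and arm events, have
#' a moderately accelerated SBS1 clock, a therapy-associated mutagenic
#' exposure (platinum) and therapy-enriched resistance drivers. Every
#' injected effect is recorded as ground truth by [simulate_cohort()].
#'
#' @param seed Integer master seed; per-sample streams are derived from it
#'   by hashing the sample id, so adding samples never perturbs existing
#'   ones.
#' @param cancer_types Tibble with `cancer_type`, `n_primary`,
#'   `n_metastatic`.
#' @param age_mean,age_sd,age_min,age_max Age-at-biopsy distribution
#'   (normal, truncated), in years.
#' @param clonal_fraction_primary,clonal_fraction_metastatic,clonal_fraction_kappa
#'   Cohort mean clonal fractions and the beta concentration around them.
#' @param sbs1_slope,sbs1_intercept,sbs1_noise_sd,sbs1_fold_change_metastatic
#'   Clock-mutation model: expected SBS1 count is
#'   `slope * age * fold_change + intercept` (fold change 1 in primaries)
#'   with additive Gaussian noise.
#' @param signature_exposures Tibble with `signature`, `mean_primary`,
#'   `mean_metastatic`, `dispersion` (gamma shape); signatures must exist
#'   in `reference`.
#' @param reference Long profile tibble of signature profiles (default
#'   [synthetic_reference_catalog()]).
#' @param arm_gain_prob,arm_loss_prob,loh_arm_prob,wgd_prob Named vectors
#'   (`primary`, `metastatic`) of per-arm and per-sample event
#'   probabilities.
#' @param sv_burden Tibble with `sv_type`, `log10_mu_primary`,
#'   `log10_mu_metastatic`, `dispersion`: expected count per type is
#'   `10^(log10_mu + features %*% effects) - 1`, drawn negative-binomially.
#' @param sv_feature_effects Optional tibble (`sv_type`, `feature`,
#'   `coefficient`) of log10-scale feature effects on SV burden.
#' @param driver_genes Tibble with `gene`, `freq_primary`,
#'   `freq_metastatic` (per-sample driver probabilities).
#' @param treatments Tibble with `mechanism_group`, `drug_name`, `prob`:
#'   probability that a metastatic sample received the mechanism
#'   (primaries are untreated).
#' @param ted_effects Optional tibble (`gene`, `mechanism_group`,
#'   `odds_ratio`): for treated samples the gene's baseline odds are
#'   multiplied by the odds ratio.
#' @param msi_prob,hrd_prob Per-sample probabilities.
#' @param biopsy_site_probs Named probabilities (`local`, `lymph`,
#'   `distant`) for metastatic biopsy sites.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    cancer_types = tibble(cancer_type = c("Breast", "Colorectum", "Prostate"),
                          n_primary = 40L, n_metastatic = 40L),
    age_mean = 61, age_sd = 12, age_min = 25, age_max = 95,
    clonal_fraction_primary = 0.87, clonal_fraction_metastatic = 0.93,
    clonal_fraction_kappa = 60,
    sbs1_slope = 4, sbs1_intercept = 0, sbs1_noise_sd = 30,
    sbs1_fold_change_metastatic = 1.5,
    signature_exposures = tibble(
      signature = c("synSBS.flat.clock", "synSBS.apobec", "synSBS.platinum",
                    "synDBS.platinum", "synDBS.flat", "synID.slippage",
                    "synID.flat"),
      mean_primary = c(1200, 250, 0, 0, 25, 70, 50),
      mean_metastatic = c(1200, 500, 250, 50, 25, 70, 50),
      dispersion = 4),
    reference = synthetic_reference_catalog(),
    arm_gain_prob = c(primary = 0.06, metastatic = 0.10),
    arm_loss_prob = c(primary = 0.06, metastatic = 0.10),
    loh_arm_prob = c(primary = 0.08, metastatic = 0.15),
    wgd_prob = c(primary = 0.25, metastatic = 0.50),
    sv_burden = tibble(
      sv_type = c("del_small", "del_large", "dup_small", "dup_large",
                  "complex_small", "complex_large", "line"),
      log10_mu_primary = c(1.0, 0.8, 0.7, 0.6, 0.8, 0.3, 0.5),
      log10_mu_metastatic = c(1.3, 1.0, 0.9, 0.9, 1.1, 0.5, 0.7),
      dispersion = 6),
    sv_feature_effects = NULL,
    driver_genes = tibble(
      gene = c("TP53", "KRAS", "PIK3CA", "APC", "PTEN", "RB1", "EGFR", "AR"),
      freq_primary = c(0.35, 0.20, 0.18, 0.15, 0.08, 0.06, 0.06, 0.02),
      freq_metastatic = c(0.55, 0.25, 0.20, 0.15, 0.12, 0.10, 0.08, 0.06)),
    treatments = tibble(
      mechanism_group = c("platinum", "pyrimidine_antagonist", "taxane",
                          "hormonal"),
      drug_name = c("cisplatin", "5-FU", "paclitaxel", "enzalutamide"),
      prob = c(0.35, 0.30, 0.25, 0.20)),
    ted_effects = tibble(gene = "AR", mechanism_group = "hormonal",
                         odds_ratio = 8),
    msi_prob = 0.03, hrd_prob = 0.08,
    biopsy_site_probs = c(local = 0.3, lymph = 0.3, distant = 0.4)) {
  cfg <- list(seed = as.integer(seed), cancer_types = cancer_types,
              age_mean = age_mean, age_sd = age_sd, age_min = age_min,
              age_max = age_max,
              clonal_fraction_primary = clonal_fraction_primary,
              clonal_fraction_metastatic = clonal_fraction_metastatic,
              clonal_fraction_kappa = clonal_fraction_kappa,
              sbs1_slope = sbs1_slope, sbs1_intercept = sbs1_intercept,
              sbs1_noise_sd = sbs1_noise_sd,
              sbs1_fold_change_metastatic = sbs1_fold_change_metastatic,
              signature_exposures = signature_exposures,
              reference = reference,
              arm_gain_prob = arm_gain_prob, arm_loss_prob = arm_loss_prob,
              loh_arm_prob = loh_arm_prob, wgd_prob = wgd_prob,
              sv_burden = sv_burden,
              sv_feature_effects = sv_feature_effects,
              driver_genes = driver_genes, treatments = treatments,
              ted_effects = ted_effects, msi_prob = msi_prob,
              hrd_prob = hrd_prob, biopsy_site_probs = biopsy_site_probs)
  probs <- c(cfg$arm_gain_prob, cfg$arm_loss_prob, cfg$loh_arm_prob,
             cfg$wgd_prob, cfg$msi_prob, cfg$hrd_prob,
             cfg$biopsy_site_probs, cfg$treatments$prob,
             cfg$driver_genes$freq_primary, cfg$driver_genes$freq_metastatic)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: all probabilities must lie in [0, 1]")
  }
  if (any(cfg$cancer_types$n_primary < 0) ||
      any(cfg$cancer_types$n_metastatic < 0)) {
    stop("sim_config: cohort sizes must be >= 0")
  }
  if (!is.null(cfg$ted_effects) && any(cfg$ted_effects$odds_ratio <= 0)) {
    stop("sim_config: ted odds ratios must be > 0")
  }
  miss <- setdiff(cfg$signature_exposures$signature, unique(reference$name))
  if (length(miss) > 0) {
    stop(sprintf("sim_config: unknown signature(s): %s",
                 paste(miss, collapse = ", ")))
  }
  class(cfg) <- "sim_config"
  cfg
}

sample_seed <- function(config_seed, sample_id) {
  as.integer((hash_string(sample_id) + as.numeric(config_seed) * 7919) %%
               2147483647)
}

parse_sbs_channel <- function(channel) {
  # "A[C>T]G" -> ref C, alt T, context ACG
  list(ref = substr(channel, 3, 3), alt = substr(channel, 5, 5),
       context = paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                        substr(channel, 7, 7)))
}

draw_subclonal_likelihood <- function(n, clonal_fraction) {
  clonal <- runif(n) < clonal_fraction
  ifelse(clonal, runif(n, 0, 0.7999), runif(n, 0.8, 1))
}

#' Simulate one sample's mutation catalogue and context counts
#'
#' SBS1 mutations are drawn so that their expected count is
#' `slope * age * fold_change + intercept` (Gaussian noise, truncated at
#' 0) and placed on the counted CpG>TpG channels; other signatures get
#' gamma-distributed exposures and their mutations are sampled from the
#' profile's channel distribution. Doublet mutations are emitted with
#' variant class `MNV` (so they count toward total mutation burden) while
#' their context counts use the DBS channels. Subclonal likelihoods come
#' from a two-component mixture controlled by the sample's clonal
#' fraction.
#'
#' @param sample One-row sample tibble (needs `sample_id`, `cohort`,
#'   `age_at_biopsy`).
#' @param config A [sim_config()].
#' @return A list: `mutations` tibble, `context_counts` (named count
#'   vector over all channels), `exposures` tibble.
#' @export
simulate_mutation_catalog <- function(sample, config) {
  arms <- arm_definitions()
  chrom_len <- tapply(arms$end, arms$chrom, max)
  fc <- if (sample$cohort == "metastatic")
    config$sbs1_fold_change_metastatic else 1
  mu_clonal <- if (sample$cohort == "metastatic")
    config$clonal_fraction_metastatic else config$clonal_fraction_primary
  kap <- config$clonal_fraction_kappa
  with_local_seed(sample_seed(config$seed, paste0(sample$sample_id, ":mut")), {
    clonal_fraction <- rbeta(1, kap * mu_clonal, kap * (1 - mu_clonal))
    n_sbs1 <- max(0, round(rnorm(1, config$sbs1_slope * sample$age_at_biopsy *
                                   fc + config$sbs1_intercept,
                                 config$sbs1_noise_sd)))
    sig_names <- c("synSBS1.clock", config$signature_exposures$signature)
    mean_col <- if (sample$cohort == "metastatic") "mean_metastatic" else
      "mean_primary"
    exp_means <- config$signature_exposures[[mean_col]]
    disp <- config$signature_exposures$dispersion
    n_per_sig <- c(n_sbs1, vapply(seq_along(exp_means), function(i) {
      if (exp_means[i] <= 0) 0 else
        round(rgamma(1, shape = disp[i], rate = disp[i] / exp_means[i]))
    }, numeric(1)))
    names(n_per_sig) <- sig_names
    all_channels <- c(sbs_channels(), dbs_channels(), id_channels())
    counts <- setNames(numeric(length(all_channels)), all_channels)
    muts <- list()
    for (s in sig_names) {
      n <- n_per_sig[[s]]
      if (n == 0) next
      prof <- config$reference[config$reference$name == s, , drop = FALSE]
      mt <- prof$mutation_type[1]
      drawn <- sample(prof$channel, n, replace = TRUE, prob = prof$prob)
      tab <- table(drawn)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      chrom <- sample(names(chrom_len), n, replace = TRUE,
                      prob = as.numeric(chrom_len))
      pos <- floor(runif(n, 0, chrom_len[chrom]))
      if (mt == "SBS") {
        pc <- parse_sbs_channel(drawn)
        muts[[s]] <- tibble(sample_id = sample$sample_id, chrom = chrom,
                            pos = pos, ref = pc$ref, alt = pc$alt,
                            variant_class = "SBS", context = pc$context,
                            subclonal_likelihood =
                              draw_subclonal_likelihood(n, clonal_fraction))
      } else if (mt == "DBS") {
        muts[[s]] <- tibble(sample_id = sample$sample_id, chrom = chrom,
                            pos = pos, ref = substr(drawn, 1, 2),
                            alt = substr(drawn, 4, 5),
                            variant_class = "MNV", context = NA_character_,
                            subclonal_likelihood =
                              draw_subclonal_likelihood(n, clonal_fraction))
      } else {
        muts[[s]] <- tibble(sample_id = sample$sample_id, chrom = chrom,
                            pos = pos, ref = "N", alt = "-",
                            variant_class = "ID", context = NA_character_,
                            subclonal_likelihood =
                              draw_subclonal_likelihood(n, clonal_fraction))
      }
    }
    exposures <- tibble(
      sample_id = sample$sample_id, signature = sig_names,
      mutation_type = vapply(sig_names, function(s) {
        config$reference$mutation_type[config$reference$name == s][1]
      }, character(1)),
      exposure = as.numeric(n_per_sig))
    list(mutations = if (length(muts) > 0) dplyr::bind_rows(muts) else
      tibble(sample_id = character(0), chrom = character(0), pos = numeric(0),
             ref = character(0), alt = character(0),
             variant_class = character(0), context = character(0),
             subclonal_likelihood = numeric(0)),
      context_counts = counts, exposures = exposures)
  })
}

#' Simulate one sample's copy-number segments and SV clusters
#'
#' WGD samples start from a doubled baseline copy number; arm gains and
#' losses are whole-arm integer shifts; LOH arms get a near-zero minor
#' allele. Per-type SV counts are negative-binomial with
#' `log10(mean + 1)` linear in the sample's features using the configured
#' coefficients.
#'
#' @param sample One-row sample tibble (needs `sample_id`, `cohort`,
#'   `wgd`).
#' @param config A [sim_config()].
#' @param features Optional named numeric vector of the sample's feature
#'   values used by `sv_feature_effects`.
#' @param arms Arm-definition tibble.
#' @return A list: `segments`, `sv_clusters`, `arm_truth` (per-arm event
#'   record), `genome_ploidy`.
#' @export
simulate_cn_and_sv <- function(sample, config, features = NULL,
                               arms = arm_definitions()) {
  co <- sample$cohort
  with_local_seed(sample_seed(config$seed, paste0(sample$sample_id, ":cn")), {
    base_cn <- if (sample$wgd) 4 else 2
    segs <- list()
    arm_truth <- list()
    for (i in seq_len(nrow(arms))) {
      arm <- arms[i, ]
      u <- runif(1)
      event <- if (u < config$arm_gain_prob[[co]]) 1L
      else if (u < config$arm_gain_prob[[co]] + config$arm_loss_prob[[co]]) -1L
      else 0L
      arm_cn <- max(0, base_cn + event)
      loh <- runif(1) < config$loh_arm_prob[[co]] && arm_cn >= 1
      n_seg <- 1L + rpois(1, 1)
      brk <- sort(c(arm$start, arm$end,
                    floor(runif(n_seg - 1, arm$start, arm$end))))
      brk <- unique(brk)
      cn_tot <- pmax(0, arm_cn + runif(length(brk) - 1, -0.25, 0.25))
      cn_min <- if (loh) runif(length(brk) - 1, 0, 0.2) else
        pmax(0, cn_tot / 2 - runif(length(brk) - 1, 0, 0.2))
      segs[[i]] <- tibble(sample_id = sample$sample_id, chrom = arm$chrom,
                          start = brk[-length(brk)], end = brk[-1],
                          cn_total = cn_tot, cn_minor = cn_min,
                          cn_major = cn_tot - cn_min)
      arm_truth[[i]] <- tibble(sample_id = sample$sample_id,
                               arm_label = paste0(arm$chrom, arm$arm),
                               event = event, loh = loh)
    }
    segments <- dplyr::bind_rows(segs)
    w <- segments$end - segments$start
    genome_ploidy <- sum(w * segments$cn_total) / sum(w)

    sv_rows <- list()
    for (i in seq_len(nrow(config$sv_burden))) {
      row <- config$sv_burden[i, ]
      lp <- if (co == "metastatic") row$log10_mu_metastatic else
        row$log10_mu_primary
      if (!is.null(config$sv_feature_effects) && !is.null(features)) {
        eff <- config$sv_feature_effects[
          config$sv_feature_effects$sv_type == row$sv_type, , drop = FALSE]
        for (j in seq_len(nrow(eff))) {
          lp <- lp + eff$coefficient[j] * (features[[eff$feature[j]]] %||% 0)
        }
      }
      mu <- max(0, 10^lp - 1)
      n <- if (mu == 0) 0L else rnbinom(1, size = row$dispersion, mu = mu)
      if (n == 0) next
      chrom <- sample(unique(arms$chrom), n, replace = TRUE)
      rec <- switch(
        as.character(row$sv_type),
        del_small = tibble(resolved_type = "DEL", n_sv = 1,
                           chrom_start = chrom, chrom_end = chrom,
                           length_bp = floor(runif(n, 50, 10000))),
        del_large = tibble(resolved_type = "DEL", n_sv = 1,
                           chrom_start = chrom, chrom_end = chrom,
                           length_bp = floor(runif(n, 10000, 5e6))),
        dup_small = tibble(resolved_type = "DUP", n_sv = 1,
                           chrom_start = chrom, chrom_end = chrom,
                           length_bp = floor(runif(n, 50, 10000))),
        dup_large = tibble(resolved_type = "DUP", n_sv = 1,
                           chrom_start = chrom, chrom_end = chrom,
                           length_bp = floor(runif(n, 10000, 5e6))),
        complex_small = tibble(
          resolved_type = sample(c("COMPLEX", "RECIP_INV", "UNBAL_TRANS"), n,
                                 replace = TRUE),
          n_sv = sample(2:19, n, replace = TRUE), chrom_start = chrom,
          chrom_end = chrom, length_bp = floor(runif(n, 1e4, 1e7))),
        complex_large = tibble(
          resolved_type = "COMPLEX", n_sv = 20 + rpois(n, 15),
          chrom_start = chrom, chrom_end = chrom,
          length_bp = floor(runif(n, 1e5, 5e7))),
        line = tibble(resolved_type = "LINE", n_sv = sample(1:3, n, TRUE),
                      chrom_start = chrom, chrom_end = chrom,
                      length_bp = floor(runif(n, 300, 6000))))
      rec$sample_id <- sample$sample_id
      sv_rows[[as.character(row$sv_type)]] <- rec
    }
    sv <- if (length(sv_rows) > 0) {
      dplyr::bind_rows(sv_rows)[, c("sample_id", "resolved_type", "n_sv",
                                    "chrom_start", "chrom_end", "length_bp")]
    } else {
      tibble(sample_id = character(0), resolved_type = character(0),
             n_sv = numeric(0), chrom_start = character(0),
             chrom_end = character(0), length_bp = numeric(0))
    }
    list(segments = segments, sv_clusters = sv,
         arm_truth = dplyr::bind_rows(arm_truth),
         genome_ploidy = genome_ploidy)
  })
}

#' Simulate one sample's treatments and driver events
#'
#' Metastatic samples receive each treatment mechanism independently with
#' its configured probability (primaries are untreated). Driver genes are
#' drawn at their cohort baseline frequency; for a gene with an injected
#' odds ratio under a mechanism the sample received, the baseline odds
#' are multiplied by the odds ratio.
#'
#' @param sample One-row sample tibble.
#' @param config A [sim_config()].
#' @return A list: `treatments` tibble, `drivers` tibble.
#' @export
simulate_drivers_and_treatments <- function(sample, config) {
  with_local_seed(sample_seed(config$seed, paste0(sample$sample_id, ":drv")), {
    trt <- if (sample$cohort == "metastatic" && nrow(config$treatments) > 0) {
      got <- runif(nrow(config$treatments)) < config$treatments$prob
      if (any(got)) {
        tibble(sample_id = sample$sample_id,
               drug_name = config$treatments$drug_name[got],
               mechanism_group = config$treatments$mechanism_group[got],
               pre_biopsy = TRUE)
      } else NULL
    } else NULL
    mechs <- if (is.null(trt)) character(0) else trt$mechanism_group
    drv <- list()
    for (i in seq_len(nrow(config$driver_genes))) {
      g <- config$driver_genes$gene[i]
      p <- if (sample$cohort == "metastatic")
        config$driver_genes$freq_metastatic[i] else
          config$driver_genes$freq_primary[i]
      if (!is.null(config$ted_effects)) {
        eff <- config$ted_effects[config$ted_effects$gene == g &
                                    config$ted_effects$mechanism_group %in% mechs, ,
                                  drop = FALSE]
        if (nrow(eff) > 0 && p > 0 && p < 1) {
          odds <- p / (1 - p) * prod(eff$odds_ratio)
          p <- odds / (1 + odds)
        }
      }
      if (runif(1) < p) {
        at <- sample(c("mutation", "deletion", "amplification",
                       "homozygous_disruption"), 1,
                     prob = c(0.7, 0.15, 0.1, 0.05))
        drv[[g]] <- tibble(sample_id = sample$sample_id, gene = g,
                           alteration_type = at,
                           driver_likelihood = runif(1, 0.6, 1))
      }
    }
    list(treatments = trt %||% tibble(sample_id = character(0),
                                      drug_name = character(0),
                                      mechanism_group = character(0),
                                      pre_biopsy = logical(0)),
         drivers = if (length(drv) > 0) dplyr::bind_rows(drv) else
           tibble(sample_id = character(0), gene = character(0),
                  alteration_type = character(0),
                  driver_likelihood = numeric(0)))
  })
}

#' Simulate a full synthetic two-cohort dataset
#'
#' Generates every cohort table (samples, treatments, segments, mutations,
#' context counts, signature profiles, exposures, SV clusters, drivers)
#' plus ground-truth tables recording all injected effects. Deterministic
#' given the configuration seed; each sample's draws use an RNG stream
#' derived from the hash of its id, so the output for a sample does not
#' depend on which other samples are simulated.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (a validated `cohort_dataset`) and
#'   `ground_truth` (a named list of tibbles).
#' @export
simulate_cohort <- function(config = sim_config()) {
  ct <- config$cancer_types
  if (sum(ct$n_primary) + sum(ct$n_metastatic) == 0) {
    stop("simulate_cohort: zero samples requested")
  }
  arms <- arm_definitions()
  plan <- list()
  idx <- 0
  for (i in seq_len(nrow(ct))) {
    for (co in c("primary", "metastatic")) {
      n <- if (co == "primary") ct$n_primary[i] else ct$n_metastatic[i]
      for (j in seq_len(n)) {
        idx <- idx + 1
        plan[[idx]] <- tibble(
          sample_id = sprintf("%s_%s_%03d",
                              gsub("[^A-Za-z0-9]+", "", ct$cancer_type[i]),
                              substr(co, 1, 3), j),
          cohort = co, cancer_type = ct$cancer_type[i])
      }
    }
  }
  plan <- dplyr::bind_rows(plan)
  log_info("simulate_cohort: ", nrow(plan), " samples planned")

  samples <- list(); treatments <- list(); segments <- list()
  mutations <- list(); sv <- list(); drivers <- list(); exposures <- list()
  arm_truth <- list(); cc_rows <- list()
  for (i in seq_len(nrow(plan))) {
    sid <- plan$sample_id[i]
    meta <- with_local_seed(sample_seed(config$seed, paste0(sid, ":meta")), {
      age <- min(config$age_max,
                 max(config$age_min, rnorm(1, config$age_mean, config$age_sd)))
      tibble(sample_id = sid, patient_id = paste0("PT_", sid),
             cohort = plan$cohort[i], cancer_type = plan$cancer_type[i],
             age_at_biopsy = round(age, 1),
             sex = sample(c("male", "female"), 1),
             biopsy_site_class = if (plan$cohort[i] == "metastatic") {
               sample(names(config$biopsy_site_probs), 1,
                      prob = config$biopsy_site_probs)
             } else "unknown",
             tumor_purity = round(runif(1, 0.3, 0.98), 3),
             wgd = runif(1) < config$wgd_prob[[plan$cohort[i]]],
             msi = runif(1) < config$msi_prob,
             hrd = runif(1) < config$hrd_prob)
    })
    dt <- simulate_drivers_and_treatments(meta, config)
    features <- c(n_treatments = nrow(dt$treatments),
                  hrd = as.numeric(meta$hrd), msi = as.numeric(meta$msi))
    cns <- simulate_cn_and_sv(meta, config, features = features, arms = arms)
    meta$genome_ploidy <- round(cns$genome_ploidy, 4)
    mc <- simulate_mutation_catalog(meta, config)
    samples[[i]] <- meta
    treatments[[i]] <- dt$treatments
    drivers[[i]] <- dt$drivers
    segments[[i]] <- cns$segments
    sv[[i]] <- cns$sv_clusters
    arm_truth[[i]] <- cns$arm_truth
    mutations[[i]] <- mc$mutations
    exposures[[i]] <- mc$exposures
    cc_rows[[i]] <- mc$context_counts
  }
  samples <- dplyr::bind_rows(samples)
  samples <- samples[, c("sample_id", "patient_id", "cohort", "cancer_type",
                         "age_at_biopsy", "sex", "biopsy_site_class",
                         "tumor_purity", "genome_ploidy", "wgd", "msi",
                         "hrd")]
  samples$cancer_subtype <- NA_character_
  samples <- samples[, names(.schemas$samples)]
  cc <- do.call(rbind, cc_rows)
  context_counts <- dplyr::bind_cols(tibble(sample_id = samples$sample_id),
                                     tibble::as_tibble(cc))
  profiles <- config$reference[, c("name", "mutation_type", "channel", "prob")]
  ds <- list(samples = samples,
             treatments = dplyr::bind_rows(treatments),
             segments = dplyr::bind_rows(segments),
             mutations = dplyr::bind_rows(mutations),
             context_counts = context_counts,
             signature_profiles = profiles,
             exposures = dplyr::bind_rows(exposures),
             sv_clusters = dplyr::bind_rows(sv),
             drivers = dplyr::bind_rows(drivers))
  class(ds) <- c("cohort_dataset", "list")
  issues <- validate_cohort(ds)
  if (nrow(issues) > 0) {
    stop("simulate_cohort: generated dataset failed validation (internal error)")
  }
  ground_truth <- list(
    parameters = tibble(
      key = c("seed", "sbs1_slope", "sbs1_intercept",
              "sbs1_fold_change_metastatic", "clonal_fraction_primary",
              "clonal_fraction_metastatic", "wgd_prob_primary",
              "wgd_prob_metastatic"),
      value = c(config$seed, config$sbs1_slope, config$sbs1_intercept,
                config$sbs1_fold_change_metastatic,
                config$clonal_fraction_primary,
                config$clonal_fraction_metastatic,
                config$wgd_prob[["primary"]], config$wgd_prob[["metastatic"]])),
    signature_exposures = config$signature_exposures,
    sv_burden = config$sv_burden,
    sv_feature_effects = config$sv_feature_effects %||%
      tibble(sv_type = character(0), feature = character(0),
             coefficient = numeric(0)),
    driver_genes = config$driver_genes,
    ted_effects = config$ted_effects %||%
      tibble(gene = character(0), mechanism_group = character(0),
             odds_ratio = numeric(0)),
    arm_events = dplyr::bind_rows(arm_truth))
  list(dataset = ds, ground_truth = ground_truth)
}

#' Simulate clock-mutation ages and counts for two cohorts
#'
#' Focused generator for the age-regression framework: ages are uniform
#' on `[age_min, age_max]`; expected counts are
#' `slope * age + intercept` in primaries and
#' `fold_change * (slope * age + intercept)` in metastatic samples, with
#' additive Gaussian noise truncated at 0, so the true mean prediction
#' ratio over any age range equals `fold_change`.
#'
#' @param n_primary,n_metastatic Cohort sizes.
#' @param fold_change Metastatic rate multiplier.
#' @param slope,intercept,noise_sd Clock model parameters
#'   (mutations/year; mutations; mutations).
#' @param age_min,age_max Age range (years).
#' @param seed Integer seed.
#' @return A tibble: `cohort`, `age`, `sbs1`.
#' @export
simulate_clock_cohort <- function(n_primary = 250, n_metastatic = 250,
                                  fold_change = 1, slope = 4, intercept = 50,
                                  noise_sd = 30, age_min = 30, age_max = 80,
                                  seed = 1) {
  with_local_seed(seed, {
    age_p <- runif(n_primary, age_min, age_max)
    age_m <- runif(n_metastatic, age_min, age_max)
    cnt_p <- pmax(0, slope * age_p + intercept + rnorm(n_primary, 0, noise_sd))
    cnt_m <- pmax(0, fold_change * (slope * age_m + intercept) +
                    rnorm(n_metastatic, 0, noise_sd))
    tibble(cohort = rep(c("primary", "metastatic"),
                        c(n_primary, n_metastatic)),
           age = c(age_p, age_m), sbs1 = c(cnt_p, cnt_m))
  })
}

#' Simulate samples, features and SV burden for the three-LM screen
#'
#' Focused generator for the feature-association framework. Burden is
#' negative-binomial with `log10(mean + 1)` equal to `base_log10` plus
#' the configured feature effects plus an optional unmodelled cohort
#' shift in metastatic samples (which makes a cohort-confounded feature
#' spuriously correlate in the combined model only).
#'
#' @param n Total samples (half metastatic, half primary).
#' @param effect_size Log10 coefficient on the effect feature
#'   (`gene_EFFECT`, prevalence 0.5 metastatic / 0.15 primary); 0 disables
#'   it.
#' @param confounded Add a null feature (`gene_CONFOUND`, prevalence 0.6
#'   metastatic / 0.05 primary) with zero coefficient.
#' @param cohort_shift Unmodelled log10 shift added for metastatic
#'   samples.
#' @param n_null_genes Number of additional null gene-status features
#'   (prevalence 0.25, no effect).
#' @param base_log10,dispersion Burden model parameters.
#' @param seed Integer seed.
#' @return A list: `burden` (counts), `features` (with `feature_kind`
#'   attribute), `cohort`, `samples`, `counts` (an [sv_type_counts()]-
#'   shaped tibble with the burden in `del_small`).
#' @export
simulate_sv_lm_cohort <- function(n = 400, effect_size = 0,
                                  confounded = FALSE, cohort_shift = 0,
                                  n_null_genes = 8, base_log10 = 1.0,
                                  dispersion = 8, seed = 1) {
  with_local_seed(seed, {
    cohort <- rep(c("metastatic", "primary"), length.out = n)
    met <- cohort == "metastatic"
    feats <- tibble(sample_id = sprintf("LM_%04d", seq_len(n)),
                    genome_ploidy = round(rnorm(n, 2.8, 0.5), 3),
                    hrd = rbinom(n, 1, 0.12), msi = rbinom(n, 1, 0.05))
    kind <- c(genome_ploidy = "numeric", hrd = "boolean", msi = "boolean")
    for (g in seq_len(n_null_genes)) {
      colname <- sprintf("gene_NULL%02d", g)
      feats[[colname]] <- rbinom(n, 1, 0.25)
      kind[colname] <- "gene"
    }
    lp <- rep(base_log10, n)
    if (effect_size != 0) {
      feats$gene_EFFECT <- rbinom(n, 1, ifelse(met, 0.5, 0.15))
      kind["gene_EFFECT"] <- "gene"
      lp <- lp + effect_size * feats$gene_EFFECT
    }
    if (confounded) {
      feats$gene_CONFOUND <- rbinom(n, 1, ifelse(met, 0.6, 0.05))
      kind["gene_CONFOUND"] <- "gene"
    }
    lp <- lp + cohort_shift * met
    mu <- pmax(0, 10^lp - 1)
    burden <- rnbinom(n, size = dispersion, mu = mu)
    attr(feats, "feature_kind") <- kind
    samples <- tibble(sample_id = feats$sample_id, cohort = cohort,
                      cancer_type = "Simulated")
    counts <- tibble(sample_id = feats$sample_id, del_small = burden)
    for (tp in setdiff(.sv_types, "del_small")) counts[[tp]] <- 0L
    counts$total <- burden
    list(burden = burden, features = feats, cohort = cohort,
         samples = samples, counts = counts)
  })
}

#' Simulate treated/untreated driver events for the TED test
#'
#' Focused generator for treatment-enriched driver detection: `n_genes`
#' candidate genes mutated at `baseline_freq` in untreated patients; in
#' treated patients the `target_gene`'s odds are multiplied by
#' `odds_ratio` (1 = null).
#'
#' @param n_treated,n_untreated Group sizes (patients).
#' @param n_genes Number of candidate genes.
#' @param baseline_freq Per-gene baseline mutation frequency.
#' @param odds_ratio Injected odds ratio on the target gene.
#' @param target_gene Name of the affected gene.
#' @param seed Integer seed.
#' @return A list: `drivers` tibble, `treated_ids`, `untreated_ids`,
#'   `target_gene`.
#' @export
simulate_ted_cohort <- function(n_treated = 40, n_untreated = 200,
                                n_genes = 200, baseline_freq = 0.05,
                                odds_ratio = 1, target_gene = "G001",
                                seed = 1) {
  with_local_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    treated_ids <- sprintf("TRT_%03d", seq_len(n_treated))
    untreated_ids <- sprintf("UNT_%03d", seq_len(n_untreated))
    p_trt <- setNames(rep(baseline_freq, n_genes), genes)
    odds <- baseline_freq / (1 - baseline_freq) * odds_ratio
    p_trt[target_gene] <- odds / (1 + odds)
    rows <- list()
    for (g in genes) {
      hit_t <- treated_ids[runif(n_treated) < p_trt[[g]]]
      hit_u <- untreated_ids[runif(n_untreated) < baseline_freq]
      ids <- c(hit_t, hit_u)
      if (length(ids) > 0) {
        rows[[g]] <- tibble(sample_id = ids, gene = g,
                            alteration_type = "mutation",
                            driver_likelihood = 0.9)
      }
    }
    list(drivers = dplyr::bind_rows(rows), treated_ids = treated_ids,
         untreated_ids = untreated_ids, target_gene = target_gene)
  })
}

#' Simulate aetiology contributions for two cohorts
#'
#' Focused generator for the exposure-comparison null/recovery studies:
#' gamma-distributed contributions for `n_aetiologies` processes in each
#' of several cancer types; one aetiology can be given a log2 fold change
#' in the metastatic cohort.
#'
#' @param n_per_cohort Samples per cohort per cancer type.
#' @param cancer_types Cancer-type labels.
#' @param n_aetiologies Number of aetiologies (all SBS).
#' @param mean_contribution Baseline mean contribution.
#' @param dispersion Gamma shape.
#' @param log2fc Injected log2 fold change on `target_aetiology` in
#'   metastatic samples.
#' @param target_aetiology Affected aetiology (default the first).
#' @param seed Integer seed.
#' @return A list: `contrib` (aetiology contributions) and `samples`.
#' @export
simulate_exposure_cohort <- function(n_per_cohort = 60,
                                     cancer_types = c("TypeA", "TypeB"),
                                     n_aetiologies = 8,
                                     mean_contribution = 500, dispersion = 4,
                                     log2fc = 0, target_aetiology = NULL,
                                     seed = 1) {
  with_local_seed(seed, {
    aes <- sprintf("aetiology_%02d", seq_len(n_aetiologies))
    if (is.null(target_aetiology)) target_aetiology <- aes[1]
    samples <- list(); contrib <- list()
    for (ct in cancer_types) {
      for (co in c("primary", "metastatic")) {
        ids <- sprintf("%s_%s_%03d", ct, substr(co, 1, 3),
                       seq_len(n_per_cohort))
        samples[[paste(ct, co)]] <- tibble(sample_id = ids, cohort = co,
                                           cancer_type = ct)
        for (ae in aes) {
          m <- mean_contribution
          if (co == "metastatic" && ae == target_aetiology) {
            m <- m * 2^log2fc
          }
          contrib[[paste(ct, co, ae)]] <- tibble(
            sample_id = ids, mutation_type = "SBS", aetiology = ae,
            contribution = rgamma(n_per_cohort, shape = dispersion,
                                  rate = dispersion / m))
        }
      }
    }
    list(contrib = dplyr::bind_rows(contrib),
         samples = dplyr::bind_rows(samples))
  })
}
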