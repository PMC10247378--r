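#' Context channel names
#'
#' Canonical channel orderings for the three mutation classes: 96
#' trinucleotide single-base-substitution channels (`"A[C>A]A"`, pyrimidine
#' strand, ordered by substitution then flanks), 78 doublet-substitution
#' channels (`"AC>CA"`, canonical strand), and 83 indel channels
#' (`"1:Del:C:0"` style: length, type, context, homopolymer/repeat/
#' microhomology size).
#'
#' @return Character vector of channel names.
#' @export
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (l in bases) for (r in bases) {
      out <- c(out, sprintf("%s[%s]%s", l, s, r))
    }
  }
  out
}

revcomp_d <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(d) {
    paste0(comp[[substr(d, 2, 2)]], comp[[substr(d, 1, 1)]])
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname sbs_channels
#' @export
dbs_channels <- function() {
  refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (ref in refs) {
    alts <- character(0)
    for (a1 in bases) for (a2 in bases) {
      if (a1 != substr(ref, 1, 1) && a2 != substr(ref, 2, 2)) {
        alts <- c(alts, paste0(a1, a2))
      }
    }
    if (revcomp_d(ref) == ref) {
      # palindromic ref: alt and its reverse complement are the same event
      alts <- unique(pmin(alts, revcomp_d(alts)))
    }
    out <- c(out, paste0(ref, ">", sort(alts)))
  }
  out
}

#' @rdname sbs_channels
#' @export
id_channels <- function() {
  out <- character(0)
  for (t in c("Del", "Ins")) for (b in c("C", "T")) {
    out <- c(out, sprintf("1:%s:%s:%d", t, b, 0:5))
  }
  for (t in c("Del", "Ins")) for (len in c("2", "3", "4", "5+")) {
    out <- c(out, sprintf("%s:%s:R:%d", len, t, 0:5))
  }
  mh <- list(`2` = 1, `3` = 1:2, `4` = 1:3, `5+` = 1:5)
  for (len in names(mh)) {
    out <- c(out, sprintf("%s:Del:M:%d", len, mh[[len]]))
  }
  out
}

channels_for <- function(mutation_type) {
  switch(mutation_type,
         SBS = sbs_channels(), DBS = dbs_channels(), ID = id_channels(),
         stop(sprintf("unknown mutation type '%s'", mutation_type)))
}

#' Synthetic reference signature catalog
#'
#' A small, fully synthetic catalog of labelled signature profiles used by
#' the simulator and the examples; it is *not* COSMIC data. Profiles are
#' shaped to exercise the pipeline's decision rules: `synSBS1.clock` puts
#' all mass on C>T at ACG/CCG/GCG (the counted CpG>TpG channels; TCG is
#' deliberately empty so clock-mutation counting is identifiable),
#' `synSBS.flat.clock` is flat outside all NpCpG C>T channels,
#' `synSBS.apobec` peaks at TpCpW, `synSBS.uv` at CC/TC contexts, and
#' `synSBS.platinum` in C>A channels. DBS and ID profiles follow the same
#' idea.
#'
#' @return A long tibble: `name`, `mutation_type`, `channel`, `prob`, plus
#'   an `aetiology` column giving each profile's ground-truth aetiology.
#' @export
synthetic_reference_catalog <- function() {
  sbs <- sbs_channels()
  mk <- function(name, type, w, aetiology) {
    w <- w / sum(w)
    tibble(name = name, mutation_type = type, channel = channels_for(type),
           prob = w, aetiology = aetiology)
  }
  ncg_ct <- sprintf("%s[C>T]G", c("A", "C", "G", "T")) # all NpCpG C>T
  w1 <- setNames(numeric(96), sbs)
  w1[c("A[C>T]G", "C[C>T]G", "G[C>T]G")] <- c(0.34, 0.33, 0.33)
  wflat <- setNames(rep(1, 96), sbs); wflat[ncg_ct] <- 0
  wap <- setNames(numeric(96), sbs)
  wap[c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")] <- c(0.3, 0.3, 0.2, 0.2)
  wuv <- setNames(numeric(96), sbs)
  wuv[c("C[C>T]A", "C[C>T]C", "C[C>T]T", "T[C>T]A", "T[C>T]C", "T[C>T]T")] <-
    c(0.25, 0.15, 0.2, 0.15, 0.1, 0.15)
  wpt <- setNames(numeric(96), sbs)
  wpt[c("A[C>A]A", "C[C>A]A", "G[C>A]C", "T[C>A]A", "A[T>A]C", "C[T>A]C")] <-
    c(0.25, 0.2, 0.15, 0.2, 0.1, 0.1)
  dbs <- dbs_channels()
  wdp <- setNames(numeric(78), dbs)
  wdp[c("CT>AA", "CT>AC")] <- c(0.7, 0.3)
  wdf <- setNames(rep(1, 78), dbs); wdf[c("CT>AA", "CT>AC")] <- 0
  idc <- id_channels()
  wir <- setNames(numeric(83), idc)
  wir[c("1:Del:T:4", "1:Del:T:5", "1:Ins:T:4", "1:Ins:T:5")] <-
    c(0.35, 0.3, 0.2, 0.15)
  wif <- setNames(rep(1, 83), idc)
  wif[c("1:Del:T:4", "1:Del:T:5", "1:Ins:T:4", "1:Ins:T:5")] <- 0
  dplyr::bind_rows(
    mk("synSBS1.clock", "SBS", w1, "clock-like SBS1"),
    mk("synSBS.flat.clock", "SBS", wflat, "clock-like SBS5/40"),
    mk("synSBS.apobec", "SBS", wap, "APOBEC"),
    mk("synSBS.uv", "SBS", wuv, "UV"),
    mk("synSBS.platinum", "SBS", wpt, "platinum"),
    mk("synDBS.platinum", "DBS", wdp, "platinum"),
    mk("synDBS.flat", "DBS", wdf, "unknown DBS"),
    mk("synID.slippage", "ID", wir, "slippage"),
    mk("synID.flat", "ID", wif, "unknown ID")
  )
}

# Long profile tibble -> matrix (profiles x channels, canonical order).
profiles_to_matrix <- function(profiles, mutation_type) {
  prof <- profiles[profiles$mutation_type == mutation_type, , drop = FALSE]
  ch <- channels_for(mutation_type)
  nm <- unique(prof$name)
  m <- matrix(0, nrow = length(nm), ncol = length(ch),
              dimnames = list(nm, ch))
  m[cbind(match(prof$name, nm), match(prof$channel, ch))] <- prof$prob
  m
}

#' Match de novo signatures to a reference catalog
#'
#' Assigns each de novo profile the reference signature of the same
#' mutation type with maximal cosine similarity, provided the similarity
#' is at or above `threshold` (default 0.85); profiles below the floor are
#' returned unmatched.
#'
#' @param denovo,reference Long profile tibbles (`name`, `mutation_type`,
#'   `channel`, `prob`).
#' @param threshold Minimum cosine similarity for a match.
#' @return A tibble: `name`, `mutation_type`, `matched_reference`
#'   (`NA` when unmatched), `similarity`, `provenance`.
#' @export
match_to_reference <- function(denovo, reference, threshold = 0.85) {
  rows <- list()
  for (mt in unique(denovo$mutation_type)) {
    dm <- profiles_to_matrix(denovo, mt)
    rm_ <- profiles_to_matrix(reference, mt)
    if (nrow(rm_) == 0) {
      rows[[mt]] <- tibble(name = rownames(dm), mutation_type = mt,
                           matched_reference = NA_character_,
                           similarity = NA_real_, provenance = "unassigned")
      next
    }
    for (i in seq_len(nrow(dm))) {
      sims <- vapply(seq_len(nrow(rm_)), function(j) {
        cosine_similarity(dm[i, ], rm_[j, ])
      }, numeric(1))
      best <- which.max(sims)
      matched <- sims[best] >= threshold
      rows[[paste(mt, i)]] <- tibble(
        name = rownames(dm)[i], mutation_type = mt,
        matched_reference = if (matched) rownames(rm_)[best] else NA_character_,
        similarity = sims[best],
        provenance = if (matched) "reference_match" else "unassigned")
    }
  }
  dplyr::bind_rows(rows)
}

#' Cluster unmatched de novo signatures
#'
#' Agglomerative hierarchical clustering on pairwise cosine distance
#' (1 - cosine similarity); the tree is cut at every k from 2 to n-1 and
#' the k maximising the mean silhouette width is chosen (smallest k on
#' ties). With fewer than 3 profiles each becomes its own cluster; when
#' all profiles are (numerically) identical the silhouette is undefined
#' and a single cluster is returned with a warning.
#'
#' @param profiles Long profile tibble of one mutation type.
#' @param linkage Linkage method: `"average"` (default), `"complete"`, or
#'   `"ward.D2"` (on euclidean distance).
#' @return Named integer vector of cluster labels, one per profile.
#' @export
cluster_unmatched <- function(profiles, linkage = c("average", "complete",
                                                    "ward.D2")) {
  linkage <- match.arg(linkage)
  mt <- unique(profiles$mutation_type)
  if (length(mt) != 1) stop("cluster_unmatched: profiles must share one mutation type")
  m <- profiles_to_matrix(profiles, mt)
  n <- nrow(m)
  if (n < 3) return(setNames(seq_len(n), rownames(m)))
  d <- if (linkage == "ward.D2") dist(m) else cosine_dist(m)
  if (max(d) < 1e-12) {
    warning("cluster_unmatched: all profiles identical; returning one cluster")
    return(setNames(rep(1L, n), rownames(m)))
  }
  hc <- stats::hclust(d, method = linkage)
  ks <- 2:(n - 1)
  sil <- vapply(ks, function(k) {
    labs <- stats::cutree(hc, k = k)
    s <- cluster::silhouette(labs, d)[, "sil_width"]
    s[is.nan(s)] <- 0
    mean(s)
  }, numeric(1))
  k_best <- ks[which.max(sil)]
  labs <- stats::cutree(hc, k = k_best)
  setNames(as.integer(labs), rownames(m))
}

#' Aggregate signature exposures by aetiology
#'
#' Sums the per-sample contributions of signatures of the same mutation
#' type that share an aetiology.
#'
#' @param exposures Long exposure tibble (`sample_id`, `signature`,
#'   `mutation_type`, `exposure`).
#' @param aetiology_map Tibble mapping `signature` to `aetiology`; every
#'   signature in `exposures` must be mapped.
#' @return A tibble: `sample_id`, `mutation_type`, `aetiology`,
#'   `contribution`.
#' @export
aggregate_aetiology <- function(exposures, aetiology_map) {
  unmapped <- setdiff(unique(exposures$signature), aetiology_map$signature)
  if (length(unmapped) > 0) {
    stop(sprintf("aggregate_aetiology: unmapped signature(s): %s",
                 paste(unmapped, collapse = ", ")))
  }
  df <- dplyr::inner_join(exposures, aetiology_map[, c("signature", "aetiology")],
                          by = "signature")
  dplyr::summarise(dplyr::group_by(df, .data$sample_id, .data$mutation_type,
                                   .data$aetiology),
                   contribution = sum(.data$exposure), .groups = "drop")
}

# Complete the per-sample aetiology grid with zero contributions, so
# samples in which a process is inactive count as zeros, not missing.
complete_contributions <- function(contrib, samples, mutation_type, aetiology) {
  grid <- tidyr::expand_grid(sample_id = samples$sample_id,
                             mutation_type = mutation_type,
                             aetiology = aetiology)
  out <- dplyr::left_join(grid, contrib,
                          by = c("sample_id", "mutation_type", "aetiology"))
  out$contribution[is.na(out$contribution)] <- 0
  out
}

#' Compare absolute aetiology contributions between cohorts
#'
#' Per cancer type, mutation type and aetiology: two-sided Mann-Whitney on
#' the per-sample aetiology contributions (samples without the process
#' contribute 0), Holm-corrected within each cancer type x mutation type
#' family. The effect is summarised as
#' `log2((median_met + 1) / (median_pri + 1))` (pseudocount 1); an
#' aetiology is significantly different when q < `q_threshold` and
#' |log2 fold change| >= `log2fc_threshold`.
#'
#' @param contrib Aetiology contributions from [aggregate_aetiology()].
#' @param samples Sample metadata (`sample_id`, `cohort`, `cancer_type`).
#' @param q_threshold,log2fc_threshold Decision thresholds (0.05, 0.4).
#' @return A tibble, one row per cancer type x mutation type x aetiology.
#' @export
compare_absolute <- function(contrib, samples, q_threshold = 0.05,
                             log2fc_threshold = 0.4) {
  rows <- list()
  for (ct in sort(unique(samples$cancer_type))) {
    sub_s <- samples[samples$cancer_type == ct, , drop = FALSE]
    sub_c <- contrib[contrib$sample_id %in% sub_s$sample_id, , drop = FALSE]
    for (mt in sort(unique(sub_c$mutation_type))) {
      aes <- sort(unique(sub_c$aetiology[sub_c$mutation_type == mt]))
      full <- complete_contributions(sub_c[sub_c$mutation_type == mt, ],
                                     sub_s, mt, aes)
      full <- dplyr::inner_join(full, sub_s[, c("sample_id", "cohort")],
                                by = "sample_id")
      fam <- list()
      for (ae in aes) {
        met <- full$contribution[full$aetiology == ae & full$cohort == "metastatic"]
        pri <- full$contribution[full$aetiology == ae & full$cohort == "primary"]
        if (length(met) == 0 || length(pri) == 0) next
        tr <- mann_whitney_two_sided(met, pri)
        fam[[ae]] <- tibble(cancer_type = ct, mutation_type = mt,
                            aetiology = ae, statistic = tr$statistic,
                            p_value = tr$p_value,
                            log2fc = log2((median(met) + 1) / (median(pri) + 1)))
      }
      if (length(fam) == 0) next
      fam <- dplyr::bind_rows(fam)
      fam$q_value <- adjust_pvalues(fam$p_value, "holm")
      rows[[paste(ct, mt)]] <- fam
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$significant <- out$q_value < q_threshold & abs(out$log2fc) >= log2fc_threshold
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$log2fc > 0, "metastatic_enriched",
                                 "primary_enriched"))
  out
}

#' Compare relative aetiology contributions between cohorts
#'
#' Relative contribution is the aetiology contribution divided by the
#' sample's total contribution of the same mutation type; samples whose
#' total is 0 are excluded. Testing and correction as in
#' [compare_absolute()]; the effect is the difference of cohort medians
#' (metastatic - primary), significant when q < `q_threshold` and
#' |median difference| >= `diff_threshold` (0.01).
#'
#' @inheritParams compare_absolute
#' @param diff_threshold Minimum absolute median difference.
#' @return A tibble, one row per cancer type x mutation type x aetiology.
#' @export
compare_relative <- function(contrib, samples, q_threshold = 0.05,
                             diff_threshold = 0.01) {
  totals <- dplyr::summarise(dplyr::group_by(contrib, .data$sample_id,
                                             .data$mutation_type),
                             total = sum(.data$contribution), .groups = "drop")
  rows <- list()
  for (ct in sort(unique(samples$cancer_type))) {
    sub_s <- samples[samples$cancer_type == ct, , drop = FALSE]
    sub_c <- contrib[contrib$sample_id %in% sub_s$sample_id, , drop = FALSE]
    for (mt in sort(unique(sub_c$mutation_type))) {
      aes <- sort(unique(sub_c$aetiology[sub_c$mutation_type == mt]))
      full <- complete_contributions(sub_c[sub_c$mutation_type == mt, ],
                                     sub_s, mt, aes)
      full <- dplyr::inner_join(full, totals, by = c("sample_id", "mutation_type"))
      full <- full[!is.na(full$total) & full$total > 0, , drop = FALSE]
      full$relative <- full$contribution / full$total
      full <- dplyr::inner_join(full, sub_s[, c("sample_id", "cohort")],
                                by = "sample_id")
      fam <- list()
      for (ae in aes) {
        met <- full$relative[full$aetiology == ae & full$cohort == "metastatic"]
        pri <- full$relative[full$aetiology == ae & full$cohort == "primary"]
        if (length(met) == 0 || length(pri) == 0) next
        tr <- mann_whitney_two_sided(met, pri)
        fam[[ae]] <- tibble(cancer_type = ct, mutation_type = mt,
                            aetiology = ae, statistic = tr$statistic,
                            p_value = tr$p_value,
                            median_diff = median(met) - median(pri))
      }
      if (length(fam) == 0) next
      fam <- dplyr::bind_rows(fam)
      fam$q_value <- adjust_pvalues(fam$p_value, "holm")
      rows[[paste(ct, mt)]] <- fam
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$significant <- out$q_value < q_threshold & abs(out$median_diff) >= diff_threshold
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$median_diff > 0, "metastatic_enriched",
                                 "primary_enriched"))
  out
}

#' Hypermutator enrichment between cohorts
#'
#' A sample is a hypermutator for an aetiology when its contribution
#' reaches the mutation-type threshold (SBS 10,000; DBS 500; ID 1,000).
#' Per cancer type and aetiology, a two-sided Fisher's exact test on
#' cohort x hypermutator status is run only when at least
#' `min_hypermutators` (5) hypermutators exist in either cohort; effect
#' size is the signed Cramer's V and p-values are Bonferroni-corrected
#' across the performed tests.
#'
#' @inheritParams compare_absolute
#' @param thresholds Named vector of hypermutator thresholds per mutation
#'   type.
#' @param min_hypermutators Minimum hypermutators in either cohort.
#' @return A tibble of performed tests.
#' @export
hypermutator_enrichment <- function(contrib, samples,
                                    thresholds = c(SBS = 10000, DBS = 500,
                                                   ID = 1000),
                                    min_hypermutators = 5) {
  rows <- list()
  for (ct in sort(unique(samples$cancer_type))) {
    sub_s <- samples[samples$cancer_type == ct, , drop = FALSE]
    sub_c <- contrib[contrib$sample_id %in% sub_s$sample_id, , drop = FALSE]
    for (mt in sort(unique(sub_c$mutation_type))) {
      thr <- thresholds[[mt]]
      aes <- sort(unique(sub_c$aetiology[sub_c$mutation_type == mt]))
      full <- complete_contributions(sub_c[sub_c$mutation_type == mt, ],
                                     sub_s, mt, aes)
      full <- dplyr::inner_join(full, sub_s[, c("sample_id", "cohort")],
                                by = "sample_id")
      full$hyper <- full$contribution >= thr
      for (ae in aes) {
        sub <- full[full$aetiology == ae, , drop = FALSE]
        n_met <- sum(sub$hyper[sub$cohort == "metastatic"])
        n_pri <- sum(sub$hyper[sub$cohort == "primary"])
        if (max(n_met, n_pri) < min_hypermutators) next
        tab <- matrix(c(n_met, sum(sub$cohort == "metastatic") - n_met,
                        n_pri, sum(sub$cohort == "primary") - n_pri),
                      nrow = 2, byrow = TRUE)
        fr <- fisher_exact_two_sided(tab)
        rows[[paste(ct, mt, ae)]] <- tibble(
          cancer_type = ct, mutation_type = mt, aetiology = ae,
          n_hyper_metastatic = n_met, n_hyper_primary = n_pri,
          odds_ratio = fr$odds_ratio, p_value = fr$p_value,
          effect_size = suppressWarnings(signed_cramers_v(tab)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(cancer_type = character(0), mutation_type = character(0),
                  aetiology = character(0), n_hyper_metastatic = integer(0),
                  n_hyper_primary = integer(0), odds_ratio = numeric(0),
                  p_value = numeric(0), effect_size = numeric(0),
                  q_value = numeric(0)))
  }
  out$q_value <- adjust_pvalues(out$p_value, "bonferroni")
  out
}
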