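#' @import tibble
NULL

# Column types per table: c = character, d = double, i = integer,
# l = logical. `context_counts` is wide (sample_id + one column per context
# channel) and is validated separately.
.schemas <- list(
  samples = c(sample_id = "c", patient_id = "c", cohort = "c",
              cancer_type = "c", cancer_subtype = "c", age_at_biopsy = "d",
              sex = "c", biopsy_site_class = "c", tumor_purity = "d",
              genome_ploidy = "d", wgd = "l", msi = "l", hrd = "l"),
  treatments = c(sample_id = "c", drug_name = "c", mechanism_group = "c",
                 pre_biopsy = "l"),
  segments = c(sample_id = "c", chrom = "c", start = "d", end = "d",
               cn_total = "d", cn_minor = "d", cn_major = "d"),
  mutations = c(sample_id = "c", chrom = "c", pos = "d", ref = "c",
                alt = "c", variant_class = "c", context = "c",
                subclonal_likelihood = "d"),
  signature_profiles = c(name = "c", mutation_type = "c", channel = "c",
                         prob = "d"),
  exposures = c(sample_id = "c", signature = "c", mutation_type = "c",
                exposure = "d"),
  sv_clusters = c(sample_id = "c", resolved_type = "c", n_sv = "d",
                  chrom_start = "c", chrom_end = "c", length_bp = "d"),
  drivers = c(sample_id = "c", gene = "c", alteration_type = "c",
              driver_likelihood = "d"),
  arm_definitions = c(chrom = "c", arm = "c", start = "d", end = "d")
)

.cohort_enums <- list(
  cohort = c("primary", "metastatic"),
  sex = c("male", "female", "unknown"),
  biopsy_site_class = c("local", "lymph", "distant", "unknown"),
  variant_class = c("SBS", "DBS", "ID", "MNV"),
  alteration_type = c("mutation", "amplification", "deletion",
                      "homozygous_disruption", "fusion", "noncoding"),
  arm = c("p", "q"),
  mutation_type = c("SBS", "DBS", "ID")
)

read_one_table <- function(path, table) {
  sch <- .schemas[[table]]
  spec <- lapply(sch, function(k) switch(k, c = readr::col_character(),
                                         d = readr::col_double(),
                                         i = readr::col_integer(),
                                         l = readr::col_logical()))
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  spec <- spec[intersect(names(spec), hdr)]
  df <- readr::read_tsv(path,
                        col_types = do.call(readr::cols,
                                            c(spec, .default = list(readr::col_guess()))),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(names(sch), names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  df <- df[, names(sch)]
  for (i in seq_along(sch)) {
    col <- names(sch)[i]
    df[[col]] <- switch(sch[[i]],
                        c = as.character(df[[col]]),
                        d = as.numeric(df[[col]]),
                        i = as.integer(df[[col]]),
                        l = as.logical(df[[col]]))
  }
  tibble::as_tibble(df)
}

#' Read a cohort dataset from TSV files
#'
#' Loads the per-sample tables written by an upstream somatic pipeline (or
#' by [simulate_cohort()]), cross-links them on `sample_id`, and validates
#' every documented invariant. All coordinates are 0-based half-open (BED
#' convention), which differs from the 1-based upstream ecosystem; lengths
#' are therefore always `end - start`.
#'
#' @param paths Either a directory containing `<table>.tsv` files, or a
#'   named list/vector of file paths. Recognised table names: `samples`,
#'   `treatments`, `segments`, `mutations`, `context_counts`,
#'   `signature_profiles`, `exposures`, `sv_clusters`, `drivers`,
#'   `arm_definitions`. `samples` is required; the rest are optional.
#' @param validate Run [validate_cohort()] and stop on violations
#'   (default `TRUE`).
#' @return A `cohort_dataset`: a named list of tibbles (wide tibble for
#'   `context_counts`).
#' @export
read_cohort <- function(paths, validate = TRUE) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
    paths <- setNames(files, sub("\\.tsv$", "", basename(files)))
  }
  paths <- as.list(paths)
  known <- c(names(.schemas), "context_counts")
  unknown <- setdiff(names(paths), known)
  if (length(unknown) > 0) {
    stop(sprintf("read_cohort: unknown table(s) %s (known: %s)",
                 paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  }
  if (!"samples" %in% names(paths)) stop("read_cohort: 'samples' table is required")
  ds <- list()
  for (tb in intersect(known, names(paths))) {
    ds[[tb]] <- if (tb == "context_counts") {
      cc <- readr::read_tsv(paths[[tb]], progress = FALSE, show_col_types = FALSE)
      if (!"sample_id" %in% names(cc)) {
        stop("schema error in context_counts: missing column(s) sample_id")
      }
      cc$sample_id <- as.character(cc$sample_id)
      tibble::as_tibble(cc)
    } else {
      read_one_table(paths[[tb]], tb)
    }
    log_debug("read_cohort: ", tb, ": ", nrow(ds[[tb]]), " rows")
  }
  class(ds) <- c("cohort_dataset", "list")
  if (validate) {
    issues <- validate_cohort(ds)
    if (nrow(issues) > 0) {
      stop(paste0("cohort validation failed:\n",
                  paste(sprintf("  [%s row %s] %s", issues$table, issues$row,
                                issues$problem), collapse = "\n")))
    }
  }
  ds
}

#' Validate a cohort dataset against its invariants
#'
#' Checks every documented invariant (unique sample ids, value ranges,
#' enum membership, segment non-overlap, pyrimidine-centred SBS contexts,
#' foreign-key resolution) and returns all violations rather than stopping
#' at the first.
#'
#' @param ds A `cohort_dataset` as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @return A tibble with columns `table`, `row`, `problem`; zero rows when
#'   the dataset is valid.
#' @export
validate_cohort <- function(ds) {
  issues <- list()
  add <- function(table, row, problem) {
    issues[[length(issues) + 1]] <<- tibble(table = table,
                                            row = as.character(row),
                                            problem = problem)
  }
  smp <- ds$samples
  if (!is.null(smp)) {
    dup <- which(duplicated(smp$sample_id))
    for (i in dup) add("samples", i, sprintf("duplicate sample_id '%s'", smp$sample_id[i]))
    bad <- which(!smp$cohort %in% .cohort_enums$cohort)
    for (i in bad) add("samples", i, sprintf("invalid cohort '%s'", smp$cohort[i]))
    bad <- which(is.na(smp$age_at_biopsy) | smp$age_at_biopsy < 0 | smp$age_at_biopsy > 120)
    for (i in bad) add("samples", i, "age_at_biopsy outside [0, 120]")
    bad <- which(!(smp$tumor_purity > 0 & smp$tumor_purity <= 1))
    for (i in bad) add("samples", i, "tumor_purity outside (0, 1]")
    bad <- which(!(smp$genome_ploidy > 0 & smp$genome_ploidy < 16))
    for (i in bad) add("samples", i, "genome_ploidy outside (0, 16)")
    bad <- which(!smp$sex %in% .cohort_enums$sex)
    for (i in bad) add("samples", i, sprintf("invalid sex '%s'", smp$sex[i]))
    bad <- which(!smp$biopsy_site_class %in% .cohort_enums$biopsy_site_class)
    for (i in bad) add("samples", i, sprintf("invalid biopsy_site_class '%s'",
                                             smp$biopsy_site_class[i]))
  }
  known_ids <- smp$sample_id %||% character(0)
  check_fk <- function(tb) {
    if (is.null(ds[[tb]])) return(invisible(NULL))
    bad <- which(!ds[[tb]]$sample_id %in% known_ids)
    for (i in head(bad, 20)) {
      add(tb, i, sprintf("unresolved sample_id '%s'", ds[[tb]]$sample_id[i]))
    }
  }
  for (tb in c("treatments", "segments", "mutations", "sv_clusters",
               "drivers", "exposures")) check_fk(tb)

  seg <- ds$segments
  if (!is.null(seg)) {
    bad <- which(!(seg$start < seg$end))
    for (i in head(bad, 20)) add("segments", i, "start >= end")
    bad <- which(seg$cn_minor > seg$cn_major + 1e-9)
    for (i in head(bad, 20)) add("segments", i, "cn_minor > cn_major")
    bad <- which(seg$cn_total < 0 | seg$cn_minor < 0)
    for (i in head(bad, 20)) add("segments", i, "negative copy number")
    # per sample per chromosome: non-overlapping intervals
    key <- paste(seg$sample_id, seg$chrom, sep = "\r")
    for (k in unique(key)) {
      idx <- which(key == k)
      o <- idx[order(seg$start[idx])]
      if (length(o) > 1) {
        ov <- which(seg$start[o][-1] < seg$end[o][-length(o)])
        for (j in ov) {
          add("segments", o[j + 1],
              sprintf("overlapping segments for sample %s chromosome %s",
                      seg$sample_id[o[j + 1]], seg$chrom[o[j + 1]]))
        }
      }
    }
  }
  mut <- ds$mutations
  if (!is.null(mut)) {
    bad <- which(!mut$variant_class %in% .cohort_enums$variant_class)
    for (i in head(bad, 20)) add("mutations", i, sprintf("invalid variant_class '%s'",
                                                         mut$variant_class[i]))
    bad <- which(is.na(mut$subclonal_likelihood) | mut$subclonal_likelihood < 0 |
                   mut$subclonal_likelihood > 1)
    for (i in head(bad, 20)) add("mutations", i, "subclonal_likelihood outside [0, 1]")
    sbs <- which(mut$variant_class == "SBS")
    ok <- grepl("^[ACGT][CT][ACGT]$", mut$context[sbs])
    for (i in head(sbs[!ok], 20)) {
      add("mutations", i, sprintf("SBS context '%s' is not a pyrimidine-centred trinucleotide",
                                  mut$context[i]))
    }
  }
  trt <- ds$treatments
  if (!is.null(trt)) {
    bad <- which(is.na(trt$mechanism_group) | trt$mechanism_group == "")
    for (i in head(bad, 20)) add("treatments", i, "empty mechanism_group")
  }
  sv <- ds$sv_clusters
  if (!is.null(sv)) {
    bad <- which(is.na(sv$n_sv) | sv$n_sv < 1)
    for (i in head(bad, 20)) add("sv_clusters", i, "n_sv < 1")
    bad <- which(!is.na(sv$length_bp) & sv$length_bp < 0)
    for (i in head(bad, 20)) add("sv_clusters", i, "negative length_bp")
  }
  drv <- ds$drivers
  if (!is.null(drv)) {
    bad <- which(is.na(drv$gene) | drv$gene == "")
    for (i in head(bad, 20)) add("drivers", i, "empty gene")
    bad <- which(is.na(drv$driver_likelihood) | drv$driver_likelihood < 0 |
                   drv$driver_likelihood > 1)
    for (i in head(bad, 20)) add("drivers", i, "driver_likelihood outside [0, 1]")
    bad <- which(!drv$alteration_type %in% .cohort_enums$alteration_type)
    for (i in head(bad, 20)) add("drivers", i, sprintf("invalid alteration_type '%s'",
                                                       drv$alteration_type[i]))
  }
  arm <- ds$arm_definitions
  if (!is.null(arm)) {
    bad <- which(!arm$arm %in% .cohort_enums$arm)
    for (i in bad) add("arm_definitions", i, sprintf("invalid arm '%s'", arm$arm[i]))
    for (ch in unique(arm$chrom)) {
      idx <- which(arm$chrom == ch)
      o <- idx[order(arm$start[idx])]
      if (length(o) > 1) {
        ov <- which(arm$start[o][-1] < arm$end[o][-length(o)])
        for (j in ov) add("arm_definitions", o[j + 1],
                          sprintf("overlapping arms on chromosome %s", ch))
      }
    }
  }
  prof <- ds$signature_profiles
  if (!is.null(prof)) {
    sums <- tapply(prof$prob, prof$name, sum)
    bad <- names(sums)[abs(sums - 1) > 1e-6]
    for (nm in bad) add("signature_profiles", "-",
                        sprintf("profile '%s' does not sum to 1", nm))
  }
  if (length(issues) == 0) {
    tibble(table = character(0), row = character(0), problem = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Write a cohort dataset to TSV files
#'
#' Inverse of [read_cohort()]: writes every table in the dataset as
#' `<table>.tsv` under `dir`, with the documented column order, so that
#' `read_cohort(write_cohort(ds))` round-trips to an identical dataset.
#'
#' @param ds A `cohort_dataset`.
#' @param dir Output directory (created if missing).
#' @return The named vector of written file paths, invisibly.
#' @export
write_cohort <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (tb in names(ds)) {
    if (!is.data.frame(ds[[tb]])) next
    path <- file.path(dir, paste0(tb, ".tsv"))
    df <- ds[[tb]]
    if (tb %in% names(.schemas)) df <- df[, names(.schemas[[tb]])]
    readr::write_tsv(df, path, progress = FALSE)
    out[tb] <- path
  }
  invisible(out)
}

#' Write a result table as TSV
#'
#' Deterministic serialisation for comparison outputs: fixed column order
#' (as given), floats at fixed precision, so re-serialising a parsed output
#' file is byte-identical.
#'
#' @param results A data frame (may have zero rows; a header-only file is
#'   written).
#' @param path Output file path.
#' @param digits Significant digits for floating-point columns (default 6).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 6) {
  if (is.null(results)) stop("write_results: results must be non-null")
  df <- as.data.frame(results)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                          formatC(df[[col]], digits = digits, format = "g"))
    }
  }
  readr::write_tsv(df, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults. Every value
#' corresponds to a documented decision rule (see the methods vignette);
#' [load_config()] overrides any subset from a flat key-value file.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    subclonal_threshold = 0.8,     # subclonal likelihood at/above => subclonal
    clonality_q = 0.05,            # BH-adjusted significance, clonality
    biopsy_min_per_group = 5,      # min samples per biopsy-site group
    arm_q = 0.01,                  # BH-adjusted significance, per-arm test
    arm_diff_threshold = 0.25,     # |mean normalized arm ploidy difference| must exceed
    instability_q = 0.01,          # BH-adjusted significance, instability indicators
    loh_minor_max = 0.25,          # LOH: minor allele CN strictly below
    loh_major_min = 0.8,           # LOH: major allele CN at/above
    wgd_min_autosomes = 10,        # WGD: strictly more autosomes than this ...
    wgd_cn_threshold = 1.5,        # ... with chromosome CN strictly above this
    cosine_match_threshold = 0.85, # signature-to-reference match floor
    linkage = "average",           # hierarchical clustering linkage
    log2fc_threshold = 0.4,        # absolute-contribution log2 fold change
    relative_diff_threshold = 0.01,# relative-contribution median difference
    hypermutator_sbs = 10000,      # hypermutator flag thresholds (at/above)
    hypermutator_dbs = 500,
    hypermutator_id = 1000,
    hypermutator_min_samples = 5,  # min hypermutators in either cohort to test
    signature_q = 0.05,            # Holm-adjusted significance, exposures
    tmb_exclude_above = 30000,     # clock regression: drop TMB strictly above
    sbs1_exclude_above = 5000,     # clock regression: drop SBS1 strictly above
    clock_n_boot = 100,            # subsampled regressions per fit
    clock_subsample_frac = 0.75,   # fraction of samples per regression
    clock_min_points = 20,         # minimum points to fit
    clock_r_gate = 0.1,            # Pearson r both cohorts must exceed
    clock_p_threshold = 0.01,      # Mann-Whitney residual-shift threshold
    fc_age_min = 40,               # fold-change averaging age range
    fc_age_max = 80,
    fc_literal_divisor = FALSE,    # TRUE reproduces the printed 1/40 coefficient
    sv_small_max_bp = 10000,       # DEL/DUP below this are "small"
    sv_complex_large_min = 20,     # complex clusters at/above this many SVs are "large"
    sv_q = 0.05,                   # Bonferroni-adjusted significance, SV burden
    sv_fc_high = 1.2,              # fold change at/above => significant (with q)
    sv_fc_low = 0.8,               # fold change at/below => significant (with q)
    lm_regression_p = 0.01,        # combined-LM overall F-test threshold
    lm_coef_p = 0.01,              # coefficient p threshold (all three LMs)
    lm_gene_min_combined = 15,     # gene-status features need >= this many TRUE (combined)
    lm_gene_min_cohort = 10,       # ... (cohort-specific)
    lm_bool_min_frac = 0.05,       # remaining boolean features need >= 5% TRUE
    driver_likelihood_min = 0.5,   # drivers strictly above are retained
    driver_q = 0.01,               # BH-adjusted significance, driver tests
    driver_min_mutated = 5,        # min mutated samples in either cohort
    ted_min_patients = 10,         # treatment/cancer-type group size gate
    ted_q_coding = 0.05,           # BH threshold, coding + CN candidates
    ted_q_noncoding = 0.1,         # BH threshold, non-coding candidates
    ted_noncoding_min_mutated = 3, # non-coding candidates need >= 3 mutated
    ted_exclusive_max_freq = 0.05, # untreated frequency strictly below => exclusive
    cn_amp_diff = 2.5,             # gene ploidy must exceed sample mean by more than this
    cn_del_ploidy = 0.3,           # gene ploidy strictly below => deleted
    mw_exact_max = 12,             # exact Mann-Whitney path limit
    arm_tie_break = "lower"        # modal arm ploidy coverage tie: lower/higher CN
  )
}

#' Load a flat key-value configuration file
#'
#' Lines of the form `key: value` (or `key = value`); `#` starts a
#' comment. Unset keys take the defaults from [default_config()]; unknown
#' keys are an error listing the valid keys.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop(sprintf("load_config: cannot parse line '%s'", ln))
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(cfg)) {
      stop(sprintf("load_config: unknown key '%s'; valid keys: %s", key,
                   paste(sort(names(cfg)), collapse = ", ")))
    }
    cfg[[key]] <- parse_config_value(val, cfg[[key]])
  }
  cfg
}

parse_config_value <- function(val, default) {
  if (is.logical(default)) {
    lv <- toupper(val) %in% c("TRUE", "T", "YES", "1")
    return(lv)
  }
  if (is.numeric(default)) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop(sprintf("load_config: expected a number, got '%s'", val))
    return(num)
  }
  val
}

#' Chromosome-arm coordinate table (GRCh37, autosomes)
#'
#' Cytoband-derived arm boundaries for the 22 autosomes, 0-based half-open,
#' with the five acrocentric short arms (13p, 14p, 15p, 21p, 22p) omitted —
#' the standard 39-arm convention for aneuploidy scoring. Shipped as a
#' replaceable TSV; pass your own table to use different coordinates or a
#' different reference build.
#'
#' @param path Optional path to a custom arm-definition TSV (`chrom`,
#'   `arm`, `start`, `end`); defaults to the shipped table.
#' @return A tibble of arm definitions.
#' @export
arm_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arm_definitions_grch37.tsv",
                        package = "metprime", mustWork = TRUE)
  }
  read_one_table(path, "arm_definitions")
}

#' Total genome length implied by an arm table
#'
#' Sum of arm widths; used as the denominator of the LOH fraction.
#'
#' @param arms An arm-definition tibble (default: the shipped table).
#' @return Total length in base pairs.
#' @export
genome_length <- function(arms = arm_definitions()) {
  sum(arms$end - arms$start)
}
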