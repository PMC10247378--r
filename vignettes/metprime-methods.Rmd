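---
title: "Methods: comparing primary and metastatic tumour cohorts with metprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing primary and metastatic tumour cohorts with metprime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metprime` compares a primary and a metastatic whole-genome tumour cohort
from per-sample tabular summaries. This vignette documents the models and
procedures, the tunable parameters and why their defaults are what they
are, the numerical decisions, what the synthetic generator does and does
not emulate, and the known limitations. All thresholds live in
`default_config()` and can be overridden from a flat key-value file.

## Data model

Every stage consumes and produces typed tables (tibbles), cross-linked on
`sample_id`, so stages are independently testable. Coordinates are
**0-based half-open** throughout — including all TSVs — so a length is
always `end - start`; this differs from the 1-based convention of most
upstream somatic pipelines and is stated here prominently for that
reason. `read_cohort()` validates every documented invariant (unique ids,
value ranges, segment non-overlap per sample and chromosome,
pyrimidine-centred SBS contexts, foreign keys) and reports *all*
violations with row numbers rather than stopping at the first.

## Statistical primitives

Cohort contrasts use the two-sided Mann–Whitney U test for ordinal
quantities and Fisher's exact test for binary ones. The Mann–Whitney
p-value is exact (enumeration of the null rank distribution) when the
pooled sample size is at most `mw_exact_max = 12` with no ties, and the
normal approximation with continuity and tie correction otherwise; the
exact-path bound keeps the enumeration cheap while covering every case
the test suite cross-checks against a brute-force oracle. Whether the
original analyses used exact or asymptotic p-values is not something the
procedure definitions pin down; both are available and the asymptotic
path is the default above n = 12. The Fisher two-sided p follows the
"probability at most that of the observed table" convention; the reported
odds ratio is the sample cross-product estimate, reported as `Inf` when a
denominator cell is zero rather than Haldane-corrected, because no
correction is part of the procedure being reproduced. Effect sizes are
Cliff's delta for numeric comparisons and Cramér's V signed by the
direction of the odds ratio for 2×2 tables, both oriented so positive
means metastatic-enriched. Multiple-testing corrections (BH, Holm,
Bonferroni) wrap `p.adjust` and each stage uses the correction its
procedure specifies. Signature refitting uses non-negative least squares
(`pracma::lsqnonneg`); silhouette widths come from `cluster::silhouette`
with singleton clusters contributing 0.

## Clonality

A mutation is subclonal when its subclonal likelihood is ≥ 0.8
(`subclonal_threshold`). The clonal fraction of a sample is the clonal
share of its SBS, MNV and ID records. Samples with no qualifying
mutations are excluded rather than assigned 0 or 1 — the fraction of an
empty set is undefined. Per cancer type, clonal fractions are compared
with Mann–Whitney tests, BH-corrected across cancer types
(`clonality_q = 0.05`); biopsy-site contrasts (local / lymph / distant)
are pairwise among groups with at least `biopsy_min_per_group = 5`
samples and reported unadjusted by default (single pairwise contrasts are
the reporting convention here), with BH available via a flag.

## Karyotype and genomic instability

Arm-level ploidy is the integer copy number with the highest base
coverage across the arm, after rounding each segment's purity-adjusted
total CN to the nearest integer. Numerical choices: rounding is
half-away-from-zero (2.5 → 3), deterministic and consistent with common
CN practice; a coverage tie breaks toward the lower CN (conservative
against calling gains; `arm_tie_break`). The observed genome ploidy is
the most recurrent arm ploidy; a tie there resolves toward the value
nearest the segment-length-weighted mean ploidy. Expected genome ploidy
is 2 without WGD, 4 with WGD below observed ploidy 6, and 8 at 6 or more;
observed ploidies above 8 are rejected as out of the supported range.
Normalised arm classes are the sign-thresholded difference (±1 at |diff|
≥ 1). Per-arm cohort tests run on the classes (matching how mean
gains/losses are summarised), with a flag for raw arm ploidies;
significance needs q < `arm_q = 0.01` *and* a mean class difference
strictly greater than `arm_diff_threshold = 0.25`.

The four instability indicators are the aneuploidy score (arms deviating
from expected ploidy), the LOH fraction (summed length of segments with
minor CN < 0.25 and major CN ≥ 0.8 over the genome length implied by the
arm table), the WGD call, and TP53 driver status (any retained driver
event in TP53, counted once). The WGD call requires strictly more than 10
autosomes with chromosome-level CN strictly above 1.5; the
chromosome-level CN is the length-weighted mean of the **major-allele**
copy number. This is a deliberate design choice: applied to total copy
number the 1.5 threshold is exceeded by every normal diploid chromosome
and the rule could not discriminate, whereas on major-allele ploidy a
diploid chromosome sits near 1 and a duplicated one near 2.
`chromosome_cn()` exposes the total-CN variant for other uses.

## Mutational signatures

De novo profiles (consumed, not extracted — NMF is out of scope) are
matched to a reference catalog by cosine similarity with an inclusive
floor of `cosine_match_threshold = 0.85`; unmatched profiles are grouped
by agglomerative hierarchical clustering on cosine distance, cutting the
tree at every k from 2 to n−1 and keeping the k with maximal mean
silhouette (smallest k on ties, so the choice is deterministic). The
linkage method is not pinned down by the procedure being reproduced;
average linkage is the default (standard for signature profiles), with
complete and Ward-on-Euclidean available. The silhouette uses the same
cosine distance as the clustering. If all profiles are numerically
identical the silhouette is undefined and a single cluster is returned
with a warning. Manual aetiology curation is a user-editable mapping
table, not code.

Exposure comparisons operate on aetiology contributions (exposures summed
within mutation type and aetiology; samples without the process count as
zeros). Absolute contributions: Mann–Whitney per aetiology, Holm within
each cancer type × mutation type family, effect
`log2((median_met + 1)/(median_pri + 1))` (pseudocount 1 to avoid
dividing by zero), significant at q < 0.05 and |log2 fc| ≥ 0.4. The 0.4
log2 threshold is taken as normative (its "×1.4" gloss does not equal
2^0.4 and is ignored). Relative contributions divide by the sample's
total of the same mutation type (samples with total 0 excluded) and gate
on a median difference of at least 0.01. Hypermutators are flagged at
contributions ≥ 10,000 (SBS), ≥ 500 (DBS) or ≥ 1,000 (ID); the Fisher
test runs only where either cohort has at least 5 hypermutators, with
Bonferroni correction across the performed tests.

## Clock-like SBS1 regression

SBS1 mutations are C>T at ACG, CCG and GCG contexts; TCG is always
excluded (it is also an APOBEC-characteristic channel) and CCG is
additionally excluded in skin melanoma (UV overlap). Samples with TMB
strictly above 30,000 or SBS1 strictly above 5,000 are excluded. Per
cancer type and cohort, 100 OLS regressions of count on age are fitted on
random 75% subsamples **without replacement** (the procedure subsamples,
it does not bootstrap with replacement), and the fit with the median
slope is the representative regression — the lower median for even
counts, so the representative line is always an actually fitted one.
Confidence bands come from the fits at the 1st and 99th slope
percentiles; collinear input therefore yields a zero-width band. The fit
is deterministic given its seed. The Pearson r attached to a fit is
computed on the representative fit's own subsample.

The cohort comparison gates on both cohorts showing r > 0.1, compares
residuals of both cohorts **against the primary fit** by Mann–Whitney
(p < 0.01), and additionally requires the metastatic intercept to exceed
the primary one, which guards against a shift driven by one extreme age
range. A consequence worth knowing: when the true intercept is near zero
and the rate difference is purely multiplicative, the fitted intercept
ordering is a coin flip and roughly half of genuinely shifted cohorts
fail the guard — visible in the README example. The fold-change and
burden-difference summaries average the per-age prediction ratio and
difference over integer ages 40–80. That range has 41 terms; the printed
form of the defining equations carries a 1/40 coefficient, but since the
quantity is described as a mean, the default divides by the number of
terms (41), and `literal_divisor = TRUE` reproduces the printed 1/40.
Ploidy-corrected variants divide counts by genome ploidy, which commutes
with fitting (a tested invariant). SBS5/SBS40 analyses reuse the same
operations with counts replaced by summed exposures, zero when nothing
was attributed; individual SBS5/SBS40 mutations are assigned by maximum
likelihood (exposure × channel probability, lexicographic tie-break). The
per-year SBS1 rate uses age at biopsy and the same hypermutator
exclusions.

## Structural variants

Clusters resolve to seven types: intrachromosomal DEL/DUP split at 10 kb
(small strictly below), complex (COMPLEX plus all inversion and
translocation resolved types) split at 20 chained SVs (large at or
above), and LINE. Anything else — including interchromosomal DEL/DUP —
is unclassified and excluded from the counts and total. Burden tests are
Mann–Whitney with Bonferroni across all cancer type × SV type tests;
enrichment and fold change use pseudocount-1 medians, with a ">" flag
when the primary median is 0; significance needs q < 0.05 and fold change
≥ 1.2 or ≤ 0.8.

The feature screen fits three OLS models of log10(burden + 1) — combined,
metastatic-only, primary-only — per (cancer type, SV type) pair whose
burden comparison showed a significant metastatic increase. Gene-status
booleans need ≥ 15 TRUE samples in the combined fit and ≥ 10 in the
cohort fits; remaining booleans need ≥ 5% TRUE; numeric features
(genome ploidy, treatment count) are never prevalence-filtered and enter
unstandardised by default (standardising changes coefficients, not signs
or p-values). "Regression P" is the combined model's overall F-test;
cohort-specific fits are filtered on coefficients alone. Rank-deficient
designs drop aliased columns with a warning — with few treatment
mechanisms the treatment count is exactly collinear with the mechanism
booleans, so this warning is expected on small synthetic cohorts. A
feature explains the metastatic increase when it passes the combined
filters (overall p < 0.01, coefficient p < 0.01, coefficient > 0), passes
either cohort-specific fit, and has a metastatic-leaning effect size.

## Drivers and treatment-enriched drivers

Driver counts retain events with likelihood strictly above 0.5 and count
a gene once regardless of how many alteration types hit it. Per-gene
enrichment folds partial amplifications into amplifications and
homozygous disruptions into deletions, requires at least 5 mutated
samples in either cohort, and BH-corrects within cancer type (q < 0.01).

Treatment groups pair a cancer type with a treatment mechanism and must
hold at least 10 patients; a patient with several therapy lines belongs
to several groups. The untreated comparison group is the
treatment-annotated metastatic patients of the same cancer type who did
not receive the tested mechanism; a strict variant (fully untreated
patients only) is available via a flag. Candidate elements default to a
frequency-based discovery stand-in — genes altered in at least 3 treated
samples — because the original discovery tools (dN/dS, non-coding driver
and CN-peak callers) are out of scope; externally produced candidate
lists plug in directly and are the faithful-reproduction path. Note the
stand-in selects candidates on the same counts it then tests, which
inflates the realised false-discovery rate relative to an independent
discovery step; the calibration tests therefore use the plug-in path.
The TED test itself is Fisher per element with BH within category
(threshold 0.05 for coding and CN variants, 0.1 for non-coding, which
additionally need 3 mutated samples), and labels significant elements
treatment-exclusive when the untreated frequency is strictly below 5%.
Focal CN status calls a gene amplified when its ploidy exceeds the sample
mean by strictly more than 2.5 and deleted below 0.3; both boundaries are
read strictly and are configurable. Overlapping CN peaks merge per cancer
type and direction, keeping the lowest-q member's gene and treatment.
Per-gene multiplicity across treatment groups resolves to the most
significant association unless a curated literature pairing pins one.
The group-level recount removes catalogued TEDs (by cancer type, gene and
category) and recomputes per-cohort mean drivers per sample.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, with every injected effect recorded as ground truth. Its
defaults are fixed study conditions, chosen once: metastatic cohorts are
more clonal (0.93 vs 0.87, beta-concentrated), carry more WGD (0.50 vs
0.25) and arm events (0.10 vs 0.06 per arm), an SBS1 fold change of 1.5
on a slope of 4 mutations/year with Gaussian noise (sd 30), a
therapy-linked mutagenic exposure, higher SV burden (log10-mean shifts of
0.2–0.3), and one driver gene with an injected odds ratio of 8 under
hormonal therapy. Mutation contexts are generated directly as channel
labels from the signature profiles — every downstream computation
consumes channels, and genomic positions are drawn uniformly only to
satisfy the schema. SV counts are negative-binomial (overdispersion is
evident in real SV burden distributions) with log10(mean + 1) linear in
the sample's features, which makes the three-LM response model exactly
well-specified. Each sample's draws come from an RNG stream derived by
hashing its id with the master seed, so adding samples never perturbs
existing ones and output is insertion-order independent.

The shipped reference catalog is synthetic: profiles are shaped to
exercise the decision rules (an SBS1-like profile concentrated on the
counted CpG>TpG channels, a flat clock-like background that is zero on
all NpCpG C>T channels so SBS1 counts stay identifiable, APOBEC-, UV- and
platinum-like shapes). Doublet mutations are emitted with variant class
MNV so they count toward total mutation burden, while their context
counts use the 78 DBS channels.

Focused generators back the acceptance studies: `simulate_clock_cohort()`
(uniform ages 30–80, mean count `fold_change × (slope × age + intercept)`
with a default intercept of 50 — a positive baseline burden present at
age zero, under which a multiplicative rate shift also shifts the fitted
intercept and the intercept guard has power), `simulate_sv_lm_cohort()`
(an effect feature with higher metastatic prevalence, an optional
cohort-confounded null feature plus an unmodelled cohort shift, and null
gene features), `simulate_ted_cohort()` and
`simulate_exposure_cohort()`.

What the generator does **not** emulate: linkage of SVs to copy-number
segments, breakpoint mechanics, kataegis/clustered mutagenesis,
signature-by-age interactions, multi-biopsy patients, or realistic
cancer-type-specific signature repertoires. Passing tests therefore show
that the procedures recover what they claim under their own model
assumptions — not that those assumptions hold in real cohorts.

## Problem sizes and test design

The test suite verifies the exact tests against brute-force enumeration
(every 2×2 table with total ≤ 40; every rank split with pooled n ≤ 12),
every decision threshold on both sides of its boundary, and the
simulation-backed stages at the sizes the studies specify: clock-rate
recovery at 250 samples per cohort over fold changes 1.0–2.0 (20 seeds
per level, estimates within ±0.1 of truth), the three-LM screen at 400
samples with a +0.3 log10 coefficient, the TED test at 40 treated vs 200
untreated patients with an odds ratio of 8, and exposure-comparison null
calibration at 60 samples per cohort. The end-to-end examples use 40–80
samples per cohort, enough for the injected effects to be comfortably
detectable while keeping the full suite fast.

## Known limitations

- The pipeline consumes upstream calls as given: no purity/ploidy
  refitting, no subclonal reconstruction, no SV calling, no NMF signature
  extraction, no dN/dS-style driver discovery.
- The frequency-based TED candidate stand-in is anti-conservative (see
  above); use externally discovered candidates for calibrated FDR.
- The shipped arm table is a GRCh37 cytoband-derived approximation
  (autosomes, 39 arms); replace it for other builds or finer boundaries.
- The synthetic reference catalog is not a real signature catalog;
  analyses of real cohorts should supply one together with a curated
  aetiology map.
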