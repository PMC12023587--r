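---
title: "One-step NGS molecular subtyping of endometrial carcinoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step NGS molecular subtyping of endometrial carcinoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsubtype)
```

## The classification problem

Endometrial carcinomas fall into four prognostic molecular groups — POLE
(ultramutated), MSI-H (hypermutated), copy-number high (CNH, serous-like,
TP53-driven) and copy-number low (CNL, endometrioid). The established
surrogates (ProMisE, TransPORTEC) need immunohistochemistry *plus*
sequencing; a single targeted NGS panel measuring POLE, TP53 and
microsatellite instability can deliver the same stratification in one assay.
`ecsubtype` implements that classifier and the analysis layers built on top
of it: cohort summarization, survival stratification, classifier
concordance, and biomarker sub-stratification of the CNL/MSI-H group.

The hierarchy is strict and total:

1. **POLE** — a pathogenic POLE variant is present (a curated
   exonuclease-domain hotspot, or any nonsynonymous exonuclease-domain
   variant accompanied by an ultramutated burden);
2. otherwise **MSI-H** — hypermutation in the context of microsatellite
   instability;
3. otherwise (MSI-L and MSS are deliberately pooled) the copy-number branch
   assigns **CNH** or **CNL**.

Samples whose decisive markers cannot be evaluated (e.g. no scoreable
microsatellite locus) are reported as `UNCLASSIFIABLE` rather than dropped
or guessed: real clinical inputs have missing layers even though a complete
study cohort may not.

## Marker derivation and its tunable parameters

All thresholds live in `caller_config()` and are serializable to JSON; the
defaults are the package's documented operating point.

* **VAF filter** (`vaf_min`, default 0.05): variants below 5% allele
  fraction are ignored everywhere, matching the panel's validated
  sensitivity. Per-gene overrides (`gene_vaf_min`) accommodate hotspot
  assays validated to 1%.
* **TMB** (`panel_size_mb`, default 1.5 Mb): nonsynonymous, VAF-passing
  variants per megabase of panel territory. TMB operationalizes the
  *ultramutated* (default ≥ 100 mut/Mb) and *hypermutated* (default
  ≥ 10 mut/Mb) notions; both are conventional panel cutoffs and both are
  exposed because the underlying concepts, not the numbers, are fixed by the
  classification scheme.
* **POLE** (`pole_pathogenic_list`): ships the recurrent exonuclease-domain
  hotspots (P286R, V411L, S297F, A456P, S459F, F367S, L424I, M295R, P436R,
  M444K, D368Y). The list is user-overridable; the ultramutated clause
  (exonuclease-domain nonsynonymous variant + TMB ≥ `tmb_ultra_threshold`)
  catches pathogenic variants absent from any fixed list.
* **MSI** — each panel locus carries a baseline read-length histogram and an
  observed histogram. The locus-level score is the *novel-read fraction*:
  reads at lengths whose baseline probability is below
  `baseline_support_floor` (default 0.01), divided by total reads. A locus
  is unstable when this fraction strictly exceeds `msi_novel_length_tau`
  (default 0.10). Sample level: MSI-H requires an unstable-locus fraction
  ≥ 0.30 *and* TMB ≥ `tmb_hyper_threshold`; MSI-L requires ≥ 0.10; MSI-L is
  pooled with MSS by the classifier. This deterministic surrogate was chosen
  over distributional tests for testability: it is invariant to rescaling
  read counts and has explicit tie-breaks (strict `>` at the locus boundary,
  `>=` at sample-level fractions). Whether an MSI-H call should itself
  require hypermutation is genuinely open; setting `tmb_hyper_threshold = 0`
  makes instability alone sufficient.
* **Copy number** — the fraction of panel territory altered (FGA) is the
  length-weighted share of bases in segments with |log2 ratio| >
  `fga_log2_threshold` (default 0.3). The production algorithm behind the
  CNH/CNL split in the assay this package models is unpublished, so the
  package defines a reproducible rule: under `cn_rule = "tp53_or_fga"`
  (default) a sample is CNH when TP53 is mutated or FGA ≥ 0.2; under
  `"tp53_only"` the TP53 call alone decides. The default reflects the
  serous-like, TP53-driven character of CNH while letting a strongly
  aneuploid TP53-wild-type sample still reach CNH.

## Survival and concordance layers

Kaplan–Meier estimation, the k-group log-rank test and Cox regression are
delegated to the `survival` package; `ecsubtype` fixes the conventions and
the derived summaries:

* time unit is months; the reporting horizon is 120 months (10 years);
* KM bands are Greenwood-variance, log-log 95% intervals;
* the horizon rate is the estimate at the last event time at or before the
  horizon; the median is the smallest time with the estimate at or below
  0.5, else "not reached";
* Cox uses Efron tie handling by default (Breslow by flag), Wald intervals,
  a complete-case rule for missing covariates, and an explicit convergence
  flag (degenerate inputs — constant covariates, fewer subjects than
  covariates — are errors, not silent output);
* for the multivariate overall-survival model, `encode_cox_covariates()`
  dichotomizes age at 55, binarizes stage I–II vs III–IV, codes LVSI yes/no
  and uses CNL (the largest group) as the subtype reference;
* no multiple-testing correction is applied anywhere.

Agreement between two classifications is summarized by overall accuracy and
Cohen's kappa, with percentile-bootstrap 95% intervals over 1000 paired
resamples by default. Resampling is by subject index from a single seeded
stream: the point statistics are order-invariant, but the bootstrap draws
depend on input order by construction — the seed plus the input file define
the result. Bias-corrected (BCa) intervals are out of scope.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage can be validated
end-to-end without patient data. Its defaults *are* the emulated study
conditions: 233 samples at proportions 19/44/27/143; per-subtype log-normal
burden (medians 200 / 40 / 5 / 5 mut/Mb, sdlog 0.4); MSI-H unstable-locus
fractions drawn from 0.40–0.70 against a 1% background; TP53 planted in
every CNH sample and as a passenger in 30% of POLE/MSI-H samples; planted
FGA 0.30–0.60 for CNH vs 0–0.08 otherwise; exponential survival laws
calibrated so the CNH median is 35 months and POLE 120-month survival is
~100%; administrative censoring uniform on 7–122 months (median follow-up
~66); overall survival available for 131/233 of samples and DSS for 126 of
those; and ARID1A/ZFHX4 mutation flags inside CNL/MSI-H with planted hazard
ratios (defaults 2 and 4).

What the generator deliberately does **not** emulate: sequencing error and
UMI structure, germline contamination, intra-tumor heterogeneity in VAFs,
correlated missingness between layers, non-exponential hazards (a Weibull
shape could be added but only medians/rates are published), and real
locus-specific microsatellite baselines. A passing end-to-end test therefore
demonstrates that the *pipeline logic* is correct under clean evidence, not
that the classifier is robust to assay noise.

Generated marker evidence is intentionally unambiguous (e.g. unstable loci
put ~40% of reads at novel lengths against a 10% threshold), so planted
labels are recoverable essentially perfectly; the acceptance suite requires
≥ 99% recovery at n = 1000. Two property tests (log-rank power on a planted
hazard ratio, Cox recovery of a planted log-hazard) override the survival
defaults to an event-rich setting (10-year survival 0.35 in CNL/MSI-H, full
OS availability) because at the study's own event rates those sample sizes
would not carry enough events to estimate the effect precisely — a property
of the data, not of the implementation under test.

## Fixtures

Two deterministic fixtures rebuild the emulated study's printed composition
in code (no data files):

* `load_fixture("table1")` — 233 samples whose subtype labels and
  stage/grade/histology/LVSI cross-tabs match the printed table cell for
  cell; ages reproduce the printed per-subtype moments only (exact shapes
  are unknown, so normal quantiles clamped to the printed ranges are used);
  survival columns are left missing because per-patient follow-up is
  unpublished. Each sample carries minimal molecular evidence consistent
  with its label, so `classify_cohort()` reproduces the printed counts
  (19/44/27/143) rather than taking them on faith.
* `load_fixture("fig4")` — the 39-sample CNL/MSI-H comprehensive-panel
  subset. Its integer composition is *derived*, not assumed:
  `derive_fig4_composition()` searches all deceased/surviving splits of 39
  for counts consistent with the printed one-decimal frequencies (ARID1A
  53.8% vs 30.8%, ZFHX4 30.8% vs 0%) and the statement that exactly four
  ZFHX4 mutations occurred, all in deceased cases. The solution is unique:
  13 deceased / 26 surviving, ARID1A in 7 and 8, ZFHX4 in 4 and 0.

## Numerical conventions and degenerate inputs

* Percentages are rounded half away from zero (`round_half_up()`), two
  decimals for cohort composition, one decimal for biomarker frequencies,
  always against the full-cohort denominator (unknown categories are their
  own level inside the total).
* Copy-number segments are 0-based half-open (BED convention); variant
  positions are 1-based (VCF convention).
* A sample with zero variant rows is a valid "no somatic calls" profile
  (TMB 0, POLE/TP53 negative); a sample with zero scoreable microsatellite
  loci is *not* evaluable and becomes `UNCLASSIFIABLE`; a sample with no
  segments has FGA 0 (the copy-number rule can still run off TP53).
* Baseline histograms must sum to 1 (tolerance 1e-9); zero-read loci are
  skipped with a warning and excluded from the unstable-fraction
  denominator.
* Writers/readers canonicalize column types so a written cohort reloads with
  every field identical.

## Problem sizes used by the validation suite

The shipped tests run the type-I-error study of the log-rank test at 2000
null replicates (two arms of 100), Cox parameter recovery at n = 2000 with
~20% censoring, end-to-end label recovery at n = 1000, bootstrap-coverage
of the kappa interval at 500 replicates of n = 100 with 1000 resamples each,
and the biomarker power study at n = 400 over 40 replicates. These sizes
give comfortable Monte-Carlo margins for the tested bands while keeping the
whole suite around a minute of CPU.

## Known limitations

* The CNH/CNL rule is a published-evidence surrogate for an unpublished
  production algorithm; concordance with that algorithm cannot be asserted.
* The MSI locus scorer assumes baseline histograms are well calibrated;
  systematic baseline shift would inflate novel-read fractions.
* Survival defaults assume proportional hazards and exponential baselines;
  the package reports no proportional-hazards diagnostics.
* Multivariate hazard-ratio estimates from the emulated study cannot be
  reproduced without patient-level data; the package validates its survival
  stack by simulation and closed-form oracles instead.
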