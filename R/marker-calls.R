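## Per-sample marker derivation: POLE status, TP53 status, tumor mutational
## burden, MSI status from read-length histograms, and fraction of panel
## territory altered (FGA). These markers feed the hierarchical classifier.

#' Default pathogenic POLE exonuclease-domain hotspots
#'
#' Recurrent pathogenic exonuclease-domain changes commonly accepted as
#' classifier-qualifying; overridable via [caller_config()].
#'
#' @return character vector of protein changes.
#' @export
pole_hotspots <- function() {
  c("p.P286R", "p.V411L", "p.S297F", "p.A456P", "p.S459F",
    "p.F367S", "p.L424I", "p.M295R", "p.P436R", "p.M444K", "p.D368Y")
}

#' Marker-caller configuration
#'
#' Thresholds driving marker derivation. Every value is overridable; the
#' defaults are documented tie-breaks: locus-level instability uses a strict
#' `>` at the boundary, sample-level fractions use `>=`.
#'
#' @param vaf_min minimum variant allele fraction for a call to count
#'   (panel sensitivity; default 0.05).
#' @param pole_pathogenic_list protein changes accepted as pathogenic POLE
#'   variants; default [pole_hotspots()].
#' @param pole_edm_range residue range of the POLE exonuclease domain used by
#'   the ultramutated clause (default 268-471).
#' @param tmb_ultra_threshold TMB (mut/Mb) above which a nonsynonymous POLE
#'   exonuclease-domain variant is treated as pathogenic (default 100).
#' @param tmb_hyper_threshold TMB required alongside locus instability for an
#'   MSI-H call (default 10).
#' @param msi_novel_length_tau fraction of reads at novel repeat lengths above
#'   which a locus is unstable (strict inequality; default 0.10).
#' @param baseline_support_floor baseline probability below which a repeat
#'   length counts as novel (default 0.01).
#' @param msi_h_locus_fraction,msi_l_locus_fraction unstable-locus fractions
#'   for MSI-H / MSI-L (defaults 0.30 / 0.10; `>=` at the boundary).
#' @param fga_log2_threshold |log2 ratio| above which a segment is altered
#'   (default 0.3).
#' @param fga_cnh_threshold FGA at or above which a sample is CNH under the
#'   `tp53_or_fga` rule (default 0.2).
#' @param cn_rule `"tp53_or_fga"` (default) or `"tp53_only"`.
#' @param panel_size_mb megabases of panel territory used as TMB denominator
#'   (default 1.5).
#' @param gene_vaf_min optional named list of per-gene VAF overrides used for
#'   gene-level mutation calls (hotspot vs non-hotspot sensitivity).
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(vaf_min = 0.05,
                          pole_pathogenic_list = pole_hotspots(),
                          pole_edm_range = c(268L, 471L),
                          tmb_ultra_threshold = 100,
                          tmb_hyper_threshold = 10,
                          msi_novel_length_tau = 0.10,
                          baseline_support_floor = 0.01,
                          msi_h_locus_fraction = 0.30,
                          msi_l_locus_fraction = 0.10,
                          fga_log2_threshold = 0.3,
                          fga_cnh_threshold = 0.2,
                          cn_rule = c("tp53_or_fga", "tp53_only"),
                          panel_size_mb = 1.5,
                          gene_vaf_min = list()) {
  cn_rule <- match.arg(cn_rule)
  cfg <- list(vaf_min = vaf_min,
              pole_pathogenic_list = pole_pathogenic_list,
              pole_edm_range = as.integer(pole_edm_range),
              tmb_ultra_threshold = tmb_ultra_threshold,
              tmb_hyper_threshold = tmb_hyper_threshold,
              msi_novel_length_tau = msi_novel_length_tau,
              baseline_support_floor = baseline_support_floor,
              msi_h_locus_fraction = msi_h_locus_fraction,
              msi_l_locus_fraction = msi_l_locus_fraction,
              fga_log2_threshold = fga_log2_threshold,
              fga_cnh_threshold = fga_cnh_threshold,
              cn_rule = cn_rule,
              panel_size_mb = panel_size_mb,
              gene_vaf_min = gene_vaf_min)
  validate_caller_config(cfg)
  structure(cfg, class = "caller_config")
}

validate_caller_config <- function(cfg) {
  pos <- c("vaf_min", "tmb_ultra_threshold", "tmb_hyper_threshold",
           "msi_novel_length_tau", "baseline_support_floor",
           "fga_log2_threshold", "fga_cnh_threshold", "panel_size_mb")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || is.na(cfg[[p]]) ||
        cfg[[p]] <= 0) {
      ec_config_error(sprintf("caller config: `%s` must be a positive number", p))
    }
  }
  if (!(cfg$msi_l_locus_fraction > 0 &&
        cfg$msi_l_locus_fraction < cfg$msi_h_locus_fraction &&
        cfg$msi_h_locus_fraction <= 1)) {
    ec_config_error("caller config requires 0 < msi_l_locus_fraction < msi_h_locus_fraction <= 1")
  }
  invisible(cfg)
}

#' Serialize / restore a caller configuration as JSON
#' @param config a `caller_config`.
#' @param path file path.
#' @return `write_caller_config` returns the path invisibly;
#'   `read_caller_config` returns a `caller_config`.
#' @export
write_caller_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_caller_config
#' @export
read_caller_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$gene_vaf_min <- as.list(raw$gene_vaf_min %||% list())
  do.call(caller_config, raw)
}

## ---------------------------------------------------------------------------
## Individual marker calls

#' Tumor mutational burden
#'
#' Nonsynonymous variants (missense, nonsense, frameshift, splice, in-frame
#' indel) with VAF at or above the panel sensitivity, per megabase of panel
#' territory.
#'
#' @param variants variant data frame for one sample.
#' @param config a [caller_config()].
#' @return mutations per Mb (numeric scalar, >= 0).
#' @export
compute_tmb <- function(variants, config = caller_config()) {
  if (config$panel_size_mb <= 0) ec_config_error("panel_size_mb must be > 0")
  if (is.null(variants) || !nrow(variants)) return(0)
  n <- sum(variants$consequence %in% NONSYNONYMOUS & variants$vaf >= config$vaf_min)
  n / config$panel_size_mb
}

#' POLE driver status
#'
#' A sample is POLE-positive if it carries a protein change from the
#' configured pathogenic list, or a nonsynonymous POLE exonuclease-domain
#' variant together with an ultramutated burden
#' (TMB >= `tmb_ultra_threshold`).
#'
#' @param variants variant data frame for one sample.
#' @param tmb the sample's tumor mutational burden (mut/Mb).
#' @param config a [caller_config()].
#' @return logical scalar.
#' @export
assess_pole <- function(variants, tmb, config = caller_config()) {
  if (is.null(variants) || !nrow(variants)) return(FALSE)
  v <- variants[variants$gene == "POLE" & variants$vaf >= config$vaf_min, ,
                drop = FALSE]
  if (!nrow(v)) return(FALSE)
  known <- normalize_hgvs(v$hgvs_p) %in% normalize_hgvs(config$pole_pathogenic_list)
  if (any(known)) return(TRUE)
  res <- hgvs_residue(v$hgvs_p)
  edm <- v$consequence %in% NONSYNONYMOUS & !is.na(res) &
    res >= config$pole_edm_range[1] & res <= config$pole_edm_range[2]
  any(edm) && tmb >= config$tmb_ultra_threshold
}

#' TP53 mutation status
#'
#' TRUE if any TP53 variant with a protein-altering consequence passes the
#' VAF filter.
#'
#' @inheritParams assess_pole
#' @return logical scalar.
#' @export
assess_tp53 <- function(variants, config = caller_config()) {
  if (is.null(variants) || !nrow(variants)) return(FALSE)
  any(variants$gene == "TP53" &
        variants$vaf >= config$vaf_min &
        variants$consequence %in% NONSYNONYMOUS)
}

#' Score one microsatellite locus for instability
#'
#' The novel-read fraction is the share of observed reads at repeat lengths
#' essentially unsupported by the baseline histogram (baseline probability
#' below `baseline_support_floor`, including lengths absent from the
#' baseline). The locus is unstable when that fraction strictly exceeds
#' `msi_novel_length_tau`; a fraction exactly at the threshold is stable.
#'
#' @param locus a list with `baseline_hist` and `observed_hist`, both named
#'   numeric vectors keyed by repeat length (as produced by
#'   [msi_loci_for_sample()]).
#' @param config a [caller_config()].
#' @return logical scalar.
#' @export
score_locus_instability <- function(locus, config = caller_config()) {
  base <- locus$baseline_hist
  obs <- locus$observed_hist
  if (abs(sum(base) - 1) > 1e-9) {
    ec_validation_error(sprintf("locus %s: baseline histogram does not sum to 1",
                                locus$locus_id %||% "?"))
  }
  total <- sum(obs)
  if (total <= 0) {
    ec_evaluability_error(sprintf("locus %s has no observed reads",
                                  locus$locus_id %||% "?"))
  }
  support <- base[match(names(obs), names(base))]
  support[is.na(support)] <- 0
  novel_fraction <- sum(obs[support < config$baseline_support_floor]) / total
  novel_fraction > config$msi_novel_length_tau
}

#' Microsatellite loci of one sample as scoreable objects
#' @param cohort an `ec_cohort`.
#' @param sample_id sample identifier.
#' @return list of locus objects (`locus_id`, `repeat_unit`,
#'   `baseline_hist`, `observed_hist`).
#' @export
msi_loci_for_sample <- function(cohort, sample_id) {
  rows <- cohort$msi[cohort$msi$sample_id == sample_id, , drop = FALSE]
  lapply(split(rows, rows$locus_id), function(d) {
    list(locus_id = d$locus_id[1],
         repeat_unit = d$repeat_unit[1],
         baseline_hist = stats::setNames(d$baseline_prob, d$length),
         observed_hist = stats::setNames(d$observed_count, d$length))
  })
}

#' Sample-level MSI status
#'
#' Scores each locus with [score_locus_instability()]; loci without reads are
#' skipped with a warning and excluded from the denominator. The sample is
#' MSI-H when the unstable fraction reaches `msi_h_locus_fraction` *and* the
#' burden reaches `tmb_hyper_threshold` (hypermutation in the context of
#' instability); otherwise MSI-L when the fraction reaches
#' `msi_l_locus_fraction`; otherwise MSS. Downstream classification treats
#' MSI-L together with MSS.
#'
#' @param loci list of locus objects (see [msi_loci_for_sample()]).
#' @param tmb the sample's tumor mutational burden (mut/Mb).
#' @param config a [caller_config()].
#' @return one of `"MSI-H"`, `"MSI-L"`, `"MSS"`.
#' @export
call_msi <- function(loci, tmb, config = caller_config()) {
  if (!length(loci)) ec_evaluability_error("MSI not evaluable: no scoreable loci")
  calls <- logical(0)
  for (locus in loci) {
    res <- tryCatch(score_locus_instability(locus, config),
                    ec_evaluability_error = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      NA
                    })
    if (!is.na(res)) calls <- c(calls, res)
  }
  if (!length(calls)) ec_evaluability_error("MSI not evaluable: no scoreable loci")
  msi_from_fraction(mean(calls), tmb, config)
}

msi_from_fraction <- function(unstable_fraction, tmb, config) {
  if (unstable_fraction >= config$msi_h_locus_fraction &&
      tmb >= config$tmb_hyper_threshold) return("MSI-H")
  if (unstable_fraction >= config$msi_l_locus_fraction) return("MSI-L")
  "MSS"
}

#' Fraction of panel territory altered
#'
#' Length-weighted fraction of covered bases lying in segments whose
#' |log2 ratio| strictly exceeds `fga_log2_threshold`; 0 when no segments
#' are available.
#'
#' @param segments segment data frame for one sample.
#' @param config a [caller_config()].
#' @return numeric scalar in [0,1].
#' @export
compute_fga <- function(segments, config = caller_config()) {
  if (is.null(segments) || !nrow(segments)) return(0)
  width <- segments$end - segments$start
  altered <- abs(segments$log2_ratio) > config$fga_log2_threshold
  sum(width[altered]) / sum(width)
}

#' Copy-number class from TP53 status and FGA
#'
#' Under the default `tp53_or_fga` rule a sample is CNH when TP53 is mutated
#' or FGA reaches `fga_cnh_threshold`; under `tp53_only` the TP53 call alone
#' decides. The rule reflects the serous-like, TP53-driven character of the
#' copy-number-high group.
#'
#' @param tp53_mutated logical.
#' @param fga fraction of territory altered.
#' @param config a [caller_config()].
#' @return `"CNH"` or `"CNL"`.
#' @export
classify_cn <- function(tp53_mutated, fga, config = caller_config()) {
  cnh <- if (config$cn_rule == "tp53_only") {
    isTRUE(tp53_mutated)
  } else {
    isTRUE(tp53_mutated) || (!is.na(fga) && fga >= config$fga_cnh_threshold)
  }
  if (cnh) "CNH" else "CNL"
}

## ---------------------------------------------------------------------------
## Whole-sample / whole-cohort profiles

#' Marker profile of one sample
#'
#' @param variants variant data frame for the sample.
#' @param loci list of microsatellite locus objects.
#' @param segments segment data frame for the sample.
#' @param config a [caller_config()].
#' @return an object of class `marker_profile`: `pole_positive`,
#'   `tp53_mutated`, `tmb`, `msi_status` (NA when not evaluable), `fga`.
#' @export
marker_profile <- function(variants, loci, segments, config = caller_config()) {
  tmb <- compute_tmb(variants, config)
  msi <- tryCatch(call_msi(loci, tmb, config),
                  ec_evaluability_error = function(e) NA_character_)
  structure(list(
    pole_positive = assess_pole(variants, tmb, config),
    tp53_mutated = assess_tp53(variants, config),
    tmb = tmb,
    msi_status = msi,
    fga = compute_fga(segments, config)
  ), class = "marker_profile")
}

#' @export
print.marker_profile <- function(x, ...) {
  cat(sprintf("<marker_profile> POLE=%s TP53=%s TMB=%.2f MSI=%s FGA=%.3f\n",
              x$pole_positive, x$tp53_mutated, x$tmb,
              ifelse(is.na(x$msi_status), "not evaluable", x$msi_status), x$fga))
  invisible(x)
}

#' Marker profiles for every sample in a cohort
#'
#' Vectorized equivalent of calling [marker_profile()] per sample; the two
#' paths agree exactly (property-tested).
#'
#' @param cohort an `ec_cohort`.
#' @param config a [caller_config()].
#' @return data frame: `sample_id`, `pole_positive`, `tp53_mutated`, `tmb`,
#'   `msi_status` (NA when not evaluable), `fga`, `n_msi_loci` (scoreable).
#' @export
profile_cohort <- function(cohort, config = caller_config()) {
  ids <- sample_ids(cohort)
  fid <- factor(ids, levels = ids)

  v <- cohort$variants
  pass <- v[v$vaf >= config$vaf_min, , drop = FALSE]
  nonsyn <- pass[pass$consequence %in% NONSYNONYMOUS, , drop = FALSE]
  tmb <- as.numeric(table(factor(nonsyn$sample_id, levels = ids))) / config$panel_size_mb

  pole <- pass[pass$gene == "POLE", , drop = FALSE]
  path_ids <- unique(pole$sample_id[normalize_hgvs(pole$hgvs_p) %in%
                                      normalize_hgvs(config$pole_pathogenic_list)])
  res <- hgvs_residue(pole$hgvs_p)
  edm_ids <- unique(pole$sample_id[pole$consequence %in% NONSYNONYMOUS &
                                     !is.na(res) &
                                     res >= config$pole_edm_range[1] &
                                     res <= config$pole_edm_range[2]])
  pole_positive <- ids %in% path_ids |
    (ids %in% edm_ids & tmb >= config$tmb_ultra_threshold)

  tp53_ids <- unique(pass$sample_id[pass$gene == "TP53" &
                                      pass$consequence %in% NONSYNONYMOUS])
  tp53_mutated <- ids %in% tp53_ids

  ## per-locus novel-read fractions, grouped sums over the long table
  m <- cohort$msi
  msi_status <- rep(NA_character_, length(ids))
  n_loci <- integer(length(ids))
  if (nrow(m)) {
    key <- paste(m$sample_id, m$locus_id, sep = "\r")
    tot <- rowsum(m$observed_count, key)
    nov <- rowsum(m$observed_count *
                    (m$baseline_prob < config$baseline_support_floor), key)
    sid <- sub("\r.*$", "", rownames(tot))
    scoreable <- tot[, 1] > 0
    if (any(tot[, 1] == 0)) {
      warning(sprintf("%d microsatellite locus/loci with no reads skipped",
                      sum(tot[, 1] == 0)), call. = FALSE)
    }
    unstable <- (nov[, 1] / tot[, 1]) > config$msi_novel_length_tau
    frac <- tapply(unstable[scoreable], factor(sid[scoreable], levels = ids), mean)
    cnt <- tapply(rep(1L, sum(scoreable)), factor(sid[scoreable], levels = ids), sum)
    n_loci <- ifelse(is.na(cnt), 0L, as.integer(cnt))
    has <- !is.na(frac)
    msi_status[has] <- mapply(msi_from_fraction, frac[has], tmb[has],
                              MoreArgs = list(config = config))
  }

  seg <- cohort$segments
  fga <- numeric(length(ids))
  if (nrow(seg)) {
    width <- seg$end - seg$start
    altered <- abs(seg$log2_ratio) > config$fga_log2_threshold
    sf <- factor(seg$sample_id, levels = ids)
    totw <- tapply(width, sf, sum)
    altw <- tapply(width * altered, sf, sum)
    has <- !is.na(totw)
    fga[has] <- altw[has] / totw[has]
  }

  data.frame(sample_id = ids, pole_positive = pole_positive,
             tp53_mutated = tp53_mutated, tmb = tmb, msi_status = msi_status,
             fga = fga, n_msi_loci = n_loci, stringsAsFactors = FALSE)
}
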