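## Seeded generator of panel-level synthetic cohorts carrying the statistical
## structure the classifier and survival analyses assume: subtype mixture,
## per-subtype mutational burden (ultra >> hyper >> MSS), microsatellite
## read-length histograms, copy-number segments, clinicopathological strata
## and subtype-dependent survival with administrative censoring.

BACKGROUND_GENES <- c("PTEN", "PIK3CA", "PIK3R1", "ARID1B", "KMT2C", "KMT2D",
                      "CTNNB1", "CTCF", "KRAS", "FBXW7", "FGFR2", "PPP2R1A",
                      "CHD4", "SPOP", "ATM", "BRCA2", "RB1", "NF1", "ESR1",
                      "AKT1")

#' Simulation configuration
#'
#' Defaults encode the cohort being emulated: 233 samples split
#' 19/44/27/143 across POLE/MSI-H/CNH/CNL, an administrative follow-up
#' window of 7-122 months (median close to 66), overall survival available
#' for 131/233 samples with disease-specific survival for 126 of those, a
#' CNH median overall survival of 35 months, and near-complete 120-month
#' survival for the POLE group. Distribution shapes (log-normal burden,
#' exponential survival) are the generator's own choices.
#'
#' @param n_samples cohort size.
#' @param subtype_proportions named or positional probabilities for
#'   POLE/MSI-H/CNH/CNL; must sum to 1.
#' @param tmb_median per-subtype median burden, mutations/Mb.
#' @param tmb_sdlog log-scale SD of the log-normal burden draw.
#' @param n_msi_loci microsatellite panel size per sample.
#' @param msi_reads_per_locus reads per locus.
#' @param msi_unstable_range range of the planted unstable-locus fraction for
#'   MSI-H samples.
#' @param msi_background_rate per-locus instability rate outside MSI-H.
#' @param tp53_passenger_prob probability of a passenger TP53 mutation in
#'   POLE/MSI-H samples (hypermutation makes these common).
#' @param fga_cnh_range,fga_other_range planted fraction-altered ranges.
#' @param surv_10yr 120-month survival for POLE/MSI-H/CNL (exponential laws).
#' @param cnh_median_os CNH median overall survival, months.
#' @param censor_window administrative censoring window, months.
#' @param os_available_fraction fraction of samples with OS follow-up.
#' @param dss_available_fraction fraction of OS-available samples that also
#'   have DSS.
#' @param dss_given_death probability a death is disease-specific.
#' @param gene_prevalence per-subtype gene-level mutation prevalences for the
#'   comprehensive-panel surrogate (CNL and MSI-H samples only).
#' @param arid1a_hr,zfhx4_hr planted hazard ratios of the two biomarkers.
#' @param subthreshold_rate,synonymous_rate Poisson means of sub-VAF-filter
#'   and synonymous decoy variants per sample.
#' @param caller the [caller_config()] the cohort is generated to satisfy.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples = 233,
    subtype_proportions = c(POLE = 19, `MSI-H` = 44, CNH = 27, CNL = 143) / 233,
    tmb_median = c(POLE = 200, `MSI-H` = 40, CNH = 5, CNL = 5),
    tmb_sdlog = 0.4,
    n_msi_loci = 25,
    msi_reads_per_locus = 100,
    msi_unstable_range = c(0.40, 0.70),
    msi_background_rate = 0.01,
    tp53_passenger_prob = 0.3,
    fga_cnh_range = c(0.30, 0.60),
    fga_other_range = c(0, 0.08),
    surv_10yr = c(POLE = 0.99, `MSI-H` = 0.80, CNL = 0.85),
    cnh_median_os = 35,
    censor_window = c(7, 122),
    os_available_fraction = 131 / 233,
    dss_available_fraction = 126 / 131,
    dss_given_death = 0.9,
    gene_prevalence = list(
      `MSI-H` = c(ARID1A = 0.45, ZFHX4 = 0.25, PTEN = 0.55, PIK3CA = 0.35,
                  PIK3R1 = 0.25, KMT2C = 0.35, KMT2D = 0.30, CTNNB1 = 0.15,
                  CTCF = 0.20, KRAS = 0.20),
      CNL = c(ARID1A = 0.35, ZFHX4 = 0.04, PTEN = 0.55, PIK3CA = 0.40,
              PIK3R1 = 0.30, KMT2C = 0.15, KMT2D = 0.12, CTNNB1 = 0.30,
              CTCF = 0.15, KRAS = 0.20)),
    arid1a_hr = 2,
    zfhx4_hr = 4,
    subthreshold_rate = 1,
    synonymous_rate = 1,
    caller = caller_config()) {
  props <- subtype_proportions
  if (length(props) != 4) {
    ec_config_error("subtype_proportions must give one value per subtype")
  }
  if (is.null(names(props))) names(props) <- SUBTYPE_LEVELS
  if (!setequal(names(props), SUBTYPE_LEVELS)) {
    ec_config_error("subtype_proportions must be named by the four subtypes")
  }
  props <- props[SUBTYPE_LEVELS]
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9) {
    ec_config_error("subtype_proportions must be non-negative and sum to 1")
  }
  if (any(tmb_median <= 0) || cnh_median_os <= 0 ||
      any(surv_10yr <= 0 | surv_10yr > 1)) {
    ec_config_error("simulation rates must be positive (and 10-year survival in (0,1])")
  }
  if (censor_window[1] <= 0 || censor_window[2] <= censor_window[1]) {
    ec_config_error("censor_window must be an increasing positive interval")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_proportions = props,
    tmb_median = tmb_median[SUBTYPE_LEVELS],
    tmb_sdlog = tmb_sdlog,
    n_msi_loci = as.integer(n_msi_loci),
    msi_reads_per_locus = as.integer(msi_reads_per_locus),
    msi_unstable_range = msi_unstable_range,
    msi_background_rate = msi_background_rate,
    tp53_passenger_prob = tp53_passenger_prob,
    fga_cnh_range = fga_cnh_range,
    fga_other_range = fga_other_range,
    surv_10yr = surv_10yr,
    cnh_median_os = cnh_median_os,
    censor_window = censor_window,
    os_available_fraction = os_available_fraction,
    dss_available_fraction = dss_available_fraction,
    dss_given_death = dss_given_death,
    gene_prevalence = gene_prevalence,
    arid1a_hr = arid1a_hr,
    zfhx4_hr = zfhx4_hr,
    subthreshold_rate = subthreshold_rate,
    synonymous_rate = synonymous_rate,
    caller = caller
  ), class = "simulation_config")
}

#' Generate a synthetic cohort
#'
#' Draws a subtype per sample, then emits the molecular evidence that makes
#' the subtype recoverable under the supplied caller configuration: a
#' pathogenic POLE hotspot for POLE samples, unstable microsatellite loci
#' plus hypermutation for MSI-H, a TP53 driver and elevated copy-number
#' burden for CNH, and quiet profiles for CNL. Clinical strata follow the
#' emulated cohort's per-subtype distributions; survival times come from
#' per-subtype exponential laws with administrative censoring, with planted
#' ARID1A/ZFHX4 hazard effects inside the CNL/MSI-H group. Fully
#' reproducible given `seed`; the session RNG state is restored on exit.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the single source of randomness.
#' @return an `ec_cohort` whose `$truth` records the planted labels.
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1L) {
  if (!inherits(config, "simulation_config")) {
    ec_config_error("`config` must be a simulation_config")
  }
  restore <- local_seed(seed)
  on.exit(restore())
  n <- config$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  subtype <- sample(SUBTYPE_LEVELS, n, replace = TRUE,
                    prob = config$subtype_proportions)

  ## --- gene-level mutation surrogate (CNL/MSI-H samples only) -------------
  genes <- unique(unlist(lapply(config$gene_prevalence, names)))
  arid1a <- integer(n)
  zfhx4 <- integer(n)
  gm_rows <- list()
  for (st in names(config$gene_prevalence)) {
    sel <- which(subtype == st)
    if (!length(sel)) next
    prev <- config$gene_prevalence[[st]][genes]
    prev[is.na(prev)] <- 0
    draws <- matrix(stats::rbinom(length(sel) * length(genes), 1,
                                  rep(prev, each = length(sel))),
                    nrow = length(sel))
    gm_rows[[st]] <- data.frame(
      sample_id = rep(ids[sel], times = length(genes)),
      gene = rep(genes, each = length(sel)),
      mutated = as.integer(draws),
      stringsAsFactors = FALSE)
    if ("ARID1A" %in% genes) arid1a[sel] <- draws[, match("ARID1A", genes)]
    if ("ZFHX4" %in% genes) zfhx4[sel] <- draws[, match("ZFHX4", genes)]
  }
  gene_mutations <- if (length(gm_rows)) {
    do.call(rbind, c(gm_rows, make.row.names = FALSE))
  }

  ## --- clinical record -----------------------------------------------------
  strata <- draw_clinical_strata(subtype)
  rate <- ifelse(subtype == "CNH", log(2) / config$cnh_median_os,
                 -log(config$surv_10yr[subtype]) / 120)
  mult <- config$arid1a_hr^arid1a * config$zfhx4_hr^zfhx4
  t_event <- stats::rexp(n, rate * mult)
  t_censor <- stats::runif(n, config$censor_window[1], config$censor_window[2])
  os_months <- round(pmin(t_event, t_censor), 1)
  os_event <- as.integer(t_event <= t_censor)
  avail <- stats::runif(n) < config$os_available_fraction
  dss_avail <- avail & stats::runif(n) < config$dss_available_fraction
  dss_event <- ifelse(os_event == 1 & stats::runif(n) < config$dss_given_death,
                      1L, 0L)
  clinical <- data.frame(
    sample_id = ids,
    age = strata$age,
    stage = strata$stage,
    grade = strata$grade,
    histology = strata$histology,
    lvsi = strata$lvsi,
    os_months = ifelse(avail, os_months, NA_real_),
    os_event = ifelse(avail, os_event, NA_integer_),
    dss_months = ifelse(dss_avail, os_months, NA_real_),
    dss_event = ifelse(dss_avail, dss_event, NA_integer_),
    vital_status = ifelse(!avail, "unknown",
                          ifelse(os_event == 1, "deceased", "alive")),
    stringsAsFactors = FALSE)

  ## --- variant layer --------------------------------------------------------
  panel <- config$caller$panel_size_mb
  tmb_target <- stats::rlnorm(n, log(config$tmb_median[subtype]), config$tmb_sdlog)
  has_pole <- subtype == "POLE"
  has_tp53 <- subtype == "CNH" |
    (subtype %in% c("POLE", "MSI-H") &
       stats::runif(n) < config$tp53_passenger_prob)
  n_bg <- pmax(0L, as.integer(round(tmb_target * panel)) -
                 as.integer(has_pole) - as.integer(has_tp53))
  n_low <- stats::rpois(n, config$subthreshold_rate)
  n_syn <- stats::rpois(n, config$synonymous_rate)
  variants <- rbind(
    random_variant_rows(rep(ids, n_bg), gene = NULL, vaf_range = c(0.05, 0.60),
                        consequence = NULL, hgvs = ""),
    random_variant_rows(rep(ids, n_low), gene = NULL, vaf_range = c(0.010, 0.049),
                        consequence = "missense", hgvs = ""),
    random_variant_rows(rep(ids, n_syn), gene = NULL, vaf_range = c(0.05, 0.60),
                        consequence = "synonymous", hgvs = ""),
    random_variant_rows(ids[has_pole], gene = "POLE", vaf_range = c(0.15, 0.50),
                        consequence = "missense",
                        hgvs = sample(pole_hotspots(), sum(has_pole), replace = TRUE)),
    random_variant_rows(ids[has_tp53], gene = "TP53", vaf_range = c(0.10, 0.60),
                        consequence = "missense", hgvs = "p.R273H"),
    make.row.names = FALSE)
  variants <- variants[order(variants$sample_id), , drop = FALSE]
  rownames(variants) <- NULL

  ## --- microsatellite layer -------------------------------------------------
  msi <- generate_msi_layer(ids, subtype, config)

  ## --- copy-number layer ----------------------------------------------------
  segments <- generate_segment_layer(ids, subtype, config)

  cohort <- new_cohort(clinical, variants, msi, segments,
                       gene_mutations = gene_mutations,
                       truth = data.frame(sample_id = ids, subtype = subtype,
                                          stringsAsFactors = FALSE))
  cohort
}

## one row per element of sample_ids; gene/consequence/hgvs recycled or drawn
random_variant_rows <- function(sample_ids, gene, vaf_range, consequence, hgvs) {
  m <- length(sample_ids)
  if (!m) return(empty_variants())
  ref_i <- sample.int(4, m, replace = TRUE)
  alt_i <- 1L + (ref_i - 1L + sample.int(3, m, replace = TRUE)) %% 4L
  bases <- c("A", "C", "G", "T")
  data.frame(
    sample_id = sample_ids,
    chrom = paste0("chr", sample.int(22, m, replace = TRUE)),
    pos = sample.int(100000000L, m, replace = TRUE),
    ref = bases[ref_i],
    alt = bases[alt_i],
    gene = if (is.null(gene)) sample(BACKGROUND_GENES, m, replace = TRUE)
           else rep(gene, length.out = m),
    hgvs_p = rep(hgvs, length.out = m),
    consequence = if (is.null(consequence)) {
      sample(c("missense", "nonsense", "frameshift"), m, replace = TRUE,
             prob = c(0.8, 0.1, 0.1))
    } else rep(consequence, length.out = m),
    vaf = round(stats::runif(m, vaf_range[1], vaf_range[2]), 4),
    stringsAsFactors = FALSE)
}

generate_msi_layer <- function(ids, subtype, config) {
  n <- length(ids)
  nl <- config$n_msi_loci
  reads <- config$msi_reads_per_locus
  centers <- 10L + seq_len(nl)
  units <- rep(c("A", "T", "CA", "AG"), length.out = nl)
  is_h <- subtype == "MSI-H"
  k_unst <- integer(n)
  k_unst[is_h] <- round(stats::runif(sum(is_h), config$msi_unstable_range[1],
                                     config$msi_unstable_range[2]) * nl)
  k_unst[!is_h] <- stats::rbinom(sum(!is_h), nl, config$msi_background_rate)
  unstable <- matrix(FALSE, n, nl)
  for (i in which(k_unst > 0)) {
    unstable[i, sample.int(nl, k_unst[i])] <- TRUE
  }
  u <- as.vector(t(unstable))                  # pair order: sample-major
  pair_sample <- rep(ids, each = nl)
  pair_locus <- rep(seq_len(nl), n)
  p_base <- c(0.05, 0.20, 0.50, 0.20, 0.05)
  off_base <- -2:2
  ## unstable loci shift ~40% of reads to lengths the baseline never shows
  p_unst <- c(p_base * 0.60, 0.25, 0.15)
  off_unst <- c(off_base, -4L, -5L)
  cnt_s <- stats::rmultinom(sum(!u), reads, p_base)
  cnt_u <- stats::rmultinom(sum(u), reads, p_unst)
  stable_rows <- data.frame(
    sample_id = rep(pair_sample[!u], each = 5),
    locus_id = sprintf("MS%02d", rep(pair_locus[!u], each = 5)),
    repeat_unit = units[rep(pair_locus[!u], each = 5)],
    length = centers[rep(pair_locus[!u], each = 5)] + rep(off_base, sum(!u)),
    baseline_prob = rep(p_base, sum(!u)),
    observed_count = as.vector(cnt_s),
    stringsAsFactors = FALSE)
  unstable_rows <- data.frame(
    sample_id = rep(pair_sample[u], each = 7),
    locus_id = sprintf("MS%02d", rep(pair_locus[u], each = 7)),
    repeat_unit = units[rep(pair_locus[u], each = 7)],
    length = centers[rep(pair_locus[u], each = 7)] + rep(off_unst, sum(u)),
    baseline_prob = rep(c(p_base, 0, 0), sum(u)),
    observed_count = as.vector(cnt_u),
    stringsAsFactors = FALSE)
  msi <- rbind(stable_rows, unstable_rows, make.row.names = FALSE)
  msi <- msi[order(msi$sample_id, msi$locus_id, msi$length), , drop = FALSE]
  rownames(msi) <- NULL
  msi
}

generate_segment_layer <- function(ids, subtype, config) {
  n <- length(ids)
  n_seg <- 8L
  width <- 250000
  fga_t <- ifelse(subtype == "CNH",
                  stats::runif(n, config$fga_cnh_range[1], config$fga_cnh_range[2]),
                  stats::runif(n, config$fga_other_range[1], config$fga_other_range[2]))
  k_alt <- round(fga_t * n_seg)
  altered <- matrix(FALSE, n, n_seg)
  for (i in which(k_alt > 0)) {
    altered[i, sample.int(n_seg, k_alt[i])] <- TRUE
  }
  a <- as.vector(t(altered))
  m <- n * n_seg
  log2 <- numeric(m)
  log2[!a] <- stats::runif(sum(!a), -0.10, 0.10)
  log2[a] <- sample(c(-1, 1), sum(a), replace = TRUE) * stats::runif(sum(a), 0.40, 1.00)
  data.frame(
    sample_id = rep(ids, each = n_seg),
    chrom = paste0("chr", rep(seq_len(n_seg), n)),
    start = 0,
    end = width,
    log2_ratio = round(log2, 4),
    stringsAsFactors = FALSE)
}

## Clinicopathological strata drawn from the emulated cohort's per-subtype
## distributions (see table1_cells()).
draw_clinical_strata <- function(subtype) {
  cells <- table1_cells()
  n <- length(subtype)
  out <- list(stage = character(n), grade = character(n),
              histology = character(n), lvsi = character(n), age = integer(n))
  for (st in SUBTYPE_LEVELS) {
    sel <- which(subtype == st)
    if (!length(sel)) next
    cs <- cells[[st]]
    out$stage[sel] <- sample(STAGE_LEVELS, length(sel), TRUE, prob = cs$stage)
    out$grade[sel] <- sample(GRADE_LEVELS, length(sel), TRUE, prob = cs$grade)
    out$histology[sel] <- sample(HISTOLOGY_LEVELS, length(sel), TRUE,
                                 prob = cs$histology)
    out$lvsi[sel] <- sample(LVSI_LEVELS, length(sel), TRUE, prob = cs$lvsi)
    age <- round(stats::rnorm(length(sel), cs$age_mean, cs$age_sd))
    out$age[sel] <- pmin(pmax(age, cs$age_range[1]), cs$age_range[2])
  }
  out
}
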