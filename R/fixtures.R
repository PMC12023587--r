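## Deterministic in-memory fixtures reconstructing the emulated cohort's
## printed composition: the 233-sample clinicopathological table ("table1")
## and the 39-sample CNL/MSI-H biomarker subset ("fig4"). Both carry minimal
## molecular layers consistent with their pre-assigned subtype labels, so the
## classifier recovers the printed counts exactly.

## Per-subtype cell counts of the 233-sample cohort summary, plus age moments.
## Order of levels follows STAGE_LEVELS / GRADE_LEVELS / HISTOLOGY_LEVELS /
## LVSI_LEVELS.
table1_cells <- function() {
  list(
    "POLE" = list(
      n = 19L,
      stage = c(16, 0, 2, 0, 1),
      lvsi = c(2, 13, 4),
      histology = c(15, 2, 0, 0, 2),
      grade = c(9, 2, 6, 0, 2),
      age_mean = 53.65, age_sd = 10.21, age_range = c(30, 68)),
    "MSI-H" = list(
      n = 44L,
      stage = c(26, 6, 6, 0, 6),
      lvsi = c(1, 33, 10),
      histology = c(34, 0, 2, 2, 6),
      grade = c(12, 13, 11, 1, 7),
      age_mean = 56.32, age_sd = 8.93, age_range = c(36, 75)),
    "CNH" = list(
      n = 27L,
      stage = c(12, 3, 8, 1, 3),
      lvsi = c(5, 18, 4),
      histology = c(15, 6, 0, 4, 2),
      grade = c(4, 5, 14, 1, 3),
      age_mean = 59.33, age_sd = 10.88, age_range = c(39, 84)),
    "CNL" = list(
      n = 143L,
      stage = c(103, 8, 18, 2, 12),
      lvsi = c(5, 109, 29),
      histology = c(119, 3, 0, 1, 20),
      grade = c(72, 35, 14, 1, 21),
      age_mean = 53.63, age_sd = 9.62, age_range = c(31, 76))
  )
}

#' Load a packaged fixture cohort
#'
#' `"table1"` rebuilds the 233-sample cohort whose subtype labels and
#' clinicopathological cross-tabs match the emulated cohort's printed
#' composition cell for cell (ages reproduce the printed moments only;
#' survival columns are left missing, since per-patient follow-up is not
#' published). `"fig4"` rebuilds the 39-sample CNL/MSI-H comprehensive-panel
#' subset: 13 deceased / 26 surviving with ARID1A mutated in 7 and 8 of them
#' respectively and all 4 ZFHX4 mutations in deceased cases — the unique
#' integer composition consistent with the printed one-decimal frequencies
#' (see [derive_fig4_composition()]). Both fixtures are fully deterministic.
#'
#' @param name `"table1"` or `"fig4"`.
#' @return an `ec_cohort` with known labels in `$truth`.
#' @export
load_fixture <- function(name) {
  switch(name,
         table1 = build_table1_fixture(),
         fig4 = build_fig4_fixture(),
         ec_validation_error(sprintf("unknown fixture '%s' (use 'table1' or 'fig4')",
                                     name)))
}

## ---------------------------------------------------------------------------
## table1

build_table1_fixture <- function() {
  cells <- table1_cells()
  clin_list <- list()
  for (st in SUBTYPE_LEVELS) {
    cs <- cells[[st]]
    n <- cs$n
    ## deterministic ages hitting the printed moments approximately:
    ## normal quantiles at evenly spaced probabilities, clamped to the range
    age <- stats::qnorm(stats::ppoints(n), cs$age_mean, cs$age_sd)
    age <- round(pmin(pmax(age, cs$age_range[1]), cs$age_range[2]))
    clin_list[[st]] <- data.frame(
      subtype = st,
      age = age,
      stage = rep(STAGE_LEVELS, cs$stage),
      grade = rep(GRADE_LEVELS, cs$grade),
      histology = rep(HISTOLOGY_LEVELS, cs$histology),
      lvsi = rep(LVSI_LEVELS, cs$lvsi),
      stringsAsFactors = FALSE)
  }
  clin <- do.call(rbind, c(clin_list, make.row.names = FALSE))
  ids <- sprintf("EC%03d", seq_len(nrow(clin)))
  clinical <- data.frame(
    sample_id = ids, age = clin$age, stage = clin$stage, grade = clin$grade,
    histology = clin$histology, lvsi = clin$lvsi,
    os_months = NA_real_, os_event = NA_integer_,
    dss_months = NA_real_, dss_event = NA_integer_,
    vital_status = "unknown", stringsAsFactors = FALSE)
  layers <- minimal_molecular_layers(ids, clin$subtype)
  new_cohort(clinical, layers$variants, layers$msi, layers$segments,
             truth = data.frame(sample_id = ids, subtype = clin$subtype,
                                stringsAsFactors = FALSE))
}

## Minimal, deterministic molecular evidence that classifies each sample to
## its pre-assigned label under the default caller configuration.
minimal_molecular_layers <- function(ids, subtype) {
  stopifnot(length(ids) == length(subtype))
  v <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    v[[i]] <- switch(subtype[i],
      "POLE" = fixture_variant(id, "POLE", "p.P286R", "missense", 0.35),
      "MSI-H" = {
        ## 16 passing nonsynonymous calls -> TMB 16/1.5 > 10 mut/Mb
        genes <- rep(c("PTEN", "ARID1A", "KMT2C", "PIK3CA"), each = 4)
        do.call(rbind, lapply(seq_along(genes), function(j) {
          fixture_variant(id, genes[j], "", "missense", 0.30, pos = 1000L + j)
        }))
      },
      "CNH" = fixture_variant(id, "TP53", "p.R273H", "missense", 0.40),
      "CNL" = fixture_variant(id, "PTEN", "p.R130G", "missense", 0.25))
  }
  variants <- do.call(rbind, c(v, make.row.names = FALSE))

  n_loci <- 10L
  centers <- 10L + seq_len(n_loci)
  p_base <- c(0.05, 0.20, 0.50, 0.20, 0.05)
  stable_obs <- p_base * 100
  unstable_obs <- c(p_base * 60, 25, 15)     # novel fraction 0.40
  msi <- list()
  for (i in seq_along(ids)) {
    unstable_loci <- if (subtype[i] == "MSI-H") 1:5 else integer(0)
    rows <- lapply(seq_len(n_loci), function(l) {
      if (l %in% unstable_loci) {
        data.frame(sample_id = ids[i], locus_id = sprintf("MS%02d", l),
                   repeat_unit = "A",
                   length = centers[l] + c(-2:2, -4L, -5L),
                   baseline_prob = c(p_base, 0, 0),
                   observed_count = unstable_obs, stringsAsFactors = FALSE)
      } else {
        data.frame(sample_id = ids[i], locus_id = sprintf("MS%02d", l),
                   repeat_unit = "A",
                   length = centers[l] + (-2:2),
                   baseline_prob = p_base,
                   observed_count = stable_obs, stringsAsFactors = FALSE)
      }
    })
    msi[[i]] <- do.call(rbind, rows)
  }
  msi <- do.call(rbind, c(msi, make.row.names = FALSE))

  seg <- list()
  for (i in seq_along(ids)) {
    log2 <- if (subtype[i] == "CNH") c(1, -1, 0, 0) else c(0, 0, 0, 0)
    seg[[i]] <- data.frame(sample_id = ids[i],
                           chrom = paste0("chr", 1:4),
                           start = 0, end = 250000,
                           log2_ratio = log2, stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, c(seg, make.row.names = FALSE))
  list(variants = variants, msi = msi, segments = segments)
}

fixture_variant <- function(id, gene, hgvs, consequence, vaf, pos = 1000L) {
  data.frame(sample_id = id, chrom = "chr1", pos = pos, ref = "A", alt = "G",
             gene = gene, hgvs_p = hgvs, consequence = consequence, vaf = vaf,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## fig4

#' Integer composition of the 39-sample biomarker subset
#'
#' Exhaustively searches the deceased/surviving splits of 39 samples for the
#' unique composition consistent with the printed one-decimal mutation
#' frequencies — ARID1A 53.8% in deceased vs 30.8% in surviving, ZFHX4 30.8%
#' vs 0% — together with the constraint that exactly four ZFHX4 mutations
#' occurred, all in deceased cases.
#'
#' @return list: `n_deceased`, `n_surviving`, `arid1a_deceased`,
#'   `arid1a_surviving`, `zfhx4_deceased`.
#' @export
derive_fig4_composition <- function() {
  match1 <- function(count, n, target) {
    n > 0 && round_half_up(100 * count / n, 1) == target
  }
  hits <- list()
  for (d in 1:38) {
    s <- 39L - d
    if (!match1(4, d, 30.8)) next                   # 4 ZFHX4, all deceased
    a_d <- which(vapply(0:d, match1, TRUE, n = d, target = 53.8)) - 1L
    a_s <- which(vapply(0:s, match1, TRUE, n = s, target = 30.8)) - 1L
    for (x in a_d) for (y in a_s) {
      hits[[length(hits) + 1L]] <- list(n_deceased = d, n_surviving = s,
                                        arid1a_deceased = x,
                                        arid1a_surviving = y,
                                        zfhx4_deceased = 4L)
    }
  }
  if (length(hits) != 1) {
    ec_integrity_error(sprintf(
      "expected a unique composition of the 39-sample subset, found %d",
      length(hits)))
  }
  hits[[1]]
}

build_fig4_fixture <- function() {
  comp <- derive_fig4_composition()
  n <- 39L
  ids <- sprintf("GP%02d", seq_len(n))
  ## 27 CNL + 12 MSI-H; deceased first within each subtype block.
  ## Deceased split 8 CNL + 5 MSI-H; three of the four ZFHX4 mutations sit in
  ## MSI-H samples and one in CNL, all deceased.
  subtype <- rep(c("CNL", "MSI-H"), c(27L, 12L))
  deceased <- c(rep(TRUE, 8), rep(FALSE, 19),   # CNL block
                rep(TRUE, 5), rep(FALSE, 7))    # MSI-H block
  stopifnot(sum(deceased) == comp$n_deceased)
  dec_idx <- which(deceased)
  sur_idx <- which(!deceased)
  zfhx4 <- integer(n)
  zfhx4[c(28, 29, 30, 1)] <- 1L                 # 3 MSI-H deceased + 1 CNL deceased
  stopifnot(sum(zfhx4[dec_idx]) == comp$zfhx4_deceased, sum(zfhx4[sur_idx]) == 0)
  arid1a <- integer(n)
  arid1a[dec_idx[seq_len(comp$arid1a_deceased)]] <- 1L
  arid1a[sur_idx[seq_len(comp$arid1a_surviving)]] <- 1L

  ## survival: ZFHX4 carriers fail earliest; survivors censored late
  os_months <- numeric(n)
  os_months[dec_idx] <- seq(8, 56, length.out = comp$n_deceased)
  os_months[which(zfhx4 == 1)] <- c(8, 12, 16, 20)
  os_months[sur_idx] <- round(seq(62, 121, length.out = comp$n_surviving), 1)
  os_months <- round(os_months, 1)
  os_event <- as.integer(deceased)

  age <- round(pmin(pmax(stats::qnorm(stats::ppoints(n), 56.54, 8.86), 31), 75))
  clinical <- data.frame(
    sample_id = ids, age = age,
    stage = rep(rep(c("I", "II", "III", "unknown"), c(28, 1, 9, 1)),
                length.out = n),
    grade = rep(rep(c("G1", "G2", "G3", "undifferentiated"), c(10, 16, 12, 1)),
                length.out = n),
    histology = rep(rep(c("endometrioid", "serous"), c(38, 1)), length.out = n),
    lvsi = rep(rep(c("yes", "no", "unknown"), c(3, 33, 3)), length.out = n),
    os_months = os_months, os_event = os_event,
    dss_months = os_months, dss_event = os_event,
    vital_status = ifelse(deceased, "deceased", "alive"),
    stringsAsFactors = FALSE)

  ## comprehensive-panel surrogate: deterministic flags for the profiled genes
  genes <- c("ARID1A", "ZFHX4", "PTEN", "PIK3CA", "PIK3R1", "KMT2C", "KMT2D",
             "CTNNB1", "CTCF", "KRAS")
  flag <- cbind(ARID1A = arid1a, ZFHX4 = zfhx4,
                PTEN = as.integer(seq_len(n) %% 2 == 0),
                PIK3CA = as.integer(seq_len(n) %% 3 == 0),
                PIK3R1 = as.integer(seq_len(n) %% 4 == 0),
                KMT2C = as.integer(subtype == "MSI-H"),
                KMT2D = as.integer(subtype == "MSI-H" & seq_len(n) %% 2 == 0),
                CTNNB1 = as.integer(seq_len(n) %% 5 == 0),
                CTCF = as.integer(seq_len(n) %% 6 == 0),
                KRAS = as.integer(seq_len(n) %% 7 == 0))
  gene_mutations <- data.frame(
    sample_id = rep(ids, times = length(genes)),
    gene = rep(genes, each = n),
    mutated = as.integer(flag[, genes]),
    stringsAsFactors = FALSE)

  layers <- minimal_molecular_layers(ids, subtype)
  new_cohort(clinical, layers$variants, layers$msi, layers$segments,
             gene_mutations = gene_mutations,
             truth = data.frame(sample_id = ids, subtype = subtype,
                                stringsAsFactors = FALSE))
}
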