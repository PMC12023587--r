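## Cohort data model: on-disk readers/writers for the four molecular/clinical
## layers, validation of the documented invariants, and cohort summarization.

## Canonical column types per layer, enforced on construction so that a
## cohort written to TSV reloads with every field identical.
CLINICAL_TYPES <- c(sample_id = "character", age = "double",
                    stage = "character", grade = "character",
                    histology = "character", lvsi = "character",
                    os_months = "double", os_event = "integer",
                    dss_months = "double", dss_event = "integer",
                    vital_status = "character")
VARIANT_TYPES <- c(sample_id = "character", chrom = "character",
                   pos = "integer", ref = "character", alt = "character",
                   gene = "character", hgvs_p = "character",
                   consequence = "character", vaf = "double")
MSI_TYPES <- c(sample_id = "character", locus_id = "character",
               repeat_unit = "character", length = "integer",
               baseline_prob = "double", observed_count = "double")
SEGMENT_TYPES <- c(sample_id = "character", chrom = "character",
                   start = "double", end = "double", log2_ratio = "double")
GENE_MUTATION_TYPES <- c(sample_id = "character", gene = "character",
                         mutated = "integer")

coerce_cols <- function(df, types) {
  miss <- setdiff(names(types), names(df))
  if (length(miss)) {
    ec_format_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  for (nm in names(types)) {
    df[[nm]] <- switch(types[[nm]],
                       character = as.character(df[[nm]]),
                       double = as.numeric(df[[nm]]),
                       integer = as.integer(df[[nm]]))
  }
  df[, names(types), drop = FALSE]
}

## ---------------------------------------------------------------------------
## Readers

read_tsv_checked <- function(path, expected_columns, what) {
  if (!file.exists(path)) ec_format_error(sprintf("%s file not found: %s", what, path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected_columns)) {
    ec_format_error(sprintf(
      "%s file %s, line 1: malformed header; expected '%s'",
      what, path, paste(expected_columns, collapse = "\t")))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA)
}

read_clinical <- function(path) {
  df <- read_tsv_checked(path, CLINICAL_COLUMNS, "clinical")
  df$sample_id <- as.character(df$sample_id)
  validate_clinical(df, path)
  df
}

validate_clinical <- function(df, where = "clinical table") {
  if (anyDuplicated(df$sample_id)) {
    ec_integrity_error(sprintf("duplicate sample_id in %s: %s", where,
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  check_enum <- function(col, levels) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% levels)
    if (any(bad)) {
      ec_validation_error(sprintf("invalid %s value(s) in %s: %s", col, where,
                                  paste(unique(df[[col]][bad]), collapse = ", ")))
    }
  }
  if (nrow(df)) {
    check_enum("stage", STAGE_LEVELS)
    check_enum("grade", GRADE_LEVELS)
    check_enum("histology", HISTOLOGY_LEVELS)
    check_enum("lvsi", LVSI_LEVELS)
    check_enum("vital_status", VITAL_LEVELS)
    bad_ev <- !is.na(df$os_event) & !(df$os_event %in% c(0, 1))
    if (any(bad_ev)) ec_validation_error(sprintf("os_event must be 0/1 in %s", where))
    ## an event indicator without a time is uninterpretable
    orphan <- !is.na(df$os_event) & is.na(df$os_months)
    if (any(orphan)) {
      ec_validation_error(sprintf(
        "sample(s) %s in %s have os_event but no os_months",
        paste(df$sample_id[orphan], collapse = ", "), where))
    }
    orphan_d <- !is.na(df$dss_event) & is.na(df$dss_months)
    if (any(orphan_d)) {
      ec_validation_error(sprintf(
        "sample(s) %s in %s have dss_event but no dss_months",
        paste(df$sample_id[orphan_d], collapse = ", "), where))
    }
    ## disease-specific death implies death
    bad_dss <- !is.na(df$dss_event) & df$dss_event == 1 &
      (is.na(df$os_event) | df$os_event != 1)
    if (any(bad_dss)) {
      ec_validation_error(sprintf(
        "sample(s) %s in %s have dss_event = 1 without os_event = 1",
        paste(df$sample_id[bad_dss], collapse = ", "), where))
    }
    neg <- (!is.na(df$os_months) & df$os_months < 0) |
      (!is.na(df$dss_months) & df$dss_months < 0)
    if (any(neg)) ec_validation_error(sprintf("negative survival time in %s", where))
  }
  invisible(df)
}

read_variants_tsv <- function(path) {
  df <- read_tsv_checked(path, VARIANT_COLUMNS, "variant")
  df$sample_id <- as.character(df$sample_id)
  df$hgvs_p <- ifelse(is.na(df$hgvs_p), "", as.character(df$hgvs_p))
  validate_variants(df, path)
  df
}

validate_variants <- function(df, where = "variant table") {
  if (!nrow(df)) return(invisible(df))
  if (any(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1)) {
    ec_validation_error(sprintf("VAF outside [0,1] in %s", where))
  }
  if (any(is.na(df$pos) | df$pos < 1)) {
    ec_validation_error(sprintf("variant position < 1 in %s", where))
  }
  if (any(df$ref == df$alt)) {
    ec_validation_error(sprintf("variant with ref == alt in %s", where))
  }
  bad <- !(df$consequence %in% CONSEQUENCE_LEVELS)
  if (any(bad)) {
    ec_validation_error(sprintf("unknown consequence value(s) in %s: %s", where,
                                paste(unique(df$consequence[bad]), collapse = ", ")))
  }
  invisible(df)
}

#' Read somatic variants from a VCF file
#'
#' Reads CHROM/POS/REF/ALT plus the annotation keys `INFO/GENE`, `INFO/HGVSP`
#' and `INFO/CONSEQ`. The variant allele fraction is taken per sample from
#' `FORMAT/AD` (alt / (ref + alt)); when AD is absent, `INFO/AF` is applied to
#' every carrier sample (genotype containing an alt allele). Requires the
#' vcfR package.
#'
#' @param path path to an uncompressed or bgzipped VCF (v4.x).
#' @return a variant data frame in the package's MAF-like layout
#'   (`sample_id, chrom, pos, ref, alt, gene, hgvs_p, consequence, vaf`).
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    ec_config_error("reading VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  gene <- vcfR::extract.info(v, element = "GENE")
  hgvs <- vcfR::extract.info(v, element = "HGVSP")
  cons <- vcfR::extract.info(v, element = "CONSEQ")
  af   <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF")))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  samples <- colnames(gt)
  rows <- list()
  for (s in samples) {
    carrier <- !is.na(gt[, s]) & grepl("1", gt[, s], fixed = TRUE)
    vaf <- rep(NA_real_, n_var)
    if (!is.null(ad)) {
      parts <- strsplit(ifelse(is.na(ad[, s]), "", ad[, s]), ",", fixed = TRUE)
      refc <- suppressWarnings(as.numeric(vapply(parts, function(p) p[1] %||% NA_character_, "")))
      altc <- suppressWarnings(as.numeric(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
      tot <- refc + altc
      vaf <- ifelse(!is.na(tot) & tot > 0, altc / tot, NA_real_)
      carrier <- carrier | (!is.na(altc) & altc > 0)
    }
    vaf[is.na(vaf)] <- af[is.na(vaf)]
    keep <- carrier & !is.na(vaf)
    if (!any(keep)) next
    rows[[s]] <- data.frame(
      sample_id = s,
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep],
      alt = fix$ALT[keep],
      gene = ifelse(is.na(gene[keep]), "", gene[keep]),
      hgvs_p = ifelse(is.na(hgvs[keep]), "", hgvs[keep]),
      consequence = ifelse(is.na(cons[keep]), "other", cons[keep]),
      vaf = vaf[keep],
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    empty_variants()
  validate_variants(df, path)
  df
}

empty_variants <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             hgvs_p = character(), consequence = character(), vaf = numeric(),
             stringsAsFactors = FALSE)
}

empty_msi <- function() {
  data.frame(sample_id = character(), locus_id = character(),
             repeat_unit = character(), length = integer(),
             baseline_prob = numeric(), observed_count = numeric(),
             stringsAsFactors = FALSE)
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), log2_ratio = numeric(), stringsAsFactors = FALSE)
}

read_msi <- function(path) {
  df <- read_tsv_checked(path, MSI_COLUMNS, "microsatellite")
  df$sample_id <- as.character(df$sample_id)
  df$locus_id <- as.character(df$locus_id)
  validate_msi(df, path)
  df
}

validate_msi <- function(df, where = "microsatellite table") {
  if (!nrow(df)) return(invisible(df))
  if (any(is.na(df$observed_count) | df$observed_count < 0)) {
    ec_validation_error(sprintf("negative observed read count in %s", where))
  }
  if (any(is.na(df$baseline_prob) | df$baseline_prob < 0 | df$baseline_prob > 1)) {
    ec_validation_error(sprintf("baseline probability outside [0,1] in %s", where))
  }
  key <- paste(df$sample_id, df$locus_id, sep = "\r")
  sums <- rowsum(df$baseline_prob, key)
  off <- abs(sums[, 1] - 1) > 1e-9
  if (any(off)) {
    ec_validation_error(sprintf(
      "baseline histogram does not sum to 1 for %d locus/loci in %s",
      sum(off), where))
  }
  invisible(df)
}

read_segments <- function(path) {
  df <- read_tsv_checked(path, SEGMENT_COLUMNS, "segment")
  df$sample_id <- as.character(df$sample_id)
  validate_segments(df, path)
  df
}

validate_segments <- function(df, where = "segment table") {
  if (!nrow(df)) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end) | df$start >= df$end)) {
    ec_validation_error(sprintf("segment with start >= end in %s", where))
  }
  ## 0-based half-open intervals must not overlap within sample+chromosome
  key <- paste(df$sample_id, df$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    o <- idx[order(df$start[idx])]
    if (any(df$start[o][-1] < df$end[o][-length(o)])) {
      ec_validation_error(sprintf("overlapping segments within a sample in %s", where))
    }
  }
  invisible(df)
}

read_gene_mutations <- function(path) {
  df <- read_tsv_checked(path, GENE_MUTATION_COLUMNS, "gene mutation")
  df$sample_id <- as.character(df$sample_id)
  if (nrow(df) && !all(df$mutated %in% c(0, 1))) {
    ec_validation_error(sprintf("gene mutation flags must be 0/1 in %s", path))
  }
  df
}

## ---------------------------------------------------------------------------
## Cohort container

#' Assemble a cohort from layer data frames
#'
#' Lower-level constructor behind [load_cohort()]; validates each layer and
#' joins them on `sample_id`. Samples missing a molecular layer are retained
#' and flagged rather than dropped.
#'
#' @param clinical clinical data frame with the documented columns.
#' @param variants,msi,segments molecular layer data frames (may be empty).
#' @param gene_mutations optional long data frame
#'   (`sample_id, gene, mutated`) from a wide comprehensive panel.
#' @param truth optional data frame (`sample_id, subtype`) of known labels
#'   (pre-assigned or planted by the simulator).
#' @return an object of class `ec_cohort`.
#' @export
new_cohort <- function(clinical, variants = empty_variants(), msi = empty_msi(),
                       segments = empty_segments(), gene_mutations = NULL,
                       truth = NULL) {
  clinical <- coerce_cols(clinical, CLINICAL_TYPES)
  variants <- coerce_cols(variants, VARIANT_TYPES)
  variants$hgvs_p[is.na(variants$hgvs_p)] <- ""
  msi <- coerce_cols(msi, MSI_TYPES)
  segments <- coerce_cols(segments, SEGMENT_TYPES)
  if (!is.null(gene_mutations)) {
    gene_mutations <- coerce_cols(gene_mutations, GENE_MUTATION_TYPES)
  }
  validate_clinical(clinical)
  validate_variants(variants)
  validate_msi(msi)
  validate_segments(segments)
  ids <- unique(c(clinical$sample_id, variants$sample_id, msi$sample_id,
                  segments$sample_id,
                  if (!is.null(gene_mutations)) gene_mutations$sample_id))
  missing_clin <- setdiff(ids, clinical$sample_id)
  if (length(missing_clin)) {
    pad <- clinical[rep(NA_integer_, length(missing_clin)), , drop = FALSE]
    pad$sample_id <- missing_clin
    for (col in setdiff(CLINICAL_COLUMNS, c("sample_id", "age", "os_months",
                                            "os_event", "dss_months", "dss_event"))) {
      pad[[col]] <- "unknown"
    }
    clinical <- rbind(clinical, pad)
    rownames(clinical) <- NULL
  }
  flags <- layer_flags(clinical$sample_id, variants, msi, segments)
  structure(list(clinical = clinical, variants = variants, msi = msi,
                 segments = segments, gene_mutations = gene_mutations,
                 truth = truth, flags = flags),
            class = "ec_cohort")
}

layer_flags <- function(ids, variants, msi, segments) {
  miss <- function(layer_ids) !(ids %in% layer_ids)
  data.frame(
    sample_id = ids,
    no_variants = miss(variants$sample_id),
    no_msi = miss(msi$sample_id),
    no_segments = miss(segments$sample_id),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ec_cohort <- function(x, ...) {
  cat(sprintf("<ec_cohort> %d sample(s); %d variant(s), %d microsatellite row(s), %d segment(s)\n",
              nrow(x$clinical), nrow(x$variants), nrow(x$msi), nrow(x$segments)))
  if (!is.null(x$gene_mutations)) {
    cat(sprintf("  gene-level mutation calls for %d sample(s)\n",
                length(unique(x$gene_mutations$sample_id))))
  }
  if (!is.null(x$truth)) cat("  carries known subtype labels ($truth)\n")
  invisible(x)
}

#' Sample identifiers of a cohort
#' @param cohort an `ec_cohort`.
#' @return character vector in clinical-table order.
#' @export
sample_ids <- function(cohort) cohort$clinical$sample_id

#' Load a cohort from its on-disk layers
#'
#' Reads the four layer files and joins them on `sample_id`. The variant file
#' may be a VCF (detected by extension or `##fileformat` header; see
#' [read_variants_vcf()]) or a MAF-like TSV with the documented header.
#' Samples present in the clinical table but absent from a molecular layer
#' are retained with that layer empty and flagged in `$flags`.
#'
#' @param variant_path VCF or MAF-like TSV of somatic calls.
#' @param msi_path long TSV of paired baseline/observed microsatellite
#'   read-length histograms.
#' @param segment_path SEG-like TSV of copy-number segments (0-based
#'   half-open intervals, log2 ratios).
#' @param clinical_path clinical TSV with the exact documented header.
#' @param gene_mutation_path optional long TSV of gene-level mutation flags.
#' @return an `ec_cohort`.
#' @export
load_cohort <- function(variant_path, msi_path, segment_path, clinical_path,
                        gene_mutation_path = NULL) {
  clinical <- read_clinical(clinical_path)
  variants <- if (is_vcf(variant_path)) read_variants_vcf(variant_path)
              else read_variants_tsv(variant_path)
  msi <- read_msi(msi_path)
  segments <- read_segments(segment_path)
  gm <- if (!is.null(gene_mutation_path)) read_gene_mutations(gene_mutation_path)
  new_cohort(clinical, variants, msi, segments, gene_mutations = gm)
}

is_vcf <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) return(TRUE)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) "")
  startsWith(first, "##fileformat=VCF")
}

#' Write a cohort's layers to a directory
#'
#' Inverse of [load_cohort()]: writes `variants.tsv`, `msi.tsv`,
#' `segments.tsv`, `clinical.tsv` (plus `gene_mutations.tsv` and
#' `truth_labels.tsv` when present) so that reloading reproduces every field.
#'
#' @param cohort an `ec_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
  }
  paths <- c(variants = w(cohort$variants, "variants.tsv"),
             msi = w(cohort$msi, "msi.tsv"),
             segments = w(cohort$segments, "segments.tsv"),
             clinical = w(cohort$clinical, "clinical.tsv"))
  if (!is.null(cohort$gene_mutations)) {
    paths <- c(paths, gene_mutations = w(cohort$gene_mutations, "gene_mutations.tsv"))
  }
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = w(cohort$truth, "truth_labels.tsv"))
  }
  invisible(paths)
}

#' Reload a cohort written by [write_cohort()]
#' @param dir directory containing the layer TSVs.
#' @return an `ec_cohort`.
#' @export
load_cohort_dir <- function(dir) {
  gm_path <- file.path(dir, "gene_mutations.tsv")
  cohort <- load_cohort(file.path(dir, "variants.tsv"),
                        file.path(dir, "msi.tsv"),
                        file.path(dir, "segments.tsv"),
                        file.path(dir, "clinical.tsv"),
                        gene_mutation_path = if (file.exists(gm_path)) gm_path)
  truth_path <- file.path(dir, "truth_labels.tsv")
  if (file.exists(truth_path)) {
    cohort$truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE,
                                      colClasses = "character")
  }
  cohort
}

## ---------------------------------------------------------------------------
## Summarization

#' Summarize a cohort against clinicopathological strata
#'
#' Produces per-subtype counts and percentages plus subtype cross-tabs for
#' stage, grade, histology, LVSI and age band. Percentages always use the
#' full cohort size as denominator (unknown categories are reported as their
#' own level and kept inside the total), rounded half-up to two decimals.
#'
#' @param cohort an `ec_cohort`.
#' @param subtype_labels character vector of subtype labels, either aligned
#'   with `sample_ids(cohort)` or named by sample id.
#' @return an object of class `cohort_summary` with elements `n_total`,
#'   `subtypes` (data frame of counts/percentages) and `cross_tabs`
#'   (named list of subtype-by-level count matrices).
#' @export
summarize_cohort <- function(cohort, subtype_labels) {
  ids <- sample_ids(cohort)
  labels <- align_labels(subtype_labels, ids)
  n_total <- length(ids)
  lev <- c(SUBTYPE_LEVELS, setdiff(unique(labels), SUBTYPE_LEVELS))
  f <- factor(labels, levels = lev)
  counts <- table(f)
  pct <- if (n_total == 0) rep(0, length(counts)) else
    round_half_up(100 * as.numeric(counts) / n_total, 2)
  subtypes <- data.frame(subtype = names(counts),
                         count = as.integer(counts),
                         percent = pct,
                         stringsAsFactors = FALSE)
  clin <- cohort$clinical
  strat <- list(
    stage = factor(ifelse(is.na(clin$stage), "unknown", clin$stage), levels = STAGE_LEVELS),
    grade = factor(ifelse(is.na(clin$grade), "unknown", clin$grade), levels = GRADE_LEVELS),
    histology = factor(ifelse(is.na(clin$histology), "unknown", clin$histology),
                       levels = HISTOLOGY_LEVELS),
    lvsi = factor(ifelse(is.na(clin$lvsi), "unknown", clin$lvsi), levels = LVSI_LEVELS),
    age_band = age_band(clin$age)
  )
  cross_tabs <- lapply(strat, function(s) unclass(table(f, s)))
  structure(list(n_total = n_total, subtypes = subtypes, cross_tabs = cross_tabs),
            class = "cohort_summary")
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels)) && any(nzchar(names(labels)))) {
    if (!all(ids %in% names(labels))) {
      ec_integrity_error("subtype labels missing for some sample ids")
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    ec_integrity_error(sprintf(
      "%d subtype labels supplied for %d samples", length(labels), length(ids)))
  }
  as.character(labels)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (N = %d)\n", x$n_total))
  print(x$subtypes, row.names = FALSE)
  invisible(x)
}
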