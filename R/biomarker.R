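## Biomarker sub-stratification of CNL/MSI-H tumors: gene-level mutation
## matrices from the comprehensive panel, mutation-frequency comparison by
## vital status, and survival stratification by mutation status.

#' Default gene sets for the comprehensive panel
#'
#' Pathway/complex groupings used when summarizing gene-level mutation
#' matrices: the mTOR signalling pathway, the SWI/SNF chromatin-remodelling
#' complex and the H3K4 methyltransferase family. Shipped as editable JSON
#' in `inst/extdata/gene_sets.json`; pass a different path for custom sets.
#'
#' @param path JSON file of named gene groups.
#' @return named list of character vectors.
#' @export
default_gene_sets <- function(path = system.file("extdata", "gene_sets.json",
                                                 package = "ecsubtype")) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(sets, as.character)
}

#' Binary sample-by-gene mutation matrix
#'
#' Built from the cohort's gene-level mutation calls when present, otherwise
#' derived from the variant layer: a gene is mutated in a sample when any
#' protein-altering variant passes the VAF filter (per-gene overrides in
#' `config$gene_vaf_min` honour hotspot vs non-hotspot sensitivities).
#' Gene-set members absent from the data are added as all-zero columns so
#' that every set is a subset of the matrix columns.
#'
#' @param cohort an `ec_cohort`.
#' @param gene_sets named list of gene groups (default [default_gene_sets()]).
#' @param genes optional restriction of the columns.
#' @param config a [caller_config()] (used only on the variant-derived path).
#' @return binary matrix (samples x genes) with a `gene_sets` attribute.
#' @export
mutation_matrix <- function(cohort, gene_sets = default_gene_sets(),
                            genes = NULL, config = caller_config()) {
  if (!is.null(cohort$gene_mutations)) {
    gm <- cohort$gene_mutations
    ids <- intersect(sample_ids(cohort), unique(gm$sample_id))
    cols <- unique(gm$gene)
    mat <- matrix(0L, length(ids), length(cols), dimnames = list(ids, cols))
    mat[cbind(match(gm$sample_id, ids), match(gm$gene, cols))] <-
      as.integer(gm$mutated)
  } else {
    v <- cohort$variants
    min_vaf <- rep(config$vaf_min, nrow(v))
    over <- match(v$gene, names(config$gene_vaf_min))
    min_vaf[!is.na(over)] <- unlist(config$gene_vaf_min)[over[!is.na(over)]]
    hit <- v[v$consequence %in% NONSYNONYMOUS & v$vaf >= min_vaf, , drop = FALSE]
    ids <- sample_ids(cohort)
    cols <- sort(unique(hit$gene))
    mat <- matrix(0L, length(ids), length(cols), dimnames = list(ids, cols))
    if (nrow(hit)) mat[cbind(match(hit$sample_id, ids), match(hit$gene, cols))] <- 1L
  }
  if (!is.null(genes)) {
    keep <- intersect(colnames(mat), genes)
    mat <- mat[, keep, drop = FALSE]
  }
  needed <- setdiff(unique(unlist(gene_sets)), colnames(mat))
  if (length(needed)) {
    pad <- matrix(0L, nrow(mat), length(needed),
                  dimnames = list(rownames(mat), needed))
    mat <- cbind(mat, pad)
  }
  attr(mat, "gene_sets") <- gene_sets
  mat
}

#' Per-gene mutation frequencies by vital status
#'
#' For each gene, the mutated fraction among deceased and among surviving
#' samples, as half-up one-decimal percentages. Samples with unknown vital
#' status are excluded with a warning; an empty stratum yields NA
#' frequencies.
#'
#' @param matrix binary mutation matrix ([mutation_matrix()]).
#' @param vital_status `"deceased"`/`"alive"` per sample, aligned with the
#'   matrix rows or named by sample id.
#' @return data frame: `gene`, `n_deceased`, `n_surviving`, `mut_deceased`,
#'   `mut_surviving`, `freq_deceased`, `freq_surviving` (percent, 1 dp).
#' @export
mutation_frequencies_by_outcome <- function(matrix, vital_status) {
  ids <- rownames(matrix)
  status <- align_labels(vital_status, ids)
  known <- status %in% c("alive", "deceased")
  if (!all(known)) {
    warning(sprintf("%d sample(s) with unknown vital status excluded",
                    sum(!known)), call. = FALSE)
    matrix <- matrix[known, , drop = FALSE]
    status <- status[known]
  }
  dead <- status == "deceased"
  n_d <- sum(dead)
  n_s <- sum(!dead)
  mut_d <- colSums(matrix[dead, , drop = FALSE])
  mut_s <- colSums(matrix[!dead, , drop = FALSE])
  pct <- function(m, n) if (n == 0) rep(NA_real_, length(m)) else
    round_half_up(100 * m / n, 1)
  data.frame(gene = colnames(matrix),
             n_deceased = n_d, n_surviving = n_s,
             mut_deceased = as.integer(mut_d),
             mut_surviving = as.integer(mut_s),
             freq_deceased = pct(mut_d, n_d),
             freq_surviving = pct(mut_s, n_s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Survival stratified by mutation status of one gene
#'
#' Splits the requested subset of the cohort into carriers and wild-type for
#' `gene`, estimates a Kaplan-Meier curve per arm and compares them with the
#' log-rank test. Only samples inside `subset_ids` (and with overall-survival
#' data) are used; the result records exactly which samples entered each arm.
#'
#' @param cohort an `ec_cohort` with gene-level mutation calls (or variants).
#' @param gene gene symbol.
#' @param subset_ids sample ids defining the analysis subset (e.g. the
#'   CNL/MSI-H group, or TP53-wild-type samples only); default all samples.
#' @param matrix optional precomputed [mutation_matrix()].
#' @param config a [caller_config()].
#' @return list: `curve_mut`, `curve_wt`, `logrank`, `n_mut`, `n_wt`,
#'   `samples_mut`, `samples_wt`.
#' @export
km_by_mutation <- function(cohort, gene, subset_ids = NULL, matrix = NULL,
                           config = caller_config()) {
  mat <- matrix %||% mutation_matrix(cohort, config = config)
  if (!(gene %in% colnames(mat))) {
    ec_validation_error(sprintf("gene %s not present in the mutation matrix", gene))
  }
  ids <- rownames(mat)
  if (!is.null(subset_ids)) ids <- intersect(ids, subset_ids)
  if (!length(ids)) ec_validation_error("requested subset is empty")
  clin <- cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
  has_os <- !is.na(clin$os_months) & !is.na(clin$os_event)
  if (!any(has_os)) ec_validation_error("no time-to-event data in the subset")
  ids <- ids[has_os]
  clin <- clin[has_os, , drop = FALSE]
  mut <- mat[ids, gene] == 1
  if (!any(mut)) ec_validation_error(sprintf("mutant arm for %s is empty", gene))
  if (all(mut)) ec_validation_error(sprintf("wild-type arm for %s is empty", gene))
  list(curve_mut = km_estimate(clin$os_months[mut], clin$os_event[mut]),
       curve_wt = km_estimate(clin$os_months[!mut], clin$os_event[!mut]),
       logrank = logrank_test(clin$os_months, clin$os_event,
                              ifelse(mut, "mutant", "wild-type")),
       n_mut = sum(mut), n_wt = sum(!mut),
       samples_mut = ids[mut], samples_wt = ids[!mut])
}

#' Long-format waterfall export
#'
#' One row per sample and gene with mutation flag, vital status and subtype,
#' for external plotting.
#'
#' @param cohort an `ec_cohort`.
#' @param subtype_labels subtype per sample (aligned or named).
#' @param matrix optional precomputed [mutation_matrix()].
#' @param path optional TSV output path.
#' @return the long data frame (invisibly when `path` is given).
#' @export
export_waterfall <- function(cohort, subtype_labels, matrix = NULL, path = NULL) {
  mat <- matrix %||% mutation_matrix(cohort)
  ids <- rownames(mat)
  labels <- align_labels(subtype_labels, sample_ids(cohort))
  names(labels) <- sample_ids(cohort)
  clin <- cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
  out <- data.frame(
    sample_id = rep(ids, times = ncol(mat)),
    gene = rep(colnames(mat), each = length(ids)),
    mutated = as.integer(mat),
    vital_status = rep(clin$vital_status, times = ncol(mat)),
    subtype = rep(unname(labels[ids]), times = ncol(mat)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(out))
  }
  out
}
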