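## Hierarchical subtype assignment: POLE first, then MSI-H, then the
## copy-number branch (MSI-L and MSS both proceed to CNH/CNL).

#' Classify one sample from its marker profile
#'
#' Strict, total precedence: a POLE-positive sample is POLE regardless of its
#' other markers; otherwise an MSI-H sample is MSI-H; otherwise (MSI-L and
#' MSS alike) the copy-number rule decides CNH vs CNL. Samples whose decisive
#' markers are undefined are labelled `"UNCLASSIFIABLE"` rather than raising
#' an error.
#'
#' @param profile a [marker_profile()] (or any list with fields
#'   `pole_positive`, `msi_status`, `tp53_mutated`, `fga`).
#' @param config a [caller_config()] (used by the copy-number rule).
#' @return one of `"POLE"`, `"MSI-H"`, `"CNH"`, `"CNL"`, `"UNCLASSIFIABLE"`.
#' @export
classify_sample <- function(profile, config = caller_config()) {
  pole <- profile$pole_positive
  if (is.null(pole) || is.na(pole)) return(UNCLASSIFIABLE)
  if (isTRUE(pole)) return("POLE")
  msi <- profile$msi_status
  if (is.null(msi) || is.na(msi)) return(UNCLASSIFIABLE)
  if (msi == "MSI-H") return("MSI-H")
  tp53 <- profile$tp53_mutated
  fga <- profile$fga %||% NA_real_
  if (is.null(tp53) || is.na(tp53)) return(UNCLASSIFIABLE)
  ## TP53-mutated decides CNH even when FGA is unavailable; a wild-type
  ## sample needs a defined FGA under the tp53_or_fga rule
  if (!isTRUE(tp53) && is.na(fga) && config$cn_rule == "tp53_or_fga") {
    return(UNCLASSIFIABLE)
  }
  classify_cn(tp53, fga, config)
}

#' Classify every sample of a cohort
#'
#' Derives marker profiles with [profile_cohort()] and applies
#' [classify_sample()] to each; deterministic given the configuration.
#' Samples with unevaluable markers are reported as `"UNCLASSIFIABLE"` with
#' the reason.
#'
#' @param cohort an `ec_cohort`.
#' @param config a [caller_config()].
#' @return data frame: `sample_id`, `subtype`, `pole_positive`, `msi_status`,
#'   `tp53_mutated`, `tmb`, `fga`, `reason` (NA unless unclassifiable).
#' @export
classify_cohort <- function(cohort, config = caller_config()) {
  prof <- profile_cohort(cohort, config)
  n <- nrow(prof)
  subtype <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    subtype[i] <- classify_sample(prof[i, ], config)
    if (subtype[i] == UNCLASSIFIABLE) {
      reason[i] <- if (is.na(prof$msi_status[i])) "MSI not evaluable"
                   else "marker(s) undefined"
    }
  }
  data.frame(sample_id = prof$sample_id, subtype = subtype,
             pole_positive = prof$pole_positive, msi_status = prof$msi_status,
             tp53_mutated = prof$tp53_mutated, tmb = prof$tmb, fga = prof$fga,
             reason = reason, stringsAsFactors = FALSE)
}

#' Write a classification table to TSV
#' @param classification output of [classify_cohort()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_classification <- function(classification, path) {
  cols <- c("sample_id", "subtype", "pole_positive", "msi_status",
            "tp53_mutated", "tmb", "fga")
  utils::write.table(classification[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
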