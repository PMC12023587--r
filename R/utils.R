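## Small internal helpers used across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero (arithmetic rounding)
#'
#' Base `round()` rounds half to even; printed cohort percentages follow the
#' usual half-up convention, so tables are reproduced with this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(8.1545, 2)  # 8.15
#' round_half_up(0.125, 2)   # 0.13 (base round() gives 0.12)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Classed errors so callers (and the CLI) can distinguish failure modes.
ec_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ec_error")))
}

ec_format_error     <- function(msg) ec_stop(msg, "ec_format_error")
ec_integrity_error  <- function(msg) ec_stop(msg, "ec_integrity_error")
ec_validation_error <- function(msg) ec_stop(msg, "ec_validation_error")
ec_config_error     <- function(msg) ec_stop(msg, "ec_config_error")
ec_degenerate_error <- function(msg) ec_stop(msg, "ec_degenerate_error")
ec_evaluability_error <- function(msg) ec_stop(msg, "ec_evaluability_error")
ec_usage_error      <- function(msg) ec_stop(msg, "ec_usage_error")

## Seed the global RNG for the duration of a call, restoring the previous
## state on exit. All package randomness flows through explicit seeds.
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    ec_config_error("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

## Parse the residue number out of a protein-change string such as
## "p.P286R", "P286R" or "p.Ser459Phe"; NA when absent.
hgvs_residue <- function(hgvs_p) {
  m <- regmatches(hgvs_p, regexpr("[0-9]+", hgvs_p))
  out <- rep(NA_integer_, length(hgvs_p))
  has <- lengths(regmatches(hgvs_p, gregexpr("[0-9]+", hgvs_p))) > 0
  out[has] <- as.integer(m)
  out
}

## Normalize protein-change notation for list membership tests.
normalize_hgvs <- function(hgvs_p) {
  x <- trimws(hgvs_p)
  x <- sub("^p\\.", "", x, ignore.case = TRUE)
  x <- sub("^\\(", "", x)
  x <- sub("\\)$", "", x)
  toupper(x)
}

age_band <- function(age) {
  band <- cut(age, breaks = c(-Inf, 49, 59, 69, Inf),
              labels = c("<50", "50-59", "60-69", ">=70"))
  band <- as.character(band)
  band[is.na(band)] <- "unknown"
  factor(band, levels = AGE_BAND_LEVELS)
}
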