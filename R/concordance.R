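## Classifier-agreement statistics: overall accuracy, Cohen's kappa, and
## percentile-bootstrap confidence intervals over paired resamples.

#' Overall accuracy and Cohen's kappa of two label vectors
#'
#' Accuracy is the fraction of exact matches; kappa is the chance-corrected
#' agreement \eqn{(p_o - p_e)/(1 - p_e)} with the expected agreement
#' \eqn{p_e} computed from the marginal label frequencies of each vector.
#' When both vectors are constant on the same label (so \eqn{p_e = 1}) kappa
#' is defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors over a shared alphabet.
#' @return list with `accuracy` and `kappa`.
#' @export
agreement_stats <- function(labels_a, labels_b) {
  code <- code_labels(labels_a, labels_b)
  stats <- kappa_from_codes(code$a, code$b, code$k)
  list(accuracy = stats[["accuracy"]], kappa = stats[["kappa"]])
}

code_labels <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    ec_validation_error("label vectors differ in length")
  }
  if (!length(labels_a)) ec_validation_error("empty label vectors")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  list(a = match(as.character(labels_a), lev),
       b = match(as.character(labels_b), lev),
       k = length(lev))
}

## kappa/accuracy from integer-coded labels; cell counts via tabulate so the
## bootstrap loop stays cheap.
kappa_from_codes <- function(a, b, k) {
  n <- length(a)
  cells <- tabulate((a - 1L) * k + b, nbins = k * k)
  cm <- matrix(cells, k, k, byrow = TRUE)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (1 - p_e < 1e-12) {
    if (p_o >= 1 - 1e-12) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  c(accuracy = p_o, kappa = kappa)
}

#' Percentile-bootstrap confidence interval for an agreement statistic
#'
#' Resamples subject indices (paired resampling) `n_boot` times and returns
#' the 2.5/97.5 percentile bounds of the statistic. Fully reproducible given
#' `seed`; the RNG state of the session is restored afterwards. Because
#' resampling operates on indices, permuting the input order changes the
#' bootstrap draws (the point estimates themselves are order-invariant).
#'
#' @param labels_a,labels_b paired label vectors (length >= 2).
#' @param statistic `"kappa"` (default), `"accuracy"`, or a function
#'   `f(labels_a, labels_b)` returning a scalar.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed RNG seed.
#' @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(labels_a, labels_b, statistic = "kappa",
                         n_boot = 1000, seed = 1L, conf_level = 0.95) {
  n <- length(labels_a)
  if (n < 2) ec_validation_error("bootstrap requires at least 2 subjects")
  if (n_boot < 1) ec_config_error("n_boot must be >= 1")
  restore <- local_seed(seed)
  on.exit(restore())
  alpha <- (1 - conf_level) / 2
  if (is.function(statistic)) {
    stat <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(labels_a[idx], labels_b[idx])
    }, numeric(1))
  } else {
    statistic <- match.arg(statistic, c("kappa", "accuracy"))
    code <- code_labels(labels_a, labels_b)
    pick <- if (statistic == "kappa") 2L else 1L
    stat <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      stat[i] <- kappa_from_codes(code$a[idx], code$b[idx], code$k)[pick]
    }
  }
  bounds <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = bounds[1], ci_high = bounds[2])
}

#' Accuracy and kappa with bootstrap confidence intervals
#'
#' Computes both agreement statistics and their percentile-bootstrap 95%
#' intervals in a single pass over the same resamples.
#'
#' @inheritParams bootstrap_ci
#' @return an object of class `kappa_result`: `accuracy`, `kappa`,
#'   `accuracy_ci`, `kappa_ci`, `n`, `n_boot`, `seed`.
#' @export
kappa_ci <- function(labels_a, labels_b, n_boot = 1000, seed = 1L,
                     conf_level = 0.95) {
  n <- length(labels_a)
  if (n < 2) ec_validation_error("bootstrap requires at least 2 subjects")
  code <- code_labels(labels_a, labels_b)
  point <- kappa_from_codes(code$a, code$b, code$k)
  restore <- local_seed(seed)
  on.exit(restore())
  acc <- numeric(n_boot)
  kap <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    s <- kappa_from_codes(code$a[idx], code$b[idx], code$k)
    acc[i] <- s[1L]
    kap[i] <- s[2L]
  }
  alpha <- (1 - conf_level) / 2
  structure(list(
    accuracy = point[["accuracy"]],
    kappa = point[["kappa"]],
    accuracy_ci = stats::quantile(acc, c(alpha, 1 - alpha), names = FALSE),
    kappa_ci = stats::quantile(kap, c(alpha, 1 - alpha), names = FALSE),
    n = n, n_boot = n_boot, seed = seed
  ), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Agreement over %d samples (%d bootstrap resamples, seed %s):\n",
              x$n, x$n_boot, format(x$seed)))
  cat(sprintf("  accuracy = %.4f  [%.4f, %.4f]\n", x$accuracy,
              x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("  kappa    = %.4f  [%.4f, %.4f]\n", x$kappa,
              x$kappa_ci[1], x$kappa_ci[2]))
  invisible(x)
}
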