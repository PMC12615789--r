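# Probability calibration for the binary natural-forest output: temperature
# scaling on the logit scale, fitted by maximum likelihood, and reliability
# assessment with adaptive (equal-count) binning.

PROB_CLAMP <- 1e-6

clamp_probs <- function(p) pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)

#' Apply temperature scaling to probabilities
#'
#' Maps \code{p} to \code{plogis(qlogis(p) / T)}. \code{T = 1} is the
#' identity; \code{T > 1} softens overconfident probabilities toward 0.5.
#' The map is strictly increasing, so thresholding calibrated probabilities
#' is equivalent to thresholding raw ones at the transformed threshold.
#'
#' @param p probabilities (clamped to [1e-6, 1 - 1e-6] before the logit).
#' @param temperature positive scalar T; the full-scale map was released
#'   with T = 1.4.
#' @return Calibrated probabilities, same shape as \code{p}.
#' @export
apply_temperature <- function(p, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 0)
    stop_invalid("temperature must be a positive scalar")
  stats::plogis(stats::qlogis(clamp_probs(p)) / temperature)
}

#' Fit a calibration temperature by maximum likelihood
#'
#' Minimizes the mean negative log-likelihood of
#' \code{apply_temperature(p, T)} against binary labels by 1-D minimization
#' over \code{log T} in \code{[log 0.1, log 10]}. Deterministic. When the
#' probabilities carry no information on the logit scale (all equal 0.5)
#' any temperature is optimal and T = 1 is returned by convention.
#'
#' @param probs predicted probabilities (n >= 100).
#' @param labels binary 0/1 reference labels; both classes must be present.
#' @return List of class \code{calibration_model} with element
#'   \code{temperature}.
#' @export
fit_temperature <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  if (length(probs) < 100)
    stop_invalid("need at least 100 observations to fit a temperature")
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop_invalid("labels are degenerate: both classes must be present")
  z <- stats::qlogis(clamp_probs(probs))
  y <- as.numeric(labels)
  if (stats::sd(z) == 0)
    return(structure(list(temperature = 1), class = "calibration_model"))
  nll <- function(logT) {
    q <- stats::plogis(z / exp(logT))
    q <- clamp_probs(q)
    -mean(y * log(q) + (1 - y) * log(1 - q))
  }
  opt <- stats::optimize(nll, c(log(0.1), log(10)), tol = 1e-8)
  structure(list(temperature = exp(opt$minimum)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> temperature T = %.4f\n", x$temperature))
  invisible(x)
}

#' Reliability table with adaptive (equal-count) binning
#'
#' Sorts predictions, splits them into \code{n_bins} bins whose counts
#' differ by at most one, and compares the mean predicted probability with
#' the (optionally design-weighted) empirical positive fraction per bin.
#' The expected calibration error (ECE) is the count-weighted mean absolute
#' gap.
#'
#' @param probs predicted probabilities.
#' @param labels binary 0/1 labels.
#' @param n_bins number of adaptive bins.
#' @param weights optional per-observation design weights (e.g. stratum
#'   inclusion weights) applied to the empirical fractions.
#' @return List of class \code{reliability_table}: \code{bins} data.frame
#'   (count, mean_pred, emp_frac, lo, hi), \code{ece}.
#' @export
reliability <- function(probs, labels, n_bins = 10, weights = NULL) {
  n <- length(probs)
  stopifnot(length(labels) == n)
  if (n < n_bins) stop_invalid("need at least n_bins observations")
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(probs)
  bin <- ceiling(seq_len(n) * n_bins / n)   # equal counts +/- 1
  p <- probs[ord]; y <- as.numeric(labels)[ord]; w <- weights[ord]
  bins <- data.frame(
    count = as.integer(tapply(p, bin, length)),
    mean_pred = as.numeric(tapply(p, bin, mean)),
    emp_frac = as.numeric(tapply(seq_along(p), bin, function(i)
      sum(w[i] * y[i]) / sum(w[i]))),
    lo = as.numeric(tapply(p, bin, min)),
    hi = as.numeric(tapply(p, bin, max)))
  ece <- sum(bins$count / n * abs(bins$mean_pred - bins$emp_frac))
  structure(list(bins = bins, ece = ece), class = "reliability_table")
}

#' @export
print.reliability_table <- function(x, ...) {
  cat(sprintf("<reliability_table> %d bins, ECE = %.4f\n",
              nrow(x$bins), x$ece))
  print(x$bins)
  invisible(x)
}
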