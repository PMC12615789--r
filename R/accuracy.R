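# Design-based accuracy assessment against stratified validation plots:
# plot-majority aggregation, general stratified estimators for OA and for
# user's / producer's accuracy as combined ratio estimators with
# Taylor-linearized variance, threshold sweeps, and high-confidence
# commission/omission summaries.

#' Plot-level prediction by strict pixel majority
#'
#' Thresholds every pixel probability in the plot footprint at \code{p >=
#' t} and calls the plot natural (1) when strictly more than half of the
#' pixels are positive.
#'
#' @param probs numeric vector/matrix of pixel probabilities within the
#'   100 x 100 m footprint.
#' @param threshold probability threshold.
#' @return 0 or 1.
#' @export
plot_prediction <- function(probs, threshold) {
  if (length(probs) == 0) stop_invalid("empty plot footprint")
  as.integer(mean(probs >= threshold) > 0.5)
}

# plot probabilities -> per-plot binary predictions at one threshold
predict_plots <- function(plot_probs, threshold) {
  vapply(plot_probs, plot_prediction, 0L, threshold = threshold)
}

#' Extract per-plot pixel probabilities from a probability map
#'
#' @param map a \code{probability_map} or plain matrix of probabilities on
#'   the truth grid.
#' @param plots data.frame with \code{row}, \code{col} giving the top-left
#'   pixel of each 10 x 10-pixel footprint.
#' @return List of numeric vectors, one per plot.
#' @export
extract_plot_probs <- function(map, plots) {
  vals <- if (inherits(map, "probability_map")) map$values else map
  lapply(seq_len(nrow(plots)), function(i) {
    r <- plots$row[i]; c <- plots$col[i]
    as.vector(vals[r:(r + 9), c:(c + 9)])
  })
}

# per-stratum means, variances and covariance of indicator pairs
strata_moments <- function(y, x, stratum, spec) {
  hs <- spec$stratum
  out <- lapply(hs, function(h) {
    i <- which(stratum == h)
    n_h <- length(i)
    list(n = n_h,
         ybar = mean(y[i]), xbar = mean(x[i]),
         s2y = if (n_h > 1) stats::var(y[i]) else 0,
         s2x = if (n_h > 1) stats::var(x[i]) else 0,
         sxy = if (n_h > 1) stats::cov(y[i], x[i]) else 0)
  })
  names(out) <- as.character(hs)
  out
}

# stratified total estimator and its variance components
strat_ratio <- function(y, x, stratum, spec) {
  mom <- strata_moments(y, x, stratum, spec)
  N <- sum(spec$N_h)
  Yhat <- sum(spec$N_h * vapply(mom, `[[`, 0, "ybar"))
  Xhat <- sum(spec$N_h * vapply(mom, `[[`, 0, "xbar"))
  if (Xhat == 0)
    return(list(est = NA_real_, se = NA_real_))
  R <- Yhat / Xhat
  v <- 0
  for (k in seq_along(mom)) {
    m <- mom[[k]]
    fpc <- 1 - m$n / spec$N_h[k]
    v <- v + spec$N_h[k]^2 * fpc *
      (m$s2y + R^2 * m$s2x - 2 * R * m$sxy) / m$n
  }
  list(est = R, se = sqrt(max(v, 0)) / Xhat)
}

#' Design-based stratified accuracy estimates
#'
#' Computes overall accuracy as a stratified mean of the agreement
#' indicator, and user's / producer's accuracy of the natural-forest class
#' as combined ratio estimators \code{R = Yhat / Xhat} over stratum totals,
#' with Taylor-linearized variances including the finite-population
#' correction \code{1 - n_h / N_h}. Standard errors use the per-stratum
#' sample variances; a stratum with a single plot contributes its mean with
#' a zero variance term (warned). 95\% confidence intervals are
#' \code{estimate +/- 1.96 SE}, clipped to [0, 1].
#'
#' @param predictions integer 0/1 plot predictions.
#' @param plots validation plot data.frame with columns \code{ref_label}
#'   and \code{stratum}.
#' @param strata_spec data.frame with columns \code{stratum} and
#'   \code{N_h} (population size per stratum).
#' @param threshold optional threshold recorded in the report.
#' @return Object of class \code{accuracy_report}: data.frame with rows
#'   OA/UA/PA and columns estimate, se, ci_lo, ci_hi; plus \code{n} and the
#'   strata summary.
#' @export
stratified_accuracy <- function(predictions, plots, strata_spec,
                                threshold = NA_real_) {
  stopifnot(length(predictions) == nrow(plots))
  spec <- strata_spec[order(strata_spec$stratum), , drop = FALSE]
  hs_data <- sort(unique(plots$stratum))
  if (!all(hs_data %in% spec$stratum))
    stop_invalid("plots reference strata missing from strata_spec: %s",
                 paste(setdiff(hs_data, spec$stratum), collapse = ", "))
  spec <- spec[spec$stratum %in% hs_data, , drop = FALSE]
  if (any(spec$N_h <= 0)) stop_invalid("stratum population sizes must be > 0")
  n_h <- vapply(spec$stratum, function(h) sum(plots$stratum == h), 0L)
  if (any(n_h > spec$N_h))
    stop_invalid("stratum sample exceeds its population size")
  if (any(n_h == 1))
    warning("stratum with a single plot: zero variance contribution",
            call. = FALSE)
  pred <- as.numeric(predictions)
  ref <- as.numeric(plots$ref_label)
  one <- rep(1, length(pred))

  oa <- strat_ratio(as.numeric(pred == ref), one, plots$stratum, spec)
  ua <- strat_ratio(as.numeric(pred == 1 & ref == 1), pred,
                    plots$stratum, spec)
  pa <- strat_ratio(as.numeric(pred == 1 & ref == 1), ref,
                    plots$stratum, spec)

  tab <- do.call(rbind, lapply(list(OA = oa, UA = ua, PA = pa), function(r)
    data.frame(estimate = r$est, se = r$se,
               ci_lo = max(0, r$est - 1.96 * r$se),
               ci_hi = min(1, r$est + 1.96 * r$se))))
  tab <- cbind(metric = rownames(tab), tab)
  rownames(tab) <- NULL
  structure(list(threshold = threshold, metrics = tab,
                 n = nrow(plots),
                 strata = cbind(spec, n_h = n_h)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  if (!is.na(x$threshold))
    cat(sprintf("Accuracy report at threshold %.3f (n = %d plots)\n",
                x$threshold, x$n))
  else cat(sprintf("Accuracy report (n = %d plots)\n", x$n))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s = %5.1f%% (SE %.1f%%)  95%% CI [%.1f%%, %.1f%%]\n",
                m$metric[i], 100 * m$estimate[i], 100 * m$se[i],
                100 * m$ci_lo[i], 100 * m$ci_hi[i]))
  invisible(x)
}

#' Accuracy sweep over probability thresholds
#'
#' Re-evaluates the stratified estimates on a threshold grid and locates
#' the OA-optimal threshold (ties to the smallest), the balanced threshold
#' minimizing \code{|UA - PA|}, and the near-optimal band of thresholds
#' whose OA is within 1 percentage point of the maximum.
#'
#' @param plot_probs list of per-plot pixel probability vectors (see
#'   \code{\link{extract_plot_probs}}).
#' @param plots,strata_spec as in \code{\link{stratified_accuracy}}.
#' @param grid strictly increasing threshold grid in [0, 1].
#' @return Object of class \code{threshold_curve}: \code{curve} data.frame
#'   (threshold, oa, oa_se, ua, ua_se, pa, pa_se, n_pred_pos),
#'   \code{t_oa}, \code{t_balanced}, \code{band} (range of near-optimal
#'   thresholds).
#' @export
threshold_sweep <- function(plot_probs, plots, strata_spec,
                            grid = seq(0, 1, by = 0.01)) {
  if (any(diff(grid) <= 0) || any(grid < 0 | grid > 1))
    stop_invalid("grid must be strictly increasing within [0, 1]")
  rows <- lapply(grid, function(t) {
    pred <- predict_plots(plot_probs, t)
    rep <- stratified_accuracy(pred, plots, strata_spec, threshold = t)
    m <- rep$metrics
    data.frame(threshold = t,
               oa = m$estimate[1], oa_se = m$se[1],
               ua = m$estimate[2], ua_se = m$se[2],
               pa = m$estimate[3], pa_se = m$se[3],
               n_pred_pos = sum(pred))
  })
  curve <- do.call(rbind, rows)
  t_oa <- curve$threshold[which.max(curve$oa)]
  gap <- abs(curve$ua - curve$pa)
  t_balanced <- curve$threshold[which.min(gap)]
  near <- curve$threshold[curve$oa >= max(curve$oa, na.rm = TRUE) - 0.01]
  structure(list(curve = curve, t_oa = t_oa, t_balanced = t_balanced,
                 band = range(near)),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(paste0("<threshold_curve> %d thresholds; t_oa = %.2f, ",
                     "t_balanced = %.2f, near-optimal band [%.2f, %.2f]\n"),
              nrow(x$curve), x$t_oa, x$t_balanced, x$band[1], x$band[2]))
  invisible(x)
}

#' High-confidence commission and omission error summary
#'
#' Unweighted counts: among plots predicted natural at \code{p >= t_hi}
#' (plot-majority rule), the number and fraction whose reference is other
#' (commission at high confidence); among plots predicted other with all
#' evidence below \code{t_lo}, the number and fraction whose reference is
#' natural (omission at high confidence). Empty selections report rate 0
#' with n = 0.
#'
#' @param plot_probs list of per-plot pixel probability vectors, or a
#'   numeric vector of one summary probability per plot.
#' @param ref_labels binary reference labels per plot.
#' @param t_hi,t_lo high/low confidence thresholds with
#'   \code{t_lo < t_hi}.
#' @return List: \code{commission} and \code{omission}, each with
#'   \code{n}, \code{errors}, \code{rate}.
#' @export
error_rates_at_extremes <- function(plot_probs, ref_labels, t_hi = 0.95,
                                    t_lo = 0.05) {
  if (t_lo >= t_hi) stop_invalid("t_lo must be smaller than t_hi")
  ref <- as.integer(ref_labels)
  if (is.list(plot_probs)) {
    pred_hi <- predict_plots(plot_probs, t_hi) == 1L
    pred_lo_other <- predict_plots(plot_probs, t_lo) == 0L
  } else {
    pred_hi <- plot_probs >= t_hi
    pred_lo_other <- plot_probs < t_lo
  }
  n_hi <- sum(pred_hi)
  e_hi <- sum(pred_hi & ref == 0L)
  n_lo <- sum(pred_lo_other)
  e_lo <- sum(pred_lo_other & ref == 1L)
  list(commission = list(n = n_hi, errors = e_hi,
                         rate = if (n_hi > 0) e_hi / n_hi else 0),
       omission = list(n = n_lo, errors = e_lo,
                       rate = if (n_lo > 0) e_lo / n_lo else 0))
}

#' Read a validation-plot CSV
#'
#' Parses the released-schema CSV (columns \code{plot_id}, \code{lon},
#' \code{lat}, \code{ref_label}, \code{stratum}, optional \code{region},
#' \code{row}, \code{col}) with validation: labels must be binary, plot ids
#' unique, strata positive integers. Stratum sample sizes are tallied from
#' the file; population sizes \code{N_h} come from \code{strata_sizes} when
#' the design totals are known (self-weighting \code{N_h = n_h} otherwise).
#'
#' @param path CSV path.
#' @param strata_sizes optional named vector or data.frame
#'   (\code{stratum}, \code{N_h}) of population sizes.
#' @return List \code{plots} (data.frame) and \code{strata} (data.frame
#'   with stratum, N_h, n_h).
#' @export
read_validation_csv <- function(path, strata_sizes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("validation file %s is empty", path)
  required <- c("plot_id", "lon", "lat", "ref_label", "stratum")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("validation file is missing column(s): %s",
                 paste(missing, collapse = ", "))
  dup <- duplicated(df$plot_id)
  if (any(dup))
    stop_invalid("duplicated plot_id at row %d: %s", which(dup)[1],
                 df$plot_id[which(dup)[1]])
  bad <- which(!(df$ref_label %in% c(0, 1)))
  if (length(bad))
    stop_invalid("non-binary ref_label at row %d", bad[1])
  bad <- which(is.na(df$stratum) | df$stratum < 1 |
                 df$stratum != as.integer(df$stratum))
  if (length(bad))
    stop_invalid("invalid stratum index at row %d", bad[1])
  if (!"region" %in% names(df)) df$region <- "global"
  hs <- sort(unique(df$stratum))
  n_h <- vapply(hs, function(h) sum(df$stratum == h), 0L)
  if (is.null(strata_sizes)) {
    N_h <- n_h
  } else if (is.data.frame(strata_sizes)) {
    N_h <- strata_sizes$N_h[match(hs, strata_sizes$stratum)]
  } else {
    N_h <- as.numeric(strata_sizes[as.character(hs)])
  }
  if (any(is.na(N_h)))
    stop_invalid("strata_sizes does not cover stratum %s",
                 hs[which(is.na(N_h))[1]])
  list(plots = df, strata = data.frame(stratum = hs, N_h = N_h, n_h = n_h))
}

#' Write validation plots to the released CSV schema
#'
#' @param plots validation plot data.frame.
#' @param path output CSV path.
#' @export
write_validation_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-region accuracy breakdown
#'
#' Re-runs the stratified estimator within each region tag; with a single
#' region covering all plots this reproduces the global report.
#'
#' @inheritParams stratified_accuracy
#' @return Named list of \code{accuracy_report} by region.
#' @export
regional_accuracy <- function(predictions, plots, strata_spec,
                              threshold = NA_real_) {
  regions <- unique(plots$region)
  out <- lapply(regions, function(rg) {
    i <- plots$region == rg
    stratified_accuracy(predictions[i], plots[i, , drop = FALSE],
                        strata_spec, threshold = threshold)
  })
  names(out) <- regions
  out
}
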