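# independent direct evaluation of the stratified estimators, written out
# symbol by symbol for use as a test oracle
oracle_strat <- function(y, x, stratum, N_h) {
  hs <- sort(unique(stratum))
  Yhat <- 0; Xhat <- 0
  for (k in seq_along(hs)) {
    i <- stratum == hs[k]
    Yhat <- Yhat + N_h[k] * mean(y[i])
    Xhat <- Xhat + N_h[k] * mean(x[i])
  }
  R <- Yhat / Xhat
  V <- 0
  for (k in seq_along(hs)) {
    i <- stratum == hs[k]
    n_h <- sum(i)
    s2y <- var(y[i]); s2x <- var(x[i]); sxy <- cov(y[i], x[i])
    V <- V + N_h[k]^2 * (1 - n_h / N_h[k]) *
      (s2y + R^2 * s2x - 2 * R * sxy) / n_h
  }
  list(est = R, se = sqrt(V) / Xhat)
}

# small two-stratum population with specified per-stratum confusion counts:
# rows are (pred, ref) cells (1,1), (1,0), (0,1), (0,0)
make_population <- function(counts_by_stratum) {
  pop <- do.call(rbind, lapply(seq_along(counts_by_stratum), function(h) {
    cc <- counts_by_stratum[[h]]
    data.frame(
      stratum = h,
      pred = rep(c(1, 1, 0, 0), cc),
      ref = rep(c(1, 0, 1, 0), cc))
  }))
  pop$id <- seq_len(nrow(pop))
  pop
}

test_that("plot-majority prediction uses a strict >50% rule", {
  probs <- c(rep(0.9, 51), rep(0.1, 49))
  expect_equal(plot_prediction(probs, 0.5), 1L)
  expect_equal(plot_prediction(c(rep(0.9, 50), rep(0.1, 50)), 0.5), 0L)
  expect_equal(plot_prediction(rep(0.001, 100), 0), 1L)
  expect_error(plot_prediction(numeric(0), 0.5), "empty")
})

test_that("census limit: estimates equal raw confusion rates with zero SE", {
  pop <- make_population(list(c(30, 5, 8, 57))) # single stratum, N = 100
  plots <- data.frame(ref_label = pop$ref, stratum = pop$stratum)
  spec <- data.frame(stratum = 1, N_h = 100)
  rep <- stratified_accuracy(pop$pred, plots, spec)
  m <- rep$metrics
  expect_equal(m$estimate[m$metric == "OA"], (30 + 57) / 100)
  expect_equal(m$estimate[m$metric == "UA"], 30 / 35)
  expect_equal(m$estimate[m$metric == "PA"], 30 / 38)
  expect_equal(m$se, rep(0, 3))
})

test_that("self-weighting designs reduce to unweighted proportions", {
  set.seed(71)
  n <- 200
  plots <- data.frame(ref_label = rbinom(n, 1, 0.4),
                      stratum = rep(1:2, each = n / 2))
  pred <- rbinom(n, 1, 0.5)
  # N_h proportional to n_h (here equal) -> estimates are plain proportions
  spec <- data.frame(stratum = 1:2, N_h = c(5000, 5000))
  m <- stratified_accuracy(pred, plots, spec)$metrics
  expect_equal(m$estimate[1], mean(pred == plots$ref_label))
  expect_equal(m$estimate[2],
               sum(pred == 1 & plots$ref_label == 1) / sum(pred == 1))
  expect_equal(m$estimate[3],
               sum(pred == 1 & plots$ref_label == 1) /
                 sum(plots$ref_label == 1))
})

test_that("two-strata estimates match the direct formula oracle", {
  set.seed(72)
  pop <- make_population(list(c(120, 30, 25, 225), c(40, 60, 80, 420)))
  N_h <- c(400, 600)
  # draw one stratified sample and compare implementation vs oracle
  samp <- do.call(rbind, lapply(1:2, function(h) {
    rows <- pop[pop$stratum == h, ]
    rows[sample(nrow(rows), 80), ]
  }))
  plots <- data.frame(ref_label = samp$ref, stratum = samp$stratum)
  spec <- data.frame(stratum = 1:2, N_h = N_h)
  m <- stratified_accuracy(samp$pred, plots, spec)$metrics
  o_oa <- oracle_strat(as.numeric(samp$pred == samp$ref),
                       rep(1, nrow(samp)), samp$stratum, N_h)
  o_ua <- oracle_strat(as.numeric(samp$pred == 1 & samp$ref == 1),
                       samp$pred, samp$stratum, N_h)
  o_pa <- oracle_strat(as.numeric(samp$pred == 1 & samp$ref == 1),
                       samp$ref, samp$stratum, N_h)
  expect_equal(m$estimate, c(o_oa$est, o_ua$est, o_pa$est),
               tolerance = 1e-12)
  expect_equal(m$se, c(o_oa$se, o_ua$se, o_pa$se), tolerance = 1e-12)
  # UA and PA are invariant to a common rescaling of all N_h
  m10 <- stratified_accuracy(samp$pred, plots,
                             data.frame(stratum = 1:2,
                                        N_h = 10000 * N_h))$metrics
  expect_equal(m10$estimate[2:3], m$estimate[2:3], tolerance = 1e-12)
  # no predicted positives -> UA reported as not available
  m0 <- stratified_accuracy(rep(0, nrow(samp)), plots, spec)$metrics
  expect_true(is.na(m0$estimate[2]))
})

test_that("threshold sweep: prevalence identity, monotonicity, bands", {
  set.seed(73)
  truth <- matrix(0L, 60, 60)
  truth[, 1:33] <- 1L
  vs <- generate_validation_set(2, 2L, truth, n_per_stratum = 12)
  # separable probabilities: natural plots ~0.9, other ~0.1
  probs <- matrix(0.1, 60, 60)
  probs[truth == 1L] <- 0.9
  plot_probs <- extract_plot_probs(probs, vs$plots)
  sw <- threshold_sweep(plot_probs, vs$plots, vs$strata,
                        grid = seq(0, 1, by = 0.05))
  # at threshold 0 everything is positive: UA equals the stratified
  # prevalence of reference positives
  prev <- sum(vs$strata$N_h *
                tapply(vs$plots$ref_label, vs$plots$stratum, mean)) /
    sum(vs$strata$N_h)
  expect_equal(sw$curve$ua[1], prev, tolerance = 1e-12)
  # predicted-positive count is non-increasing in the threshold
  expect_true(all(diff(sw$curve$n_pred_pos) <= 0))
  # perfectly separable probabilities: OA = 1 strictly inside (0.1, 0.9]
  inside <- sw$curve$threshold > 0.1 & sw$curve$threshold <= 0.9
  expect_true(all(sw$curve$oa[inside] == 1))
  expect_true(sw$t_oa %in% sw$curve$threshold)
  expect_true(sw$t_balanced %in% sw$curve$threshold)
  expect_true(sw$band[1] <= sw$t_oa && sw$t_oa <= sw$band[2])
})

test_that("high-confidence commission/omission summaries count correctly", {
  # per-plot summary probabilities with known composition
  probs <- c(rep(0.97, 47), rep(0.5, 10), rep(0.01, 997))
  ref <- c(rep(1, 43), rep(0, 4), rep(1, 10), rep(1, 60), rep(0, 937))
  er <- error_rates_at_extremes(probs, ref, t_hi = 0.95, t_lo = 0.05)
  expect_equal(er$commission$n, 47)
  expect_equal(er$commission$errors, 4)
  expect_equal(round(100 * er$commission$rate, 1), 8.5)
  expect_equal(er$omission$n, 997)
  expect_equal(er$omission$errors, 60)
  expect_equal(round(100 * er$omission$rate), 6)
  # empty selections report zero counts and rate 0
  er0 <- error_rates_at_extremes(rep(0.5, 10), rep(1, 10))
  expect_equal(er0$commission$n, 0)
  expect_equal(er0$commission$rate, 0)
  expect_error(error_rates_at_extremes(probs, ref, t_hi = 0.1, t_lo = 0.5),
               "smaller")
})

test_that("validation CSV parsing validates schema and tallies strata", {
  path <- fix_validation_csv()
  v <- read_validation_csv(path)
  expect_equal(nrow(v$plots), 2072)
  expect_equal(sum(v$plots$ref_label == 1), 800)
  expect_equal(sum(v$plots$ref_label == 0), 1272)
  expect_equal(sum(v$strata$n_h), 2072)
  # population sizes can be supplied explicitly
  v2 <- read_validation_csv(path, strata_sizes = data.frame(
    stratum = 1:4, N_h = c(1e5, 2e5, 3e5, 4e5)))
  expect_equal(v2$strata$N_h, c(1e5, 2e5, 3e5, 4e5))
  # malformed inputs are rejected with informative errors
  empty <- tempfile(fileext = ".csv")
  writeLines("plot_id,lon,lat,ref_label,stratum", empty)
  expect_error(read_validation_csv(empty), "empty")
  missing <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,lon,lat", "a,0,0"), missing)
  expect_error(read_validation_csv(missing), "ref_label")
  dup <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,lon,lat,ref_label,stratum",
               "a,0,0,1,1", "a,1,1,0,1"), dup)
  expect_error(read_validation_csv(dup), "duplicated")
  nonbin <- tempfile(fileext = ".csv")
  writeLines(c("plot_id,lon,lat,ref_label,stratum",
               "a,0,0,2,1"), nonbin)
  expect_error(read_validation_csv(nonbin), "non-binary")
})

test_that("regional breakdown with one region reproduces the global report", {
  set.seed(74)
  plots <- data.frame(ref_label = rbinom(120, 1, 0.5),
                      stratum = rep(1:2, 60), region = "global")
  pred <- rbinom(120, 1, 0.5)
  spec <- data.frame(stratum = 1:2, N_h = c(1000, 3000))
  whole <- stratified_accuracy(pred, plots, spec)
  reg <- regional_accuracy(pred, plots, spec)
  expect_equal(reg$global$metrics, whole$metrics)
})
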