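test_that("topography: flat surface has zero slope and convention aspect", {
  flat <- topo_from_elevation(matrix(250, 20, 20))
  expect_true(all(flat[1, , , 2] == 0))
  expect_true(all(flat[1, , , 3] == 0))
})

test_that("topography: inclined plane matches the analytic slope/aspect", {
  # elevation rises northward (row 1 is north) by g per 10 m pixel:
  # downslope points due south => aspect 180, slope atan(g/10)
  g <- 3
  n <- 24
  elev <- matrix(rep(g * (n:1), times = n), n, n)
  topo <- topo_from_elevation(elev)
  expected_slope <- atan(g / 10) * 180 / pi
  # interior pixels see the exact plane gradient (edges are replicated)
  expect_equal(as.vector(topo[1, 2:(n - 1), 2:(n - 1), 2]),
               rep(expected_slope, (n - 2)^2), tolerance = 1e-12)
  expect_equal(as.vector(topo[1, , , 3]), rep(180, n * n), tolerance = 1e-12)
  # eastward-rising plane: downslope west => aspect 270
  elev_e <- matrix(rep(g * (1:n), each = n), n, n)
  expect_equal(as.vector(topo_from_elevation(elev_e)[1, , , 3]),
               rep(270, n * n), tolerance = 1e-12)
})

test_that("generators are deterministic in the seed and validate arguments", {
  expect_identical(generate_topography(11, 32), generate_topography(11, 32))
  expect_error(generate_topography(1, 8), "size")
  a <- generate_scene(5, scene_layout(size = 32))
  b <- generate_scene(5, scene_layout(size = 32))
  expect_identical(a$sample$s2, b$sample$s2)
  expect_identical(a$stack$tree_height, b$stack$tree_height)
  expect_error(scene_layout(fractions = c(`1` = 0.7, `6` = 0.5)), "sum")
  expect_error(scene_layout(fractions = c(0.5, 0.5)), "named")
})

test_that("scene samples satisfy their shape and range invariants", {
  s <- fix_scene()$sample
  expect_equal(dim(s$s2), c(4, 32, 32, 10))
  expect_equal(dim(s$topo), c(1, 32, 32, 3))
  expect_true(all(is.finite(s$s2)) && all(s$s2 >= 0) && all(s$s2 <= 1))
  expect_equal(sqrt(sum(s$loc^2)), 1, tolerance = 1e-9)
  expect_true(all(s$labels %in% 0:8))
  expect_true(all(s$topo[1, , , 2] >= 0))
})

test_that("noiseless source layers equal the true class maps", {
  sc <- fix_scene()
  expect_identical(sc$stack$tmf_natural, sc$sample$labels == 1L)
  expect_identical(sc$stack$planted_src, sc$sample$labels == 2L)
  expect_identical(sc$stack$water_src, sc$sample$labels == 6L)
})

test_that("an all-water layout keeps NIR/SWIR means under the water ceiling", {
  layout <- scene_layout(fractions = c(`6` = 1), size = 32, n_seeds = 6)
  s <- generate_scene(2, layout)$sample
  expect_true(all(s$labels == 6L))
  for (t in 1:4) for (b in 7:10)
    expect_lt(mean(s$s2[t, , , b]), layout$water_ceiling)
})

test_that("realized natural-forest fraction tracks the configured fraction", {
  layout <- scene_layout(size = 128)
  fr <- vapply(1:20, function(i)
    mean(generate_scene(i, layout)$sample$labels == 1L), 0)
  expect_lt(abs(mean(fr) - 0.35), 0.03)
})

test_that("source corruption rates match their configured values", {
  layout <- scene_layout(size = 128, source_fp = 0.05, source_fn = 0.10)
  # pool flip counts over scenes and layers for a stable binomial check
  fp_flips <- 0; fp_n <- 0; fn_flips <- 0; fn_n <- 0
  for (seed in 31:33) {
    sc <- generate_scene(seed, layout)
    truth <- sc$sample$labels == 1L
    for (nm in c("tmf_natural", "sbtn_natural")) {
      layer <- sc$stack[[nm]]
      fp_flips <- fp_flips + sum(layer[!truth]); fp_n <- fp_n + sum(!truth)
      fn_flips <- fn_flips + sum(!layer[truth]); fn_n <- fn_n + sum(truth)
    }
  }
  # binomial 99% bounds at the pooled counts
  expect_lt(abs(fp_flips / fp_n - 0.05),
            2.576 * sqrt(0.05 * 0.95 / fp_n) + 1e-12)
  expect_lt(abs(fn_flips / fn_n - 0.10),
            2.576 * sqrt(0.10 * 0.90 / fn_n) + 1e-12)
})

test_that("high-separation noiseless scenes are nearest-centroid separable", {
  layout <- scene_layout(size = 32, separation = 1.5, noise_sd = 0,
                         corr_sd = 0, texture_amp = 0)
  scenes <- lapply(1:4, function(i) generate_scene(100 + i, layout)$sample)
  X <- do.call(rbind, lapply(scenes, function(s) {
    m <- apply(s$s2, c(2, 3, 4), mean)
    cbind(matrix(m, ncol = 10), as.vector(s$labels))
  }))
  lab <- X[, 11]; X <- X[, 1:10]
  keep <- lab != 0
  centroids <- sapply(1:8, function(k)
    colMeans(X[lab == k, , drop = FALSE]))
  d <- as.matrix(dist(rbind(t(centroids), X[keep, ])))[-(1:8), 1:8]
  expect_gt(mean(max.col(-d) == lab[keep]), 0.99)
})

test_that("validation sampling respects strata and the census limit", {
  truth <- matrix(0L, 60, 60)
  truth[1:60, 1:30] <- 1L                       # left half natural
  strata <- matrix(rep(c(1L, 2L), each = 3), 6, 6, byrow = TRUE)
  # census: every unit appears exactly once
  vs <- generate_validation_set(1, strata, truth, n_per_stratum = 18)
  expect_equal(nrow(vs$plots), 36)
  expect_equal(anyDuplicated(vs$plots$plot_id), 0)
  expect_equal(vs$strata$N_h, c(18L, 18L))
  # disjoint strata: no plot id in both
  s1 <- vs$plots$plot_id[vs$plots$stratum == 1]
  s2 <- vs$plots$plot_id[vs$plots$stratum == 2]
  expect_length(intersect(s1, s2), 0)
  expect_error(generate_validation_set(1, strata, truth, 19),
               "insufficient")
})

test_that("sampled prevalence matches the stratum prevalence (binomial MC)", {
  # 900 footprints, 60% fully natural, single stratum, n = 500
  set.seed(4)
  units <- sample(rep(c(1L, 0L), c(540, 360)))
  truth <- matrix(0L, 300, 300)
  for (u in which(units == 1L)) {
    i <- (u - 1) %% 30; j <- (u - 1) %/% 30
    truth[(10 * i + 1):(10 * i + 10), (10 * j + 1):(10 * j + 10)] <- 1L
  }
  strata <- matrix(1L, 30, 30)
  prev <- vapply(1:20, function(s)
    mean(generate_validation_set(s, strata, truth, 500)$plots$ref_label), 0)
  expect_lt(abs(mean(prev) - 0.60), 0.05)
})
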