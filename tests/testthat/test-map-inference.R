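test_that("window planning covers regions at the required stride", {
  # a region exactly one window wide gets a single centered window
  one <- plan_windows(c(xmin = 0, ymin = 0, xmax = 1280, ymax = 1280))
  expect_equal(nrow(one), 1)
  expect_equal(unname(one[1, ]), c(640, 640))
  # span of window + one stride -> two centers per axis
  two <- plan_windows(c(xmin = 0, ymin = 0, xmax = 1490, ymax = 1490),
                      stride = 210)
  expect_equal(nrow(two), 4)
  expect_equal(sort(unique(two[, 1])), c(640, 850))
  # every interior pixel of random regions is covered by >= 1 window
  set.seed(21)
  for (rep in 1:5) {
    w <- 1280 + round(runif(1, 0, 2000) / 10) * 10
    h <- 1280 + round(runif(1, 0, 2000) / 10) * 10
    centers <- plan_windows(c(xmin = 0, ymin = 0, xmax = w, ymax = h))
    px <- seq(5, w - 5, by = 10)
    py <- seq(5, h - 5, by = 10)
    covx <- outer(px, centers[, 1], function(x, c) abs(x - c) <= 640)
    covy <- outer(py, centers[, 2], function(y, c) abs(y - c) <= 640)
    # pixel (i,j) covered iff some window covers both of its coordinates
    expect_true(all((covx * 1) %*% t(covy * 1) > 0))
  }
})

test_that("stitching identities: single window and constant fields", {
  geo <- geo_ref(0, 1280)
  tile <- matrix(runif(128 * 128), 128, 128)
  single <- list(list(tile = tile, cx = 640, cy = 640, geo = geo))
  out <- stitch(single)
  expect_equal(out$values, tile)
  # all windows constant c -> constant c everywhere covered
  preds <- list(
    list(tile = matrix(0.4, 128, 128), cx = 640, cy = 640, geo = geo),
    list(tile = matrix(0.4, 128, 128), cx = 850, cy = 640,
         geo = geo_ref(210, 1280)))
  cons <- stitch(preds)
  expect_equal(max(abs(cons$values - 0.4), na.rm = TRUE), 0,
               tolerance = 1e-12)
})

test_that("stitching matches a scalar weighted-mean oracle", {
  # two 1x3-pixel windows overlapping on the middle pixel column
  geo1 <- geo_ref(0, 10); geo2 <- geo_ref(10, 10)
  t1 <- matrix(c(0.2, 0.4, 0.6), 1)
  t2 <- matrix(c(0.9, 0.5, 0.1), 1)
  p <- list(list(tile = t1, cx = 15, cy = 5, geo = geo1),
            list(tile = t2, cx = 25, cy = 5, geo = geo2))
  out <- stitch(p)
  # overlap pixels are x = 15 (distance 0 to cx1, 10 to cx2) and x = 25
  # (distance 10 to cx1, 0 to cx2); the zero distance floors at 5 m
  wt <- function(d) 1 / max(d, 5)
  exp2 <- (wt(0) * t1[1, 2] + wt(10) * t2[1, 1]) / (wt(0) + wt(10))
  exp3 <- (wt(10) * t1[1, 3] + wt(0) * t2[1, 2]) / (wt(10) + wt(0))
  expect_equal(out$values[1, 1], t1[1, 1])
  expect_equal(out$values[1, 2], exp2, tolerance = 1e-12)
  expect_equal(out$values[1, 3], exp3, tolerance = 1e-12)
  expect_equal(out$values[1, 4], t2[1, 3])
})

test_that("stitching is a convex combination on randomized windows", {
  set.seed(31)
  for (rep in 1:5) {
    tiles <- lapply(1:3, function(i) matrix(runif(16 * 16), 16, 16))
    offs <- sample(0:6, 3) * 10
    preds <- lapply(1:3, function(i)
      list(tile = tiles[[i]], cx = offs[i] + 80, cy = 80,
           geo = geo_ref(offs[i], 160)))
    out <- stitch(preds)
    lo <- min(vapply(tiles, min, 0)); hi <- max(vapply(tiles, max, 0))
    expect_true(all(out$values >= lo - 1e-12, na.rm = TRUE))
    expect_true(all(out$values <= hi + 1e-12, na.rm = TRUE))
  }
})

test_that("quantization is the documented 0-250 code with 0.4% resolution", {
  expect_identical(quantize(1.0), 250L)
  expect_identical(quantize(0.0), 0L)
  expect_equal(dequantize(quantize(1.0)), 1.0)
  # the recommended 0.52 threshold is exactly representable
  expect_identical(quantize(0.52), 130L)
  expect_equal(dequantize(130L), 0.52)
  grid <- seq(0, 1, by = 1e-4)
  err <- abs(grid - dequantize(quantize(grid)))
  expect_lte(max(err), 0.002 + 1e-12)
  expect_equal(dequantize(1L) - dequantize(0L), 0.004)  # resolution 0.4%
  expect_error(quantize(1.2), "outside")
  expect_error(dequantize(251L), "outside")
})

test_that("tile write/read round-trips quantized values and geo-metadata", {
  set.seed(41)
  vals <- matrix(runif(96 * 96), 96, 96)
  vals[1:3, 1:3] <- NA                       # nodata corner
  map <- structure(list(values = vals, geo = geo_ref(1000, 5000)),
                   class = "probability_map")
  dir <- tempfile("tiles")
  paths <- write_tiles(map, dir, tile_px = 64)
  expect_equal(length(list.files(dir, pattern = "tif$")), 4)  # 2x2 mosaic
  back <- read_tiles(dir)
  expect_equal(back$values, dequantize(quantize(vals)))
  expect_equal(back$geo$xmin, 1000)
  expect_equal(back$geo$ymax, 5000)
  # written bytes stay within the 0-250 range (255 = nodata)
  for (p in paths) {
    q <- round(tiff::readTIFF(p) * 255)
    expect_true(all(q <= 250 | q == 255))
  }
  # CRS mismatch on mosaic read is an explicit error
  meta_files <- list.files(dir, pattern = "json$", full.names = TRUE)
  meta <- jsonlite::read_json(meta_files[1], simplifyVector = TRUE)
  meta$crs <- "EPSG:4326"
  jsonlite::write_json(meta, meta_files[1], auto_unbox = TRUE, digits = NA)
  expect_error(read_tiles(dir), "CRS mismatch")
})

test_that("thresholded maps ignore monotone rescaling of probabilities", {
  set.seed(51)
  p <- matrix(runif(100), 10, 10)
  t0 <- 0.52
  rescale <- function(x) x^1.7                 # strictly monotone on [0,1]
  expect_equal(p >= t0, rescale(p) >= rescale(t0))
})

test_that("overlapping ensemble windows stitch seamlessly over a scene", {
  run <- fix_desk_run()
  big_layout <- run$preset$layout
  big_layout$size <- 64
  big <- generate_scene(4242, big_layout)$sample
  preds <- predict_windows(run$ensemble, big, stride = 160)
  expect_gt(length(preds), 1)
  map <- stitch(preds)
  expect_equal(dim(map$values), c(64, 64))
  expect_true(all(map$values >= 0 & map$values <= 1, na.rm = TRUE))
  expect_true(!anyNA(map$values))
})

test_that("agreeing overlapping windows leave no seams", {
  # tiles cut from one deterministic field of absolute map position, as an
  # ideal translation-equivariant predictor would produce on a uniform
  # scene: the stitched mosaic must reproduce the field exactly
  field <- function(x, y) 0.5 + 0.4 * sin(x / 37) * cos(y / 53)
  make_pred <- function(x0) {
    xs <- x0 + (1:16) * 10 - 5
    ys <- 160 - (1:16) * 10 + 5
    list(tile = outer(ys, xs, function(y, x) field(x, y)),
         cx = x0 + 80, cy = 80, geo = geo_ref(x0, 160))
  }
  preds <- lapply(c(0, 40, 80, 120), make_pred)
  out <- stitch(preds)
  xs <- (1:28) * 10 - 5
  ys <- 160 - (1:16) * 10 + 5
  expect_equal(out$values, outer(ys, xs, function(y, x) field(x, y)),
               tolerance = 1e-12)
})
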