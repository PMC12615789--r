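# Overlapping-window inference and stitching into a seamless probability
# map, probability quantization to 0-250, and 8-bit tile I/O with JSON
# georeferencing sidecars.

WINDOW_M <- 1280      # inference window side (m)
STRIDE_M <- 210       # default distance between window centers (m)
DMIN_M <- 5           # weight floor distance: half a 10 m pixel

#' Plan overlapping inference window centers
#'
#' Lays a regular grid of 1280 m window centers at the given stride over a
#' region so that every interior pixel is covered by at least one window;
#' the last center per axis is pulled back to keep windows inside the
#' region. A region smaller than one window gets a single centered window.
#'
#' @param bounds named numeric vector \code{(xmin, ymin, xmax, ymax)} in map
#'   units (m).
#' @param stride distance between neighboring window centers (m); the
#'   full-scale map used 210 m, desk-scale tests may use the window side
#'   for non-overlapping tiling.
#' @param window window side (m).
#' @return Two-column matrix of center coordinates \code{(x, y)}.
#' @export
plan_windows <- function(bounds, stride = STRIDE_M, window = WINDOW_M) {
  b <- as.numeric(bounds[c("xmin", "ymin", "xmax", "ymax")])
  if (any(is.na(b))) stop_invalid("bounds must name xmin, ymin, xmax, ymax")
  half <- window / 2
  axis_centers <- function(lo, hi) {
    span <- hi - lo
    if (span <= window) return((lo + hi) / 2)
    cs <- seq(lo + half, hi - half, by = stride)
    if (cs[length(cs)] < hi - half) cs <- c(cs, hi - half)
    cs
  }
  cx <- axis_centers(b[1], b[3])
  cy <- axis_centers(b[2], b[4])
  as.matrix(expand.grid(x = cx, y = cy))
}

#' Predict overlapping windows over a scene
#'
#' Runs the ensemble on every planned window of a (possibly larger) scene
#' and returns the per-window natural-forest probability tiles ready for
#' \code{\link{stitch}}.
#'
#' @param models list of \code{mtsvit_weights} or a \code{mtsvit_ensemble}.
#' @param sample a \code{scene_sample}; its raster may be larger than one
#'   window.
#' @param stride center spacing in meters.
#' @param class_index probability channel to keep (1 = natural forest).
#' @return List of window predictions, each \code{list(tile, cx, cy, geo)}.
#' @export
predict_windows <- function(models, sample, stride = STRIDE_M,
                            class_index = 1L) {
  if (inherits(models, "mtsvit_ensemble")) models <- models$members
  cfg <- models[[1]]$config
  side_px <- cfg$image_size
  px <- sample$geo$px
  win_m <- side_px * px
  nr <- dim(sample$s2)[2]; nc <- dim(sample$s2)[3]
  bounds <- c(xmin = sample$geo$xmin, ymin = sample$geo$ymax - nr * px,
              xmax = sample$geo$xmin + nc * px, ymax = sample$geo$ymax)
  centers <- plan_windows(bounds, stride = stride, window = win_m)
  out <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    c0 <- round((cx - win_m / 2 - sample$geo$xmin) / px)
    r0 <- round((sample$geo$ymax - (cy + win_m / 2)) / px)
    rows <- (r0 + 1):(r0 + side_px); cols <- (c0 + 1):(c0 + side_px)
    sub <- sample
    sub$s2 <- sample$s2[, rows, cols, , drop = FALSE]
    sub$topo <- sample$topo[, rows, cols, , drop = FALSE]
    sub$labels <- sample$labels[rows, cols]
    sub$geo <- geo_ref(sample$geo$xmin + c0 * px,
                       sample$geo$ymax - r0 * px, px, sample$geo$crs)
    probs <- ensemble_predict(models, sub)
    out[[i]] <- list(tile = probs[, , class_index], cx = cx, cy = cy,
                     geo = sub$geo)
  }
  out
}

#' Stitch overlapping window predictions
#'
#' Averages overlapping pixels with weights inversely proportional to the
#' Euclidean distance from the pixel center to the window center,
#' \code{w = 1 / max(d, 5 m)} (the floor avoids a singular weight at the
#' center pixel). Pixels covered by no window are NA (nodata). The result is
#' a convex combination, so stitched values stay inside the range of the
#' contributing tiles.
#'
#' @param predictions list of window predictions from
#'   \code{\link{predict_windows}} (or hand-built: \code{tile} matrix,
#'   \code{cx}, \code{cy}, \code{geo}).
#' @param out_geo optional \code{\link{geo_ref}} of the output grid; by
#'   default the union extent of the windows.
#' @param out_dim optional \code{c(rows, cols)} of the output grid.
#' @return Object of class \code{probability_map}: \code{values} matrix in
#'   [0, 1] with NA nodata, \code{geo}.
#' @export
stitch <- function(predictions, out_geo = NULL, out_dim = NULL) {
  stopifnot(length(predictions) >= 1)
  px <- predictions[[1]]$geo$px
  if (is.null(out_geo)) {
    xmin <- min(vapply(predictions, function(p) p$geo$xmin, 0))
    ymax <- max(vapply(predictions, function(p) p$geo$ymax, 0))
    xmax <- max(vapply(predictions,
                       function(p) p$geo$xmin + ncol(p$tile) * px, 0))
    ymin <- min(vapply(predictions,
                       function(p) p$geo$ymax - nrow(p$tile) * px, 0))
    out_geo <- geo_ref(xmin, ymax, px, predictions[[1]]$geo$crs)
    out_dim <- c(round((ymax - ymin) / px), round((xmax - xmin) / px))
  }
  num <- matrix(0, out_dim[1], out_dim[2])
  den <- matrix(0, out_dim[1], out_dim[2])
  for (p in predictions) {
    if (!identical(p$geo$crs, out_geo$crs))
      stop_invalid("window CRS %s does not match output CRS %s",
                   p$geo$crs, out_geo$crs)
    nr <- nrow(p$tile); nc <- ncol(p$tile)
    r0 <- round((out_geo$ymax - p$geo$ymax) / px)
    c0 <- round((p$geo$xmin - out_geo$xmin) / px)
    ctr <- pixel_centers(p$geo, nr, nc)
    dx <- ctr$x - p$cx; dy <- ctr$y - p$cy
    d <- sqrt(outer(dy^2, dx^2, "+"))
    w <- 1 / pmax(d, DMIN_M)
    rows <- (r0 + 1):(r0 + nr); cols <- (c0 + 1):(c0 + nc)
    num[rows, cols] <- num[rows, cols] + w * p$tile
    den[rows, cols] <- den[rows, cols] + w
  }
  vals <- num / den
  vals[den == 0] <- NA_real_
  structure(list(values = vals, geo = out_geo), class = "probability_map")
}

#' Quantize probabilities to the 0-250 integer scale
#'
#' \code{q = round(250 p)} (round half to even); \code{dequantize} divides
#' by 250, so the probability resolution is 0.4\% and the round-trip error
#' is at most 1/500.
#'
#' @param p numeric vector/matrix of probabilities in [0, 1]; NA passes
#'   through as NA.
#' @return Integer values 0..250 of the same shape.
#' @export
quantize <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop_invalid("probabilities outside [0, 1]")
  q <- round(250 * p)
  storage.mode(q) <- "integer"
  q
}

#' @rdname quantize
#' @param q integer values 0..250.
#' @export
dequantize <- function(q) {
  bad <- !is.na(q) & (q < 0 | q > 250)
  if (any(bad)) stop_invalid("quantized values outside 0..250")
  q / 250
}

#' Write / read a quantized probability map as 8-bit tiles
#'
#' Splits the map into square tiles, writes each as an 8-bit single-channel
#' TIFF (values 0-250, nodata 255) with a JSON sidecar carrying the affine
#' transform, CRS and nodata code; \code{read_tiles} mosaics them back
#' losslessly.
#'
#' @param map a \code{probability_map} (float values; quantized on write).
#' @param dir output directory.
#' @param tile_px tile side in pixels.
#' @return \code{write_tiles} returns the written file paths;
#'   \code{read_tiles} returns a \code{probability_map} whose values are
#'   dequantized floats.
#' @export
write_tiles <- function(map, dir, tile_px = 256) {
  stopifnot(inherits(map, "probability_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- quantize(map$values)
  q[is.na(q)] <- 255L
  nr <- nrow(q); nc <- ncol(q)
  paths <- character(0)
  for (r0 in seq(1, nr, by = tile_px)) for (c0 in seq(1, nc, by = tile_px)) {
    rows <- r0:min(r0 + tile_px - 1, nr)
    cols <- c0:min(c0 + tile_px - 1, nc)
    tile <- q[rows, cols, drop = FALSE]
    base <- sprintf("tile_r%05d_c%05d", r0, c0)
    tiff::writeTIFF(tile / 255, file.path(dir, paste0(base, ".tif")),
                    bits.per.sample = 8L)
    meta <- list(xmin = map$geo$xmin + (c0 - 1) * map$geo$px,
                 ymax = map$geo$ymax - (r0 - 1) * map$geo$px,
                 px = map$geo$px, crs = map$geo$crs, nodata = 255,
                 scale = 250, rows = length(rows), cols = length(cols))
    jsonlite::write_json(meta, file.path(dir, paste0(base, ".json")),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(dir, paste0(base, ".tif")))
  }
  invisible(paths)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir) {
  metas <- list.files(dir, pattern = "^tile_.*\\.json$", full.names = TRUE)
  if (length(metas) == 0) stop_invalid("no tiles found in %s", dir)
  tiles <- lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    img <- tiff::readTIFF(sub("\\.json$", ".tif", mp))
    q <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    list(meta = meta, q = q)
  })
  crs <- tiles[[1]]$meta$crs; px <- tiles[[1]]$meta$px
  for (t in tiles)
    if (!identical(t$meta$crs, crs))
      stop_invalid("CRS mismatch across tiles: %s vs %s", t$meta$crs, crs)
  xmin <- min(vapply(tiles, function(t) t$meta$xmin, 0))
  ymax <- max(vapply(tiles, function(t) t$meta$ymax, 0))
  xmax <- max(vapply(tiles, function(t) t$meta$xmin + t$meta$cols * px, 0))
  ymin <- min(vapply(tiles, function(t) t$meta$ymax - t$meta$rows * px, 0))
  nr <- round((ymax - ymin) / px); nc <- round((xmax - xmin) / px)
  q <- matrix(255L, nr, nc)
  for (t in tiles) {
    r0 <- round((ymax - t$meta$ymax) / px)
    c0 <- round((t$meta$xmin - xmin) / px)
    q[(r0 + 1):(r0 + t$meta$rows), (c0 + 1):(c0 + t$meta$cols)] <- t$q
  }
  vals <- dequantize(ifelse(q == 255L, NA_integer_, q))
  structure(list(values = vals, geo = geo_ref(xmin, ymax, px, crs)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d px, %.0f m origin (%.0f, %.0f), %s\n",
              nrow(x$values), ncol(x$values), x$geo$px, x$geo$xmin,
              x$geo$ymax, x$geo$crs))
  invisible(x)
}
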