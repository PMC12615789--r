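#' Georeferencing descriptor for a north-up raster
#'
#' Lightweight georeferencing used by all rasters in the package: a north-up
#' affine transform (no rotation terms) plus a CRS identifier. Map coordinates
#' of the center of pixel \code{(row, col)} (1-based, row 1 at the top) are
#' \code{x = xmin + (col - 0.5) * px}, \code{y = ymax - (row - 0.5) * px}.
#'
#' @param xmin map x of the left edge of the raster (m).
#' @param ymax map y of the top edge of the raster (m).
#' @param px pixel size in map units (m); default 10.
#' @param crs CRS identifier string (e.g. an EPSG code).
#' @return An object of class \code{geo_ref}.
#' @export
geo_ref <- function(xmin = 0, ymax = 0, px = 10, crs = "EPSG:32633") {
  stopifnot(is.numeric(xmin), is.numeric(ymax), px > 0)
  structure(list(xmin = xmin, ymax = ymax, px = px, crs = crs),
            class = "geo_ref")
}

#' @export
print.geo_ref <- function(x, ...) {
  cat(sprintf("<geo_ref> origin (%.1f, %.1f), pixel %.1f m, %s\n",
              x$xmin, x$ymax, x$px, x$crs))
  invisible(x)
}

# map coordinates of pixel centers for an nrow x ncol raster
pixel_centers <- function(geo, nrow, ncol) {
  list(x = geo$xmin + (seq_len(ncol) - 0.5) * geo$px,
       y = geo$ymax - (seq_len(nrow) - 0.5) * geo$px)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
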