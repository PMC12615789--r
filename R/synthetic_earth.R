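# Synthetic scene generation: seeded landscapes with class-specific spectra,
# phenology and texture, plus emulated label-source stacks and stratified
# validation sets. Everything downstream of real Sentinel-2 / DEM acquisition
# is exercised on these scenes.

#' Land-cover class scheme
#'
#' The 9-code class scheme used throughout: 0 is reserved for unknown/masked
#' pixels and is never a prediction target.
#'
#' @return Named integer vector mapping class names to codes 0..8.
#' @export
class_scheme <- function() {
  c(unknown = 0L, natural_forest = 1L, planted_forest = 2L, tree_crops = 3L,
    other_vegetation = 4L, built = 5L, water = 6L, ice_snow = 7L,
    bare_sparse = 8L)
}

# Sentinel-2 band order used for all spectral tensors
S2_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")

# evaluate code under a fixed RNG stream, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# spatially correlated standard field: white noise smoothed by a separable
# gaussian kernel (length scale in pixels), re-standardized to mean 0 / sd 1
smooth_field <- function(size, scale = 12) {
  w <- matrix(stats::rnorm(size * size), size, size)
  if (scale <= 0) return(w)
  idx <- seq_len(size)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * scale^2))
  K <- K / rowSums(K)
  f <- K %*% w %*% t(K)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic topography stack
#'
#' Draws a smooth random elevation field and derives slope and aspect from it
#' with Horn's 3x3 finite-difference kernel on the 10 m grid. Aspect is the
#' downslope azimuth in degrees clockwise from north; flat pixels get slope 0
#' and aspect 0 by convention.
#'
#' @param seed integer RNG seed; the output is a pure function of
#'   \code{(seed, size)}.
#' @param size raster side in pixels (>= 16).
#' @param relief_m peak-to-trough scale of the elevation field in meters.
#' @return Array of dimension \code{(1, size, size, 3)}; bands are elevation
#'   (m), slope (degrees) and aspect (degrees, 0-360).
#' @export
generate_topography <- function(seed, size, relief_m = 300) {
  if (!is.numeric(size) || size < 16) stop_invalid("size must be >= 16")
  with_seed(seed, {
    elev <- 500 + relief_m * smooth_field(size, scale = size / 8)
    topo_from_elevation(elev)
  })
}

#' Slope and aspect from an elevation raster
#'
#' Horn's 3x3 finite-difference kernel on a square grid with replicated
#' edges. Aspect is the downslope azimuth clockwise from north; flat pixels
#' get slope 0 and aspect 0.
#'
#' @param elev elevation matrix (m), row 1 at the north edge.
#' @param px pixel size (m).
#' @return Array \code{(1, rows, cols, 3)}: elevation, slope (deg), aspect
#'   (deg).
#' @export
topo_from_elevation <- function(elev, px = 10) {
  n <- nrow(elev); m <- ncol(elev)
  pad <- rbind(elev[1, , drop = FALSE], elev, elev[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, m, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(n + dr), (1 + dc):(m + dc)]
  # Horn: weights 1,2,1 on the three rows/cols either side
  gx <- ((sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
         (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))) / (8 * px)   # d(elev)/d(east)
  gy <- ((sh(0, 0) + 2 * sh(0, 1) + sh(0, 2)) -
         (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2))) / (8 * px)   # d(elev)/d(north)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360             # downslope azimuth
  aspect[slope == 0] <- 0
  out <- array(0, c(1, n, m, 3))
  out[1, , , 1] <- elev; out[1, , , 2] <- slope; out[1, , , 3] <- aspect
  out
}

# base reflectance spectra per class (rows: classes 1..8, cols: the 10 bands)
class_spectra <- function() {
  rbind(
    natural_forest   = c(0.030, 0.050, 0.040, 0.080, 0.200, 0.300, 0.350, 0.370, 0.200, 0.100),
    planted_forest   = c(0.030, 0.060, 0.050, 0.105, 0.230, 0.330, 0.400, 0.420, 0.230, 0.115),
    tree_crops       = c(0.040, 0.070, 0.060, 0.125, 0.215, 0.270, 0.310, 0.320, 0.265, 0.150),
    other_vegetation = c(0.050, 0.080, 0.075, 0.150, 0.240, 0.300, 0.370, 0.390, 0.320, 0.200),
    built            = c(0.120, 0.140, 0.150, 0.170, 0.190, 0.200, 0.210, 0.220, 0.240, 0.220),
    water            = c(0.050, 0.040, 0.030, 0.020, 0.012, 0.010, 0.008, 0.008, 0.005, 0.004),
    ice_snow         = c(0.850, 0.850, 0.830, 0.800, 0.750, 0.700, 0.650, 0.600, 0.100, 0.080),
    bare_sparse      = c(0.150, 0.180, 0.220, 0.260, 0.300, 0.320, 0.340, 0.350, 0.400, 0.350))
}

# phenology amplitude per class and per-band sensitivity of the seasonal cycle
PHENO_AMP <- c(0.10, 0.08, 0.15, 0.30, 0, 0, 0, 0)
PHENO_BAND_W <- c(0.2, 0.2, 0.2, 0.5, 0.8, 1, 1, 1, 0.6, 0.5)

#' Default layout configuration for scene synthesis
#'
#' Describes the landscape a synthetic scene emulates: target class-area
#' fractions, spectral separation, noise levels, planted/crop row texture,
#' label-source corruption rates and the scene location. Fractions may sum to
#' less than 1; the remainder is allocated to bare/sparse ground.
#'
#' @param fractions named numeric vector of target area fractions for class
#'   codes "1".."8" (subset allowed); must sum to at most 1.
#' @param size scene side in pixels.
#' @param n_seeds number of blob seed points used to draw the class mosaic.
#' @param separation spectral separation dial: 1 uses the nominal class
#'   spectra, values > 1 push class means apart around the grand mean.
#' @param noise_sd per-pixel iid reflectance noise sd.
#' @param corr_sd sd of the spatially correlated reflectance noise field.
#' @param texture_amp amplitude of the periodic planting texture
#'   (rows for planted forest, grids for tree crops) and of the unstructured
#'   within-stand texture of natural forest.
#' @param source_fp,source_fn false-positive / false-negative corruption
#'   rates applied to every boolean label-source layer.
#' @param wildfire_frac fraction of natural-forest pixels carrying a recent
#'   wildfire loss (low canopy, loss year set, wildfire driver).
#' @param lat,lon scene center in degrees; drives the phenology phase
#'   (growing-season peak in JJA for northern, DJF for southern latitudes).
#' @param water_ceiling upper bound on NIR/SWIR reflectance generated over
#'   water.
#' @return A list of class \code{nf_layout}.
#' @export
scene_layout <- function(fractions = c(`1` = 0.35, `2` = 0.10, `3` = 0.10,
                                       `4` = 0.15, `5` = 0.05, `6` = 0.10,
                                       `7` = 0.05, `8` = 0.10),
                         size = 128, n_seeds = 48, separation = 1,
                         noise_sd = 0.01, corr_sd = 0.02, texture_amp = 0.05,
                         source_fp = 0, source_fn = 0, wildfire_frac = 0.02,
                         lat = 45, lon = 8, water_ceiling = 0.05) {
  f <- rep(0, 8); names(f) <- as.character(1:8)
  if (length(fractions)) {
    if (is.null(names(fractions)) ||
        !all(names(fractions) %in% names(f)))
      stop_invalid("fractions must be named with class codes '1'..'8'")
    f[names(fractions)] <- fractions
  }
  if (any(f < 0) || sum(f) > 1 + 1e-9)
    stop_invalid("class fractions must be nonnegative and sum to <= 1")
  f["8"] <- f["8"] + max(0, 1 - sum(f))   # remainder -> bare/sparse
  structure(list(fractions = f, size = size, n_seeds = n_seeds,
                 separation = separation, noise_sd = noise_sd,
                 corr_sd = corr_sd, texture_amp = texture_amp,
                 source_fp = source_fp, source_fn = source_fn,
                 wildfire_frac = wildfire_frac, lat = lat, lon = lon,
                 water_ceiling = water_ceiling),
            class = "nf_layout")
}

# largest-remainder apportionment of n seeds to the positive-fraction classes
apportion_seeds <- function(fractions, n) {
  pos <- which(fractions > 0)
  quota <- fractions[pos] / sum(fractions[pos]) * n
  k <- floor(quota)
  short <- n - sum(k)
  if (short > 0) {
    ord <- order(quota - k, decreasing = TRUE)
    k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1
  }
  k[k == 0 & quota > 0] <- pmax(k[k == 0 & quota > 0], 1L)
  stats::setNames(as.integer(k), names(fractions)[pos])
}

# class mosaic as a seeded Voronoi tessellation: contiguous polygonal stands
draw_label_mosaic <- function(layout) {
  size <- layout$size
  counts <- apportion_seeds(layout$fractions, layout$n_seeds)
  cls <- rep(as.integer(names(counts)), counts)
  ns <- length(cls)
  sr <- stats::runif(ns, 0.5, size + 0.5)
  sc <- stats::runif(ns, 0.5, size + 0.5)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  best_d <- matrix(Inf, size, size)
  lab <- matrix(0L, size, size)
  for (i in seq_len(ns)) {
    d <- (rows - sr[i])^2 + (cols - sc[i])^2
    hit <- d < best_d
    best_d[hit] <- d[hit]
    lab[hit] <- cls[i]
  }
  lab
}

#' Unit-sphere Cartesian coordinates from latitude/longitude
#'
#' @param lat,lon location in degrees.
#' @return Numeric 3-vector with unit Euclidean norm.
#' @export
latlon_to_unit_sphere <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

# corrupt a boolean layer with independent false positives / negatives
corrupt_layer <- function(truth, fp, fn) {
  u <- matrix(stats::runif(length(truth)), nrow(truth))
  out <- truth
  out[!truth & u < fp] <- TRUE
  out[truth & u < fn] <- FALSE
  out
}

#' Generate a synthetic scene and its label-source stack
#'
#' Draws a contiguous class mosaic, renders four seasonal 10-band reflectance
#' composites with class-specific spectra, phenology and planting texture,
#' derives topography, and builds an emulated stack of noisy label-source
#' rasters (natural/planted/crop/other sources plus tree height, loss year,
#' loss driver, natural-forest probability and tree cover) consistent with
#' the mosaic at zero noise.
#'
#' @param seed integer RNG seed; output is a pure function of
#'   \code{(seed, layout)}.
#' @param layout a \code{\link{scene_layout}}.
#' @return List with elements \code{sample} (class \code{scene_sample}:
#'   \code{s2} array (4, size, size, 10), \code{topo} array (1, size, size,
#'   3), \code{loc} unit 3-vector, \code{labels} integer matrix, \code{geo})
#'   and \code{stack} (class \code{source_stack}: named list of layers).
#' @export
generate_scene <- function(seed, layout = scene_layout()) {
  stopifnot(inherits(layout, "nf_layout"))
  size <- layout$size
  if (size < 16 || size %% 2 != 0) stop_invalid("layout size must be even and >= 16")
  with_seed(seed, {
    labels <- draw_label_mosaic(layout)
    topo <- topo_from_elevation(500 + 300 * smooth_field(size, size / 8))

    mu <- class_spectra()
    gm <- colMeans(mu)
    mu <- sweep(sweep(mu, 2, gm, "-") * layout$separation, 2, gm, "+")
    s_peak <- if (layout$lat >= 0) 3 else 1          # JJA north, DJF south

    # multiplicative texture fields shared across bands/seasons
    theta <- stats::runif(1, 0, pi)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    stripes <- 1 + layout$texture_amp *
      sin(2 * pi * (rows * cos(theta) + cols * sin(theta)) / 4)
    grid_tx <- 1 + layout$texture_amp *
      sin(2 * pi * rows / 4) * sin(2 * pi * cols / 4)
    nat_tx <- 1 + layout$texture_amp * smooth_field(size, 3)
    tex <- matrix(1, size, size)
    tex[labels == 1L] <- nat_tx[labels == 1L]
    tex[labels == 2L] <- stripes[labels == 2L]
    tex[labels == 3L] <- grid_tx[labels == 3L]

    s2 <- array(0, c(4, size, size, 10))
    for (s in 1:4) {
      pheno <- 1 + PHENO_AMP * cos(2 * pi * (s - s_peak) / 4)
      corr <- smooth_field(size, 8) * layout$corr_sd
      for (b in 1:10) {
        base <- matrix(0, size, size)
        for (k in 1:8) {
          sel <- labels == k
          if (!any(sel)) next
          m <- mu[k, b] * (1 + (pheno[k] - 1) * PHENO_BAND_W[b])
          base[sel] <- m
        }
        img <- base * tex + corr +
          matrix(stats::rnorm(size^2, sd = layout$noise_sd), size)
        if (b >= 7) img[labels == 6L] <- pmin(img[labels == 6L],
                                              layout$water_ceiling - 1e-4)
        s2[s, , , b] <- pmin(pmax(img, 0), 1)
      }
    }

    # supporting layers, consistent with the mosaic at zero corruption
    nat <- labels == 1L; pla <- labels == 2L; crp <- labels == 3L
    height <- matrix(stats::runif(size^2, 0, 2), size)
    height[nat | pla] <- stats::runif(sum(nat | pla), 8, 25)
    height[crp] <- stats::runif(sum(crp), 3, 7)
    loss_year <- matrix(0L, size, size)
    driver <- matrix(0L, size, size)
    if (layout$wildfire_frac > 0 && any(nat)) {
      idx <- which(nat)
      burn <- sample(idx, round(layout$wildfire_frac * length(idx)))
      loss_year[burn] <- sample(2001:2020, length(burn), replace = TRUE)
      driver[burn] <- 5L                              # wildfire
      height[burn] <- stats::runif(length(burn), 0, 4)
    }
    gfm <- matrix(stats::runif(size^2, 0, 0.25), size)
    gfm[nat] <- stats::runif(sum(nat), 0.6, 1)
    tc2000 <- matrix(stats::runif(size^2, 0, 8), size)
    tc2000[nat | pla] <- stats::runif(sum(nat | pla), 60, 95)
    tc2000[crp] <- stats::runif(sum(crp), 20, 80)

    fp <- layout$source_fp; fn <- layout$source_fn
    src <- function(truth) corrupt_layer(truth, fp, fn)
    stack <- list(
      tmf_natural = src(nat), sbtn_natural = src(nat), gft_natural = src(nat),
      planted_src = src(pla), crop_src = src(crp),
      otherveg_src_a = src(labels == 4L), otherveg_src_b = src(labels == 4L),
      built_src = src(labels == 5L), water_src = src(labels == 6L),
      ice_src = src(labels == 7L), bare_src = src(labels == 8L),
      forest_type_src = src(nat | pla),
      tree_height = height, loss_year = loss_year, driver_class = driver,
      gfm_p_natural = gfm, tree_cover_2000 = tc2000)

    geo <- geo_ref(xmin = round(stats::runif(1, 0, 1e5) / 10) * 10,
                   ymax = round(stats::runif(1, 1e6, 2e6) / 10) * 10)
    sample <- structure(
      list(s2 = s2, topo = topo,
           loc = latlon_to_unit_sphere(layout$lat, layout$lon),
           labels = labels, geo = geo, seed = seed),
      class = "scene_sample")
    stack <- structure(c(stack, list(geo = geo)), class = "source_stack")
    list(sample = sample, stack = stack)
  })
}

#' @export
print.scene_sample <- function(x, ...) {
  d <- dim(x$s2)
  cat(sprintf("<scene_sample> %dx%d px, %d seasons x %d bands, seed %s\n",
              d[2], d[3], d[1], d[4], format(x$seed)))
  invisible(x)
}

#' Sample a stratified validation set from a truth map
#'
#' Tiles the truth raster into non-overlapping 10x10-pixel (100 x 100 m) plot
#' footprints, stratifies the footprint population, and samples plots
#' uniformly without replacement within each stratum. The reference label of
#' a plot is 1 when strictly more than half of its pixels are natural forest.
#'
#' @param seed RNG seed.
#' @param strata_spec either an integer matrix over the plot grid assigning a
#'   stratum to every footprint, or a single integer K to stratify footprints
#'   into K strata by their natural-forest pixel fraction (equal-width bins).
#' @param truth_map integer label matrix (class codes 0..8); class 1 is the
#'   positive class.
#' @param n_per_stratum sample size per stratum (scalar or named by stratum),
#'   each >= 2 and at most the stratum population.
#' @param geo optional \code{\link{geo_ref}} for plot center coordinates.
#' @param region optional region tag stored with every plot.
#' @return List with \code{plots} (data.frame: plot_id, lon, lat, row, col,
#'   ref_label, stratum, region) and \code{strata} (data.frame: stratum,
#'   N_h, n_h). \code{row}/\code{col} index the top-left pixel of the
#'   footprint in the truth raster.
#' @export
generate_validation_set <- function(seed, strata_spec, truth_map,
                                    n_per_stratum, geo = NULL,
                                    region = "global") {
  nr <- nrow(truth_map) %/% 10; nc <- ncol(truth_map) %/% 10
  if (nr < 1 || nc < 1) stop_invalid("truth map smaller than one plot footprint")
  # natural fraction per footprint
  frac <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- truth_map[(10 * i - 9):(10 * i), (10 * j - 9):(10 * j)]
    frac[i, j] <- mean(blk == 1L)
  }
  if (is.matrix(strata_spec)) {
    if (!all(dim(strata_spec) == c(nr, nc)))
      stop_invalid("strata matrix must match the %d x %d plot grid", nr, nc)
    strata <- strata_spec
  } else {
    K <- as.integer(strata_spec)
    if (is.na(K) || K < 1) stop_invalid("strata_spec must be a matrix or K >= 1")
    strata <- matrix(pmin(K, 1L + as.integer(floor(frac * K))), nr, nc)
  }
  hs <- sort(unique(as.vector(strata)))
  N_h <- vapply(hs, function(h) sum(strata == h), 0L)
  n_h <- if (length(n_per_stratum) == 1) rep(n_per_stratum, length(hs))
         else as.integer(n_per_stratum[as.character(hs)])
  if (any(is.na(n_h)) || any(n_h < 2)) stop_invalid("n_per_stratum must be >= 2 per stratum")
  if (any(n_h > N_h))
    stop_invalid("insufficient population: stratum %s has %d units, %d requested",
                 hs[which(n_h > N_h)[1]], N_h[which(n_h > N_h)[1]],
                 n_h[which(n_h > N_h)[1]])
  if (is.null(geo)) geo <- geo_ref()
  with_seed(seed, {
    out <- vector("list", length(hs))
    for (k in seq_along(hs)) {
      units <- which(strata == hs[k])
      take <- if (length(units) == 1) units else sample(units, n_h[k])
      ui <- ((take - 1) %% nr) + 1; uj <- ((take - 1) %/% nr) + 1
      px_row <- 10 * (ui - 1) + 1; px_col <- 10 * (uj - 1) + 1
      ref <- frac[take] > 0.5
      cx <- geo$xmin + (px_col + 4.5) * geo$px
      cy <- geo$ymax - (px_row + 4.5) * geo$px
      out[[k]] <- data.frame(
        plot_id = sprintf("p%06d", take), lon = cx * 1e-5, lat = cy * 1e-5,
        row = px_row, col = px_col, ref_label = as.integer(ref),
        stratum = hs[k], region = region, stringsAsFactors = FALSE)
    }
    plots <- do.call(rbind, out)
    rownames(plots) <- NULL
    list(plots = plots,
         strata = data.frame(stratum = hs, N_h = N_h, n_h = n_h))
  })
}
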