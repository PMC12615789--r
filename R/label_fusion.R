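# Rule-based fusion of heterogeneous label sources into 0-8 training labels.
# Layer roles are configurable so the same rules apply to emulated or real
# source stacks.

# thresholds from the label-construction rules
GFM_SUPPORT <- 0.5   # p(natural) above this counts as a natural source
GFM_VETO <- 0.3      # p(natural) below this vetoes the natural class
TREE_COVER_MIN <- 10 # percent; at or below counts as "no tree cover"
FOREST_HEIGHT_M <- 5 # strictly greater than this meets the forest definition
DRIVER_NATURAL <- c(5L, 7L)       # wildfire, other natural disturbances
DRIVER_PERMANENT <- c(1L, 2L, 6L) # permanent agriculture, hard commodities,
                                  # settlements & infrastructure

#' Default layer-role configuration for label fusion
#'
#' Maps layer names in a source stack to the roles the fusion rules consume.
#' The defaults match the layer names emitted by \code{\link{generate_scene}}.
#'
#' @param natural_sources names of boolean natural-forest source layers.
#' @param planted_source,crop_source names of the planted-forest and
#'   tree-crop source layers.
#' @param otherveg_sources names of the other-vegetation source layers; the
#'   class is assigned only where all of them agree.
#' @param built_source,water_source,ice_source,bare_source soft-negative
#'   source layer names.
#' @param forest_type_source boolean forest-per-forest-type layer used in the
#'   forest mask.
#' @return Named list of roles.
#' @export
fusion_config <- function(natural_sources = c("tmf_natural", "sbtn_natural",
                                              "gft_natural"),
                          planted_source = "planted_src",
                          crop_source = "crop_src",
                          otherveg_sources = c("otherveg_src_a",
                                               "otherveg_src_b"),
                          built_source = "built_src",
                          water_source = "water_src",
                          ice_source = "ice_src",
                          bare_source = "bare_src",
                          forest_type_source = "forest_type_src") {
  list(natural_sources = natural_sources, planted_source = planted_source,
       crop_source = crop_source, otherveg_sources = otherveg_sources,
       built_source = built_source, water_source = water_source,
       ice_source = ice_source, bare_source = bare_source,
       forest_type_source = forest_type_source)
}

need_layer <- function(stack, name) {
  if (is.null(stack[[name]]))
    stop_invalid("source stack is missing required layer '%s'", name)
  stack[[name]]
}

# recent (2001-2020) loss attributed to any of the given driver classes
loss_with_driver <- function(stack, drivers) {
  loss <- need_layer(stack, "loss_year")
  drv <- need_layer(stack, "driver_class")
  loss >= 2001 & loss <= 2020 & matrix(drv %in% drivers, nrow(drv))
}

#' Build the forest-definition mask
#'
#' A pixel meets the forest definition when canopy height strictly exceeds
#' 5 m, or it experienced a natural disturbance (wildfire or other natural
#' driver with a 2001-2020 loss year, assuming natural regrowth), or the
#' forest-type source layer calls it forest.
#'
#' @param stack a \code{source_stack} (named list of aligned layers).
#' @param config layer-role configuration, see \code{\link{fusion_config}}.
#' @return Logical matrix on the stack grid.
#' @export
build_forest_mask <- function(stack, config = fusion_config()) {
  height <- need_layer(stack, "tree_height")
  ft <- need_layer(stack, config$forest_type_source)
  (height > FOREST_HEIGHT_M) | loss_with_driver(stack, DRIVER_NATURAL) | ft
}

#' Fuse label sources into a 0-8 training label raster
#'
#' Ordered rule evaluation: (1) the initial natural-forest layer is the union
#' of the natural sources (including GFM p(natural) > 0.5) plus
#' wildfire-loss areas; (2) pixels with permanent-conversion loss (permanent
#' agriculture, hard commodities, settlements with a 2001-2020 loss year) or
#' GFM p(natural) < 0.3 are removed; (3) the result is intersected with the
#' forest mask; (4) planted forest is its source intersected with the forest
#' mask, tree crops are taken from their source unmasked; (5) pixels claimed
#' by natural and by planted/crops become unknown (class 0); (6) other
#' vegetation is assigned only where every other-vegetation source agrees,
#' tree cover is at most 10 percent and the forest mask is false; (7) built,
#' water, ice and bare come from their sources outside the forest mask, with
#' overlap priority water > ice > built > bare > other vegetation; natural,
#' planted and crop claims take precedence over the soft negatives; (8)
#' everything else is unknown.
#'
#' @inheritParams build_forest_mask
#' @return Object of class \code{label_raster}: integer matrix 0..8 with a
#'   \code{rules} attribute recording which rule fired per class.
#' @export
assign_classes <- function(stack, config = fusion_config()) {
  gfm <- need_layer(stack, "gfm_p_natural")
  fmask <- build_forest_mask(stack, config)

  nat_union <- Reduce(`|`, lapply(config$natural_sources,
                                  function(nm) need_layer(stack, nm)))
  nat_union <- nat_union | (gfm > GFM_SUPPORT)
  nat_initial <- nat_union | loss_with_driver(stack, DRIVER_NATURAL) # step 1
  nat <- nat_initial & !loss_with_driver(stack, DRIVER_PERMANENT) &  # step 2
    !(gfm < GFM_VETO)
  nat <- nat & fmask                                                 # step 3

  planted <- need_layer(stack, config$planted_source) & fmask        # step 4
  crops <- need_layer(stack, config$crop_source)

  # step 5: overlap of the natural candidate set (before the removal rules)
  # with planted/crops is irreducibly ambiguous -> unknown; judging against
  # the pre-removal set keeps label assignment monotone in the loss layers
  ambiguous <- nat_initial & (planted | crops)
  nat[ambiguous] <- FALSE; planted[ambiguous] <- FALSE; crops[ambiguous] <- FALSE

  tc <- need_layer(stack, "tree_cover_2000")
  otherveg <- Reduce(`&`, lapply(config$otherveg_sources,          # step 6
                                 function(nm) need_layer(stack, nm)))
  otherveg <- otherveg & (tc <= TREE_COVER_MIN) & !fmask

  soft <- function(nm) need_layer(stack, nm) & !fmask              # step 7
  labels <- matrix(0L, nrow(fmask), ncol(fmask))
  # soft negatives, lowest priority first so later assignments win overlaps
  labels[otherveg] <- 4L
  labels[soft(config$bare_source)] <- 8L
  labels[soft(config$built_source)] <- 5L
  labels[soft(config$ice_source)] <- 7L
  labels[soft(config$water_source)] <- 6L
  # hard classes take precedence over soft negatives
  labels[crops] <- 3L
  labels[planted] <- 2L
  labels[nat] <- 1L
  labels[ambiguous] <- 0L

  structure(labels, class = c("label_raster", class(labels)),
            rules = list(forest_mask = fmask, ambiguous = ambiguous))
}

#' Per-class pixel fractions of a label raster
#'
#' @param labels integer matrix of class codes 0..8.
#' @return Named numeric vector of fractions over codes "0".."8", summing
#'   to 1.
#' @export
class_distribution <- function(labels) {
  if (length(labels) == 0) stop_invalid("label raster is empty")
  tab <- tabulate(as.integer(labels) + 1L, nbins = 9L)
  stats::setNames(tab / length(labels), as.character(0:8))
}
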