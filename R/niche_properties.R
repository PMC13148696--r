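#' Per-species extremes of selected climate layers
#'
#' Min and max of each requested layer over a species' occurrence cells, the
#' raw material for univariate niche breadth and centroids.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [climate_stack()].
#' @param layers layer names to summarize (default all).
#' @return named list with `min` and `max` numeric vectors per layer.
#' @export
occurrence_extremes <- function(occ, stack, layers = names(stack$layers)) {
  missing_layers <- setdiff(layers, names(stack$layers))
  if (length(missing_layers) > 0L) {
    stop_ns("missing layer(s): ", paste(missing_layers, collapse = ", "))
  }
  env <- extract_env(occ, stack)[, layers, drop = FALSE]
  list(min = apply(env, 2, min), max = apply(env, 2, max))
}

#' Univariate niche breadth
#'
#' Temperature breadth is the span from the coldest-month minimum to the
#' warmest-month maximum experienced by the species; precipitation breadth the
#' span from the driest-month minimum to the wettest-month maximum.
#'
#' @param extremes output of [occurrence_extremes()].
#' @param temp_max,temp_min,prec_max,prec_min layer names of the warmest-month
#'   maximum, coldest-month minimum, wettest-month maximum and driest-month
#'   minimum (bioclim defaults bio5, bio6, bio13, bio14).
#' @return named numeric: `TB` (degrees C) and `PB` (mm), both >= 0.
#' @export
univariate_breadth <- function(extremes, temp_max = "bio5", temp_min = "bio6",
                               prec_max = "bio13", prec_min = "bio14") {
  need <- c(temp_max, temp_min, prec_max, prec_min)
  if (!all(need %in% names(extremes$min))) {
    stop_ns("extremes lack layer(s): ",
            paste(setdiff(need, names(extremes$min)), collapse = ", "))
  }
  c(TB = unname(extremes$max[temp_max] - extremes$min[temp_min]),
    PB = unname(extremes$max[prec_max] - extremes$min[prec_min]))
}

#' Univariate niche centroid
#'
#' Midpoint between the extreme values used for breadth, per dimension.
#'
#' @inheritParams univariate_breadth
#' @return named numeric: `temp` (degrees C) and `prec` (mm).
#' @export
univariate_centroid <- function(extremes, temp_max = "bio5", temp_min = "bio6",
                                prec_max = "bio13", prec_min = "bio14") {
  c(temp = unname((extremes$min[temp_min] + extremes$max[temp_max]) / 2),
    prec = unname((extremes$min[prec_min] + extremes$max[prec_max]) / 2))
}

#' Univariate niche marginality
#'
#' Absolute (Euclidean, one-dimensional) distance between a species' centroid
#' and the mean study-area climate, per dimension.
#'
#' @param centroid output of [univariate_centroid()].
#' @param reference an [env_summary()] of the masked study area.
#' @param temp_mean,prec_mean layer names of the study-area reference means
#'   (bioclim defaults bio1 and bio12).
#' @return named numeric: `TM` (degrees C) and `PM` (mm), both >= 0.
#' @export
univariate_marginality <- function(centroid, reference,
                                   temp_mean = "bio1", prec_mean = "bio12") {
  c(TM = unname(abs(centroid["temp"] - reference$mean_by_layer[temp_mean])),
    PM = unname(abs(centroid["prec"] - reference$mean_by_layer[prec_mean])))
}

#' Multivariate niche marginality
#'
#' Mahalanobis distance from the species' niche centroid to the study-area
#' mean of the principal components, which is the origin by construction of
#' the centered PCA. The metric uses the species' own ellipsoid covariance:
#' the distance is measured through the shape of the niche.
#'
#' @param ell the species' [ellipsoid()] in component space.
#' @param reference an [env_summary()] (supplies `pc_origin`).
#' @return `NM`, a non-negative scalar.
#' @export
multivariate_marginality <- function(ell, reference) {
  origin <- reference$pc_origin
  if (length(origin) != ell$d) stop_ns("pc_origin dimension mismatch")
  sqrt(as.numeric(mahalanobis2(origin, ell)))
}

#' Assemble the per-species niche-property table
#'
#' One row per modeled species with multivariate properties (NB = ellipsoid
#' volume, NM = multivariate marginality, NP = multivariate phylogenetic
#' position) and univariate ones (TB/TM/TP for temperature, PB/PM/PP for
#' precipitation), plus the centroids they derive from. Species absent from
#' the phylogeny get `NA` positions and are excluded from position maps.
#'
#' @param ellipsoids named list of [ellipsoid()]s (names = species ids).
#' @param extremes named list of [occurrence_extremes()] per species.
#' @param reference an [env_summary()].
#' @param positions optional data frame with columns `species`, `NP`, `TP`,
#'   `PP` from the comparative module; `NULL` leaves positions `NA`.
#' @param layer_map named list of layer-name overrides for the univariate
#'   helpers: `temp_max`, `temp_min`, `prec_max`, `prec_min`, `temp_mean`,
#'   `prec_mean` (bioclim defaults).
#' @return data frame of class `niche_property_table`.
#' @export
assemble_property_table <- function(ellipsoids, extremes, reference,
                                    positions = NULL, layer_map = list()) {
  lm0 <- list(temp_max = "bio5", temp_min = "bio6", prec_max = "bio13",
              prec_min = "bio14", temp_mean = "bio1", prec_mean = "bio12")
  lm0[names(layer_map)] <- layer_map
  layer_map <- lm0
  sp <- names(ellipsoids)
  if (is.null(sp) || !identical(sort(sp), sort(names(extremes)))) {
    bad <- union(setdiff(sp, names(extremes)), setdiff(names(extremes), sp))
    stop_ns("ellipsoids/extremes keyed differently for: ",
            paste(bad, collapse = ", "))
  }
  rows <- lapply(sp, function(s) {
    e <- ellipsoids[[s]]
    br <- univariate_breadth(extremes[[s]], layer_map$temp_max,
                             layer_map$temp_min, layer_map$prec_max,
                             layer_map$prec_min)
    ce <- univariate_centroid(extremes[[s]], layer_map$temp_max,
                              layer_map$temp_min, layer_map$prec_max,
                              layer_map$prec_min)
    ma <- univariate_marginality(ce, reference, layer_map$temp_mean,
                                 layer_map$prec_mean)
    data.frame(
      species = s,
      NB = e$volume,
      NM = multivariate_marginality(e, reference),
      NP = NA_real_,
      TB = br[["TB"]], TM = ma[["TM"]], TP = NA_real_,
      PB = br[["PB"]], PM = ma[["PM"]], PP = NA_real_,
      temp_centroid = ce[["temp"]], prec_centroid = ce[["prec"]],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  mv <- do.call(rbind, lapply(sp, function(s) ellipsoids[[s]]$centroid))
  colnames(mv) <- paste0("mv_centroid_", seq_len(ncol(mv)))
  tab <- cbind(tab, mv)
  if (!is.null(positions)) {
    unknown <- setdiff(positions$species, sp)
    if (length(unknown) > 0L) {
      stop_ns("positions given for unknown species: ",
              paste(unknown, collapse = ", "))
    }
    i <- match(positions$species, tab$species)
    for (col in intersect(c("NP", "TP", "PP"), names(positions))) {
      tab[[col]][i] <- positions[[col]]
    }
  }
  class(tab) <- c("niche_property_table", "data.frame")
  tab
}

#' Named property vector from a property table
#'
#' @param tab a [assemble_property_table()] table.
#' @param property column name (e.g. `"NB"`).
#' @return named numeric vector keyed by species.
#' @export
property_vector <- function(tab, property) {
  if (!property %in% names(tab)) stop_ns("no such property: ", property)
  stats::setNames(tab[[property]], tab$species)
}
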