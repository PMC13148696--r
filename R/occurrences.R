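#' Occurrence records for one species
#'
#' A thin data-frame wrapper carrying, per record, numeric coordinates plus
#' the coordinate text as written in the source. The text is preserved through
#' all cleaning steps because the precision filter counts decimal digits as
#' written, which numeric round-tripping would destroy.
#'
#' @param species_id non-empty species identifier.
#' @param lon,lat numeric coordinates (planar km in synthetic mode, decimal
#'   degrees in real-data mode).
#' @param source_id optional per-record identifiers.
#' @param lon_txt,lat_txt coordinates as written; defaults to a plain decimal
#'   formatting of the numeric values.
#' @return an object of class `occurrence_set` (also a data frame).
#' @export
occurrence_set <- function(species_id, lon, lat, source_id = NULL,
                           lon_txt = NULL, lat_txt = NULL) {
  if (!is.character(species_id) || length(species_id) != 1L ||
      is.na(species_id) || species_id == "") {
    stop_ns("species_id must be a non-empty string")
  }
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (anyNA(lon) || anyNA(lat)) stop_ns("coordinates must not be NA")
  n <- length(lon)
  if (length(lat) != n) stop_ns("lon and lat lengths differ")
  fmt <- function(v) format(v, trim = TRUE, scientific = FALSE, digits = 15)
  df <- data.frame(
    species = rep(species_id, n),
    lon = lon, lat = lat,
    lon_txt = as.character(lon_txt %||% fmt(lon)),
    lat_txt = as.character(lat_txt %||% fmt(lat)),
    source_id = as.character(source_id %||% seq_len(max(n, 0))),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("occurrence_set", "data.frame"),
            species_id = species_id)
}

occ_species <- function(occ) attr(occ, "species_id")

occ_subset <- function(occ, idx) {
  out <- occ[idx, , drop = FALSE]
  structure(out, class = c("occurrence_set", "data.frame"),
            species_id = occ_species(occ))
}

n_decimals <- function(txt) {
  # decimal digits as written; no decimal point (or scientific notation) -> 0
  has_exp <- grepl("[eE]", txt)
  dec <- ifelse(grepl("\\.", txt) & !has_exp,
                nchar(sub("^-?[0-9]*\\.", "", txt)), 0L)
  as.integer(dec)
}

#' Drop low-precision records
#'
#' Keeps records whose written longitude and latitude both carry at least
#' `min_decimals` decimal digits; coarse coordinates (e.g. whole degrees)
#' usually indicate country- or grid-centroid georeferencing.
#'
#' @param occ an [occurrence_set()].
#' @param min_decimals minimum decimal digits required in each coordinate
#'   (default 2).
#' @return the filtered occurrence set (possibly empty).
#' @export
filter_precision <- function(occ, min_decimals = 2) {
  keep <- n_decimals(occ$lon_txt) >= min_decimals &
    n_decimals(occ$lat_txt) >= min_decimals
  occ_subset(occ, keep)
}

#' Keep one record per raster pixel
#'
#' The first record (input order) in each cell of the stack's grid survives;
#' records falling outside the raster extent are dropped with a warning.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [climate_stack()] defining the pixel grid.
#' @return the deduplicated occurrence set.
#' @export
dedupe_pixel <- function(occ, stack) {
  if (nrow(occ) == 0L) return(occ)
  loc <- locate_cells(stack, occ$lon, occ$lat)
  outside <- is.na(loc$cell)
  if (any(outside)) {
    warning(sum(outside), " record(s) of ", occ_species(occ),
            " outside raster extent dropped", call. = FALSE)
  }
  keep <- !outside & !duplicated(loc$cell) | FALSE
  keep[outside] <- FALSE
  occ_subset(occ, keep)
}

#' Spatially thin records to a minimum pairwise distance
#'
#' Greedy thinning: the record with the most neighbors closer than `min_km`
#' is removed repeatedly (ties broken by a seeded draw) until all pairwise
#' distances are at least `min_km`. Records are canonicalized by coordinate
#' sort before the greedy pass so the result does not depend on input order.
#'
#' @param occ an [occurrence_set()].
#' @param min_km minimum pairwise distance to enforce, km (default 5).
#' @param seed integer seed for tie-breaking.
#' @param great_circle if `TRUE`, treat coordinates as lon/lat degrees and use
#'   haversine distances; default `FALSE` (planar km).
#' @return the thinned occurrence set.
#' @export
thin_distance <- function(occ, min_km = 5, seed = 1, great_circle = FALSE) {
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  ord <- order(occ$lon, occ$lat, occ$source_id)
  pts <- cbind(occ$lon, occ$lat)[ord, , drop = FALSE]
  dm <- if (great_circle) {
    hav_km(pts)
  } else {
    as.matrix(stats::dist(pts))
  }
  close <- dm < min_km
  diag(close) <- FALSE
  alive <- rep(TRUE, n)
  with_seed(seed, {
    repeat {
      deg <- rowSums(close[, alive, drop = FALSE]) * alive
      if (max(deg) == 0) break
      worst <- which(deg == max(deg))
      drop_i <- if (length(worst) > 1L) worst[sample.int(length(worst), 1)] else worst
      alive[drop_i] <- FALSE
    }
  })
  occ_subset(occ, sort(ord[alive]))
}

hav_km <- function(pts) {
  # pairwise haversine distances, km (pts = lon/lat degrees)
  rad <- pi / 180
  lon <- pts[, 1] * rad
  lat <- pts[, 2] * rad
  n <- nrow(pts)
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  6371.0088 * 2 * asin(pmin(1, sqrt(a)))
}

#' Does a species meet the minimum-locality requirement?
#'
#' @param occ a cleaned [occurrence_set()].
#' @param minimum required number of unique coordinate pairs (default 5).
#' @return `TRUE` iff the count of unique coordinates reaches the minimum.
#' @export
check_min_records <- function(occ, minimum = 5) {
  nrow(unique(cbind(occ$lon, occ$lat))) >= minimum
}

#' Extract per-record environment values
#'
#' Nearest-cell lookup of every stack layer at each record; records on nodata
#' cells (or outside the extent) are dropped with a warning.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [climate_stack()].
#' @return numeric matrix, one row per surviving record, one column per layer.
#' @export
extract_env <- function(occ, stack) {
  vals <- stack_values(stack)
  if (nrow(occ) == 0L) {
    return(matrix(numeric(0), 0, n_layers(stack),
                  dimnames = list(NULL, names(stack$layers))))
  }
  loc <- locate_cells(stack, occ$lon, occ$lat)
  out <- matrix(NA_real_, nrow(occ), n_layers(stack),
                dimnames = list(NULL, names(stack$layers)))
  ok <- !is.na(loc$cell)
  out[ok, ] <- vals[loc$cell[ok], , drop = FALSE]
  good <- stats::complete.cases(out)
  if (!any(good)) stop_ns("all records of ", occ_species(occ),
                          " fall on nodata cells")
  if (any(!good)) {
    warning(sum(!good), " record(s) of ", occ_species(occ),
            " on nodata cells dropped", call. = FALSE)
  }
  out[good, , drop = FALSE]
}

#' Read / write occurrence CSVs
#'
#' CSV columns: `species, lon, lat, source_id` (header required). Coordinates
#' are kept as text alongside their numeric values.
#'
#' @param path CSV file path.
#' @param occs a single [occurrence_set()] or a list of them.
#' @return `read_occurrences` returns a named list of occurrence sets.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, colClasses = c(species = "character",
                                             lon = "character",
                                             lat = "character"))
  if (!all(c("species", "lon", "lat") %in% names(df))) {
    stop_ns("occurrence CSV needs columns species, lon, lat")
  }
  if (is.null(df$source_id)) df$source_id <- as.character(seq_len(nrow(df)))
  sp <- unique(df$species)
  out <- lapply(sp, function(s) {
    d <- df[df$species == s, , drop = FALSE]
    occurrence_set(s, as.numeric(d$lon), as.numeric(d$lat),
                   source_id = as.character(d$source_id),
                   lon_txt = d$lon, lat_txt = d$lat)
  })
  stats::setNames(out, sp)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occs, path) {
  if (inherits(occs, "occurrence_set")) occs <- list(occs)
  df <- do.call(rbind, lapply(occs, function(o) {
    data.frame(species = o$species, lon = o$lon_txt, lat = o$lat_txt,
               source_id = o$source_id, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
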