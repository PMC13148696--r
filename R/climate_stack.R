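#' Multi-layer climate raster on a planar grid
#'
#' A `climate_stack` holds named co-registered 2-D layers (e.g. bioclim-style
#' variables, or principal-component scores) on a regular planar grid.
#' Row 1 is the southern (lowest-y) row; cell `(r, c)` has its center at
#' `origin + (c - 0.5, r - 0.5) * res_km`. `NA` marks nodata; all layers must
#' share the same nodata footprint, shape and geometry.
#'
#' @param layers named list of numeric matrices, identical dimensions.
#' @param res_km cell size (km in synthetic/planar mode; any planar unit).
#' @param origin numeric length-2, planar coordinates of the grid's lower-left
#'   corner.
#' @param crs text tag describing the coordinate frame (default `"planar_km"`).
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, res_km = 1, origin = c(0, 0),
                          crs = "planar_km") {
  if (!is.list(layers) || length(layers) == 0L) {
    stop_ns("`layers` must be a non-empty named list of matrices")
  }
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop_ns("layer names must be unique and non-empty")
  }
  dims <- lapply(layers, dim)
  if (any(vapply(layers, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stop_ns("every layer must be a numeric matrix")
  }
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), TRUE))) {
    stop_ns("all layers must share the same dimensions")
  }
  # enforce a shared nodata mask
  na1 <- is.na(layers[[1]])
  for (k in seq_along(layers)) {
    if (!identical(is.na(layers[[k]]), na1)) {
      stop_ns("all layers must share the same nodata mask (layer '",
              nms[k], "' differs)")
    }
  }
  structure(
    list(layers = layers, res_km = res_km, origin = as.numeric(origin),
         crs = crs),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat("<climate_stack> ", length(x$layers), " layer(s), ",
      d[1], " x ", d[2], " cells @ ", x$res_km, " km [", x$crs, "]\n",
      sep = "")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  valid cells:", sum(!is.na(x$layers[[1]])), "\n")
  invisible(x)
}

stack_dim <- function(stack) dim(stack$layers[[1]])

n_layers <- function(stack) length(stack$layers)

#' Planar coordinates of all cell centers
#'
#' @param stack a [climate_stack()].
#' @return data frame with columns `cell` (row-major index over the grid,
#'   rows varying slowest), `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(stack) {
  d <- stack_dim(stack)
  rows <- rep(seq_len(d[1]), each = d[2])
  cols <- rep(seq_len(d[2]), times = d[1])
  data.frame(
    cell = seq_len(d[1] * d[2]),
    row = rows, col = cols,
    x = stack$origin[1] + (cols - 0.5) * stack$res_km,
    y = stack$origin[2] + (rows - 0.5) * stack$res_km
  )
}

# row-major (row varies slowest) linear index <-> (row, col)
cell_index <- function(row, col, ncol) (row - 1L) * ncol + col

#' Map planar coordinates to grid cells
#'
#' @param stack a [climate_stack()].
#' @param x,y planar coordinates.
#' @return data frame with `row`, `col`, `cell`; `NA` for points outside the
#'   grid extent.
#' @export
locate_cells <- function(stack, x, y) {
  d <- stack_dim(stack)
  col <- floor((x - stack$origin[1]) / stack$res_km) + 1
  row <- floor((y - stack$origin[2]) / stack$res_km) + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1] |
    !is.finite(col) | !is.finite(row)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = ifelse(bad, NA_integer_,
                           cell_index(as.integer(row), as.integer(col), d[2])))
}

# cells x layers value matrix (row-major cell order); rownames = cell index
stack_values <- function(stack) {
  vals <- vapply(stack$layers, function(m) as.vector(t(m)),
                 numeric(prod(stack_dim(stack))))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = n_layers(stack))
  colnames(vals) <- names(stack$layers)
  vals
}

# rebuild a layer matrix from a row-major cell vector
vector_to_layer <- function(v, dims) {
  matrix(v, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Drop named layers from a stack
#'
#' Used to exclude variables known to behave badly in the modelled region
#' (for bioclim inputs, the four combined temperature-precipitation layers
#' bio8, bio9, bio18 and bio19 are the usual exclusions).
#'
#' @param stack a [climate_stack()].
#' @param excluded character vector of layer names to drop (may be empty).
#' @return the stack without the excluded layers, order preserved.
#' @export
drop_excluded_layers <- function(stack, excluded) {
  excluded <- as.character(excluded)
  unknown <- setdiff(excluded, names(stack$layers))
  if (length(unknown) > 0L) {
    stop_ns("unknown layer(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(names(stack$layers), excluded)
  if (length(keep) == 0L) stop_ns("cannot drop every layer")
  out <- stack
  out$layers <- stack$layers[keep]
  out
}

#' Mask a stack to a study-area polygon
#'
#' Cells whose centers fall outside the polygon become nodata in every layer;
#' the grid geometry is unchanged. Cell membership is decided by cell-center
#' containment (boundary counts as inside).
#'
#' @param stack a [climate_stack()].
#' @param area an [area_polygon()] in the stack's coordinate frame.
#' @return the masked stack.
#' @export
mask_to_area <- function(stack, area) {
  cc <- cell_centers(stack)
  inside <- polygon_contains(area, cc$x, cc$y)
  if (!any(inside)) stop_ns("study area does not overlap raster")
  d <- stack_dim(stack)
  mask <- vector_to_layer(inside, d)
  out <- stack
  out$layers <- lapply(stack$layers, function(m) {
    m[!mask] <- NA_real_
    m
  })
  out
}

#' Per-layer means over the valid study-area cells
#'
#' Summarizes the climate available in the study area; the per-layer means are
#' the reference point for univariate niche marginality. In the centered
#' principal-component space the analogous reference is the origin, so
#' `pc_origin` is an all-zero vector with one entry per retained component.
#'
#' @param stack a [climate_stack()] already masked to the study area.
#' @param n_components number of retained components for the `pc_origin`
#'   reference (default 3).
#' @return list with `mean_by_layer` (named numeric) and `pc_origin`.
#' @export
env_summary <- function(stack, n_components = 3) {
  vals <- stack_values(stack)
  ok <- stats::complete.cases(vals)
  if (!any(ok)) stop_ns("no valid cells to summarize")
  structure(
    list(mean_by_layer = colMeans(vals[ok, , drop = FALSE]),
         pc_origin = rep(0, n_components)),
    class = "env_summary"
  )
}

#' Write / read a climate stack as plain-text artifacts
#'
#' One CSV of cell values per layer plus a JSON metadata sidecar; a plain-text
#' interchange format that round-trips exactly at full double precision.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if missing).
#' @return `write_stack` returns the directory invisibly; `read_stack`
#'   returns the reconstructed stack.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(res_km = stack$res_km, origin = stack$origin, crs = stack$crs,
               dims = stack_dim(stack), layer_names = names(stack$layers))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(stack$layers)) {
    utils::write.table(
      format(stack$layers[[nm]], digits = 17, trim = TRUE, scientific = TRUE),
      file.path(dir, paste0("layer_", nm, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- lapply(meta$layer_names, function(nm) {
    as.matrix(utils::read.table(file.path(dir, paste0("layer_", nm, ".csv")),
                                sep = ",", header = FALSE))
  })
  layers <- lapply(layers, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(layers) <- meta$layer_names
  climate_stack(layers, res_km = meta$res_km, origin = meta$origin,
                crs = meta$crs)
}
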