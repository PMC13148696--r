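#' Presence-absence matrix on a coarse equal-area grid
#'
#' Aggregates fine-resolution species ranges onto an axis-aligned coarse grid
#' (default cell size 110 km, the planar analog of a one-degree grid). A
#' species occupies a coarse cell iff at least one of its fine range-cell
#' centers falls inside it (presence-anywhere rule). Empty cells are retained
#' as all-zero rows.
#'
#' @param ranges list of [constrain_range()] range maps on a shared fine grid.
#' @param grid_res_km coarse cell size in km (default 110).
#' @param stack optional [climate_stack()]; when given, coarse cells holding
#'   at least one valid (non-nodata) fine cell define the analysis domain
#'   (used by the geometric-constraint null).
#' @return an object of class `pam`: binary `matrix` (cells x species),
#'   `cell_ids`, `centroids` (cells x 2, km), `dims` (coarse grid), `res_km`,
#'   `origin`, logical `domain` per cell.
#' @export
build_pam <- function(ranges, grid_res_km = 110, stack = NULL) {
  if (length(ranges) == 0L) stop_ns("no ranges supplied")
  sp <- vapply(ranges, function(r) r$species_id, character(1))
  if (anyDuplicated(sp)) {
    stop_ns("duplicated species_id: ", sp[duplicated(sp)][1])
  }
  g <- ranges[[1]]$geometry
  for (r in ranges) {
    if (!identical(r$geometry, g)) stop_ns("ranges are on different grids")
  }
  fine_nrow <- g$dims[1]; fine_ncol <- g$dims[2]
  ratio <- grid_res_km / g$res_km
  c_nrow <- ceiling(fine_nrow / ratio)
  c_ncol <- ceiling(fine_ncol / ratio)
  n_cells <- c_nrow * c_ncol

  fine_to_coarse <- function(cells) {
    row <- (cells - 1L) %/% fine_ncol + 1L
    col <- (cells - 1L) %% fine_ncol + 1L
    # fine-cell center position in km from the grid origin
    x <- (col - 0.5) * g$res_km
    y <- (row - 0.5) * g$res_km
    crow <- pmin(floor(y / grid_res_km) + 1L, c_nrow)
    ccol <- pmin(floor(x / grid_res_km) + 1L, c_ncol)
    cell_index(crow, ccol, c_ncol)
  }

  mat <- matrix(0L, n_cells, length(ranges),
                dimnames = list(NULL, sp))
  for (k in seq_along(ranges)) {
    occ_cells <- unique(fine_to_coarse(ranges[[k]]$cells))
    mat[occ_cells, k] <- 1L
  }
  crow <- rep(seq_len(c_nrow), each = c_ncol)
  ccol <- rep(seq_len(c_ncol), times = c_nrow)
  centroids <- cbind(x = g$origin[1] + (ccol - 0.5) * grid_res_km,
                     y = g$origin[2] + (crow - 0.5) * grid_res_km)
  domain <- rep(TRUE, n_cells)
  if (!is.null(stack)) {
    valid_fine <- which(!is.na(as.vector(t(stack$layers[[1]]))))
    domain <- rep(FALSE, n_cells)
    domain[unique(fine_to_coarse(valid_fine))] <- TRUE
  }
  structure(
    list(matrix = mat, cell_ids = seq_len(n_cells), centroids = centroids,
         dims = c(c_nrow, c_ncol), res_km = grid_res_km, origin = g$origin,
         domain = domain),
    class = "pam"
  )
}

#' @export
print.pam <- function(x, ...) {
  cat("<pam> ", nrow(x$matrix), " cells (", x$dims[1], " x ", x$dims[2],
      " @ ", x$res_km, " km) x ", ncol(x$matrix), " species\n", sep = "")
  cat("  occupied cells: ", sum(rowSums(x$matrix) > 0),
      "; total presences: ", sum(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Species richness per cell
#'
#' @param pam a [build_pam()] object.
#' @return integer vector of row sums (species per cell).
#' @export
richness <- function(pam) {
  as.integer(rowSums(pam$matrix))
}

#' Per-cell mean of a species-level niche property
#'
#' The assemblage-level map of a property: each cell takes the arithmetic mean
#' of the property over the species present there; cells with no species get
#' `NA`. Species without a property value are dropped from this map with a
#' warning.
#'
#' @param pam a [build_pam()] object.
#' @param prop named numeric vector (names = species ids).
#' @param fun aggregation function, default `mean` (the assemblage average);
#'   `median` is a robust alternative.
#' @return numeric per-cell vector.
#' @export
map_property <- function(pam, prop, fun = mean) {
  sp <- colnames(pam$matrix)
  have <- sp[sp %in% names(prop) & !is.na(prop[sp])]
  if (length(have) < length(sp)) {
    warning(length(sp) - length(have),
            " species lack the property and are dropped from this map",
            call. = FALSE)
  }
  m <- pam$matrix[, have, drop = FALSE]
  v <- prop[have]
  if (identical(fun, mean)) {
    n_here <- rowSums(m)
    out <- as.vector(m %*% v) / n_here
    out[n_here == 0] <- NA_real_
    return(out)
  }
  apply(m, 1, function(row) {
    if (sum(row) == 0) NA_real_ else fun(v[row == 1])
  })
}

#' Compare two richness surfaces by rank correlation
#'
#' Spearman correlation (average ranks for ties) between two per-cell
#' richness vectors, excluding cells empty in both; the standard check that a
#' model-based richness map reproduces an independent (e.g. expert-range)
#' richness map.
#'
#' @param r1,r2 per-cell richness vectors on the same grid.
#' @return list with `rho` and two-sided `p`.
#' @export
compare_richness <- function(r1, r2) {
  if (length(r1) != length(r2)) stop_ns("richness vectors differ in length")
  keep <- !(r1 %in% c(0, NA) & r2 %in% c(0, NA)) &
    !is.na(r1) & !is.na(r2)
  if (sum(keep) < 3) stop_ns("fewer than 3 shared occupied cells")
  ct <- suppressWarnings(
    stats::cor.test(r1[keep], r2[keep], method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Write / read a PAM as wide CSV
#'
#' Columns: `cell_id, x, y, domain`, then one 0/1 column per species.
#'
#' @param pam a [build_pam()] object.
#' @param path CSV file path.
#' @return `read_pam` returns the PAM (grid dims and resolution are carried
#'   in a JSON sidecar next to the CSV).
#' @export
write_pam <- function(pam, path) {
  df <- data.frame(cell_id = pam$cell_ids, x = pam$centroids[, 1],
                   y = pam$centroids[, 2],
                   domain = as.integer(pam$domain))
  df <- cbind(df, as.data.frame(pam$matrix))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dims = pam$dims, res_km = pam$res_km, origin = pam$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_pam
#' @export
read_pam <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sp_cols <- setdiff(names(df), c("cell_id", "x", "y", "domain"))
  mat <- as.matrix(df[, sp_cols, drop = FALSE])
  storage.mode(mat) <- "integer"
  structure(
    list(matrix = mat, cell_ids = df$cell_id,
         centroids = cbind(x = df$x, y = df$y),
         dims = meta$dims, res_km = meta$res_km, origin = meta$origin,
         domain = as.logical(df$domain)),
    class = "pam"
  )
}
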