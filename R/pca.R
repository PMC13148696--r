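#' Principal-component model of the climate space
#'
#' Fits a PCA to the valid cells of a climate stack. Because bioclim-style
#' layers carry incommensurate units, variables are standardized (centered and
#' scaled to unit variance) before decomposition, i.e. the PCA is computed on
#' the correlation matrix. Component signs are fixed so the largest-magnitude
#' loading of each component is positive, making results reproducible across
#' eigen-solvers.
#'
#' @param stack a [climate_stack()] (typically masked to the study area).
#' @param n_components number of components to retain (default 3).
#' @return an object of class `pca_model`: `means`, `sds`, `loadings`
#'   (layers x components), `explained_variance_fraction`, `layer_names`.
#' @export
fit_pca <- function(stack, n_components = 3) {
  vals <- stack_values(stack)
  ok <- stats::complete.cases(vals)
  v <- vals[ok, , drop = FALSE]
  p <- ncol(v)
  if (n_components > p) stop_ns("n_components exceeds the number of layers")
  if (nrow(v) < n_components + 1) stop_ns("too few valid cells for PCA")
  sds <- apply(v, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop_ns("zero variance over valid cells in layer(s): ",
            paste(colnames(v)[sds < 1e-12], collapse = ", "))
  }
  pr <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  load <- pr$rotation
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  ev <- pr$sdev^2
  structure(
    list(means = pr$center, sds = pr$scale,
         loadings = load[, seq_len(n_components), drop = FALSE],
         explained_variance_fraction = (ev / sum(ev))[seq_len(n_components)],
         layer_names = colnames(v)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", length(x$layer_names), " layers -> ",
      ncol(x$loadings), " components (",
      format(100 * sum(x$explained_variance_fraction), digits = 4),
      "% variance)\n", sep = "")
  invisible(x)
}

#' Project a stack into component space
#'
#' Standardizes each layer with the model's means/sds and applies the
#' loadings; output layers are named `pc1..pcK`. Nodata propagates.
#'
#' @param model a [fit_pca()] model.
#' @param stack a [climate_stack()] whose layers include the model's layers.
#' @return a [climate_stack()] of component scores.
#' @export
project_pca <- function(model, stack) {
  missing_layers <- setdiff(model$layer_names, names(stack$layers))
  if (length(missing_layers) > 0L) {
    stop_ns("stack lacks layer(s): ", paste(missing_layers, collapse = ", "))
  }
  vals <- stack_values(stack)[, model$layer_names, drop = FALSE]
  z <- sweep(sweep(vals, 2, model$means), 2, model$sds, "/")
  scores <- z %*% model$loadings
  d <- stack_dim(stack)
  out <- lapply(seq_len(ncol(scores)),
                function(k) vector_to_layer(scores[, k], d))
  names(out) <- paste0("pc", seq_len(ncol(scores)))
  climate_stack(out, res_km = stack$res_km, origin = stack$origin,
                crs = stack$crs)
}

#' Serialize / load a PCA model as JSON
#'
#' @param model a `pca_model`.
#' @param path file path.
#' @return `read_pca_model` returns the model.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(layer_names = model$layer_names,
         means = unname(model$means), sds = unname(model$sds),
         loadings = unname(model$loadings),
         explained_variance_fraction = model$explained_variance_fraction),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- matrix(unlist(j$loadings), nrow = length(j$layer_names),
                 byrow = TRUE)
  rownames(load) <- j$layer_names
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(
    list(means = stats::setNames(j$means, j$layer_names),
         sds = stats::setNames(j$sds, j$layer_names),
         loadings = load,
         explained_variance_fraction = j$explained_variance_fraction,
         layer_names = j$layer_names),
    class = "pca_model"
  )
}
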