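#' Ellipsoid niche model
#'
#' An ellipsoid in environment (component) space: centroid `mu`, symmetric
#' positive-definite shape matrix `covariance` (Sigma), and squared coverage
#' radius `radius2` (c^2) such that a point x is inside iff its squared
#' Mahalanobis distance (x - mu)' Sigma^-1 (x - mu) <= c^2. The volume is
#' V_d * sqrt(det(Sigma)) * c^d with V_d the unit-ball volume.
#'
#' @param centroid numeric d-vector.
#' @param covariance d x d SPD matrix.
#' @param radius2 positive scalar.
#' @param species_id optional species label.
#' @return an object of class `ellipsoid`.
#' @export
ellipsoid <- function(centroid, covariance, radius2, species_id = NULL) {
  centroid <- as.numeric(centroid)
  covariance <- as.matrix(covariance)
  d <- length(centroid)
  if (!all(dim(covariance) == d)) stop_ns("covariance dimension mismatch")
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop_ns("covariance is not positive definite")
  if (!is_scalar_num(radius2) || radius2 <= 0) stop_ns("radius2 must be > 0")
  structure(
    list(centroid = centroid, covariance = covariance, radius2 = radius2,
         volume = ellipsoid_volume(covariance, radius2),
         d = d, species_id = species_id),
    class = "ellipsoid"
  )
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat("<ellipsoid> d = ", x$d,
      if (!is.null(x$species_id)) paste0(", species ", x$species_id) else "",
      "\n  centroid: ", paste(format(x$centroid, digits = 4), collapse = ", "),
      "\n  radius2: ", format(x$radius2, digits = 4),
      "  volume: ", format(x$volume, digits = 4), "\n", sep = "")
  invisible(x)
}

unit_ball_volume <- function(d) pi^(d / 2) / gamma(d / 2 + 1)

ellipsoid_volume <- function(covariance, radius2) {
  d <- nrow(covariance)
  unit_ball_volume(d) * sqrt(det(covariance)) * radius2^(d / 2)
}

#' Squared Mahalanobis distance to an ellipsoid centroid
#'
#' The shared kernel of presence prediction, niche marginality and
#' phylogenetic niche position: D2 = (x - mu)' Sigma^-1 (x - mu).
#'
#' @param point numeric d-vector, or an n x d matrix of points.
#' @param ell an [ellipsoid()].
#' @return squared distance(s), >= 0.
#' @export
mahalanobis2 <- function(point, ell) {
  x <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (ncol(x) != ell$d) stop_ns("point dimension mismatch")
  stats::mahalanobis(x, center = ell$centroid, cov = ell$covariance)
}

#' Fit a minimum-volume ellipsoid to occurrence environments
#'
#' Finds a small-volume ellipsoid containing exactly `h = ceiling(coverage*n)`
#' of the points, so a 0.95 coverage yields a 5% omission design. Exhaustive
#' search over h-subsets is infeasible, so a seeded multi-start concentration
#' heuristic is used: random h-subsets are refined by recomputing the subset
#' mean/covariance, re-selecting the h smallest-distance points, and iterating
#' to a fixed point; every visited subset is scored and the minimum-volume
#' ellipsoid over all starts is returned. `radius2` is set to the h-th
#' smallest squared Mahalanobis distance under the final shape, which makes
#' the exact-coverage contract testable. Deterministic given `seed`.
#'
#' @param points n x d numeric matrix of environment values (n >= d + 2).
#' @param coverage fraction of points the ellipsoid must contain,
#'   in (0.5, 1]; default 0.95.
#' @param seed integer seed.
#' @param n_starts number of random starts (default 50).
#' @param max_iter concentration iteration cap per start.
#' @param species_id optional species label.
#' @return an [ellipsoid()].
#' @export
fit_mve <- function(points, coverage = 0.95, seed = 1, n_starts = 50,
                    max_iter = 100, species_id = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  d <- ncol(points)
  if (d < 1) stop_ns("need at least one dimension")
  if (n < d + 2) stop_ns("too few occurrences (need n >= d + 2)")
  if (!(coverage > 0.5 && coverage <= 1)) stop_ns("coverage must be in (0.5, 1]")
  sv <- svd(scale(points, center = TRUE, scale = FALSE), nu = 0, nv = 0)
  if (sv$d[d] < 1e-10 * max(sv$d[1], 1)) {
    stop_ns("degenerate points (rank < d); reduce the dimensionality")
  }
  h <- ceiling(coverage * n)

  score_subset <- function(idx) {
    mu <- colMeans(points[idx, , drop = FALSE])
    S <- stats::cov(points[idx, , drop = FALSE])
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev, 1)) return(NULL)
    d2 <- stats::mahalanobis(points, mu, S)
    ord <- order(d2)
    r2 <- d2[ord[h]]
    list(mu = mu, S = S, r2 = r2, vol = ellipsoid_volume(S, r2),
         inside = sort(ord[seq_len(h)]), d2 = d2)
  }

  # deterministic envelope candidate: full-sample shape, h-th smallest radius
  mu_full <- colMeans(points)
  S_full <- stats::cov(points)
  d2_full <- stats::mahalanobis(points, mu_full, S_full)
  ord_full <- order(d2_full)
  r2_full <- d2_full[ord_full[h]]
  best <- list(mu = mu_full, S = S_full, r2 = r2_full,
               vol = ellipsoid_volume(S_full, r2_full),
               inside = sort(ord_full[seq_len(h)]))
  with_seed(seed, {
    for (s in seq_len(n_starts + 1)) {
      idx <- if (s == 1) best$inside else sort(sample.int(n, h))
      for (it in seq_len(max_iter)) {
        cand <- score_subset(idx)
        if (is.null(cand)) break
        if (is.null(best) || cand$vol < best$vol) best <- cand
        if (identical(cand$inside, idx)) break
        idx <- cand$inside
      }
    }
  })
  if (is.null(best)) stop_ns("MVE search failed (degenerate subsets)")
  ellipsoid(best$mu, best$S, best$r2, species_id = species_id)
}

#' Project an ellipsoid to geography as a binary presence grid
#'
#' A cell is predicted present iff its environment lies inside the ellipsoid
#' (squared Mahalanobis distance <= radius2); nodata cells stay nodata.
#'
#' @param ell an [ellipsoid()] fitted in the space of `pc_stack`'s layers.
#' @param pc_stack a [climate_stack()] whose layers are, in order, the d
#'   dimensions used when fitting.
#' @return a 0/1 matrix with the stack's grid shape (`NA` = nodata).
#' @export
predict_presence <- function(ell, pc_stack) {
  if (n_layers(pc_stack) != ell$d) {
    stop_ns("stack has ", n_layers(pc_stack), " layers but ellipsoid is ",
            ell$d, "-dimensional")
  }
  vals <- stack_values(pc_stack)
  pres <- rep(NA_real_, nrow(vals))
  ok <- stats::complete.cases(vals)
  pres[ok] <- as.numeric(mahalanobis2(vals[ok, , drop = FALSE], ell) <=
                           ell$radius2)
  vector_to_layer(pres, stack_dim(pc_stack))
}

#' Species range on the analysis grid
#'
#' The set of fine-grid cells predicted present and whose centers fall inside
#' the accessible-area constraint polygon (minimum convex polygon + buffer).
#'
#' @param presence 0/1 presence matrix from [predict_presence()].
#' @param constraint an [area_polygon()].
#' @param stack the [climate_stack()] defining the grid geometry.
#' @param species_id species label.
#' @return an object of class `range_map`: `species_id`, `cells` (row-major
#'   fine-cell indices), `geometry`, `constraint`.
#' @export
constrain_range <- function(presence, constraint, stack, species_id) {
  pres_v <- as.vector(t(presence))
  cand <- which(!is.na(pres_v) & pres_v == 1)
  cc <- cell_centers(stack)
  keep <- cand[polygon_contains(constraint, cc$x[cand], cc$y[cand])]
  if (length(keep) == 0L) {
    message("range of ", species_id, " is empty after constraint")
  }
  structure(
    list(species_id = species_id, cells = keep,
         geometry = list(dims = stack_dim(stack), res_km = stack$res_km,
                         origin = stack$origin),
         constraint = constraint),
    class = "range_map"
  )
}

#' @export
print.range_map <- function(x, ...) {
  cat("<range_map> ", x$species_id, ": ", length(x$cells), " cells\n",
      sep = "")
  invisible(x)
}

#' Serialize / load ellipsoids as JSON
#'
#' @param ells a single [ellipsoid()] or list of them.
#' @param path file path.
#' @return `read_ellipsoids` returns a list of ellipsoids.
#' @export
write_ellipsoids <- function(ells, path) {
  if (inherits(ells, "ellipsoid")) ells <- list(ells)
  out <- lapply(ells, function(e) {
    list(species = e$species_id %||% "", d = e$d, centroid = e$centroid,
         covariance_rowmajor = as.vector(t(e$covariance)),
         radius2 = e$radius2, volume = e$volume)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ellipsoids
#' @export
read_ellipsoids <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(j, function(e) {
    d <- e$d
    ellipsoid(unlist(e$centroid),
              matrix(unlist(e$covariance_rowmajor), d, d, byrow = TRUE),
              e$radius2,
              species_id = if (nzchar(e$species)) e$species else NULL)
  })
}
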