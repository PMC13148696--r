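#' Synthetic multi-layer climate landscape
#'
#' Generates a planar climate stack with the statistical structure the
#' analysis assumes: every layer is a latitudinal (north-south) gradient plus
#' a spatially autocorrelated Gaussian random field (white noise smoothed
#' with a separable Gaussian kernel, giving approximately squared-exponential
#' correlation at the stated range). Layer 1 (`env1`) is temperature-like
#' (strong gradient, warm at low y); layer 2 (`env2`) is precipitation-like
#' (patchy, weak gradient, optionally bimodal to emulate a bimodal
#' distribution of available environments).
#'
#' @param n_rows,n_cols grid dimensions (>= 10 each), cell = 1 km.
#' @param n_layers number of layers (>= 2).
#' @param gradient_strength multiplier on the latitudinal gradient
#'   (0 removes it).
#' @param autocorr_range_km correlation range of the noise field, km.
#' @param seed integer seed.
#' @param bimodal if `TRUE` (default) the precipitation-like layer gets a
#'   two-regime (wet/dry) component.
#' @return a [climate_stack()] with layers `env1..envK`.
#' @export
make_landscape <- function(n_rows = 60, n_cols = 60, n_layers = 6,
                           gradient_strength = 1, autocorr_range_km = 8,
                           seed = 1, bimodal = TRUE) {
  if (n_rows < 10 || n_cols < 10) stop_ns("landscape must be at least 10 x 10")
  if (n_layers < 2) stop_ns("need at least 2 layers")
  lat <- (seq_len(n_rows) - 0.5) / n_rows  # 0 (south, warm) -> 1 (north)
  grad <- matrix(rep(lat, n_cols), n_rows, n_cols)
  layers <- with_seed(seed, {
    out <- vector("list", n_layers)
    for (k in seq_len(n_layers)) {
      noise <- gaussian_field(n_rows, n_cols, autocorr_range_km)
      if (k == 1) {
        # temperature-like: tropical gradient, degC scale
        out[[k]] <- 27 - gradient_strength * 18 * grad + 2 * noise
      } else if (k == 2) {
        # precipitation-like: patchy, mm scale, optionally bimodal
        regime <- if (bimodal) {
          800 * (gaussian_field(n_rows, n_cols, 4 * autocorr_range_km) > 0)
        } else {
          0
        }
        out[[k]] <- 1200 - gradient_strength * 300 * grad + 350 * noise + regime
      } else {
        w <- 0.5 * gradient_strength * (if (k %% 2 == 0) 1 else -1)
        out[[k]] <- w * 10 * grad + 5 * noise
      }
    }
    out
  })
  names(layers) <- paste0("env", seq_len(n_layers))
  climate_stack(layers, res_km = 1, origin = c(0, 0), crs = "planar_km")
}

# white noise smoothed with a separable Gaussian kernel (reflected edges),
# standardized to mean 0 / sd 1
gaussian_field <- function(n_rows, n_cols, range_km) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  s <- max(range_km, 1) / 2
  half <- max(1L, ceiling(3 * s))
  kern <- stats::dnorm(seq(-half, half), sd = s)
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    n <- length(v)
    p <- seq(1 - half, n + half)
    q <- (p - 1) %% (2 * n)           # periodic mirror fold of the margins
    idx <- ifelse(q < n, q + 1, 2 * n - q)
    as.numeric(stats::filter(v[idx], kern, sides = 2))[half + seq_len(n)]
  }
  z <- apply(z, 2, smooth_vec)
  z <- t(apply(z, 1, smooth_vec))
  (z - mean(z)) / stats::sd(z)
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' A Yule tree with the requested tip count, rescaled to height 1 (time in
#' tree-height units).
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed integer seed.
#' @return an `ape::phylo` tree with tip labels `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 3) stop_ns("need at least 3 tips")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Evolve species niches along a phylogeny
#'
#' Tip niche centroids evolve per axis under an exact Ornstein-Uhlenbeck
#' process from the given root (conditional normal transitions per branch,
#' no time discretization; `alpha = 0` gives Brownian motion). Each species
#' then receives a diagonal ellipsoid covariance with log-normal axis
#' standard deviations; `breadth_model` optionally couples the overall niche
#' scale to one centroid axis, which is how a breadth-richness gradient is
#' built into a scenario.
#'
#' @param tree an ultrametric `ape::phylo` tree.
#' @param root numeric d-vector, the ancestral niche centroid.
#' @param ou_params list with `alpha` (>= 0), `sigma2` (> 0), and optional
#'   `theta` (optimum d-vector, defaults to `root`).
#' @param breadth_model `NULL`, or a list coupling niche scale to centroid
#'   position; one of: `direction` + `origin` (log niche scale grows by
#'   `slope` per unit signed projection of `centroid - origin` onto the unit
#'   d-vector `direction`), `center` (growth per unit Euclidean distance from
#'   that point), or `axis` (growth per unit of one centroid axis); plus
#'   optional `base_log_sd`.
#' @param seed integer seed.
#' @param radius2 coverage radius passed to each [ellipsoid()] (default
#'   `qchisq(0.95, d)`).
#' @param niche_sd list with `base` (typical axis standard deviation, in
#'   component units) and `sdlog` (log-normal spread of axis standard
#'   deviations across species and axes).
#' @return named list of [ellipsoid()]s, one per tip.
#' @export
simulate_niche_evolution <- function(tree, root, ou_params = list(),
                                     breadth_model = NULL, seed = 1,
                                     radius2 = NULL,
                                     niche_sd = list(base = 0.35,
                                                     sdlog = 0.25)) {
  d <- length(root)
  alpha <- ou_params$alpha %||% 0
  sigma2 <- ou_params$sigma2 %||% 0.5
  theta <- ou_params$theta %||% root
  if (alpha < 0 || sigma2 <= 0) stop_ns("need alpha >= 0 and sigma2 > 0")
  if (length(theta) != d) stop_ns("theta dimension mismatch")
  radius2 <- radius2 %||% stats::qchisq(0.95, df = d)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- matrix(NA_real_, ntip + nnode, d)
  root_node <- ntip + 1L
  states[root_node, ] <- root
  # preorder traversal: parent state is always set before its children
  ord <- ape::reorder.phylo(tree, "cladewise")
  with_seed(seed, {
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t_e <- ord$edge.length[e]
      x0 <- states[par, ]
      if (alpha < 1e-12) {
        mu <- x0
        v <- sigma2 * t_e
      } else {
        w <- exp(-alpha * t_e)
        mu <- x0 * w + theta * (1 - w)
        v <- sigma2 * (1 - w^2) / (2 * alpha)
      }
      states[child, ] <- stats::rnorm(d, mean = mu, sd = sqrt(v))
    }
    tips <- states[seq_len(ntip), , drop = FALSE]
    ells <- lapply(seq_len(ntip), function(i) {
      log_sd <- stats::rnorm(d, mean = log(niche_sd$base),
                             sd = niche_sd$sdlog)
      if (!is.null(breadth_model)) {
        coord <- if (!is.null(breadth_model$direction)) {
          sum((tips[i, ] - (breadth_model$origin %||% 0)) *
                breadth_model$direction)
        } else if (!is.null(breadth_model$center)) {
          sqrt(sum((tips[i, ] - breadth_model$center)^2))
        } else {
          tips[i, breadth_model$axis]
        }
        log_sd <- log_sd + (breadth_model$base_log_sd %||% 0) +
          breadth_model$slope * coord
      }
      ellipsoid(tips[i, ], diag(exp(2 * log_sd), d), radius2,
                species_id = tree$tip.label[i])
    })
    stats::setNames(ells, tree$tip.label)
  })
}

#' Sample occurrence records from a species' niche
#'
#' Finds the landscape cells whose environment lies inside the ellipsoid,
#' draws `n_points` of them with replacement, and jitters each point
#' uniformly within its cell. Coordinate text carries three decimals so the
#' records pass the default precision filter.
#'
#' @param ell the species' [ellipsoid()] in the space of `pc_stack`.
#' @param pc_stack [climate_stack()] of the environment the ellipsoid lives
#'   in (component scores or raw layers, matching the fit space).
#' @param n_points number of records to draw.
#' @param seed integer seed.
#' @return an [occurrence_set()].
#' @export
sample_occurrences <- function(ell, pc_stack, n_points, seed) {
  vals <- stack_values(pc_stack)
  ok <- stats::complete.cases(vals)
  suitable <- which(ok)
  d2 <- mahalanobis2(vals[ok, , drop = FALSE], ell)
  suitable <- suitable[d2 <= ell$radius2]
  if (length(suitable) == 0L) {
    stop_ns("no suitable cell for species ",
            ell$species_id %||% "(unnamed)")
  }
  cc <- cell_centers(pc_stack)
  res <- pc_stack$res_km
  with_seed(seed, {
    cells <- suitable[sample.int(length(suitable), n_points, replace = TRUE)]
    x <- cc$x[cells] + stats::runif(n_points, -0.499, 0.499) * res
    y <- cc$y[cells] + stats::runif(n_points, -0.499, 0.499) * res
    occurrence_set(ell$species_id %||% "sp", x, y,
                   lon_txt = sprintf("%.3f", x), lat_txt = sprintf("%.3f", y))
  })
}

#' Build a complete synthetic study scenario
#'
#' Bundles a landscape, a phylogeny, evolved true niches and sampled
#' occurrences into one seeded, reproducible object. Landscape layers follow
#' bioclim-style naming so the univariate properties are computable: `bio1`
#' (mean temperature), `bio5`/`bio6` (warm/cold extremes, built as `bio1`
#' plus/minus positive seasonality fields), `bio12` (annual precipitation),
#' `bio13`/`bio14` (wet/dry extremes) plus two unstructured layers. Niches
#' are evolved in the landscape's own 3-component space.
#'
#' Presets fix the effect structure:
#' \describe{
#'   \item{`breadth_gradient`}{species centroids pulled toward the warm,
#'     species-rich end of the gradient, with niche scale increasing away
#'     from it: richness peaks where niches are narrow, so the
#'     richness-breadth SAR slope is negative by construction.}
#'   \item{`neutral`}{niche scale independent of centroid position and a
#'     root at the middle of the available environment: no built-in
#'     richness-property relationship.}
#'   \item{`conserved_position`}{strong OU pull toward the warm-end root, so
#'     high-richness assemblages hold species near the ancestral niche
#'     (negative richness-position slope).}
#' }
#'
#' @param preset `"breadth_gradient"`, `"neutral"` or `"conserved_position"`.
#' @param master_seed integer; every stage seed is derived from it.
#' @param n_species number of species (default 60).
#' @param n_rows,n_cols fine-grid dimensions (default 300 x 300 km at 1 km,
#'   i.e. a 30 x 30 assemblage grid at the default 10 km cell).
#' @param n_points occurrence records drawn per species (default 60).
#' @param params named list overriding the preset's evolutionary settings:
#'   `alpha`, `sigma2` (OU pull and rate of centroid evolution),
#'   `breadth_slope` (log niche scale per component unit away from the
#'   richness peak; `breadth_gradient` only), `niche_base_sd`, `niche_sdlog`
#'   (typical axis standard deviation and its log-normal spread).
#' @return an object of class `niche_scenario`: `landscape` (bio-style
#'   stack), `pc_model`, `pc_stack`, `tree`, `true_niches`, `true_root`,
#'   `occurrences` (named list), `config`.
#' @export
make_scenario <- function(preset = c("breadth_gradient", "neutral",
                                     "conserved_position"),
                          master_seed = 1, n_species = 60,
                          n_rows = 300, n_cols = 300, n_points = 60,
                          params = list()) {
  preset <- match.arg(preset)
  config <- list(preset = preset, master_seed = master_seed,
                 n_species = n_species, n_rows = n_rows, n_cols = n_cols,
                 n_points = n_points, n_components = 3, params = params)

  defaults <- scenario_defaults(preset)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop_ns("unknown scenario parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(params)] <- params
  pp <- defaults

  base <- make_landscape(n_rows, n_cols, n_layers = 4,
                         gradient_strength = pp$gradient_strength,
                         autocorr_range_km = pp$autocorr_range_km,
                         seed = derive_seed(master_seed, 1))
  amp <- function(seed, scale, floor_v) {
    floor_v + scale * abs(with_seed(seed, gaussian_field(n_rows, n_cols,
                                                         pp$autocorr_range_km)))
  }
  bio1 <- base$layers$env1
  bio12 <- pmax(base$layers$env2, 0)
  layers <- list(
    bio1 = bio1,
    bio5 = bio1 + amp(derive_seed(master_seed, 21), 3, 4),
    bio6 = bio1 - amp(derive_seed(master_seed, 22), 4, 6),
    bio12 = bio12,
    bio13 = bio12 * 0.15 + amp(derive_seed(master_seed, 23), 20, 30),
    bio14 = pmax(bio12 * 0.02 - amp(derive_seed(master_seed, 24), 5, 0), 0),
    env3 = base$layers$env3,
    env4 = base$layers$env4
  )
  landscape <- climate_stack(layers, res_km = 1, origin = c(0, 0),
                             crs = "planar_km")

  pc_model <- fit_pca(landscape, n_components = config$n_components)
  pc_stack <- project_pca(pc_model, landscape)
  pcs <- stack_values(pc_stack)

  # warm-end reference: mean component vector of the warmest decile of cells
  warm <- pcs[bio_rank(landscape$layers$bio1) >= 0.9, , drop = FALSE]
  warm_root <- colMeans(warm)
  # realized gradient direction in component space: from the warm-end mean
  # toward the landscape-wide mean climate (the origin of the centered PCA)
  away_dir <- -warm_root / sqrt(sum(warm_root^2))

  root <- if (preset == "neutral") {
    colMeans(pcs[stats::complete.cases(pcs), , drop = FALSE])
  } else {
    warm_root
  }
  # niche scale grows away from the warm end along the realized gradient
  # direction (mirroring breadth tracking latitude), so richness peaks where
  # niches are narrow; the origin at the root keeps warm-end species at the
  # baseline scale
  breadth <- if (pp$breadth_slope != 0) {
    list(direction = away_dir, origin = warm_root, slope = pp$breadth_slope)
  } else {
    NULL
  }
  scen_pars <- list(root = root,
                    ou = list(alpha = pp$alpha, sigma2 = pp$sigma2),
                    breadth = breadth)

  tree <- simulate_tree(n_species, birth_rate = 1,
                        seed = derive_seed(master_seed, 2))
  niches <- simulate_niche_evolution(tree, scen_pars$root,
                                     ou_params = scen_pars$ou,
                                     breadth_model = scen_pars$breadth,
                                     seed = derive_seed(master_seed, 3),
                                     niche_sd = list(base = pp$niche_base_sd,
                                                     sdlog = pp$niche_sdlog))
  niches <- lapply(niches, ensure_suitable, pc_stack = pc_stack)

  occs <- lapply(seq_along(niches), function(i) {
    sample_occurrences(niches[[i]], pc_stack, n_points,
                       seed = derive_seed(master_seed, 4, i))
  })
  names(occs) <- names(niches)

  structure(
    list(landscape = landscape, pc_model = pc_model, pc_stack = pc_stack,
         tree = tree, true_niches = niches, true_root = scen_pars$root,
         occurrences = occs, config = config),
    class = "niche_scenario"
  )
}

scenario_defaults <- function(preset) {
  switch(
    preset,
    breadth_gradient = list(alpha = 1.5, sigma2 = 0.6, breadth_slope = 0.3,
                            niche_base_sd = 0.5, niche_sdlog = 0.1,
                            gradient_strength = 1, autocorr_range_km = 25),
    neutral = list(alpha = 0.75, sigma2 = 0.6, breadth_slope = 0,
                   niche_base_sd = 0.5, niche_sdlog = 0.25,
                   gradient_strength = 1, autocorr_range_km = 25),
    conserved_position = list(alpha = 4, sigma2 = 0.4, breadth_slope = 0,
                              niche_base_sd = 0.5, niche_sdlog = 0.25,
                              gradient_strength = 1, autocorr_range_km = 25)
  )
}

bio_rank <- function(m) {
  v <- as.vector(t(m))
  rank(v, ties.method = "average", na.last = "keep") / sum(!is.na(v))
}

# A simulated niche can miss the realized environments entirely; inflate its
# covariance (up to 8 doublings) until at least 5 landscape cells fall inside,
# so every species can be occupied and sampled.
ensure_suitable <- function(ell, pc_stack) {
  vals <- stack_values(pc_stack)
  ok <- stats::complete.cases(vals)
  for (i in 0:8) {
    d2 <- mahalanobis2(vals[ok, , drop = FALSE], ell)
    if (sum(d2 <= ell$radius2) >= 5) return(ell)
    ell <- ellipsoid(ell$centroid, ell$covariance * 2, ell$radius2,
                     species_id = ell$species_id)
  }
  stop_ns("could not make a suitable niche for ", ell$species_id)
}

#' @export
print.niche_scenario <- function(x, ...) {
  cat("<niche_scenario> preset ", x$config$preset, ", seed ",
      x$config$master_seed, "\n  ", x$config$n_species, " species, ",
      x$config$n_rows, " x ", x$config$n_cols, " km landscape, ",
      x$config$n_points, " records/species\n", sep = "")
  invisible(x)
}

#' Write a scenario bundle to disk
#'
#' Plain-text artifacts: the landscape stack (CSV + JSON), the Newick tree,
#' an occurrences CSV and a truth JSON (root, preset parameters, per-species
#' true ellipsoids).
#'
#' @param scen a [make_scenario()] object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scen$landscape, file.path(dir, "landscape"))
  ape::write.tree(scen$tree, file.path(dir, "tree.nwk"))
  write_occurrences(scen$occurrences, file.path(dir, "occurrences.csv"))
  write_ellipsoids(scen$true_niches, file.path(dir, "true_niches.json"))
  jsonlite::write_json(
    list(true_root = scen$true_root, config = scen$config),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
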