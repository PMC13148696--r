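#' Prune a phylogeny to a species set
#'
#' Induced subtree on the kept tips; degree-2 internal nodes are collapsed
#' with branch lengths summed (ape semantics), so root-to-tip path lengths
#' are preserved.
#'
#' @param tree an `ape::phylo` rooted tree with branch lengths.
#' @param keep character vector of tip labels to retain.
#' @return the pruned `phylo` tree.
#' @export
prune_to_species <- function(tree, keep) {
  keep <- intersect(keep, tree$tip.label)
  if (length(keep) == 0L) stop_ns("no requested species are in the tree")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Scaled trait covariance V0 (so that V = sigma2 * V0) for each model.
# C = shared root-to-MRCA path lengths (ape::vcv), depths = diag(C).
evo_cov <- function(model, C, par) {
  depths <- diag(C)
  switch(
    model,
    BM = C,
    OU = {
      a <- par
      # general (non-stationary-safe) OU covariance; reduces to
      # exp(-2a(T - t_ij)) (1 - exp(-2a t_ij)) / (2a) on ultrametric trees
      outer_d <- outer(depths, depths, "+") - 2 * C
      if (a < 1e-10) C else exp(-a * outer_d) * (1 - exp(-2 * a * C)) / (2 * a)
    },
    EB = {
      r <- par
      if (abs(r) < 1e-12) C else (exp(r * C) - 1) / r
    },
    trend = {
      # linear-in-time rate multiplier 1 + b t, integrated along shared paths
      b <- par
      C + b * C^2 / 2
    },
    stop_ns("unknown model: ", model)
  )
}

# Profile log-likelihood of z ~ N(m * 1, sigma2 * V0): the mean (root state,
# or the optimum for OU) and sigma2 are profiled out analytically.
profile_loglik <- function(z, V0) {
  n <- length(z)
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf))
  one <- rep(1, n)
  Li_one <- backsolve(L, one, transpose = TRUE)
  Li_z <- backsolve(L, z, transpose = TRUE)
  denom <- sum(Li_one^2)
  m <- sum(Li_one * Li_z) / denom
  r <- Li_z - m * Li_one
  s2 <- sum(r^2) / n
  if (s2 <= 0) return(list(loglik = -Inf))
  logdet <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(loglik = ll, mean = m, sigma2 = s2, mean_var_unit = 1 / denom)
}

#' Fit a continuous-trait evolutionary model by maximum likelihood
#'
#' Fits one of four models of trait evolution along a phylogeny: Brownian
#' motion (`BM`), single-optimum Ornstein-Uhlenbeck (`OU`), early burst
#' (`EB`, exponentially decaying rate) or a linear rate trend (`trend`, rate
#' proportional to `1 + b t`). Likelihood is the multivariate normal density
#' with the model-implied tip covariance; the rate `sigma2` and the mean
#' (root state; for OU the optimum `theta`) are profiled analytically, so
#' only the single shape parameter is optimized numerically, over a seeded
#' multi-start grid refined by golden-section search. Bounds: OU
#' `alpha in [1e-8, 50/T]`, EB `r in [-10/T, -1e-8]`, trend
#' `b in (-0.99/T, 10/T]`, with `T` the tree height.
#'
#' @param tree an `ape::phylo` tree with positive branch lengths.
#' @param trait named numeric vector of tip states (names = tip labels).
#' @param model one of `"BM"`, `"OU"`, `"EB"`, `"trend"`.
#' @param n_starts number of multi-start points for the shape parameter.
#' @param seed integer seed (start-point jitter).
#' @return an object of class `evo_fit`: `model`, `params` (named list incl.
#'   `sigma2` and `z0`), `logLik`, `k`, `AIC`, `at_bound` flag.
#' @export
fit_evo_model <- function(tree, trait, model = c("BM", "OU", "EB", "trend"),
                          n_starts = 10, seed = 1) {
  model <- match.arg(model)
  if (is.null(names(trait))) stop_ns("trait must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(trait))
  if (length(missing_tips) > 0L) {
    stop_ns("trait missing for tips: ", paste(missing_tips, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop_ns("negative branch lengths")
  z <- trait[tree$tip.label]
  C <- ape::vcv(tree)
  Tht <- max(diag(C))
  if (model == "OU" && !ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("tree is not ultrametric; using the general OU covariance",
            call. = FALSE)
  }

  if (model == "BM") {
    pf <- profile_loglik(z, C)
    if (!is.finite(pf$loglik)) stop_ns("non-finite likelihood under BM")
    k <- 2
    fit <- list(model = "BM",
                params = list(sigma2 = pf$sigma2, z0 = pf$mean),
                logLik = pf$loglik, k = k, AIC = 2 * k - 2 * pf$loglik,
                at_bound = FALSE, shape_par = NULL, tree_height = Tht)
    class(fit) <- "evo_fit"
    return(fit)
  }

  bounds <- switch(model,
                   OU = c(1e-8, 50 / Tht),
                   EB = c(-10 / Tht, -1e-8),
                   trend = c(-0.99 / Tht, 10 / Tht))
  obj <- function(p) {
    ll <- profile_loglik(z, evo_cov(model, C, p))$loglik
    if (!is.finite(ll)) -1e10 else ll
  }
  # seeded multi-start: jittered grid over the feasible interval
  starts <- with_seed(seed, {
    g <- seq(bounds[1], bounds[2], length.out = n_starts)
    jit <- stats::runif(n_starts, -0.5, 0.5) * diff(bounds) / (2 * n_starts)
    pmin(pmax(g + jit, bounds[1]), bounds[2])
  })
  vals <- vapply(starts, obj, numeric(1))
  best_start <- starts[which.max(vals)]
  span <- diff(bounds) / (n_starts - 1)
  lo <- max(bounds[1], best_start - span)
  hi <- min(bounds[2], best_start + span)
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-9)
  p_hat <- opt$maximum
  if (obj(bounds[2]) > opt$objective) p_hat <- bounds[2]
  if (obj(bounds[1]) > opt$objective && obj(bounds[1]) >= obj(p_hat)) {
    p_hat <- bounds[1]
  }
  pf <- profile_loglik(z, evo_cov(model, C, p_hat))
  if (!is.finite(pf$loglik)) stop_ns("non-finite likelihood under ", model)
  at_bound <- min(abs(p_hat - bounds)) < 1e-6 * diff(bounds)
  if (model == "OU" && abs(p_hat - bounds[2]) < 1e-6 * diff(bounds)) {
    warning("OU alpha estimate is at its upper bound", call. = FALSE)
  }
  k <- 3
  params <- switch(model,
                   OU = list(sigma2 = pf$sigma2, alpha = p_hat,
                             theta = pf$mean, z0 = pf$mean),
                   EB = list(sigma2 = pf$sigma2, r = p_hat, z0 = pf$mean),
                   trend = list(sigma2 = pf$sigma2, b = p_hat, z0 = pf$mean))
  fit <- list(model = model, params = params, logLik = pf$loglik, k = k,
              AIC = 2 * k - 2 * pf$loglik, at_bound = at_bound,
              shape_par = p_hat, tree_height = Tht)
  class(fit) <- "evo_fit"
  fit
}

#' @export
print.evo_fit <- function(x, ...) {
  cat("<evo_fit> ", x$model, ": logLik = ", format(x$logLik, digits = 6),
      ", AIC = ", format(x$AIC, digits = 6), "\n  params: ",
      paste(names(x$params), format(unlist(x$params), digits = 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select among fitted evolutionary models by AIC
#'
#' Akaike weights `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)` with
#' `D_i = AIC_i - min AIC`; the best model is the AIC minimizer, ties broken
#' by fewest parameters.
#'
#' @param fits list of [fit_evo_model()] fits of the same trait.
#' @return list with `best` (an `evo_fit`), `weights` (named numeric) and an
#'   AIC `table` data frame sorted ascending.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop_ns("need at least two fits to compare")
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  models <- vapply(fits, function(f) f$model, character(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aic, k)
  best <- fits[[ord[1]]]
  tab <- data.frame(model = models, k = k, logLik =
                      vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = aic, delta_AIC = delta, weight = w)[ord, ]
  rownames(tab) <- NULL
  list(best = best, weights = stats::setNames(w, models), table = tab)
}

#' Reconstruct the root (ancestral) state under a fitted model
#'
#' Generalized-least-squares estimate of the root state under the fitted tip
#' covariance: `z0_hat = (1' V^-1 1)^-1 1' V^-1 z`, with standard error
#' `sqrt((1' V^-1 1)^-1)`.
#'
#' @param tree the tree the fit was made on.
#' @param trait named numeric tip states.
#' @param fit the selected [fit_evo_model()] fit for this trait.
#' @return an object of class `recon_result`: `ancestral_state`, `se`,
#'   `model_used`.
#' @export
reconstruct_root <- function(tree, trait, fit) {
  z <- trait[tree$tip.label]
  C <- ape::vcv(tree)
  V0 <- if (fit$model == "BM") C else evo_cov(fit$model, C, fit$shape_par)
  pf <- profile_loglik(z, V0)
  if (!is.finite(pf$loglik)) stop_ns("singular covariance in reconstruction")
  structure(
    list(ancestral_state = pf$mean,
         se = sqrt(fit$params$sigma2 * pf$mean_var_unit),
         model_used = fit$model),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> root = ", format(x$ancestral_state, digits = 6),
      " (se ", format(x$se, digits = 4), ", model ", x$model_used, ")\n",
      sep = "")
  invisible(x)
}

#' Phylogenetic niche position of one species
#'
#' Distance from the species' current niche centroid to the reconstructed
#' ancestral centroid: Mahalanobis through the species' ellipsoid covariance
#' for the multivariate approach, absolute (Euclidean) difference per
#' dimension for the univariate one.
#'
#' @param species_centroid numeric d-vector (or scalar for univariate).
#' @param ancestral numeric d-vector (or scalar) of ancestral states.
#' @param metric `"mahalanobis"` or `"euclidean"`.
#' @param ell the species' [ellipsoid()]; required for `"mahalanobis"`.
#' @return non-negative scalar distance.
#' @export
phylo_position <- function(species_centroid, ancestral,
                           metric = c("mahalanobis", "euclidean"),
                           ell = NULL) {
  metric <- match.arg(metric)
  if (length(species_centroid) != length(ancestral)) {
    stop_ns("centroid/ancestral dimension mismatch")
  }
  if (metric == "mahalanobis") {
    if (is.null(ell)) stop_ns("mahalanobis metric requires an ellipsoid")
    diff <- species_centroid - ancestral
    shifted <- ell$centroid - diff  # reuse the shared Mahalanobis kernel
    return(sqrt(as.numeric(mahalanobis2(shifted, ell))))
  }
  if (!is.null(ell)) stop_ns("euclidean metric does not take an ellipsoid")
  sqrt(sum((species_centroid - ancestral)^2))
}
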