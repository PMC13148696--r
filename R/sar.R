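#' Simultaneous autoregressive (spatial error) model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma2 I)` by
#' maximum likelihood. The log-likelihood is concentrated over `lambda`
#' (profiling `beta` and `sigma2` through the spatially filtered regression
#' `(I - lambda W) y ~ (I - lambda W) X`), with the log-determinant
#' `log|I - lambda W| = sum log(1 - lambda e_i)` evaluated from the real
#' eigenvalues of `W`. A grid search over the feasible interval
#' `(1/min(e), 1/max(e))` is refined by golden-section search. Coefficient
#' standard errors are the GLS asymptotics conditional on `lambda_hat`.
#'
#' @param y numeric response per cell (e.g. richness).
#' @param X numeric predictor matrix (no intercept column; one is added) with
#'   column names, or a data frame.
#' @param w a [build_weights()] object matching `y`.
#' @return an object of class `sar_fit`: `coefficients` data frame
#'   (`estimate`, `se`, `z`, `p`), `lambda`, `sigma2`, `logLik`, `k`, `AIC`,
#'   `residuals` (spatially filtered innovations) and `response_residuals`.
#' @export
fit_sar_error <- function(y, X, w) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X) || length(y) != w$n) {
    stop_ns("y, X and weights disagree on the number of cells")
  }
  if (anyNA(y) || anyNA(X)) stop_ns("missing values in y or X")
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) stop_ns("predictor matrix is rank deficient")
  n <- length(y)
  ev <- w$eigenvalues
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  eps <- 1e-6
  lo <- max(lo, -1e3) + eps * max(1, abs(lo))
  hi <- min(hi, 1e3) - eps * max(1, abs(hi))

  Wy <- w$W %*% y
  WX <- w$W %*% Xi
  conc <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- Xi - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    s2 <- sum(fit$residuals^2) / n
    if (s2 <= 0) return(-Inf)
    logdet <- sum(log1p(-lambda * ev))
    -n / 2 * (log(2 * pi * s2) + 1) + logdet
  }
  grid <- seq(lo, hi, length.out = 60)
  vals <- vapply(grid, conc, numeric(1))
  if (!any(is.finite(vals))) stop_ns("SAR likelihood is non-finite everywhere")
  b <- which.max(vals)
  bracket <- c(grid[max(1, b - 1)], grid[min(length(grid), b + 1)])
  opt <- stats::optimize(conc, bracket, maximum = TRUE, tol = 1e-10)
  lambda <- opt$maximum
  if (conc(0) > opt$objective) lambda <- 0  # guard: never do worse than OLS

  ys <- y - lambda * Wy
  Xs <- Xi - lambda * WX
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  res_eps <- fit$residuals
  s2 <- sum(res_eps^2) / n
  ll <- conc(lambda)
  XtX <- crossprod(Xs)
  vcov_beta <- s2 * solve(XtX)
  se <- sqrt(diag(vcov_beta))
  zstat <- beta / se
  p <- 2 * stats::pnorm(-abs(zstat))
  k <- ncol(Xi) + 2  # beta, sigma2, lambda
  structure(
    list(coefficients = data.frame(term = colnames(Xi), estimate = unname(beta),
                                   se = unname(se), z = unname(zstat),
                                   p = unname(p), stringsAsFactors = FALSE),
         lambda = lambda, sigma2 = s2, logLik = ll, k = k,
         AIC = 2 * k - 2 * ll,
         residuals = as.numeric(res_eps),
         response_residuals = as.numeric(y - Xi %*% beta),
         n = n, weights_scheme = w$scheme,
         weights_distance_class = w$distance_class),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("<sar_fit> n = ", x$n, ", lambda = ", format(x$lambda, digits = 4),
      ", AIC = ", format(x$AIC, digits = 6), " [", x$weights_scheme, "/",
      x$weights_distance_class, "]\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Coefficient (slope) of one predictor from a SAR fit
#'
#' @param fit a [fit_sar_error()] fit.
#' @param term predictor name.
#' @return the estimate.
#' @export
sar_slope <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop_ns("no such term: ", term)
  fit$coefficients$estimate[i]
}

#' Fit a SAR model under several candidate weights and select by AIC
#'
#' @param y,X as in [fit_sar_error()].
#' @param weights_list list of [build_weights()] candidates (e.g. three
#'   schemes x two distance classes).
#' @return list with `best` (the minimum-AIC [fit_sar_error()]), `fits`
#'   (all successful fits) and `table` (AIC table sorted ascending).
#' @export
select_sar <- function(y, X, weights_list) {
  if (length(weights_list) == 0L) stop_ns("no candidate weights")
  fits <- list()
  rows <- list()
  for (i in seq_along(weights_list)) {
    w <- weights_list[[i]]
    f <- tryCatch(fit_sar_error(y, X, w), error = function(e) e)
    label <- paste0(w$scheme, "/", w$distance_class)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(weights = label, AIC = NA_real_,
                              logLik = NA_real_, lambda = NA_real_,
                              error = conditionMessage(f))
    } else {
      fits[[label]] <- f
      rows[[i]] <- data.frame(weights = label, AIC = f$AIC, logLik = f$logLik,
                              lambda = f$lambda, error = "")
    }
  }
  if (length(fits) == 0L) stop_ns("all SAR fits failed")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  list(best = fits[[tab$weights[1]]], fits = fits, table = tab)
}

#' Split predictors into models free of strong cross-correlation
#'
#' Computes pairwise Spearman correlations among the per-cell predictor
#' columns and returns a small set of models such that no model contains a
#' pair with `|rho| > cutoff`. Conflicting predictors are separated by greedy
#' graph coloring (input order), and every model is then extended with all
#' remaining predictors that conflict with none of its members, so
#' uncorrelated predictors appear in every model.
#'
#' @param props per-cell predictor matrix or data frame with column names.
#' @param cutoff correlation magnitude threshold (default 0.7).
#' @return list of character vectors, one per model; attribute `"rho"` holds
#'   the Spearman correlation matrix.
#' @export
screen_predictors <- function(props, cutoff = 0.7) {
  props <- as.matrix(props)
  p <- ncol(props)
  if (p < 2) stop_ns("need at least two predictors")
  nms <- colnames(props)
  rho <- stats::cor(props, method = "spearman",
                    use = "pairwise.complete.obs")
  conflict <- abs(rho) > cutoff
  diag(conflict) <- FALSE
  color <- rep(NA_integer_, p)
  for (i in seq_len(p)) {
    used <- color[conflict[i, ] & !is.na(color)]
    color[i] <- setdiff(seq_len(p), used)[1]
  }
  models <- lapply(sort(unique(color)), function(k) which(color == k))
  # extend each model with non-conflicting leftovers, deterministic order
  models <- lapply(models, function(members) {
    for (i in seq_len(p)) {
      if (!(i %in% members) && !any(conflict[i, members])) {
        members <- c(members, i)
      }
    }
    nms[sort(members)]
  })
  models <- unique(models)
  attr(models, "rho") <- rho
  models
}
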