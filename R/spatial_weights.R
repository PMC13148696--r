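#' Spatial weights from cell centroids
#'
#' Distance-band neighbors scaled by one of three schemes: `"W"` (row
#' standardized: each nonzero row sums to 1), `"C"` (globally standardized:
#' `w_ij = n b_ij / S0`), `"S"` (variance stabilizing: each row scaled by its
#' L2 norm, then globally rescaled so the weights sum to n). Two distance
#' classes are offered: `"min"` uses the largest first-nearest-neighbor
#' distance as the band (the smallest band that guarantees no island),
#' `"max"` twice that value; an explicit `threshold_km` overrides both.
#'
#' @param centroids n x 2 matrix of planar cell coordinates (km).
#' @param scheme `"W"`, `"C"` or `"S"`.
#' @param distance_class `"min"` or `"max"`.
#' @param threshold_km optional explicit neighbor distance band.
#' @return an object of class `spatial_weights`: dense matrix `W`, `scheme`,
#'   `distance_class`, `threshold_km`, `n`, `S0`, and the real `eigenvalues`
#'   of `W` (computed through a symmetric similarity transform, used for the
#'   SAR log-determinant).
#' @export
build_weights <- function(centroids, scheme = c("W", "C", "S"),
                          distance_class = c("min", "max"),
                          threshold_km = NULL) {
  scheme <- match.arg(scheme)
  distance_class <- match.arg(distance_class)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop_ns("need at least two cells")
  dm <- as.matrix(stats::dist(centroids))
  dimnames(dm) <- NULL
  diag(dm) <- Inf
  explicit <- !is.null(threshold_km)
  if (!explicit) {
    nn <- apply(dm, 1, min)
    base <- max(nn)
    threshold_km <- if (distance_class == "min") base else 2 * base
  }
  # small tolerance so lattice neighbors at exactly the band are kept
  B <- (dm <= threshold_km * (1 + 1e-9)) * 1
  deg <- rowSums(B)
  if (any(deg == 0)) {
    if (explicit) {
      stop_ns("isolated cell(s) under threshold ", threshold_km, " km: ",
              paste(utils::head(which(deg == 0), 10), collapse = ", "))
    }
    stop_ns("internal error: island despite max-NN threshold")
  }
  S0_b <- sum(B)
  if (scheme == "W") {
    scale_row <- 1 / deg
    W <- B * scale_row
  } else if (scheme == "C") {
    scale_row <- rep(n / S0_b, n)
    W <- B * (n / S0_b)
  } else {
    q <- sqrt(rowSums(B^2))
    Wr <- B / q
    g <- n / sum(Wr)
    scale_row <- g / q
    W <- Wr * g
  }
  # W = diag(scale_row) %*% B with symmetric B, so W is similar to the
  # symmetric matrix D^{1/2} B D^{1/2} (D = diag(scale_row)): eigenvalues are
  # real and cheap to compute symmetrically.
  rs <- sqrt(scale_row)
  M <- B * outer(rs, rs)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(W = W, scheme = scheme, distance_class = distance_class,
         threshold_km = threshold_km, n = n, S0 = sum(W),
         eigenvalues = ev, centroids = centroids),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> n = ", x$n, ", scheme ", x$scheme, ", ",
      x$distance_class, " distance class (", format(x$threshold_km,
                                                    digits = 5),
      " km)\n  links: ", sum(x$W > 0), ", S0 = ", format(x$S0, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Moran's I with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`;
#' expectation under no autocorrelation is `-1/(n-1)`. The p-value comes from
#' seeded random permutations of `x` with the add-one rule, two-sided on the
#' deviation from the permutation mean.
#'
#' @param x per-cell numeric vector.
#' @param w a [build_weights()] object.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `I`, `expectation`, `p`, `n_perm`.
#' @export
morans_i <- function(x, w, n_perm = 999, seed = 1) {
  if (length(x) != w$n) stop_ns("x length does not match weights")
  if (stats::var(x) == 0) stop_ns("x is constant")
  z <- x - mean(x)
  denom <- sum(z^2)
  i_of <- function(zz) (w$n / w$S0) * sum(zz * (w$W %*% zz)) / sum(zz^2)
  I_obs <- i_of(z)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) i_of(z[sample.int(w$n)]), numeric(1))
  })
  center <- mean(perm)
  p <- (1 + sum(abs(perm - center) >= abs(I_obs - center))) / (n_perm + 1)
  list(I = I_obs, expectation = -1 / (w$n - 1), p = p, n_perm = n_perm)
}

#' Write spatial weights as sparse triplets + metadata
#'
#' @param w a [build_weights()] object.
#' @param path CSV path for the `(i, j, w)` triplets; a `.json` sidecar holds
#'   the metadata.
#' @return the path, invisibly.
#' @export
write_weights <- function(w, path) {
  idx <- which(w$W > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], w = w$W[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = w$n, scheme = w$scheme, distance_class = w$distance_class,
         threshold_km = w$threshold_km, S0 = w$S0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
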