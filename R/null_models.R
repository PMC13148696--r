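#' Spreading-dye cohesive random range
#'
#' Grows a random cohesive range inside a domain: a seed cell is drawn
#' uniformly, then unoccupied domain neighbors of the occupied set (the
#' frontier) are added one at a time, each drawn uniformly from the current
#' frontier, until the target range size is reached. Adjacency is rook
#' (4-neighbor) by default; queen (8-neighbor) is available. If the frontier
#' empties before the target (a disconnected pocket), growth restarts from a
#' fresh seed cell, up to 100 restarts.
#'
#' @param domain logical matrix: `TRUE` cells belong to the domain.
#' @param range_size number of cells to occupy (1..`sum(domain)`).
#' @param seed integer seed.
#' @param adjacency `"rook"` (default) or `"queen"`.
#' @return integer vector of occupied cell indices (row-major over the
#'   domain grid, rows varying slowest).
#' @export
spreading_dye <- function(domain, range_size, seed, adjacency = c("rook", "queen")) {
  adjacency <- match.arg(adjacency)
  if (!is.matrix(domain) || !is.logical(domain)) {
    stop_ns("domain must be a logical matrix")
  }
  nr <- nrow(domain); nc <- ncol(domain)
  dom_v <- as.vector(t(domain))
  n_dom <- sum(dom_v)
  if (range_size < 1 || range_size > n_dom) {
    stop_ns("range_size must be in 1..", n_dom)
  }
  dom_cells <- which(dom_v)

  offsets <- if (adjacency == "rook") {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(c(-1L, 0L, 1L), each = 3)[-5],
          dc = rep(c(-1L, 0L, 1L), times = 3)[-5])
  }
  neighbors <- function(cell) {
    r <- (cell - 1L) %/% nc + 1L
    c <- (cell - 1L) %% nc + 1L
    rr <- r + offsets[, 1]; cc <- c + offsets[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    cells <- (rr[ok] - 1L) * nc + cc[ok]
    cells[dom_v[cells]]
  }

  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      occupied <- logical(nr * nc)
      start <- dom_cells[sample.int(n_dom, 1)]
      occupied[start] <- TRUE
      n_occ <- 1L
      # frontier as a vector with O(1) add/remove via a position index
      frontier <- integer(0)
      in_frontier <- integer(nr * nc)  # 0 = absent, else position in frontier
      push <- function(cell) {
        if (!occupied[cell] && in_frontier[cell] == 0L) {
          frontier[length(frontier) + 1L] <<- cell
          in_frontier[cell] <<- length(frontier)
        }
      }
      pop_at <- function(pos) {
        cell <- frontier[pos]
        last <- frontier[length(frontier)]
        frontier[pos] <<- last
        in_frontier[last] <<- pos
        frontier <<- frontier[-length(frontier)]
        in_frontier[cell] <<- 0L
        cell
      }
      for (nb in neighbors(start)) push(nb)
      failed <- FALSE
      while (n_occ < range_size) {
        if (length(frontier) == 0L) {
          failed <- TRUE
          break
        }
        cell <- pop_at(sample.int(length(frontier), 1))
        occupied[cell] <- TRUE
        n_occ <- n_occ + 1L
        for (nb in neighbors(cell)) push(nb)
      }
      if (!failed) return(which(occupied))
    }
    stop_ns("spreading dye could not reach range_size ", range_size,
            " after 100 restarts (disconnected domain pocket?)")
  })
}

#' Geometric-constraint null PAM
#'
#' Replaces every species' cell set by a spreading-dye random range of the
#' same size inside the analysis domain, keeping the species count and all
#' range sizes fixed while randomizing their positions.
#'
#' @param pam an observed [build_pam()] object.
#' @param seed integer seed (per-species streams are derived from it).
#' @param adjacency passed to [spreading_dye()].
#' @return a `pam` with the same species and column sums.
#' @export
random_pam <- function(pam, seed, adjacency = "rook") {
  dom <- matrix(pam$domain, nrow = pam$dims[1], ncol = pam$dims[2],
                byrow = TRUE)
  sizes <- colSums(pam$matrix)
  out <- pam
  m <- matrix(0L, nrow(pam$matrix), ncol(pam$matrix),
              dimnames = dimnames(pam$matrix))
  for (k in seq_along(sizes)) {
    if (sizes[k] == 0L) next
    cells <- spreading_dye(dom, sizes[k], seed = derive_seed(seed, k),
                           adjacency = adjacency)
    m[cells, k] <- 1L
  }
  out$matrix <- m
  out
}

#' Shuffle a species-level property among species
#'
#' Uniform random permutation of the property values over species: each
#' species keeps its range but receives another species' property value, so
#' the value multiset is exactly conserved.
#'
#' @param prop named numeric vector (names = species ids).
#' @param seed integer seed.
#' @return named numeric vector with permuted values.
#' @export
shuffle_properties <- function(prop, seed) {
  n <- length(prop)
  perm <- with_seed(seed, sample.int(n))
  stats::setNames(unname(prop)[perm], names(prop))
}

#' Null distribution of SAR slopes
#'
#' Re-runs the assemblage stage of the pipeline under one of two nulls and
#' refits the observed SAR specification each time, recording the slope of
#' every predictor. `"spreading_dye"` regenerates the PAM with cohesive
#' random ranges (richness and all property maps change); `"property_shuffle"`
#' keeps the PAM but permutes whole species rows of the property table (the
#' per-species property multiset, and richness, are conserved). Replicate
#' failures are recorded as missing; more than 20% failures is an error.
#' The observed best weight scheme is reused for every refit.
#'
#' @param pam observed [build_pam()].
#' @param prop_table observed [assemble_property_table()] table.
#' @param predictors character vector of property columns in the SAR model.
#' @param w the observed best [build_weights()] object (built on the occupied
#'   cells used for the observed fit).
#' @param null_type `"spreading_dye"` or `"property_shuffle"`.
#' @param n_reps number of replicates (default 100).
#' @param master_seed integer; per-replicate seeds are derived from it.
#' @param adjacency passed to [spreading_dye()].
#' @return an object of class `null_ensemble`: `slopes` (reps x predictors),
#'   `seeds`, `null_type`, `n_failures`.
#' @export
null_slope_distribution <- function(pam, prop_table, predictors, w,
                                    null_type = c("spreading_dye",
                                                  "property_shuffle"),
                                    n_reps = 100, master_seed = 1,
                                    adjacency = "rook") {
  null_type <- match.arg(null_type)
  cells <- attr(w, "cells") %||% which(richness(pam) > 0)
  if (length(cells) != w$n) {
    stop_ns("weights were not built on the observed occupied cells")
  }
  seeds <- vapply(seq_len(n_reps), function(i) derive_seed(master_seed, 977, i),
                  integer(1))
  slopes <- matrix(NA_real_, n_reps, length(predictors),
                   dimnames = list(NULL, predictors))
  n_fail <- 0L
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      if (null_type == "spreading_dye") {
        pam_i <- random_pam(pam, seed = seeds[i], adjacency = adjacency)
        tab_i <- prop_table
      } else {
        pam_i <- pam
        perm <- with_seed(seeds[i], sample.int(nrow(prop_table)))
        tab_i <- prop_table
        tab_i[setdiff(names(tab_i), "species")] <-
          prop_table[perm, setdiff(names(prop_table), "species")]
      }
      fit_null_sar(pam_i, tab_i, predictors, w, cells)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      warning("null replicate ", i, " failed", call. = FALSE)
    } else {
      slopes[i, ] <- res
    }
  }
  if (n_fail > 0.2 * n_reps) {
    stop_ns(n_fail, " of ", n_reps, " null replicates failed")
  }
  structure(
    list(null_type = null_type, n_reps = n_reps, slopes = slopes,
         seeds = seeds, n_failures = n_fail),
    class = "null_ensemble"
  )
}

# Refit the SAR specification on a (possibly null) PAM + property table over
# the fixed modelling cells the observed weights were built on. A null
# replicate occasionally leaves a few of those cells empty; such cells keep
# their true replicate richness (0) and take the species-mean property (the
# expected assemblage mean under random membership) so the single shared
# weight matrix, and its eigenvalues, can be reused across all replicates.
fit_null_sar <- function(pam, tab, predictors, w, cells) {
  rich <- richness(pam)
  maps <- vapply(predictors,
                 function(pr) map_property(pam, property_vector(tab, pr)),
                 numeric(nrow(pam$matrix)))
  if (length(predictors) == 1L) maps <- matrix(maps, ncol = 1,
                                               dimnames = list(NULL, predictors))
  y <- rich[cells]
  X <- maps[cells, , drop = FALSE]
  for (j in seq_len(ncol(X))) {
    empty <- is.na(X[, j])
    if (any(empty)) X[empty, j] <- mean(tab[[predictors[j]]], na.rm = TRUE)
  }
  f <- fit_sar_error(y, X, w)
  vapply(predictors, function(pr) sar_slope(f, pr), numeric(1))
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", x$null_type, ", ", x$n_reps, " replicates (",
      x$n_failures, " failed)\n", sep = "")
  cat("  mean |slope|: ",
      paste(colnames(x$slopes),
            format(colMeans(abs(x$slopes), na.rm = TRUE), digits = 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Two-sided slope test against a null ensemble
#'
#' `p = (1 + #{|slope_null| >= |slope_obs|}) / (n + 1)` over the non-missing
#' replicates (the add-one permutation rule); small p means the observed
#' slope magnitude is not reproduced by the null.
#'
#' @param observed_slope observed SAR slope for one predictor.
#' @param ensemble a [null_slope_distribution()] ensemble.
#' @param predictor predictor name.
#' @return p-value in (0, 1].
#' @export
null_slope_test <- function(observed_slope, ensemble, predictor) {
  s <- ensemble$slopes[, predictor]
  s <- s[!is.na(s)]
  if (length(s) == 0L) stop_ns("ensemble has no successful replicates")
  if (length(unique(s)) < 2L) {
    warning("degenerate null ensemble (all slopes equal)", call. = FALSE)
  }
  (1 + sum(abs(s) >= abs(observed_slope))) / (length(s) + 1)
}
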