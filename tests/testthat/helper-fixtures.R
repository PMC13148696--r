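# Small deterministic fixtures shared across test files.

# stack with hand-chosen layers on an n x n unit grid
toy_stack <- function(n = 10, layers = NULL) {
  if (is.null(layers)) {
    layers <- list(
      a = matrix(seq_len(n * n), n, n),
      b = matrix(rev(seq_len(n * n)), n, n) / 7,
      c = outer(seq_len(n), seq_len(n), function(r, c) sin(r) + c)
    )
  }
  climate_stack(layers, res_km = 1, origin = c(0, 0))
}

# random multi-layer stack (seeded), optionally with a nodata blob
random_stack <- function(n = 12, k = 4, seed = 1, nodata = FALSE) {
  layers <- with_seed_test(seed, {
    out <- lapply(seq_len(k), function(i) matrix(rnorm(n * n), n, n))
    names(out) <- paste0("L", seq_len(k))
    out
  })
  if (nodata) {
    for (i in seq_along(layers)) layers[[i]][1:3, 1:2] <- NA
  }
  climate_stack(layers, res_km = 1, origin = c(0, 0))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# independent ray-casting point-in-polygon (even-odd rule), used as an oracle
# against the package's containment test; boundary behaviour may differ so
# oracle comparisons use interior points only.
raycast_inside <- function(ring, x, y) {
  n <- nrow(ring)
  vapply(seq_along(x), function(i) {
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      xi <- ring[k, 1]; yi <- ring[k, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y[i]) != (yj > y[i]) &&
          x[i] < (xj - xi) * (y[i] - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

# independent Felsenstein pruning log-likelihood for BM with given root state
# profiled out analytically afterwards is avoided: this returns the ML value
# over (z0, sigma2) by an inner optimization on the contrast decomposition.
bm_loglik_pruning <- function(tree, trait) {
  # postorder pruning: returns the exact BM log-likelihood maximized over
  # sigma2 and z0 using the standard conditional-normal elimination
  ll_given <- function(sigma2, z0) {
    tr <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tr$tip.label)
    x <- numeric(ntip + tr$Nnode)
    v <- numeric(ntip + tr$Nnode)  # extra variance accumulated at each node
    x[seq_len(ntip)] <- trait[tr$tip.label]
    ll <- 0
    children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
    # ape numbers internal nodes root-first, so descending order is postorder
    for (node in sort(as.integer(names(children)), decreasing = TRUE)) {
      kids <- children[[as.character(node)]]
      xs <- x[tr$edge[kids, 2]]
      vs <- v[tr$edge[kids, 2]] + tr$edge.length[kids] * sigma2
      # combine children pairwise (works for multifurcations too)
      cx <- xs[1]; cv <- vs[1]
      if (length(xs) > 1) {
        for (m in 2:length(xs)) {
          ll <- ll + dnorm(xs[m], cx, sqrt(cv + vs[m]), log = TRUE)
          new_v <- 1 / (1 / cv + 1 / vs[m])
          cx <- new_v * (cx / cv + xs[m] / vs[m])
          cv <- new_v
        }
      }
      x[node] <- cx
      v[node] <- cv
    }
    root <- ntip + 1
    ll + dnorm(x[root], z0, sqrt(v[root]), log = TRUE)
  }
  obj <- function(par) -ll_given(exp(par[1]), par[2])
  o <- optim(c(0, mean(trait)), obj, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  -o$value
}

# quick scenario small enough for unit tests
tiny_scenario <- function(seed = 11, preset = "breadth_gradient") {
  make_scenario(preset, master_seed = seed, n_species = 12,
                n_rows = 80, n_cols = 80, n_points = 25)
}

flood_fill_connected <- function(cells, nr, nc, queen = FALSE) {
  # oracle: is the cell set rook-connected (row-major indices)?
  if (length(cells) <= 1) return(TRUE)
  inset <- logical(nr * nc)
  inset[cells] <- TRUE
  seen <- logical(nr * nc)
  stack <- cells[1]
  seen[cells[1]] <- TRUE
  offs <- if (queen) expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- (cur - 1) %/% nc + 1; c <- (cur - 1) %% nc + 1
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        nb <- (rr - 1) * nc + cc
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
  }
  all(seen[cells])
}

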