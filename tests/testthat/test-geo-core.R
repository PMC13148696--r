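test_that("layer exclusion preserves order and validates names", {
  layers <- lapply(1:19, function(i) matrix(i + 0, 5, 5))
  names(layers) <- paste0("bio", 1:19)
  st <- climate_stack(layers)
  kept <- drop_excluded_layers(st, c("bio8", "bio9", "bio18", "bio19"))
  expect_length(kept$layers, 15)
  expect_identical(names(kept$layers),
                   setdiff(paste0("bio", 1:19),
                           c("bio8", "bio9", "bio18", "bio19")))
  expect_identical(drop_excluded_layers(st, character(0)), st)
  expect_error(drop_excluded_layers(st, "bio99"), "bio99")
})

test_that("stack construction enforces shared geometry and nodata", {
  expect_error(climate_stack(list(a = matrix(0, 3, 3), b = matrix(0, 4, 3))),
               "dimensions")
  m1 <- matrix(1, 3, 3); m2 <- matrix(2, 3, 3); m2[1, 1] <- NA
  expect_error(climate_stack(list(a = m1, b = m2)), "nodata")
  expect_error(climate_stack(list(matrix(0, 2, 2))), "names")
})

test_that("masking keeps geometry and matches a brute-force oracle", {
  st <- toy_stack(10)
  full <- rectangle_polygon(-1, 11, -1, 11)
  expect_equal(mask_to_area(st, full)$layers, st$layers)

  left <- rectangle_polygon(-1, 5, -1, 11)  # covers columns with centers < 5
  masked <- mask_to_area(st, left)
  expect_identical(nichescape:::stack_dim(masked), nichescape:::stack_dim(st))
  expect_equal(sum(!is.na(masked$layers$a)), 50)

  with_seed_test(42, {
    for (i in 1:5) {
      ring <- cbind(runif(6, 0, 10), runif(6, 0, 10))
      ring <- ring[grDevices::chull(ring), , drop = FALSE]
      poly <- area_polygon(ring)
      cc <- cell_centers(st)
      oracle <- raycast_inside(ring, cc$x, cc$y)
      if (!any(oracle)) next
      masked <- mask_to_area(st, poly)
      got <- !is.na(as.vector(t(masked$layers$a)))
      # boundary cells may differ between implementations; interior must match
      on_boundary <- polygon_contains(poly, cc$x, cc$y) != oracle
      expect_lte(sum(on_boundary), 1)
      expect_equal(got[!on_boundary], oracle[!on_boundary])
    }
  })
  expect_error(mask_to_area(st, rectangle_polygon(50, 60, 50, 60)),
               "does not overlap")
})

test_that("PCA matches an independent eigendecomposition and is sign-fixed", {
  st <- random_stack(15, 5, seed = 7)
  pm <- fit_pca(st, 5)
  vals <- nichescape:::stack_values(st)
  ev_oracle <- eigen(cor(vals), symmetric = TRUE)$values
  expect_equal(pm$explained_variance_fraction, ev_oracle / sum(ev_oracle),
               tolerance = 1e-10)
  expect_equal(sum(pm$explained_variance_fraction), 1, tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(pm$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-|loading| entry positive
  for (k in 1:5) {
    expect_gt(pm$loadings[which.max(abs(pm$loadings[, k])), k], 0)
  }
  # a correlated pair + an independent layer: the leading component is
  # carried by the pair with (near) equal loadings, the independent layer
  # dominates its own component
  n <- 20
  g <- with_seed_test(3, {
    sig <- matrix(rnorm(n * n), n, n)
    list(x = sig + matrix(rnorm(n * n, sd = 0.1), n, n),
         y = -2 * sig + matrix(rnorm(n * n, sd = 0.1), n, n),
         z = matrix(rnorm(n * n), n, n))
  })
  pm2 <- fit_pca(climate_stack(g), 3)
  expect_equal(abs(pm2$loadings["x", 1]), abs(pm2$loadings["y", 1]),
               tolerance = 0.05)
  expect_lt(abs(pm2$loadings["z", 1]), 0.15)
  expect_gt(abs(pm2$loadings["z", 2]), 0.95)
})

test_that("PCA scores are centered, uncorrelated, and match manual projection", {
  st <- random_stack(12, 4, seed = 5, nodata = TRUE)
  pm <- fit_pca(st, 3)
  pcs <- project_pca(pm, st)
  sc <- nichescape:::stack_values(pcs)
  ok <- complete.cases(sc)
  expect_equal(colMeans(sc[ok, ]), rep(0, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  cv <- cov(sc[ok, ])
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # single-cell score equals loadings' x standardized values
  vals <- nichescape:::stack_values(st)
  i <- which(ok)[5]
  z <- (vals[i, ] - pm$means) / pm$sds
  expect_equal(sc[i, ], as.numeric(z %*% pm$loadings), tolerance = 1e-10,
               ignore_attr = TRUE)
  # nodata propagates
  expect_true(all(is.na(sc[!ok, ])))
  # re-fitting on the scores is idempotent in the span sense: the refit
  # loadings are orthogonal, so between-cell distances in standardized score
  # space are preserved (components cannot be pinned individually because
  # standardization makes the score correlation matrix the identity)
  pm2 <- fit_pca(pcs, 3)
  z <- scale(sc[ok, ])
  expect_equal(as.matrix(dist(z %*% pm2$loadings)), as.matrix(dist(z)),
               tolerance = 1e-8)
})

test_that("PCA rejects degenerate inputs", {
  st <- toy_stack(6, layers = list(a = matrix(7, 6, 6),
                                   b = matrix(rnorm(36), 6, 6)))
  expect_error(fit_pca(st, 2), "variance")
  expect_error(fit_pca(random_stack(6, 2), 3), "n_components")
})

test_that("env_summary means equal a naive accumulation oracle", {
  st <- random_stack(9, 3, seed = 2, nodata = TRUE)
  s <- env_summary(st)
  vals <- nichescape:::stack_values(st)
  for (k in 1:3) {
    v <- vals[, k]
    expect_equal(unname(s$mean_by_layer[k]), sum(v[!is.na(v)]) / sum(!is.na(v)))
  }
  expect_identical(s$pc_origin, rep(0, 3))
  const <- toy_stack(5, layers = list(k7 = matrix(7, 5, 5)))
  expect_equal(unname(env_summary(const)$mean_by_layer["k7"]), 7)
})

test_that("masking then summarizing equals oracle-restricted summaries", {
  st <- toy_stack(10)
  with_seed_test(9, {
    for (i in 1:3) {
      x0 <- runif(1, 0, 4); y0 <- runif(1, 0, 4)
      poly <- rectangle_polygon(x0, x0 + 5, y0, y0 + 5)
      masked <- mask_to_area(st, poly)
      cc <- cell_centers(st)
      sel <- cc$x >= x0 & cc$x <= x0 + 5 & cc$y >= y0 & cc$y <= y0 + 5
      vals <- nichescape:::stack_values(st)
      expect_equal(unname(env_summary(masked)$mean_by_layer["a"]),
                   mean(vals[sel, "a"]))
    }
  })
})

test_that("stack round-trips through its plain-text serialization", {
  st <- random_stack(8, 3, seed = 13, nodata = TRUE)
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  back <- read_stack(dir)
  expect_equal(back$layers, st$layers, tolerance = 1e-15)
  expect_equal(back$res_km, st$res_km)
  expect_equal(back$origin, st$origin)
})
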