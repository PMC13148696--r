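# minimal permutation enumerator (base R) used by the Moran test
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

lattice_centroids <- function(nr, nc, res = 1) {
  cbind(x = rep(seq_len(nc) - 0.5, times = nr) * res,
        y = rep(seq_len(nr) - 0.5, each = nc) * res)
}

test_that("weight schemes scale as specified", {
  two <- rbind(c(0, 0), c(1, 0))
  w <- build_weights(two, "W", "min")
  expect_equal(rowSums(w$W), c(1, 1))
  expect_equal(diag(w$W), c(0, 0))

  cc <- lattice_centroids(3, 3)
  wc <- build_weights(cc, "C", "min")
  expect_equal(sum(wc$W), 9, tolerance = 1e-9)   # closed-form scaling
  ws <- build_weights(cc, "S", "min")
  expect_equal(sum(ws$W), 9, tolerance = 1e-9)
  # symmetric neighbor structure in all schemes
  for (w2 in list(wc, ws, build_weights(cc, "W", "min"))) {
    expect_identical(w2$W > 0, t(w2$W) > 0)
  }
})

test_that("neighbor pairs match an all-pairs distance oracle", {
  with_seed_test(50, {
    pts <- matrix(runif(60, 0, 10), 30, 2)
    thr <- 3
    w <- build_weights(pts, "W", threshold_km = thr)
    dm <- as.matrix(dist(pts)); diag(dm) <- Inf
    expect_equal(unname(w$W > 0), unname(dm <= thr * (1 + 1e-9)))
    # isolated cell errors under an explicit threshold
    far <- rbind(pts, c(100, 100))
    expect_error(build_weights(far, "W", threshold_km = thr), "isolated")
    # default min class guarantees no island
    w_min <- build_weights(far, "W", "min")
    expect_true(all(rowSums(w_min$W) > 0))
    expect_equal(build_weights(far, "W", "max")$threshold_km,
                 2 * w_min$threshold_km)
  })
})

test_that("weight eigenvalues agree with a direct eigensolve", {
  with_seed_test(51, {
    pts <- matrix(runif(40, 0, 6), 20, 2)
    for (sc in c("W", "C", "S")) {
      w <- build_weights(pts, sc, "min")
      direct <- sort(Re(eigen(w$W, only.values = TRUE)$values))
      expect_equal(sort(w$eigenvalues), direct, tolerance = 1e-8)
    }
  })
})

test_that("Moran's I hits closed-form cases and the permutation identity", {
  # checkerboard on a rook lattice with row-standardized weights -> I = -1
  cc <- lattice_centroids(4, 4)
  w <- build_weights(cc, "W", threshold_km = 1.01)
  chk <- rep(c(1, -1), 8) * rep(c(1, -1), each = 4)[rep(1:4, each = 4) * 0 + 1]
  board <- outer(1:4, 1:4, function(r, c) (-1)^(r + c))
  x <- as.vector(t(board))
  res <- morans_i(x, w, n_perm = 99, seed = 1)
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$expectation, -1 / 15)

  # full-permutation mean of I equals -1/(n-1) at n = 8
  cc8 <- lattice_centroids(2, 4)
  w8 <- build_weights(cc8, "W", threshold_km = 1.01)
  x8 <- c(3, 1, 4, 1, 5, 9, 2, 6)
  perms <- gtools_permutations(8)
  i_of <- function(z) {
    zz <- z - mean(z)
    (w8$n / w8$S0) * sum(zz * (w8$W %*% zz)) / sum(zz^2)
  }
  all_i <- apply(perms, 1, function(p) i_of(x8[p]))
  expect_equal(mean(all_i), -1 / 7, tolerance = 1e-10)

  # clustered pattern has positive I; affine invariance
  half <- c(rep(0, 8), rep(5, 8))
  res_h <- morans_i(half, w, n_perm = 99, seed = 2)
  expect_gt(res_h$I, 0)
  res_aff <- morans_i(3 * half - 10, w, n_perm = 99, seed = 2)
  expect_equal(res_aff$I, res_h$I, tolerance = 1e-12)
  expect_equal(res_aff$p, res_h$p)
  expect_error(morans_i(rep(1, 16), w), "constant")
})

test_that("SAR reduces to OLS at lambda = 0 and is exact without noise", {
  with_seed_test(52, {
    cc <- lattice_centroids(20, 20)
    w <- build_weights(cc, "W", threshold_km = 1.01)
    X <- cbind(a = rnorm(400), b = runif(400))
    # noiseless, lambda = 0: coefficients recovered to 1e-8
    y0 <- 1.5 + X %*% c(2, -1)
    f0 <- fit_sar_error(as.numeric(y0), X, w)
    expect_equal(f0$coefficients$estimate, c(1.5, 2, -1), tolerance = 1e-8)
    # iid noise: lambda near 0, beta within 2 se of OLS
    y <- as.numeric(1.5 + X %*% c(2, -1) + rnorm(400))
    f <- fit_sar_error(y, X, w)
    expect_lt(abs(f$lambda), 0.1)
    ols <- coef(lm(y ~ X))
    expect_true(all(abs(f$coefficients$estimate - ols) <
                      2 * f$coefficients$se))
    # optimizer sanity: profiled optimum at least as good as lambda = 0,
    # whose log-likelihood is the OLS value (log-determinant term vanishes)
    ols_fit <- lm(y ~ X)
    s2_ols <- sum(residuals(ols_fit)^2) / 400
    ll0 <- -400 / 2 * (log(2 * pi * s2_ols) + 1)
    expect_gte(f$logLik, ll0 - 1e-9)
  })
})

test_that("SAR recovers coefficients and lambda in simulation", {
  with_seed_test(53, {
    cc <- lattice_centroids(20, 20)
    w <- build_weights(cc, "W", threshold_km = 1.01)
    lambda <- 0.7
    A <- diag(400) - lambda * w$W
    Ainv <- solve(A)
    X <- cbind(a = rnorm(400), b = runif(400))
    n_rep <- 25
    est <- matrix(NA_real_, n_rep, 3)
    for (i in seq_len(n_rep)) {
      u <- Ainv %*% rnorm(400)
      y <- as.numeric(2 * X[, 1] - 1 * X[, 2] + u)
      f <- fit_sar_error(y, X, w)
      est[i, ] <- c(f$coefficients$estimate[2:3], f$lambda)
    }
    bias <- colMeans(est) - c(2, -1, lambda)
    expect_lt(abs(bias[1]), 0.05)
    expect_lt(abs(bias[2]), 0.05)
    expect_lt(abs(bias[3]), 0.05)
  })
})

test_that("SAR input validation and AIC selection behave", {
  cc <- lattice_centroids(5, 5)
  w <- build_weights(cc, "W", threshold_km = 1.01)
  X <- cbind(a = rnorm(25), b = rnorm(25))
  y <- rnorm(25)
  expect_error(fit_sar_error(y, cbind(X, a2 = X[, "a"]), w), "rank")
  expect_error(fit_sar_error(c(y[-1], NA), X, w), "missing")

  sel1 <- select_sar(y, X, list(w))
  expect_identical(sel1$best$AIC, sel1$table$AIC[1])
  w2 <- build_weights(cc, "C", threshold_km = 1.5)
  sel <- select_sar(y, X, list(w, w2))
  expect_false(is.unsorted(sel$table$AIC))
  sel_rev <- select_sar(y, X, list(w2, w))
  expect_equal(sel_rev$best$AIC, sel$best$AIC)
  expect_equal(sel_rev$best$weights_scheme, sel$best$weights_scheme)
})

test_that("predictor screening separates only strong conflicts", {
  with_seed_test(54, {
    a <- rnorm(100); b <- rnorm(100); c <- rnorm(100)
    m_ok <- cbind(a = a, b = b, c = c)
    expect_equal(screen_predictors(m_ok, 0.7), list(c("a", "b", "c")),
                 ignore_attr = TRUE)
    m_bad <- cbind(a = a, b = -a + rnorm(100, sd = 0.01), c = c)
    out <- screen_predictors(m_bad, 0.7)
    expect_length(out, 2)
    # conflict-free by brute force
    rho <- cor(m_bad, method = "spearman")
    for (model in out) {
      prs <- combn(model, 2, simplify = FALSE)
      for (p2 in prs) expect_lte(abs(rho[p2[1], p2[2]]), 0.7)
    }
    # both models keep the uncorrelated predictor
    expect_true(all(vapply(out, function(m) "c" %in% m, logical(1))))
  })
})
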