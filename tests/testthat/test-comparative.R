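test_that("pruning preserves path lengths and tree height", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  expect_identical(prune_to_species(tree, c("a", "b", "c", "d")), tree)
  pr <- prune_to_species(tree, c("a", "c"))
  expect_setequal(pr$tip.label, c("a", "c"))
  # path a-c in the original: 1 + 1 + 0.5 + 1.5 = 4; preserved after pruning
  expect_equal(sum(pr$edge.length), 4)
  expect_equal(max(ape::node.depth.edgelength(pr)), 2)
  expect_error(prune_to_species(tree, "zz"), "no requested species")
})

test_that("BM likelihood equals the MVN density and a pruning oracle", {
  with_seed_test(40, {
    for (rep in 1:4) {
      tree <- ape::rtree(10)
      trait <- setNames(rnorm(10, sd = 2), tree$tip.label)
      fit <- fit_evo_model(tree, trait, "BM")
      # direct MVN density at the ML parameters
      C <- ape::vcv(tree)
      V <- fit$params$sigma2 * C
      r <- trait[tree$tip.label] - fit$params$z0
      ll_mvn <- -0.5 * (10 * log(2 * pi) +
                          determinant(V, logarithm = TRUE)$modulus +
                          t(r) %*% solve(V, r))
      expect_equal(fit$logLik, as.numeric(ll_mvn), tolerance = 1e-8)
      # independent pruning-algorithm implementation (helper)
      expect_equal(fit$logLik, bm_loglik_pruning(tree, trait),
                   tolerance = 1e-6)
    }
  })
})

test_that("OU collapses to BM as alpha -> 0 and AIC bookkeeping holds", {
  with_seed_test(41, {
    tree <- ape::rcoal(20)
    trait <- setNames(rnorm(20), tree$tip.label)
    bm <- fit_evo_model(tree, trait, "BM")
    C <- ape::vcv(tree)
    ll_ou_small <- nichescape:::profile_loglik(
      trait[tree$tip.label], nichescape:::evo_cov("OU", C, 1e-9))$loglik
    expect_lt(abs(ll_ou_small - bm$logLik), 1e-4)
    for (m in c("OU", "EB", "trend")) {
      # random traits can push alpha to its bound; the flag is expected here
      f <- suppressWarnings(fit_evo_model(tree, trait, m))
      expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
      expect_gte(f$logLik, bm$logLik - 1e-6)  # BM nested in all three
    }
  })
})

test_that("model selection recovers the generating model under BM", {
  # simulate BM on a fixed tree; BM should win AIC in a clear majority
  # (three one-extra-parameter alternatives catch pure-BM data by chance in
  # a minority of replicates, so the bar is a majority, not near-certainty)
  with_seed_test(42, {
    tree <- ape::rcoal(60)
    wins <- 0
    n_rep <- 20
    for (i in seq_len(n_rep)) {
      trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      fits <- lapply(c("BM", "OU", "EB", "trend"), function(m) {
        fit_evo_model(tree, trait, m)
      })
      sel <- select_model(fits)
      if (sel$best$model == "BM") wins <- wins + 1
    }
    expect_gte(wins, ceiling(0.6 * n_rep))
  })
})

test_that("AIC weights follow the closed form", {
  mk <- function(model, aic, k) {
    structure(list(model = model, AIC = aic, k = k, logLik = (2 * k - aic) / 2,
                   params = list()), class = "evo_fit")
  }
  s <- select_model(list(mk("BM", 100, 2), mk("OU", 100, 3)))
  expect_equal(unname(s$weights), c(0.5, 0.5))
  expect_equal(s$best$model, "BM")  # tie broken by fewer parameters
  s2 <- select_model(list(mk("BM", 100, 2), mk("OU", 102, 3)))
  expect_equal(unname(s2$weights[1]), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(unname(s2$weights[2]), exp(-1) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(sum(s2$weights), 1)
})

test_that("root reconstruction has the GLS closed-form limits", {
  # two tips, equal branches, BM: midpoint
  two <- ape::read.tree(text = "(a:1,b:1);")
  tr2 <- c(a = 2, b = 4)
  f2 <- fit_evo_model(two, tr2, "BM")
  expect_equal(reconstruct_root(two, tr2, f2)$ancestral_state, 3)
  # star tree, BM: arithmetic mean
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  trs <- c(a = 1, b = 2, c = 3, d = 4, e = 10)
  fs <- fit_evo_model(star, trs, "BM")
  expect_equal(reconstruct_root(star, trs, fs)$ancestral_state, mean(trs))
  # strong OU: root approaches the grand mean regardless of topology
  with_seed_test(44, {
    tree <- ape::rcoal(30)
    trait <- setNames(rnorm(30, 5), tree$tip.label)
    C <- ape::vcv(tree)
    strong <- list(model = "OU", shape_par = 200,
                   params = list(sigma2 = 1, alpha = 200))
    class(strong) <- "evo_fit"
    rec <- reconstruct_root(tree, trait, strong)
    expect_equal(rec$ancestral_state, mean(trait), tolerance = 0.02)
  })
  # invariance: tip order and uniform translation
  with_seed_test(45, {
    tree <- ape::rcoal(12)
    trait <- setNames(rnorm(12), tree$tip.label)
    f <- fit_evo_model(tree, trait, "BM")
    r0 <- reconstruct_root(tree, trait, f)$ancestral_state
    perm <- sample(names(trait))
    expect_equal(reconstruct_root(tree, trait[perm], f)$ancestral_state, r0)
    f_sh <- fit_evo_model(tree, trait + 7, "BM")
    expect_equal(reconstruct_root(tree, trait + 7, f_sh)$ancestral_state,
                 r0 + 7, tolerance = 1e-8)
  })
})

test_that("phylogenetic position distances reduce and match a solve", {
  expect_equal(phylo_position(c(1, 2), c(1, 2), "euclidean"), 0)
  e_id <- ellipsoid(c(9, 9), diag(2), 1)
  expect_equal(phylo_position(c(0, 0), c(3, 4), "mahalanobis", e_id), 5)
  with_seed_test(46, {
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.3
    mu <- rnorm(3); anc <- rnorm(3)
    e <- ellipsoid(mu, S, 1)
    oracle <- sqrt(as.numeric(t(mu - anc) %*% solve(S, mu - anc)))
    expect_equal(phylo_position(mu, anc, "mahalanobis", e), oracle,
                 tolerance = 1e-10)
  })
  expect_error(phylo_position(1, 2, "mahalanobis"), "requires an ellipsoid")
  expect_error(phylo_position(1, c(1, 2), "euclidean"), "mismatch")
})

test_that("OU parameter recovery is unbiased enough at moderate size", {
  # smaller cousin of the acceptance-scale recovery check; guards the
  # optimizer wiring rather than asymptotics
  with_seed_test(47, {
    tree <- ape::rcoal(80)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    errs <- replicate(8, {
      trait <- ape::rTraitCont(tree, model = "OU", sigma = 1, alpha = 2,
                               theta = 5, root.value = 5)
      f <- fit_evo_model(tree, trait, "OU")
      abs(f$params$theta - 5)
    })
    expect_lt(median(errs), 0.6)
  })
})
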