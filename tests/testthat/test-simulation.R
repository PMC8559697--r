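test_that("the default base model is valid, fixed and well-separated", {
  b1 <- default_base_model()
  b2 <- default_base_model()
  expect_identical(b1, b2)
  expect_identical(length(b1$w), 10L)
  expect_identical(dim(b1$e), c(6L, 96L))
  validate_mix_params(b1)
  # every cluster concentrates most of its mass on 2-3 dominant signatures
  top3 <- apply(b1$pi, 1, function(r) sum(sort(r, decreasing = TRUE)[1:3]))
  expect_true(all(top3 >= 0.75))
  # marginal signature usage is balanced (each signature earns its keep)
  p_k <- as.numeric(b1$w %*% b1$pi)
  expect_true(all(p_k > 0.1) && all(p_k < 0.25))
  # signatures pairwise distinct
  cs <- cosine_similarity(b1$e, b1$e)
  expect_lt(max(cs[upper.tri(cs)]), 0.5)
})

test_that("ground-truth construction subsets and renormalises the base", {
  base <- default_base_model()
  # full subset returns the base up to ordering
  gt_full <- build_ground_truth(base, L_sub = 10, K_sub = 6, seed = 1)
  cl <- attr(gt_full, "clusters"); sg <- attr(gt_full, "signatures")
  expect_setequal(cl, 1:10)
  expect_setequal(sg, 1:6)
  expect_equal(gt_full$w, base$w[cl], tolerance = 1e-12)
  expect_equal(unname(gt_full$e), unname(base$e[sg, ]), tolerance = 1e-12)
  expect_equal(unname(gt_full$pi), unname(base$pi[cl, sg]), tolerance = 1e-12)
  # certain cluster under a degenerate prior
  b2 <- mix_params(c(1, 0), rbind(c(0.3, 0.7), c(0.5, 0.5)),
                   rbind(c(0.5, 0.5), c(0.2, 0.8)))
  for (s in 1:5) {
    g <- build_ground_truth(b2, L_sub = 1, K_sub = 2, seed = s)
    expect_identical(attr(g, "clusters"), 1L)
  }
  expect_error(build_ground_truth(base, L_sub = 11, K_sub = 2, seed = 1),
               "exceeds")
  expect_error(build_ground_truth(base, L_sub = 2, K_sub = 7, seed = 1),
               "exceeds")
})

test_that("signature subsampling frequencies follow the marginal usage p_k", {
  # K_sub = 1 makes the draw a single categorical sample with probs p_k
  base <- default_base_model()
  gt <- build_ground_truth(base, L_sub = 10, K_sub = 6, seed = 5)
  p_k <- as.numeric(gt$w %*% gt$pi)[order(attr(gt, "signatures"))]
  draws <- vapply(1:10000, function(s) {
    attr(build_ground_truth(base, L_sub = 10, K_sub = 1, seed = 100000 + s),
         "signatures")
  }, integer(1))
  obs <- tabulate(draws, nbins = 6)
  # chi-square goodness of fit against p_k (w is the same for L_sub = L)
  expect_gt(chisq.test(obs, p = p_k)$p.value, 0.01)
})

test_that("generated catalogs realise the generative process exactly", {
  # deterministic emission: a single indicator signature
  e <- rbind(`5` = c(0, 0, 0, 0, 1, 0))
  p <- mix_params(1, rbind(1), e)
  sim <- simulate_catalog(p, n_samples = 20, budgets = c(3, 5), seed = 2)
  expect_true(all(sim$catalog[, -5] == 0))
  expect_true(all(rowSums(sim$catalog) %in% c(3, 5)))
  # conservation between catalog, budgets and signature counts
  expect_equal(unname(rowSums(sim$catalog)), sim$truth$mutation_budgets)
  expect_equal(rowSums(sim$truth$signature_counts),
               sim$truth$mutation_budgets)
  # reproducibility and seed sensitivity
  sim2 <- simulate_catalog(p, n_samples = 20, budgets = c(3, 5), seed = 2)
  expect_identical(sim$catalog, sim2$catalog)
  sim3 <- simulate_catalog(p, n_samples = 20, budgets = c(3, 5), seed = 3)
  expect_false(identical(sim$catalog, sim3$catalog))
  expect_error(simulate_catalog(p, 5, budgets = integer(0)), "empty budget")
})

test_that("realised signature usage matches the exposures", {
  set.seed(113)
  p <- mix_params(1, rbind(c(0.3, 0.7)),
                  rbind(rand_params(1, 1, 8)$e[1, ], rand_params(1, 1, 8)$e[1, ]))
  sim <- simulate_catalog(p, n_samples = 1000, budget_mean = 100, seed = 7)
  tot <- sum(sim$truth$signature_counts)
  frac1 <- sum(sim$truth$signature_counts[, 1]) / tot
  expect_lt(abs(frac1 - 0.3), 3 * sqrt(0.3 * 0.7 / tot))
})

test_that("Poisson downsampling keeps a subset with the right mean size", {
  set.seed(127)
  V <- rand_catalog(30, 8)
  d <- poisson_downsample(V, d = 3, seed = 5)
  expect_true(all(unclass(d) <= unclass(V)))
  expect_identical(dimnames(d), dimnames(V))
  # nothing to remove when totals are already tiny
  V0 <- as_catalog(matrix(0, 3, 4))
  expect_equal(unclass(poisson_downsample(V0, d = 2, seed = 1)),
               unclass(V0), ignore_attr = TRUE)
  # retained totals follow min(Pois(d), T): with T = 100 >> d = 6 the
  # truncation is negligible and the mean tends to d
  one <- as_catalog(rbind(s = c(60, 40)))
  kept <- vapply(1:10000, function(s) {
    sum(poisson_downsample(one, d = 6, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(kept) - 6), 3 * sqrt(6 / 10000))
  expect_error(poisson_downsample(V, d = 0), "d must be > 0")
})

test_that("budget pool and simulated sparsity emulate a panel cohort", {
  pool <- default_budget_pool()
  expect_true(all(pool >= 1))
  expect_gt(mean(pool), 6)
  expect_lt(mean(pool), 8)
  expect_identical(pool, default_budget_pool())
})
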