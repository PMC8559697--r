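test_that("single-sample mixture log-likelihood matches the product formula", {
  # empty data: empty product = 1
  expect_identical(mmm_log_likelihood(c(0, 0), 1, rbind(c(0.5, 0.5))), 0)
  # uniform single signature
  expect_equal(mmm_log_likelihood(c(1, 1), 1, rbind(c(0.5, 0.5))), log(0.25))
  # two signatures with structural zeros: log(0.6^2 * 0.2)
  pi <- c(0.6, 0.4)
  e <- rbind(c(1, 0, 0), c(0, 0.5, 0.5))
  expect_equal(mmm_log_likelihood(c(2, 1, 0), pi, e), log(0.072))
  # -Inf exactly when a positive count hits a structural zero
  expect_identical(mmm_log_likelihood(c(0, 0, 1), c(1, 0), e), -Inf)
  expect_error(mmm_log_likelihood(c(1, 1), c(0.5, 0.5), e), "ncol")
  expect_error(mmm_log_likelihood(c(-1, 0, 0), pi, e), "non-negative")
})

test_that("per-sample expectations split counts by posterior and conserve them", {
  pi <- c(0.6, 0.4)
  e <- rbind(c(1, 0, 0), c(0, 0.5, 0.5))
  ex <- mmm_expectations(c(2, 1, 0), pi, e)
  expect_equal(ex$E[1, 1], 2)
  expect_equal(ex$E[2, 2], 1)
  expect_equal(ex$E[1, 2], 0)
  expect_equal(ex$A, c(2, 1))
  # K = 1: everything attributed to the lone signature
  ex1 <- mmm_expectations(c(3, 0, 2), 1, rbind(c(0.2, 0.3, 0.5)))
  expect_equal(ex1$E[1, ], c(3, 0, 2))
  expect_equal(ex1$A, 5)
  # conservation on random instances: colSums(E) == V
  set.seed(101)
  for (rep in 1:20) {
    K <- sample(1:4, 1); M <- sample(2:6, 1)
    p <- rand_params(1, K, M)
    V <- rpois(M, 3)
    ex <- mmm_expectations(V, as.numeric(p$pi), p$e)
    expect_equal(colSums(ex$E), as.numeric(V), tolerance = 1e-12)
    expect_equal(ex$A, rowSums(ex$E), tolerance = 1e-12)
  }
  expect_error(mmm_expectations(c(0, 0, 1), c(1, 0), e), "category 3")
})

test_that("catalog log-likelihood matches brute-force enumeration on small instances", {
  set.seed(7)
  for (rep in 1:30) {
    N <- sample(1:3, 1); M <- sample(2:4, 1)
    L <- sample(1:3, 1); K <- sample(1:3, 1)
    p <- rand_params(L, K, M)
    # at most 6 mutations in the whole catalog
    V <- matrix(0, N, M)
    for (t in seq_len(sample(0:6, 1))) {
      n <- sample(N, 1); j <- sample(M, 1)
      V[n, j] <- V[n, j] + 1
    }
    V <- as_catalog(V)
    expect_equal(mix_log_likelihood(V, p),
                 oracle_mix_loglik(unclass(V), p$w, p$pi, p$e),
                 tolerance = 1e-10)
  }
})

test_that("mixture likelihood is invariant to label permutations and duplication", {
  set.seed(13)
  p <- rand_params(3, 4, 6)
  V <- rand_catalog(5, 6)
  base <- mix_log_likelihood(V, p)
  # permute clusters
  pc <- sample(3)
  p_cl <- mix_params(p$w[pc], p$pi[pc, ], p$e)
  expect_equal(mix_log_likelihood(V, p_cl), base, tolerance = 1e-13)
  # permute signatures jointly in pi columns and e rows
  ps <- sample(4)
  p_sg <- mix_params(p$w, p$pi[, ps], p$e[ps, ])
  expect_equal(mix_log_likelihood(V, p_sg), base, tolerance = 1e-12)
  # duplicating a cluster and splitting its weight changes nothing
  p_dup <- mix_params(c(p$w[1] * 0.3, p$w[1] * 0.7, p$w[2:3]),
                      p$pi[c(1, 1, 2, 3), ], p$e)
  expect_equal(mix_log_likelihood(V, p_dup), base, tolerance = 1e-12)
})

test_that("L = 1 reduces exactly to the single-cluster multinomial mixture", {
  set.seed(19)
  p1 <- rand_params(1, 3, 5)
  V <- rand_catalog(6, 5)
  pooled <- sum(apply(unclass(V), 1, function(v) {
    mmm_log_likelihood(v, as.numeric(p1$pi), p1$e)
  }))
  expect_equal(mix_log_likelihood(V, p1), pooled, tolerance = 1e-13)
})

test_that("responsibilities normalise correctly and handle edge cases", {
  e <- rbind(c(1, 0), c(0, 1))
  # degenerate emissions: sample V=(1,0) can only come from cluster 1
  p <- mix_params(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)), e)
  r <- mix_responsibilities(as_catalog(rbind(s = c(1, 0))), p)
  expect_equal(as.numeric(r), c(1, 0))
  # identical clusters: posterior equals the prior for every sample
  set.seed(23)
  pi_eq <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7))
  p_eq <- mix_params(c(0.2, 0.5, 0.3), pi_eq, rand_params(1, 2, 4)$e)
  r_eq <- mix_responsibilities(rand_catalog(4, 4), p_eq)
  for (n in 1:4) expect_equal(as.numeric(r_eq[n, ]), p_eq$w, tolerance = 1e-12)
  # degenerate prior w = (1, 0)
  p_w <- mix_params(c(1, 0), rbind(c(0.5, 0.5), c(0.1, 0.9)),
                    rand_params(1, 2, 4)$e)
  r_w <- mix_responsibilities(rand_catalog(3, 4), p_w)
  expect_equal(unname(r_w[, 1]), rep(1, 3))
  # a zero-mutation sample gets the prior
  V0 <- as_catalog(rbind(a = c(0, 0), b = c(2, 1)))
  p2 <- mix_params(c(0.25, 0.75), rbind(c(0.9, 0.1), c(0.2, 0.8)),
                   rbind(c(0.5, 0.5), c(0.3, 0.7)))
  expect_equal(as.numeric(mix_responsibilities(V0, p2)[1, ]), c(0.25, 0.75))
  # all-cluster zero likelihood is an error naming the sample
  p_dead <- mix_params(c(0.5, 0.5), rbind(c(1, 0), c(1, 0)),
                       rbind(c(1, 0), c(0, 1)))
  expect_error(mix_responsibilities(as_catalog(rbind(bad = c(0, 1))), p_dead),
               "bad")
  expect_true(all(abs(rowSums(r_eq) - 1) < 1e-12))
})
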