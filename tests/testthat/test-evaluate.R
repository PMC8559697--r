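test_that("NNLS exposures solve the per-sample non-negative least squares", {
  S <- rbind(c(1, 0), c(0.5, 0.5))
  # exact representation: V = 2*S1 + 2*S2
  E <- nnls_exposures(rbind(c(3, 1)), S)
  expect_equal(as.numeric(E), c(2, 2), tolerance = 1e-6)
  # agrees with the exhaustive grid oracle
  grid <- oracle_nnls_grid(c(3, 1), S)
  expect_lt(max(abs(as.numeric(E) - grid)), 2e-3)
  # exact multiple of an orthogonal signature
  S2 <- rbind(c(1, 0, 0), c(0, 0.5, 0.5))
  expect_equal(as.numeric(nnls_exposures(rbind(7 * S2[1, ]), S2)), c(7, 0),
               tolerance = 1e-8)
  # zero row gives zero exposures
  expect_equal(as.numeric(nnls_exposures(rbind(c(0, 0, 0)), S2)), c(0, 0))
  # random instances beat any perturbed non-negative candidate
  set.seed(131)
  for (rep in 1:5) {
    S3 <- rand_params(1, 3, 4)$e
    v <- rpois(4, 5)
    x <- as.numeric(nnls_exposures(rbind(v), S3))
    base_res <- sum((v - x %*% S3)^2)
    for (t in 1:20) {
      y <- pmax(x + rnorm(3, 0, 0.1), 0)
      expect_gte(sum((v - y %*% S3)^2), base_res - 1e-9)
    }
  }
  expect_warning(nnls_exposures(rbind(c(1, 1)), rbind(c(0.5, 0.5), c(0.5, 0.5))),
                 "rank-deficient")
  # a single signature keeps matrix shape
  E1 <- nnls_exposures(rbind(c(2, 2), c(4, 4)), rbind(c(0.5, 0.5)))
  expect_identical(dim(E1), c(2L, 1L))
  expect_equal(as.numeric(E1), c(4, 8), tolerance = 1e-8)
})

test_that("reconstruction error is the L1 gap on normalised profiles", {
  S <- rbind(c(1, 0), c(0, 1))
  # perfect reconstruction
  re0 <- reconstruction_error(rbind(c(2, 2)), rbind(c(0.5, 0.5)), S)
  expect_equal(re0$mean, 0)
  # hand example: V~ = (.5,.5), E_d = (1,0) -> |(.5,.5)-(1,0)| = 1
  re1 <- reconstruction_error(rbind(c(1, 1)), rbind(c(1, 0)), S)
  expect_equal(re1$mean, 1)
  # bound 0 <= RE <= 2 on random instances; zero-count rows skipped
  set.seed(137)
  V <- rbind(matrix(rpois(40, 2), 10, 4), rep(0, 4))
  p <- rand_params(1, 2, 4)
  Ed <- matrix(rgamma(22, 1), 11, 2)
  Ed <- Ed / rowSums(Ed)
  re <- reconstruction_error(V, Ed, p$e)
  expect_true(all(re$per_sample >= 0 & re$per_sample <= 2, na.rm = TRUE))
  expect_true(is.na(re$per_sample[11]))
  expect_identical(re$n_evaluated, sum(rowSums(V) > 0))
})

test_that("exposure reconstruction error compares normalised exposure vectors", {
  expect_equal(exposure_reconstruction_error(rbind(c(0.8, 0.2)),
                                             rbind(c(0.6, 0.4)))$mean, 0.4)
  # reference is normalised before comparison
  expect_equal(exposure_reconstruction_error(rbind(c(8, 2)),
                                             rbind(c(0.6, 0.4)))$mean, 0.4)
  expect_equal(exposure_reconstruction_error(rbind(c(3, 1)),
                                             rbind(c(0.75, 0.25)))$mean, 0)
  # zero reference rows are skipped with a warning
  expect_warning(
    ere <- exposure_reconstruction_error(rbind(c(1, 1), c(0, 0)),
                                         rbind(c(0.5, 0.5), c(0.5, 0.5))),
    "skipped")
  expect_identical(ere$n_evaluated, 1L)
  expect_true(is.na(ere$per_sample[2]))
  # bound
  set.seed(139)
  A <- matrix(rgamma(30, 1), 10, 3)
  B <- matrix(rgamma(30, 1), 10, 3); B <- B / rowSums(B)
  expect_true(all(exposure_reconstruction_error(A, B)$per_sample <= 2 + 1e-12))
})

test_that("signature matching maximises cosine, one-to-one or best-match", {
  set.seed(149)
  E <- rand_params(1, 4, 8)$e
  # identity
  m <- match_signatures(E, E, mode = "one_to_one")
  expect_equal(m$pairs$reference, 1:4)
  expect_equal(m$mean_cosine, 1, tolerance = 1e-12)
  # permutation recovery for orthogonal indicator signatures
  I4 <- diag(4)
  perm <- c(3L, 1L, 4L, 2L)
  mp <- match_signatures(I4[perm, ], I4, mode = "one_to_one")
  expect_identical(mp$pairs$reference, perm)
  expect_equal(mp$pairs$cosine, rep(1, 4))
  # best-match ties break to the lowest reference index
  mt <- match_signatures(rbind(c(0.5, 0.5, 0, 0)),
                         rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                         mode = "best_match")
  expect_identical(mt$pairs$reference, 1L)
  expect_equal(mt$pairs$cosine, sqrt(2) / 2, tolerance = 1e-12)
  # best-match may reuse references; one-to-one may not
  two <- rbind(c(0.9, 0.1, 0, 0), c(0.8, 0.2, 0, 0))
  refs <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  bm <- match_signatures(two, refs, mode = "best_match")
  expect_identical(bm$pairs$reference, c(1L, 1L))
  oo <- match_signatures(two, refs, mode = "one_to_one")
  expect_identical(sort(oo$pairs$reference), 1:2)
  expect_error(match_signatures(rbind(c(0, 0, 0, 0)), refs), "zero-vector")
})

test_that("the assignment solver matches brute-force enumeration", {
  set.seed(151)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    R <- K + sample(0:2, 1)
    sc <- matrix(runif(K * R), K, R)
    got <- mixmm:::hungarian_max(sc)
    want <- oracle_assignment(sc)
    expect_equal(sum(sc[cbind(seq_len(K), got)]), want$total, tolerance = 1e-12)
  }
})

test_that("adjusted mutual information matches the reference implementation", {
  # frozen values from an independent reference implementation
  expect_equal(adjusted_mutual_information(c(0, 0, 0, 1, 1, 1),
                                           c(0, 0, 1, 1, 2, 2)),
               0.22504228319830885, tolerance = 1e-12)
  expect_equal(adjusted_mutual_information(c(0, 1, 0, 1, 2, 2, 1, 0),
                                           c(1, 0, 1, 0, 2, 2, 0, 1)),
               1.0, tolerance = 1e-12)
  expect_equal(adjusted_mutual_information(c(0, 0, 1, 1, 2, 2, 0, 1, 2, 0),
                                           c(0, 1, 0, 1, 0, 1, 1, 1, 0, 0)),
               -0.10677318981252805, tolerance = 1e-12)
  # relabeling gives 1, a constant partition gives 0
  expect_equal(adjusted_mutual_information(c("a", "a", "b"), c(2, 2, 9)), 1)
  expect_equal(adjusted_mutual_information(rep(1, 6), c(0, 0, 1, 1, 2, 2)), 0)
  expect_equal(adjusted_mutual_information(rep(1, 4), rep(2, 4)), 1)
  # near zero for independent partitions at moderate n
  set.seed(157)
  vals <- vapply(1:30, function(i) {
    adjusted_mutual_information(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(adjusted_mutual_information(integer(0), integer(0)), "empty")
  expect_error(adjusted_mutual_information(1:3, 1:4), "length")
})

test_that("metric reports serialise per-sample errors and the summary", {
  re <- list(per_sample = c(a = 0.5, b = 1.0), mean = 0.75, n_evaluated = 2L)
  ere <- list(per_sample = c(a = 0.2, b = 0.4), mean = 0.3, n_evaluated = 2L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  out <- write_metric_report(re, ere, tsv_path = tsv, json_path = js)
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("sample_id", "re", "ere"))
  expect_equal(tab$re, c(0.5, 1.0))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$mean_re, 0.75)
  expect_equal(parsed$mean_ere, 0.3)
  expect_identical(parsed$n_evaluated, 2L)
})
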