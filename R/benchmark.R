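#' Downsampling refit benchmark
#'
#' The controlled experiment behind the package's evaluation metrics: a
#' rich catalog is Poisson-downsampled to panel-like sparsity; the model is
#' trained in refitting mode (signatures fixed to \code{S}) on the
#' downsampled half of the samples; exposures for the held-out half are
#' inferred from their downsampled counts by soft clustering, hard
#' clustering, and per-sample NNLS; each estimate is scored against the
#' held-out samples' \emph{full} catalog with the reconstruction error
#' (RE) and against NNLS exposures on the full data with the exposure
#' reconstruction error (ERE).
#'
#' @param full_catalog N x M rich count catalog.
#' @param S K x M signature matrix (rows sum to 1).
#' @param L Number of clusters for the refit model.
#' @param d Poisson downsampling mean (mutations kept per sample).
#' @param seed Integer seed driving the downsampling, the train/test
#'   split and the fit restarts.
#' @param n_restarts,max_iterations,tol Passed to [mix_fit()].
#' @return data.frame with one row per method (\code{mix_soft},
#'   \code{mix_hard}, \code{nnls}) and columns \code{mean_re},
#'   \code{mean_ere}, \code{n_test}.
#' @export
refit_benchmark <- function(full_catalog, S, L, d, seed = 1L,
                            n_restarts = 10L, max_iterations = 1000L,
                            tol = 1e-6) {
  V <- check_catalog(full_catalog)
  S <- as.matrix(S)
  N <- nrow(V)
  sparse <- poisson_downsample(V, d = d, seed = seed)
  idx <- with_seed(seed, sample.int(N, floor(N / 2)))
  train <- sparse[idx, , drop = FALSE]
  test_sparse <- sparse[-idx, , drop = FALSE]
  test_full <- V[-idx, , drop = FALSE]

  fit <- mix_fit(train, L = L, K = nrow(S), signatures = S,
                 n_restarts = n_restarts, max_iterations = max_iterations,
                 tol = tol, seed = seed)

  E_soft <- infer_exposures(test_sparse, fit$params, scheme = "soft")
  E_hard <- infer_exposures(test_sparse, fit$params, scheme = "hard")
  E_nnls <- row_normalize(nnls_exposures(test_sparse, S))
  E_ref <- nnls_exposures(test_full, S)   # "true" exposures from rich data

  score <- function(E_d) {
    re <- reconstruction_error(test_full, E_d, S)
    ere <- suppressWarnings(exposure_reconstruction_error(E_ref, E_d))
    c(mean_re = re$mean, mean_ere = ere$mean, n_test = re$n_evaluated)
  }
  out <- rbind(mix_soft = score(E_soft),
               mix_hard = score(E_hard),
               nnls = score(E_nnls))
  data.frame(method = rownames(out), out, row.names = NULL)
}
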