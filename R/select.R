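#' Number of free parameters of a Mix model
#'
#' De novo, the model learns L-1 free cluster priors, L rows of K-1 free
#' exposures and K rows of M-1 free signature probabilities:
#' \deqn{(L-1) + L(K-1) + K(M-1).}
#' In refitting mode the signatures are fixed inputs, leaving
#' \eqn{(L-1) + L(K-1)} estimated parameters.
#'
#' @param L Number of clusters.
#' @param K Number of signatures.
#' @param M Number of mutation categories.
#' @param refit_mode Signatures fixed?
#' @return Integer parameter count.
#' @examples
#' parameter_count(10, 6, 96)  # 629
#' @export
parameter_count <- function(L, K, M, refit_mode = FALSE) {
  if (L < 1 || K < 1 || M < 1) stop("need L, K, M >= 1")
  n <- (L - 1) + L * (K - 1)
  if (!refit_mode) n <- n + K * (M - 1)
  as.integer(n)
}

#' BIC of a fitted Mix model
#'
#' \deqn{BIC = size \cdot \log(n) - 2 \log \Pr[V | model],}
#' where \emph{size} is the number of estimated parameters and \emph{n} the
#' number of data points — individual mutations, the iid units of the
#' likelihood.  Lower is better.
#'
#' @param fit A \code{"mix_fit"} object (or a list with \code{params} and
#'   \code{log_likelihood}).
#' @param total_mutations Number of mutations n; defaults to the fit's
#'   training total.
#' @return The BIC score (scalar).
#' @export
bic_score <- function(fit, total_mutations = fit$total_mutations) {
  if (is.null(total_mutations) || total_mutations < 1) {
    stop("total_mutations must be >= 1")
  }
  p <- fit$params
  size <- parameter_count(length(p$w), nrow(p$e), ncol(p$e),
                          refit_mode = isTRUE(p$refit))
  size * log(total_mutations) - 2 * fit$log_likelihood
}

#' BIC grid search over the number of clusters and signatures
#'
#' Fits the model once per (L, K) pair and scores each fit with
#' [bic_score()].  The selected pair minimises BIC; ties are broken
#' towards smaller K, then smaller L (parsimony).  A cell whose fit fails
#' is annotated with the error message and excluded from the argmin rather
#' than aborting the grid.
#'
#' @param catalog A \code{"mutation_catalog"} or count matrix.
#' @param L_range,K_range Integer vectors (or ranges) of candidate values.
#' @param signatures Optional fixed signature matrix: every cell is fitted
#'   in refitting mode and \code{K_range} is ignored.
#' @param n_restarts,max_iterations,tol,seed Passed to [mix_fit()]; each
#'   cell uses the same base seed so cells are independent of grid order.
#' @param keep_fits Keep the full \code{"mix_fit"} objects (default TRUE).
#' @param verbose Print one line per cell.
#' @return An object of class \code{"mix_grid"}: list with \code{grid}
#'   (data.frame of L, K, n_parameters, log_likelihood, bic, selected,
#'   error), \code{best} (list with L, K), \code{best_fit}, \code{fits}.
#' @examples
#' V <- as_catalog(matrix(rpois(60, 2), nrow = 10))
#' g <- mix_select(V, L_range = 1:2, K_range = 1:2, n_restarts = 2, seed = 1)
#' g$best
#' @export
mix_select <- function(catalog, L_range, K_range, signatures = NULL,
                       n_restarts = 10L, max_iterations = 1000L,
                       tol = 1e-6, seed = 1L, keep_fits = TRUE,
                       verbose = FALSE) {
  L_range <- sort(unique(as.integer(L_range)))
  if (!is.null(signatures)) K_range <- nrow(as.matrix(signatures))
  K_range <- sort(unique(as.integer(K_range)))
  if (!length(L_range) || !length(K_range)) stop("empty hyperparameter range")
  V <- check_catalog(catalog)
  n_mut <- sum(V)

  cells <- expand.grid(K = K_range, L = L_range)[, c("L", "K")]
  fits <- vector("list", nrow(cells))
  grid <- data.frame(L = cells$L, K = cells$K,
                     n_parameters = NA_integer_,
                     log_likelihood = NA_real_, bic = NA_real_,
                     selected = 0L, error = NA_character_)
  for (idx in seq_len(nrow(cells))) {
    Lc <- cells$L[idx]; Kc <- cells$K[idx]
    res <- tryCatch(
      mix_fit(V, L = Lc, K = Kc, signatures = signatures,
              n_restarts = n_restarts, max_iterations = max_iterations,
              tol = tol, seed = seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      grid$error[idx] <- conditionMessage(res)
      if (verbose) message(sprintf("L=%d K=%d: ERROR %s", Lc, Kc, grid$error[idx]))
      next
    }
    grid$n_parameters[idx] <- parameter_count(Lc, Kc, ncol(V),
                                              refit_mode = !is.null(signatures))
    grid$log_likelihood[idx] <- res$log_likelihood
    grid$bic[idx] <- bic_score(res, n_mut)
    if (keep_fits) fits[[idx]] <- res
    if (verbose) {
      message(sprintf("L=%d K=%d: loglik %.2f, BIC %.2f", Lc, Kc,
                      res$log_likelihood, grid$bic[idx]))
    }
  }
  ok <- which(!is.na(grid$bic))
  if (!length(ok)) stop("every grid cell failed to fit")
  # argmin with parsimony tie-break: smaller K first, then smaller L
  ord <- ok[order(grid$bic[ok], grid$K[ok], grid$L[ok])]
  best_idx <- ord[1L]
  grid$selected[best_idx] <- 1L
  structure(list(grid = grid,
                 best = list(L = grid$L[best_idx], K = grid$K[best_idx]),
                 best_fit = if (keep_fits) fits[[best_idx]] else NULL,
                 fits = if (keep_fits) fits else NULL,
                 total_mutations = n_mut),
            class = "mix_grid")
}

#' @export
print.mix_grid <- function(x, ...) {
  cat(sprintf("BIC grid over L in {%s}, K in {%s} (n = %d mutations)\n",
              paste(sort(unique(x$grid$L)), collapse = ","),
              paste(sort(unique(x$grid$K)), collapse = ","),
              as.integer(x$total_mutations)))
  cat(sprintf("  selected: L = %d, K = %d (BIC %.2f)\n", x$best$L, x$best$K,
              x$grid$bic[x$grid$selected == 1L]))
  invisible(x)
}

#' Write a BIC grid to TSV
#'
#' Columns: L, K, n_parameters, log_likelihood, bic, selected (0/1).
#'
#' @param grid A \code{"mix_grid"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$grid[, c("L", "K", "n_parameters",
                                   "log_likelihood", "bic", "selected")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
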