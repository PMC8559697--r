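#' Fit the Mix model to a mutation catalog
#'
#' Trains a mixture of multinomial mixture models: samples fall into L
#' latent clusters, each cluster has its own relative signature exposures,
#' and K signatures are shared across clusters.  Training maximises the
#' likelihood by expectation-maximization, restarted \code{n_restarts}
#' times from independent Dirichlet(1) initialisations; the restart with
#' the highest final log-likelihood wins.  Supplying \code{signatures}
#' switches to refitting mode: the signature matrix is fixed and only the
#' cluster priors and exposures are learned.
#'
#' @param catalog A \code{"mutation_catalog"} or N x M count matrix.
#' @param L Number of clusters (>= 1).
#' @param K Number of signatures (>= 1); ignored (taken from the matrix)
#'   when \code{signatures} is given.
#' @param signatures Optional K x M signature matrix to refit against
#'   (rows must sum to 1).
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iterations EM iteration cap per restart (default 1000).
#' @param tol Absolute log-likelihood improvement below which EM stops
#'   (default 1e-6); a relative improvement below \code{tol_rel} also
#'   stops it.
#' @param tol_rel Relative-improvement stopping threshold (default 1e-10).
#' @param seed Integer seed; restart r uses \code{seed + r - 1}, so the fit
#'   is reproducible bit-for-bit.
#' @param verbose Print one line per restart.
#' @return An object of class \code{"mix_fit"}: a list with
#'   \code{params} (\code{"mix_params"}), \code{log_likelihood},
#'   \code{trace} (per-iteration log-likelihoods of the winning restart),
#'   \code{n_iterations}, \code{converged}, \code{seed} (the winning
#'   restart's seed), \code{restart_index}, \code{restart_logliks}, and
#'   catalog bookkeeping (\code{n_samples}, \code{n_categories},
#'   \code{total_mutations}, \code{categories}, \code{sample_ids}).
#' @examples
#' V <- as_catalog(matrix(rpois(40, 3), nrow = 5))
#' fit <- mix_fit(V, L = 2, K = 2, n_restarts = 2, seed = 1)
#' logLik(fit)
#' @seealso [predict.mix_fit()], [mix_select()], [simulate.mix_fit()]
#' @export
mix_fit <- function(catalog, L, K, signatures = NULL,
                    n_restarts = 10L, max_iterations = 1000L,
                    tol = 1e-6, tol_rel = 1e-10, seed = 1L,
                    verbose = FALSE) {
  V <- check_catalog(catalog)
  if (nrow(V) < 1L) stop("empty catalog")
  L <- as.integer(L); K <- as.integer(K)
  if (L < 1L || K < 1L) stop("need L >= 1 and K >= 1")
  M <- ncol(V)
  if (!is.null(signatures)) {
    signatures <- as.matrix(signatures)
    if (ncol(signatures) != M) stop("signatures and catalog disagree on M")
    if (any(abs(rowSums(signatures) - 1) > 1e-6)) {
      stop("signature rows must sum to 1")
    }
    K <- nrow(signatures)
  }
  if (K > M) warning("K > M: more signatures than categories (over-parameterized)")

  best <- NULL
  restart_logliks <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    rseed <- as.integer(seed) + r - 1L
    set.seed(rseed)
    init <- random_params(L, K, M, refit_e = signatures,
                          categories = colnames(V))
    run <- em_run(V, init, max_iterations = max_iterations,
                  tol_abs = tol, tol_rel = tol_rel)
    restart_logliks[r] <- run$log_likelihood
    if (verbose) {
      message(sprintf("restart %d (seed %d): loglik %.4f after %d iterations",
                      r, rseed, run$log_likelihood, run$n_iterations))
    }
    if (is.null(best) || run$log_likelihood > best$log_likelihood) {
      best <- run
      best$seed <- rseed
      best$restart_index <- r
    }
  }

  structure(list(
    params = best$params,
    log_likelihood = best$log_likelihood,
    trace = best$trace,
    n_iterations = best$n_iterations,
    converged = best$converged,
    seed = best$seed,
    restart_index = best$restart_index,
    restart_logliks = restart_logliks,
    n_samples = nrow(V),
    n_categories = M,
    total_mutations = sum(V),
    categories = colnames(V),
    sample_ids = rownames(V),
    call = match.call()
  ), class = "mix_fit")
}

#' @export
print.mix_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Mix model fit%s\n", if (isTRUE(p$refit)) " (refitting mode)" else ""))
  cat(sprintf("  %d samples, %d categories, %d mutations\n",
              x$n_samples, x$n_categories, as.integer(x$total_mutations)))
  cat(sprintf("  L = %d clusters, K = %d signatures\n", length(p$w), nrow(p$e)))
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (%s), best of %d restarts\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "iteration cap",
              length(x$restart_logliks)))
  invisible(x)
}

#' @export
summary.mix_fit <- function(object, ...) {
  p <- object$params
  sizes <- p$w * object$n_samples
  out <- list(fit = object,
              n_parameters = parameter_count(length(p$w), nrow(p$e),
                                             ncol(p$e), refit_mode = p$refit),
              bic = bic_score(object, object$total_mutations),
              expected_cluster_sizes = sizes,
              dominant_signature = apply(p$pi, 1L, which.max))
  class(out) <- "summary.mix_fit"
  out
}

#' @export
print.summary.mix_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d free parameters, BIC %.2f\n", x$n_parameters, x$bic))
  cat("  expected cluster sizes:",
      paste(sprintf("%.1f", x$expected_cluster_sizes), collapse = " "), "\n")
  cat("  dominant signature per cluster:",
      paste(x$dominant_signature, collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.mix_fit <- function(object, ...) {
  list(w = object$params$w, pi = object$params$pi, e = object$params$e)
}

#' @export
logLik.mix_fit <- function(object, ...) {
  p <- object$params
  structure(object$log_likelihood,
            df = parameter_count(length(p$w), nrow(p$e), ncol(p$e),
                                 refit_mode = p$refit),
            nobs = object$total_mutations,
            class = "logLik")
}

#' Number of observations of a Mix fit
#'
#' The iid units of the likelihood are individual mutations, so
#' \code{nobs} is the total mutation count of the training catalog.  This
#' makes \code{stats::BIC(fit)} evaluate the model-selection criterion on
#' the same scale as [bic_score()].
#' @param object A \code{"mix_fit"}.
#' @param ... Unused.
#' @export
nobs.mix_fit <- function(object, ...) object$total_mutations

#' Predict from a fitted Mix model
#'
#' @param object A \code{"mix_fit"}.
#' @param newdata A catalog (defaults are not kept; the training catalog —
#'   or any new one with the same categories — must be supplied).
#' @param type \code{"responsibility"} (N x L posterior),
#'   \code{"cluster"} (hard assignments) or \code{"exposure"}
#'   (per-sample exposures).
#' @param scheme,scale Passed to [infer_exposures()] when
#'   \code{type = "exposure"}.
#' @param ... Unused.
#' @return Matrix or vector according to \code{type}.
#' @export
predict.mix_fit <- function(object, newdata, type = c("responsibility",
                                                      "cluster", "exposure"),
                            scheme = c("soft", "hard"),
                            scale = c("relative", "counts"), ...) {
  type <- match.arg(type)
  switch(type,
    responsibility = mix_responsibilities(newdata, object$params),
    cluster = assign_clusters(newdata, object$params),
    exposure = infer_exposures(newdata, object$params,
                               scheme = match.arg(scheme),
                               scale = match.arg(scale)))
}

#' Simulate catalogs from a fitted Mix model
#'
#' Draws new catalogs from the model's generative process with the same
#' number of samples as the training data; per-sample mutation budgets are
#' resampled from \code{budgets} (default: the package's panel-like pool).
#'
#' @param object A \code{"mix_fit"}.
#' @param nsim Number of catalogs.
#' @param seed Integer seed.
#' @param budgets Integer vector to resample budgets from, or a single
#'   Poisson mean.
#' @param ... Unused.
#' @return A list of \code{nsim} \code{"mutation_catalog"} objects (a
#'   single catalog when \code{nsim = 1}).
#' @export
simulate.mix_fit <- function(object, nsim = 1, seed = NULL, budgets = NULL, ...) {
  if (is.null(budgets)) budgets <- default_budget_pool()
  if (is.null(seed)) seed <- 1L
  out <- lapply(seq_len(nsim), function(s) {
    simulate_catalog(object$params, n_samples = object$n_samples,
                     budgets = budgets, seed = as.integer(seed) + s - 1L)$catalog
  })
  if (nsim == 1) out[[1L]] else out
}

#' Reconstruction residuals of a Mix fit
#'
#' Per-sample difference between the row-normalised observed mutation
#' profile and its reconstruction from soft-clustering exposures,
#' \eqn{\tilde V - E_d \cdot e}.  Rows with zero mutations are NA.
#'
#' @param object A \code{"mix_fit"}.
#' @param catalog The catalog to reconstruct (e.g. the training catalog).
#' @param ... Unused.
#' @return N x M matrix of residuals.
#' @export
residuals.mix_fit <- function(object, catalog, ...) {
  V <- check_catalog(catalog)
  Ed <- infer_exposures(V, object$params, scheme = "soft", scale = "relative")
  Tn <- rowSums(V)
  Vt <- V / ifelse(Tn > 0, Tn, NA_real_)
  res <- Vt - Ed %*% object$params$e
  dimnames(res) <- dimnames(V)
  res
}

#' Plot the signatures of a Mix fit
#'
#' Barplots of each signature's category distribution (base graphics).
#'
#' @param x A \code{"mix_fit"}.
#' @param which Signature indices to plot (default all).
#' @param ... Passed to \code{barplot}.
#' @export
plot.mix_fit <- function(x, which = NULL, ...) {
  e <- x$params$e
  if (is.null(which)) which <- seq_len(nrow(e))
  op <- graphics::par(mfrow = c(length(which), 1L),
                      mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (i in which) {
    graphics::barplot(e[i, ], main = sprintf("signature %d", i),
                      ylab = "probability", border = NA,
                      names.arg = if (ncol(e) <= 16) colnames(e) else NULL,
                      las = 2, ...)
  }
  invisible(x)
}
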