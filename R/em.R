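#' One EM iteration of the Mix model
#'
#' E-step: compute responsibilities \eqn{f^{n,\ell}}, pooled expected
#' emissions \eqn{E_i(j) = \sum_n \sum_\ell f^{n,\ell} E_i(j, V^n, \pi^\ell, e)},
#' per-cluster expected signature usage
#' \eqn{A_i^\ell = \sum_n f^{n,\ell} A_i(V^n, \pi^\ell, e)} and expected
#' cluster occupancies \eqn{W_\ell = \sum_n f^{n,\ell}}.
#' M-step: normalise each of these to new \code{pi}, \code{e}, \code{w}.
#' In refit mode the signature update is skipped and \code{e} is returned
#' unchanged.
#'
#' A component that receives zero total expectation (a cluster with
#' \eqn{W_\ell = 0} or a signature with \eqn{\sum_j E_i(j) = 0}) keeps its
#' previous parameters, with a warning.
#'
#' @inheritParams mix_log_likelihood
#' @return List with \code{params} (updated \code{"mix_params"}),
#'   \code{stats} (list \code{E}, \code{A}, \code{W} of sufficient
#'   statistics) and \code{log_likelihood} — the log-likelihood of the
#'   \emph{input} parameters, a free by-product of the E-step.
#' @examples
#' V <- as_catalog(rbind(s1 = c(2, 0), s2 = c(1, 1)))
#' p <- mix_params(1, rbind(1), rbind(c(0.5, 0.5)))
#' mix_em_step(V, p)$params$e   # pooled empirical frequencies (0.75, 0.25)
#' @export
mix_em_step <- function(catalog, params) {
  V <- check_catalog(catalog)
  validate_mix_params(params)
  if (ncol(V) != ncol(params$e)) stop("catalog and params disagree on M")
  w <- params$w; pi <- params$pi; e <- params$e
  L <- length(w); K <- nrow(e); M <- ncol(e); N <- nrow(V)

  cp <- cluster_log_probs(pi, e)
  ll <- V %*% t(cp$lq)
  if (any(cp$zero)) {
    hits <- V %*% t(cp$zero)
    ll[hits > 0] <- -Inf
  }
  ll <- sweep(ll, 2L, ifelse(w > 0, log(w), -Inf), "+")
  f <- responsibilities_from_loglik(ll, rownames(V))
  loglik <- sum(apply(ll, 1L, logsumexp))

  # pooled statistics: with q[l,j] = sum_i pi[l,i] e[i,j],
  #   G[l,j] = sum_n f[n,l] V[n,j] / q[l,j]
  #   E[i,j] = e[i,j] * sum_l pi[l,i] G[l,j]
  #   A[l,i] = pi[l,i] * sum_j e[i,j] G[l,j]
  q <- pmax(pi %*% e, PROB_FLOOR)
  G <- crossprod(f, V) / q              # L x M
  E <- e * crossprod(pi, G)             # K x M
  A <- pi * (G %*% t(e))                # L x K
  W <- colSums(f)

  new <- m_step(w, pi, e, E, A, W, refit = isTRUE(params$refit))
  new_params <- mix_params(new$w, new$pi, new$e, refit = params$refit,
                           categories = colnames(params$e))
  list(params = new_params,
       stats = list(E = E, A = A, W = W),
       log_likelihood = loglik)
}

# shared M-step normalisation with zero-expectation guard
m_step <- function(w, pi, e, E, A, W, refit) {
  new_w <- W / sum(W)
  new_pi <- pi
  arow <- rowSums(A)
  if (any(arow == 0) || any(W == 0)) {
    warning("cluster with zero expected occupancy: keeping its previous exposures")
  }
  ok <- arow > 0
  new_pi[ok, ] <- A[ok, , drop = FALSE] / arow[ok]
  new_e <- e
  if (!refit) {
    erow <- rowSums(E)
    if (any(erow == 0)) {
      warning("signature with zero expected emissions: keeping its previous profile")
    }
    ok <- erow > 0
    new_e[ok, ] <- E[ok, , drop = FALSE] / erow[ok]
  }
  list(w = new_w, pi = new_pi, e = new_e)
}

# Run the full EM loop via the compiled core.  Returns final parameters,
# the log-likelihood trace (one entry per iteration, evaluated at the
# parameters entering that iteration, plus the final value), iteration
# count and convergence flag.
em_run <- function(V, params, max_iterations = 1000L,
                   tol_abs = 1e-6, tol_rel = 1e-10) {
  tr <- triplets(V)
  res <- mix_em_cpp(tr$i, tr$j, tr$x, nrow(V), ncol(V),
                    params$w, params$pi, params$e,
                    isTRUE(params$refit), as.integer(max_iterations),
                    tol_abs, tol_rel)
  if (res$n_guard > 0L) {
    warning("EM kept previous parameters for ", res$n_guard,
            " zero-expectation component update(s)")
  }
  list(params = mix_params(res$w, res$pi, res$e, refit = params$refit,
                           categories = colnames(params$e)),
       log_likelihood = res$loglik,
       trace = res$trace,
       n_iterations = res$iterations,
       converged = res$converged)
}

# sparse triplet view of a count matrix, sorted by sample for locality
# (0-based indices for the C++ core)
triplets <- function(V) {
  nz <- which(V > 0)
  i <- as.integer((nz - 1L) %% nrow(V))
  ord <- order(i)
  list(i = i[ord],
       j = as.integer((nz - 1L) %/% nrow(V))[ord],
       x = as.numeric(V[nz])[ord])
}

# Dirichlet(1) initialisation of a full parameter set, from the current RNG
random_params <- function(L, K, M, refit_e = NULL, categories = NULL) {
  rdir <- function(n, k) {
    g <- matrix(stats::rgamma(n * k, shape = 1), nrow = n)
    g / rowSums(g)
  }
  w <- as.numeric(rdir(1L, L))
  pi <- rdir(L, K)
  e <- if (is.null(refit_e)) rdir(K, M) else refit_e
  mix_params(w, pi, e, refit = !is.null(refit_e), categories = categories)
}
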