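# Numerical floor for per-category mixture probabilities before taking logs.
# Genuine structural zeros (probability exactly 0 with a positive count) are
# still reported as -Inf / errors; the floor only guards underflow of
# positive probabilities.
PROB_FLOOR <- 1e-300

# log of the per-cluster category mixture matrix q[l, j] = sum_i pi[l,i] e[i,j],
# floored; structural zeros tracked separately.
cluster_log_probs <- function(pi, e) {
  q <- pi %*% e
  lq <- log(pmax(q, PROB_FLOOR))
  list(lq = lq, zero = q == 0)
}

#' Log-likelihood of one sample under a multinomial mixture
#'
#' The probability of a count vector V under signatures \code{e} with
#' relative exposures \code{pi} is
#' \deqn{f(V, \pi, e) = \prod_j \Big(\sum_i \pi_i e_i(j)\Big)^{V_j},}
#' the multinomial mixture likelihood (without the combinatorial constant,
#' which depends only on the data).  Returns \code{log f}, computed in log
#' space; the result is \code{-Inf} exactly when some category with a
#' positive count has mixture probability zero.
#'
#' @param V Non-negative integer count vector of length M.
#' @param pi Probability vector of length K (relative exposures).
#' @param e K x M matrix of signatures.
#' @return The log-likelihood (a scalar, \code{<= 0}).
#' @examples
#' mmm_log_likelihood(c(1, 1), pi = 1, e = rbind(c(0.5, 0.5)))  # log(0.25)
#' @export
mmm_log_likelihood <- function(V, pi, e) {
  e <- as.matrix(e)
  V <- as.numeric(V)
  if (length(pi) != nrow(e)) stop("length(pi) must equal nrow(e)")
  if (length(V) != ncol(e)) stop("length(V) must equal ncol(e)")
  if (any(V < 0)) stop("counts must be non-negative")
  if (any(V != round(V))) stop("counts must be integers")
  q <- as.numeric(pi %*% e)
  pos <- V > 0
  if (any(pos & q == 0)) return(-Inf)
  sum(V[pos] * log(pmax(q[pos], PROB_FLOOR)))
}

#' Expected signature emissions for one sample (MMM E-step)
#'
#' For each signature i and category j, the expected number of mutations of
#' category j emitted by signature i under the posterior of the mixture:
#' \deqn{E_i(j) = V_j \pi_i e_i(j) / \sum_k \pi_k e_k(j),}
#' and the expected total usage \eqn{A_i = \sum_j E_i(j)}.
#'
#' @inheritParams mmm_log_likelihood
#' @return List with \code{E} (K x M matrix) and \code{A} (length-K vector).
#' @export
mmm_expectations <- function(V, pi, e) {
  e <- as.matrix(e)
  V <- as.numeric(V)
  if (length(pi) != nrow(e)) stop("length(pi) must equal nrow(e)")
  if (length(V) != ncol(e)) stop("length(V) must equal ncol(e)")
  if (any(V < 0)) stop("counts must be non-negative")
  q <- as.numeric(pi %*% e)
  bad <- which(V > 0 & q == 0)
  if (length(bad)) {
    stop("category ", bad[1L],
         " has a positive count but zero mixture probability")
  }
  ratio <- ifelse(V > 0, V / q, 0)
  E <- (pi * e) * rep(ratio, each = nrow(e))
  list(E = E, A = rowSums(E))
}

#' Log-likelihood of a catalog under the Mix model
#'
#' \deqn{\log \Pr[V | w, \pi, e] = \sum_n \log \sum_\ell w_\ell
#'   f(V^n, \pi^\ell, e),}
#' computed with a log-sum-exp over clusters.  With a single cluster this
#' reduces exactly to the summed multinomial-mixture log-likelihood.
#'
#' @param catalog A \code{"mutation_catalog"} or count matrix (N x M).
#' @param params A \code{"mix_params"} object.
#' @return Total log-likelihood (scalar).
#' @export
mix_log_likelihood <- function(catalog, params) {
  V <- check_catalog(catalog)
  validate_mix_params(params)
  if (ncol(V) != ncol(params$e)) stop("catalog and params disagree on M")
  sum(sample_log_likelihoods(V, params))
}

# per-sample log sum_l w_l f(V^n, pi^l, e); -Inf rows are genuine
sample_log_likelihoods <- function(V, params) {
  ll <- cluster_loglik_matrix(V, params)  # N x L, includes log w
  apply(ll, 1L, logsumexp)
}

# N x L matrix of log(w_l) + log f(V^n, pi^l, e), exact -Inf for
# structural zeros hit by positive counts
cluster_loglik_matrix <- function(V, params) {
  cp <- cluster_log_probs(params$pi, params$e)
  ll <- V %*% t(cp$lq)
  if (any(cp$zero)) {
    hits <- V %*% t(cp$zero)  # mutations falling on structurally zero categories
    ll[hits > 0] <- -Inf
  }
  lw <- ifelse(params$w > 0, log(params$w), -Inf)
  sweep(ll, 2L, lw, "+")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior cluster probabilities (responsibilities)
#'
#' The E-step quantity
#' \eqn{f^{n,\ell} = w_\ell f(V^n,\pi^\ell,e) / \sum_{\ell'} w_{\ell'}
#' f(V^n,\pi^{\ell'},e)}, normalised in log space.  A sample with zero
#' mutations has likelihood 1 under every cluster, so its posterior equals
#' the prior \code{w}.
#'
#' @inheritParams mix_log_likelihood
#' @return N x L matrix whose rows sum to 1.
#' @export
mix_responsibilities <- function(catalog, params) {
  V <- check_catalog(catalog)
  validate_mix_params(params)
  ll <- cluster_loglik_matrix(V, params)
  resp <- responsibilities_from_loglik(ll, rownames(V))
  dimnames(resp) <- list(rownames(V), paste0("cluster", seq_along(params$w)))
  resp
}

responsibilities_from_loglik <- function(ll, ids = NULL) {
  m <- apply(ll, 1L, max)
  dead <- !is.finite(m)
  if (any(dead)) {
    who <- if (is.null(ids)) which(dead)[1L] else ids[which(dead)[1L]]
    stop("sample ", who, " has zero likelihood under every cluster")
  }
  u <- exp(ll - m)
  u / rowSums(u)
}
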