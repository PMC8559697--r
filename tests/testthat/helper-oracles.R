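# Independent oracles used to freeze expected values.  These deliberately
# follow the definitions term by term (per-mutation products, exhaustive
# grids, permutation enumeration) rather than the package's vectorised or
# compiled code paths.

# Likelihood of one sample as the literal per-mutation product:
# Pr[O] = prod_t sum_i pi_i e_i(o_t), expanding the count vector into the
# observed mutation sequence.  Only usable for small totals.
oracle_mmm_prob <- function(V, pi, e) {
  cats <- rep(seq_along(V), V)
  out <- 1
  for (o in cats) {
    out <- out * sum(pi * e[, o])
  }
  out
}

oracle_mix_loglik <- function(V_mat, w, pi, e) {
  tot <- 0
  for (n in seq_len(nrow(V_mat))) {
    pn <- 0
    for (l in seq_along(w)) {
      pn <- pn + w[l] * oracle_mmm_prob(V_mat[n, ], pi[l, ], e)
    }
    tot <- tot + log(pn)
  }
  tot
}

# Pooled MMM EM step for a whole catalog with shared exposures: the
# single-cluster model's E-step summed over samples, normalised in the
# M-step.  Used as the reduction oracle for Mix with L = 1.
oracle_mmm_em_step <- function(V_mat, pi, e) {
  E <- matrix(0, nrow = nrow(e), ncol = ncol(e))
  A <- numeric(nrow(e))
  for (n in seq_len(nrow(V_mat))) {
    ex <- mmm_expectations(V_mat[n, ], pi, e)
    E <- E + ex$E
    A <- A + ex$A
  }
  list(pi = A / sum(A), e = E / rowSums(E))
}

# Two-stage exhaustive grid search for the 2-signature NNLS toy at final
# resolution 1e-3 (coarse pass at 1e-2, refined around the optimum).
oracle_nnls_grid <- function(v, S, upper = NULL) {
  stopifnot(nrow(S) == 2L)
  if (is.null(upper)) upper <- sum(v) + 1
  eval_grid <- function(g1, g2) {
    best <- c(NA, NA); best_val <- Inf
    for (w1 in g1) {
      vals <- vapply(g2, function(w2) {
        r <- v - (w1 * S[1, ] + w2 * S[2, ])
        sum(r^2)
      }, numeric(1))
      k <- which.min(vals)
      if (vals[k] < best_val) {
        best_val <- vals[k]
        best <- c(w1, g2[k])
      }
    }
    best
  }
  coarse <- eval_grid(seq(0, upper, by = 1e-2), seq(0, upper, by = 1e-2))
  lo <- pmax(coarse - 2e-2, 0)
  eval_grid(seq(lo[1], coarse[1] + 2e-2, by = 1e-3),
            seq(lo[2], coarse[2] + 2e-2, by = 1e-3))
}

# Brute-force maximum-total-score assignment by permutation enumeration
# (rows of `score` to distinct columns), for small instances.
oracle_assignment <- function(score) {
  K <- nrow(score); R <- ncol(score)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_val <- -Inf
  for (cols in perms(seq_len(R))) {
    pick <- cols[seq_len(K)]
    val <- sum(score[cbind(seq_len(K), pick)])
    if (val > best_val + 1e-12) {
      best_val <- val; best <- pick
    }
  }
  list(assignment = best, total = best_val)
}

# random valid parameter set from the current RNG
rand_params <- function(L, K, M, refit = FALSE) {
  rdir <- function(n, k) {
    g <- matrix(rgamma(n * k, 1), nrow = n)
    g / rowSums(g)
  }
  mix_params(as.numeric(rdir(1, L)), rdir(L, K), rdir(K, M), refit = refit)
}

rand_catalog <- function(N, M, lambda = 2) {
  as_catalog(matrix(rpois(N * M, lambda), nrow = N))
}
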