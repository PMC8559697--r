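# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default base model for synthetic-data generation
#'
#' A documented, fixed Mix parameter set playing the role of a model
#' trained on a large pan-cancer panel cohort: 10 clusters and 6
#' signatures over the 96 SBS categories.  Because the reference for such
#' a base is itself a BIC-selected model, the construction is required to
#' be \emph{self-consistently identifiable}: a BIC grid run on a
#' 5000-sample panel-sparse catalog generated from this base recovers
#' (L = 10, K = 6), and the subsetted ground truths drawn from it (the
#' study's 5-9 cluster, 4-signature settings) never contain effectively
#' duplicate clusters.
#'
#' Concretely: signatures are sparse Dirichlet draws (concentration
#' 0.05), giving distinct, COSMIC-like concentrated profiles.  Each
#' cluster's exposure row is a sorted normalised Gamma draw with shape
#' (t_l, 2, 1, 0.3, 0.3, 0.3) — two to three dominant signatures over a
#' varied low background, with the dominance strength t_l varying across
#' clusters from 2.5 to 8.  Shares are assigned to signatures preferring
#' the least-used signature (keeping the marginal usage of all six
#' balanced, as it must be for each signature to justify its own BIC
#' cost), subject to a distinguishability constraint: a row is accepted
#' only if, under \emph{every} 4-signature subset, its renormalised
#' projection stays below cosine 0.98 to every previously accepted
#' cluster — the property that makes each subsetted ground truth
#' identifiable, as the clusters of a BIC-selected model are.  Cluster
#' priors are a moderately balanced Dirichlet(5) draw.  The construction
#' is deterministic (fixed internal seed) and cached within the session.
#'
#' @return A \code{"mix_params"} object (L = 10, K = 6, M = 96).
#' @seealso [build_ground_truth()], [simulate_catalog()]
#' @export
default_base_model <- function() {
  if (!is.null(.mixmm_cache$base)) return(.mixmm_cache$base)
  base <- with_seed(20211101L, {
    L <- 10L; K <- 6L; M <- 96L
    e <- matrix(stats::rgamma(K * M, shape = 0.05), nrow = K)
    e <- e / rowSums(e)
    w <- stats::rgamma(L, shape = 5)
    w <- w / sum(w)
    tops <- c(8, 2.5, 5, 3, 6, 2.8, 4, 3.5, 7, 4.5)
    subsets <- utils::combn(K, 4L)
    proj_close <- function(a, b) {
      for (s in seq_len(ncol(subsets))) {
        i <- subsets[, s]
        x <- a[i] / sum(a[i]); y <- b[i] / sum(b[i])
        if (sum(x * y) / sqrt(sum(x^2) * sum(y^2)) > 0.98) return(TRUE)
      }
      FALSE
    }
    perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == K), ]
    pi <- matrix(0, nrow = L, ncol = K)
    usage <- rep(0, K)
    for (l in seq_len(L)) {
      chosen <- NULL; fallback <- NULL
      for (draw in 1:50) {
        g <- stats::rgamma(K, shape = c(tops[l], 2, 1, 0.3, 0.3, 0.3))
        shares <- sort(g / sum(g), decreasing = TRUE)
        # candidate assignments, best usage balance first
        score <- apply(perms, 1L, function(p) sum(shares * usage[p]))
        ord <- order(score)
        if (is.null(fallback)) {
          p <- perms[ord[1L], ]; fallback <- numeric(K); fallback[p] <- shares
        }
        for (cand in ord) {
          p <- perms[cand, ]
          row <- numeric(K); row[p] <- shares
          ok <- TRUE
          if (l > 1L) {
            for (m in seq_len(l - 1L)) {
              if (proj_close(row, pi[m, ])) { ok <- FALSE; break }
            }
          }
          if (ok) { chosen <- row; break }
        }
        if (!is.null(chosen)) break
      }
      if (is.null(chosen)) chosen <- fallback
      pi[l, ] <- chosen
      usage <- usage + w[l] * chosen
    }
    mix_params(w, pi, e, categories = sbs96_categories())
  })
  .mixmm_cache$base <- base
  base
}

.mixmm_cache <- new.env(parent = emptyenv())

#' Default per-sample mutation budget pool
#'
#' An empirical-style pool of per-sample mutation totals to resample from,
#' emulating a targeted-panel cohort: long-tailed, minimum 1, mean about 7
#' mutations per sample (1 + negative binomial, size 1.5, mean 6).  The
#' pool is deterministic (fixed internal seed).
#'
#' @param n Pool size (default 500).
#' @return Integer vector of length \code{n}.
#' @export
default_budget_pool <- function(n = 500L) {
  with_seed(19680402L, 1L + stats::rnbinom(n, size = 1.5, mu = 6))
}

#' Build a simulation ground truth by subsampling a base model
#'
#' The synthetic-data construction: draw \code{L_sub} clusters from the
#' base model without replacement with probabilities \code{w}, renormalise
#' the selected priors; compute the marginal signature usage
#' \eqn{p_k = \sum_\ell w_\ell \pi^\ell_k} on the selected clusters; draw
#' \code{K_sub} signatures without replacement with probabilities
#' \eqn{p_k}; restrict exposures to the selected signatures and
#' renormalise each cluster's row to sum to 1.
#'
#' @param base A \code{"mix_params"} base model (default
#'   [default_base_model()]).
#' @param L_sub Number of clusters to keep.
#' @param K_sub Number of signatures to keep.
#' @param seed Integer seed.
#' @return A \code{"mix_params"} object with attributes
#'   \code{"clusters"} and \code{"signatures"} recording the selected
#'   base-model indices (in draw order).
#' @export
build_ground_truth <- function(base = default_base_model(), L_sub, K_sub, seed) {
  validate_mix_params(base)
  L <- length(base$w); K <- nrow(base$e)
  if (L_sub > L) stop("L_sub exceeds the base model's cluster count")
  if (K_sub > K) stop("K_sub exceeds the base model's signature count")
  with_seed(seed, {
    cl <- sample.int(L, L_sub, replace = FALSE, prob = base$w)
    w <- base$w[cl] / sum(base$w[cl])
    pi_sel <- base$pi[cl, , drop = FALSE]
    p <- as.numeric(w %*% pi_sel)           # marginal signature usage
    sg <- sample.int(K, K_sub, replace = FALSE, prob = p)
    pi <- pi_sel[, sg, drop = FALSE]
    pi <- pi / rowSums(pi)
    out <- mix_params(w, pi, base$e[sg, , drop = FALSE],
                      categories = colnames(base$e))
    attr(out, "clusters") <- cl
    attr(out, "signatures") <- sg
    out
  })
}

#' Generate a synthetic catalog from a Mix model
#'
#' The model's generative process: for each sample draw a cluster
#' \eqn{c^n \sim w}; draw a mutation budget \eqn{T_n}, either uniformly
#' with replacement from the empirical pool \code{budgets} or from
#' \eqn{Pois(\code{budget_mean})}; draw \eqn{T_n} signatures iid from
#' \eqn{\pi^{c^n}}; draw each mutation's category from the corresponding
#' signature.
#'
#' @param params A \code{"mix_params"} object.
#' @param n_samples Number of samples to generate.
#' @param budgets Integer vector of totals to resample uniformly with
#'   replacement (default [default_budget_pool()]).  Mutually exclusive
#'   with \code{budget_mean}.
#' @param budget_mean Poisson mean for per-sample totals.
#' @param seed Integer seed.
#' @return List with \code{catalog} (a \code{"mutation_catalog"}) and
#'   \code{truth}: a list with \code{params}, \code{cluster_assignments}
#'   (length N), \code{signature_counts} (N x K realized emissions per
#'   signature) and \code{mutation_budgets} (length N).
#' @export
simulate_catalog <- function(params, n_samples, budgets = NULL,
                             budget_mean = NULL, seed = 1L) {
  validate_mix_params(params)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (is.null(budgets) && is.null(budget_mean)) budgets <- default_budget_pool()
  if (!is.null(budgets) && !is.null(budget_mean)) {
    stop("give either budgets or budget_mean, not both")
  }
  if (!is.null(budgets) && !length(budgets)) stop("empty budget list")
  L <- length(params$w); K <- nrow(params$e); M <- ncol(params$e)
  with_seed(seed, {
    cl <- sample.int(L, n_samples, replace = TRUE, prob = params$w)
    Tn <- if (!is.null(budgets)) {
      as.integer(budgets)[sample.int(length(budgets), n_samples, replace = TRUE)]
    } else {
      stats::rpois(n_samples, budget_mean)
    }
    V <- matrix(0, nrow = n_samples, ncol = M)
    sig_counts <- matrix(0L, nrow = n_samples, ncol = K)
    for (n in seq_len(n_samples)) {
      if (Tn[n] == 0L) next
      z <- sample.int(K, Tn[n], replace = TRUE, prob = params$pi[cl[n], ])
      zc <- tabulate(z, nbins = K)
      sig_counts[n, ] <- zc
      for (i in which(zc > 0L)) {
        V[n, ] <- V[n, ] + stats::rmultinom(1L, zc[i], params$e[i, ])
      }
    }
    catalog <- as_catalog(V, sample_ids = sprintf("sim%05d", seq_len(n_samples)),
                          categories = colnames(params$e))
    list(catalog = catalog,
         truth = list(params = params,
                      cluster_assignments = cl,
                      signature_counts = sig_counts,
                      mutation_budgets = Tn))
  })
}

#' Poisson downsampling of a catalog
#'
#' Emulates shallow targeted sequencing: for each sample draw
#' \eqn{n_i \sim Pois(d)} and keep a uniform subset of
#' \eqn{\min(n_i, T_i)} of its mutations, sampled without replacement from
#' the sample's mutation multiset.
#'
#' @param catalog A \code{"mutation_catalog"} or count matrix.
#' @param d Target mean number of retained mutations per sample (> 0).
#' @param seed Integer seed.
#' @return A downsampled \code{"mutation_catalog"} (elementwise \code{<=}
#'   the input).
#' @export
poisson_downsample <- function(catalog, d, seed = 1L) {
  V <- check_catalog(catalog)
  if (d <= 0) stop("d must be > 0")
  M <- ncol(V)
  with_seed(seed, {
    keep <- stats::rpois(nrow(V), d)
    out <- V
    for (n in seq_len(nrow(V))) {
      Tn <- sum(V[n, ])
      k <- min(keep[n], Tn)
      if (k >= Tn) next
      if (k == 0L) { out[n, ] <- 0; next }
      pool <- rep.int(seq_len(M), V[n, ])
      out[n, ] <- tabulate(sample(pool, k, replace = FALSE), nbins = M)
    }
    as_catalog(out, sample_ids = rownames(V), categories = colnames(V))
  })
}
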