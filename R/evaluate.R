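#' Non-negative least-squares exposures
#'
#' The standard refitting baseline for rich data: for each sample row
#' \eqn{V_n}, finds the non-negative exposure vector minimising
#' \eqn{\|V_n - x^\top S\|_2} against the fixed signature matrix S
#' (Lawson-Hanson NNLS).
#'
#' @param V N x M count (or profile) matrix.
#' @param S K x M signature matrix, rows summing to 1.
#' @return N x K non-negative exposure matrix.
#' @export
nnls_exposures <- function(V, S) {
  V <- as.matrix(V); S <- as.matrix(S)
  if (ncol(V) != ncol(S)) stop("V and S disagree on the number of categories")
  if (any(abs(rowSums(S) - 1) > 1e-6)) stop("signature rows must sum to 1")
  if (qr(S)$rank < nrow(S)) warning("signature matrix is rank-deficient")
  A <- t(S)
  rows <- lapply(seq_len(nrow(V)), function(n) {
    v <- V[n, ]
    if (all(v == 0)) return(numeric(nrow(S)))
    pracma::lsqnonneg(A, as.numeric(v))$x
  })
  E <- do.call(rbind, rows)
  dimnames(E) <- list(rownames(V), rownames(S))
  E
}

# row-normalise, leaving zero rows as zero
row_normalize <- function(X) {
  rs <- rowSums(X)
  X / ifelse(rs > 0, rs, 1)
}

#' Reconstruction error (RE)
#'
#' Per-sample L1 distance between the row-normalised full mutation profile
#' \eqn{\tilde V} and its reconstruction \eqn{E_d \cdot S} from relative
#' exposures inferred on (possibly downsampled) data:
#' \eqn{RE = |\tilde V - E_d S|_1}.  Samples with zero mutations in
#' \code{V_full} (or an all-zero exposure row) are skipped.
#'
#' @param V_full N x M count matrix of the full (rich) catalog.
#' @param E_d N x K relative exposure matrix (rows sum to 1).
#' @param S K x M signature matrix.
#' @return List with \code{per_sample} (named vector, NA for skipped
#'   samples), \code{mean} over evaluable samples and \code{n_evaluated}.
#' @export
reconstruction_error <- function(V_full, E_d, S) {
  V_full <- as.matrix(V_full); E_d <- as.matrix(E_d); S <- as.matrix(S)
  if (nrow(V_full) != nrow(E_d)) stop("V_full and E_d disagree on N")
  if (ncol(E_d) != nrow(S) || ncol(V_full) != ncol(S)) stop("dimension mismatch")
  evaluable <- rowSums(V_full) > 0 & rowSums(E_d) > 0
  Vt <- row_normalize(V_full)
  err <- rowSums(abs(Vt - E_d %*% S))
  err[!evaluable] <- NA_real_
  names(err) <- rownames(V_full)
  list(per_sample = err, mean = mean(err[evaluable]),
       n_evaluated = sum(evaluable))
}

#' Exposure reconstruction error (ERE)
#'
#' Per-sample L1 distance between row-normalised reference exposures
#' \eqn{\tilde E} (e.g. NNLS on the full data) and relative exposures
#' \eqn{E_d} inferred on downsampled data: \eqn{ERE = |\tilde E - E_d|_1}.
#' Samples whose reference exposure row is all zero are skipped with a
#' warning.
#'
#' @param E_true N x K non-negative reference exposures (will be
#'   row-normalised).
#' @param E_d N x K relative exposures.
#' @return List with \code{per_sample}, \code{mean}, \code{n_evaluated}.
#' @export
exposure_reconstruction_error <- function(E_true, E_d) {
  E_true <- as.matrix(E_true); E_d <- as.matrix(E_d)
  if (!all(dim(E_true) == dim(E_d))) stop("E_true and E_d dimensions differ")
  evaluable <- rowSums(E_true) > 0
  if (!all(evaluable)) {
    warning(sum(!evaluable), " sample(s) with all-zero reference exposures skipped")
  }
  err <- rowSums(abs(row_normalize(E_true) - E_d))
  err[!evaluable] <- NA_real_
  names(err) <- rownames(E_true)
  list(per_sample = err, mean = mean(err[evaluable]),
       n_evaluated = sum(evaluable))
}

#' Cosine similarity matrix between signature sets
#'
#' @param A K x M matrix (rows compared).
#' @param B R x M matrix.
#' @return K x R matrix of cosine similarities.
#' @export
cosine_similarity <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B disagree on M")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-vector signature")
  (A %*% t(B)) / outer(na, nb)
}

#' Match learned signatures to a reference set
#'
#' \code{mode = "best_match"} pairs every learned signature with its
#' maximum-cosine reference (repeats allowed), as used when reporting
#' learned signatures against a catalogue of known signatures.
#' \code{mode = "one_to_one"} solves the assignment problem maximising
#' total cosine (Hungarian algorithm), requiring distinct references —
#' used for parameter-recovery scoring.  Cosine ties break to the lowest
#' reference index.
#'
#' @param learned K x M matrix.
#' @param reference R x M matrix (R >= K for one-to-one mode).
#' @param mode \code{"best_match"} or \code{"one_to_one"}.
#' @return List of class \code{"signature_match"}: \code{pairs}
#'   (data.frame learned, reference, cosine), \code{mode},
#'   \code{mean_cosine}.
#' @export
match_signatures <- function(learned, reference,
                             mode = c("best_match", "one_to_one")) {
  mode <- match.arg(mode)
  cs <- cosine_similarity(learned, reference)
  K <- nrow(cs); R <- ncol(cs)
  if (mode == "best_match") {
    ref <- apply(cs, 1L, which.max)   # which.max takes the first (lowest) tie
    cosv <- cs[cbind(seq_len(K), ref)]
  } else {
    if (K > R) stop("one_to_one matching needs at least as many references")
    ref <- hungarian_max(cs)
    cosv <- cs[cbind(seq_len(K), ref)]
  }
  structure(list(pairs = data.frame(learned = seq_len(K), reference = ref,
                                    cosine = cosv),
                 mode = mode, mean_cosine = mean(cosv)),
            class = "signature_match")
}

#' @export
print.signature_match <- function(x, ...) {
  cat(sprintf("Signature matching (%s): mean cosine %.4f\n",
              x$mode, x$mean_cosine))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

# Hungarian algorithm (potentials formulation) on a K x R score matrix,
# K <= R, maximising total score.  Returns the column assigned to each row.
# Ties favour lower column indices through strict-inequality updates.
hungarian_max <- function(score) {
  K <- nrow(score); R <- ncol(score)
  cost <- max(score) - score            # minimise
  INF <- .Machine$double.xmax / 4
  u <- numeric(K + 1L); v <- numeric(R + 1L)
  p <- integer(R + 1L)                  # p[j]: row assigned to column j
  for (i in seq_len(K)) {
    p[R + 1L] <- i
    j0 <- R + 1L
    minv <- rep(INF, R + 1L)
    used <- rep(FALSE, R + 1L)
    way <- integer(R + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(R)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(R + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == R + 1L) break
    }
  }
  assign <- integer(K)
  for (j in seq_len(R)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model and normalised by \eqn{\max(H(a), H(b))}:
#' \deqn{AMI = (MI - E[MI]) / (\max(H_a, H_b) - E[MI]).}
#' Equals 1 for identical partitions up to relabelling, is about 0 for
#' independent partitions (and can be slightly negative).  Two constant
#' partitions are identical, giving 1 by convention; one constant
#' partition carries no information, giving 0.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return The AMI score (scalar).
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (!length(labels_a)) stop("empty input")
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  N <- length(labels_a)
  if (N < 2L) stop("need at least 2 items")
  tab <- unclass(table(labels_a, labels_b))
  a <- unname(rowSums(tab)); b <- unname(colSums(tab))
  Ha <- entropy_counts(a, N); Hb <- entropy_counts(b, N)
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / N * log(N * nij / (a[i] * b[j]))
    }
  }
  emi <- expected_mi(a, b, N)
  (mi - emi) / (max(Ha, Hb) - emi)
}

entropy_counts <- function(cnt, N) {
  p <- cnt[cnt > 0] / N
  -sum(p * log(p))
}

# E[MI] under the permutation model: sum over cells and over the
# hypergeometric support of n_ij, with log-factorial weights.
expected_mi <- function(a, b, N) {
  lf <- lgamma(seq_len(N + 1L))           # lf[x+1] = log(x!)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        term <- nij / N * log(N * nij / (ai * bj))
        lp <- lf[ai + 1L] + lf[bj + 1L] + lf[N - ai + 1L] + lf[N - bj + 1L] -
          lf[N + 1L] - lf[nij + 1L] - lf[ai - nij + 1L] - lf[bj - nij + 1L] -
          lf[N - ai - bj + nij + 1L]
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Write a metric report
#'
#' Writes per-sample RE/ERE as TSV (sample_id, re, ere) and a JSON summary
#' \code{{mean_re, mean_ere, n_evaluated}}.
#'
#' @param re Result of [reconstruction_error()].
#' @param ere Result of [exposure_reconstruction_error()] (optional).
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, a list with the summary values.
#' @export
write_metric_report <- function(re, ere = NULL, tsv_path = NULL,
                                json_path = NULL) {
  ids <- names(re$per_sample)
  df <- data.frame(sample_id = if (is.null(ids)) seq_along(re$per_sample) else ids,
                   re = unname(re$per_sample),
                   ere = if (is.null(ere)) NA_real_ else unname(ere$per_sample))
  if (!is.null(tsv_path)) {
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(mean_re = re$mean,
                  mean_ere = if (is.null(ere)) NULL else ere$mean,
                  n_evaluated = re$n_evaluated)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(summary)
}
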