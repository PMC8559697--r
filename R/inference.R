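#' Hard cluster assignment
#'
#' Assigns each sample to the cluster with maximal posterior probability;
#' posterior ties go to the lowest cluster index.
#'
#' @inheritParams mix_log_likelihood
#' @return Integer vector of 1-based cluster indices, named by sample.
#' @export
assign_clusters <- function(catalog, params) {
  resp <- mix_responsibilities(catalog, params)
  out <- apply(resp, 1L, which.max)
  names(out) <- rownames(resp)
  out
}

#' Per-sample signature exposures
#'
#' Hard clustering takes the exposure row of the maximum-posterior cluster,
#' \eqn{E = \pi^{\ell^*}}; soft clustering takes the posterior-weighted sum
#' \eqn{E = \sum_\ell f^{n,\ell} \pi^\ell}.  Both yield relative exposures
#' (rows summing to 1); \code{scale = "counts"} multiplies row n by the
#' sample's mutation total \eqn{T_n} to obtain absolute exposures.
#'
#' @inheritParams mix_log_likelihood
#' @param scheme \code{"soft"} (default, recommended for exposures) or
#'   \code{"hard"}.
#' @param scale \code{"relative"} (default) or \code{"counts"}.
#' @return N x K exposure matrix with attributes \code{scheme} and
#'   \code{scale}.
#' @export
infer_exposures <- function(catalog, params,
                            scheme = c("soft", "hard"),
                            scale = c("relative", "counts")) {
  scheme <- match.arg(scheme)
  scale <- match.arg(scale)
  V <- check_catalog(catalog)
  resp <- mix_responsibilities(V, params)
  E <- if (scheme == "soft") {
    resp %*% params$pi
  } else {
    params$pi[apply(resp, 1L, which.max), , drop = FALSE]
  }
  if (scale == "counts") E <- E * rowSums(V)
  dimnames(E) <- list(rownames(V), paste0("sig", seq_len(ncol(E))))
  structure(E, scheme = scheme, scale = scale)
}

#' Write an exposure matrix to TSV
#'
#' Rows are sample ids, columns signature names.
#'
#' @param exposures Matrix from [infer_exposures()] (or any N x K matrix
#'   with dimnames).
#' @param path Output path.
#' @param signature_names Optional replacement column names.
#' @return Invisibly, \code{path}.
#' @export
write_exposures <- function(exposures, path, signature_names = NULL) {
  E <- as.matrix(exposures)
  if (!is.null(signature_names)) colnames(E) <- signature_names
  df <- cbind(data.frame(sample_id = rownames(E)),
              as.data.frame(E, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hard cluster assignments to TSV
#'
#' Columns: sample_id, cluster (1-based index) and the maximal posterior.
#'
#' @inheritParams mix_log_likelihood
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_clusters <- function(catalog, params, path) {
  resp <- mix_responsibilities(catalog, params)
  df <- data.frame(sample_id = rownames(resp),
                   cluster = apply(resp, 1L, which.max),
                   posterior_max = apply(resp, 1L, max))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
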