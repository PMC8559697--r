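#' Construct a Mix parameter set
#'
#' The full state of the model: cluster prior probabilities \code{w}
#' (length L), per-cluster relative exposures \code{pi} (L x K, rows sum
#' to 1) and shared signatures \code{e} (K x M, rows sum to 1).  In
#' refitting mode the signatures are fixed and are not updated by EM.
#'
#' @param w Numeric probability vector of cluster priors.
#' @param pi L x K matrix of per-cluster signature exposures.
#' @param e K x M matrix of signatures (rows are probability vectors over
#'   mutation categories).
#' @param refit Logical; \code{TRUE} marks \code{e} as frozen.
#' @param categories Optional category labels for the columns of \code{e}.
#' @return A list of class \code{"mix_params"} with elements
#'   \code{w}, \code{pi}, \code{e}, \code{refit}.
#' @examples
#' p <- mix_params(w = c(0.5, 0.5),
#'                 pi = rbind(c(1, 0), c(0, 1)),
#'                 e  = rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' p$w
#' @export
mix_params <- function(w, pi, e, refit = FALSE, categories = NULL) {
  w <- as.numeric(w)
  pi <- as.matrix(pi)
  e <- as.matrix(e)
  storage.mode(pi) <- storage.mode(e) <- "double"
  if (!is.null(categories)) {
    if (length(categories) != ncol(e)) stop("categories length != ncol(e)")
    colnames(e) <- categories
  }
  obj <- structure(list(w = w, pi = pi, e = e, refit = isTRUE(refit)),
                   class = "mix_params")
  validate_mix_params(obj)
  obj
}

#' Validate Mix parameter invariants
#'
#' Checks dimensions, non-negativity and that \code{w} and every row of
#' \code{pi} and \code{e} sum to 1 within \code{tol}.
#'
#' @param params A \code{"mix_params"} object (or compatible list).
#' @param tol Tolerance on the unit-sum constraints.
#' @return Invisibly, \code{params}; errors on violation.
#' @export
validate_mix_params <- function(params, tol = 1e-9) {
  w <- params$w; pi <- params$pi; e <- params$e
  L <- length(w); K <- nrow(pi); M <- ncol(e)
  if (L < 1L || K < 1L || ncol(e) < 1L) stop("need L >= 1, K >= 1")
  if (nrow(pi) != L) stop(sprintf("pi has %d rows but w has length %d", nrow(pi), L))
  if (ncol(pi) != nrow(e)) {
    stop(sprintf("pi has %d columns but e has %d rows", ncol(pi), nrow(e)))
  }
  if (any(w < 0) || any(pi < 0) || any(e < 0)) stop("probabilities must be >= 0")
  if (abs(sum(w) - 1) > tol) stop("w must sum to 1")
  if (any(abs(rowSums(pi) - 1) > tol)) stop("rows of pi must sum to 1")
  if (any(abs(rowSums(e) - 1) > tol)) stop("rows of e must sum to 1")
  invisible(params)
}

#' @export
print.mix_params <- function(x, ...) {
  cat(sprintf("Mix parameters: L = %d clusters, K = %d signatures, M = %d categories%s\n",
              length(x$w), nrow(x$e), ncol(x$e),
              if (isTRUE(x$refit)) " (refit mode: signatures fixed)" else ""))
  cat("  w:", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a Mix model to JSON
#'
#' Writes \code{w}, \code{pi}, \code{e} (row-major arrays), the category
#' labels, the refit flag and a metadata block to a JSON file, at full
#' double precision.
#'
#' @param params A \code{"mix_params"} or \code{"mix_fit"} object.
#' @param path Output path.
#' @param meta Optional named list of metadata (seed, loglik, iterations);
#'   filled automatically for a fitted model.
#' @return Invisibly, \code{path}.
#' @seealso [read_mix_model()]
#' @export
write_mix_model <- function(params, path, meta = NULL) {
  if (inherits(params, "mix_fit")) {
    if (is.null(meta)) {
      meta <- list(seed = params$seed, loglik = params$log_likelihood,
                   iterations = params$n_iterations)
    }
    params <- params$params
  }
  obj <- list(
    w = params$w,
    pi = apply(params$pi, 1L, identity, simplify = FALSE),
    e = apply(params$e, 1L, identity, simplify = FALSE),
    category_labels = colnames(params$e),
    refit_mode = isTRUE(params$refit),
    meta = if (is.null(meta)) structure(list(), names = character()) else meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a Mix model from JSON
#'
#' @param path Path written by [write_mix_model()].
#' @return A \code{"mix_params"} object; metadata (if any) is attached as
#'   attribute \code{"meta"}.
#' @export
read_mix_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pi <- obj$pi
  e <- obj$e
  if (is.list(pi)) pi <- do.call(rbind, pi)
  if (is.list(e)) e <- do.call(rbind, e)
  p <- mix_params(w = obj$w, pi = pi, e = e, refit = isTRUE(obj$refit_mode),
                  categories = obj$category_labels)
  if (!is.null(obj$meta) && length(obj$meta)) attr(p, "meta") <- obj$meta
  p
}
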