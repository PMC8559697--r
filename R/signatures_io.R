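#' Read a signature matrix in COSMIC v2 layout
#'
#' Tab-delimited, one row per SBS-96 context with a
#' \code{"Somatic Mutation Type"} column carrying the \code{"A[C>A]A"}
#' style label, and one column per signature.  Signature columns are
#' reordered to the canonical category order and renormalised to sum
#' exactly to 1, with a warning for noticeable deviations; a column off by
#' more than 1e-3 is rejected.
#'
#' @param path Path to the signature file.
#' @param subset Optional character vector of signature column names to
#'   load, in the requested order.
#' @return K x 96 matrix, rows named by signature, columns by category.
#' @seealso [write_signatures()]
#' @export
read_signatures <- function(path, subset = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  type_col <- which(names(df) == "Somatic Mutation Type")
  if (!length(type_col)) stop("no 'Somatic Mutation Type' column in ", path)
  labs <- as.character(df[[type_col[1L]]])
  if (!setequal(labs, sbs96_categories()) || anyDuplicated(labs)) {
    stop("'Somatic Mutation Type' values are not the SBS-96 label set in ", path)
  }
  drop <- names(df) %in% c("Substitution Type", "Trinucleotide",
                           "Somatic Mutation Type")
  sig <- df[, !drop, drop = FALSE]
  numeric_cols <- vapply(sig, is.numeric, logical(1L))
  sig <- sig[, numeric_cols, drop = FALSE]
  if (!ncol(sig)) stop("no numeric signature columns in ", path)
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(sig))
    if (length(missing)) {
      stop("signature(s) not in file: ", paste(missing, collapse = ", "),
           "; available: ", paste(names(sig), collapse = ", "))
    }
    sig <- sig[, subset, drop = FALSE]
  }
  S <- t(as.matrix(sig))
  colnames(S) <- labs
  S <- S[, sbs96_categories(), drop = FALSE]
  if (any(S < 0)) stop("negative signature entry in ", path)
  sums <- rowSums(S)
  if (any(abs(sums - 1) > 1e-3 + 1e-12)) {
    stop("signature column(s) ",
         paste(rownames(S)[abs(sums - 1) > 1e-3 + 1e-12], collapse = ", "),
         " deviate from unit sum by more than 1e-3 in ", path)
  }
  off <- abs(sums - 1) > 1e-8
  if (any(off)) {
    warning("renormalising signature column(s) ",
            paste(rownames(S)[off], collapse = ", "),
            " to unit sum")
  }
  S / sums
}

#' Write a signature matrix in COSMIC v2 layout
#'
#' @param S K x 96 signature matrix with SBS-96 column labels.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_signatures <- function(S, path) {
  S <- as.matrix(S)
  labs <- colnames(S)
  if (is.null(labs) || !setequal(labs, sbs96_categories())) {
    stop("S must have the SBS-96 category labels as colnames")
  }
  S <- S[, sbs96_categories(), drop = FALSE]
  if (is.null(rownames(S))) rownames(S) <- paste0("Signature ", seq_len(nrow(S)))
  labs <- sbs96_categories()
  df <- data.frame(
    `Substitution Type` = substr(labs, 3L, 5L),
    Trinucleotide = paste0(substr(labs, 1L, 1L), substr(labs, 3L, 3L),
                           substr(labs, 7L, 7L)),
    `Somatic Mutation Type` = labs,
    check.names = FALSE)
  df <- cbind(df, as.data.frame(t(S), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
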