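#' Construct a mutation catalog
#'
#' A mutation catalog is the observed data of the model: an N x M matrix of
#' non-negative integer counts, one row per sample and one column per
#' mutation category (SBS-96 by default).  Internally a catalog is a plain
#' numeric matrix with unique rownames (sample identifiers) and colnames
#' (category labels); this constructor validates and normalises the input.
#'
#' @param counts Matrix-like object of non-negative integer counts,
#'   samples in rows.
#' @param sample_ids Optional character vector of unique sample identifiers;
#'   defaults to existing rownames or \code{"sample1"...}.
#' @param categories Optional character vector of category labels; defaults
#'   to existing colnames, or to \code{sbs96_categories()} when the catalog
#'   has 96 columns.
#' @return A numeric matrix of class \code{"mutation_catalog"} with
#'   \code{dimnames} set.
#' @examples
#' V <- as_catalog(rbind(a = c(2, 0, 1), b = c(0, 3, 0)),
#'                 categories = c("x", "y", "z"))
#' rowSums(V)
#' @export
as_catalog <- function(counts, sample_ids = NULL, categories = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) {
    stop("a mutation catalog needs at least 2 categories (columns)")
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("catalog counts contain NA")
  if (any(counts < 0)) stop("catalog counts must be non-negative")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("catalog counts must be integers; cell (%d, %d) is not",
                 bad[1L], bad[2L]))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) {
      sample_ids <- if (nrow(counts)) paste0("sample", seq_len(nrow(counts)))
                    else character(0)
    }
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(counts)) stop("sample_ids length != rows")
  if (is.null(categories)) {
    categories <- colnames(counts)
    if (is.null(categories)) {
      categories <- if (ncol(counts) == 96L) sbs96_categories()
                    else paste0("cat", seq_len(ncol(counts)))
    }
  }
  if (length(categories) != ncol(counts)) stop("categories length != columns")
  dimnames(counts) <- list(sample_ids, categories)
  class(counts) <- c("mutation_catalog", class(counts))
  counts
}

# accept either a mutation_catalog or a bare count matrix
check_catalog <- function(catalog) {
  if (inherits(catalog, "mutation_catalog")) return(unclass(catalog))
  unclass(as_catalog(catalog))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("Mutation catalog: %d samples x %d categories, %d mutations\n",
              nrow(x), ncol(x), as.integer(sum(x))))
  cat(sprintf("  mutations per sample: mean %.2f, range [%d, %d]\n",
              mean(rowSums(x)), as.integer(min(rowSums(x))),
              as.integer(max(rowSums(x)))))
  invisible(x)
}

#' Read a mutation catalog from TSV
#'
#' Expects samples in rows: a header of category labels, first column
#' \code{sample_id}.  When the labels are the SBS-96 set the columns are
#' reordered to the canonical COSMIC order of \code{sbs96_categories()}.
#'
#' @param path Path to a tab-separated catalog file.
#' @return A \code{"mutation_catalog"} matrix.
#' @seealso [write_catalog()]
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("catalog file needs a sample_id column plus >= 2 categories")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  labs <- colnames(m)
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad)) {
      stop(sprintf("invalid count '%s' at row %d, column '%s' of %s",
                   m[bad[1L], j], bad[1L], labs[j], path))
    }
  }
  storage.mode(m) <- "double"
  if (setequal(labs, sbs96_categories())) {
    if (anyDuplicated(labs)) stop("duplicate category labels in ", path)
    m <- m[, sbs96_categories(), drop = FALSE]
  } else if (all(is_sbs96_label(labs))) {
    stop("category labels look like SBS-96 but do not form the full 96-set in ",
         path, "; missing: ",
         paste(utils::head(setdiff(sbs96_categories(), labs), 5L), collapse = ", "))
  }
  as_catalog(m, sample_ids = ids)
}

#' Write a mutation catalog to TSV
#'
#' @param catalog A \code{"mutation_catalog"} (or count matrix).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_catalog <- function(catalog, path) {
  V <- check_catalog(catalog)
  df <- data.frame(sample_id = rownames(V), check.names = FALSE)
  df <- cbind(df, as.data.frame(V, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
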