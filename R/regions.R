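#' Read a BED file of panel intervals
#'
#' Accepts 3+ tab-separated columns (chrom, start, end, ...); coordinates
#' are 0-based, half-open, the BED convention.  Malformed lines (fewer
#' than 3 fields, non-numeric or inverted coordinates) raise an error
#' naming the line.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(chrom = character(length(lines)),
                    start = integer(length(lines)),
                    end = integer(length(lines)))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 3L) stop("malformed BED line ", k, ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(p[2L]))
    e <- suppressWarnings(as.integer(p[3L]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", k, ": non-numeric coordinates")
    }
    if (s >= e) stop("malformed BED line ", k, ": start >= end")
    out$chrom[k] <- p[1L]; out$start[k] <- s; out$end[k] <- e
  }
  out
}

#' Read per-mutation records from TSV
#'
#' Columns: \code{sample_id}, \code{chrom}, \code{pos} (1-based),
#' \code{category}.
#'
#' @param path Path to a records TSV.
#' @return data.frame of mutation records.
#' @export
read_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(is.na(df$pos)) || any(df$pos < 1)) stop("record pos must be >= 1")
  df[, need]
}

#' Write per-mutation records to TSV
#' @param records data.frame with sample_id, chrom, pos, category.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict mutation records to panel regions
#'
#' Keeps exactly the records whose position falls inside some interval of
#' the panel, emulating targeted-panel downsampling of WGS/WXS cohorts.
#' BED intervals are 0-based half-open and positions 1-based, so a record
#' is kept iff \code{start < pos <= end} for some interval on its
#' chromosome.
#'
#' @param records data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{category} (see [read_records()]).
#' @param panel data.frame of BED intervals from [read_bed()] (or with
#'   columns chrom, start, end in BED coordinates).
#' @return The subset of \code{records} overlapping the panel.
#' @export
region_downsample <- function(records, panel) {
  if (!nrow(records) || !nrow(panel)) return(records[integer(0), , drop = FALSE])
  if (any(panel$start >= panel$end)) stop("panel has an interval with start >= end")
  q <- GenomicRanges::GRanges(records$chrom,
                              IRanges::IRanges(records$pos, records$pos))
  s <- GenomicRanges::GRanges(panel$chrom,
                              IRanges::IRanges(panel$start + 1L, panel$end))
  # records on chromosomes absent from the panel simply do not overlap
  hit <- suppressWarnings(IRanges::overlapsAny(q, s))
  records[hit, , drop = FALSE]
}

#' Tally mutation records into a catalog
#'
#' Counts records per (sample, category).  Useful after
#' [region_downsample()] to rebuild a count catalog.
#'
#' @param records data.frame of mutation records.
#' @param categories Category labels for the catalog columns (default
#'   SBS-96); records with categories outside this set are an error.
#' @param sample_ids Optional sample universe (rows), so samples that
#'   lost all mutations keep a zero row.
#' @return A \code{"mutation_catalog"}.
#' @export
records_to_catalog <- function(records, categories = sbs96_categories(),
                               sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(records$sample_id)
  bad <- setdiff(unique(records$category), categories)
  if (length(bad)) stop("unknown category in records: ", bad[1L])
  V <- matrix(0, nrow = length(sample_ids), ncol = length(categories),
              dimnames = list(sample_ids, categories))
  if (nrow(records)) {
    tab <- table(factor(records$sample_id, levels = sample_ids),
                 factor(records$category, levels = categories))
    V <- V + unclass(tab)
  }
  as_catalog(V, sample_ids = sample_ids, categories = categories)
}
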