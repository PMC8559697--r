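#' Canonical SBS-96 category labels
#'
#' Labels for the 96 single-base-substitution categories in the COSMIC
#' convention: the six pyrimidine-centred substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G), each combined with the 16 possible
#' 5'/3' flanking-base contexts in lexicographic order.  The label format is
#' \code{"A[C>A]A"}: 5' base, bracketed substitution, 3' base.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbs96_categories())
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }), use.names = FALSE)
}

# single regex check for an SBS-96 style label
is_sbs96_label <- function(x) {
  grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", x)
}
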