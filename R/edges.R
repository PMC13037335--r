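#' Canonical edge enumeration for a P-parcel atlas
#'
#' All edge-indexed objects in pcscore (edge vectors, CSS templates) share one
#' canonical ordering: the strict upper triangle of the symmetric P x P
#' connectivity matrix, enumerated row-major, i.e. (1,2), (1,3), ..., (1,P),
#' (2,3), ..., (P-1,P). Scoring never relies on implicit ordering when reading
#' files — edge lists on disk carry explicit parcel labels — but all in-memory
#' vectors are stored in this order.
#'
#' @param p Number of parcels (>= 2).
#' @return Integer matrix with `p*(p-1)/2` rows and columns `i`, `j` (1-based,
#'   `i < j`).
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 2L) {
    stop("edge_pairs() needs at least 2 parcels, got ", p, call. = FALSE)
  }
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) seq.int(a + 1L, p)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Number of edges for a P-parcel atlas
#' @param p Number of parcels.
#' @return `p * (p - 1) / 2` as an integer.
#' @export
n_edges <- function(p) {
  as.integer(p * (p - 1) / 2)
}

# Shared check that two edge-indexed objects live on the same atlas:
# identical parcel count and, when both carry labels, identical label order.
check_same_atlas <- function(labels_a, labels_b, what_a = "edges", what_b = "template") {
  if (length(labels_a) != length(labels_b)) {
    stop(sprintf("atlas mismatch: %s has %d parcels, %s has %d",
                 what_a, length(labels_a), what_b, length(labels_b)),
         call. = FALSE)
  }
  if (!is.null(labels_a) && !is.null(labels_b) && !identical(labels_a, labels_b)) {
    bad <- which(labels_a != labels_b)[1L]
    stop(sprintf("atlas mismatch: parcel %d is '%s' in %s but '%s' in %s",
                 bad, labels_a[bad], what_a, labels_b[bad], what_b),
         call. = FALSE)
  }
  invisible(TRUE)
}
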