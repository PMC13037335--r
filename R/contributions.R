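#' Strongest positive or negative template contributors
#'
#' Ranks the edges of a CSS template by weight to expose the connections that
#' drive the score: descending for `sign = "positive"`, ascending for
#' `sign = "negative"`. Ties are broken by canonical edge order. These
#' summaries are computed on the template alone — no subject data enters.
#'
#' @param template A [css_template()].
#' @param k Number of edges to return; must not exceed the count of edges with
#'   the requested sign.
#' @param sign `"positive"` or `"negative"`.
#' @return Tibble with columns `rank`, `parcel_i`, `parcel_j`, `weight`,
#'   `network_i`, `network_j`.
#' @export
top_edges <- function(template, k, sign = c("positive", "negative")) {
  stopifnot(inherits(template, "css_template"))
  sign <- match.arg(sign)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  w <- template$weights
  avail <- if (sign == "positive") which(w > 0) else which(w < 0)
  if (k > length(avail)) {
    stop(sprintf("requested top %d %s edges but only %d available",
                 k, sign, length(avail)), call. = FALSE)
  }
  # order() is stable, so equal weights keep canonical edge order
  ord <- if (sign == "positive") avail[order(-w[avail])] else avail[order(w[avail])]
  sel <- ord[seq_len(k)]
  idx <- template$edge_index[sel, , drop = FALSE]
  net <- template$network_partition
  lab <- template$parcel_labels
  tibble::tibble(
    rank = seq_len(k),
    parcel_i = lab[idx[, 1L]],
    parcel_j = lab[idx[, 2L]],
    weight = w[sel],
    network_i = unname(net[lab[idx[, 1L]]]),
    network_j = unname(net[lab[idx[, 2L]]])
  )
}

#' Aggregate template weights into within/between-network blocks
#'
#' Collapses the edge-level weight map onto the template's network partition
#' (e.g. the 7 Yeo networks): block (a, b) aggregates the weights of all edges
#' with one endpoint in network a and the other in network b; diagonal blocks
#' are within-network. Networks are ordered alphabetically so the summary is
#' invariant to parcel permutation. Blocks with no edges report aggregate 0
#' and count 0.
#'
#' @param template A [css_template()].
#' @param statistic `"mean"` (default; comparable across blocks of different
#'   sizes) or `"sum"` (conserves the template's weight total).
#' @return An object of class `network_block_summary`: list with
#'   `network_labels`, `block_matrix` (K x K symmetric aggregate),
#'   `block_counts` (K x K symmetric edge counts) and `statistic`.
#' @export
network_aggregate <- function(template, statistic = c("mean", "sum")) {
  stopifnot(inherits(template, "css_template"))
  statistic <- match.arg(statistic)
  net <- template$network_partition
  missing <- template$parcel_labels[!template$parcel_labels %in% names(net)]
  if (length(missing) > 0L) {
    stop("parcel(s) missing from network partition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nets <- sort(unique(unname(net)))
  kk <- length(nets)
  ni <- match(net[template$parcel_labels[template$edge_index[, 1L]]], nets)
  nj <- match(net[template$parcel_labels[template$edge_index[, 2L]]], nets)
  a <- pmin(ni, nj)
  b <- pmax(ni, nj)
  sums <- matrix(0, kk, kk, dimnames = list(nets, nets))
  counts <- matrix(0L, kk, kk, dimnames = list(nets, nets))
  flat <- (a - 1L) * kk + b  # unordered block key, upper-triangle canonical
  agg_sum <- tapply(template$weights, flat, sum)
  agg_n <- tapply(template$weights, flat, length)
  pos <- as.integer(names(agg_sum))
  bi <- ((pos - 1L) %/% kk) + 1L
  bj <- ((pos - 1L) %% kk) + 1L
  for (t in seq_along(pos)) {
    sums[bi[t], bj[t]] <- agg_sum[t]
    sums[bj[t], bi[t]] <- agg_sum[t]
    counts[bi[t], bj[t]] <- as.integer(agg_n[t])
    counts[bj[t], bi[t]] <- as.integer(agg_n[t])
  }
  block <- if (statistic == "mean") {
    out <- sums
    nz <- counts > 0L
    out[nz] <- sums[nz] / counts[nz]
    out
  } else {
    sums
  }
  structure(
    list(network_labels = nets, block_matrix = block, block_counts = counts,
         statistic = statistic),
    class = "network_block_summary"
  )
}

#' @export
print.network_block_summary <- function(x, ...) {
  cat(sprintf("<network_block_summary> %d networks, statistic = %s\n",
              length(x$network_labels), x$statistic))
  print(round(x$block_matrix, 4))
  invisible(x)
}

#' Write a network block summary as CSV with network-label headers
#' @param summary A `network_block_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(summary, path) {
  stopifnot(inherits(summary, "network_block_summary"))
  tab <- tibble::as_tibble(summary$block_matrix)
  tab <- dplyr::bind_cols(tibble::tibble(network = summary$network_labels), tab)
  readr::write_csv(tab, path)
  invisible(path)
}
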