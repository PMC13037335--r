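#' Connectome-summary-statistic (CSS) template
#'
#' A disorder-specific edge-weight map: one meta-analytic effect size (Cohen's
#' d contrasting patients and controls) per connection of a fixed atlas, plus a
#' parcel-to-network partition used for contribution summaries. Weights are
#' stored in the canonical edge order of [edge_pairs()]. Published maps (e.g.
#' the MDD map distributed with the pcs-toolbox) are not bundled; this package
#' defines its own documented plain-text format and treats any template as an
#' opaque weight map.
#'
#' @param weights Numeric vector, length P(P-1)/2, in canonical edge order.
#' @param parcel_labels Character vector of P unique parcel names.
#' @param network_partition Named character vector mapping every parcel label
#'   to a network label (e.g. the 7 Yeo networks).
#' @param template_id Template identifier.
#' @param atlas_id Atlas identifier.
#' @return An object of class `css_template`.
#' @export
css_template <- function(weights, parcel_labels, network_partition,
                         template_id = "template", atlas_id = "atlas") {
  parcel_labels <- as.character(parcel_labels)
  p <- length(parcel_labels)
  if (p < 2L) stop("template needs at least 2 parcels", call. = FALSE)
  if (anyDuplicated(parcel_labels)) {
    stop("duplicate parcel labels in template", call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (length(weights) != n_edges(p)) {
    stop("expected ", n_edges(p), " weights for ", p, " parcels, got ",
         length(weights), call. = FALSE)
  }
  if (anyNA(weights)) stop("template weights contain NA", call. = FALSE)
  if (all(weights == 0)) {
    stop("template has no non-zero weights", call. = FALSE)
  }
  network_partition <- vapply(network_partition, as.character, character(1))
  missing_parcels <- setdiff(parcel_labels, names(network_partition))
  if (length(missing_parcels) > 0L) {
    stop("network partition missing parcel(s): ",
         paste(missing_parcels, collapse = ", "), call. = FALSE)
  }
  network_partition <- network_partition[parcel_labels]
  structure(
    list(template_id = as.character(template_id),
         atlas_id = as.character(atlas_id),
         weights = weights,
         edge_index = edge_pairs(p),
         parcel_labels = parcel_labels,
         network_partition = network_partition),
    class = "css_template"
  )
}

#' @export
print.css_template <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf(
    "<css_template> '%s' on atlas '%s': %d parcels, %d edges (%d non-zero), %d networks\n",
    x$template_id, x$atlas_id, length(x$parcel_labels), length(x$weights),
    nz, length(unique(x$network_partition))))
  invisible(x)
}

# sidecar path convention: template file plus ".json"
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_template_sidecar <- function(path) {
  if (!file.exists(path)) {
    stop("template sidecar not found: ", path,
         " (expected JSON with template_id, atlas_id, parcel_labels, network_partition)",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("template_id", "atlas_id", "parcel_labels", "network_partition")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("template sidecar ", path, " missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta$network_partition <- unlist(meta$network_partition)
  meta
}

#' Load a CSS template from disk
#'
#' Two on-disk forms are supported, both accompanied by a JSON sidecar
#' (`<stem>.json`) carrying `template_id`, `atlas_id`, `parcel_labels` and
#' `network_partition`:
#'
#' * `edge_tsv` — long format with columns `parcel_i`, `parcel_j`, `weight`;
#'   edges absent from the file get weight 0, each unordered pair may appear
#'   at most once, and every label must resolve against the sidecar's atlas.
#' * `square_csv` — full P x P matrix with parcel-label header; must be
#'   symmetric (tolerance 1e-12) with zero diagonal.
#'
#' @param path Path to the template file.
#' @param format `"edge_tsv"` or `"square_csv"`.
#' @param sidecar Optional explicit sidecar path.
#' @return A [css_template()].
#' @export
load_template <- function(path, format = c("edge_tsv", "square_csv"),
                          sidecar = NULL) {
  format <- match.arg(format)
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  meta <- read_template_sidecar(sidecar)
  labels <- as.character(meta$parcel_labels)
  p <- length(labels)
  idx <- edge_pairs(p)
  if (format == "edge_tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      parcel_i = readr::col_character(),
      parcel_j = readr::col_character(),
      weight = readr::col_double()), progress = FALSE)
    ii <- match(tab$parcel_i, labels)
    jj <- match(tab$parcel_j, labels)
    unknown <- unique(c(tab$parcel_i[is.na(ii)], tab$parcel_j[is.na(jj)]))
    if (length(unknown) > 0L) {
      stop("edge list references unknown parcel label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(ii == jj)) {
      stop("edge list contains self-loop(s): ",
           paste(unique(tab$parcel_i[ii == jj]), collapse = ", "), call. = FALSE)
    }
    lo <- pmin(ii, jj)
    hi <- pmax(ii, jj)
    key <- (lo - 1) * p + hi
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop(sprintf("duplicate edge row: %s -- %s", tab$parcel_i[d], tab$parcel_j[d]),
           call. = FALSE)
    }
    weights <- numeric(n_edges(p))
    pos <- match(key, (idx[, 1L] - 1) * p + idx[, 2L])
    weights[pos] <- tab$weight
  } else {
    tab <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_double()), progress = FALSE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) {
      stop("square template must have as many rows as columns", call. = FALSE)
    }
    if (!setequal(colnames(m), labels) || nrow(m) != p) {
      stop("square template header does not match the sidecar's parcel labels",
           call. = FALSE)
    }
    rownames(m) <- colnames(m)  # rows follow the file's header order
    m <- m[labels, labels, drop = FALSE]
    asym <- max(abs(m - t(m)))
    if (asym > 1e-12) {
      stop(sprintf("square template asymmetric: max |A - t(A)| = %g", asym),
           call. = FALSE)
    }
    weights <- m[idx]
  }
  css_template(weights, parcel_labels = labels,
               network_partition = meta$network_partition,
               template_id = meta$template_id, atlas_id = meta$atlas_id)
}

#' Write a CSS template (and its JSON sidecar) to disk
#'
#' `edge_tsv` writes only non-zero weights (the sparse edges carry all the
#' information; absent edges read back as 0). `square_csv` writes the full
#' symmetric matrix with zero diagonal.
#'
#' @param template A [css_template()].
#' @param path Output path for the template file.
#' @param format `"edge_tsv"` or `"square_csv"`.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path, format = c("edge_tsv", "square_csv")) {
  stopifnot(inherits(template, "css_template"))
  format <- match.arg(format)
  labels <- template$parcel_labels
  if (format == "edge_tsv") {
    keep <- template$weights != 0
    tab <- tibble::tibble(
      parcel_i = labels[template$edge_index[keep, 1L]],
      parcel_j = labels[template$edge_index[keep, 2L]],
      weight = template$weights[keep]
    )
    readr::write_tsv(tab, path)
  } else {
    p <- length(labels)
    m <- matrix(0, p, p, dimnames = list(labels, labels))
    m[template$edge_index] <- template$weights
    m[template$edge_index[, c(2L, 1L)]] <- template$weights
    tab <- tibble::as_tibble(m)
    readr::write_csv(tab, path)
  }
  meta <- list(template_id = template$template_id,
               atlas_id = template$atlas_id,
               p = length(labels),
               parcel_labels = labels,
               network_partition = as.list(template$network_partition))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
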