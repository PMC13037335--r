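#' Compute a subject's functional connectivity matrix
#'
#' Pairwise Pearson correlation between the mean BOLD signals of all parcel
#' pairs. Correlations are used directly — no Fisher-Z transform is applied and
#' no covariates are regressed out here — so the matrix holds raw r values in
#' \[-1, 1\] with a unit diagonal.
#'
#' Zero-variance (degenerate) parcels make the correlation undefined. Policy:
#' `"strict"` (default) raises an error naming the offending parcels;
#' `"lenient"` sets every correlation involving a degenerate parcel to 0
#' (including its diagonal) and emits a warning.
#'
#' @param ts A [parcel_ts()] object.
#' @param degenerate_policy `"strict"` or `"lenient"`.
#' @return An object of class `fc_matrix` with fields `subject_id`, `values`
#'   (P x P symmetric correlation matrix) and `parcel_labels`.
#' @export
compute_fc <- function(ts, degenerate_policy = c("strict", "lenient")) {
  stopifnot(inherits(ts, "parcel_ts"))
  degenerate_policy <- match.arg(degenerate_policy)
  x <- ts$data
  if (degenerate_policy == "strict" && anyNA(x)) {
    stop("missing values in time series for subject '", ts$subject_id,
         "' (strict mode)", call. = FALSE)
  }
  use <- if (anyNA(x)) "pairwise.complete.obs" else "everything"
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  degenerate <- which(!is.finite(sds) | sds == 0)
  if (length(degenerate) > 0L && degenerate_policy == "strict") {
    stop("degenerate (zero-variance) parcel(s) in subject '", ts$subject_id,
         "': ", paste(ts$parcel_labels[degenerate], collapse = ", "),
         call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x, use = use))
  diag(r) <- 1
  if (length(degenerate) > 0L) {
    warning("subject '", ts$subject_id, "': correlations of degenerate parcel(s) ",
            paste(ts$parcel_labels[degenerate], collapse = ", "),
            " set to 0", call. = FALSE)
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  if (anyNA(r)) {
    r[is.na(r)] <- 0
    warning("subject '", ts$subject_id,
            "': undefined pairwise correlations set to 0", call. = FALSE)
  }
  r <- (r + t(r)) / 2  # enforce exact symmetry against floating-point asymmetry
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(
    list(subject_id = ts$subject_id, values = r,
         parcel_labels = ts$parcel_labels),
    class = "fc_matrix"
  )
}

#' Construct an fc_matrix from an existing correlation matrix
#'
#' @param values Symmetric P x P correlation matrix.
#' @param subject_id Subject identifier.
#' @param parcel_labels Optional parcel names.
#' @param tol Symmetry tolerance.
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(values, subject_id, parcel_labels = NULL, tol = 1e-12) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("fc_matrix must be square", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("fc_matrix asymmetric beyond tolerance: max |A - t(A)| = %g", asym),
         call. = FALSE)
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- colnames(values)
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- paste0("parcel_", seq_len(ncol(values)))
  }
  dimnames(values) <- list(parcel_labels, parcel_labels)
  structure(
    list(subject_id = as.character(subject_id), values = values,
         parcel_labels = as.character(parcel_labels)),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> subject '%s': %d x %d, mean off-diagonal r = %.3f\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Vectorize an FC matrix into the canonical edge order
#'
#' Extracts the strict upper triangle row-major (see [edge_pairs()]); the k-th
#' element of the result is the connectivity of the k-th canonical edge, the
#' "connection i" entering the polyconnectomic score.
#'
#' @param fc An `fc_matrix`.
#' @param tol Symmetry tolerance (validation guard).
#' @return An object of class `edge_vector` with fields `subject_id`, `values`
#'   (length P(P-1)/2) and `edge_index` (canonical (i, j) pairs).
#' @export
vectorize_fc <- function(fc, tol = 1e-12) {
  stopifnot(inherits(fc, "fc_matrix"))
  asym <- max(abs(fc$values - t(fc$values)))
  if (asym > tol) {
    stop(sprintf("cannot vectorize: asymmetry %g exceeds tolerance %g", asym, tol),
         call. = FALSE)
  }
  idx <- edge_pairs(ncol(fc$values))
  structure(
    list(subject_id = fc$subject_id,
         values = fc$values[idx],
         edge_index = idx,
         parcel_labels = fc$parcel_labels),
    class = "edge_vector"
  )
}

#' Rebuild the symmetric FC matrix from an edge vector
#'
#' Exact inverse of [vectorize_fc()] on the off-diagonal; the diagonal is set
#' to `diag_value`.
#'
#' @param edges An `edge_vector`.
#' @param diag_value Diagonal fill (1 for correlation matrices).
#' @return An `fc_matrix`.
#' @export
devectorize_fc <- function(edges, diag_value = 1) {
  stopifnot(inherits(edges, "edge_vector"))
  idx <- edges$edge_index
  p <- max(idx)
  m <- matrix(0, p, p)
  m[idx] <- edges$values
  m[idx[, c(2L, 1L)]] <- edges$values
  diag(m) <- diag_value
  fc_matrix(m, subject_id = edges$subject_id,
            parcel_labels = edges$parcel_labels)
}

#' Construct an edge vector directly
#'
#' @param values Numeric vector of length P(P-1)/2 in canonical edge order.
#' @param subject_id Subject identifier.
#' @param p Parcel count; inferred from `length(values)` when omitted.
#' @param parcel_labels Optional parcel names.
#' @return An `edge_vector`.
#' @export
edge_vector <- function(values, subject_id = "subject", p = NULL,
                        parcel_labels = NULL) {
  if (is.null(p)) {
    p <- (1 + sqrt(1 + 8 * length(values))) / 2
    if (abs(p - round(p)) > 1e-9) {
      stop("length ", length(values), " is not P(P-1)/2 for any integer P",
           call. = FALSE)
    }
    p <- as.integer(round(p))
  }
  if (length(values) != n_edges(p)) {
    stop("expected ", n_edges(p), " edge values for P = ", p, ", got ",
         length(values), call. = FALSE)
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- paste0("parcel_", seq_len(p))
  }
  structure(
    list(subject_id = as.character(subject_id),
         values = as.numeric(values),
         edge_index = edge_pairs(p),
         parcel_labels = as.character(parcel_labels)),
    class = "edge_vector"
  )
}

#' @export
print.edge_vector <- function(x, ...) {
  cat(sprintf("<edge_vector> subject '%s': %d edges (%d parcels)\n",
              x$subject_id, length(x$values), length(x$parcel_labels)))
  invisible(x)
}

#' Write an FC matrix as a square CSV with parcel-label header
#' @param fc An `fc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_csv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  tab <- tibble::as_tibble(fc$values)
  names(tab) <- fc$parcel_labels
  readr::write_csv(tab, path)
  invisible(path)
}

#' Write an edge vector as long-format TSV (parcel_i, parcel_j, r)
#' @param edges An `edge_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(edges, path) {
  stopifnot(inherits(edges, "edge_vector"))
  tab <- tibble::tibble(
    parcel_i = edges$parcel_labels[edges$edge_index[, 1L]],
    parcel_j = edges$parcel_labels[edges$edge_index[, 2L]],
    r = edges$values
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
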