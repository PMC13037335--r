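#' Parcel-level BOLD time series for one subject
#'
#' Container for a subject's regional mean BOLD signals after upstream fMRI
#' preprocessing (volume discarding, motion correction, nuisance regression,
#' normalization and bandpass filtering all happen before this package; inputs
#' are assumed preprocessed). Rows are timepoints, columns are parcels of a
#' fixed atlas.
#'
#' @param data Numeric matrix, timepoints x parcels.
#' @param subject_id Subject identifier.
#' @param parcel_labels Optional character vector of parcel names; defaults to
#'   column names of `data` or `parcel_1 ... parcel_P`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, subject_id, parcel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop("parcel time series must be numeric", call. = FALSE)
  }
  if (nrow(data) < 3L) {
    stop("parcel time series needs at least 3 timepoints (got ", nrow(data),
         "): Pearson correlation would have no residual degrees of freedom",
         call. = FALSE)
  }
  if (ncol(data) < 2L) {
    stop("parcel time series needs at least 2 parcels", call. = FALSE)
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- colnames(data)
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- paste0("parcel_", seq_len(ncol(data)))
  }
  parcel_labels <- as.character(parcel_labels)
  if (length(parcel_labels) != ncol(data)) {
    stop("parcel_labels length (", length(parcel_labels),
         ") does not match parcel count (", ncol(data), ")", call. = FALSE)
  }
  if (anyDuplicated(parcel_labels)) {
    stop("parcel_labels must be unique; duplicated: ",
         paste(unique(parcel_labels[duplicated(parcel_labels)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(data) <- parcel_labels
  structure(
    list(subject_id = as.character(subject_id),
         data = data,
         parcel_labels = parcel_labels),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject '%s': %d timepoints x %d parcels\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Read a subject's parcel time series from delimited text
#'
#' One file per subject: rows = timepoints, columns = parcels, header row =
#' parcel labels. The filename stem (without extension) is taken as the
#' subject id unless overridden. Tab- and comma-delimited files are both
#' accepted (chosen by extension, `.tsv`/`.txt` vs `.csv`).
#'
#' @param path Path to the file.
#' @param subject_id Optional explicit subject id.
#' @return A [parcel_ts()] object.
#' @export
read_parcel_ts <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop("time-series file not found: ", path, call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE)
  parcel_ts(as.matrix(tab), subject_id = subject_id,
            parcel_labels = names(tab))
}

#' Write a parcel time series to delimited text
#'
#' @param ts A [parcel_ts()] object.
#' @param path Output path (`.csv` writes comma-delimited, otherwise tabs).
#' @return `path`, invisibly.
#' @export
write_parcel_ts <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  tab <- tibble::as_tibble(ts$data)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tab, path)
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}
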