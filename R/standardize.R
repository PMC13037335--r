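#' Mean-center or z-score continuous variables
#'
#' All association and moderation models in this package work on mean-centered
#' (and, for standardized coefficients, z-scored) continuous variables.
#' `standardize_center()` applies the transformation column-wise and records
#' the parameters so the transformation is invertible. Binary variables
#' (at most two distinct non-missing values, e.g. 0/1 sex codes) are left
#' untouched even when named.
#'
#' @param table A data frame / tibble.
#' @param variables Character vector of column names to transform.
#' @param mode `"center"` (subtract the sample mean) or `"zscore"` (also divide
#'   by the sample SD, n-1 denominator).
#' @return The table with transformed columns; attribute `"standardization"`
#'   holds a tibble of (variable, mean, sd, mode).
#' @export
standardize_center <- function(table, variables, mode = c("center", "zscore")) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols) > 0L) {
    stop("variable(s) not present: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  params <- vector("list", length(variables))
  for (k in seq_along(variables)) {
    v <- variables[k]
    x <- table[[v]]
    if (!is.numeric(x)) {
      stop("variable '", v, "' is not numeric", call. = FALSE)
    }
    n_distinct <- length(unique(x[!is.na(x)]))
    if (n_distinct == 2L) {  # binary covariates keep their coding
      params[[k]] <- tibble::tibble(variable = v, mean = NA_real_,
                                    sd = NA_real_, mode = "untouched")
      next
    }
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (mode == "zscore") {
      if (!is.finite(s) || s == 0 || n_distinct < 2L) {
        stop("variable '", v, "' has zero variance: cannot z-score",
             call. = FALSE)
      }
      table[[v]] <- (x - m) / s
    } else {
      table[[v]] <- x - m
    }
    params[[k]] <- tibble::tibble(variable = v, mean = m, sd = s, mode = mode)
  }
  attr(table, "standardization") <- dplyr::bind_rows(params)
  table
}

# binary = exactly two distinct non-missing values (0/1 codes, factors-as-int)
is_binary <- function(x) {
  length(unique(x[!is.na(x)])) == 2L
}
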