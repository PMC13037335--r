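#' Polyconnectomic score of one subject against one template
#'
#' The polyconnectomic score (PCS) is the weighted average of the template's
#' meta-analytic edge weights and the subject's functional connectivity over
#' the connections carrying information in the template:
#'
#' \deqn{PCS = \frac{1}{n} \sum_{i : \beta_i \neq 0} \beta_i C_i}
#'
#' where \eqn{C_i} is the subject's correlation at connection i, \eqn{\beta_i}
#' the template weight (Cohen's d), and n the number of connections with
#' non-zero weight. No further scaling is applied; higher scores mean stronger
#' alignment of the individual connectome with the disorder-related pattern.
#'
#' The non-zero test is exact (`beta != 0`) by default since template weights
#' are stored values, not computed quantities; `zero_tol` allows an explicit
#' tolerance when a template has been through lossy processing.
#'
#' @param edges An `edge_vector` (see [vectorize_fc()]).
#' @param template A [css_template()] on the same atlas.
#' @param zero_tol Weights with `abs(weight) <= zero_tol` are treated as zero.
#' @return An object of class `pcs_result`: list with `subject_id`,
#'   `template_id`, `score`, `n_nonzero`.
#' @examples
#' ev <- edge_vector(c(0.5, -0.2, 0.1), subject_id = "s1")
#' tpl <- css_template(c(2, 0, -1), paste0("p", 1:3),
#'                     stats::setNames(rep("net1", 3), paste0("p", 1:3)))
#' compute_pcs(ev, tpl)$score  # (2*0.5 + (-1)*0.1) / 2 = 0.45
#' @export
compute_pcs <- function(edges, template, zero_tol = 0) {
  stopifnot(inherits(edges, "edge_vector"), inherits(template, "css_template"))
  check_same_atlas(edges$parcel_labels, template$parcel_labels,
                   "edge vector", paste0("template '", template$template_id, "'"))
  if (length(edges$values) != length(template$weights)) {
    stop("edge count mismatch between edge vector and template", call. = FALSE)
  }
  nz <- abs(template$weights) > zero_tol
  n_nonzero <- sum(nz)
  if (n_nonzero == 0L) {
    stop("template '", template$template_id,
         "' has no non-zero weights: score undefined", call. = FALSE)
  }
  if (anyNA(edges$values[nz])) {
    stop("subject '", edges$subject_id,
         "' has undefined connectivity at non-zero-weight edges", call. = FALSE)
  }
  score <- sum(template$weights[nz] * edges$values[nz]) / n_nonzero
  structure(
    list(subject_id = edges$subject_id,
         template_id = template$template_id,
         score = score,
         n_nonzero = as.integer(n_nonzero)),
    class = "pcs_result"
  )
}

#' @export
print.pcs_result <- function(x, ...) {
  cat(sprintf("<pcs_result> subject '%s' x template '%s': score = %.6g (n = %d)\n",
              x$subject_id, x$template_id, x$score, x$n_nonzero))
  invisible(x)
}

#' Score a cohort of edge vectors against one or more templates
#'
#' One row per subject x template, subjects in input order (outer loop) and
#' templates in input order (inner loop). In strict mode any per-subject
#' failure aborts with the offending subject named; in lenient mode failing
#' combinations are skipped with a warning and reported as NA rows.
#'
#' @param cohort_edges List of `edge_vector` objects.
#' @param templates A single [css_template()] or a list of them.
#' @param policy `"strict"` or `"lenient"`.
#' @param zero_tol Passed to [compute_pcs()].
#' @return A tibble with columns `subject_id`, `template_id`, `pcs`,
#'   `n_nonzero`.
#' @export
batch_score <- function(cohort_edges, templates, policy = c("strict", "lenient"),
                        zero_tol = 0) {
  policy <- match.arg(policy)
  if (inherits(templates, "css_template")) templates <- list(templates)
  if (inherits(cohort_edges, "edge_vector")) cohort_edges <- list(cohort_edges)
  rows <- vector("list", length(cohort_edges) * length(templates))
  k <- 0L
  for (ev in cohort_edges) {
    for (tpl in templates) {
      k <- k + 1L
      res <- tryCatch(compute_pcs(ev, tpl, zero_tol = zero_tol),
                      error = function(e) e)
      if (inherits(res, "error")) {
        if (policy == "strict") {
          stop("batch_score failed for subject '", ev$subject_id,
               "' x template '", tpl$template_id, "': ",
               conditionMessage(res), call. = FALSE)
        }
        warning("skipping subject '", ev$subject_id, "' x template '",
                tpl$template_id, "': ", conditionMessage(res), call. = FALSE)
        rows[[k]] <- tibble::tibble(subject_id = ev$subject_id,
                                    template_id = tpl$template_id,
                                    pcs = NA_real_, n_nonzero = NA_integer_)
      } else {
        rows[[k]] <- tibble::tibble(subject_id = res$subject_id,
                                    template_id = res$template_id,
                                    pcs = res$score,
                                    n_nonzero = res$n_nonzero)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a PCS score table as CSV
#' @param scores Tibble from [batch_score()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}
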