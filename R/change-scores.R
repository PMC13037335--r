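#' Longitudinal change scores (follow-up minus baseline)
#'
#' Builds the change-score table for the longitudinal arm: one row per subject
#' observed at both timepoints, with `delta_<var> = followup - baseline` for
#' every repeated measure, plus `followup_duration` (follow-up age minus
#' baseline age, years). Subjects lacking a follow-up row are excluded and
#' counted in the `"n_excluded"` attribute. Baseline-anchored columns
#' (family, sex, motion, PCS columns, latent ground truth when present) are
#' carried over at their baseline values.
#'
#' @param table Long-format cohort tibble with columns `subject_id`,
#'   `timepoint` (values `"baseline"`, `"followup"`), `family_id`, `age`, and
#'   the repeated measures.
#' @param variables Repeated-measure columns to difference; defaults to
#'   `stress`, `anxiety`, `depression` and every `cog_*` column present.
#' @return Tibble with one row per followed-up subject; attributes
#'   `"n_excluded"` (baseline-only subjects) and `"excluded_subjects"`.
#' @export
compute_change_scores <- function(table, variables = NULL) {
  required <- c("subject_id", "timepoint", "family_id", "age")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(table$timepoint %in% c("baseline", "followup"))) {
    stop("timepoint must be 'baseline' or 'followup'", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- c(intersect(c("stress", "anxiety", "depression"), names(table)),
                   grep("^cog_", names(table), value = TRUE))
  }
  if (length(variables) == 0L) {
    stop("no repeated-measure variables to difference", call. = FALSE)
  }
  bl <- table[table$timepoint == "baseline", , drop = FALSE]
  fu <- table[table$timepoint == "followup", , drop = FALSE]
  if (anyDuplicated(bl$subject_id) || anyDuplicated(fu$subject_id)) {
    stop("a subject has more than one row per timepoint", call. = FALSE)
  }
  orphan <- setdiff(fu$subject_id, bl$subject_id)
  if (length(orphan) > 0L) {
    stop("follow-up rows without baseline rows: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  both <- bl$subject_id %in% fu$subject_id
  excluded <- bl$subject_id[!both]
  blb <- bl[both, , drop = FALSE]
  fub <- fu[match(blb$subject_id, fu$subject_id), , drop = FALSE]
  dur <- fub$age - blb$age
  if (any(dur <= 0)) {
    bad <- blb$subject_id[dur <= 0]
    stop("follow-up age not greater than baseline age for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  carry <- setdiff(names(table), c(variables, "timepoint", "age"))
  out <- blb[, carry, drop = FALSE]
  out$followup_duration <- dur
  out$baseline_age <- blb$age
  for (v in variables) {
    out[[paste0("delta_", v)]] <- fub[[v]] - blb[[v]]
    out[[paste0(v, "_baseline")]] <- blb[[v]]
    out[[paste0(v, "_followup")]] <- fub[[v]]
  }
  out <- tibble::as_tibble(out)
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_subjects") <- excluded
  out
}
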