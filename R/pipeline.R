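# End-to-end orchestration with plain-file handoff between stages.
#
# Stage graph (canonical order):
#   simulate -> fc -> score -> {baseline, longitudinal, sensitivity,
#                               exploratory} -> report
# Every stage reads its inputs from out_dir and writes its outputs there, so
# any subset of stages can be re-run against existing files; a missing input
# raises an error naming the stage that produces it. All randomness funnels
# through sub-seeds derived from the config's master seed, so a re-run with
# the same config is bit-reproducible in every result table.

pipeline_paths <- function(out_dir) {
  list(
    out_dir = out_dir,
    timeseries = file.path(out_dir, "timeseries"),
    templates = file.path(out_dir, "templates"),
    edges = file.path(out_dir, "edges"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    scores = file.path(out_dir, "scores.csv"),
    results = file.path(out_dir, "results"),
    manifest = file.path(out_dir, "manifest.json")
  )
}

require_stage_input <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input '", path, "': run the '", producer, "' stage first",
         call. = FALSE)
  }
  invisible(path)
}

config_hash <- function(config) {
  plain <- unclass(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from JSON
#'
#' The JSON object holds [sim_config()] arguments (nested lists for
#' `template_spec`, `outcome_params`, `covariate_params`).
#'
#' @param path Path to a JSON config file.
#' @return A [sim_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, args)
}

# registered template set: the main synthetic disorder map plus alternatives
# for the sensitivity arm, each generated from its own sub-stream
pipeline_templates <- function(config, n_alternatives = 3L) {
  ids <- c("css_synthetic_mdd",
           c("css_synthetic_anxiety", "css_synthetic_bipolar",
             "css_synthetic_scz")[seq_len(n_alternatives)])
  offsets <- 11L + seq_along(ids) - 1L
  mapply(function(id, off) generate_template(config, template_id = id,
                                             seed_offset = off),
         ids, offsets, SIMPLIFY = FALSE)
}

stage_simulate <- function(config, paths, n_alternatives) {
  dir.create(paths$timeseries, recursive = TRUE, showWarnings = FALSE)
  dir.create(paths$templates, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config, include_timeseries = TRUE)
  templates <- pipeline_templates(config, n_alternatives)
  for (tpl in templates) {
    write_template(tpl, file.path(paths$templates, paste0(tpl$template_id, ".tsv")))
  }
  for (ts in sim$timeseries) {
    write_parcel_ts(ts, file.path(paths$timeseries, paste0(ts$subject_id, ".tsv")))
  }
  readr::write_csv(sim$cohort, paths$phenotypes)
  list(n_subjects = length(sim$timeseries), n_rows = nrow(sim$cohort),
       n_templates = length(templates))
}

stage_fc <- function(config, paths, strict = TRUE) {
  require_stage_input(paths$timeseries, "simulate")
  dir.create(paths$edges, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(paths$timeseries, pattern = "\\.(tsv|csv|txt)$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no time-series files under ", paths$timeseries,
         ": run the 'simulate' stage first", call. = FALSE)
  }
  policy <- if (strict) "strict" else "lenient"
  for (f in files) {
    ts <- read_parcel_ts(f)
    ev <- vectorize_fc(compute_fc(ts, degenerate_policy = policy))
    write_edge_tsv(ev, file.path(paths$edges, paste0(ts$subject_id, "_edges.tsv")))
  }
  list(n_subjects = length(files))
}

read_edge_file <- function(path, parcel_labels, subject_id) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    parcel_i = readr::col_character(), parcel_j = readr::col_character(),
    r = readr::col_double()), progress = FALSE)
  p <- length(parcel_labels)
  idx <- edge_pairs(p)
  ii <- match(tab$parcel_i, parcel_labels)
  jj <- match(tab$parcel_j, parcel_labels)
  if (anyNA(ii) || anyNA(jj)) {
    stop("edge file ", path, " references parcels outside the atlas",
         call. = FALSE)
  }
  pos <- match((pmin(ii, jj) - 1) * p + pmax(ii, jj),
               (idx[, 1L] - 1) * p + idx[, 2L])
  values <- numeric(nrow(idx))
  values[pos] <- tab$r
  edge_vector(values, subject_id = subject_id, p = p,
              parcel_labels = parcel_labels)
}

stage_score <- function(config, paths, strict = TRUE) {
  require_stage_input(paths$edges, "fc")
  require_stage_input(paths$templates, "simulate")
  tpl_files <- sort(list.files(paths$templates, pattern = "\\.tsv$",
                               full.names = TRUE))
  templates <- lapply(tpl_files, load_template, format = "edge_tsv")
  edge_files <- sort(list.files(paths$edges, pattern = "_edges\\.tsv$",
                                full.names = TRUE))
  labels <- templates[[1L]]$parcel_labels
  cohort_edges <- lapply(edge_files, function(f) {
    sid <- sub("_edges$", "", tools::file_path_sans_ext(basename(f)))
    read_edge_file(f, labels, sid)
  })
  scores <- batch_score(cohort_edges, templates,
                        policy = if (strict) "strict" else "lenient")
  write_scores_csv(scores, paths$scores)
  list(n_rows = nrow(scores), n_templates = length(templates))
}

read_phenotypes <- function(paths) {
  require_stage_input(paths$phenotypes, "simulate")
  readr::read_csv(paths$phenotypes, col_types = readr::cols(
    subject_id = readr::col_character(), family_id = readr::col_character(),
    timepoint = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}

read_scores <- function(paths) {
  require_stage_input(paths$scores, "score")
  readr::read_csv(paths$scores, col_types = readr::cols(
    subject_id = readr::col_character(), template_id = readr::col_character(),
    pcs = readr::col_double(), n_nonzero = readr::col_integer()),
    progress = FALSE)
}

# phenotypes with one pcs_<template_id> column per registered template
analysis_table <- function(paths) {
  pheno <- read_phenotypes(paths)
  scores <- read_scores(paths)
  wide <- tidyr::pivot_wider(scores[, c("subject_id", "template_id", "pcs")],
                             names_from = "template_id", values_from = "pcs",
                             names_prefix = "pcs_")
  dplyr::left_join(pheno, wide, by = "subject_id")
}

cog_columns <- function(tab) grep("^cog_", names(tab), value = TRUE)

write_result <- function(tab, paths, name) {
  dir.create(paths$results, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(paths$results, paste0(name, ".tsv"))
  readr::write_tsv(tab, out)
  out
}

stage_baseline <- function(config, paths, main_template = "css_synthetic_mdd") {
  tab <- analysis_table(paths)
  bl <- tab[tab$timepoint == "baseline", , drop = FALSE]
  pcs_col <- paste0("pcs_", main_template)
  emotional <- c("anxiety", "depression")
  cognitive <- cog_columns(bl)
  assoc_block <- function(predictor, covs) {
    emo <- dplyr::bind_rows(lapply(emotional, function(y) {
      fit_association(bl, y, predictor, covariates = covs, engine = "lmm")
    }))
    cogn <- dplyr::bind_rows(lapply(cognitive, function(y) {
      fit_association(bl, y, predictor, covariates = covs, engine = "lmm")
    }))
    dplyr::bind_rows(bonferroni_adjust(emo, family_size = length(emotional)),
                     bonferroni_adjust(cogn, family_size = length(cognitive)))
  }
  assoc <- dplyr::bind_rows(
    assoc_block("stress", c("age", "sex")),
    assoc_block(pcs_col, c("age", "sex", "mean_fd"))
  )
  mods <- dplyr::bind_rows(lapply(c(emotional, cognitive), function(y) {
    tidy_moderation(fit_moderation(bl, y, "stress", pcs_col,
                                   covariates = c("age", "sex", "mean_fd"),
                                   engine = "lmm"))
  }))
  mods <- bonferroni_adjust(mods, family_size = length(emotional))
  f1 <- write_result(assoc, paths, "baseline_associations")
  f2 <- write_result(mods, paths, "baseline_moderation")
  list(files = c(f1, f2), n_models = nrow(assoc) + nrow(mods),
       converged = all(assoc$converged) && all(mods$converged))
}

stage_longitudinal <- function(config, paths, main_template = "css_synthetic_mdd") {
  tab <- analysis_table(paths)
  ch <- compute_change_scores(tab)
  pcs_col <- paste0("pcs_", main_template)
  d_emotional <- c("delta_anxiety", "delta_depression")
  d_cognitive <- paste0("delta_", cog_columns(tab))
  assoc <- dplyr::bind_rows(
    bonferroni_adjust(dplyr::bind_rows(lapply(d_emotional, function(y) {
      fit_association(ch, y, "delta_stress",
                      covariates = c("sex", "followup_duration"),
                      engine = "lmm")
    })), family_size = length(d_emotional)),
    bonferroni_adjust(dplyr::bind_rows(lapply(d_cognitive, function(y) {
      fit_association(ch, y, "delta_stress",
                      covariates = c("sex", "followup_duration"),
                      engine = "lmm")
    })), family_size = length(d_cognitive))
  )
  mods <- dplyr::bind_rows(lapply(c(d_emotional, d_cognitive), function(y) {
    tidy_moderation(fit_moderation(ch, y, "delta_stress", pcs_col,
                                   covariates = c("followup_duration", "sex",
                                                  "mean_fd"),
                                   engine = "lmm"))
  }))
  mods <- bonferroni_adjust(mods, family_size = length(d_emotional))
  # baseline PCS -> follow-up symptom levels
  prosp <- bonferroni_adjust(dplyr::bind_rows(lapply(
    c("anxiety_followup", "depression_followup"), function(y) {
      fit_association(ch, y, pcs_col,
                      covariates = c("baseline_age", "sex", "mean_fd"),
                      engine = "lmm")
    })), family_size = 2L)
  f1 <- write_result(assoc, paths, "longitudinal_associations")
  f2 <- write_result(mods, paths, "longitudinal_moderation")
  f3 <- write_result(prosp, paths, "longitudinal_prospective")
  list(files = c(f1, f2, f3),
       n_change_rows = nrow(ch), n_excluded = attr(ch, "n_excluded"),
       converged = all(assoc$converged) && all(mods$converged) &&
         all(prosp$converged))
}

stage_sensitivity <- function(config, paths) {
  tab <- analysis_table(paths)
  ch <- compute_change_scores(tab)
  pcs_cols <- grep("^pcs_", names(ch), value = TRUE)
  rows <- list()
  for (pcs_col in sort(pcs_cols)) {
    for (y in c("delta_anxiety", "delta_depression")) {
      res <- tidy_moderation(fit_moderation(
        ch, y, "delta_stress", pcs_col,
        covariates = c("followup_duration", "sex", "mean_fd"),
        engine = "lmm"))
      res$template <- sub("^pcs_", "", pcs_col)
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  f <- write_result(out, paths, "sensitivity_moderation")
  list(files = f, n_templates = length(pcs_cols), n_models = nrow(out))
}

# independent clinical-style arm: smaller unrelated-singleton cohort with a
# shifted vulnerability distribution, analyzed with the OLS engine
clinical_config <- function(config, n_clinical = 80L) {
  sim_config(
    seed = derive_seed(config$seed, 61L),
    n_families = n_clinical, twins_per_family = 1L, n_subjects = n_clinical,
    followup_rate = 1, attrition = "deterministic",
    atlas_p = config$atlas_p, series_length = config$series_length,
    template_spec = config$template_spec,
    vulnerability_sd = config$vulnerability_sd,
    fc_coupling = config$fc_coupling,
    max_distortion = config$max_distortion,
    outcome_params = config$outcome_params,
    covariate_params = utils::modifyList(config$covariate_params,
                                         list(age_range = c(12, 18),
                                              sex_ratio = 0.76)),
    discretize = config$discretize
  )
}

stage_exploratory <- function(config, paths, main_template = "css_synthetic_mdd",
                              n_clinical = 80L, vulnerability_shift = 0.5) {
  tab <- analysis_table(paths)
  bl <- tab[tab$timepoint == "baseline", , drop = FALSE]
  pcs_col <- paste0("pcs_", main_template)
  ccfg <- clinical_config(config, n_clinical)
  # the clinical arm shares the main cohort's template (same scoring pipeline)
  # and plants a higher mean vulnerability, which flows into both the symptom
  # model and the connectome shift
  main_tpl <- load_template(file.path(paths$templates,
                                      paste0(main_template, ".tsv")))
  shift_v <- withr::with_seed(derive_seed(ccfg$seed, 41L),
                              stats::rnorm(n_clinical, vulnerability_shift,
                                           ccfg$vulnerability_sd))
  clin_long <- generate_outcomes(shift_v, ccfg)
  subj <- unique(clin_long$subject_id)
  base <- base_covariance(ccfg)
  sh <- template_shift(main_tpl)
  ts <- withr::with_seed(derive_seed(ccfg$seed, 51L), {
    lapply(seq_along(shift_v), function(i) {
      generate_subject_timeseries(shift_v[i], main_tpl, ccfg,
                                  subject_id = subj[i],
                                  base = base, shift = sh)
    })
  })
  edges <- lapply(ts, function(x) vectorize_fc(compute_fc(x)))
  cscores <- batch_score(edges, main_tpl)
  clin <- clin_long[clin_long$timepoint == "baseline", , drop = FALSE]
  clin <- dplyr::left_join(clin,
                           stats::setNames(cscores[, c("subject_id", "pcs")],
                                           c("subject_id", pcs_col)),
                           by = "subject_id")
  assoc <- dplyr::bind_rows(
    fit_association(clin, "depression", "stress",
                    covariates = c("sex", "age"), engine = "ols"),
    fit_association(clin, "depression", pcs_col,
                    covariates = c("sex", "age", "mean_fd"), engine = "ols")
  )
  assoc <- bonferroni_adjust(assoc, family_size = nrow(assoc))
  mod <- tidy_moderation(fit_moderation(clin, "depression", "stress", pcs_col,
                                        covariates = c("sex", "age", "mean_fd"),
                                        engine = "ols"))
  grp <- tertile_split(clin[[pcs_col]])
  clin$pcs_group <- grp
  subgroup <- dplyr::bind_rows(lapply(levels(grp), function(g) {
    res <- fit_association(clin[clin$pcs_group == g, , drop = FALSE],
                           "depression", "stress",
                           covariates = c("sex", "age"), engine = "ols")
    res$group <- g
    res
  }))
  both <- dplyr::bind_rows(
    dplyr::mutate(bl[, c("subject_id", "age", "sex", pcs_col)],
                  cohort = "community"),
    dplyr::mutate(clin[, c("subject_id", "age", "sex", pcs_col)],
                  cohort = "clinical")
  )
  anc <- ancova_group_compare(both, pcs_col, "cohort",
                              covariates = c("age", "sex"))
  anc_tab <- tibble::tibble(
    term = "cohort", f_statistic = anc$f_statistic, df1 = anc$df1,
    df2 = anc$df2, p = anc$p,
    adjusted_mean_clinical = anc$adjusted_means$mean[
      anc$adjusted_means$group == "clinical"],
    adjusted_mean_community = anc$adjusted_means$mean[
      anc$adjusted_means$group == "community"],
    n_obs = anc$n_obs
  )
  f1 <- write_result(assoc, paths, "exploratory_associations")
  f2 <- write_result(mod, paths, "exploratory_moderation")
  f3 <- write_result(subgroup, paths, "exploratory_subgroups")
  f4 <- write_result(anc_tab, paths, "exploratory_ancova")
  list(files = c(f1, f2, f3, f4), n_clinical = nrow(clin))
}

stage_report <- function(config, paths, stage_info) {
  dir.create(paths$results, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(paths$results, pattern = "\\.tsv$",
                           full.names = TRUE))
  lines <- c("pcscore pipeline report",
             sprintf("seed: %d", config$seed),
             sprintf("subjects: %d", config$n_subjects),
             sprintf("atlas parcels: %d, series length: %d",
                     config$atlas_p, config$series_length),
             "",
             "result tables:")
  for (f in files) {
    tab <- readr::read_tsv(f, col_types = readr::cols(), progress = FALSE)
    lines <- c(lines, sprintf("  %s: %d rows", basename(f), nrow(tab)))
  }
  out <- file.path(paths$results, "report.txt")
  writeLines(lines, out)
  list(files = out)
}

PIPELINE_STAGES <- c("simulate", "fc", "score", "baseline", "longitudinal",
                     "sensitivity", "exploratory", "report")

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in canonical order with plain-file handoff
#' under `out_dir`, and writes a JSON run manifest recording the config hash,
#' seed, per-stage row counts and the full output-file registry. Re-running
#' with an identical config reproduces every result table byte-for-byte
#' (manifest timestamps aside).
#'
#' @param config A [sim_config()], a list of its arguments, or the path to a
#'   JSON config file.
#' @param stages Subset of
#'   `c("simulate", "fc", "score", "baseline", "longitudinal", "sensitivity",
#'   "exploratory", "report")`; default all.
#' @param out_dir Output directory (created if absent).
#' @param strict Strict (`TRUE`, default) or lenient handling of degenerate
#'   subjects in the fc/score stages.
#' @param n_alternative_templates Number of alternative disorder templates
#'   registered for the sensitivity arm (default 3).
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES,
                         out_dir = tempfile("pcs_run_"), strict = TRUE,
                         n_alternative_templates = 3L) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  } else if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(out_dir)
  info <- list()
  for (st in stages) {
    info[[st]] <- switch(
      st,
      simulate = stage_simulate(config, paths, n_alternative_templates),
      fc = stage_fc(config, paths, strict = strict),
      score = stage_score(config, paths, strict = strict),
      baseline = stage_baseline(config, paths),
      longitudinal = stage_longitudinal(config, paths),
      sensitivity = stage_sensitivity(config, paths),
      exploratory = stage_exploratory(config, paths),
      report = stage_report(config, paths, info)
    )
  }
  registry <- sort(list.files(out_dir, recursive = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pcscore")),
    created_at = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    stage_info = info,
    outputs = registry
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
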