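# Synthetic twin-family cohort generator with known ground truth.
#
# The generator states one simulated world and the tests measure against it:
# a latent per-subject vulnerability v shifts (a) the subject's parcel-level
# BOLD covariance along the template pattern (so the PCS computed from the
# simulated time series is a noisy proxy of v) and (b) the change in symptom
# scores through a planted stress-by-vulnerability interaction, with a family
# random intercept providing twin clustering. Defaults are chosen once for
# test power (see the methods vignette) and mirror the cohort sizes of the
# motivating design: 407 subjects at baseline, 298 retained at follow-up.

# deterministic sub-stream seeds below 2^31, one per generator stage
derive_seed <- function(seed, k) {
  as.integer((((as.numeric(seed) %% 1000003) * 1009) + k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

YEO7 <- c("visual", "somatomotor", "dorsal_attention", "salience",
          "limbic", "control", "default_mode")

#' Simulation configuration for the synthetic twin cohort
#'
#' Collects and validates every knob of the generator. Defaults state the
#' standard scenario: 407 subjects in two-twin families, follow-up retention
#' 298/407 with deterministic thinning, a 20-parcel atlas with 300 timepoints
#' per subject, a sparse signed template (negative within the somatomotor
#' network, positive between somatomotor and salience, mirroring the
#' structure described for the MDD map), vulnerability coupling into the BOLD
#' covariance of 0.25, and a planted outcome model
#' `delta_symptom = b0 + b1*delta_stress + b2*v + b3*delta_stress*v + u_family + e`
#' with `b1 = 0.5`, `b2 = 0.2`, `b3 = 0.15`, family-intercept SD 0.4 and
#' residual SD solved so the planted outcome has unit total variance (so
#' standardized coefficient recovery targets the planted values directly).
#'
#' @param seed Integer master seed; every stage derives its own sub-seed.
#' @param n_families Number of families.
#' @param twins_per_family Subjects per family (default 2).
#' @param n_subjects Total subjects; defaults to `n_families *
#'   twins_per_family` but may be set lower (the last families are trimmed),
#'   e.g. 407 with 204 two-twin families.
#' @param followup_rate Fraction of subjects retained at follow-up, in (0, 1].
#' @param attrition `"deterministic"` (exactly `round(n * followup_rate)`
#'   subjects retained) or `"bernoulli"`.
#' @param atlas_p Parcel count (default 20; configurable to 400).
#' @param series_length Timepoints per subject (default 300).
#' @param template_spec List: `fraction_nonzero` in (0, 1], `weight_scale`
#'   (Cohen's d scale of the weights), `n_networks`.
#' @param vulnerability_sd SD of the latent vulnerability v.
#' @param fc_coupling alpha, scaling v's shift of the BOLD covariance along
#'   the template pattern.
#' @param max_distortion Maximal tolerated relative Frobenius distortion from
#'   positive-semidefinite ridge repair of a subject covariance.
#' @param outcome_params List: `b0`, `b1`, `b2`, `b3`, `family_intercept_sd`,
#'   `residual_sd` (NULL = solve for unit total outcome variance),
#'   `cognition_coupling` (near-zero stress coupling of the six cognitive
#'   subscales).
#' @param covariate_params List: `age_range` (years), `sex_ratio` (fraction
#'   coded 1), `fd_meanlog`/`fd_sdlog` (lognormal mean framewise
#'   displacement, mm), `followup_years_mean`/`followup_years_sd`,
#'   `left_handed_rate`.
#' @param discretize Round and clip questionnaire scores to instrument-like
#'   integer ranges instead of leaving them Gaussian (robustness mode).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 204L,
                       twins_per_family = 2L,
                       n_subjects = 407L,
                       followup_rate = 298 / 407,
                       attrition = c("deterministic", "bernoulli"),
                       atlas_p = 20L,
                       series_length = 300L,
                       template_spec = list(),
                       vulnerability_sd = 1,
                       fc_coupling = 0.25,
                       max_distortion = 0.1,
                       outcome_params = list(),
                       covariate_params = list(),
                       discretize = FALSE) {
  attrition <- match.arg(attrition)
  template_spec <- utils::modifyList(
    list(fraction_nonzero = 0.3, weight_scale = 0.3, n_networks = 4L),
    template_spec)
  outcome_params <- utils::modifyList(
    list(b0 = 0, b1 = 0.5, b2 = 0.2, b3 = 0.15,
         family_intercept_sd = 0.4, residual_sd = NULL,
         cognition_coupling = 0.05),
    outcome_params, keep.null = TRUE)
  covariate_params <- utils::modifyList(
    list(age_range = c(9, 13), sex_ratio = 0.5,
         fd_meanlog = log(0.15), fd_sdlog = 0.4,
         followup_years_mean = 20 / 12, followup_years_sd = 0.25,
         left_handed_rate = 0.18),
    covariate_params)
  if (is.null(n_subjects)) n_subjects <- n_families * twins_per_family
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              twins_per_family = as.integer(twins_per_family),
              n_subjects = as.integer(n_subjects),
              followup_rate = followup_rate, attrition = attrition,
              atlas_p = as.integer(atlas_p),
              series_length = as.integer(series_length),
              template_spec = template_spec,
              vulnerability_sd = vulnerability_sd,
              fc_coupling = fc_coupling, max_distortion = max_distortion,
              outcome_params = outcome_params,
              covariate_params = covariate_params,
              discretize = isTRUE(discretize))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
    if (n_subjects > n_families * twins_per_family) {
      stop("n_subjects exceeds n_families * twins_per_family", call. = FALSE)
    }
    if (followup_rate <= 0 || followup_rate > 1) {
      stop("followup_rate must be in (0, 1]", call. = FALSE)
    }
    if (template_spec$fraction_nonzero <= 0 || template_spec$fraction_nonzero > 1) {
      stop("template_spec$fraction_nonzero must be in (0, 1]", call. = FALSE)
    }
    if (template_spec$weight_scale <= 0) {
      stop("template_spec$weight_scale must be > 0", call. = FALSE)
    }
    if (template_spec$n_networks < 2L || template_spec$n_networks > length(YEO7)) {
      stop("template_spec$n_networks must be between 2 and ", length(YEO7),
           call. = FALSE)
    }
    if (atlas_p < 2L * template_spec$n_networks) {
      stop("atlas_p too small for the requested network count", call. = FALSE)
    }
    if (series_length < 3L) stop("series_length must be >= 3", call. = FALSE)
    if (vulnerability_sd <= 0) stop("vulnerability_sd must be > 0", call. = FALSE)
    if (outcome_params$family_intercept_sd < 0) {
      stop("family_intercept_sd must be >= 0", call. = FALSE)
    }
    if (!is.null(outcome_params$residual_sd) && outcome_params$residual_sd <= 0) {
      stop("residual_sd must be > 0", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d subjects (%d families), atlas P = %d, T = %d, followup %.3f (%s)\n",
    x$seed, x$n_subjects, ceiling(x$n_subjects / x$twins_per_family),
    x$atlas_p, x$series_length, x$followup_rate, x$attrition))
  invisible(x)
}

# residual SD solving Var(planted outcome) = 1 given the other components
solve_residual_sd <- function(cfg) {
  op <- cfg$outcome_params
  if (!is.null(op$residual_sd)) return(op$residual_sd)
  vs2 <- cfg$vulnerability_sd^2
  expl <- op$b1^2 + op$b2^2 * vs2 + op$b3^2 * vs2 + op$family_intercept_sd^2
  if (expl >= 0.98) {
    stop("planted effects plus family variance leave no room for residual ",
         "noise at unit total variance; set residual_sd explicitly",
         call. = FALSE)
  }
  sqrt(1 - expl)
}

#' Generate a synthetic CSS template with planted block structure
#'
#' Stand-in for a meta-analytic disorder map: negative weights on every
#' within-somatomotor edge, positive weights on every somatomotor-salience
#' edge, and the remaining non-zero weights (up to
#' `fraction_nonzero * E` in total) drawn symmetrically about 0. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @param template_id Identifier for the generated template.
#' @param seed_offset Sub-stream offset; alternative templates for
#'   sensitivity analyses use different offsets.
#' @return A [css_template()].
#' @export
generate_template <- function(config, template_id = "css_synthetic_mdd",
                              seed_offset = 11L) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$template_spec
  p <- config$atlas_p
  withr::with_seed(derive_seed(config$seed, seed_offset), {
    labels <- sprintf("parcel_%03d", seq_len(p))
    nets <- YEO7[seq_len(spec$n_networks)]
    assignment <- nets[cut(seq_len(p), spec$n_networks, labels = FALSE)]
    partition <- stats::setNames(assignment, labels)
    idx <- edge_pairs(p)
    e_total <- nrow(idx)
    ni <- assignment[idx[, 1L]]
    nj <- assignment[idx[, 2L]]
    neg_block <- ni == "somatomotor" & nj == "somatomotor"
    pos_block <- (ni == "somatomotor" & nj == "salience") |
      (ni == "salience" & nj == "somatomotor")
    w <- numeric(e_total)
    sc <- spec$weight_scale
    w[neg_block] <- -abs(stats::rnorm(sum(neg_block), mean = sc, sd = sc / 3))
    w[pos_block] <- abs(stats::rnorm(sum(pos_block), mean = sc, sd = sc / 3))
    n_target <- max(round(spec$fraction_nonzero * e_total),
                    sum(neg_block | pos_block))
    other <- which(!(neg_block | pos_block))
    n_extra <- min(n_target - sum(neg_block | pos_block), length(other))
    if (n_extra > 0L) {
      sel <- if (n_extra == length(other)) other else sample(other, n_extra)
      w[sel] <- stats::rnorm(n_extra, mean = 0, sd = sc)
    }
    css_template(w, parcel_labels = labels, network_partition = partition,
                 template_id = template_id, atlas_id = sprintf("synthetic_p%d", p))
  })
}

#' Well-conditioned base correlation matrix shared by all subjects
#'
#' A two-factor structure plus dominant diagonal, rescaled to a correlation
#' matrix: the population connectome of a subject with vulnerability v = 0.
#'
#' @param config A [sim_config()].
#' @return P x P correlation matrix.
#' @export
base_covariance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$atlas_p
  withr::with_seed(derive_seed(config$seed, 21L), {
    loading <- matrix(stats::rnorm(p * 2L), p, 2L) * 0.35
    # the 2I ridge keeps the minimal eigenvalue >= ~0.63 across seeds, so the
    # default vulnerability coupling rarely needs PSD repair (and never beyond
    # a few percent relative distortion)
    stats::cov2cor(tcrossprod(loading) + 2 * diag(p))
  })
}

#' Symmetrized template weight matrix scaled to unit spectral norm
#'
#' The direction along which vulnerability shifts a subject's covariance.
#'
#' @param template A [css_template()].
#' @return P x P symmetric matrix with spectral norm 1.
#' @export
template_shift <- function(template) {
  stopifnot(inherits(template, "css_template"))
  p <- length(template$parcel_labels)
  w <- matrix(0, p, p)
  w[template$edge_index] <- template$weights
  w <- w + t(w)
  ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  w / max(abs(ev))
}

# Sigma(v) = Sigma0 + alpha * v * shift, with ridge repair when the requested
# matrix loses positive semidefiniteness: add (|min eigenvalue| + 1e-6) * I,
# renormalize the diagonal to 1, and log the relative Frobenius distortion.
sigma_for_vulnerability <- function(v, base, shift, coupling,
                                    max_distortion = 0.1) {
  requested <- base + coupling * v * shift
  diag(requested) <- 1
  eigs <- eigen(requested, symmetric = TRUE, only.values = TRUE)$values
  min_eig <- min(eigs)
  sigma <- requested
  repaired <- FALSE
  if (min_eig < 1e-10) {
    lambda <- abs(min_eig) + 1e-6
    sigma <- stats::cov2cor(requested + lambda * diag(nrow(requested)))
    repaired <- TRUE
  }
  distortion <- norm(sigma - requested, "F") / norm(requested, "F")
  if (distortion > max_distortion) {
    stop(sprintf(
      "covariance repair distortion %.3f exceeds bound %.3f at v = %.2f: reduce fc_coupling",
      distortion, max_distortion, v), call. = FALSE)
  }
  list(sigma = sigma, repaired = repaired, distortion = distortion)
}

#' Simulate one subject's parcel time series at a given vulnerability
#'
#' Draws `series_length` timepoints from a zero-mean multivariate normal whose
#' correlation is the base connectome shifted along the template pattern in
#' proportion to the subject's latent vulnerability, so the subject's PCS
#' against that template increases with v by construction.
#'
#' Uses the current RNG state; seed at the cohort level (see
#' [simulate_cohort()]) or via `seed`.
#'
#' @param v Latent vulnerability of the subject.
#' @param template A [css_template()].
#' @param config A [sim_config()].
#' @param subject_id Subject identifier.
#' @param base,shift Optional precomputed [base_covariance()] /
#'   [template_shift()] (recomputed when omitted; precompute for cohorts).
#' @param seed Optional seed for standalone deterministic draws.
#' @return A [parcel_ts()] with attributes `vulnerability`, `repaired`,
#'   `distortion`.
#' @export
generate_subject_timeseries <- function(v, template, config,
                                        subject_id = "subject",
                                        base = NULL, shift = NULL,
                                        seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(template, "css_template"))
  if (is.null(base)) base <- base_covariance(config)
  if (is.null(shift)) shift <- template_shift(template)
  rep_cov <- sigma_for_vulnerability(v, base, shift, config$fc_coupling,
                                     config$max_distortion)
  draw <- function() {
    z <- matrix(stats::rnorm(config$series_length * config$atlas_p),
                config$series_length, config$atlas_p)
    z %*% chol(rep_cov$sigma)
  }
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ts <- parcel_ts(x, subject_id = subject_id,
                  parcel_labels = template$parcel_labels)
  attr(ts, "vulnerability") <- v
  attr(ts, "repaired") <- rep_cov$repaired
  attr(ts, "distortion") <- rep_cov$distortion
  ts
}

# instrument-like integer scales for the optional discretization mode
discretize_scores <- function(tab) {
  clip <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
  tab$stress <- clip(22 + 12 * tab$stress, 0, 60)
  tab$anxiety <- clip(25 + 14 * tab$anxiety, 0, 114)
  tab$depression <- clip(4.3 + 3.5 * tab$depression, 0, 26)
  tab
}

#' Generate phenotypes and outcomes for a vulnerability vector
#'
#' Builds the long-format cohort table (baseline rows for everyone, follow-up
#' rows for retained subjects) with the planted moderation structure:
#'
#' * baseline symptom = `b0 + b1*stress + b2*v + u_family + e`
#' * symptom change  = `b0 + b1*delta_stress + b2*v + b3*delta_stress*v +
#'   u_family + e`
#' * six cognitive subscales with near-zero stress coupling and no
#'   interaction (mirroring null cognitive findings)
#'
#' Stress (baseline and change) and the latent vulnerability are standard
#' normal on the latent scale; `discretize = TRUE` in the config maps scores
#' to bounded integer questionnaire ranges instead. Ages, sex, handedness and
#' mean framewise displacement are drawn per `covariate_params`. Attrition is
#' exact-count under `"deterministic"` thinning and per-subject Bernoulli
#' otherwise.
#'
#' @param vulnerability Numeric vector of latent v, one per subject.
#' @param config A [sim_config()] (`n_subjects` must equal
#'   `length(vulnerability)`).
#' @param family_id Optional family assignment; defaults to consecutive
#'   blocks of `twins_per_family`.
#' @return Long-format tibble: `subject_id`, `family_id`, `timepoint`, `age`,
#'   `sex`, `handedness`, `mean_fd`, `stress`, `anxiety`, `depression`,
#'   `cog_*` (6 columns), `vulnerability`.
#' @export
generate_outcomes <- function(vulnerability, config, family_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(vulnerability)
  if (n != config$n_subjects) {
    stop("length(vulnerability) must equal config$n_subjects", call. = FALSE)
  }
  op <- config$outcome_params
  cp <- config$covariate_params
  resid_sd <- solve_residual_sd(config)
  if (is.null(family_id)) {
    family_id <- sprintf("fam_%04d", ceiling(seq_len(n) / config$twins_per_family))
  }
  fam_levels <- unique(family_id)
  fam_idx <- match(family_id, fam_levels)
  cog_names <- paste0("cog_", c("flanker", "cardsort", "pattern", "picseq",
                                "vocab", "reading"))
  withr::with_seed(derive_seed(config$seed, 31L), {
    subject_id <- sprintf("sub_%04d", seq_len(n))
    age_bl <- stats::runif(n, cp$age_range[1L], cp$age_range[2L])
    sex <- stats::rbinom(n, 1L, cp$sex_ratio)
    handedness <- stats::rbinom(n, 1L, 1 - cp$left_handed_rate)  # 1 = right
    mean_fd <- stats::rlnorm(n, cp$fd_meanlog, cp$fd_sdlog)
    duration <- pmax(stats::rnorm(n, cp$followup_years_mean,
                                  cp$followup_years_sd), 0.5)
    stress_bl <- stats::rnorm(n)
    d_stress <- stats::rnorm(n)
    fam_draw <- function() stats::rnorm(length(fam_levels),
                                        sd = op$family_intercept_sd)[fam_idx]
    planted <- function(x, interaction) {
      op$b0 + op$b1 * x + op$b2 * vulnerability +
        (if (interaction) op$b3 * x * vulnerability else 0) +
        fam_draw() + stats::rnorm(n, sd = resid_sd)
    }
    anxiety_bl <- planted(stress_bl, interaction = FALSE)
    depression_bl <- planted(stress_bl, interaction = FALSE)
    d_anxiety <- planted(d_stress, interaction = TRUE)
    d_depression <- planted(d_stress, interaction = TRUE)
    cog_bl <- replicate(6L, op$cognition_coupling * stress_bl +
                          fam_draw() + stats::rnorm(n))
    d_cog <- replicate(6L, op$cognition_coupling * d_stress +
                         fam_draw() + stats::rnorm(n))
    colnames(cog_bl) <- colnames(d_cog) <- cog_names
    n_keep <- round(n * config$followup_rate)
    kept <- if (config$attrition == "deterministic") {
      sort(sample.int(n, n_keep))
    } else {
      which(stats::rbinom(n, 1L, config$followup_rate) == 1L)
    }
    baseline <- tibble::tibble(
      subject_id = subject_id, family_id = family_id, timepoint = "baseline",
      age = age_bl, sex = sex, handedness = handedness, mean_fd = mean_fd,
      stress = stress_bl, anxiety = anxiety_bl, depression = depression_bl,
      vulnerability = vulnerability
    )
    baseline <- dplyr::bind_cols(baseline, tibble::as_tibble(cog_bl))
    followup <- tibble::tibble(
      subject_id = subject_id[kept], family_id = family_id[kept],
      timepoint = "followup",
      age = age_bl[kept] + duration[kept], sex = sex[kept],
      handedness = handedness[kept], mean_fd = mean_fd[kept],
      stress = stress_bl[kept] + d_stress[kept],
      anxiety = anxiety_bl[kept] + d_anxiety[kept],
      depression = depression_bl[kept] + d_depression[kept],
      vulnerability = vulnerability[kept]
    )
    followup <- dplyr::bind_cols(
      followup, tibble::as_tibble(cog_bl[kept, , drop = FALSE] +
                                    d_cog[kept, , drop = FALSE]))
    tab <- dplyr::bind_rows(baseline, followup)
    if (config$discretize) tab <- discretize_scores(tab)
    tab
  })
}

#' Simulate a full twin cohort: template, vulnerabilities, phenotypes, BOLD
#'
#' Runs the whole generator under the config's master seed: a planted-block
#' CSS template, latent vulnerabilities (one per subject), the phenotype /
#' outcome table, and optionally each subject's parcel time series whose
#' covariance is shifted along the template in proportion to v.
#'
#' @param config A [sim_config()].
#' @param include_timeseries Generate per-subject BOLD series (set `FALSE`
#'   when only the phenotype/outcome layer is needed).
#' @return List of class `sim_cohort`: `config`, `template`, `vulnerability`
#'   (tibble subject_id, family_id, v), `cohort` (long phenotype table),
#'   `timeseries` (named list of [parcel_ts()] or NULL), `repair_log`
#'   (tibble: subject_id, repaired, distortion).
#' @export
simulate_cohort <- function(config, include_timeseries = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  template <- generate_template(config)
  n <- config$n_subjects
  v <- withr::with_seed(derive_seed(config$seed, 41L),
                        stats::rnorm(n, 0, config$vulnerability_sd))
  cohort <- generate_outcomes(v, config)
  subj <- unique(cohort$subject_id)
  vt <- tibble::tibble(
    subject_id = subj,
    family_id = cohort$family_id[match(subj, cohort$subject_id)],
    vulnerability = v
  )
  timeseries <- NULL
  repair_log <- NULL
  if (include_timeseries) {
    base <- base_covariance(config)
    shift <- template_shift(template)
    timeseries <- withr::with_seed(derive_seed(config$seed, 51L), {
      lapply(seq_len(n), function(i) {
        generate_subject_timeseries(v[i], template, config,
                                    subject_id = subj[i],
                                    base = base, shift = shift)
      })
    })
    names(timeseries) <- subj
    repair_log <- tibble::tibble(
      subject_id = subj,
      repaired = vapply(timeseries, function(x) attr(x, "repaired"), logical(1)),
      distortion = vapply(timeseries, function(x) attr(x, "distortion"), numeric(1))
    )
  }
  structure(
    list(config = config, template = template, vulnerability = vt,
         cohort = cohort, timeseries = timeseries, repair_log = repair_log),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d cohort rows, timeseries: %s\n",
              nrow(x$vulnerability), nrow(x$cohort),
              if (is.null(x$timeseries)) "no" else "yes"))
  invisible(x)
}

#' Score a simulated cohort and attach PCS columns to its phenotype table
#'
#' Computes each subject's FC matrix from the simulated series, vectorizes it,
#' scores it against the given templates, and joins the scores onto the long
#' cohort table as `pcs_<template_id>` columns (imaging is baseline-only, so
#' both timepoints carry the same score).
#'
#' @param sim A `sim_cohort` with time series.
#' @param templates Template or list of templates (default: the cohort's own).
#' @param degenerate_policy Passed to [compute_fc()].
#' @return List: `scores` (tibble from [batch_score()]), `cohort` (phenotype
#'   table with PCS columns).
#' @export
score_cohort <- function(sim, templates = NULL,
                         degenerate_policy = "strict") {
  stopifnot(inherits(sim, "sim_cohort"))
  if (is.null(sim$timeseries)) {
    stop("cohort was simulated without time series", call. = FALSE)
  }
  if (is.null(templates)) templates <- list(sim$template)
  if (inherits(templates, "css_template")) templates <- list(templates)
  edges <- lapply(sim$timeseries, function(ts) {
    vectorize_fc(compute_fc(ts, degenerate_policy = degenerate_policy))
  })
  scores <- batch_score(edges, templates)
  wide <- tidyr::pivot_wider(scores[, c("subject_id", "template_id", "pcs")],
                             names_from = "template_id",
                             values_from = "pcs", names_prefix = "pcs_")
  cohort <- dplyr::left_join(sim$cohort, wide, by = "subject_id")
  list(scores = scores, cohort = cohort)
}
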