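# Family-clustered inference layer: standardized association models,
# moderation with conditional slopes and delta-R2, group ANCOVA.
#
# Engines:
#   lmm_random_intercept — lme4::lmer with a per-family random intercept,
#     Wald z intervals and p-values on the fixed effects (Satterthwaite
#     refinements deliberately not attempted);
#   ols — base lm (used for the unclustered clinical-style arm), t intervals.
#
# Continuous outcome/predictor/moderator/covariates are z-scored internally
# (n-1 denominator) so reported coefficients are standardized betas; binary
# covariates stay on their 0/1 coding.

prepare_model_frame <- function(data, vars, cluster, engine) {
  missing_cols <- setdiff(c(vars, if (engine == "lmm_random_intercept") cluster),
                          names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not present: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- c(vars, if (engine == "lmm_random_intercept") cluster)
  df <- data[stats::complete.cases(data[, keep, drop = FALSE]), keep, drop = FALSE]
  if (nrow(df) < length(vars) + 2L) {
    stop("too few complete cases (", nrow(df), ") to fit the model", call. = FALSE)
  }
  if (engine == "lmm_random_intercept") {
    if (length(unique(df[[cluster]])) < 2L) {
      stop("mixed-model engine needs at least 2 families/clusters", call. = FALSE)
    }
    df[[cluster]] <- as.factor(df[[cluster]])
  }
  df <- standardize_center(df, vars, mode = "zscore")
  df
}

fit_engine <- function(formula, df, engine) {
  converged <- TRUE
  singular <- FALSE
  messages <- character()
  if (engine == "lmm_random_intercept") {
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.nobs.vs.nlev = "ignore",  # singleton-family limit
                   check.nobs.vs.nRE = "ignore")),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    conv_msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(conv_msgs)) messages <- c(messages, unlist(conv_msgs))
    converged <- !any(grepl("fail|unable|conv", messages, ignore.case = TRUE))
    singular <- lme4::isSingular(fit, tol = 1e-5)
  } else {
    fit <- stats::lm(formula, data = df)
  }
  list(fit = fit, converged = converged, singular = singular,
       messages = messages)
}

# coefficient, se, Wald/t CI and two-tailed p for one fixed-effect term
extract_term <- function(fitted, term, engine, df_resid = NULL) {
  if (engine == "lmm_random_intercept") {
    co <- lme4::fixef(fitted)
    vc <- as.matrix(stats::vcov(fitted))
    est <- unname(co[term])
    se <- sqrt(vc[term, term])
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    crit <- stats::qnorm(0.975)
  } else {
    sm <- summary(fitted)$coefficients
    est <- sm[term, "Estimate"]
    se <- sm[term, "Std. Error"]
    if (se == 0) {  # perfect fit: p collapses to 0
      p <- 0
      crit <- 0
    } else {
      p <- sm[term, "Pr(>|t|)"]
      crit <- stats::qt(0.975, df = stats::df.residual(fitted))
    }
  }
  list(beta = est, se = se, ci_low = est - crit * se, ci_high = est + crit * se,
       p = unname(p))
}

# squared correlation between fixed-effect-only predictions and the observed
# outcome; the engine-agnostic "fixed-effects R2" used for delta-R2
r2_fixed <- function(fitted, df, outcome, engine) {
  pred <- if (engine == "lmm_random_intercept") {
    stats::predict(fitted, re.form = NA)
  } else {
    stats::predict(fitted)
  }
  if (stats::sd(pred) == 0) return(0)
  stats::cor(pred, df[[outcome]])^2
}

normalize_engine <- function(engine) {
  engine <- match.arg(engine[1L], c("lmm_random_intercept", "lmm", "ols"))
  if (engine == "lmm") engine <- "lmm_random_intercept"
  engine
}

#' Standardized association between a predictor and an outcome
#'
#' Fits `outcome ~ predictor + covariates`, with a per-family random intercept
#' under the `lmm_random_intercept` engine (twin/sibling cohorts) or plain OLS
#' (independent samples). Outcome, predictor and continuous covariates are
#' z-scored internally, so `beta` is a standardized coefficient; binary
#' covariates keep their coding. Non-convergence never raises — the result is
#' flagged `converged = FALSE` with the optimizer's diagnostics attached.
#'
#' @param data Data frame with one row per observation.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate column names.
#' @param cluster Clustering column for the random intercept (default
#'   `"family_id"`).
#' @param engine `"lmm_random_intercept"` (alias `"lmm"`) or `"ols"`.
#' @return A one-row tibble of class `assoc_result`: `outcome`, `predictor`,
#'   `beta`, `ci_low`, `ci_high`, `p`, `p_adjusted` (NA until
#'   [bonferroni_adjust()]), `n_obs`, `converged`, `singular`.
#' @export
fit_association <- function(data, outcome, predictor, covariates = character(),
                            cluster = "family_id",
                            engine = c("lmm_random_intercept", "ols")) {
  engine <- normalize_engine(engine)
  vars <- c(outcome, predictor, covariates)
  df <- prepare_model_frame(data, vars, cluster, engine)
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  fstr <- if (engine == "lmm_random_intercept") {
    sprintf("%s ~ %s + (1 | %s)", outcome, rhs, cluster)
  } else {
    sprintf("%s ~ %s", outcome, rhs)
  }
  eng <- fit_engine(stats::as.formula(fstr), df, engine)
  term <- extract_term(eng$fit, predictor, engine)
  out <- tibble::tibble(
    outcome = outcome, predictor = predictor,
    beta = term$beta, ci_low = term$ci_low, ci_high = term$ci_high,
    p = term$p, p_adjusted = NA_real_, n_obs = nrow(df),
    converged = eng$converged, singular = eng$singular
  )
  attr(out, "formula") <- fstr
  attr(out, "messages") <- eng$messages
  class(out) <- c("assoc_result", class(out))
  out
}

#' Moderation model with conditional slopes and delta-R2
#'
#' Fits `Y ~ X + W + X:W + covariates` (plus a family random intercept under
#' the mixed-model engine) and quantifies the moderation three ways, matching
#' standard moderation-analysis reporting:
#'
#' * the standardized interaction coefficient with its 95% CI and p;
#' * `delta_r2`, the gain in fixed-effects explained variance from adding the
#'   interaction, where the fixed-effects R2 is the squared correlation
#'   between fixed-effect-only predictions and the observed outcome (clipped
#'   at 0 for reporting);
#' * conditional (simple) slopes of X at W = mean - 1 SD and mean + 1 SD, each
#'   with a delta-method CI and p from the fitted covariance of estimates.
#'
#' Because X, W and Y are z-scored internally, the conditional slopes are
#' evaluated at W = -1 and +1 and satisfy
#' `slope_high - slope_low = 2 * interaction_beta` exactly.
#'
#' @inheritParams fit_association
#' @param moderator Moderator column name (W).
#' @return An object of class `moderation_result`: list with
#'   `interaction_beta`, `ci_low`, `ci_high`, `p`, `delta_r2`, `slopes`
#'   (tibble: level, w_value, slope, ci_low, ci_high, p), `n_obs`,
#'   `converged`, `singular`, `engine`, `formula_full`, `formula_reduced`.
#' @export
fit_moderation <- function(data, outcome, predictor, moderator,
                           covariates = character(), cluster = "family_id",
                           engine = c("lmm_random_intercept", "ols")) {
  engine <- normalize_engine(engine)
  vars <- c(outcome, predictor, moderator, covariates)
  df <- prepare_model_frame(data, vars, cluster, engine)
  rhs_main <- paste(c(predictor, moderator, covariates), collapse = " + ")
  inter <- paste0(predictor, ":", moderator)
  re <- if (engine == "lmm_random_intercept") sprintf(" + (1 | %s)", cluster) else ""
  f_full <- sprintf("%s ~ %s + %s%s", outcome, rhs_main, inter, re)
  f_red <- sprintf("%s ~ %s%s", outcome, rhs_main, re)
  eng_full <- fit_engine(stats::as.formula(f_full), df, engine)
  eng_red <- fit_engine(stats::as.formula(f_red), df, engine)
  term <- extract_term(eng_full$fit, inter, engine)
  dr2 <- r2_fixed(eng_full$fit, df, outcome, engine) -
    r2_fixed(eng_red$fit, df, outcome, engine)
  dr2 <- max(0, dr2)
  # conditional slopes of X at W = -1 / +1 SD (z-scored scale): delta method
  # on slope(w) = bX + w * bXW using the fitted covariance of estimates
  vc <- as.matrix(stats::vcov(eng_full$fit))
  co <- if (engine == "lmm_random_intercept") lme4::fixef(eng_full$fit) else stats::coef(eng_full$fit)
  crit <- if (engine == "lmm_random_intercept") stats::qnorm(0.975) else stats::qt(0.975, stats::df.residual(eng_full$fit))
  slope_at <- function(w) {
    est <- unname(co[predictor] + w * co[inter])
    v <- vc[predictor, predictor] + w^2 * vc[inter, inter] +
      2 * w * vc[predictor, inter]
    se <- sqrt(max(v, 0))
    p <- if (se == 0) {
      if (est == 0) 1 else 0
    } else if (engine == "lmm_random_intercept") {
      2 * stats::pnorm(-abs(est / se))
    } else {
      2 * stats::pt(-abs(est / se), stats::df.residual(eng_full$fit))
    }
    tibble::tibble(w_value = w, slope = est, ci_low = est - crit * se,
                   ci_high = est + crit * se, p = p)
  }
  slopes <- dplyr::bind_rows(
    dplyr::mutate(slope_at(-1), level = "low", .before = 1),
    dplyr::mutate(slope_at(1), level = "high", .before = 1)
  )
  structure(
    list(outcome = outcome, predictor = predictor, moderator = moderator,
         interaction_beta = term$beta, ci_low = term$ci_low,
         ci_high = term$ci_high, p = term$p, delta_r2 = dr2,
         slopes = slopes, n_obs = nrow(df),
         converged = eng_full$converged && eng_red$converged,
         singular = eng_full$singular || eng_red$singular,
         engine = engine, formula_full = f_full, formula_reduced = f_red),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("<moderation_result> %s ~ %s x %s (%s)\n", x$outcome,
              x$predictor, x$moderator, x$engine))
  cat(sprintf("  interaction beta = %.4f [%.4f, %.4f], p = %.4g, delta R2 = %.4f\n",
              x$interaction_beta, x$ci_low, x$ci_high, x$p, x$delta_r2))
  cat(sprintf("  slope at W = -1 SD: %.4f;  W = +1 SD: %.4f\n",
              x$slopes$slope[x$slopes$level == "low"],
              x$slopes$slope[x$slopes$level == "high"]))
  if (!x$converged) cat("  [non-converged fit]\n")
  invisible(x)
}

#' Flatten a moderation_result into a one-row tibble
#' @param x A `moderation_result`.
#' @return One-row tibble suitable for binding into result tables.
#' @export
tidy_moderation <- function(x) {
  stopifnot(inherits(x, "moderation_result"))
  lo <- x$slopes[x$slopes$level == "low", ]
  hi <- x$slopes[x$slopes$level == "high", ]
  tibble::tibble(
    outcome = x$outcome, predictor = x$predictor, moderator = x$moderator,
    interaction_beta = x$interaction_beta, ci_low = x$ci_low,
    ci_high = x$ci_high, p = x$p, p_adjusted = NA_real_,
    delta_r2 = x$delta_r2,
    slope_low = lo$slope, slope_low_p = lo$p,
    slope_high = hi$slope, slope_high_p = hi$p,
    n_obs = x$n_obs, converged = x$converged
  )
}

#' Bonferroni adjustment over a family of association tests
#'
#' @param results Tibble with a `p` column (e.g. rows from
#'   [fit_association()]).
#' @param family_size Number of tests in the family; defaults to
#'   `nrow(results)`.
#' @return `results` with `p_adjusted = min(1, family_size * p)` and a logical
#'   `significant` flag at adjusted alpha = 0.05.
#' @export
bonferroni_adjust <- function(results, family_size = nrow(results)) {
  if (family_size < 1L) stop("family_size must be >= 1", call. = FALSE)
  results$p_adjusted <- pmin(1, family_size * results$p)
  results$significant <- results$p_adjusted < 0.05
  results
}

#' Balanced low/medium/high split on a score vector
#'
#' Orders subjects by score and cuts into three groups whose sizes differ by
#' at most one (extras go to the lower groups first). Ties are broken by
#' stable input order.
#'
#' @param scores Numeric vector, length >= 3.
#' @return Factor with levels `low`, `medium`, `high` in input order;
#'   attribute `"boundaries"` holds the maximal score of the low and medium
#'   groups.
#' @export
tertile_split <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 scores to form tertile groups", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("all scores equal: tertile assignment follows input order only",
            call. = FALSE)
  }
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  ord <- order(scores)  # stable for ties
  grp <- integer(n)
  grp[ord] <- rep.int(1:3, times = sizes)
  out <- factor(c("low", "medium", "high")[grp],
                levels = c("low", "medium", "high"))
  attr(out, "boundaries") <- c(
    low_max = max(scores[out == "low"]),
    medium_max = max(scores[out == "medium"])
  )
  out
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Tests whether the response differs between groups after adjusting for
#' covariates: `response ~ covariates + group`, with the group F-test from the
#' comparison of the covariate-only and full models, and adjusted group means
#' evaluated at the sample means of the covariates.
#'
#' @param data Data frame.
#' @param response Response column name (e.g. a PCS column).
#' @param group Grouping column (coerced to factor, >= 2 levels with >= 2
#'   observations each).
#' @param covariates Covariate column names (default `c("age", "sex")`).
#' @return An object of class `ancova_result`: list with `f_statistic`, `df1`,
#'   `df2`, `p`, `adjusted_means` (tibble: group, mean, n), `n_obs`.
#' @export
ancova_group_compare <- function(data, response, group,
                                 covariates = c("age", "sex")) {
  vars <- c(response, covariates, group)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not present: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  df[[group]] <- droplevels(as.factor(df[[group]]))
  tab <- table(df[[group]])
  if (length(tab) < 2L) {
    stop("ANCOVA needs at least 2 groups, got ", length(tab), call. = FALSE)
  }
  if (any(tab < 2L)) {
    stop("every group needs >= 2 observations; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  f_red <- stats::as.formula(sprintf("%s ~ %s", response,
                                     paste(covariates, collapse = " + ")))
  f_full <- stats::as.formula(sprintf("%s ~ %s + %s", response,
                                      paste(covariates, collapse = " + "), group))
  fit_red <- stats::lm(f_red, data = df)
  fit_full <- stats::lm(f_full, data = df)
  an <- stats::anova(fit_red, fit_full)
  # adjusted means: prediction per group at the sample means of the covariates
  lv <- levels(df[[group]])
  newdata <- as.data.frame(lapply(df[covariates], function(x) {
    if (is.numeric(x)) mean(x) else x[1L]
  }))
  newdata <- newdata[rep(1L, length(lv)), , drop = FALSE]
  newdata[[group]] <- factor(lv, levels = lv)
  adj <- tibble::tibble(
    group = lv,
    mean = as.numeric(stats::predict(fit_full, newdata = newdata)),
    n = as.integer(tab[lv])
  )
  structure(
    list(f_statistic = an$F[2L], df1 = an$Df[2L],
         df2 = an$Res.Df[2L], p = an$`Pr(>F)`[2L],
         adjusted_means = adj, n_obs = nrow(df)),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f_statistic, x$p))
  print(x$adjusted_means)
  invisible(x)
}
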