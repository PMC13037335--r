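test_that("standardize_center centers and z-scores with n-1 denominator", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(2, 4, 6), sex = c(0, 1, 0))
  cen <- standardize_center(tab, "a", mode = "center")
  expect_equal(cen$a, c(-1, 0, 1))
  z <- standardize_center(tab, c("b", "sex"), mode = "zscore")
  expect_equal(z$b, c(-1, 0, 1))  # SD = 2
  expect_equal(z$sex, c(0, 1, 0))  # binary untouched
  params <- attr(z, "standardization")
  expect_equal(params$sd[params$variable == "b"], 2)
  expect_error(standardize_center(tibble::tibble(x = c(3, 3, 3, 4)),
                                  "x", "zscore"), NA)
  expect_error(standardize_center(tibble::tibble(x = rep(3, 4) + 0:3 * 0,
                                                 y = 1:4), "x", "zscore"),
               "zero variance")
})

test_that("OLS standardized beta equals the Pearson correlation", {
  for (seed in 1:5) {
    df <- withr::with_seed(seed, tibble::tibble(
      x = rnorm(60), y = 0.4 * x + rnorm(60)))
    res <- fit_association(df, "y", "x", engine = "ols")
    expect_equal(res$beta, cor(df$y, df$x), tolerance = 1e-8)
    expect_true(res$ci_low <= res$beta && res$beta <= res$ci_high)
  }
  # identity regression: beta 1, p collapses to 0
  df <- tibble::tibble(x = rnorm(30), y = NA)
  df$y <- df$x
  res <- suppressWarnings(fit_association(df, "y", "x", engine = "ols"))
  expect_equal(res$beta, 1, tolerance = 1e-8)
  expect_lt(res$p, 1e-200)
})

test_that("the mixed-model engine recovers a planted association", {
  cfg <- sim_config(seed = 5, n_families = 200, twins_per_family = 2,
                    n_subjects = 400, followup_rate = 1,
                    outcome_params = list(b1 = 0.6, b2 = 0, b3 = 0))
  v <- withr::with_seed(55, rnorm(400))
  tab <- generate_outcomes(v, cfg)
  bl <- tab[tab$timepoint == "baseline", ]
  res <- fit_association(bl, "anxiety", "stress", covariates = c("age", "sex"),
                         engine = "lmm")
  expect_true(res$converged)
  expect_equal(res$n_obs, 400L)
  # the planted standardized effect lies inside the model's own 95% CI
  expect_true(res$ci_low <= 0.6 && 0.6 <= res$ci_high)
  expect_equal(res$beta, 0.6, tolerance = 0.15)
})

test_that("moderation reporting satisfies its internal identities", {
  cfg <- sim_config(seed = 9, n_families = 150, twins_per_family = 2,
                    n_subjects = 300, followup_rate = 1)
  v <- withr::with_seed(99, rnorm(300))
  tab <- generate_outcomes(v, cfg)
  ch <- compute_change_scores(tab)
  mod <- fit_moderation(ch, "delta_anxiety", "delta_stress", "vulnerability",
                        covariates = c("sex"), engine = "lmm")
  expect_true(mod$converged)
  expect_gte(mod$delta_r2, 0)
  lo <- mod$slopes$slope[mod$slopes$level == "low"]
  hi <- mod$slopes$slope[mod$slopes$level == "high"]
  # conditional slopes at +/- 1 SD differ by exactly twice the interaction
  expect_equal(hi - lo, 2 * mod$interaction_beta, tolerance = 1e-8)

  # delta-R2 is invariant to affine rescaling of X and W
  resc <- ch
  resc$delta_stress <- 3 * resc$delta_stress + 2
  resc$vulnerability <- -0.5 * resc$vulnerability + 7
  mod2 <- fit_moderation(resc, "delta_anxiety", "delta_stress",
                         "vulnerability", covariates = c("sex"),
                         engine = "lmm")
  expect_equal(mod2$delta_r2, mod$delta_r2, tolerance = 1e-6)
})

test_that("noiseless interaction matches an independent two-fit R2 oracle", {
  df <- withr::with_seed(3, tibble::tibble(x = rnorm(80), w = rnorm(80)))
  df$y <- df$x + df$x * df$w
  mod <- suppressWarnings(
    fit_moderation(df, "y", "x", "w", engine = "ols"))
  expect_gt(mod$interaction_beta, 0)
  # oracle: standardized two-fit lm difference in R2
  zs <- function(v) (v - mean(v)) / sd(v)
  d2 <- tibble::tibble(y = zs(df$y), x = zs(df$x), w = zs(df$w))
  r2_full <- suppressWarnings(summary(lm(y ~ x + w + x:w, data = d2))$r.squared)
  r2_red <- summary(lm(y ~ x + w, data = d2))$r.squared
  expect_equal(mod$delta_r2, r2_full - r2_red, tolerance = 1e-10)
})

test_that("lmm and ols engines agree when every family has one subject", {
  df <- withr::with_seed(21, tibble::tibble(
    family_id = paste0("f", 1:150),
    x = rnorm(150), z = rnorm(150),
    y = 0.5 * x + 0.2 * z + rnorm(150)))
  a_lmm <- fit_association(df, "y", "x", covariates = "z", engine = "lmm")
  a_ols <- fit_association(df, "y", "x", covariates = "z", engine = "ols")
  expect_equal(a_lmm$beta, a_ols$beta, tolerance = 1e-4)
})

test_that("change scores subtract baseline from follow-up and log exclusions", {
  ch <- compute_change_scores(two_timepoint_cohort())
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$delta_stress[ch$subject_id == "s1"], 7)
  expect_equal(ch$delta_anxiety[ch$subject_id == "s3"], 2)
  expect_equal(ch$followup_duration[ch$subject_id == "s1"], 1.5)
  expect_equal(attr(ch, "n_excluded"), 1L)
  expect_equal(attr(ch, "excluded_subjects"), "s2")

  # a follow-up age not after baseline is a data-integrity error
  bad <- two_timepoint_cohort()
  bad$age[2] <- 9.5
  expect_error(compute_change_scores(bad), "s1")
})

test_that("bonferroni adjustment clips at 1 and flags significance", {
  res <- tibble::tibble(p = c(0.02, 0.04, 0.9))
  adj2 <- bonferroni_adjust(res[1:2, ], family_size = 2)
  expect_equal(adj2$p_adjusted, c(0.04, 0.08))
  expect_equal(adj2$significant, c(TRUE, FALSE))
  adj8 <- bonferroni_adjust(res[3, ], family_size = 8)
  expect_equal(adj8$p_adjusted, 1)
})

test_that("tertile_split balances group sizes and keeps stable tie order", {
  g <- tertile_split(1:9)
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_equal(which(g == "low"), 1:3)

  g80 <- tertile_split(withr::with_seed(1, rnorm(80)))
  sizes <- as.vector(table(g80))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(sizes), 80L)

  expect_warning(ge <- tertile_split(rep(2, 7)), "equal")
  expect_lte(max(table(ge)) - min(table(ge)), 1L)
  expect_equal(as.character(ge[1]), "low")  # stable assignment by input order

  expect_error(tertile_split(c(1, 2)), "at least 3")
})

test_that("ANCOVA separates real group effects from age confounding", {
  # group difference fully explained by a planted age effect: the adjusted
  # group test should be quiet while the unadjusted comparison fires
  df <- withr::with_seed(31, {
    age <- c(rnorm(150, 11, 1), rnorm(80, 15, 1))
    tibble::tibble(
      group = rep(c("a", "b"), c(150, 80)),
      age = age, sex = rbinom(230, 1, 0.5),
      pcs = 0.3 * age + rnorm(230, sd = 0.8))
  })
  adj <- ancova_group_compare(df, "pcs", "group", covariates = c("age", "sex"))
  raw_p <- t.test(pcs ~ group, data = df)$p.value
  expect_lt(raw_p, 1e-6)
  expect_gt(adj$p, 0.05)
  expect_equal(nrow(adj$adjusted_means), 2L)

  # planted true group shift of 0.5 SD survives adjustment (scaled-down
  # replicate count; power at this design is near 1)
  hits <- sapply(1:40, function(r) {
    d <- withr::with_seed(400 + r, tibble::tibble(
      group = rep(c("a", "b"), c(150, 80)),
      age = rnorm(230, 12, 1.5), sex = rbinom(230, 1, 0.5),
      pcs = rnorm(230) + 0.5 * (rep(c(0, 1), c(150, 80)))))
    ancova_group_compare(d, "pcs", "group")$p < 0.05
  })
  expect_gte(mean(hits), 0.8)

  expect_error(ancova_group_compare(df[df$group == "a", ], "pcs", "group"),
               "2 groups")
})
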