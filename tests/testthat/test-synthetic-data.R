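test_that("template generation is deterministic with the planted sign blocks", {
  cfg <- sim_config(seed = 12, n_subjects = 20, n_families = 10)
  tpl1 <- generate_template(cfg)
  tpl2 <- generate_template(cfg)
  expect_identical(tpl1$weights, tpl2$weights)
  expect_identical(tpl1$network_partition, tpl2$network_partition)

  # designated block signs verified through the aggregation oracle
  agg <- network_aggregate(tpl1, statistic = "mean")
  expect_lt(agg$block_matrix["somatomotor", "somatomotor"], 0)
  expect_gt(agg$block_matrix["somatomotor", "salience"], 0)

  # full-density template: every edge carries weight
  cfg_full <- sim_config(seed = 12, n_subjects = 20, n_families = 10,
                         template_spec = list(fraction_nonzero = 1))
  expect_true(all(generate_template(cfg_full)$weights != 0))

  expect_error(sim_config(template_spec = list(fraction_nonzero = 0)),
               "fraction_nonzero")
  expect_error(sim_config(followup_rate = 0), "followup_rate")
  expect_error(sim_config(vulnerability_sd = -1), "vulnerability_sd")
})

test_that("zero-vulnerability subjects score at the base connectome's PCS", {
  cfg <- sim_config(seed = 31, n_subjects = 60, n_families = 30,
                    series_length = 250)
  tpl <- generate_template(cfg)
  base <- base_covariance(cfg)
  shift <- template_shift(tpl)
  # population oracle straight from the base covariance
  pop <- compute_pcs(vectorize_fc(fc_matrix(
    base, "pop", parcel_labels = tpl$parcel_labels)), tpl)$score
  scores <- withr::with_seed(77, sapply(1:60, function(i) {
    ts <- generate_subject_timeseries(0, tpl, cfg, base = base, shift = shift)
    compute_pcs(vectorize_fc(compute_fc(ts)), tpl)$score
  }))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - pop), 3 * se + 1e-3)
})

test_that("PCS increases with the planted vulnerability", {
  cfg <- sim_config(seed = 13, n_subjects = 20, n_families = 10,
                    series_length = 2000, fc_coupling = 0.3)
  tpl <- generate_template(cfg)
  base <- base_covariance(cfg)
  shift <- template_shift(tpl)
  score_at <- function(v, seed) {
    ts <- generate_subject_timeseries(v, tpl, cfg, base = base, shift = shift,
                                      seed = seed)
    compute_pcs(vectorize_fc(compute_fc(ts)), tpl)$score
  }
  expect_gt(score_at(2, 501), score_at(-2, 502))

  # planted-signal recovery across a small cohort
  v <- withr::with_seed(14, rnorm(100))
  pcs <- withr::with_seed(15, sapply(v, function(vi) {
    ts <- generate_subject_timeseries(vi, tpl, sim_config(
      seed = 13, n_subjects = 20, n_families = 10, series_length = 500,
      fc_coupling = 0.3), base = base, shift = shift)
    compute_pcs(vectorize_fc(compute_fc(ts)), tpl)$score
  }))
  expect_gt(cor(pcs, v), 0.3)
})

test_that("covariance repair stays inside the distortion budget by default", {
  cfg <- sim_config(seed = 8, n_subjects = 40, n_families = 20,
                    series_length = 50)
  sim <- simulate_cohort(cfg, include_timeseries = TRUE)
  expect_true(all(sim$repair_log$distortion < 0.05))
  # an aggressive coupling is refused with actionable advice
  cfg_hot <- sim_config(seed = 8, n_subjects = 4, n_families = 2,
                        fc_coupling = 1.5, max_distortion = 0.05)
  tpl <- generate_template(cfg_hot)
  expect_error(
    generate_subject_timeseries(3, tpl, cfg_hot, seed = 1),
    "fc_coupling")
})

test_that("outcome generation is deterministic and honors exact attrition", {
  cfg <- sim_config(seed = 44)  # default 407 subjects, followup 298/407
  v <- withr::with_seed(45, rnorm(cfg$n_subjects))
  tab1 <- generate_outcomes(v, cfg)
  tab2 <- generate_outcomes(v, cfg)
  expect_identical(tab1, tab2)
  expect_equal(sum(tab1$timepoint == "baseline"), 407L)
  expect_equal(sum(tab1$timepoint == "followup"), 298L)
  ch <- compute_change_scores(tab1)
  expect_equal(nrow(ch), 298L)
  expect_equal(attr(ch, "n_excluded"), 109L)
  # twins share families: 2 subjects per family except possibly the last
  fam_sizes <- table(tab1$family_id[tab1$timepoint == "baseline"])
  expect_true(all(fam_sizes <= 2))
  expect_equal(sum(fam_sizes), 407L)
})

test_that("planted family intercepts produce recoverable clustering", {
  cfg <- sim_config(seed = 77, n_families = 500, twins_per_family = 2,
                    n_subjects = 1000, followup_rate = 1,
                    outcome_params = list(family_intercept_sd = 0.4))
  v <- withr::with_seed(78, rnorm(1000))
  tab <- generate_outcomes(v, cfg)
  bl <- tab[tab$timepoint == "baseline", ]
  fit <- lme4::lmer(anxiety ~ 1 + (1 | family_id), data = bl, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc <- vc$vcov[1] / sum(vc$vcov)
  expect_gt(icc, 0)
  expect_lt(abs(icc - 0.4^2), 0.1)  # absolute recovery band
})

test_that("whole-cohort simulation is reproducible end to end", {
  cfg <- sim_config(seed = 3, n_subjects = 12, n_families = 6,
                    series_length = 60)
  sim1 <- simulate_cohort(cfg, include_timeseries = TRUE)
  sim2 <- simulate_cohort(cfg, include_timeseries = TRUE)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$template$weights, sim2$template$weights)
  expect_identical(lapply(sim1$timeseries, function(x) x$data),
                   lapply(sim2$timeseries, function(x) x$data))
  sc1 <- score_cohort(sim1)
  sc2 <- score_cohort(sim2)
  expect_identical(sc1$scores, sc2$scores)
  expect_true(paste0("pcs_", sim1$template$template_id) %in%
                names(sc1$cohort))
})

test_that("discretization maps scores onto bounded instrument ranges", {
  cfg <- sim_config(seed = 19, n_subjects = 100, n_families = 50,
                    discretize = TRUE)
  v <- withr::with_seed(20, rnorm(100))
  tab <- generate_outcomes(v, cfg)
  expect_true(all(tab$stress >= 0 & tab$stress <= 60))
  expect_true(all(tab$depression >= 0 & tab$depression <= 26))
  expect_true(all(tab$stress == round(tab$stress)))
})
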