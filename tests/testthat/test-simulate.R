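test_that("scenario presets set the scenario-defining parameters", {
  null <- scenario_preset("null")
  expect_equal(null$causal_log_hr, 0)
  expect_equal(null$adherence_slope, 0)
  causal <- scenario_preset("causal")
  expect_equal(causal$causal_log_hr, log(0.75))
  bias <- scenario_preset("survival_bias")
  expect_equal(bias$causal_log_hr, 0)
  expect_gt(bias$adherence_slope, 0)
  expect_gt(bias$decline_drop, 0)
  trend <- scenario_preset("improving_trend")
  expect_gt(trend$trend_slope, 0)
  expect_identical(scenario_preset("causal"), scenario_preset("causal"))
  expect_error(scenario_preset("bogus"), "valid names")
})

test_that("generation is deterministic and exports byte-identically", {
  cfg <- scenario_preset("survival_bias", n_persons = 40, seed = 123,
                         study_end_day = 4500, hosp_rate = 0.2)
  s1 <- generate_bundle(cfg)
  s2 <- generate_bundle(cfg)
  expect_identical(s1$bundle, s2$bundle)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_claims_bundle(s1$bundle, d1)
  write_claims_bundle(s2$bundle, d2)
  for (f in c("dispensations.csv", "hospitalizations.csv", "registry.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("an empty configuration yields empty tables", {
  s <- generate_bundle(sim_config(n_persons = 0))
  expect_equal(nrow(s$bundle$dispensations), 0)
  expect_equal(nrow(s$bundle$registry), 0)
  sel <- select_cohort(s$bundle)
  expect_equal(nrow(sel$cohort), 0)
})

test_that("every generated person passes cohort selection by construction", {
  for (scn in c("null", "causal", "survival_bias", "improving_trend")) {
    cfg <- scenario_preset(scn, n_persons = 120, seed = 77)
    sim <- generate_bundle(cfg)
    sel <- select_cohort(sim$bundle, sim_criteria(cfg))
    expect_equal(nrow(sel$cohort), 120)
    expect_true(all(sel$cohort$first_statin_day - sel$cohort$index_day >= 0))
    expect_true(all(sel$cohort$first_statin_day - sel$cohort$index_day <= 90))
    expect_true(all(sel$cohort$span >= 102))
  }
})

test_that("refill propensity limits give the extreme adherence levels", {
  cfg_hi <- scenario_preset("null", n_persons = 25, seed = 5,
                            fill_alpha = 30, early_refill_prob = 0)
  sim <- generate_bundle(cfg_hi)
  sel <- select_cohort(sim$bundle, sim_criteria(cfg_hi))
  adh <- cohort_adherence(sel$cohort, sim$bundle$dispensations,
                          statin_codes = c("statin_A", "statin_B"))
  expect_true(all(adh$summary$pdc == 1))

  cfg_lo <- scenario_preset("null", n_persons = 25, seed = 5,
                            fill_alpha = -30, early_refill_prob = 0)
  sim <- generate_bundle(cfg_lo)
  sel <- select_cohort(sim$bundle, sim_criteria(cfg_lo))
  adh <- cohort_adherence(sel$cohort, sim$bundle$dispensations,
                          statin_codes = c("statin_A", "statin_B"))
  expect_equal(adh$summary$pdc, 34 / adh$summary$W)
})

test_that("mean interval PDC matches the renewal-process expectation", {
  cfg <- scenario_preset("null", n_persons = 2000, seed = 8)
  sim <- generate_bundle(cfg)
  sel <- select_cohort(sim$bundle, sim_criteria(cfg))
  adh <- cohort_adherence(sel$cohort, sim$bundle$dispensations,
                          statin_codes = c("statin_A", "statin_B"))
  # long-run covered fraction of the renewal process: supply / mean cycle,
  # cycle = fill_quantity + (1 - early_refill_prob) * E[geometric gap],
  # averaged over the logit-normal person propensity intercept
  b <- qnorm(seq(0.0005, 0.9995, length.out = 4000), 0, cfg$propensity_sd)
  p <- plogis(cfg$fill_alpha + b)
  expected <- mean(cfg$fill_quantity /
    (cfg$fill_quantity + (1 - cfg$early_refill_prob) * (1 - p) / p))
  iv <- adh$intervals
  obs <- mean(iv$pdc[iv$complete & iv$k >= 2])
  expect_lt(abs(obs - expected), 0.03)
})

test_that("survival sampling matches closed forms", {
  # beta = theta = 0: exponential deaths after the first interval
  cfg <- scenario_preset("null", n_persons = 2500, seed = 13,
                         baseline_hazard = 2e-4,
                         study_start_day = 1900, study_end_day = 1900 + 192 + 1500)
  sim <- generate_bundle(cfg)
  reg <- sim$bundle$registry
  sel <- select_cohort(sim$bundle, sim_criteria(cfg))
  # maximum at-risk time (to administrative censoring) per person; deaths
  # are exponential over it once the first interval has passed
  risk <- cfg$study_end_day - sel$cohort$first_statin_day - 102
  p_emp <- mean(sel$cohort$died)
  p_exp <- mean(1 - exp(-cfg$baseline_hazard * risk))
  expect_lt(abs(p_emp - p_exp), 0.03)

  # all-or-none adherence with beta = log(0.5): person-day death-rate ratio
  cfg2 <- scenario_preset("causal", n_persons = 4000, seed = 14,
                          causal_log_hr = log(0.5), all_or_none = TRUE,
                          baseline_hazard = 2e-4)
  sim2 <- generate_bundle(cfg2)
  sel2 <- select_cohort(sim2$bundle, sim_criteria(cfg2))
  adh2 <- cohort_adherence(sel2$cohort, sim2$bundle$dispensations,
                           statin_codes = c("statin_A", "statin_B"))
  suppressWarnings(fx <- build_fixed_dataset(sel2$cohort, adh2))
  grp <- split(fx, fx$adherent)
  rate <- vapply(grp, function(g) sum(g$event) / sum(g$time), numeric(1))
  expect_lt(abs(log(rate[["optimal"]] / rate[["suboptimal"]]) - log(0.5)), 0.2)

  # administrative censoring at entry: no deaths anywhere
  cfg3 <- scenario_preset("null", n_persons = 30, seed = 15,
                          admin_censor_days = 0)
  sim3 <- generate_bundle(cfg3)
  expect_true(all(is.na(sim3$bundle$registry$death_day)))
})

test_that("truth table aligns with the engine's interval measurements", {
  cfg <- scenario_preset("causal", n_persons = 150, seed = 19)
  sim <- generate_bundle(cfg)
  sel <- select_cohort(sim$bundle, sim_criteria(cfg))
  adh <- cohort_adherence(sel$cohort, sim$bundle$dispensations,
                          statin_codes = c("statin_A", "statin_B"))
  iv <- adh$intervals
  key <- paste(iv$person_id, iv$k)
  tr <- sim$truth[match(key, paste(sim$truth$person_id, sim$truth$k)), ]
  expect_equal(iv$pdc, tr$pdc_true)
  expect_equal(as.integer(iv$adherent == "optimal"), tr$A_true)
})
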