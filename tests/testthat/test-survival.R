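# small cohort with hand-computable datasets: persons followed from a first
# fill at day 0 of their follow-up, no hospital stays
mini_cohort <- function() {
  data.frame(person_id = c("A", "B", "C"),
             index_day = 0L, first_statin_day = 0L,
             followup_end_day = c(250L, 102L, 400L),
             span = c(250L, 102L, 400L),
             died = c(TRUE, FALSE, FALSE),
             sex = c("M", "F", "M"), stringsAsFactors = FALSE)
}

mini_adh <- function() {
  disp <- make_disp(c("A", "A", "C", "C", "C", "C"),
                    c(0L, 102L, 0L, 34L, 68L, 102L),
                    days_supplied = 34L)
  disp$days_supplied[4:6] <- c(34L, 34L, 300L)
  cohort_adherence(mini_cohort(), disp)
}

test_that("fixed dataset arithmetic and zero-risk drops", {
  adh <- mini_adh()
  expect_warning(fixed <- build_fixed_dataset(mini_cohort(), adh, "sex"),
                 "zero at-risk")
  # person B censored exactly at the origin is dropped
  expect_setequal(fixed$person_id, c("A", "C"))
  expect_equal(attr(fixed, "n_zero_risk"), 1L)
  a <- fixed[fixed$person_id == "A", ]
  expect_equal(a$time, 148L)
  expect_true(a$event)
})

test_that("counting-process rows follow the interval definitions", {
  adh <- mini_adh()
  cp <- build_counting_process(mini_cohort(), adh, "sex")
  a <- cp[cp$person_id == "A", ]
  expect_equal(a$start, c(0L, 102L))
  expect_equal(a$stop, c(102L, 148L))
  expect_equal(a$pdc, c(34 / 102, 0))
  expect_equal(a$event, c(FALSE, TRUE))
  # fully covered person is optimal on every row
  c_rows <- cp[cp$person_id == "C", ]
  expect_true(all(c_rows$adherent == "optimal"))
  # at-risk time conservation against the fixed dataset
  suppressWarnings(fixed <- build_fixed_dataset(mini_cohort(), adh, "sex"))
  risk_cp <- tapply(cp$stop - cp$start, cp$person_id, sum)
  expect_equal(as.numeric(risk_cp[fixed$person_id]), as.numeric(fixed$time))
  # lagged timing shifts the covariate by one interval
  lag <- build_counting_process(mini_cohort(), adh, timing = "lagged")
  al <- lag[lag$person_id == "A", ]
  expect_equal(al$pdc, c(34 / 102, 34 / 102))
})

test_that("counting-process construction rejects gapped intervals", {
  adh <- mini_adh()
  broken <- adh
  k2 <- broken$intervals$person_id == "C" & broken$intervals$k == 2
  broken$intervals$obs_start[k2] <- broken$intervals$obs_start[k2] + 1L
  expect_error(build_counting_process(mini_cohort(), broken), "gap or overlap.*C")
})

test_that("Cox wrapper recovers a known hazard ratio and flags degeneracy", {
  set.seed(11)
  covered <- 0
  for (r in 1:20) {
    d <- sim_two_group(1500, hr = 0.5)
    fit <- fit_cox(d, "adherent")
    ci <- fit$table[1, c("ci_low", "ci_high")]
    covered <- covered + (ci$ci_low <= 0.5 && 0.5 <= ci$ci_high)
  }
  expect_gte(covered / 20, 0.9)

  d <- sim_two_group(200, hr = 1)
  d$adherent[] <- "optimal"
  expect_error(fit_cox(d, "adherent"), "does not vary")
  d2 <- sim_two_group(50, hr = 1)
  d2$event <- FALSE
  expect_error(fit_cox(d2, "adherent"), "no events")
})

test_that("null-coefficient partial likelihood equals the null model loglik", {
  set.seed(12)
  d <- sim_two_group(400, hr = 0.7)
  fit <- fit_cox(d, "adherent")
  forced <- survival::coxph(survival::Surv(time, event) ~ adherent, data = d,
                            init = 0, control = survival::coxph.control(iter.max = 0))
  expect_equal(unname(forced$loglik[2]), unname(fit$loglik["null"]))
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  d <- data.frame(person_id = c("a", "b", "c"), time = c(5, 8, 10),
                  event = c(TRUE, TRUE, FALSE),
                  adherent = factor(rep("optimal", 3),
                                    levels = c("suboptimal", "optimal")))
  km <- kaplan_meier(d, group = NULL)
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 5], 2 / 3)
  expect_equal(km$surv[km$time == 8], 1 / 3)
  expect_true(all(diff(km$surv) <= 0))
  # no events: flat at 1
  d2 <- d; d2$event <- FALSE
  km2 <- kaplan_meier(d2, group = NULL)
  expect_true(all(km2$surv == 1))
  # invariant to row order
  km3 <- kaplan_meier(d[c(3, 1, 2), ], group = NULL)
  expect_equal(km3, km)
})

test_that("concordance percentages partition the eligible persons", {
  # 4 persons observed at interval 2: summary/interval classes
  # (adh,adh), (non,non), (non,adh), (non,adh)
  smry <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                     adherent = factor(c("optimal", "suboptimal",
                                         "suboptimal", "suboptimal"),
                                       levels = c("suboptimal", "optimal")))
  iv <- data.frame(person_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
                   k = rep(1:2, 4), complete = TRUE,
                   adherent = factor(c("optimal", "optimal",
                                       "suboptimal", "suboptimal",
                                       "suboptimal", "optimal",
                                       "suboptimal", "optimal"),
                                     levels = c("suboptimal", "optimal")))
  adh <- structure(list(summary = smry, intervals = iv),
                   class = "cohort_adherence")
  conc <- concordance_over_time(adh)
  k2 <- conc[conc$k == 2, ]
  expect_equal(k2$pct_match, 50)
  expect_equal(k2$pct_summary_nonadh_interval_adh, 50)
  expect_equal(k2$pct_summary_adh_interval_nonadh, 0)
  sums <- conc$pct_match + conc$pct_summary_nonadh_interval_adh +
    conc$pct_summary_adh_interval_nonadh
  expect_equal(sums, rep(100, nrow(conc)))
})

test_that("Schoenfeld diagnostics: residual bookkeeping and power", {
  set.seed(21)
  d <- sim_two_group(600, hr = 0.6)
  fit <- fit_cox(d, "adherent")
  ph <- check_ph(fit)
  expect_equal(nrow(ph$residuals), fit$events)
  expect_true(all(c("term", "chisq", "p") %in% names(ph$test)))

  # reversing hazard ratio mid-study: the slope test should reject often
  rejections <- 0
  for (r in 1:25) {
    x <- rbinom(250, 1, 0.5)
    # piecewise-constant effect: HR exp(1.3) before t=200, exp(-1.3) after
    lam1 <- 0.003 * exp(1.3 * x)
    t1 <- rexp(250, lam1)
    lam2 <- 0.003 * exp(-1.3 * x)
    t <- ifelse(t1 <= 200, t1, 200 + rexp(250, lam2))
    d <- data.frame(time = pmin(t, 800), event = t <= 800,
                    adherent = factor(ifelse(x == 1, "optimal", "suboptimal"),
                                      levels = c("suboptimal", "optimal")))
    ph <- check_ph(fit_cox(d, "adherent"))
    rejections <- rejections + (ph$test$p[1] < 0.05)
  }
  expect_gt(rejections / 25, 0.5)
})

test_that("VIF flags collinearity and honours orthogonality", {
  x1 <- rep(c(-1, 1), 50)
  x2 <- rep(c(-1, -1, 1, 1), 25)
  v <- compute_vif(data.frame(x1, x2))
  expect_equal(v$vif, c(1, 1))
  expect_false(any(v$flagged))

  set.seed(5)
  a <- rnorm(100)
  near <- a + rnorm(100, sd = 0.05)
  v2 <- compute_vif(data.frame(a, near, b = rnorm(100)))
  expect_true(all(v2$flagged[1:2]))
  expect_true(all(v2$vif[1:2] > 10))

  v3 <- compute_vif(data.frame(a, dup = a))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(all(v3$flagged))
})

test_that("sensitivity suite covers every variant and records errors", {
  cfg <- scenario_preset("null", n_persons = 250, seed = 31,
                         study_end_day = 5000)
  sim <- generate_bundle(cfg)
  sel <- select_cohort(sim$bundle, sim_criteria(cfg))
  adh <- cohort_adherence(sel$cohort, sim$bundle$dispensations,
                          statin_codes = c("statin_A", "statin_B"))
  suppressWarnings(
    res <- sensitivity_suite(sel$cohort, adh, covariates = c("sex")))
  combos <- unique(res[, c("method", "variant", "adjustment")])
  expect_equal(nrow(combos), 16)
  expect_true(all(c("summary", "repeated", "last_interval",
                    "first_interval") %in% res$method))
  # binary and continuous variants share the same coverage kernel: the
  # summary pdc underlying both is identical
  expect_true(all(!is.na(res$hr) | !is.na(res$error)))
})
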