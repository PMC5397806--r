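member <- function(span) list(person_id = "X", first_statin_day = 0L,
                              followup_end_day = span, span = span)

test_that("timeline compression removes hospitalized days", {
  tl <- compress_timeline(member(50))
  expect_equal(tl$W, 50)
  expect_equal(observed_to_adherence(tl, 25), 25)

  # one stay covering observed days 10-19
  ep <- data.frame(person_id = "X", admit_day = 10L, discharge_day = 20L)
  tl <- compress_timeline(member(50), ep)
  expect_equal(tl$W, 40)
  expect_equal(observed_to_adherence(tl, 25), 15)
  expect_equal(adherence_to_observed(tl, 15), 25)
  # a day in hospital maps to the first post-discharge adherence day
  expect_equal(observed_to_adherence(tl, 12), 10)

  # overlapping stays, union of day sets
  ep2 <- rbind(ep, data.frame(person_id = "X", admit_day = 15L,
                              discharge_day = 25L))
  tl2 <- compress_timeline(member(50), ep2)
  expect_equal(length(tl2$hosp_days), 15)
  expect_equal(tl2$W, 35)

  # fully hospitalized window is flagged undefined
  tl3 <- compress_timeline(member(10),
                           data.frame(person_id = "X", admit_day = 0L,
                                      discharge_day = 10L))
  expect_equal(tl3$W, 0)
  expect_true(attr(tl3, "undefined_adherence"))
})

test_that("completion-date chaining defers early refills and truncates", {
  sched <- build_coverage_schedule(
    data.frame(dispense_day = c(0L, 20L), days_supplied = c(30L, 30L)), 70L)
  expect_equal(as.data.frame(sched), data.frame(start = 0L, end = 60L),
               ignore_attr = TRUE)
  expect_equal(covered_days(sched, c(0, 70)), 60)

  tr <- build_coverage_schedule(
    data.frame(dispense_day = 0L, days_supplied = 30L), 20L)
  expect_equal(covered_days(tr, c(0, 20)), 20)

  none <- build_coverage_schedule(
    data.frame(dispense_day = integer(0), days_supplied = integer(0)), 50L)
  expect_equal(nrow(none), 0)
  expect_equal(covered_days(none, c(0, 50)), 0)

  # a fill at/after the end of the window contributes nothing
  late <- build_coverage_schedule(
    data.frame(dispense_day = 50L, days_supplied = 34L), 50L)
  expect_equal(nrow(late), 0)
  expect_equal(attr(late, "n_noncontributing"), 1L)
})

test_that("covered-day counting matches brute force and rejects empty windows", {
  sched <- build_coverage_schedule(
    data.frame(dispense_day = c(0L, 20L), days_supplied = c(30L, 30L)), 70L)
  expect_equal(covered_days(sched, c(10, 40)), 30)
  expect_equal(covered_days(sched, c(60, 70)), 0)
  expect_equal(covered_days(sched, c(0, 60)), 60)
  expect_error(covered_days(sched, c(10, 10)), "empty")
})

test_that("summary PDC and interval PDCs follow the worked examples", {
  sched <- build_coverage_schedule(
    data.frame(dispense_day = c(0L, 20L), days_supplied = c(30L, 30L)), 70L)
  s <- summary_pdc(sched, 70L)
  expect_equal(s$pdc, 6 / 7)

  # supply spanning an interval boundary is carried over
  sp <- build_coverage_schedule(
    data.frame(dispense_day = 0L, days_supplied = 204L), 204L)
  iv <- interval_pdcs(sp, 204L)
  expect_equal(iv$pdc, c(1, 1))
  expect_equal(iv$complete, c(TRUE, TRUE))

  one <- build_coverage_schedule(
    data.frame(dispense_day = 0L, days_supplied = 34L), 204L)
  iv <- interval_pdcs(one, 204L)
  expect_equal(iv$pdc, c(34 / 102, 0))

  iv <- interval_pdcs(build_coverage_schedule(NULL, 250L), 250L)
  expect_equal(iv$pdc, c(0, 0, 0))
  expect_equal(iv$denominator, c(102L, 102L, 46L))
  expect_equal(iv$complete, c(TRUE, TRUE, FALSE))
  expect_equal(sum(!iv$complete), 1L)

  expect_warning(expect_null(summary_pdc(build_coverage_schedule(NULL, 0L), 0L)),
                 "missing")
})

test_that("classification uses inclusive cuts at 0.20 and 0.80", {
  expect_equal(as.character(classify(c(0.80, 0.7999, 1, 0))),
               c("optimal", "suboptimal", "optimal", "suboptimal"))
  expect_equal(as.character(classify(c(0.15, 0.20, 0.2001, 0.80, 0.79),
                                     "three_level")),
               c("low", "low", "middle", "optimal", "middle"))
  expect_true(is.na(classify(NA_real_)))
})

test_that("engine equals the day-by-day supply-stack oracle on random histories", {
  set.seed(2024)
  for (rep in 1:250) {
    h <- random_history(600)
    o <- oracle_coverage(h$span, h$hosp, h$fill_days, h$supplies)
    e <- engine_coverage(h)
    expect_identical(e$W, as.integer(o$W))
    expect_identical(e$summary_covered, as.integer(o$summary_covered))
    expect_identical(e$interval_covered, o$interval_covered)
    expect_identical(e$interval_denominator, o$interval_denominator)
  }
})

test_that("conservation, aggregation, monotonicity and truncation hold", {
  set.seed(99)
  for (rep in 1:60) {
    h <- random_history(800)
    e <- engine_coverage(h)
    if (e$W == 0) next
    # sum of interval covered days equals the summary count, exactly
    expect_identical(sum(e$interval_covered), e$summary_covered)
    # summary PDC is the length-weighted mean of interval PDCs
    iv <- e$intervals
    expect_equal(sum(iv$denominator * iv$pdc) / e$W, e$summary_covered / e$W)
    # covered days never exceed window or total supply
    expect_lte(e$summary_covered, min(e$W, sum(h$supplies)))
    # adding a fill never decreases coverage anywhere
    h2 <- h
    extra_day <- sample.int(h$span, 1) - 1L
    h2$fill_days <- sort(c(h$fill_days, extra_day))
    h2$supplies <- c(h$supplies, 34L)[order(c(h$fill_days, extra_day))]
    e2 <- engine_coverage(h2)
    expect_true(all(e2$interval_covered >= e$interval_covered))
    expect_gte(e2$summary_covered, e$summary_covered)
  }
})

test_that("denominator-only hospital mode excludes hospital days from both counts", {
  # span 60, stay on days 10-19, single 34-day fill at day 0
  m <- member(60)
  ep <- data.frame(person_id = "X", admit_day = 10L, discharge_day = 20L)
  fills <- data.frame(person_id = "X", dispense_day = 0L,
                      days_supplied = 34L)
  pa <- person_adherence(m, fills, ep,
                         adherence_config(hospital_mode = "denominator_only"))
  # supply runs days 0-33 on the calendar; 10 of those days are in hospital
  expect_equal(pa$summary$covered_days, 24)
  expect_equal(pa$summary$denominator_days, 50)
  # compress mode pauses consumption instead
  pc <- person_adherence(m, fills, ep, adherence_config())
  expect_equal(pc$summary$covered_days, 34)
  expect_equal(pc$summary$denominator_days, 50)
})
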