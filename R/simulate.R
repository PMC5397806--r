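#' Simulation configuration for synthetic claims bundles
#'
#' Parameters of the synthetic administrative-claims generator. The
#' generator emulates the structure of a provincial claims cohort: an
#' index ACS hospitalization, a first statin fill within 90 days of
#' discharge, refill sequences in ~34-day quantities, and death or
#' administrative censoring — with configurable dependence among latent
#' health, refill behaviour and mortality.
#'
#' The refill process is a renewal process: after each supply exhausts,
#' the gap until the next fill is geometric with per-day fill probability
#' `p = plogis(fill_alpha + b + adherence_slope * H + trend_slope * years)`,
#' where `b` is a person-level random intercept (stable adherence
#' propensity) and `H` is the person's latent health state for the
#' interval; with
#' probability `early_refill_prob` the refill instead arrives 1-7 days
#' *before* exhaustion (exercising the early-refill deferral rule without
#' changing coverage). Mortality is piecewise-constant per measurement
#' interval, `lambda = baseline_hazard * exp(causal_log_hr * A +
#' health_log_hr * H)` where `A` indicates optimal adherence in the
#' current interval; the hazard is zero during the first interval, so
#' every generated person survives the 102-day inclusion window.
#'
#' @param n_persons cohort size.
#' @param seed integer seed; the generator is fully deterministic given
#'   the config (one RNG substream per person).
#' @param scenario one of `"null"`, `"causal"`, `"survival_bias"`,
#'   `"improving_trend"` (see [scenario_preset()]).
#' @param baseline_hazard events per person-day after the first interval.
#' @param causal_log_hr log hazard ratio while currently adherent (beta).
#' @param health_log_hr log hazard ratio per unit latent health (theta).
#' @param frailty_sd innovation SD of the latent-health random walk.
#' @param adherence_slope effect of latent health on the fill-propensity
#'   logit (gamma).
#' @param trend_slope calendar improvement of the fill-propensity logit,
#'   per year.
#' @param decline_drop total latent-health drop spread over the final two
#'   intervals before a sampled death (survival-bias mechanism; 0 = off).
#' @param fill_alpha intercept of the fill-propensity logit.
#' @param propensity_sd SD of the person-level random intercept on the
#'   fill-propensity logit. The default, with `fill_alpha`, reproduces the
#'   wide, stable between-person adherence distribution seen in claims
#'   cohorts (population summary PDC mean near 0.71, SD near 0.29, just
#'   over half the cohort at or above the 0.80 optimum).
#' @param fill_quantity days supplied per fill (default 34).
#' @param early_refill_prob probability a refill arrives 1-7 days early.
#' @param interval_len measurement-interval length (default 102).
#' @param study_start_day,study_end_day study window in integer days
#'   (defaults: a 15-year window starting 1826 days after the epoch, so
#'   5 years of pre-index coverage fit before it).
#' @param admin_censor_days administrative truncation of follow-up this
#'   many days after the first fill (`Inf` = study end governs).
#' @param hosp_rate mid-follow-up hospital episodes per person-year
#'   (default 0; episodes exist to exercise timeline compression).
#' @param other_fill_rate non-statin dispensations per person-month
#'   (noise rows exercising drug-class filtering).
#' @param max_fill_delay latest first fill, days after index discharge.
#' @param epoch origin date mapped to day 0 in exports.
#' @param all_or_none if `TRUE`, each person is either perfectly adherent
#'   (back-to-back refills) or takes only the first fill — behaviour that
#'   never changes over follow-up.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 9000L, seed = 1L,
                       scenario = c("null", "causal", "survival_bias",
                                    "improving_trend"),
                       baseline_hazard = 1e-4, causal_log_hr = 0,
                       health_log_hr = 0, frailty_sd = 0.4,
                       adherence_slope = 0, trend_slope = 0,
                       decline_drop = 0, fill_alpha = -2.2,
                       propensity_sd = 2.2,
                       fill_quantity = 34L, early_refill_prob = 0.2,
                       interval_len = 102L,
                       study_start_day = 1826L, study_end_day = 7304L,
                       admin_censor_days = Inf,
                       hosp_rate = 0, other_fill_rate = 0,
                       max_fill_delay = 90L, epoch = "1989-01-01",
                       all_or_none = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(n_persons >= 0, baseline_hazard > 0, fill_quantity >= 1,
            interval_len >= 1, study_end_day > study_start_day)
  cfg <- as.list(environment())
  cfg$epoch <- as.Date(epoch)
  structure(cfg, class = "sim_config")
}

#' Scenario presets
#'
#' Named parameterizations of [sim_config()]:
#' \describe{
#'   \item{null}{no adherence effect, no health-adherence link
#'     (beta = 0, gamma = 0).}
#'   \item{causal}{a genuine protective effect of current adherence,
#'     beta = log(0.75) — a 25% hazard reduction while adherent.}
#'   \item{survival_bias}{beta = 0 but gamma > 0 with a deterministic
#'     latent-health decline over the final two intervals before death:
#'     dying people stop refilling shortly before death, so recent
#'     adherence is a marker, not a cause, of survival.}
#'   \item{improving_trend}{adds a calendar improvement in fill propensity
#'     (adherence rising over the study period).}
#' }
#'
#' @param name scenario name.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
scenario_preset <- function(name, ...) {
  presets <- list(
    null = list(causal_log_hr = 0, adherence_slope = 0),
    causal = list(causal_log_hr = log(0.75), adherence_slope = 0),
    survival_bias = list(causal_log_hr = 0, adherence_slope = 1,
                         decline_drop = 1),
    improving_trend = list(causal_log_hr = 0, adherence_slope = 0,
                           trend_slope = 0.12, fill_alpha = -3.5)
  )
  if (!name %in% names(presets)) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  args <- utils::modifyList(c(presets[[name]], scenario = name), list(...))
  do.call(sim_config, args)
}

# geometric-tailed refill gaps after supply exhaustion; early refills
# (negative gaps) are deferred by the coverage engine so they do not change
# covered days, only exercise the deferral rule
.draw_gap <- function(n, p, early_prob, rng_early = runif(n)) {
  early <- rng_early < early_prob
  gap <- rgeom(n, p)
  gap[early] <- -sample.int(7L, sum(early), replace = TRUE)
  gap
}

#' Simulate one person's refill process
#'
#' Renewal refill sequence from the first fill (day 0) to `horizon`: each
#' fill supplies `fill_quantity` days; after exhaustion the next fill is
#' delayed by a geometric gap whose per-day probability follows the fill
#' propensity logit for the interval containing the exhaustion day.
#'
#' @param config a [sim_config()].
#' @param p_by_interval per-interval fill probabilities (from the latent
#'   health path and calendar trend).
#' @param horizon days of follow-up after the first fill.
#' @return integer vector of fill days (relative, day 0 first).
#' @export
simulate_refill_process <- function(config, p_by_interval, horizon) {
  f <- config$fill_quantity
  if (horizon <= 0) return(integer(0))
  if (isTRUE(config$all_or_none)) {
    if (p_by_interval[1] >= 0.5) {
      return(as.integer(seq(0L, max(0L, horizon - 1L), by = f)))
    }
    return(0L)
  }
  K <- length(p_by_interval)
  constant_p <- length(unique(p_by_interval)) == 1L
  if (constant_p) {
    p <- p_by_interval[1]
    if (p <= 0) return(0L)
    nmax <- ceiling(horizon / f) + 2L
    repeat {
      gaps <- .draw_gap(nmax, p, config$early_refill_prob)
      # completion chain: fill i+1 lands gap_i days after completion date i
      # (negative = early; coverage starts at the completion date anyway)
      ends <- f * seq_len(nmax) +
        c(0, cumsum(pmax(gaps, 0))[-nmax])  # completion date of fill i
      days <- c(0L, (ends + gaps)[-nmax])
      if (ends[nmax] >= horizon + f) break
      nmax <- nmax * 2L
    }
    return(as.integer(days[days < horizon]))
  }
  days <- integer(0)
  day <- 0L
  completion <- 0L
  repeat {
    days <- c(days, day)
    completion <- max(day, completion) + f
    if (completion >= horizon) break
    k <- min(completion %/% config$interval_len + 1L, K)
    p <- p_by_interval[k]
    if (p <= 0) break
    gap <- .draw_gap(1L, p, config$early_refill_prob)
    day <- completion + gap
    if (day >= horizon) break
  }
  days
}

#' Simulate one person's death or censoring time
#'
#' Piecewise-constant hazard per measurement interval,
#' `lambda_k = baseline_hazard * exp(beta * A_k + theta * H_k)`, zero
#' during the first interval; the event time is sampled by inversion of
#' the cumulative hazard, with administrative censoring at `horizon`.
#'
#' @param config a [sim_config()].
#' @param A per-interval optimal-adherence indicators (0/1).
#' @param H per-interval latent health states.
#' @param horizon days of follow-up after the first fill.
#' @param E standard-exponential draw (supplied so callers control the RNG
#'   stream); default draws one.
#' @return list with `day` (relative to first fill), `died`, and `hazard`
#'   (the per-interval hazard vector).
#' @export
simulate_survival <- function(config, A, H, horizon, E = rexp(1)) {
  L <- config$interval_len
  K <- length(A)
  lambda <- config$baseline_hazard *
    exp(config$causal_log_hr * A + config$health_log_hr * H)
  lambda[1] <- 0
  len <- pmin(seq_len(K) * L, horizon) - (seq_len(K) - 1L) * L
  len <- pmax(len, 0L)
  cumhaz <- cumsum(lambda * len)
  if (E >= cumhaz[K] || horizon <= 0) {
    return(list(day = as.integer(horizon), died = FALSE, hazard = lambda))
  }
  k <- which(cumhaz > E)[1]
  prev <- if (k == 1) 0 else cumhaz[k - 1]
  within <- (E - prev) / lambda[k]
  day <- (k - 1L) * L + min(ceiling(within), len[k])
  day <- max(day, (k - 1L) * L + 1L)
  list(day = as.integer(day), died = TRUE, hazard = lambda)
}

#' Generate a synthetic claims bundle
#'
#' Produces the three-table bundle read by [read_claims_bundle()] /
#' consumed by [select_cohort()] (registry with baseline covariates,
#' hospitalizations including the index ACS episode, dispensations), plus
#' a truth table of the latent state used to generate each person. Every
#' generated person satisfies the cohort criteria by construction. Fully
#' reproducible from the config: each person has a dedicated RNG substream
#' keyed by person index.
#'
#' @param config a [sim_config()].
#' @param truth assemble the per-interval truth table (skipped in large
#'   replicate studies where only the bundle is needed).
#' @return a `claims_sim` list: `bundle` (class `claims_bundle`), `truth`
#'   (person_id, k, H, p_fill, pdc_true, A_true, hazard; `NULL` when
#'   `truth = FALSE`), `config`.
#' @export
generate_bundle <- function(config, truth = TRUE) {
  n <- config$n_persons
  L <- config$interval_len
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (n == 0) {
    bundle <- structure(list(
      dispensations = empty(person_id = character(0),
                            dispense_day = integer(0),
                            days_supplied = integer(0),
                            drug_class = character(0)),
      hospitalizations = empty(person_id = character(0),
                               admit_day = integer(0),
                               discharge_day = integer(0),
                               primary_dx = character(0)),
      registry = empty(person_id = character(0), birth_day = integer(0),
                       sex = character(0), coverage_start_day = integer(0),
                       coverage_end_day = integer(0),
                       death_day = integer(0), revasc = logical(0),
                       comorbidity = logical(0))),
      class = "claims_bundle")
    return(structure(list(bundle = bundle,
                          truth = empty(person_id = character(0)),
                          config = config), class = "claims_sim"))
  }

  set.seed(config$seed)
  person_seed <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("P%06d", seq_len(n))

  # latest index discharge leaving room for fill delay + first interval
  idx_max <- config$study_end_day - config$max_fill_delay - L
  stopifnot(idx_max > config$study_start_day)

  disp_id <- vector("list", n); disp_day <- vector("list", n)
  disp_sup <- vector("list", n); disp_cls <- vector("list", n)
  h_id <- vector("list", n); h_admit <- vector("list", n)
  h_disch <- vector("list", n); h_dx <- vector("list", n)
  r_birth <- integer(n); r_sex <- character(n); r_cov0 <- integer(n)
  r_cov1 <- integer(n); r_death <- rep(NA_integer_, n)
  r_revasc <- logical(n); r_comorb <- logical(n)
  t_id <- vector("list", n); t_k <- vector("list", n)
  t_H <- vector("list", n); t_p <- vector("list", n)
  t_pdc <- vector("list", n); t_haz <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(person_seed[i])
    index_day <- as.integer(floor(runif(1, config$study_start_day,
                                        idx_max + 1)))
    dur <- sample(3:14, 1)
    admit <- index_day - dur
    primary_dx <- sample(c("MI", "UA"), 1, prob = c(0.6, 0.4))
    age <- min(max(as.integer(round(rnorm(1, 64.8, 12.3))), 31L), 100L)
    birth_day <- index_day - as.integer(age * 365.25) -
      sample.int(300L, 1)
    sex <- sample(c("M", "F"), 1, prob = c(0.692, 0.308))
    revasc <- runif(1) < 0.585
    comorbidity <- runif(1) < 0.367
    delay <- if (runif(1) < 0.6) 0L else
      min(1L + rgeom(1, 0.12), config$max_fill_delay)
    first_fill <- index_day + delay
    cov_start <- index_day - .sim_prior_coverage -
      as.integer(floor(runif(1, 0, 365)))
    horizon_max <- as.integer(min(config$study_end_day - first_fill,
                                  config$admin_censor_days))
    K <- max(ceiling(horizon_max / L), 1L)

    # latent health path: random walk from a standard-normal start, and a
    # stable person-level adherence propensity independent of health
    H <- cumsum(c(rnorm(1), rnorm(max(K - 1L, 0L), 0, config$frailty_sd)))
    b <- rnorm(1, 0, config$propensity_sd)
    years <- ((first_fill + (seq_len(K) - 0.5) * L) -
                config$study_start_day) / 365.25
    p_fill <- plogis(config$fill_alpha + b + config$adherence_slope * H +
                       config$trend_slope * years)
    if (isTRUE(config$all_or_none)) {
      p_fill <- rep(if (runif(1) < 0.5) 1 else 0, K)
    }

    E <- rexp(1)
    if (config$decline_drop > 0) {
      # survival-bias mechanism: sample death first (valid because the
      # hazard ignores adherence when beta = 0), then impose the pre-death
      # health decline so refill behaviour deteriorates before death
      stopifnot(config$causal_log_hr == 0)
      sv <- simulate_survival(config, A = rep(0L, K), H = H,
                              horizon = horizon_max, E = E)
      if (sv$died) {
        k_death <- (sv$day - 1L) %/% L + 1L
        H[k_death] <- H[k_death] - config$decline_drop
        if (k_death > 1L)
          H[k_death - 1L] <- H[k_death - 1L] - config$decline_drop / 2
        p_fill <- plogis(config$fill_alpha + b +
                           config$adherence_slope * H +
                           config$trend_slope * years)
      }
      fills <- simulate_refill_process(config, p_fill, horizon_max)
      died <- sv$died
      horizon <- sv$day
      if (died) {
        sched0 <- build_coverage_schedule(.fills_df(fills, config),
                                          horizon_max)
        horizon <- .align_death_day(sched0, sv$day, L, horizon_max)
      }
      truth_hazard <- sv$hazard
      fills <- fills[fills < horizon]
    } else {
      fills <- simulate_refill_process(config, p_fill, horizon_max)
      sched0 <- build_coverage_schedule(.fills_df(fills, config),
                                        horizon_max)
      A <- rep(0L, K)
      if (horizon_max > 0) {
        ivt <- interval_pdcs(sched0, horizon_max, L)
        A[ivt$k] <- as.integer(ivt$pdc >= 0.80)
      }
      sv <- simulate_survival(config, A = A, H = H, horizon = horizon_max,
                              E = E)
      died <- sv$died
      horizon <- sv$day
      if (died) horizon <- .align_death_day(sched0, sv$day, L, horizon_max)
      truth_hazard <- sv$hazard
      fills <- fills[fills < horizon]
    }

    death_day <- if (died) first_fill + horizon else NA_integer_
    cov_end <- if (died) death_day else
      as.integer(min(config$study_end_day, first_fill + horizon))

    ep_admit <- as.integer(admit); ep_disch <- index_day
    ep_dx <- primary_dx
    if (config$hosp_rate > 0 && horizon > L) {
      n_ep <- rpois(1, config$hosp_rate * horizon / 365.25)
      if (n_ep > 0) {
        # mid-follow-up stays, placed after the first interval so the
        # at-risk origin stays on the uncompressed grid
        a <- as.integer(floor(runif(n_ep, first_fill + L,
                                    first_fill + horizon)))
        d <- a + sample(3:14, n_ep, replace = TRUE)
        ep_admit <- c(ep_admit, a)
        ep_disch <- c(ep_disch, as.integer(pmin(d, cov_end)))
        ep_dx <- c(ep_dx, rep("OTHER", n_ep))
      }
    }
    h_id[[i]] <- rep(ids[i], length(ep_admit))
    h_admit[[i]] <- ep_admit; h_disch[[i]] <- ep_disch; h_dx[[i]] <- ep_dx

    dd_day <- as.integer(first_fill + fills)
    dd_sup <- rep(as.integer(config$fill_quantity), length(fills))
    dd_cls <- sample(c("statin_A", "statin_B"), length(fills),
                     replace = TRUE, prob = c(0.7, 0.3))
    if (config$other_fill_rate > 0 && horizon > 0) {
      n_o <- rpois(1, config$other_fill_rate * horizon / 34)
      if (n_o > 0) {
        od <- as.integer(floor(runif(n_o, first_fill, first_fill + horizon)))
        dd_day <- c(dd_day, od)
        dd_sup <- c(dd_sup, rep(30L, n_o))
        dd_cls <- c(dd_cls, rep("other", n_o))
      }
    }
    disp_id[[i]] <- rep(ids[i], length(dd_day))
    disp_day[[i]] <- dd_day; disp_sup[[i]] <- dd_sup; disp_cls[[i]] <- dd_cls

    r_birth[i] <- as.integer(birth_day); r_sex[i] <- sex
    r_cov0[i] <- as.integer(cov_start); r_cov1[i] <- cov_end
    if (died) r_death[i] <- death_day
    r_revasc[i] <- revasc; r_comorb[i] <- comorbidity

    if (truth && horizon > 0) {
      # truth table on the realized follow-up
      sched <- build_coverage_schedule(.fills_df(fills, config), horizon)
      ivt <- interval_pdcs(sched, horizon, L)
      Kr <- nrow(ivt)
      t_id[[i]] <- rep(ids[i], Kr); t_k[[i]] <- ivt$k
      t_H[[i]] <- H[seq_len(Kr)]; t_p[[i]] <- p_fill[seq_len(Kr)]
      t_pdc[[i]] <- ivt$pdc; t_haz[[i]] <- truth_hazard[seq_len(Kr)]
    }
  }

  cat0 <- function(x) unlist(x, use.names = FALSE)
  bundle <- structure(list(
    dispensations = data.frame(person_id = cat0(disp_id),
                               dispense_day = cat0(disp_day),
                               days_supplied = cat0(disp_sup),
                               drug_class = cat0(disp_cls),
                               stringsAsFactors = FALSE),
    hospitalizations = data.frame(person_id = cat0(h_id),
                                  admit_day = cat0(h_admit),
                                  discharge_day = cat0(h_disch),
                                  primary_dx = cat0(h_dx),
                                  stringsAsFactors = FALSE),
    registry = data.frame(person_id = ids, birth_day = r_birth,
                          sex = r_sex, coverage_start_day = r_cov0,
                          coverage_end_day = r_cov1, death_day = r_death,
                          revasc = r_revasc, comorbidity = r_comorb,
                          stringsAsFactors = FALSE)),
    class = "claims_bundle")
  truth_df <- NULL
  if (truth) {
    pdc_true <- cat0(t_pdc)
    truth_df <- data.frame(person_id = cat0(t_id), k = cat0(t_k),
                           H = cat0(t_H), p_fill = cat0(t_p),
                           pdc_true = pdc_true,
                           A_true = as.integer(pdc_true >= 0.80),
                           hazard = cat0(t_haz), stringsAsFactors = FALSE)
  }
  structure(list(bundle = bundle, truth = truth_df, config = config),
            class = "claims_sim")
}

.fills_df <- function(fills, config) {
  list(dispense_day = fills,
       days_supplied = rep(as.integer(config$fill_quantity),
                           length(fills)))
}

# required pre-index coverage emitted by the generator (matches the default
# cohort criteria)
.sim_prior_coverage <- 1825L

# Place a sampled death day within its interval so that the realized
# (death-truncated) interval classification equals the full-window
# classification that generated the hazard. The generator's truth is
# defined at interval resolution; this pins down the day-resolution
# realization consistently, so the concurrent covariate measured by the
# coverage engine equals the covariate that drove the hazard. The interval
# end always satisfies the condition, so a valid day exists.
.align_death_day <- function(sched, day, L, horizon_max, threshold = 0.80) {
  k <- (day - 1L) %/% L + 1L
  s <- (k - 1L) * L
  e <- min(k * L, horizon_max)
  cand <- seq.int(s + 1L, e)
  cum <- .covered_before(sched, c(s, cand))
  pdc <- (cum[-1] - cum[1]) / (cand - s)
  target <- pdc[length(cand)] >= threshold
  ok <- cand[(pdc >= threshold) == target]
  ok[which.min(abs(ok - day))]
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: n = %d, scenario = %s, beta = %.4f, gamma = %.2f, theta = %.2f\n",
    x$n_persons, x$scenario, x$causal_log_hr, x$adherence_slope,
    x$health_log_hr))
  invisible(x)
}

#' Cohort criteria matching the generator's construction guarantees
#'
#' Convenience wrapper: [cohort_criteria()] parameterized with the study
#' window and code sets the generator emits.
#'
#' @param config a [sim_config()].
#' @return a `cohort_criteria`.
#' @export
sim_criteria <- function(config) {
  cohort_criteria(study_start_day = config$study_start_day,
                  study_end_day = config$study_end_day,
                  statin_codes = c("statin_A", "statin_B"))
}
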