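#' Adherence-measurement settings
#'
#' @param interval_len measurement-interval length in days. The default,
#'   102 days, is three 34-day fills (the usual one-month dispensed
#'   quantity), i.e. one "3-month" interval.
#' @param threshold PDC at or above which adherence is optimal (default
#'   0.80, inclusive).
#' @param hospital_mode how hospitalized days are handled: `"compress"`
#'   (default) removes them from the timeline, so they are excluded from
#'   PDC denominators *and* outpatient supply is not consumed while
#'   hospitalized; `"denominator_only"` keeps the calendar timeline and
#'   only excludes hospital days from numerator and denominator counts.
#' @return an object of class `adherence_config`.
#' @export
adherence_config <- function(interval_len = 102L, threshold = 0.80,
                             hospital_mode = c("compress", "denominator_only")) {
  hospital_mode <- match.arg(hospital_mode)
  structure(list(interval_len = as.integer(interval_len),
                 threshold = threshold, hospital_mode = hospital_mode),
            class = "adherence_config")
}

#' Compress a follow-up timeline by removing hospitalized days
#'
#' Builds the mapping between observed follow-up days (day 0 = first statin
#' fill) and "adherence days": observed days spent in hospital are removed,
#' because inpatient medication does not appear in the dispensation file.
#' The mapping is strictly monotone on non-hospital days and invertible.
#'
#' @param member one cohort row (needs `first_statin_day` and either `span`
#'   or `followup_end_day`), or a list with those fields.
#' @param episodes data.frame of hospital episodes (`person_id`,
#'   `admit_day`, `discharge_day`, calendar days); only rows matching
#'   `member$person_id` and overlapping the follow-up window are used.
#'   Hospital stays cover days `admit_day` to `discharge_day - 1`: the
#'   discharge day is spent at home, matching inpatient-day accounting, so
#'   a fill on the discharge day starts its supply that same day.
#' @param mode see `hospital_mode` in [adherence_config()];
#'   `"denominator_only"` yields an identity mapping with the hospital-day
#'   set retained for exclusion during counting.
#' @return an `adherence_timeline`: list with `person_id`, `span`,
#'   `hosp_days` (sorted observed-day offsets in hospital), `W` (adherence
#'   days; equals `span - length(hosp_days)` under compression), `mode`.
#'   `W = 0` (fully hospitalized follow-up) is flagged with attribute
#'   `undefined_adherence = TRUE`.
#' @export
compress_timeline <- function(member, episodes = NULL,
                              mode = c("compress", "denominator_only")) {
  mode <- match.arg(mode)
  span <- if (!is.null(member$span)) member$span else
    member$followup_end_day - member$first_statin_day
  span <- as.integer(span)
  stopifnot(span >= 0)
  hosp <- integer(0)
  if (!is.null(episodes) && nrow(episodes)) {
    ep <- episodes[episodes$person_id == member$person_id, , drop = FALSE]
    if (nrow(ep)) {
      a <- pmax(ep$admit_day - member$first_statin_day, 0L)
      b <- pmin(ep$discharge_day - 1L - member$first_statin_day, span - 1L)
      keep <- a <= b
      if (any(keep)) {
        hosp <- sort(unique(unlist(
          mapply(seq.int, a[keep], b[keep], SIMPLIFY = FALSE))))
      }
    }
  }
  W <- if (mode == "compress") span - length(hosp) else span
  structure(list(person_id = member$person_id, span = span,
                 hosp_days = as.integer(hosp), W = as.integer(W),
                 mode = mode),
            class = "adherence_timeline",
            undefined_adherence = (span - length(hosp)) == 0L && span > 0L)
}

#' Map observed follow-up days to adherence days
#'
#' Under compression, an observed day maps to the number of non-hospital
#' days strictly before it; a day spent in hospital therefore maps to the
#' position of the first subsequent non-hospital day (a fill dispensed
#' in hospital starts its supply after discharge).
#'
#' @param timeline an `adherence_timeline`.
#' @param obs_day integer vector of observed-day offsets.
#' @return integer vector of adherence-day offsets.
#' @export
observed_to_adherence <- function(timeline, obs_day) {
  if (timeline$mode == "denominator_only" || !length(timeline$hosp_days))
    return(as.integer(obs_day))
  as.integer(obs_day - findInterval(obs_day - 0.5, timeline$hosp_days))
}

#' Map adherence days back to observed follow-up days
#'
#' Inverse of [observed_to_adherence()] on non-hospital days; adherence day
#' `a` maps to the (a+1)-th non-hospital observed day, and `a = W` maps to
#' the end of follow-up (`span`).
#'
#' @param timeline an `adherence_timeline`.
#' @param adh_day integer vector of adherence-day offsets in `[0, W]`.
#' @return integer vector of observed-day offsets.
#' @export
adherence_to_observed <- function(timeline, adh_day) {
  adh_day <- as.integer(adh_day)
  if (timeline$mode == "denominator_only" || !length(timeline$hosp_days)) {
    return(adh_day)
  }
  stopifnot(all(adh_day >= 0 & adh_day <= timeline$W))
  nonhosp <- setdiff(seq_len(timeline$span) - 1L, timeline$hosp_days)
  out <- ifelse(adh_day == timeline$W, timeline$span, nonhosp[adh_day + 1L])
  as.integer(out)
}

#' Build a coverage schedule by completion-date supply chaining
#'
#' Implements the adjusted-PDC coverage rule: each dispensation is assigned
#' a completion date equal to its start plus days supplied; a refill
#' obtained before the previous completion date is deferred and starts only
#' when the previous supply is exhausted (`start_i = max(day_i, end_{i-1})`
#' in half-open day arithmetic), and supply extending beyond the end of
#' follow-up is truncated. Carryover is uncapped: stockpiled supply can be
#' pushed arbitrarily far forward (truncation at `W` bounds its effect).
#'
#' @param fills data.frame with columns `dispense_day` (adherence-day
#'   offsets, see [observed_to_adherence()]) and `days_supplied`; statin
#'   fills only, all statin products pooled.
#' @param W length of the adherence window; covered days are counted on
#'   `[0, W)`.
#' @return a `coverage_schedule`: data.frame of disjoint, sorted, merged
#'   half-open intervals (`start`, `end`) within `[0, W)`, with attributes
#'   `W` and `n_noncontributing` (fills whose entire supply fell at or
#'   beyond `W`).
#' @export
build_coverage_schedule <- function(fills, W) {
  W <- as.integer(W)
  empty <- structure(.fast_df(list(start = integer(0), end = integer(0))),
                     class = c("coverage_schedule", "data.frame"),
                     W = W, n_noncontributing = 0L)
  if (is.null(fills) || !length(fills$dispense_day) || W <= 0) return(empty)
  o <- order(fills$dispense_day)
  d <- as.integer(fills$dispense_day[o])
  s <- as.integer(fills$days_supplied[o])
  stopifnot(all(s >= 1))
  n <- length(d)
  if (length(unique(s)) == 1L) {
    # constant supply: end_i = cummax(d_i - i*s) + (i+1)*s
    i <- seq_len(n)
    e <- cummax(d - i * s[1]) + (i + 1L) * s[1]
  } else {
    e <- numeric(n)
    prev <- 0
    for (i in seq_len(n)) {
      e[i] <- max(d[i], prev) + s[i]
      prev <- e[i]
    }
  }
  st <- pmax(d, c(0, e[-n]))
  en <- pmin(e, W)
  st2 <- pmin(st, W)
  keep <- en > st2
  n_non <- sum(!keep & st >= W)
  st <- st2[keep]; en <- en[keep]
  if (length(st)) {
    # merge contiguous/adjacent intervals (chain guarantees sortedness)
    new_grp <- c(TRUE, st[-1] > en[-length(en)])
    g <- cumsum(new_grp)
    st <- st[new_grp]
    en <- as.numeric(tapply(en, g, max))
  }
  structure(.fast_df(list(start = as.integer(st), end = as.integer(en))),
            class = c("coverage_schedule", "data.frame"),
            W = W, n_noncontributing = n_non)
}

# zero-copy data.frame assembly for per-person hot paths
.fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}

# cumulative covered days strictly before adherence day x (vectorized over
# x; schedule intervals are sorted and disjoint)
.covered_before <- function(schedule, x) {
  st <- schedule$start
  if (!length(st)) return(rep(0L, length(x)))
  en <- schedule$end
  cs <- c(0L, cumsum(en - st))
  j <- findInterval(x, st)
  partial <- pmin(pmax(x - st[pmax(j, 1L)], 0L), (en - st)[pmax(j, 1L)])
  partial[j == 0L] <- 0L
  as.integer(cs[pmax(j, 1L)] + partial)
}

#' Count covered days within a window
#'
#' @param schedule a [build_coverage_schedule()] result.
#' @param window integer vector `c(a, b)` giving the half-open window
#'   `[a, b)` on the adherence timeline, `0 <= a < b <= W`.
#' @param exclude_days optional integer vector of adherence days excluded
#'   from the count (used by `hospital_mode = "denominator_only"`).
#' @return integer count of covered days in the window.
#' @export
covered_days <- function(schedule, window, exclude_days = NULL) {
  a <- window[1]; b <- window[2]
  if (!(a < b)) stop("empty or inverted window [a, b) with a >= b",
                     call. = FALSE)
  n <- .covered_before(schedule, b) - .covered_before(schedule, a)
  if (length(exclude_days)) {
    ex <- exclude_days[exclude_days >= a & exclude_days < b]
    if (length(ex) && nrow(schedule)) {
      idx <- findInterval(ex, schedule$start)
      n <- n - sum(idx >= 1 & ex < schedule$end[pmax(idx, 1L)])
    }
  }
  as.integer(n)
}

#' Summary proportion of days covered (Method A)
#'
#' Single adherence measure over the whole follow-up: covered days over
#' `[0, W)` divided by `W`.
#'
#' @param schedule a [build_coverage_schedule()] result.
#' @param W adherence-window length; `W = 0` (adherence undefined, e.g.
#'   fully hospitalized follow-up) returns the missing-adherence state.
#' @param exclude_days see [covered_days()].
#' @return a `pdc_value`: list with `covered_days`, `denominator_days`,
#'   `pdc`; or `NULL` with a warning when the denominator is zero.
#' @export
summary_pdc <- function(schedule, W, exclude_days = NULL) {
  denom <- W - length(exclude_days)
  if (denom <= 0) {
    warning("zero-denominator adherence window: PDC is missing")
    return(NULL)
  }
  cov <- covered_days(schedule, c(0L, W), exclude_days)
  structure(list(covered_days = cov, denominator_days = as.integer(denom),
                 pdc = cov / denom), class = "pdc_value")
}

#' Interval proportions of days covered (Method B)
#'
#' Divides the adherence window into consecutive intervals of
#' `interval_len` days (the last possibly incomplete) and measures PDC in
#' each. Carryover of unused supply into later intervals is automatic: the
#' schedule is built by the completion-date chain over the whole follow-up.
#'
#' @inheritParams summary_pdc
#' @param interval_len interval length in days (default 102).
#' @return data.frame with one row per interval: `k` (1-based index),
#'   `start`, `end` (adherence days), `covered`, `denominator`, `pdc`,
#'   `complete` (spans the full `interval_len`).
#' @export
interval_pdcs <- function(schedule, W, interval_len = 102L,
                          exclude_days = NULL) {
  W <- as.integer(W); interval_len <- as.integer(interval_len)
  if (W <= 0) {
    warning("zero-length adherence window: interval PDCs are missing")
    return(NULL)
  }
  K <- ceiling(W / interval_len)
  st <- (seq_len(K) - 1L) * interval_len
  en <- pmin(seq_len(K) * interval_len, W)
  cum <- .covered_before(schedule, c(st[1], en))
  cov <- as.integer(diff(cum))
  denom <- en - st
  if (length(exclude_days)) {
    ex <- exclude_days[exclude_days >= 0 & exclude_days < W]
    if (length(ex)) {
      k_ex <- findInterval(ex, st)
      denom <- denom - tabulate(k_ex, nbins = K)
      if (nrow(schedule)) {
        idx <- findInterval(ex, schedule$start)
        covered_ex <- idx >= 1 & ex < schedule$end[pmax(idx, 1L)]
        cov <- cov - tabulate(k_ex[covered_ex], nbins = K)
      }
    }
  }
  .fast_df(list(k = seq_len(K), start = st, end = en, covered = cov,
                denominator = as.integer(denom),
                pdc = ifelse(denom > 0, cov / denom, NA_real_),
                complete = (en - st) == interval_len))
}

#' Classify a PDC value into adherence categories
#'
#' Binary scheme: optimal adherence iff PDC >= `threshold` (0.80,
#' inclusive). Three-level scheme: `low` iff PDC <= 0.20, `optimal` iff
#' PDC >= 0.80, `middle` otherwise.
#'
#' @param pdc numeric vector of PDC fractions in `[0, 1]`; `NA` (missing
#'   adherence) propagates.
#' @param scheme `"binary"` or `"three_level"`.
#' @param threshold optimal-adherence cut for the binary scheme.
#' @return a factor: levels `suboptimal < optimal` (binary) or
#'   `low < middle < optimal` (three-level).
#' @export
classify <- function(pdc, scheme = c("binary", "three_level"),
                     threshold = 0.80) {
  scheme <- match.arg(scheme)
  stopifnot(all(is.na(pdc) | (pdc >= 0 & pdc <= 1)))
  if (scheme == "binary") {
    factor(ifelse(pdc >= threshold, "optimal", "suboptimal"),
           levels = c("suboptimal", "optimal"))
  } else {
    factor(ifelse(pdc <= 0.20, "low",
                  ifelse(pdc >= 0.80, "optimal", "middle")),
           levels = c("low", "middle", "optimal"))
  }
}

#' Per-person adjusted-PDC adherence
#'
#' Runs the full coverage engine for one cohort member: timeline
#' compression, mapping of fill dates, completion-date chaining, then the
#' summary measure and interval measures.
#'
#' @param member one cohort row (see [select_cohort()]).
#' @param fills dispensation rows for this person (calendar days); only
#'   fills from the first statin day onward contribute.
#' @param episodes hospital episodes (calendar days) or `NULL`.
#' @param config an [adherence_config()].
#' @return list with `timeline`, `schedule`, `summary` (a `pdc_value` or
#'   `NULL`), `intervals` (see [interval_pdcs()], plus observed-day
#'   boundaries `obs_start`, `obs_end`), and `origin_obs` (observed day of
#'   the end of the first interval, the at-risk origin; `NA` if the window
#'   is shorter than one interval).
#' @export
person_adherence <- function(member, fills, episodes = NULL,
                             config = adherence_config()) {
  tl <- compress_timeline(member, episodes, mode = config$hospital_mode)
  keep <- fills$dispense_day >= member$first_statin_day &
    fills$dispense_day < member$followup_end_day
  fd <- observed_to_adherence(tl, fills$dispense_day[keep] -
                                member$first_statin_day)
  sched <- build_coverage_schedule(
    list(dispense_day = fd, days_supplied = fills$days_supplied[keep]),
    tl$W)
  ex <- if (tl$mode == "denominator_only") tl$hosp_days else NULL
  if (tl$W - length(ex) <= 0) {
    return(list(timeline = tl, schedule = sched, summary = NULL,
                intervals = NULL, origin_obs = NA_integer_))
  }
  sm <- summary_pdc(sched, tl$W, ex)
  iv <- interval_pdcs(sched, tl$W, config$interval_len, ex)
  iv$obs_start <- adherence_to_observed(tl, iv$start)
  iv$obs_end <- adherence_to_observed(tl, iv$end)
  origin <- if (tl$W >= config$interval_len)
    adherence_to_observed(tl, config$interval_len) else NA_integer_
  list(timeline = tl, schedule = sched, summary = sm, intervals = iv,
       origin_obs = origin)
}

#' Cohort-wide adherence tables
#'
#' Applies [person_adherence()] to every cohort member and assembles tidy
#' tables for the survival module.
#'
#' @param cohort cohort data.frame from [select_cohort()].
#' @param dispensations dispensation table (calendar days); non-statin rows
#'   should already be filtered out or identified via `statin_codes`.
#' @param episodes hospital-episode table or `NULL`.
#' @param config an [adherence_config()].
#' @param statin_codes `drug_class` values treated as statin fills.
#' @return list of class `cohort_adherence`:
#'   \describe{
#'     \item{summary}{per person: covered, denominator, pdc, adherent
#'       (binary class at `config$threshold`), category (three-level), W,
#'       origin_obs.}
#'     \item{intervals}{long table of interval PDCs with observed-day
#'       boundaries and classifications.}
#'     \item{missing}{person_ids with undefined (zero-denominator)
#'       adherence.}
#'   }
#' @export
cohort_adherence <- function(cohort, dispensations, episodes = NULL,
                             config = adherence_config(),
                             statin_codes = c("statin", "statin_A", "statin_B")) {
  disp <- dispensations[dispensations$drug_class %in% statin_codes, ,
                        drop = FALSE]
  fill_day_by <- split(disp$dispense_day, disp$person_id)
  fill_sup_by <- split(disp$days_supplied, disp$person_id)
  ep_by <- if (!is.null(episodes) && nrow(episodes))
    split(episodes, episodes$person_id) else list()

  n <- nrow(cohort)
  pid <- cohort$person_id
  first_day <- cohort$first_statin_day
  end_day <- cohort$followup_end_day
  sum_rows <- vector("list", n)
  int_rows <- vector("list", n)
  missing <- character(0)
  none <- integer(0)
  for (i in seq_len(n)) {
    m <- list(person_id = pid[i], first_statin_day = first_day[i],
              followup_end_day = end_day[i],
              span = end_day[i] - first_day[i])
    fd <- fill_day_by[[pid[i]]]
    if (is.null(fd)) fd <- none
    fs <- fill_sup_by[[pid[i]]]
    keep <- fd >= first_day[i] & fd < end_day[i]
    f <- list(dispense_day = fd[keep], days_supplied = fs[keep])
    pa <- person_adherence(m, f, ep_by[[pid[i]]], config)
    if (is.null(pa$summary)) {
      missing <- c(missing, pid[i])
      next
    }
    sum_rows[[i]] <- c(pa$summary$covered_days, pa$summary$denominator_days,
                       pa$summary$pdc, pa$timeline$W, pa$origin_obs)
    int_rows[[i]] <- pa$intervals
  }
  got <- !vapply(sum_rows, is.null, logical(1))
  sm <- matrix(unlist(sum_rows[got], use.names = FALSE), ncol = 5,
               byrow = TRUE)
  smry <- data.frame(person_id = pid[got], covered = as.integer(sm[, 1]),
                     denominator = as.integer(sm[, 2]), pdc = sm[, 3],
                     W = as.integer(sm[, 4]),
                     origin_obs = as.integer(sm[, 5]),
                     stringsAsFactors = FALSE)
  nk <- vapply(int_rows[got], nrow, integer(1))
  cat0 <- function(col) unlist(lapply(int_rows[got], `[[`, col),
                               use.names = FALSE)
  ints <- data.frame(person_id = rep(pid[got], nk), k = cat0("k"),
                     start = cat0("start"), end = cat0("end"),
                     covered = cat0("covered"),
                     denominator = cat0("denominator"), pdc = cat0("pdc"),
                     complete = cat0("complete"),
                     obs_start = cat0("obs_start"), obs_end = cat0("obs_end"),
                     stringsAsFactors = FALSE)
  smry$adherent <- classify(smry$pdc, "binary", config$threshold)
  smry$category <- classify(smry$pdc, "three_level")
  ints$adherent <- classify(ints$pdc, "binary", config$threshold)
  ints$category <- classify(ints$pdc, "three_level")
  structure(list(summary = smry, intervals = ints, missing = missing,
                 config = config),
            class = "cohort_adherence")
}

#' Export per-person adherence as a delimited table
#'
#' One row per measurement interval plus a summary row per person flagged
#' `interval_index = 0`.
#'
#' @param adh a [cohort_adherence()] result.
#' @param file output path; `NULL` returns the table without writing.
#' @param sep field separator.
#' @return the exported data.frame, invisibly when written to file.
#' @export
export_adherence <- function(adh, file = NULL, sep = ",") {
  s <- adh$summary
  srow <- data.frame(person_id = s$person_id, interval_index = 0L,
                     interval_start = 0L, interval_end = s$W,
                     covered_days = s$covered, denominator_days = s$denominator,
                     pdc = s$pdc, adherent = as.character(s$adherent),
                     complete = TRUE, stringsAsFactors = FALSE)
  iv <- adh$intervals
  irow <- data.frame(person_id = iv$person_id, interval_index = iv$k,
                     interval_start = iv$start, interval_end = iv$end,
                     covered_days = iv$covered,
                     denominator_days = iv$denominator, pdc = iv$pdc,
                     adherent = as.character(iv$adherent),
                     complete = iv$complete, stringsAsFactors = FALSE)
  out <- rbind(srow, irow)
  out <- out[order(out$person_id, out$interval_index), ]
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}
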