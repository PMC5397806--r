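# Literal day-by-day supply-stack simulation, independent of the interval
# arithmetic in the coverage engine. Walks observed days 0..span-1 keeping a
# stock of remaining supply: a fill adds its days to the stock; on every
# non-hospital day one day of stock (if any) is consumed and the day counts
# as covered; hospital days consume nothing and are not counted.
oracle_coverage <- function(span, hosp_days, fill_days, supplies,
                            interval_len = 102L) {
  stock <- 0L
  covered <- logical(span)
  is_hosp <- logical(span)
  is_hosp[hosp_days + 1L] <- TRUE
  adh_index <- integer(span)
  a <- 0L
  for (d in seq_len(span) - 1L) {
    stock <- stock + sum(supplies[fill_days == d])
    if (is_hosp[d + 1L]) next
    if (stock > 0L) {
      covered[d + 1L] <- TRUE
      stock <- stock - 1L
    }
    adh_index[d + 1L] <- a
    a <- a + 1L
  }
  W <- a
  cov_adh <- covered[!is_hosp]
  K <- if (W > 0) ceiling(W / interval_len) else 0L
  per_interval <- integer(K)
  denom <- integer(K)
  for (k in seq_len(K)) {
    lo <- (k - 1L) * interval_len
    hi <- min(k * interval_len, W)
    per_interval[k] <- sum(cov_adh[(lo + 1L):hi])
    denom[k] <- hi - lo
  }
  list(W = W, summary_covered = sum(cov_adh),
       interval_covered = per_interval, interval_denominator = denom)
}

# random refill/hospitalization history for property tests
random_history <- function(max_span = 2000L) {
  span <- sample(5:max_span, 1)
  n_hosp <- rpois(1, 1.5)
  hosp <- integer(0)
  if (n_hosp > 0) {
    starts <- sample.int(span, n_hosp) - 1L
    lens <- sample(1:21, n_hosp, replace = TRUE)
    hosp <- sort(unique(unlist(mapply(
      function(s, l) seq.int(s, min(s + l - 1L, span - 1L)),
      starts, lens, SIMPLIFY = FALSE))))
  }
  n_fill <- rpois(1, max(1, span / 45))
  fill_days <- if (n_fill > 0) sort(sample.int(span, n_fill, replace = TRUE) - 1L)
               else integer(0)
  supplies <- sample(c(7L, 30L, 34L, 90L), length(fill_days), replace = TRUE)
  list(span = span, hosp = hosp, fill_days = fill_days, supplies = supplies)
}

# run the full engine path (compression, fill mapping, chaining) on a raw
# history; returns the same quantities as oracle_coverage
engine_coverage <- function(h, interval_len = 102L) {
  member <- list(person_id = "X", first_statin_day = 0L,
                 followup_end_day = h$span, span = h$span)
  # episodes with discharge_day = last inpatient day + 1 (discharge at home)
  runs <- if (length(h$hosp)) split(h$hosp, cumsum(c(1L, diff(h$hosp) != 1L)))
          else list()
  episodes <- if (length(runs)) data.frame(
    person_id = "X",
    admit_day = vapply(runs, min, integer(1)),
    discharge_day = vapply(runs, max, integer(1)) + 1L) else NULL
  tl <- compress_timeline(member, episodes)
  fd <- observed_to_adherence(tl, h$fill_days)
  sched <- build_coverage_schedule(
    data.frame(dispense_day = fd, days_supplied = h$supplies), tl$W)
  if (tl$W == 0) {
    return(list(W = 0L, summary_covered = 0L, interval_covered = integer(0),
                interval_denominator = integer(0)))
  }
  iv <- interval_pdcs(sched, tl$W, interval_len)
  list(W = tl$W, summary_covered = summary_pdc(sched, tl$W)$covered_days,
       interval_covered = iv$covered, interval_denominator = iv$denominator,
       schedule = sched, intervals = iv)
}
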