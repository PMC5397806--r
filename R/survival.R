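#' Build the fixed-covariate survival dataset (Method A)
#'
#' One row per person; time at risk runs from the origin (the observed day
#' closing the first measurement interval, i.e. 102 adherence days after
#' the first fill) to the end of follow-up, and the adherence covariate is
#' the fixed summary PDC classification.
#'
#' @param cohort cohort data.frame from [select_cohort()].
#' @param adh a [cohort_adherence()] result.
#' @param covariates names of baseline-covariate columns in `cohort` to
#'   carry into the dataset.
#' @return data.frame with columns `person_id`, `time`, `event`, `pdc`,
#'   `adherent`, `category`, and the baseline covariates. Persons with
#'   missing adherence or zero at-risk time are dropped; counts are in
#'   attributes `n_missing_adherence` and `n_zero_risk` (with a warning).
#' @export
build_fixed_dataset <- function(cohort, adh, covariates = character(0)) {
  s <- adh$summary
  idx <- match(cohort$person_id, s$person_id)
  miss <- is.na(idx) | is.na(s$origin_obs[idx])
  d <- cohort[!miss, , drop = FALSE]
  si <- idx[!miss]
  time <- d$span - s$origin_obs[si]
  zero <- time <= 0
  if (any(zero)) {
    warning(sprintf("%d person(s) with zero at-risk time dropped", sum(zero)))
  }
  out <- data.frame(person_id = d$person_id[!zero],
                    time = as.integer(time[!zero]),
                    event = d$died[!zero],
                    pdc = s$pdc[si][!zero],
                    adherent = s$adherent[si][!zero],
                    category = s$category[si][!zero],
                    stringsAsFactors = FALSE)
  for (cc in covariates) out[[cc]] <- d[[cc]][!zero]
  structure(out, n_missing_adherence = sum(miss), n_zero_risk = sum(zero))
}

#' Build the counting-process dataset (Method B)
#'
#' One row per person-interval from the second measurement interval onward,
#' in (start, stop] format relative to the at-risk origin, carrying the
#' interval's adherence as a time-dependent covariate. With
#' `timing = "concurrent"` (default) the covariate over (start, stop] is
#' that interval's own PDC; with `timing = "lagged"` it is the previous
#' interval's.
#'
#' @inheritParams build_fixed_dataset
#' @param timing `"concurrent"` or `"lagged"`.
#' @return data.frame with columns `person_id`, `start`, `stop`, `event`,
#'   `k` (interval index), `pdc`, `adherent`, `category`, and baseline
#'   covariates; rows per person are contiguous and non-overlapping, and
#'   `event` is `TRUE` at most on the final row.
#' @export
build_counting_process <- function(cohort, adh, covariates = character(0),
                                   timing = c("concurrent", "lagged")) {
  timing <- match.arg(timing)
  s <- adh$summary
  iv <- adh$intervals
  keep_ids <- s$person_id[!is.na(s$origin_obs)]
  iv <- iv[iv$person_id %in% keep_ids, , drop = FALSE]
  iv <- iv[order(iv$person_id, iv$k), , drop = FALSE]

  # contiguity check on observed-day boundaries within person
  same <- c(FALSE, iv$person_id[-1] == iv$person_id[-nrow(iv)])
  bad <- which(same & c(0L, iv$obs_end[-nrow(iv)]) != iv$obs_start)
  if (length(bad)) {
    stop(sprintf("gap or overlap in measurement intervals for person(s): %s",
                 paste(unique(iv$person_id[bad]), collapse = ", ")),
         call. = FALSE)
  }

  if (timing == "lagged") {
    lag_pdc <- c(NA_real_, iv$pdc[-nrow(iv)])
    lag_pdc[!same] <- NA_real_
    cov_pdc <- lag_pdc
  } else {
    cov_pdc <- iv$pdc
  }

  origin <- s$origin_obs[match(iv$person_id, s$person_id)]
  rows <- iv$k >= 2L
  out <- data.frame(person_id = iv$person_id[rows],
                    start = iv$obs_start[rows] - origin[rows],
                    stop = iv$obs_end[rows] - origin[rows],
                    k = iv$k[rows],
                    pdc = cov_pdc[rows],
                    stringsAsFactors = FALSE)
  out <- out[out$stop > out$start, , drop = FALSE]
  died <- cohort$died[match(out$person_id, cohort$person_id)]
  last <- rev(!duplicated(rev(out$person_id)))
  out$event <- died & last
  out$adherent <- classify(out$pdc, "binary", adh$config$threshold)
  out$category <- classify(out$pdc, "three_level")
  ci <- match(out$person_id, cohort$person_id)
  for (cc in covariates) out[[cc]] <- cohort[[cc]][ci]
  rownames(out) <- NULL
  out[, c("person_id", "start", "stop", "event", "k", "pdc", "adherent",
          "category", covariates)]
}

#' Fit a Cox proportional-hazards model for an adherence term
#'
#' Thin wrapper around [survival::coxph()] that accepts either the fixed
#' dataset (columns `time`, `event`) or the counting-process dataset
#' (columns `start`, `stop`, `event`), checks estimability, and returns a
#' tidy result. Crude fits use the adherence term alone; adjusted fits add
#' baseline covariates.
#'
#' @param data a [build_fixed_dataset()] or [build_counting_process()]
#'   result.
#' @param adherence_term column name of the adherence covariate
#'   (`"adherent"`, `"category"`, or `"pdc"` for the continuous version).
#' @param covariates baseline covariate column names (empty for a crude
#'   fit).
#' @param ties tie-handling method (default Efron).
#' @return a `cox_result`: list with `table` (term, coef, hr, ci_low,
#'   ci_high, se, p), `loglik` (null, final), `n`, `events`, `ties`, and
#'   the underlying `fit`.
#' @export
fit_cox <- function(data, adherence_term = "adherent",
                    covariates = character(0), ties = "efron") {
  if (!any(data$event)) stop("no events in dataset", call. = FALSE)
  v <- data[[adherence_term]]
  if (length(unique(v[!is.na(v)])) < 2) {
    stop(sprintf("adherence covariate '%s' does not vary; model not estimable",
                 adherence_term), call. = FALSE)
  }
  for (cc in c(adherence_term, covariates)) {
    if (is.factor(data[[cc]])) data[[cc]] <- droplevels(data[[cc]])
  }
  surv <- if ("time" %in% names(data)) "survival::Surv(time, event)"
          else "survival::Surv(start, stop, event)"
  rhs <- paste(c(adherence_term, covariates), collapse = " + ")
  f <- stats::as.formula(paste(surv, "~", rhs))
  fit <- survival::coxph(f, data = data, ties = ties)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox model did not converge: ", paste(fit$info, collapse = "; "),
         call. = FALSE)
  }
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    se = sm$coefficients[, "se(coef)"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 loglik = c(null = fit$loglik[1], final = fit$loglik[2]),
                 n = sm$n, events = sm$nevent, ties = ties, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$events))
  tab <- x$table
  tab[c("coef", "hr", "ci_low", "ci_high", "se")] <-
    lapply(tab[c("coef", "hr", "ci_low", "ci_high", "se")], round,
           digits = digits)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier survival estimates by adherence group
#'
#' For the fixed dataset this is the ordinary product-limit estimator by
#' summary-adherence class. For the counting-process dataset it is the
#' extended (Simon-Makuch-style) estimator: each subject contributes
#' person-time to the group matching their current interval class.
#'
#' @param data a fixed or counting-process dataset.
#' @param group grouping column name (default `"adherent"`); `NULL` for a
#'   single overall curve.
#' @return a `km_estimate` data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (each group's step function starts at
#'   `time = 0`, `surv = 1`).
#' @export
kaplan_meier <- function(data, group = "adherent") {
  surv <- if ("time" %in% names(data)) "survival::Surv(time, event)"
          else "survival::Surv(start, stop, event)"
  rhs <- if (is.null(group)) "1" else group
  if (!is.null(group)) {
    sizes <- table(data[[group]])
    empty <- names(sizes)[sizes == 0]
    if (length(empty)) {
      warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    }
    data[[group]] <- droplevels(factor(data[[group]]))
  }
  f <- stats::as.formula(paste(surv, "~", rhs))
  sf <- survival::survfit(f, data = data)
  grp <- if (is.null(sf$strata)) "all"
         else rep(sub("^[^=]*=", "", names(sf$strata)), sf$strata)
  out <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv, stringsAsFactors = FALSE)
  zero <- data.frame(group = unique(grp), time = 0,
                     n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
                     surv = 1, stringsAsFactors = FALSE)
  out <- rbind(zero, out)
  out <- out[order(out$group, out$time), ]
  rownames(out) <- NULL
  structure(out, class = c("km_estimate", "data.frame"))
}

#' Complementary log-log survival curves
#'
#' Transforms Kaplan-Meier estimates to `log(-log S(t))` against `log(t)`
#' for the visual proportional-hazards ("log-log") check. Points with
#' `S(t)` equal to 0 or 1 are dropped (transform undefined).
#'
#' @param km a [kaplan_meier()] result.
#' @return data.frame with `group`, `time`, `log_time`, `loglog`.
#' @export
loglog_curves <- function(km) {
  keep <- km$surv > 0 & km$surv < 1 & km$time > 0
  data.frame(group = km$group[keep], time = km$time[keep],
             log_time = log(km$time[keep]),
             loglog = log(-log(km$surv[keep])))
}

#' Concordance between summary and interval adherence over time
#'
#' For each interval index `k`, among persons whose k-th interval is
#' complete, cross-tabulates the fixed summary class against the interval-k
#' class (same binary scheme) and reports the three percentages: matched,
#' summary-nonadherent but interval-adherent, and summary-adherent but
#' interval-nonadherent.
#'
#' @param adh a [cohort_adherence()] result.
#' @return data.frame: `k`, `n`, `pct_match`,
#'   `pct_summary_nonadh_interval_adh`, `pct_summary_adh_interval_nonadh`
#'   (percentages summing to 100 within rounding); intervals with no
#'   eligible persons are omitted.
#' @export
concordance_over_time <- function(adh) {
  iv <- adh$intervals[adh$intervals$complete, , drop = FALSE]
  s_adh <- adh$summary$adherent[match(iv$person_id, adh$summary$person_id)]
  i_adh <- iv$adherent
  out <- do.call(rbind, lapply(split(seq_len(nrow(iv)), iv$k), function(ix) {
    n <- length(ix)
    data.frame(k = iv$k[ix[1]], n = n,
               pct_match = 100 * mean(s_adh[ix] == i_adh[ix]),
               pct_summary_nonadh_interval_adh =
                 100 * mean(s_adh[ix] == "suboptimal" & i_adh[ix] == "optimal"),
               pct_summary_adh_interval_nonadh =
                 100 * mean(s_adh[ix] == "optimal" & i_adh[ix] == "suboptimal"))
  }))
  rownames(out) <- NULL
  out[order(out$k), ]
}

#' Concordance at the last completed interval
#'
#' Percentage of persons whose summary class matches their class in the
#' last interval that spans the full measurement length (the single-number
#' analogue of [concordance_over_time()]).
#'
#' @param adh a [cohort_adherence()] result.
#' @return list with `n` and `pct_match`.
#' @export
concordance_last_interval <- function(adh) {
  iv <- adh$intervals[adh$intervals$complete, , drop = FALSE]
  last <- iv[rev(!duplicated(rev(iv$person_id))), , drop = FALSE]
  s_adh <- adh$summary$adherent[match(last$person_id, adh$summary$person_id)]
  list(n = nrow(last), pct_match = 100 * mean(s_adh == last$adherent))
}

#' Proportional-hazards diagnostics from Schoenfeld residuals
#'
#' Computes per-covariate Schoenfeld residuals keyed by event time, and the
#' score test for zero slope of the scaled residuals on (untransformed)
#' event time — the programmatic criterion; the visual log-log check is
#' available via [loglog_curves()].
#'
#' @param result a [fit_cox()] result.
#' @return a `ph_diagnostics` list: `test` (data.frame term, chisq, df, p,
#'   including a GLOBAL row for multi-term models), `residuals` (data.frame
#'   time plus one column per coefficient), `transform`.
#' @export
check_ph <- function(result) {
  fit <- result$fit
  if (result$events < 2) stop("need at least 2 events for PH diagnostics",
                              call. = FALSE)
  zp <- survival::cox.zph(fit, transform = "identity")
  tt <- as.data.frame(zp$table)
  test <- data.frame(term = rownames(tt), chisq = tt$chisq, df = tt$df,
                     p = tt$p, row.names = NULL, stringsAsFactors = FALSE)
  res <- stats::residuals(fit, type = "schoenfeld")
  if (is.null(dim(res))) res <- matrix(res, ncol = 1,
                                       dimnames = list(names(res),
                                                       names(coef(fit))[1]))
  residuals <- data.frame(time = as.numeric(rownames(res)), res,
                          check.names = FALSE, row.names = NULL)
  structure(list(test = test, residuals = residuals,
                 transform = "identity"),
            class = "ph_diagnostics")
}

#' Variance inflation factors for a covariate table
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from the linear regression of each
#' numeric-encoded covariate on all the others; values above 10 are flagged
#' as substantial multicollinearity. A perfectly collinear covariate is
#' reported as infinite and flagged.
#'
#' @param x data.frame or matrix of at least two numeric-encoded
#'   covariates.
#' @param flag_threshold VIF above which a covariate is flagged.
#' @return data.frame: `covariate`, `vif`, `flagged`.
#' @export
compute_vif <- function(x, flag_threshold = 10) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 covariates for VIF", call. = FALSE)
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  vifs <- vapply(seq_along(x), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(x[[j]] ~ ., data = x[-j]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = names(x), vif = vifs,
             flagged = vifs > flag_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Sensitivity suite across adherence parameterizations
#'
#' Fits the full set of model variants, each crude (adherence term only)
#' and adjusted (adherence plus baseline covariates):
#' binary and three-category and continuous-PDC versions of the fixed
#' summary measure (Method A) and the repeated measures (Method B), plus
#' the class of the last completed interval and of the first interval each
#' entered as fixed covariates. Per-variant errors are recorded, not
#' propagated.
#'
#' @param cohort cohort data.frame.
#' @param adh a [cohort_adherence()] result.
#' @param covariates baseline covariate names for the adjusted fits.
#' @param timing covariate timing for the repeated measures (see
#'   [build_counting_process()]).
#' @return tidy data.frame: `method`, `variant`, `adjustment`, `term`,
#'   `coef`, `hr`, `ci_low`, `ci_high`, `p`, `n`, `events`, `error`.
#' @export
sensitivity_suite <- function(cohort, adh, covariates = character(0),
                              timing = "concurrent") {
  fixed <- build_fixed_dataset(cohort, adh, covariates)
  cp <- build_counting_process(cohort, adh, covariates, timing)

  iv <- adh$intervals
  ivc <- iv[iv$complete, , drop = FALSE]
  last <- ivc[rev(!duplicated(rev(ivc$person_id))), , drop = FALSE]
  first <- iv[iv$k == 1L, , drop = FALSE]
  fixed$adherent_last <- last$adherent[match(fixed$person_id, last$person_id)]
  fixed$adherent_first <- first$adherent[match(fixed$person_id,
                                               first$person_id)]

  specs <- list(
    list(method = "summary",  variant = "binary",      data = fixed, term = "adherent"),
    list(method = "repeated", variant = "binary",      data = cp,    term = "adherent"),
    list(method = "summary",  variant = "three_level", data = fixed, term = "category"),
    list(method = "repeated", variant = "three_level", data = cp,    term = "category"),
    list(method = "summary",  variant = "continuous",  data = fixed, term = "pdc"),
    list(method = "repeated", variant = "continuous",  data = cp,    term = "pdc"),
    list(method = "last_interval",  variant = "binary", data = fixed, term = "adherent_last"),
    list(method = "first_interval", variant = "binary", data = fixed, term = "adherent_first")
  )
  rows <- list()
  for (sp in specs) {
    for (adj in c("crude", "adjusted")) {
      covs <- if (adj == "adjusted") covariates else character(0)
      dat <- sp$data
      if (sp$term %in% c("adherent_last", "adherent_first")) {
        dat <- dat[!is.na(dat[[sp$term]]), , drop = FALSE]
      }
      res <- tryCatch(fit_cox(dat, sp$term, covs),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        rows[[length(rows) + 1]] <- data.frame(
          method = sp$method, variant = sp$variant, adjustment = adj,
          term = sp$term, coef = NA_real_, hr = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, n = NA_integer_,
          events = NA_integer_, error = res, stringsAsFactors = FALSE)
      } else {
        tab <- res$table[grepl(sp$term, res$table$term, fixed = TRUE), ,
                         drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          method = sp$method, variant = sp$variant, adjustment = adj,
          term = tab$term, coef = tab$coef, hr = tab$hr,
          ci_low = tab$ci_low, ci_high = tab$ci_high, p = tab$p,
          n = res$n, events = res$events, error = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
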