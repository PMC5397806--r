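#' Schema and dialect settings for claims files
#'
#' Describes how the three delimited input files (dispensations,
#' hospitalizations, registry) map onto the canonical fields used by the
#' package, how dates are encoded, and the day-numbering epoch.
#'
#' Date columns may hold ISO-8601 dates (converted to integer days since
#' `epoch`) or already-converted integer day numbers.
#'
#' @param sep field separator (default comma).
#' @param epoch origin date mapped to day 0, as `Date` or ISO string.
#' @param dispensations,hospitalizations,registry named character vectors
#'   mapping canonical field names to source column names. Canonical fields:
#'   dispensations `person_id, dispense_day, days_supplied, drug_class`
#'   (optional `dose_flag`); hospitalizations
#'   `person_id, admit_day, discharge_day, primary_dx`; registry
#'   `person_id, birth_day, sex, coverage_start_day, coverage_end_day,
#'   death_day`. Registry columns not mentioned in the mapping are carried
#'   through unchanged and become candidate baseline covariates.
#' @return an object of class `claims_schema`.
#' @export
claims_schema <- function(sep = ",", epoch = "1989-01-01",
                          dispensations = NULL, hospitalizations = NULL,
                          registry = NULL) {
  identity_map <- function(fields) setNames(fields, fields)
  disp_fields <- c("person_id", "dispense_day", "days_supplied", "drug_class")
  hosp_fields <- c("person_id", "admit_day", "discharge_day", "primary_dx")
  reg_fields  <- c("person_id", "birth_day", "sex", "coverage_start_day",
                   "coverage_end_day", "death_day")
  merge_map <- function(default, user) {
    if (is.null(user)) return(default)
    default[names(user)] <- user
    default
  }
  structure(list(
    sep = sep,
    epoch = as.Date(epoch),
    dispensations = merge_map(identity_map(disp_fields), dispensations),
    hospitalizations = merge_map(identity_map(hosp_fields), hospitalizations),
    registry = merge_map(identity_map(reg_fields), registry)
  ), class = "claims_schema")
}

# Convert a column to integer day numbers. Accepts integers, numerics that
# are whole, ISO-8601 strings, or Date. Unparseable entries become NA and
# their positions are returned alongside.
.parse_day_col <- function(x, epoch) {
  if (inherits(x, "Date")) {
    return(list(day = as.integer(x - epoch), bad = integer(0)))
  }
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & x != floor(x))
    day <- as.integer(floor(x))
    day[bad] <- NA_integer_
    return(list(day = day, bad = bad))
  }
  x <- as.character(x)
  blank <- !is.na(x) & !nzchar(trimws(x))
  x[blank] <- NA_character_
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- which(!is.na(x) & is.na(d))
  list(day = as.integer(d - epoch), bad = bad)
}

.read_table <- function(path, map, day_fields, schema, table_name,
                        required = names(map)) {
  df <- utils::read.csv(path, sep = schema$sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing_cols <- setdiff(unname(map[required]), names(df))
  if (length(missing_cols)) {
    stop(sprintf("claims schema error in '%s': missing column(s) %s",
                 table_name, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  out <- df
  present <- map[map %in% names(df)]
  names(df)[match(unname(present), names(df))] <- names(present)
  rejects <- data.frame(table = character(0), row = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (f in intersect(day_fields, names(df))) {
    p <- .parse_day_col(df[[f]], schema$epoch)
    df[[f]] <- p$day
    if (length(p$bad)) {
      rejects <- rbind(rejects, data.frame(
        table = table_name, row = p$bad,
        reason = sprintf("unparseable date in '%s'", f),
        stringsAsFactors = FALSE))
    }
  }
  df$person_id <- as.character(df$person_id)
  list(data = df, rejects = rejects)
}

#' Read a claims bundle from delimited files
#'
#' Loads the three administrative tables, converts date columns to integer
#' days since the schema epoch, enforces the record-level invariants
#' (`days_supplied >= 1`, `admit_day <= discharge_day`,
#' `coverage_start_day <= coverage_end_day`, `death_day <= coverage_end_day`,
#' dispensations within the person's coverage period), and drops violating
#' rows into a rejection log rather than failing.
#'
#' @param paths named list/vector with elements `dispensations`,
#'   `hospitalizations`, `registry` giving file locations.
#' @param schema a [claims_schema()].
#' @return a `claims_bundle`: list with data.frames `dispensations`,
#'   `hospitalizations`, `registry`, plus attribute `"rejections"`
#'   (data.frame with columns table, row, reason; row numbers refer to data
#'   rows of the source file, excluding the header).
#' @export
read_claims_bundle <- function(paths, schema = claims_schema()) {
  for (nm in c("dispensations", "hospitalizations", "registry")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop(sprintf("input file for '%s' not found", nm), call. = FALSE)
  }
  disp <- .read_table(paths$dispensations, schema$dispensations,
                      "dispense_day", schema, "dispensations",
                      required = c("person_id", "dispense_day",
                                   "days_supplied", "drug_class"))
  hosp <- .read_table(paths$hospitalizations, schema$hospitalizations,
                      c("admit_day", "discharge_day"), schema,
                      "hospitalizations")
  reg <- .read_table(paths$registry, schema$registry,
                     c("birth_day", "coverage_start_day", "coverage_end_day",
                       "death_day"), schema, "registry",
                     required = setdiff(names(schema$registry), "death_day"))
  bundle <- structure(list(dispensations = disp$data,
                           hospitalizations = hosp$data,
                           registry = reg$data),
                      class = "claims_bundle")
  validate_bundle(bundle,
                  rejections = rbind(disp$rejects, hosp$rejects, reg$rejects))
}

#' Validate a claims bundle against record-level invariants
#'
#' @param bundle a `claims_bundle` (or a plain list with the three tables).
#' @param rejections an initial rejection log to extend.
#' @return the bundle with invalid rows removed and the full rejection log
#'   in `attr(bundle, "rejections")`.
#' @export
validate_bundle <- function(bundle, rejections = NULL) {
  rej <- rejections
  if (is.null(rej)) {
    rej <- data.frame(table = character(0), row = integer(0),
                      reason = character(0), stringsAsFactors = FALSE)
  }
  add_rej <- function(table, rows, reason) {
    if (!length(rows)) return()
    rej <<- rbind(rej, data.frame(table = table, row = rows, reason = reason,
                                  stringsAsFactors = FALSE))
  }

  reg <- bundle$registry
  bad <- which(is.na(reg$coverage_start_day) | is.na(reg$coverage_end_day) |
                 reg$coverage_start_day > reg$coverage_end_day)
  add_rej("registry", bad, "coverage_start_day > coverage_end_day or missing")
  ok <- setdiff(seq_len(nrow(reg)), bad)
  bad2 <- ok[!is.na(reg$death_day[ok]) &
               reg$death_day[ok] > reg$coverage_end_day[ok]]
  add_rej("registry", bad2, "death_day after coverage_end_day")
  reg <- reg[setdiff(ok, bad2), , drop = FALSE]

  hosp <- bundle$hospitalizations
  bad <- which(is.na(hosp$admit_day) | is.na(hosp$discharge_day) |
                 hosp$admit_day > hosp$discharge_day)
  add_rej("hospitalizations", bad, "admit_day > discharge_day or missing")
  hosp <- hosp[setdiff(seq_len(nrow(hosp)), bad), , drop = FALSE]

  disp <- bundle$dispensations
  bad <- which(is.na(disp$days_supplied) | disp$days_supplied < 1 |
                 is.na(disp$dispense_day))
  add_rej("dispensations", bad, "days_supplied < 1 or missing day")
  keep <- setdiff(seq_len(nrow(disp)), bad)
  # dispense_day must fall inside the person's coverage period
  idx <- match(disp$person_id[keep], reg$person_id)
  inside <- !is.na(idx) &
    disp$dispense_day[keep] >= reg$coverage_start_day[idx] &
    disp$dispense_day[keep] <= reg$coverage_end_day[idx]
  add_rej("dispensations", keep[!inside],
          "dispense_day outside coverage period (or unknown person)")
  disp <- disp[keep[inside], , drop = FALSE]

  structure(list(dispensations = disp, hospitalizations = hosp,
                 registry = reg),
            class = "claims_bundle", rejections = rej)
}

#' Write a claims bundle to delimited files
#'
#' Inverse of [read_claims_bundle()]: integer day columns are rendered as
#' ISO-8601 dates relative to the schema epoch, so a round trip reproduces
#' the records exactly.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @param schema a [claims_schema()].
#' @return invisibly, the named vector of file paths written.
#' @export
write_claims_bundle <- function(bundle, dir, schema = claims_schema()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  day_fields <- list(
    dispensations = "dispense_day",
    hospitalizations = c("admit_day", "discharge_day"),
    registry = c("birth_day", "coverage_start_day", "coverage_end_day",
                 "death_day"))
  paths <- c(dispensations = file.path(dir, "dispensations.csv"),
             hospitalizations = file.path(dir, "hospitalizations.csv"),
             registry = file.path(dir, "registry.csv"))
  for (nm in names(paths)) {
    df <- bundle[[nm]]
    for (f in intersect(day_fields[[nm]], names(df))) {
      df[[f]] <- format(schema$epoch + df[[f]], "%Y-%m-%d")
    }
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = TRUE,
                     na = "")
  }
  invisible(paths)
}

#' Cohort selection criteria
#'
#' Thresholds for selecting new statin users after an acute coronary
#' syndrome (ACS) hospitalization. Defaults follow the conventional design:
#' age >= 30 at the index date, 1825 days (5 years) of continuous coverage
#' before index, no statin in the 365 days before the index admission
#' (new-user washout), first statin fill within 90 days of discharge, and
#' survival with coverage for at least 102 days after that first fill.
#'
#' @param min_age minimum age in completed years at the index date.
#' @param statin_window days after index discharge within which the first
#'   statin fill must occur (inclusive).
#' @param prior_coverage required days of beneficiary status before index.
#' @param min_survival required days of follow-up after the first fill.
#' @param statin_washout statin-free days required before the index
#'   admission.
#' @param statin_codes `drug_class` values counted as statins (all pooled;
#'   switching between statins is allowed).
#' @param acs_codes `primary_dx` values defining an ACS hospitalization.
#' @param revasc_codes `primary_dx` values for revascularization without an
#'   ACS diagnosis (grounds for exclusion when the person has no ACS
#'   hospitalization).
#' @param study_start_day,study_end_day study window in integer days; index
#'   discharges must fall inside it. `study_end_day = NULL` uses the
#'   maximum registry coverage end.
#' @return an object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(min_age = 30, statin_window = 90,
                            prior_coverage = 1825, min_survival = 102,
                            statin_washout = 365,
                            statin_codes = c("statin", "statin_A", "statin_B"),
                            acs_codes = c("MI", "UA"),
                            revasc_codes = "REVASC_ONLY",
                            study_start_day = 0, study_end_day = NULL) {
  structure(as.list(environment()), class = "cohort_criteria")
}

.age_at <- function(day, birth_day) as.integer(floor((day - birth_day) / 365.25))

#' Select the analysis cohort from a claims bundle
#'
#' Applies the inclusion/exclusion rules of [cohort_criteria()] in a fixed
#' order (age, prior coverage, revascularization-only, statin washout,
#' statin-within-window, minimum survival), producing the cohort and a
#' flow-chart-style exclusion tally. The candidate pool is every person with
#' at least one ACS or revascularization hospitalization discharged inside
#' the study window; for persons with several eligible hospitalizations the
#' earliest ACS discharge is the index date. The application order affects
#' only the tally, never membership.
#'
#' @param bundle a `claims_bundle`.
#' @param criteria a [cohort_criteria()].
#' @param covariate_cols registry columns (beyond the canonical schema) to
#'   carry into the cohort as baseline covariates; `NULL` takes all extras.
#' @return a list of class `cohort_selection` with elements
#'   \describe{
#'     \item{cohort}{data.frame: person_id, index_day, first_statin_day,
#'       followup_end_day, span (follow-up days from first fill), died, age,
#'       age_group, plus baseline covariates.}
#'     \item{exclusions}{data.frame: criterion, n_excluded, in application
#'       order, with a final `retained` row.}
#'   }
#' @export
select_cohort <- function(bundle, criteria = cohort_criteria(),
                          covariate_cols = NULL) {
  cr <- criteria
  reg <- bundle$registry
  hosp <- bundle$hospitalizations
  disp <- bundle$dispensations
  study_end <- cr$study_end_day
  if (is.null(study_end)) {
    study_end <- if (nrow(reg)) max(reg$coverage_end_day) else 0L
  }

  cand_dx <- c(cr$acs_codes, cr$revasc_codes)
  hh <- hosp[hosp$primary_dx %in% cand_dx &
               hosp$discharge_day >= cr$study_start_day &
               hosp$discharge_day <= study_end, , drop = FALSE]
  hh <- hh[hh$person_id %in% reg$person_id, , drop = FALSE]
  persons <- unique(hh$person_id)

  empty_tally <- data.frame(
    criterion = c("age", "prior_coverage", "revascularization_only",
                  "statin_washout", "no_statin_within_window",
                  "insufficient_survival", "retained"),
    n = 0L, stringsAsFactors = FALSE)

  if (!length(persons)) {
    return(structure(list(
      cohort = data.frame(person_id = character(0)),
      exclusions = empty_tally[0, ]), class = "cohort_selection"))
  }

  is_acs <- hh$primary_dx %in% cr$acs_codes
  # index day: earliest ACS discharge; for revascularization-only persons a
  # provisional index (earliest candidate discharge) anchors age/coverage.
  acs_min <- tapply(ifelse(is_acs, hh$discharge_day, NA_integer_),
                    hh$person_id, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  acs_min[!is.finite(acs_min)] <- NA
  any_min <- tapply(hh$discharge_day, hh$person_id, min)
  ord <- persons
  has_acs <- !is.na(acs_min[ord])
  index_day <- ifelse(has_acs, acs_min[ord], any_min[ord])
  # admit day of the index hospitalization (earliest admit among episodes
  # discharged on the index day), anchors the washout window
  key <- paste(hh$person_id, hh$discharge_day)
  admit_min <- tapply(hh$admit_day, key, min)
  index_admit <- as.integer(admit_min[paste(ord, index_day)])

  ri <- match(ord, reg$person_id)
  birth <- reg$birth_day[ri]
  cov_start <- reg$coverage_start_day[ri]
  cov_end <- reg$coverage_end_day[ri]
  death <- reg$death_day[ri]
  if (is.null(death)) death <- rep(NA_integer_, length(ord))
  age <- .age_at(index_day, birth)

  statins <- disp[disp$drug_class %in% cr$statin_codes, , drop = FALSE]
  sp <- split(statins$dispense_day, statins$person_id)
  first_fill <- rep(NA_integer_, length(ord))
  washout_hit <- rep(FALSE, length(ord))
  for (i in seq_along(ord)) {
    days <- sp[[ord[i]]]
    if (is.null(days)) next
    washout_hit[i] <- any(days >= index_admit[i] - cr$statin_washout &
                            days < index_admit[i])
    eligible <- days[days >= index_day[i] &
                       days <= index_day[i] + cr$statin_window]
    if (length(eligible)) first_fill[i] <- min(eligible)
  }

  followup_end <- pmin(ifelse(is.na(death), .Machine$integer.max, death),
                       cov_end, study_end)
  died <- !is.na(death) & death <= pmin(cov_end, study_end)

  fail <- list(
    age = age < cr$min_age,
    prior_coverage = (index_day - cov_start) < cr$prior_coverage,
    revascularization_only = !has_acs,
    statin_washout = washout_hit,
    no_statin_within_window = is.na(first_fill),
    insufficient_survival = !is.na(first_fill) &
      (followup_end - first_fill) < cr$min_survival
  )
  # survival criterion is undefined without a fill; charge such persons to
  # the window criterion only
  fail$insufficient_survival[is.na(first_fill)] <- FALSE

  remaining <- rep(TRUE, length(ord))
  tally <- empty_tally
  for (j in seq_along(fail)) {
    hit <- remaining & fail[[j]]
    tally$n[j] <- sum(hit)
    remaining <- remaining & !hit
  }
  tally$n[nrow(tally)] <- sum(remaining)

  keep <- which(remaining)
  cohort <- data.frame(
    person_id = ord[keep],
    index_day = as.integer(index_day[keep]),
    first_statin_day = as.integer(first_fill[keep]),
    followup_end_day = as.integer(followup_end[keep]),
    span = as.integer(followup_end[keep] - first_fill[keep]),
    died = died[keep],
    age = age[keep],
    stringsAsFactors = FALSE)
  cohort$age_group <- cut(cohort$age, breaks = c(-Inf, 54, 65, 73, Inf),
                          labels = c("<55", "55-65", "66-73", ">=74"))
  extras <- setdiff(names(reg),
                    c("person_id", "birth_day", "coverage_start_day",
                      "coverage_end_day", "death_day"))
  if (!is.null(covariate_cols)) extras <- intersect(extras, covariate_cols)
  for (cc in extras) cohort[[cc]] <- reg[[cc]][ri[keep]]

  structure(list(cohort = cohort, exclusions = tally),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat("Cohort selection:", nrow(x$cohort), "members retained\n")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}
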