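#' End-to-end run configuration
#'
#' @param input `"simulate"` with a [sim_config()] in `sim`, or `"files"`
#'   with `paths` (see [read_claims_bundle()]) and optional `schema`.
#' @param sim a [sim_config()] (simulate mode).
#' @param paths named file paths (files mode).
#' @param schema a [claims_schema()] (files mode).
#' @param criteria a [cohort_criteria()]; `NULL` derives it from the sim
#'   config in simulate mode or uses defaults in files mode.
#' @param adherence an [adherence_config()].
#' @param covariates baseline covariate columns for adjusted models.
#' @param timing covariate timing for the repeated measures.
#' @param variants `"headline"` fits the binary Method A / Method B pair;
#'   `"full"` runs the whole [sensitivity_suite()].
#' @param out_dir output directory for delimited artifacts and the summary
#'   file; `NULL` skips writing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = c("simulate", "files"), sim = sim_config(),
                       paths = NULL, schema = claims_schema(),
                       criteria = NULL, adherence = adherence_config(),
                       covariates = c("age_group", "sex", "revasc",
                                      "comorbidity"),
                       timing = "concurrent",
                       variants = c("full", "headline"), out_dir = NULL) {
  input <- match.arg(input)
  variants <- match.arg(variants)
  stopifnot(adherence$threshold > 0, adherence$threshold < 1)
  structure(as.list(environment()), class = "run_config")
}

# stable hash of a configuration (or any R object): md5 of its canonical
# deparsed form
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full adherence-measurement comparison pipeline
#'
#' Executes read/generate, cohort selection, the adherence engine, dataset
#' construction, model fits, diagnostics and concordance, and assembles a
#' report. When `config$out_dir` is set, writes the cohort, exclusion
#' flow, adherence, counting-process, results, concordance and
#' Kaplan-Meier tables as delimited text plus a machine-readable
#' `summary.json` holding the Method A and Method B hazard ratios side by
#' side. Identical config (including seed) yields identical outputs.
#'
#' @param config a [run_config()].
#' @return a `report_bundle`: list with `cohort_flow`,
#'   `adherence_summary`, `concordance`, `concordance_last`, `km_fixed`,
#'   `km_timedep`, `results`, `diagnostics` (PH test and VIF tables),
#'   `headline` (Method A vs Method B adjusted and crude HRs), and
#'   `meta` (seed, config hash, package version).
#' @export
run_pipeline <- function(config) {
  if (config$input == "simulate") {
    sim <- generate_bundle(config$sim)
    bundle <- sim$bundle
    criteria <- if (is.null(config$criteria)) sim_criteria(config$sim)
                else config$criteria
    seed <- config$sim$seed
  } else {
    bundle <- read_claims_bundle(config$paths, config$schema)
    criteria <- if (is.null(config$criteria)) cohort_criteria()
                else config$criteria
    seed <- NA_integer_
  }

  sel <- select_cohort(bundle, criteria)
  if (!nrow(sel$cohort)) stop("empty cohort at selection stage", call. = FALSE)
  covariates <- intersect(config$covariates, names(sel$cohort))

  adh <- cohort_adherence(sel$cohort, bundle$dispensations,
                          bundle$hospitalizations, config$adherence,
                          statin_codes = criteria$statin_codes)
  fixed <- build_fixed_dataset(sel$cohort, adh, covariates)
  cp <- build_counting_process(sel$cohort, adh, covariates, config$timing)

  results <- if (config$variants == "full") {
    sensitivity_suite(sel$cohort, adh, covariates, config$timing)
  } else {
    rbind_fits <- function(method, data) {
      do.call(rbind, lapply(c("crude", "adjusted"), function(adj) {
        covs <- if (adj == "adjusted") covariates else character(0)
        r <- fit_cox(data, "adherent", covs)
        tab <- r$table[grepl("adherent", r$table$term, fixed = TRUE), ]
        data.frame(method = method, variant = "binary", adjustment = adj,
                   term = tab$term, coef = tab$coef, hr = tab$hr,
                   ci_low = tab$ci_low, ci_high = tab$ci_high, p = tab$p,
                   n = r$n, events = r$events, error = NA_character_,
                   stringsAsFactors = FALSE)
      }))
    }
    rbind(rbind_fits("summary", fixed), rbind_fits("repeated", cp))
  }

  pick <- function(method, adjustment) {
    r <- results[results$method == method & results$variant == "binary" &
                   results$adjustment == adjustment & is.na(results$error), ]
    if (!nrow(r)) return(list(hr = NA, ci_low = NA, ci_high = NA, p = NA))
    as.list(r[1, c("hr", "ci_low", "ci_high", "p")])
  }
  headline <- list(method_a = list(crude = pick("summary", "crude"),
                                   adjusted = pick("summary", "adjusted")),
                   method_b = list(crude = pick("repeated", "crude"),
                                   adjusted = pick("repeated", "adjusted")))

  adj_a <- fit_cox(fixed, "adherent", covariates)
  adj_b <- fit_cox(cp, "adherent", covariates)
  vif_tab <- tryCatch({
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
      data = fixed)[, -1, drop = FALSE]
    compute_vif(as.data.frame(mm))
  }, error = function(e) NULL)
  diagnostics <- list(ph_fixed = check_ph(adj_a)$test,
                      ph_timedep = check_ph(adj_b)$test,
                      vif = vif_tab)

  s <- adh$summary
  adherence_summary <- data.frame(
    n = nrow(s), mean_pdc = mean(s$pdc), median_pdc = median(s$pdc),
    sd_pdc = sd(s$pdc), pct_optimal = 100 * mean(s$adherent == "optimal"))
  conc <- concordance_over_time(adh)
  conc_last <- concordance_last_interval(adh)

  hashed <- unclass(config)
  hashed$out_dir <- NULL  # where results land is not part of the analysis
  meta <- list(seed = seed, config_hash = config_hash(hashed),
               package_version = as.character(utils::packageVersion("pdcsurv")))
  report <- structure(list(
    cohort_flow = sel$exclusions, adherence_summary = adherence_summary,
    concordance = conc, concordance_last = conc_last,
    km_fixed = kaplan_meier(fixed), km_timedep = kaplan_meier(cp),
    results = results, diagnostics = diagnostics, headline = headline,
    meta = meta), class = "report_bundle")

  if (!is.null(config$out_dir)) {
    .write_report(report, sel, adh, cp, config$out_dir)
  }
  report
}

.write_report <- function(report, sel, adh, cp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE, na = "")
  w(sel$cohort, "cohort.csv")
  w(sel$exclusions, "exclusion_flow.csv")
  export_adherence(adh, file.path(dir, "adherence.csv"))
  w(cp, "counting_process.csv")
  w(report$results, "results.csv")
  w(report$concordance, "concordance.csv")
  w(as.data.frame(report$km_fixed), "km_fixed.csv")
  w(as.data.frame(report$km_timedep), "km_timedep.csv")
  summary <- list(meta = report$meta,
                  cohort = list(n = sum(report$cohort_flow$n[
                    report$cohort_flow$criterion == "retained"])),
                  adherence = as.list(report$adherence_summary),
                  concordance_last = report$concordance_last,
                  headline = report$headline)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Adherence-measurement comparison report\n")
  cat(sprintf("  cohort retained: %d\n",
              x$cohort_flow$n[x$cohort_flow$criterion == "retained"]))
  cat(sprintf("  mean summary PDC: %.1f%%; optimal adherence: %.1f%%\n",
              100 * x$adherence_summary$mean_pdc,
              x$adherence_summary$pct_optimal))
  cat(sprintf("  concordance at last completed interval: %.1f%%\n",
              x$concordance_last$pct_match))
  ha <- x$headline$method_a$adjusted; hb <- x$headline$method_b$adjusted
  cat(sprintf("  Method A (summary)  adjusted HR %.2f (95%% CI %.2f-%.2f)\n",
              ha$hr, ha$ci_low, ha$ci_high))
  cat(sprintf("  Method B (repeated) adjusted HR %.2f (95%% CI %.2f-%.2f)\n",
              hb$hr, hb$ci_low, hb$ci_high))
  invisible(x)
}
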