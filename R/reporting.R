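#' Cohort coverage against national birth statistics
#'
#' Compares cohort births per year with the national count of singleton
#' live births. The reference table supplies either
#' `singleton_births` directly or `total_births`, in which case the
#' singleton count is estimated as total x `singleton_ratio` (the
#' singleton share of live births, 97.0% across 1998--2015).
#'
#' @param cohort_by_year tibble with `year` and `births` (cohort counts).
#' @param reference tibble with `year` and `singleton_births` or
#'   `total_births`.
#' @param singleton_ratio applied when only `total_births` is given.
#' @return tibble of class `coverage_table`: per-year rows plus a
#'   `"total"` row; `coverage_pct` at full precision and
#'   `coverage_display` rounded to 1 decimal place.
#' @export
coverage_table <- function(cohort_by_year, reference, singleton_ratio = 0.97) {
  if (!"singleton_births" %in% names(reference)) {
    if (!"total_births" %in% names(reference)) {
      stop("reference needs a singleton_births or total_births column")
    }
    reference$singleton_births <- reference$total_births * singleton_ratio
  }
  missing_years <- setdiff(cohort_by_year$year, reference$year)
  if (length(missing_years) > 0L) {
    stop("reference table missing year(s): ",
         paste(missing_years, collapse = ", "))
  }
  x <- dplyr::inner_join(cohort_by_year,
                         reference[, c("year", "singleton_births")],
                         by = "year")
  x <- dplyr::arrange(x, .data$year)
  out <- tibble::tibble(
    year = as.character(x$year),
    cohort_births = x$births,
    reference_singleton_births = x$singleton_births
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    year = "total",
    cohort_births = sum(out$cohort_births),
    reference_singleton_births = sum(out$reference_singleton_births)
  ))
  out$coverage_pct <- 100 * out$cohort_births / out$reference_singleton_births
  out$coverage_display <- round(out$coverage_pct, 1)
  structure(out, class = c("coverage_table", class(out)))
}

#' Packaged national reference tables
#'
#' Published comparison figures for England, 1998--2015, shipped so
#' coverage and linkage arithmetic runs without any download:
#' `hes_reference_births()` returns per-year cohort birth counts
#' alongside the ONS-derived estimate of singleton live births;
#' `hes_reference_death_linkage()` the per-year infant-death counts with
#' the percentage lacking a register link (cohort side) and the
#' percentage lacking a hospital link (register side);
#' `hes_reference_headline()` headline totals (cohort births, infants
#' readmitted, infant deaths).
#'
#' @return a tibble.
#' @name reference_tables
NULL

ref_csv <- function(name) {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", name, package = "hesbirths", mustWork = TRUE)
  ))
}

#' @rdname reference_tables
#' @export
hes_reference_births <- function() ref_csv("england_births_reference.csv")

#' @rdname reference_tables
#' @export
hes_reference_death_linkage <- function() {
  ref_csv("infant_death_linkage_reference.csv")
}

#' @rdname reference_tables
#' @export
hes_reference_headline <- function() ref_csv("england_headline_counts.csv")

#' Aggregate summary report
#'
#' Headline totals with every displayed ratio recomputable from its
#' displayed numerator and denominator, plus the segmented-regression
#' table and per-period linkage diagnostics.
#'
#' @param cohort the built cohort.
#' @param outcomes death outcomes from [detect_infant_deaths()].
#' @param fit an `itsa_fit`.
#' @param series the quarterly readmission series.
#' @param diagnostics optional [linkage_diagnostics()] table.
#' @return list of class `hes_report`.
#' @export
aggregate_report <- function(cohort, outcomes, fit, series,
                             diagnostics = NULL) {
  if (nrow(cohort) == 0L) stop("cannot report on an empty cohort")
  n <- nrow(cohort)
  n_re <- sum(cohort$readmitted)
  rates <- mortality_rates(cohort, outcomes)
  totals <- tibble::tibble(
    n_births = n,
    n_readmitted = n_re,
    pct_readmitted = 100 * n_re / n,
    n_infant_deaths = rates$n_deaths[rates$measure == "infant"],
    n_neonatal_deaths = rates$n_deaths[rates$measure == "neonatal"],
    n_post_neonatal_deaths = rates$n_deaths[rates$measure == "post_neonatal"],
    infant_mortality_per_1000 = rates$rate_per_1000[rates$measure == "infant"]
  )
  structure(
    list(
      totals = totals, rates = rates, itsa = fit$coefficients,
      counterfactuals = fit$counterfactuals, series = series,
      diagnostics = diagnostics,
      linkage_summary = if (!is.null(diagnostics)) {
        weighted_linkage_summary(diagnostics)
      }
    ),
    class = "hes_report"
  )
}

#' @export
print.hes_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Births: %s\n", format(t$n_births, big.mark = ",")))
  cat(sprintf("Readmitted in infancy: %s (%.1f%%)\n",
              format(t$n_readmitted, big.mark = ","), t$pct_readmitted))
  cat(sprintf(
    "Infant deaths: %s (%.2f per 1000 live births; %s neonatal, %s post-neonatal)\n",
    format(t$n_infant_deaths, big.mark = ","), t$infant_mortality_per_1000,
    format(t$n_neonatal_deaths, big.mark = ","),
    format(t$n_post_neonatal_deaths, big.mark = ",")
  ))
  for (k in seq_len(nrow(x$counterfactuals))) {
    cf <- x$counterfactuals[k, ]
    cat(sprintf("  %s: observed %.1f%%, expected %.1f%%, shift %+.1f pp\n",
                cf$change_point, cf$observed, cf$expected, cf$shift))
  }
  if (!is.null(x$linkage_summary)) {
    for (k in seq_len(nrow(x$linkage_summary))) {
      s <- x$linkage_summary[k, ]
      cat(sprintf("  deaths %s: %.0f%% identified from discharge method only\n",
                  s$period, s$pct))
    }
  }
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' @param report a `hes_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    data.table::fwrite(x, file.path(dir, f), dateTimeAs = "ISO", na = "")
  }
  w(report$totals, "totals.csv")
  w(report$rates, "rates.csv")
  w(report$series, "series.csv")
  w(report$itsa, "itsa_coefficients.csv")
  w(report$counterfactuals, "counterfactuals.csv")
  if (!is.null(report$diagnostics)) w(report$diagnostics, "diagnostics.csv")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Run the full pipeline on a synthetic scenario
#'
#' simulate -> build cohort -> merge admissions -> readmission and
#' mortality outcomes -> segmented regression -> report. Deterministic
#' given the configuration's seed. Row counts are logged per stage;
#' stage errors are re-signalled with the stage name attached.
#'
#' @param config a [scenario_config()].
#' @param ruleset a [birth_ruleset()].
#' @param out_dir optional directory for all artifacts (scenario tables,
#'   cohort, ledger, series, fit JSON, report tables).
#' @param quiet suppress progress messages.
#' @return list: `scenario`, `cohort`, `ledger`, `admissions`, `series`,
#'   `series_by_stratum`, `fit`, `outcomes`, `rates`, `diagnostics`,
#'   `cause_audit`, `report`.
#' @export
run_pipeline <- function(config = scenario_config(),
                         ruleset = birth_ruleset(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scn <- stage("simulate", generate_scenario(config))
  say("simulate: ", nrow(scn$episodes), " episodes, ",
      nrow(scn$deaths), " deaths")
  built <- stage("cohort", build_cohort(scn$episodes, ruleset))
  say("cohort: ", nrow(built$cohort), " births retained")
  adm <- stage("admissions", build_admissions(scn$episodes))
  say("admissions: ", nrow(adm))
  adm <- stage("admissions", flag_birth_admission(adm, built$cohort))
  cohort <- stage("outcomes", readmitted_in_infancy(built$cohort, adm))
  cohort <- stratify_by_birth_los(cohort)
  series <- stage("outcomes", quarterly_readmission_series(cohort))
  series_by_stratum <- lapply(
    split(cohort, cohort$birth_los_stratum), quarterly_readmission_series
  )
  fit <- stage("itsa", fit_itsa(itsa_design(series, config$change_points)))
  outcomes <- stage("mortality",
                    detect_infant_deaths(cohort, scn$deaths, adm))
  rates <- stage("mortality", mortality_rates(cohort, outcomes))
  diagnostics <- stage(
    "mortality",
    linkage_diagnostics(outcomes, cohort, scn$deaths, scn$episodes)
  )
  audit <- stage("mortality", missing_cause_audit(outcomes))
  report <- stage("report",
                  aggregate_report(cohort, outcomes, fit, series, diagnostics))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scenario(scn, file.path(out_dir, "scenario"))
    data.table::fwrite(cohort[, setdiff(names(cohort), "birth_los_stratum")],
                       file.path(out_dir, "cohort.csv"),
                       dateTimeAs = "ISO", na = "")
    data.table::fwrite(built$ledger, file.path(out_dir, "ledger.csv"))
    jsonlite::write_json(
      list(coefficients = fit$coefficients,
           counterfactuals = fit$counterfactuals,
           segment_slopes = fit$segment_slopes),
      file.path(out_dir, "fit.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    write_report(report, file.path(out_dir, "report"))
  }
  list(
    scenario = scn, cohort = cohort, ledger = built$ledger, admissions = adm,
    series = series, series_by_stratum = series_by_stratum, fit = fit,
    outcomes = outcomes, rates = rates, diagnostics = diagnostics,
    cause_audit = audit, report = report
  )
}
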