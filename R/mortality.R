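#' Detect infant deaths from linked mortality records and discharge method
#'
#' An infant death (age 0--364 days; day of birth is day 0) is recorded
#' if a mortality-register row links to the child by person ID, or if
#' any of the child's admissions ends with discharge method "died"
#' within the first year. A death seen both ways (dates within 1 day of
#' each other, allowing registration jitter) is one death with
#' `source = "both"`; the death date and cause codes then come from the
#' register. Deaths seen only through the discharge method carry no
#' cause codes -- that is precisely the information lost when the
#' register link fails.
#'
#' Register rows implying a negative age at death are rejected (kept in
#' the `rejected` attribute). Deaths after day 364 are outside follow-up
#' and ignored.
#'
#' @param cohort a built cohort (`person_id`, `birth_date`).
#' @param deaths mortality table: `person_id` (nullable), `dod`,
#'   `cause_01` ... columns.
#' @param admissions output of [build_admissions()] on the cohort's
#'   episodes (needs `dismeth`).
#' @return tibble of outcomes: `person_id`, `death_date`,
#'   `age_at_death`, `source` (`ons_linked` / `hes_discharge_only` /
#'   `both`), `band` (`neonatal` / `post_neonatal`), `causes`
#'   (list-column, possibly empty).
#' @export
detect_infant_deaths <- function(cohort, deaths, admissions) {
  cols <- grep("^cause_", names(deaths), value = TRUE)
  ons <- dplyr::inner_join(
    deaths[!is.na(deaths$person_id), c("person_id", "dod", cols)],
    cohort[, c("person_id", "birth_date")],
    by = "person_id"
  )
  ons$age <- as.numeric(ons$dod - ons$birth_date)
  rejected <- ons[ons$age < 0, ]
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " mortality record(s) dated before birth rejected")
  }
  ons <- ons[ons$age >= 0 & ons$age <= 364, ]
  ons$causes <- lapply(seq_len(nrow(ons)), function(i) {
    v <- unlist(ons[i, cols], use.names = FALSE)
    v[!is.na(v) & v != ""]
  })

  hes <- admissions[!is.na(admissions$dismeth) & admissions$dismeth == "4",
                    c("person_id", "admi_end")]
  hes <- dplyr::inner_join(hes, cohort[, c("person_id", "birth_date")],
                           by = "person_id")
  hes$age <- as.numeric(hes$admi_end - hes$birth_date)
  hes <- hes[hes$age >= 0 & hes$age <= 364, ]
  # a person can in principle carry several "died" admissions in bad
  # data; keep the earliest
  hes <- dplyr::distinct(
    dplyr::arrange(hes, .data$person_id, .data$admi_end),
    .data$person_id, .keep_all = TRUE
  )
  ons <- dplyr::distinct(dplyr::arrange(ons, .data$person_id, .data$dod),
                         .data$person_id, .keep_all = TRUE)

  both_ids <- intersect(ons$person_id, hes$person_id)
  agree <- abs(as.numeric(ons$dod[match(both_ids, ons$person_id)] -
                            hes$admi_end[match(both_ids, hes$person_id)])) <= 1
  both_ids <- both_ids[agree]

  src <- rep("ons_linked", nrow(ons))
  src[ons$person_id %in% both_ids] <- "both"
  out_ons <- tibble::tibble(
    person_id = ons$person_id,
    death_date = ons$dod,
    age_at_death = ons$age,
    source = src,
    causes = ons$causes
  )
  hes_only <- hes[!(hes$person_id %in% ons$person_id), ]
  out_hes <- tibble::tibble(
    person_id = hes_only$person_id,
    death_date = hes_only$admi_end,
    age_at_death = hes_only$age,
    source = "hes_discharge_only",
    causes = lapply(seq_len(nrow(hes_only)), function(i) character())
  )
  out <- dplyr::bind_rows(out_ons, out_hes)
  out$band <- ifelse(out$age_at_death <= 27, "neonatal", "post_neonatal")
  out <- dplyr::arrange(out, .data$person_id)
  attr(out, "rejected") <- rejected[, c("person_id", "dod", "birth_date")]
  out
}

#' Infant, neonatal and post-neonatal mortality rates per 1000 live births
#'
#' All three rates share the cohort denominator, so neonatal +
#' post-neonatal equals the infant rate exactly.
#'
#' @param cohort the cohort (denominator = number of rows).
#' @param outcomes output of [detect_infant_deaths()].
#' @return tibble: `measure`, `n_deaths`, `n_births`, `rate_per_1000`.
#' @export
mortality_rates <- function(cohort, outcomes) {
  n <- nrow(cohort)
  if (n == 0L) stop("mortality rates undefined for an empty cohort")
  n_neo <- sum(outcomes$band == "neonatal")
  n_post <- sum(outcomes$band == "post_neonatal")
  tibble::tibble(
    measure = c("infant", "neonatal", "post_neonatal"),
    n_deaths = c(n_neo + n_post, n_neo, n_post),
    n_births = n,
    rate_per_1000 = 1000 * c(n_neo + n_post, n_neo, n_post) / n
  )
}

#' Linkage-agreement diagnostics by year of birth
#'
#' Two complementary failure rates: among cohort infant deaths, the
#' percentage seen only through the hospital discharge method (no
#' register link); and among register infant deaths, the percentage
#' whose person ID matches no hospital episode. Register rows are
#' grouped by year of death, the closest available stand-in for year of
#' birth when the row carries no usable link.
#'
#' @param outcomes output of [detect_infant_deaths()].
#' @param cohort the cohort (supplies birth years).
#' @param deaths the full mortality table.
#' @param episodes the full episode table (for the register-to-episode
#'   check).
#' @return tibble per year: `year`, `cohort_deaths`, `pct_hes_only`,
#'   `ons_deaths`, `pct_ons_unlinked`.
#' @export
linkage_diagnostics <- function(outcomes, cohort, deaths, episodes) {
  oc <- dplyr::inner_join(outcomes, cohort[, c("person_id", "birth_date")],
                          by = "person_id")
  oc$year <- as.integer(format(oc$birth_date, "%Y"))
  co <- dplyr::summarise(
    dplyr::group_by(oc, .data$year),
    cohort_deaths = dplyr::n(),
    pct_hes_only = 100 * mean(.data$source == "hes_discharge_only"),
    .groups = "drop"
  )
  dth <- deaths
  dth$year <- as.integer(format(dth$dod, "%Y"))
  dth$linked <- !is.na(dth$person_id) & dth$person_id %in% episodes$person_id
  on <- dplyr::summarise(
    dplyr::group_by(dth, .data$year),
    ons_deaths = dplyr::n(),
    pct_ons_unlinked = 100 * mean(!.data$linked),
    .groups = "drop"
  )
  dplyr::full_join(co, on, by = "year")
}

#' Deaths-weighted summary of a linkage-diagnostics table
#'
#' Collapses per-year failure percentages to period summaries, weighting
#' each year by its death count (so the summary equals the pooled
#' percentage computed from the underlying counts).
#'
#' @param diagnostics a table with `year`, a count column and a
#'   percentage column (defaults match [linkage_diagnostics()] output).
#' @param groups named list of year vectors; the default splits at the
#'   NN4B and RON changes. An `overall` row is always included.
#' @param count_col,pct_col column names to weight and average.
#' @return tibble: `period`, `n_deaths`, `pct`.
#' @export
weighted_linkage_summary <- function(diagnostics,
                                     groups = list(
                                       "1998-2002" = 1998:2002,
                                       "2003-2009" = 2003:2009,
                                       "2010-2015" = 2010:2015
                                     ),
                                     count_col = "cohort_deaths",
                                     pct_col = "pct_hes_only") {
  one <- function(name, years) {
    d <- diagnostics[diagnostics$year %in% years, ]
    d <- d[!is.na(d[[count_col]]) & !is.na(d[[pct_col]]), ]
    w <- d[[count_col]]
    tibble::tibble(
      period = name, n_deaths = sum(w),
      pct = sum(w * d[[pct_col]]) / sum(w)
    )
  }
  rows <- dplyr::bind_rows(mapply(one, names(groups), groups,
                                  SIMPLIFY = FALSE))
  dplyr::bind_rows(rows, one("overall", unique(diagnostics$year)))
}

#' Audit of register-linked deaths with no recorded cause
#'
#' Every register-linked death should carry cause codes; empty cause
#' lists flag extraction defects. Reported by single day of age, with
#' the 28--30-day band (where the known defect concentrates)
#' summarised separately.
#'
#' @param outcomes output of [detect_infant_deaths()].
#' @return list: `by_age` (tibble `age_at_death`, `n_linked`,
#'   `n_empty_cause`, `pct_empty`), `overall_pct`, `band_28_30`
#'   (same columns, pooled over ages 28--30).
#' @export
missing_cause_audit <- function(outcomes) {
  linked <- outcomes[outcomes$source != "hes_discharge_only", ]
  linked$empty <- lengths(linked$causes) == 0L
  by_age <- dplyr::summarise(
    dplyr::group_by(linked, .data$age_at_death),
    n_linked = dplyr::n(), n_empty_cause = sum(.data$empty), .groups = "drop"
  )
  by_age$pct_empty <- 100 * by_age$n_empty_cause / by_age$n_linked
  band <- linked[linked$age_at_death >= 28 & linked$age_at_death <= 30, ]
  list(
    by_age = by_age,
    overall_pct = if (nrow(linked) > 0) 100 * mean(linked$empty) else 0,
    band_28_30 = tibble::tibble(
      n_linked = nrow(band), n_empty_cause = sum(band$empty),
      pct_empty = if (nrow(band) > 0) 100 * mean(band$empty) else 0
    )
  )
}
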