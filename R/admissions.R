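#' Merge consultant episodes into continuous inpatient admissions
#'
#' A hospital admission is a continuous period a child spends under
#' hospital care; transfers and admissions within 1 day of each other
#' are treated as one admission. Per person, episodes sorted by start
#' join the current admission when their start is no more than 1 day
#' after the running maximum end (overlaps and next-day contiguity
#' merge; a 2-day gap starts a new admission). This is an interval
#' union with 1-day tolerance, and is equivalent to the transitive
#' closure of the pairwise "within 1 day" relation.
#'
#' Episodes with end before start are rejected (dropped, returned in the
#' `rejected` attribute); episodes missing an end date take end = start
#' for merging.
#'
#' @param episodes tibble with at least `person_id`, `episode_id`,
#'   `epistart`, `epiend`; `dismeth` is carried to the admission (taken
#'   from the episode ending last) when present.
#' @return tibble of admissions: `person_id`, `admission_id`,
#'   `admi_start`, `admi_end`, `n_episodes`, `length_of_stay` (days,
#'   end - start), `dismeth`; attribute `episode_map` maps every kept
#'   `episode_id` to exactly one `admission_id`; attribute `rejected`
#'   holds dropped rows.
#' @export
build_admissions <- function(episodes) {
  need <- c("person_id", "episode_id", "epistart", "epiend")
  if (!all(need %in% names(episodes))) {
    stop("episodes must contain columns: ", paste(need, collapse = ", "))
  }
  dt <- data.table::as.data.table(
    episodes[, intersect(c(need, "dismeth"), names(episodes))]
  )
  if (!"dismeth" %in% names(dt)) dt[, "dismeth" := NA_character_]
  dt[, `:=`(start = as.numeric(epistart), end = as.numeric(epiend))]
  dt[is.na(end), end := start]  # unfinished episode: end = start for merging
  rejected <- dt[end < start]
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " episode(s) with end before start rejected")
    dt <- dt[end >= start]
  }
  if (nrow(dt) == 0L) {
    out <- tibble::tibble(
      person_id = character(), admission_id = character(),
      admi_start = as.Date(character()), admi_end = as.Date(character()),
      n_episodes = integer(), length_of_stay = numeric(), dismeth = character()
    )
    attr(out, "episode_map") <- tibble::tibble(
      episode_id = character(), admission_id = character()
    )
    attr(out, "rejected") <- tibble::as_tibble(rejected)
    return(out)
  }
  data.table::setorder(dt, person_id, start, end)
  # single global cummax pass: shifting every person's dates by a distinct
  # multiple of a span larger than the whole date range stops the running
  # maximum bleeding across persons and forces a break at each boundary
  big <- diff(range(c(dt$start, dt$end))) + 3
  pid <- data.table::rleid(dt$person_id)
  adj_start <- dt$start + pid * big
  adj_end <- dt$end + pid * big
  run_end <- cummax(adj_end)
  new_adm <- adj_start > data.table::shift(run_end, fill = -Inf) + 1
  dt[, adm_seq := cumsum(new_adm)]
  dt[, ord := .I]
  adm <- dt[, list(
    person_id = data.table::first(person_id),
    admi_start = min(start),
    admi_end = max(end),
    n_episodes = .N
  ), by = "adm_seq"]
  adm[, admi_start := as.Date(admi_start, origin = "1970-01-01")]
  adm[, admi_end := as.Date(admi_end, origin = "1970-01-01")]
  adm[, admission_id := paste0(person_id, "-", data.table::rowid(person_id))]
  # admission discharge method = that of the episode ending last (input
  # order breaks ties towards the later row)
  data.table::setorder(dt, adm_seq, end, ord)
  adm$dismeth <- dt$dismeth[!duplicated(dt$adm_seq, fromLast = TRUE)]
  dt[, admission_id := adm$admission_id[match(adm_seq, adm$adm_seq)]]
  adm[, length_of_stay := as.numeric(admi_end - admi_start)]
  out <- tibble::as_tibble(adm[, c(
    "person_id", "admission_id", "admi_start", "admi_end", "n_episodes",
    "length_of_stay", "dismeth"
  )])
  attr(out, "episode_map") <- tibble::as_tibble(
    dt[, c("episode_id", "admission_id")]
  )
  attr(out, "rejected") <- tibble::as_tibble(
    rejected[, intersect(c(need, "dismeth"), names(rejected)), with = FALSE]
  )
  out
}

#' Flag each cohort member's birth admission
#'
#' The birth admission is the admission containing the birth episode;
#' because merging already absorbs transfers within 1 day, it includes
#' moves to neonatal intensive care or other hospitals straight after
#' birth.
#'
#' @param admissions output of [build_admissions()] run on the episodes.
#' @param cohort tibble with `person_id` and `birth_episode_id`.
#' @return `admissions` with a logical `is_birth_admission` column.
#' @export
flag_birth_admission <- function(admissions, cohort) {
  map <- attr(admissions, "episode_map")
  hit <- dplyr::inner_join(
    cohort[, c("person_id", "birth_episode_id")], map,
    by = c(birth_episode_id = "episode_id")
  )
  missing <- setdiff(cohort$birth_episode_id, map$episode_id)
  if (length(missing) > 0L) {
    stop("birth episode(s) absent from any admission: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  admissions$is_birth_admission <- admissions$admission_id %in% hit$admission_id
  admissions
}

#' Infant readmission outcome
#'
#' A child counts as readmitted if any non-birth admission starts after
#' discharge from the birth admission and within the first year of life
#' (ages 0--364 days inclusive; the admission may end later). Linkage
#' failure makes this observable outcome fall short of the true one:
#' post-birth admissions under a different person ID do not join.
#'
#' @param cohort tibble with `person_id`, `birth_episode_id`, `birth_date`.
#' @param admissions output of [build_admissions()]; the birth-admission
#'   flag is computed here if absent.
#' @return `cohort` with logical `readmitted`, plus `birth_admi_end` and
#'   `birth_los` (birth-admission length of stay in days).
#' @export
readmitted_in_infancy <- function(cohort, admissions) {
  if (!"is_birth_admission" %in% names(admissions)) {
    admissions <- flag_birth_admission(admissions, cohort)
  }
  birth_adm <- dplyr::inner_join(
    dplyr::inner_join(
      cohort[, c("person_id", "birth_episode_id", "birth_date")],
      attr(admissions, "episode_map"),
      by = c(birth_episode_id = "episode_id")
    ),
    admissions[, c("admission_id", "admi_end", "length_of_stay")],
    by = "admission_id"
  )
  later <- dplyr::inner_join(
    admissions[!admissions$is_birth_admission,
               c("person_id", "admi_start")],
    birth_adm[, c("person_id", "admi_end", "birth_date")],
    by = "person_id", relationship = "many-to-many"
  )
  later <- later[later$admi_start > later$admi_end &
                   later$admi_start <= later$birth_date + 364, ]
  cohort$readmitted <- cohort$person_id %in% later$person_id
  cohort$birth_admi_end <- birth_adm$admi_end[
    match(cohort$person_id, birth_adm$person_id)]
  cohort$birth_los <- birth_adm$length_of_stay[
    match(cohort$person_id, birth_adm$person_id)]
  cohort
}

#' Stratify a cohort by length of the birth admission
#'
#' Identifier quality was hypothesised to differ for babies whose birth
#' admission was long enough for identifiers to be updated in hospital;
#' the split is at 7 days.
#'
#' @param cohort output of [readmitted_in_infancy()] (has `birth_los`).
#' @return `cohort` with factor `birth_los_stratum`, levels
#'   `"short"` (< 7 days) and `"long"` (>= 7 days).
#' @export
stratify_by_birth_los <- function(cohort) {
  cohort$birth_los_stratum <- factor(
    ifelse(cohort$birth_los >= 7, "long", "short"),
    levels = c("short", "long")
  )
  cohort
}

#' Quarterly readmission series
#'
#' The proportion of babies with at least one readmission after birth,
#' by annual quarter of birth. Quarters between the first and last birth
#' with zero births are omitted with a warning.
#'
#' @param cohort output of [readmitted_in_infancy()].
#' @return tibble: `quarter` (label), `n_births`, `n_readmitted`,
#'   `proportion`.
#' @export
quarterly_readmission_series <- function(cohort) {
  qi <- date_quarter(cohort$birth_date)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(qi = qi, r = cohort$readmitted), .data$qi),
    n_births = dplyr::n(), n_readmitted = sum(.data$r), .groups = "drop"
  )
  if (nrow(out) > 0L) {
    full <- seq(min(out$qi), max(out$qi))
    gap <- setdiff(full, out$qi)
    if (length(gap) > 0L) {
      warning("omitting ", length(gap), " quarter(s) with zero births: ",
              paste(quarter_label(gap), collapse = ", "))
    }
  }
  tibble::tibble(
    quarter = quarter_label(out$qi),
    n_births = out$n_births,
    n_readmitted = out$n_readmitted,
    proportion = out$n_readmitted / out$n_births
  )
}
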