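#' Ruleset for identifying and cleaning birth episodes
#'
#' Broad union criteria identify candidate births: an episode qualifies
#' if its episode type is a birth type, or its admission method is a
#' birth method, or any diagnosis matches a live-born-infant code
#' (ICD-10 Z38 family). The exact national code lists sit in restricted
#' supplementary material, so every list and range here is a
#' configurable stand-in default, chosen to be clinically conventional.
#'
#' ICD-10 codes are matched on dot-free prefixes (`"Z38"` matches
#' `Z380`, `Z381`, ...), the 4-character form the source data uses.
#'
#' @param birth_epitypes episode-type codes marking a birth episode.
#' @param birth_admission_methods admission-method codes for babies born
#'   in (or on the way to) hospital.
#' @param birth_diagnosis_prefixes ICD-10 prefixes indicating a live-born
#'   infant.
#' @param multiple_birth_diag_prefixes Z38 members specific to twins and
#'   higher-order multiples.
#' @param stillbirth_birstat birth-status codes for stillbirth.
#' @param stillbirth_diag_prefixes ICD-10 prefixes indicating stillbirth.
#' @param birweit_range,gestat_range,matage_range plausible ranges
#'   (grams; completed weeks; years); values outside are set missing.
#' @param joint_grid data frame (`gestat_lo`, `gestat_hi`, `birweit_lo`,
#'   `birweit_hi`): the plausible birth-weight envelope per gestation
#'   band; a weight outside its band's envelope sets both values missing.
#' @param england_region_prefix region codes starting with this prefix
#'   count as resident in England (residency is judged on region, not
#'   postcode, because postcode is blanked for births in the extraction
#'   error window).
#' @param drop_implausible if `TRUE`, children with any out-of-range
#'   value are excluded (ledger reason `implausible_values`) instead of
#'   having the value set missing. Default keeps the child.
#' @return list of class `birth_ruleset`.
#' @export
birth_ruleset <- function(birth_epitypes = c(3L, 6L),
                          birth_admission_methods = c("82", "83"),
                          birth_diagnosis_prefixes = "Z38",
                          multiple_birth_diag_prefixes =
                            c("Z383", "Z384", "Z385", "Z386", "Z387", "Z388"),
                          stillbirth_birstat = c(2L, 3L, 4L),
                          stillbirth_diag_prefixes = c("Z371", "P95"),
                          birweit_range = c(200, 7000),
                          gestat_range = c(22, 44),
                          matage_range = c(10, 60),
                          joint_grid = data.frame(
                            gestat_lo = c(22, 28, 32, 37),
                            gestat_hi = c(27, 31, 36, 44),
                            birweit_lo = c(200, 300, 500, 1000),
                            birweit_hi = c(2500, 4000, 5500, 7000)
                          ),
                          england_region_prefix = "E",
                          drop_implausible = FALSE) {
  stopifnot(
    length(birth_epitypes) + length(birth_admission_methods) +
      length(birth_diagnosis_prefixes) > 0,
    birweit_range[1] < birweit_range[2],
    gestat_range[1] < gestat_range[2],
    matage_range[1] < matage_range[2]
  )
  structure(
    list(
      birth_epitypes = birth_epitypes,
      birth_admission_methods = as.character(birth_admission_methods),
      birth_diagnosis_prefixes = birth_diagnosis_prefixes,
      multiple_birth_diag_prefixes = multiple_birth_diag_prefixes,
      stillbirth_birstat = stillbirth_birstat,
      stillbirth_diag_prefixes = stillbirth_diag_prefixes,
      birweit_range = birweit_range, gestat_range = gestat_range,
      matage_range = matage_range, joint_grid = joint_grid,
      england_region_prefix = england_region_prefix,
      drop_implausible = isTRUE(drop_implausible)
    ),
    class = "birth_ruleset"
  )
}

diag_cols <- function(episodes) grep("^diag_", names(episodes), value = TRUE)

# TRUE where any diagnosis column starts with any of the prefixes
any_diag_matches <- function(episodes, prefixes) {
  hit <- rep(FALSE, nrow(episodes))
  if (length(prefixes) == 0L) return(hit)
  for (col in diag_cols(episodes)) {
    v <- episodes[[col]]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) next
    vv <- v[ok]
    m <- rep(FALSE, length(ok))
    for (p in prefixes) m <- m | startsWith(vv, p)
    hit[ok] <- hit[ok] | m
  }
  hit
}

#' Identify candidate birth episodes
#'
#' Union semantics: any single criterion suffices. Children with more
#' than one qualifying episode are deduplicated to the earliest (by
#' `epistart`, ties broken on `episode_id`).
#'
#' @param episodes an episode table.
#' @param ruleset a [birth_ruleset()].
#' @return the candidate birth rows, one per person, with attribute
#'   `n_not_birth` counting input rows not selected.
#' @export
identify_birth_episodes <- function(episodes, ruleset = birth_ruleset()) {
  need <- c("person_id", "episode_id", "epistart")
  if (!all(need %in% names(episodes))) {
    stop("episodes must contain columns: ", paste(need, collapse = ", "))
  }
  is_cand <- (("epitype" %in% names(episodes)) &
                episodes$epitype %in% ruleset$birth_epitypes) |
    (("admimeth" %in% names(episodes)) &
       episodes$admimeth %in% ruleset$birth_admission_methods) |
    any_diag_matches(episodes, ruleset$birth_diagnosis_prefixes)
  idx <- which(is_cand)
  ord <- idx[order(episodes$person_id[idx], episodes$epistart[idx],
                   episodes$episode_id[idx])]
  cand <- episodes[ord[!duplicated(episodes$person_id[ord])], ]
  attr(cand, "n_not_birth") <- nrow(episodes) - nrow(cand)
  cand
}

#' Apply cohort exclusions to candidate birth episodes
#'
#' Exclusions are applied in a fixed order -- multiple birth, then
#' stillbirth, then unfinished episode (and, when the ruleset drops
#' implausible values, implausible, then non-resident) -- and each child
#' is counted once, under the first firing reason, so the ledger always
#' reconciles exactly. Multiple births are excluded because same-sex
#' siblings sharing identifiers carry a high risk of false matches.
#'
#' @param candidates output of [identify_birth_episodes()].
#' @param ruleset a [birth_ruleset()].
#' @return `list(retained = tibble, ledger = tibble)`; the ledger has
#'   one row per reason (`not_birth`, `multiple_birth`, `stillbirth`,
#'   `unfinished_episode`, `implausible_values`, `non_resident`) plus
#'   `retained`, and its counts sum to the episode-table row count.
#' @export
apply_exclusions <- function(candidates, ruleset = birth_ruleset()) {
  n_not_birth <- attr(candidates, "n_not_birth")
  if (is.null(n_not_birth)) n_not_birth <- 0L
  multiple <- (("birordr" %in% names(candidates)) &
                 !is.na(candidates$birordr) & candidates$birordr > 1) |
    any_diag_matches(candidates, ruleset$multiple_birth_diag_prefixes)
  stillb <- (("birstat" %in% names(candidates)) &
               !is.na(candidates$birstat) &
               candidates$birstat %in% ruleset$stillbirth_birstat) |
    any_diag_matches(candidates, ruleset$stillbirth_diag_prefixes)
  unfinished <- if ("disdate" %in% names(candidates)) {
    is.na(candidates$disdate)
  } else {
    rep(FALSE, nrow(candidates))
  }
  why <- rep(NA_character_, nrow(candidates))
  why[unfinished] <- "unfinished_episode"
  why[stillb] <- "stillbirth"
  why[multiple] <- "multiple_birth"   # assigned last = highest priority
  retained <- candidates[is.na(why), ]
  ledger <- tibble::tibble(
    reason = c("not_birth", "multiple_birth", "stillbirth",
               "unfinished_episode"),
    n = c(n_not_birth, sum(why == "multiple_birth", na.rm = TRUE),
          sum(why == "stillbirth", na.rm = TRUE),
          sum(why == "unfinished_episode", na.rm = TRUE))
  )
  list(retained = retained, ledger = ledger)
}

#' Clean risk factors recorded at the birth admission
#'
#' Value-level cleaning: birth weight, gestational age and maternal age
#' outside their plausible range are set missing; a joint
#' weight-for-gestation check sets both weight and gestation missing
#' when the weight falls outside the envelope for its gestation band.
#' Children resident outside England are dropped (reason
#' `non_resident`); with `drop_implausible`, children with any
#' out-of-range value are dropped instead of cleaned. Cleaning is
#' idempotent.
#'
#' @param retained retained candidates from [apply_exclusions()].
#' @param ruleset a [birth_ruleset()].
#' @return `list(records = tibble, ledger = tibble)` where the ledger
#'   carries the `implausible_values` and `non_resident` counts.
#' @export
clean_risk_factors <- function(retained, ruleset = birth_ruleset()) {
  x <- retained
  out_of_range <- function(v, rng) !is.na(v) & (v < rng[1] | v > rng[2])
  bad_bw <- out_of_range(x$birweit, ruleset$birweit_range)
  bad_ga <- out_of_range(x$gestat, ruleset$gestat_range)
  bad_ma <- out_of_range(x$matage, ruleset$matage_range)
  joint_bad <- rep(FALSE, nrow(x))
  g <- ruleset$joint_grid
  for (i in seq_len(nrow(g))) {
    in_band <- !is.na(x$gestat) & !is.na(x$birweit) &
      x$gestat >= g$gestat_lo[i] & x$gestat <= g$gestat_hi[i]
    joint_bad <- joint_bad | (in_band & (x$birweit < g$birweit_lo[i] |
                                           x$birweit > g$birweit_hi[i]))
  }
  # the joint rule targets pairs that are individually plausible but
  # mutually implausible; individually bad values are already handled
  joint_bad <- joint_bad & !bad_bw & !bad_ga
  any_implausible <- bad_bw | bad_ga | bad_ma | joint_bad
  non_resident <- !is.na(x$region_code) &
    !startsWith(as.character(x$region_code), ruleset$england_region_prefix)
  n_implausible <- 0L
  if (ruleset$drop_implausible) {
    n_implausible <- sum(any_implausible & !non_resident)
    keep <- !any_implausible
  } else {
    x$birweit[bad_bw | joint_bad] <- NA
    x$gestat[bad_ga | joint_bad] <- NA
    x$matage[bad_ma] <- NA
    keep <- rep(TRUE, nrow(x))
  }
  n_non_resident <- sum(non_resident & keep)
  records <- x[keep & !non_resident, ]
  ledger <- tibble::tibble(
    reason = c("implausible_values", "non_resident"),
    n = c(n_implausible, n_non_resident)
  )
  list(records = records, ledger = ledger)
}

#' Complete ethnicity and IMD from longitudinal records
#'
#' A single admission often lacks ethnicity or deprivation score;
#' both are completed from the child's linked first-year hospital
#' records: ethnicity as the most frequently recorded non-missing value
#' (tie broken by earliest recording), IMD quintile as the earliest
#' non-missing recording in the first year of life.
#'
#' @param cohort tibble with `person_id`, `birth_date` and any existing
#'   `ethnos`, `imd_quintile` (overwritten by the resolved values).
#' @param episodes full episode table (records link by `person_id`).
#' @return `cohort` with resolved `ethnos` and `imd_quintile`.
#' @export
resolve_ethnicity_imd <- function(cohort, episodes) {
  eps <- dplyr::inner_join(
    episodes[, c("person_id", "epistart", "ethnos", "imd_quintile")],
    cohort[, c("person_id", "birth_date")],
    by = "person_id"
  )
  eps <- eps[eps$epistart >= eps$birth_date &
               eps$epistart <= eps$birth_date + 364, ]
  dt <- data.table::as.data.table(eps)
  data.table::setorder(dt, person_id, epistart)
  dt[, ord := .I]

  eth <- dt[!is.na(ethnos),
            list(n = .N, first_seen = min(ord)),
            by = c("person_id", "ethnos")]
  data.table::setorder(eth, person_id, -n, first_seen)
  eth_pick <- eth[!duplicated(person_id)]  # mode; ties -> earliest recorded

  imd <- dt[!is.na(imd_quintile)]
  imd_pick <- imd[!duplicated(person_id)]  # earliest non-missing in year 1

  cohort$ethnos <- eth_pick$ethnos[match(cohort$person_id, eth_pick$person_id)]
  cohort$imd_quintile <-
    imd_pick$imd_quintile[match(cohort$person_id, imd_pick$person_id)]
  cohort
}

#' Completeness of key risk factors by year of birth
#'
#' @param cohort a built cohort (one row per child, `birth_date` set).
#' @param factors columns to audit.
#' @return tibble: `birth_year`, `factor`, `n_births`, `n_complete`,
#'   `pct_complete`; empty for an empty cohort.
#' @export
completeness_by_year <- function(cohort,
                                 factors = c("birweit", "gestat", "matage",
                                             "sex", "ethnos", "imd_quintile")) {
  factors <- intersect(factors, names(cohort))
  if (nrow(cohort) == 0L) {
    return(tibble::tibble(
      birth_year = integer(), factor = character(), n_births = integer(),
      n_complete = integer(), pct_complete = numeric()
    ))
  }
  yr <- as.integer(format(cohort$birth_date, "%Y"))
  wide <- dplyr::mutate(cohort[, factors],
                        dplyr::across(dplyr::everything(), as.character))
  wide$birth_year <- yr
  long <- tidyr::pivot_longer(
    wide, -dplyr::all_of("birth_year"),
    names_to = "factor", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$birth_year, .data$factor),
    n_births = dplyr::n(), n_complete = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  out$pct_complete <- 100 * out$n_complete / out$n_births
  out
}

#' Build the cleaned singleton live-birth cohort
#'
#' Runs identification, exclusion, cleaning and longitudinal completion
#' in order and assembles the exclusion ledger, which reconciles exactly
#' against the input row count.
#'
#' @param episodes an episode table.
#' @param ruleset a [birth_ruleset()].
#' @return `list(cohort, ledger)`. The cohort has one row per child:
#'   `person_id`, `birth_episode_id`, `birth_date`, `birth_quarter`,
#'   risk factors, `region_code`.
#' @export
build_cohort <- function(episodes, ruleset = birth_ruleset()) {
  cand <- identify_birth_episodes(episodes, ruleset)
  exc <- apply_exclusions(cand, ruleset)
  cln <- clean_risk_factors(exc$retained, ruleset)
  x <- cln$records
  cohort <- tibble::tibble(
    person_id = x$person_id,
    birth_episode_id = x$episode_id,
    birth_date = x$epistart,
    birth_quarter = quarter_label(date_quarter(x$epistart)),
    sex = x$sex, birweit = x$birweit, gestat = x$gestat, matage = x$matage,
    ethnos = x$ethnos, imd_quintile = x$imd_quintile,
    region_code = x$region_code
  )
  cohort <- resolve_ethnicity_imd(cohort, episodes)
  ledger <- dplyr::bind_rows(
    exc$ledger, cln$ledger,
    tibble::tibble(reason = "retained", n = nrow(cohort))
  )
  stopifnot(sum(ledger$n) == nrow(episodes))
  list(cohort = cohort, ledger = ledger)
}
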