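#' Scenario configuration for the synthetic HES/ONS generator
#'
#' Describes a birth-cohort simulation: how many babies are born per
#' calendar quarter, their true readmission and death processes, and --
#' the point of the exercise -- how often the identifiers that drive
#' record linkage fail, by era of the three data-collection change
#' points (NN4B at Q4 2002, RON at Q3 2009, the postcode-extraction fix
#' at Q2 2013).
#'
#' Era-dependent parameters (`p_person_id_continuity`, `p_ons_link`, and
#' per-era missingness) are length-4 vectors indexed by era 0..3 (a
#' scalar is recycled). `p_person_id_continuity` is the probability that
#' a child's post-birth hospital records carry the same person ID as the
#' birth episode; on failure all of the child's post-birth records share
#' one fresh ID, mirroring how a pseudonymised identifier is regenerated
#' when NHS number/postcode change between records. `p_ons_link` is the
#' probability that the child's death registration carries a usable
#' person link; an in-hospital death still leaves a discharge method of
#' "died" in the hospital record even when that link fails.
#'
#' @param start_quarter,end_quarter quarter labels bounding the birth
#'   window (inclusive).
#' @param births_per_quarter non-negative integer.
#' @param readmission_knots data frame with columns `quarter`, `prob`:
#'   the true probability of at least one readmission in infancy,
#'   piecewise-linear in quarter index between knots (constant outside).
#' @param infant_death_prob probability of death at age 0--364 days.
#' @param neonatal_fraction probability a death falls at 0--27 days
#'   (ages drawn uniformly within the 0--27 / 28--364 band).
#' @param p_death_in_hospital probability a death occurs under hospital
#'   care (and so is visible through the discharge method).
#' @param p_person_id_continuity,p_ons_link per-era probabilities, see above.
#' @param p_missing named list of per-field missingness probabilities for
#'   the baby-tail fields (`birweit`, `gestat`, `matage`, `sex`,
#'   `ethnos`, `imd_quintile`); each entry scalar or per-era length 4.
#' @param postcode_error_window `Date` vector of length 2; birth episodes
#'   starting inside it have postcode (and postcode-derived IMD) blanked.
#' @param change_points three increasing quarter labels.
#' @param p_long_birth_admission probability of a long (>= 7 day) birth
#'   admission; short stays are 0--6 days, long stays 7--30.
#' @param p_non_england probability a baby is resident outside England.
#' @param empty_cause_ages,p_empty_cause ages at death (days) whose
#'   linked death registrations lose their cause codes, and with what
#'   probability -- emulates the extraction defect concentrated at ages
#'   28--30 days.
#' @param seed integer seed driving the single PRNG stream.
#' @return a list of class `hes_scenario_config`.
#' @export
scenario_config <- function(start_quarter = "1998Q1",
                            end_quarter = "2015Q4",
                            births_per_quarter = 1000L,
                            readmission_knots = data.frame(
                              quarter = c("1998Q1", "2015Q4"),
                              prob = c(0.20, 0.20)
                            ),
                            infant_death_prob = 0.0042,
                            neonatal_fraction = 0.7,
                            p_death_in_hospital = 0.9,
                            p_person_id_continuity = c(0.70, 1, 1, 1),
                            p_ons_link = c(0.67, 0.90, 0.95, 0.95),
                            p_missing = list(
                              birweit = 0.34, gestat = 0.37, matage = 0.38,
                              sex = 0.005, ethnos = 0.26, imd_quintile = 0.10
                            ),
                            postcode_error_window = as.Date(c("1900-01-01", "2013-03-31")),
                            change_points = c("2002Q4", "2009Q3", "2013Q2"),
                            p_long_birth_admission = 0.10,
                            p_non_england = 0.005,
                            empty_cause_ages = 28:30,
                            p_empty_cause = 0.75,
                            seed = 2020L) {
  cfg <- list(
    start_quarter = start_quarter, end_quarter = end_quarter,
    births_per_quarter = as.integer(births_per_quarter),
    readmission_knots = readmission_knots,
    infant_death_prob = infant_death_prob,
    neonatal_fraction = neonatal_fraction,
    p_death_in_hospital = p_death_in_hospital,
    p_person_id_continuity = rep_len(p_person_id_continuity, 4L),
    p_ons_link = rep_len(p_ons_link, 4L),
    p_missing = lapply(p_missing, rep_len, 4L),
    postcode_error_window = as.Date(postcode_error_window),
    change_points = change_points,
    p_long_birth_admission = p_long_birth_admission,
    p_non_england = p_non_england,
    empty_cause_ages = as.integer(empty_cause_ages),
    p_empty_cause = p_empty_cause,
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "hes_scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (quarter_index(cfg$end_quarter) < quarter_index(cfg$start_quarter)) {
    stop("end_quarter precedes start_quarter")
  }
  if (cfg$births_per_quarter < 0L) stop("births_per_quarter must be >= 0")
  probs <- c(
    cfg$readmission_knots$prob, cfg$infant_death_prob, cfg$neonatal_fraction,
    cfg$p_death_in_hospital, cfg$p_person_id_continuity, cfg$p_ons_link,
    unlist(cfg$p_missing), cfg$p_long_birth_admission, cfg$p_non_england,
    cfg$p_empty_cause
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  cp <- quarter_index(cfg$change_points)
  if (length(cp) != 3L || is.unsorted(cp, strictly = TRUE)) {
    stop("change_points must be three strictly increasing quarters")
  }
  invisible(cfg)
}

#' Read a scenario configuration from YAML
#'
#' Scalar fields map directly onto [scenario_config()] arguments;
#' `readmission_knots` is a mapping of quarter label to probability and
#' `postcode_error_window` a two-element list of ISO dates.
#'
#' @param path path to a YAML file.
#' @return a `hes_scenario_config`.
#' @export
scenario_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$readmission_knots)) {
    y$readmission_knots <- data.frame(
      quarter = names(y$readmission_knots),
      prob = unname(unlist(y$readmission_knots))
    )
  }
  if (!is.null(y$postcode_error_window)) {
    y$postcode_error_window <- as.Date(unlist(y$postcode_error_window))
  }
  if (!is.null(y$p_missing)) y$p_missing <- lapply(y$p_missing, unlist)
  do.call(scenario_config, y)
}

# interpolate the true readmission probability at given quarter indices
readmission_prob_at <- function(cfg, qidx) {
  kq <- quarter_index(cfg$readmission_knots$quarter)
  kp <- cfg$readmission_knots$prob
  if (length(kq) == 1L) return(rep(kp, length(qidx)))
  stats::approx(kq, kp, xout = qidx, rule = 2)$y
}

empty_episode_table <- function() {
  base <- tibble::tibble(
    person_id = character(), episode_id = character(),
    epistart = as.Date(character()), epiend = as.Date(character()),
    epitype = integer(), admimeth = character(),
    admidate = as.Date(character()), disdate = as.Date(character()),
    dismeth = character()
  )
  for (i in 1:20) base[[sprintf("diag_%02d", i)]] <- character()
  dplyr::bind_cols(base, tibble::tibble(
    birweit = integer(), gestat = integer(), matage = integer(),
    birordr = integer(), birstat = integer(), sex = integer(),
    ethnos = character(), postcode_district = character(),
    imd_quintile = integer(), region_code = character()
  ))
}

empty_mortality_table <- function() {
  base <- tibble::tibble(person_id = character(), dod = as.Date(character()))
  for (i in 1:15) base[[sprintf("cause_%02d", i)]] <- character()
  base$match_rank <- integer()
  base
}

#' Generate a synthetic HES-like episode table and ONS-like mortality table
#'
#' One birth episode per child; at most one readmission; deaths split
#' into neonatal / post-neonatal bands; all driven by a single seeded
#' PRNG stream. Per child the stream is consumed in a fixed order
#' regardless of outcomes, so two runs sharing a seed (and cohort size)
#' are coupled draw-for-draw -- lowering one probability flips only the
#' children whose draw sits between the old and new value, which makes
#' monotonicity checks on paired runs exact in expectation.
#'
#' Mechanisms reproduced: when person-ID continuity fails, every
#' post-birth record of that child (readmission and any terminal death
#' admission) carries one fresh person ID and so cannot be linked back
#' to the birth; when the ONS link fails, the death registration's
#' person ID is null while an in-hospital death still shows discharge
#' method "died"; birth episodes starting inside the postcode error
#' window have postcode and IMD blanked.
#'
#' @param config a [scenario_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `hes_scenario` with elements `episodes`,
#'   `deaths`, `truth` (one row per child, including its birth and
#'   post-birth person IDs), `expected_series` (the generator-implied
#'   observed readmission proportion by quarter) and `implied_shifts_pp`
#'   (the level shift, in percentage points, that the continuity change
#'   at each change point induces in the observed series), plus `config`.
#' @export
generate_scenario <- function(config, seed = config$seed) {
  validate_scenario_config(config)
  cp <- quarter_index(config$change_points)
  q0 <- quarter_index(config$start_quarter)
  q1 <- quarter_index(config$end_quarter)
  quarters <- seq(q0, q1)
  bpq <- config$births_per_quarter
  n <- bpq * length(quarters)

  p_re_q <- readmission_prob_at(config, quarters)
  era_q <- findInterval(quarters, cp)
  expected_series <- tibble::tibble(
    quarter = quarter_label(quarters),
    expected_proportion = p_re_q * config$p_person_id_continuity[era_q + 1L]
  )
  shifts <- vapply(1:3, function(k) {
    p_at <- readmission_prob_at(config, cp[k])
    100 * p_at * (config$p_person_id_continuity[k + 1L] -
                    config$p_person_id_continuity[k])
  }, numeric(1))

  if (n == 0L) {
    return(structure(
      list(
        episodes = empty_episode_table(), deaths = empty_mortality_table(),
        truth = empty_truth_table(), expected_series = expected_series,
        implied_shifts_pp = shifts, config = config
      ),
      class = "hes_scenario"
    ))
  }

  set.seed(seed)
  # one uniform (or normal) per child per decision, consumed in this fixed
  # order; do not reorder without revisiting the paired-run coupling
  u <- list(
    jitter = stats::runif(n), los_long = stats::runif(n), los = stats::runif(n),
    readmit = stats::runif(n), readmit_age = stats::runif(n),
    readmit_dur = stats::runif(n),
    death = stats::runif(n), death_band = stats::runif(n),
    death_age = stats::runif(n), death_hosp = stats::runif(n),
    continuity = stats::runif(n), ons = stats::runif(n),
    empty_cause = stats::runif(n), non_england = stats::runif(n),
    z_birweit = stats::rnorm(n), z_gestat = stats::rnorm(n),
    z_matage = stats::rnorm(n), sex = stats::runif(n),
    ethnos = stats::runif(n), region = stats::runif(n),
    postcode = stats::runif(n), imd = stats::runif(n),
    miss = lapply(stats::setNames(nm = names(config$p_missing)),
                  function(f) stats::runif(n))
  )

  qidx <- rep(quarters, each = bpq)
  era <- findInterval(qidx, cp)
  birth_date <- quarter_midpoint(qidx) + (floor(u$jitter * 81) - 40L)
  los <- ifelse(u$los_long < config$p_long_birth_admission,
                7L + floor(u$los * 24), floor(u$los * 7))

  true_death <- u$death < config$infant_death_prob
  neonatal <- u$death_band < config$neonatal_fraction
  death_age <- ifelse(neonatal, floor(u$death_age * 28),
                      28L + floor(u$death_age * 337))
  death_in_hosp <- true_death & u$death_hosp < config$p_death_in_hospital
  death_date <- birth_date + death_age

  readmit_drawn <- u$readmit < readmission_prob_at(config, qidx)
  # at least 2 days after birth discharge: a next-day admission is a
  # transfer and would merge into the birth admission, not a readmission
  readmit_age <- los + 2L + floor(u$readmit_age * pmax(363L - los, 1L))
  # a readmission is only realised if the child lives to see it
  readmit <- readmit_drawn & (!true_death | readmit_age < death_age)
  readmit_dur <- floor(u$readmit_dur * 4)

  continuity_ok <- u$continuity < config$p_person_id_continuity[era + 1L]
  ons_ok <- true_death & u$ons < config$p_ons_link[era + 1L]

  birth_id <- sprintf("B%07d", seq_len(n))
  post_id <- ifelse(continuity_ok, birth_id, sprintf("A%07d", seq_len(n)))

  died_in_birth_adm <- death_in_hosp & death_age <= los
  birth_end <- as.Date(ifelse(died_in_birth_adm, death_date, birth_date + los),
                       origin = "1970-01-01")

  miss_p <- function(field) config$p_missing[[field]][era + 1L]
  in_window <- birth_date >= config$postcode_error_window[1] &
    birth_date <= config$postcode_error_window[2]

  birweit <- as.integer(pmin(pmax(round(3400 + 600 * u$z_birweit), 250), 6500))
  gestat <- as.integer(pmin(pmax(round(39.5 + 2 * u$z_gestat), 23), 43))
  matage <- as.integer(pmin(pmax(round(29.5 + 6 * u$z_matage), 13), 50))
  sex <- ifelse(u$sex < 0.512, 1L, 2L)
  ethnos <- c("A", "B", "C", "H", "J", "M", "N", "P", "R")[
    1L + floor(u$ethnos * 9)]
  region <- ifelse(u$non_england < config$p_non_england, "W99999999",
                   sprintf("E120000%02d", 1L + floor(u$region * 9)))
  postcode <- sprintf("ZZ%02d", floor(u$postcode * 99))
  imd <- 1L + as.integer(floor(u$imd * 5))

  na_if_u <- function(x, uu, p) replace(x, uu < p, NA)

  birth_eps <- tibble::tibble(
    person_id = birth_id,
    episode_id = sprintf("E%08d", seq_len(n)),
    epistart = birth_date, epiend = birth_end,
    epitype = 3L, admimeth = "82",
    admidate = birth_date, disdate = birth_end,
    dismeth = ifelse(died_in_birth_adm, "4", "1"),
    diag_01 = "Z380",
    birweit = na_if_u(birweit, u$miss$birweit, miss_p("birweit")),
    gestat = na_if_u(gestat, u$miss$gestat, miss_p("gestat")),
    matage = na_if_u(matage, u$miss$matage, miss_p("matage")),
    birordr = 1L, birstat = 1L,
    sex = na_if_u(sex, u$miss$sex, miss_p("sex")),
    ethnos = na_if_u(ethnos, u$miss$ethnos, miss_p("ethnos")),
    postcode_district = replace(postcode, in_window, NA),
    imd_quintile = na_if_u(replace(imd, in_window, NA_integer_),
                           u$miss$imd_quintile, miss_p("imd_quintile")),
    region_code = region
  )

  readm_diag <- c("J219", "A099", "R509", "J459", "K529", "N390")
  readm_eps <- tibble::tibble(
    person_id = post_id[readmit],
    episode_id = sprintf("E1%07d", which(readmit)),
    epistart = birth_date[readmit] + readmit_age[readmit],
    epiend = birth_date[readmit] + readmit_age[readmit] + readmit_dur[readmit],
    epitype = 1L, admimeth = "21",
    admidate = birth_date[readmit] + readmit_age[readmit],
    disdate = birth_date[readmit] + readmit_age[readmit] + readmit_dur[readmit],
    dismeth = "1",
    diag_01 = readm_diag[1L + floor(u$ethnos[readmit] * 6)],
    birweit = NA_integer_, gestat = NA_integer_, matage = NA_integer_,
    birordr = NA_integer_, birstat = NA_integer_, sex = sex[readmit],
    ethnos = ethnos[readmit], postcode_district = postcode[readmit],
    imd_quintile = na_if_u(imd[readmit], u$miss$imd_quintile[readmit],
                           miss_p("imd_quintile")[readmit]),
    region_code = region[readmit]
  )

  term <- death_in_hosp & death_age > los
  term_eps <- tibble::tibble(
    person_id = post_id[term],
    episode_id = sprintf("E2%07d", which(term)),
    epistart = pmax(death_date[term] - 2L, birth_date[term]),
    epiend = death_date[term],
    epitype = 1L, admimeth = "21",
    admidate = pmax(death_date[term] - 2L, birth_date[term]),
    disdate = death_date[term], dismeth = "4",
    diag_01 = "P285",
    birweit = NA_integer_, gestat = NA_integer_, matage = NA_integer_,
    birordr = NA_integer_, birstat = NA_integer_, sex = sex[term],
    ethnos = ethnos[term], postcode_district = postcode[term],
    imd_quintile = imd[term], region_code = region[term]
  )

  episodes <- dplyr::bind_rows(birth_eps, readm_eps, term_eps)
  for (i in 2:20) episodes[[sprintf("diag_%02d", i)]] <- NA_character_
  episodes <- episodes[order(episodes$epistart, episodes$episode_id),
                       names(empty_episode_table())]

  cause_pool <- c("P220", "P072", "Q249", "R95X", "J189", "G809")
  dd <- which(true_death)
  empty_cause <- death_age[dd] %in% config$empty_cause_ages &
    u$empty_cause[dd] < config$p_empty_cause
  deaths <- tibble::tibble(
    person_id = ifelse(ons_ok[dd], birth_id[dd], NA_character_),
    dod = death_date[dd],
    cause_01 = ifelse(empty_cause, NA_character_,
                      cause_pool[1L + floor(u$death_band[dd] * 6)]),
    match_rank = ifelse(ons_ok[dd], 1L, NA_integer_)
  )
  for (i in 2:15) deaths[[sprintf("cause_%02d", i)]] <- NA_character_
  deaths <- deaths[, names(empty_mortality_table())]
  deaths <- dplyr::arrange(deaths, .data$dod, .data$person_id)

  truth <- tibble::tibble(
    child_id = sprintf("C%07d", seq_len(n)),
    birth_person_id = birth_id, post_birth_person_id = post_id,
    birth_quarter = quarter_label(qidx), era = era,
    birth_date = birth_date, birth_los = los,
    true_readmission = readmit, readmission_age = ifelse(readmit, readmit_age, NA),
    true_death = true_death,
    death_age = ifelse(true_death, death_age, NA),
    death_in_hospital = death_in_hosp,
    continuity_ok = continuity_ok, ons_link_ok = ons_ok
  )

  structure(
    list(episodes = episodes, deaths = deaths, truth = truth,
         expected_series = expected_series, implied_shifts_pp = shifts,
         config = config),
    class = "hes_scenario"
  )
}

empty_truth_table <- function() {
  tibble::tibble(
    child_id = character(), birth_person_id = character(),
    post_birth_person_id = character(), birth_quarter = character(),
    era = integer(), birth_date = as.Date(character()), birth_los = integer(),
    true_readmission = logical(), readmission_age = numeric(),
    true_death = logical(), death_age = numeric(),
    death_in_hospital = logical(), continuity_ok = logical(),
    ons_link_ok = logical()
  )
}

#' Write a scenario's tables as delimited text
#'
#' Writes `episodes.csv`, `deaths.csv` and `truth.csv` (comma-separated,
#' UTF-8, ISO-8601 dates). Output is byte-identical for identical
#' config + seed.
#'
#' @param scenario a `hes_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "hes_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("episodes", "deaths", "truth")) {
    data.table::fwrite(scenario[[nm]], file.path(dir, paste0(nm, ".csv")),
                       dateTimeAs = "ISO", na = "")
  }
  invisible(dir)
}

#' Read an episode or mortality table written by [write_scenario()]
#'
#' @param path a CSV path.
#' @return a tibble with `Date` date columns and character diagnosis/cause
#'   columns.
#' @export
read_hes_table <- function(path) {
  dt <- data.table::fread(path, na.strings = "", colClasses = list(
    character = grep("^(diag|cause)_", names(data.table::fread(path, nrows = 0)),
                     value = TRUE)
  ))
  for (col in intersect(c("epistart", "epiend", "admidate", "disdate", "dod"),
                        names(dt))) {
    dt[[col]] <- as.Date(dt[[col]])
  }
  tibble::as_tibble(dt)
}
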