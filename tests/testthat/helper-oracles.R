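# Brute-force interval merging: repeatedly merge any pair of intervals
# whose gap is <= 1 day until no pair merges (transitive closure of the
# "within 1 day" relation). Independent of the package's single-pass
# implementation; O(n^3), for small fixtures only.
bf_merge_intervals <- function(start, end) {
  ints <- Map(c, as.numeric(start), as.numeric(end))
  repeat {
    merged <- FALSE
    for (i in seq_along(ints)) {
      if (merged) break
      for (j in seq_along(ints)) {
        if (i >= j) next
        a <- ints[[i]]; b <- ints[[j]]
        gap <- max(a[1], b[1]) - min(a[2], b[2])
        if (gap <= 1) {
          ints[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
          ints[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  m <- do.call(rbind, ints)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# minimal episode-table fixture; defaults give a plain finished episode
ep <- function(person_id, episode_id, start, end = start,
               epitype = 1L, admimeth = "21", dismeth = "1",
               diag_01 = NA_character_, birordr = NA_integer_,
               birstat = NA_integer_, birweit = NA_integer_,
               gestat = NA_integer_, matage = NA_integer_,
               sex = NA_integer_, ethnos = NA_character_,
               imd_quintile = NA_integer_, region_code = "E12000003",
               disdate = end) {
  tibble::tibble(
    person_id = person_id, episode_id = episode_id,
    epistart = as.Date(start), epiend = as.Date(end),
    epitype = epitype, admimeth = admimeth,
    admidate = as.Date(start), disdate = as.Date(disdate),
    dismeth = dismeth, diag_01 = diag_01,
    birweit = birweit, gestat = gestat, matage = matage,
    birordr = birordr, birstat = birstat, sex = sex, ethnos = ethnos,
    postcode_district = NA_character_, imd_quintile = imd_quintile,
    region_code = region_code
  )
}

# a birth episode fixture
birth_ep <- function(person_id, episode_id, start, end = start,
                     diag_01 = "Z380", birordr = 1L, birstat = 1L, ...) {
  ep(person_id, episode_id, start, end,
     epitype = 3L, admimeth = "82", diag_01 = diag_01,
     birordr = birordr, birstat = birstat, ...)
}

# random per-person episode set for merge-oracle checks
random_episode_set <- function(n, person = "P1") {
  s <- sample.int(40, n, replace = TRUE)
  len <- sample.int(6, n, replace = TRUE) - 1L
  ep(person, sprintf("%s-E%02d", person, seq_len(n)),
     as.Date("2000-01-01") + s, as.Date("2000-01-01") + s + len)
}

# light pipeline: scenario -> cohort -> admissions -> readmission series
observed_series <- function(config) {
  scn <- generate_scenario(config)
  b <- build_cohort(scn$episodes)
  adm <- flag_birth_admission(build_admissions(scn$episodes), b$cohort)
  co <- readmitted_in_infancy(b$cohort, adm)
  list(scenario = scn, cohort = co, admissions = adm,
       series = quarterly_readmission_series(co))
}
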