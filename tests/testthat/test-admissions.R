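d <- function(x) as.Date("2010-01-01") + x

test_that("episodes within 1 day merge; 2-day gaps split", {
  # gap of exactly 1 day: one admission
  eps <- dplyr::bind_rows(
    ep("P1", "E1", d(0), d(3)),
    ep("P1", "E2", d(4), d(6))
  )
  adm <- build_admissions(eps)
  expect_identical(nrow(adm), 1L)
  expect_identical(adm$admi_start, d(0))
  expect_identical(adm$admi_end, d(6))
  expect_identical(adm$n_episodes, 2L)

  # gap of 2 days: two admissions
  adm2 <- build_admissions(dplyr::bind_rows(
    ep("P1", "E1", d(0), d(3)),
    ep("P1", "E2", d(5), d(6))
  ))
  expect_identical(nrow(adm2), 2L)

  # single episode: admission equals it
  adm3 <- build_admissions(ep("P1", "E1", d(2), d(4)))
  expect_identical(adm3$admi_start, d(2))
  expect_identical(adm3$admi_end, d(4))
  expect_identical(adm3$length_of_stay, 2)
})

test_that("invalid and unfinished episodes are handled", {
  eps <- dplyr::bind_rows(
    ep("P1", "E1", d(0), d(3)),
    ep("P1", "Ebad", d(10), d(8)),          # end before start: rejected
    ep("P2", "E2", d(0), NA)                # unfinished: end = start
  )
  expect_message(adm <- build_admissions(eps), "rejected")
  expect_identical(nrow(adm), 2L)
  expect_identical(attr(adm, "rejected")$episode_id, "Ebad")
  p2 <- adm[adm$person_id == "P2", ]
  expect_identical(p2$admi_end, d(0))
})

test_that("merging equals the brute-force transitive-closure oracle", {
  set.seed(404)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    eps <- random_episode_set(n)
    adm <- build_admissions(eps)
    got <- cbind(as.numeric(adm$admi_start), as.numeric(adm$admi_end))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- bf_merge_intervals(eps$epistart, eps$epiend)
    expect_identical(got, unname(want))
  }
})

test_that("every episode belongs to exactly one admission", {
  cfg <- scenario_config(start_quarter = "2005Q1", end_quarter = "2005Q4",
                         births_per_quarter = 300, seed = 8)
  eps <- generate_scenario(cfg)$episodes
  adm <- build_admissions(eps)
  map <- attr(adm, "episode_map")
  expect_setequal(map$episode_id, eps$episode_id)
  expect_false(any(duplicated(map$episode_id)))
  expect_setequal(map$admission_id, adm$admission_id)
  # and admission episode counts agree with the map
  expect_identical(sum(adm$n_episodes), nrow(eps))
})

test_that("the birth admission absorbs transfers within 1 day of birth", {
  cohort <- tibble::tibble(person_id = "P1", birth_episode_id = "E1",
                           birth_date = d(0))
  eps <- dplyr::bind_rows(
    birth_ep("P1", "E1", d(0), d(2)),
    ep("P1", "E2", d(3), d(9)),    # transfer, merges into birth admission
    ep("P1", "E3", d(40), d(41))   # later admission
  )
  adm <- flag_birth_admission(build_admissions(eps), cohort)
  birth <- adm[adm$is_birth_admission, ]
  expect_identical(nrow(birth), 1L)
  expect_identical(birth$admi_end, d(9))
  expect_false(adm$is_birth_admission[adm$admi_start == d(40)])
  # birth episode missing from the admission set is a pipeline error
  expect_error(
    flag_birth_admission(build_admissions(eps),
                         tibble::tibble(person_id = "P1",
                                        birth_episode_id = "EX",
                                        birth_date = d(0))),
    "absent"
  )
})

test_that("readmission requires a post-discharge admission inside days 0-364", {
  mk <- function(extra) {
    cohort <- tibble::tibble(person_id = "P1", birth_episode_id = "E1",
                             birth_date = d(0))
    eps <- dplyr::bind_rows(birth_ep("P1", "E1", d(0), d(2)), extra)
    adm <- flag_birth_admission(build_admissions(eps), cohort)
    readmitted_in_infancy(cohort, adm)$readmitted
  }
  expect_true(mk(ep("P1", "E2", d(100), d(101))))
  expect_false(mk(NULL))                                 # birth only
  expect_true(mk(ep("P1", "E2", d(364), d(370))))        # day 364 counts
  expect_false(mk(ep("P1", "E2", d(365), d(366))))       # day 365 does not
  expect_false(mk(ep("P1", "E2", d(3), d(5))))           # merges into birth
})

test_that("adding an episode never turns readmitted off", {
  set.seed(77)
  for (i in 1:50) {
    cohort <- tibble::tibble(person_id = "P1", birth_episode_id = "E0",
                             birth_date = d(0))
    base <- dplyr::bind_rows(
      birth_ep("P1", "E0", d(0), d(2)),
      random_episode_set(sample(1:6, 1))
    )
    extra <- random_episode_set(1)
    extra$episode_id <- "EXTRA"
    r1 <- readmitted_in_infancy(
      cohort, flag_birth_admission(build_admissions(base), cohort)
    )$readmitted
    r2 <- readmitted_in_infancy(
      cohort,
      flag_birth_admission(build_admissions(dplyr::bind_rows(base, extra)),
                           cohort)
    )$readmitted
    expect_true(r2 >= r1)
  }
})

test_that("birth length of stay stratifies at 7 days", {
  cohort <- tibble::tibble(
    person_id = c("P1", "P2", "P3"),
    birth_episode_id = c("E1", "E2", "E3"),
    birth_date = d(0)
  )
  eps <- dplyr::bind_rows(
    birth_ep("P1", "E1", d(0), d(7)),   # LOS 7: long
    birth_ep("P2", "E2", d(0), d(6)),   # LOS 6: short
    birth_ep("P3", "E3", d(0), d(0))    # same-day: short
  )
  co <- stratify_by_birth_los(readmitted_in_infancy(
    cohort, flag_birth_admission(build_admissions(eps), cohort)
  ))
  expect_identical(as.character(co$birth_los_stratum),
                   c("long", "short", "short"))
})

test_that("the quarterly series is the exact ratio and omits empty quarters", {
  cohort <- tibble::tibble(
    person_id = sprintf("P%04d", 1:1000),
    birth_date = as.Date("2005-02-15"),
    readmitted = rep(c(TRUE, FALSE), c(195, 805))
  )
  s <- quarterly_readmission_series(cohort)
  expect_identical(s$quarter, "2005Q1")
  expect_identical(s$proportion, 0.195)
  # a quarter with no births inside the span is omitted, with a warning
  cohort2 <- dplyr::bind_rows(
    cohort,
    tibble::tibble(person_id = "X", birth_date = as.Date("2005-08-15"),
                   readmitted = FALSE)
  )
  expect_warning(s2 <- quarterly_readmission_series(cohort2), "zero births")
  expect_identical(s2$quarter, c("2005Q1", "2005Q3"))
})
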