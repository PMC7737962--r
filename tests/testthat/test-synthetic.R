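test_that("truth bookkeeping is exact and rows trace to truth records", {
  cfg <- scenario_config(start_quarter = "2001Q1", end_quarter = "2003Q4",
                         births_per_quarter = 50, seed = 11)
  scn <- generate_scenario(cfg)
  expect_identical(nrow(scn$truth), 50L * 12L)
  # every episode's person ID belongs to exactly one truth record
  ids <- c(scn$truth$birth_person_id, scn$truth$post_birth_person_id)
  expect_true(all(scn$episodes$person_id %in% ids))
  expect_false(any(duplicated(scn$truth$birth_person_id)))
  linked_deaths <- scn$deaths$person_id[!is.na(scn$deaths$person_id)]
  expect_true(all(linked_deaths %in% scn$truth$birth_person_id))
  # one birth episode per child
  expect_identical(sum(scn$episodes$epitype == 3L), nrow(scn$truth))
})

test_that("a zero-birth scenario yields empty tables with full schemas", {
  cfg <- scenario_config(births_per_quarter = 0)
  scn <- generate_scenario(cfg)
  expect_identical(nrow(scn$episodes), 0L)
  expect_identical(nrow(scn$deaths), 0L)
  expect_identical(nrow(scn$truth), 0L)
  expect_true(all(c("person_id", "epistart", "diag_20", "region_code") %in%
                    names(scn$episodes)))
  expect_true(all(c("person_id", "dod", "cause_15", "match_rank") %in%
                    names(scn$deaths)))
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(infant_death_prob = 1.2), "probability")
  expect_error(scenario_config(p_ons_link = c(-0.1, 1, 1, 1)), "probability")
  expect_error(scenario_config(start_quarter = "2005Q1",
                               end_quarter = "2004Q4"), "precedes")
  expect_error(scenario_config(change_points = c("2009Q3", "2002Q4", "2013Q2")),
               "increasing")
})

test_that("with perfect continuity the observed readmission proportion matches truth", {
  cfg <- scenario_config(start_quarter = "2004Q1", end_quarter = "2009Q4",
                         births_per_quarter = 500,
                         p_person_id_continuity = 1, seed = 7)
  res <- observed_series(cfg)
  p <- mean(res$cohort$readmitted)
  # binomial Monte-Carlo tolerance around the generating probability
  n <- nrow(res$cohort)
  expect_lt(abs(p - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # with IDs never changing, every true readmission is observed (terminal
  # death admissions may add a few observed-only readmissions on top)
  tr <- res$scenario$truth
  true_ids <- tr$birth_person_id[tr$true_readmission &
                                   tr$birth_person_id %in% res$cohort$person_id]
  obs_ids <- res$cohort$person_id[res$cohort$readmitted]
  expect_true(all(true_ids %in% obs_ids))
  extra <- setdiff(obs_ids, true_ids)
  died_ids <- tr$birth_person_id[tr$true_death & tr$death_in_hospital]
  expect_true(all(extra %in% died_ids))
})

test_that("with no register linkage every detected death is discharge-method-only", {
  cfg <- scenario_config(start_quarter = "2006Q1", end_quarter = "2008Q4",
                         births_per_quarter = 800,
                         p_person_id_continuity = 1, p_ons_link = 0,
                         p_death_in_hospital = 1, infant_death_prob = 0.02,
                         seed = 3)
  res <- observed_series(cfg)
  out <- detect_infant_deaths(res$cohort, res$scenario$deaths, res$admissions)
  expect_gt(nrow(out), 0)
  expect_true(all(out$source == "hes_discharge_only"))
  expect_true(all(lengths(out$causes) == 0L))
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- scenario_config(start_quarter = "2002Q1", end_quarter = "2003Q4",
                         births_per_quarter = 120, seed = 42)
  d1 <- file.path(tempdir(), "scn_a")
  d2 <- file.path(tempdir(), "scn_b")
  write_scenario(generate_scenario(cfg), d1)
  write_scenario(generate_scenario(cfg), d2)
  for (f in c("episodes.csv", "deaths.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("lowering era-0 continuity lowers era-0 observed readmission only", {
  base <- list(start_quarter = "2001Q1", end_quarter = "2004Q4",
               births_per_quarter = 400, seed = 99)
  hi <- do.call(scenario_config,
                c(base, list(p_person_id_continuity = c(0.95, 1, 1, 1))))
  lo <- do.call(scenario_config,
                c(base, list(p_person_id_continuity = c(0.60, 1, 1, 1))))
  s_hi <- observed_series(hi)$series
  s_lo <- observed_series(lo)$series
  era <- era_of(s_hi$quarter)
  p_hi0 <- sum(s_hi$n_readmitted[era == 0]) / sum(s_hi$n_births[era == 0])
  p_lo0 <- sum(s_lo$n_readmitted[era == 0]) / sum(s_lo$n_births[era == 0])
  expect_lt(p_lo0, p_hi0)
  # shared seed + per-child coupled draws: later eras byte-identical
  expect_identical(s_hi[era > 0, ], s_lo[era > 0, ])
})

test_that("the postcode error window blanks postcode and IMD at birth only", {
  cfg <- scenario_config(
    start_quarter = "2012Q1", end_quarter = "2014Q4", births_per_quarter = 200,
    postcode_error_window = as.Date(c("1900-01-01", "2013-03-31")), seed = 5
  )
  scn <- generate_scenario(cfg)
  births <- scn$episodes[scn$episodes$epitype == 3L, ]
  before <- births$epistart <= as.Date("2013-03-31")
  expect_true(all(is.na(births$postcode_district[before])))
  expect_true(all(is.na(births$imd_quintile[before])))
  expect_true(any(!is.na(births$postcode_district[!before])))
})

test_that("YAML round-trip reproduces a configuration", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "start_quarter: 2000Q1", "end_quarter: 2003Q4",
    "births_per_quarter: 77",
    "readmission_knots:", "  2000Q1: 0.15", "  2003Q4: 0.25",
    "p_ons_link: [0.5, 0.9, 0.95, 0.95]", "seed: 123"
  ), path)
  cfg <- scenario_config_from_yaml(path)
  expect_identical(cfg$births_per_quarter, 77L)
  expect_identical(cfg$readmission_knots$prob, c(0.15, 0.25))
  expect_identical(cfg$p_ons_link, c(0.5, 0.9, 0.95, 0.95))
  expect_identical(generate_scenario(cfg)$truth,
                   generate_scenario(cfg)$truth)
  unlink(path)
})
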