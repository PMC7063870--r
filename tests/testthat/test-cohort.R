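test_that("event time is the first check-up meeting the criteria", {
  rec <- make_records(
    make_record("A", 0),
    sick_record("A", 2.0)
  )
  ch <- build_cohort(rec, "mets", standardize = FALSE)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$time, 2.0)
  expect_equal(ch$event, 1L)
})

test_that("subjects with the outcome at baseline are excluded", {
  rec <- make_records(
    sick_record("A", 0),
    sick_record("A", 1)
  )
  ch <- build_cohort(rec, "mets", standardize = FALSE)
  expect_equal(nrow(ch), 0L)
  expect_equal(attr(ch, "exclusions")[["baseline_mets_or_cvd"]], 1L)
})

test_that("a three-subject cohort enumerates to 2 subjects, 1 event, 4.5 person-years", {
  rec <- make_records(
    sick_record("A", 0), sick_record("A", 1),              # baseline-prevalent
    make_record("B", 0, age = 30), sick_record("B", 1.5, age = 31.5), # incident
    make_record("C", 0, age = 50), make_record("C", 3.0, age = 53)    # censored
  )
  ch <- build_cohort(rec, "mets", standardize = FALSE)
  expect_equal(nrow(ch), 2L)
  expect_equal(sum(ch$event), 1L)
  expect_equal(attr(ch, "person_years"), 4.5)
  expect_equal(incidence_density(sum(ch$event), attr(ch, "person_years")),
               222.2222, tolerance = 1e-4)
})

test_that("cohort construction conserves subjects and person-years", {
  cfg <- sim_config(n_subjects = 300, seed = 99)
  st <- simulate_study(cfg)
  for (oc in c("mets", "hypertension")) {
    ch <- suppressWarnings(build_cohort(st$records, oc))
    ex <- attr(ch, "exclusions")
    expect_equal(nrow(ch) + sum(ex), length(unique(st$records$subject_id)))
    expect_equal(attr(ch, "person_years"), sum(ch$time))
    expect_true(all(ch$time > 0))
    # no subject retained with the target at baseline
    expect_true(all(ch[[oc]] == 0L))
  }
})

test_that("component subcohorts also exclude baseline syndrome cases", {
  rec <- make_records(
    # hypertensive at baseline but MetS-free: out of the hypertension subcohort
    make_record("A", 0, sbp = 150), make_record("A", 1, sbp = 150),
    make_record("B", 0), make_record("B", 2)
  )
  ch <- build_cohort(rec, "hypertension", standardize = FALSE)
  expect_equal(ch$subject_id, "B")
  expect_equal(attr(ch, "exclusions")[["baseline_outcome"]], 1L)
})

test_that("degenerate longitudinal input is rejected or logged", {
  rec <- make_records(make_record("A", 0), make_record("A", 0))
  expect_error(build_cohort(rec, "mets"), "strictly increasing")

  rec2 <- make_records(make_record("A", 0),
                       make_record("B", 0), make_record("B", 1))
  ch <- build_cohort(rec2, "mets", standardize = FALSE)
  expect_equal(attr(ch, "exclusions")[["lt2_records"]], 1L)
  expect_equal(nrow(ch), 1L)
})
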