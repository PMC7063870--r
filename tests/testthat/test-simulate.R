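test_that("genotype doses follow Hardy-Weinberg proportions", {
  d <- simulate_genotypes(60000, 0.5, seed = 71)
  freq <- table(factor(d, 0:2)) / length(d)
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_error(simulate_genotypes(10, 0), "strictly")
  expect_error(simulate_genotypes(10, 1), "strictly")
})

test_that("simulated genotypes rarely reject HWE at n = 1381", {
  ok <- vapply(1:100, function(s) {
    d <- simulate_genotypes(1381, 0.4, seed = 7000 + s)
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("with no genetic or confounder effect the exposure matches its target moments", {
  cfg <- sim_config(n_subjects = 1381, b_g = 0, b_u = 0)
  set.seed(72)
  ages <- runif(1381, 21, 81)
  d <- simulate_genotypes(1381, 0.4)
  ua <- simulate_exposure(d, ages, cfg)
  se_mean <- 52.80 / sqrt(1381)
  expect_lt(abs(mean(ua) - 257.33), 3 * se_mean)
  expect_equal(sd(ua), 52.80, tolerance = 0.1)
})

test_that("the per-allele exposure shift is recovered on the analysis scale", {
  cfg <- sim_config(n_subjects = 1381, seed = 73)
  co <- suppressWarnings(simulate_survival_cohort(cfg))
  e <- suppressWarnings(linear_fit(co$ua_z, co$dose))
  expect_lt(abs(e$beta - 0.23), 0.05)
})

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_study(sim_config(n_subjects = 50, seed = 74))
  b <- simulate_study(sim_config(n_subjects = 50, seed = 74))
  expect_identical(a$records, b$records)
  ages <- seq(21, 79, length.out = 30)
  ua1 <- simulate_exposure(rep(0:2, 10), ages, sim_config(), seed = 5)
  ua2 <- simulate_exposure(rep(0:2, 10), ages, sim_config(), seed = 5)
  expect_identical(as.numeric(ua1), as.numeric(ua2))
})

test_that("generated records are phenotype-consistent at every visit", {
  st <- simulate_study(sim_config(n_subjects = 200, seed = 75))
  expect_silent(flags <- phenotype(st$records))
  # events discovered by the cohort builder occur at visits that truly
  # satisfy the diagnostic criteria they were generated to trip
  for (oc in c("mets", "hypertension")) {
    ch <- suppressWarnings(build_cohort(st$records, oc))
    ev <- ch[ch$event == 1, ]
    for (i in seq_len(nrow(ev))) {
      rows <- st$records$subject_id == ev$subject_id[i]
      t_rel <- st$records$visit_time[rows] - min(st$records$visit_time[rows])
      at_event <- which(abs(t_rel - ev$time[i]) < 1e-9)
      expect_equal(phenotype(st$records[rows, ][at_event, ])[[oc]], 1L)
    }
  }
})

test_that("the default study emulates the target cohort's frame", {
  st <- simulate_study(sim_config(seed = 76))
  base <- st$records[!duplicated(st$records$subject_id), ]
  expect_equal(nrow(base), 1381L)
  expect_true(all(base$sex == "female"))
  expect_true(all(base$age >= 21 & base$age <= 81))
  n_visits <- table(st$records$subject_id)
  expect_true(all(n_visits >= 2))
})

test_that("configurations round-trip through YAML", {
  cfg <- sim_config(n_subjects = 42, seed = 9, gamma_x = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("truth files round-trip alongside the cohort CSV", {
  dir <- withr::local_tempdir()
  st <- simulate_study(sim_config(n_subjects = 10, seed = 77), out_dir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$true_causal_log_hr_per_sd, 0)
  expect_equal(truth$config$b_g, 0.23)
  back <- read_cohort_csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), nrow(st$records))
})
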