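# Synthetic cohort generator and its file round trip.

test_that("identical seeds give identical cohorts", {
  a <- simulate_cohort(ref_model(), 500, seed = 123)
  b <- simulate_cohort(ref_model(), 500, seed = 123)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$study_end_date, b$study_end_date)
  expect_identical(attr(a, "latent"), attr(b, "latent"))
  c <- simulate_cohort(ref_model(), 500, seed = 124)
  expect_false(identical(a$events, c$events))
})

test_that("a chain that sends every transient state to Dead yields exactly one death in cycle 1", {
  forced <- canonical_amc(R = matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE),
                          Q = matrix(0, 3, 3))
  coh <- simulate_cohort(forced, 200, seed = 4)
  expect_equal(nrow(coh$events), 200L)
  expect_true(all(coh$events$event_kind == "death"))
  s <- assign_states(coh, K = 3)
  expect_true(all(s$states[, 1] == "D"))
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulate_cohort(ref_model(), 100, horizon_cycles = 2),
               "horizon_cycles")
  expect_error(simulate_cohort(ref_model(), 0), "n_patients")
  bad <- ref_model()$P
  bad[3, 3] <- 0.9 # breaks row sum
  expect_error(simulate_cohort(bad, 10), "stochastic")
  expect_error(simulate_cohort(ref_model(), 10,
                               first_transition = c(0.5, 0.5, 0.1, 0, 0)),
               "first_transition")
})

test_that("empirical first-transition frequencies match the target within 3 binomial SE", {
  target <- unname(reference_tally / sum(reference_tally))
  coh <- simulate_cohort(ref_model(), 7496, seed = 2026,
                         first_transition = target)
  s <- assign_states(coh, K = 1)
  freq <- as.numeric(table(factor(s$states[, 1],
                                  levels = c("D", "L", "H", "O", "N")))) / 7496
  se <- sqrt(target * (1 - target) / 7496)
  expect_true(all(abs(freq - target) <= 3 * se))
})

test_that("empirical cycle-k distributions follow the analytically iterated chain", {
  n <- 10000
  ft <- unname(reference_tally / sum(reference_tally))
  coh <- simulate_cohort(ref_model(), n, seed = 99, first_transition = ft,
                         horizon_cycles = 6)
  obs <- observed_distributions(assign_states(coh, K = 6))
  expected <- analytic_cycle_dist(ref_model()$P, 6, first_transition = ft)
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(obs$dist - expected) <= 3 * se + 1e-12))
})

test_that("reconstructing states from generated events recovers the latent path exactly", {
  coh <- simulate_cohort(ref_model(), 1500, seed = 55)
  lat <- attr(coh, "latent")
  s <- assign_states(coh)
  K <- min(ncol(lat), s$K)
  for (k in seq_len(K)) {
    def <- !is.na(s$states[, k])
    expect_true(all(s$states[def, k] == lat[def, k]))
    # every latent cycle within the administrative window is reconstructed
    expect_true(all(def[s$n_complete >= k]))
  }
})

test_that("stratum-specific ground-truth chains drive stratum-specific dynamics", {
  riskier <- ref_R()
  riskier[, 1] <- riskier[, 1] + 0.10 # more death from every transient state
  Q2 <- ref_Q() - diag(c(0.10, 0.10, 0.10))
  old <- canonical_amc(R = riskier, Q = Q2)
  coh <- simulate_cohort(ref_model(), 4000, seed = 77, strata = list(
    list(p = 0.5, model = ref_model(), label = "young",
         covariates = cov_spec(age_mean = 55, age_sd = 5, age_max = 64.9)),
    list(p = 0.5, model = old, label = "old",
         covariates = cov_spec(age_mean = 78, age_sd = 5, age_min = 65))))
  expect_setequal(unique(attr(coh, "stratum")), c("young", "old"))
  young_age <- coh$patients$age_years[attr(coh, "stratum") == "young"]
  expect_true(all(young_age < 65))
})

test_that("cohorts round-trip losslessly through the CSV format", {
  coh <- simulate_cohort(ref_model(), 30, seed = 12)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$patients, coh$patients)
  expect_equal(back$events, coh$events)
  expect_equal(back$study_end_date, coh$study_end_date)
})

test_that("an empty cohort survives the file round trip", {
  empty <- hf_cohort(data.frame(patient_id = character(),
                                baseline_date = as.Date(character())),
                     NULL, as.Date("2010-01-01"))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(empty, path)
  back <- read_cohort(path)
  expect_equal(nrow(back$patients), 0L)
  expect_equal(nrow(back$events), 0L)
})

test_that("malformed cohort files fail with the offending line number", {
  lines <- c("# study_end_date: 2006-01-01",
             "patient_id,row_type,date,event_kind,age_years,sex,lvef_percent,ntprobnp_ng_per_l",
             "P1,baseline,2005-06-01,,70,male,35,900",
             "P1,event,2005-01-15,death,,,,")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(lines, path)
  expect_error(read_cohort(path), "line 4: death dated before baseline")
  writeLines(c(lines[1:3], "P1,wibble,2005-07-01,,,,,"), path)
  expect_error(read_cohort(path), "line 4: unknown row_type")
  writeLines(c(lines[1:3], "P2,event,2005-07-01,clinic_visit,,,,"), path)
  expect_error(read_cohort(path), "line 4: .*without a baseline row")
  writeLines(lines[2:4], path)
  expect_error(read_cohort(path), "line 1")
})
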