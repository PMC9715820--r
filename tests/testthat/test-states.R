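# State engine: event histories -> cycle-indexed five-state sequences.

test_that("a single clinic visit with no later events gives O then Left", {
  coh <- one_patient(data.frame(date = "2005-02-10",
                                event_kind = "clinic_visit"))
  expect_equal(states_of(coh), c("O", "L", "L", "L", "L", "L"))
})

test_that("no service contact at all after baseline is Left from cycle 1", {
  coh <- one_patient()
  expect_equal(states_of(coh), rep("L", 6))
})

test_that("hospitalization dominates a clinic visit; empty cycles before a death are NoEvent", {
  coh <- one_patient(data.frame(
    date = c("2005-02-01", "2005-03-01", "2005-10-15"),
    event_kind = c("clinic_visit", "hf_hospitalization", "death")))
  expect_equal(states_of(coh), c("H", "N", "D", "D", "D", "D"))
})

test_that("death and hospitalization in the same cycle give Dead, for every admissible ordering of dates", {
  # cycle 2 window is [2005-05-01, 2005-09-01); enumerate day pairs with the
  # admission on or before the death (an event after death is not a valid
  # event log and is rejected)
  days <- as.Date("2005-05-01") + c(5, 60, 120)
  for (dh in days) for (dd in days) {
    ev <- data.frame(date = as.Date(c(dh, dd), origin = "1970-01-01"),
                     event_kind = c("hf_hospitalization", "death"))
    if (dh <= dd) {
      coh <- one_patient(ev)
      expect_equal(states_of(coh)[2], "D")
    } else {
      expect_error(one_patient(ev), "after death")
    }
  }
})

test_that("events before baseline or after the study end are input errors", {
  expect_error(one_patient(data.frame(date = "2004-12-31",
                                      event_kind = "death")),
               "before baseline")
  expect_error(one_patient(data.frame(date = "2010-01-01",
                                      event_kind = "clinic_visit")),
               "after study_end_date")
})

test_that("windows crossing the study end are censored and excluded from complete cycles", {
  # study end mid-cycle-4: only 3 complete cycles
  base <- as.Date("2005-01-01")
  coh <- hf_cohort(data.frame(patient_id = "P1", baseline_date = base),
                   data.frame(patient_id = "P1", date = as.Date("2005-02-01"),
                              event_kind = "clinic_visit"),
                   as.Date("2006-03-01"))
  s <- assign_states(coh, K = 5)
  expect_equal(s$n_complete, 3L)
  expect_equal(as.vector(s$states), c("O", "L", "L", NA, NA))
})

test_that("death determines the state of censored cycles once dated", {
  base <- as.Date("2005-01-01")
  coh <- hf_cohort(data.frame(patient_id = "P1", baseline_date = base),
                   data.frame(patient_id = "P1", date = as.Date("2006-02-20"),
                              event_kind = "death"),
                   as.Date("2006-03-01")) # death in (incomplete) cycle 4
  s <- assign_states(coh, K = 5)
  expect_equal(as.vector(s$states), c("N", "N", "N", "D", "D"))
})

test_that("extending follow-up converts trailing Left to NoEvent only when new events appear, leaving event-bearing cycles untouched", {
  ev1 <- data.frame(date = "2005-02-01", event_kind = "clinic_visit")
  short <- one_patient(ev1, complete_cycles = 6)
  expect_equal(states_of(short), c("O", "L", "L", "L", "L", "L"))
  # same events, longer window: still Left (backdated to cycle 2)
  longer <- one_patient(ev1, complete_cycles = 9)
  expect_equal(states_of(longer, K = 9),
               c("O", rep("L", 8)))
  # a later visit appears in cycle 8: the gap becomes NoEvent, cycle 1 unchanged
  ev2 <- rbind(ev1, data.frame(date = "2007-06-15",
                               event_kind = "clinic_visit"))
  extended <- one_patient(ev2, complete_cycles = 9)
  expect_equal(states_of(extended, K = 9),
               c("O", rep("N", 6), "O", "L"))
})

test_that("every complete cycle maps to exactly one state and D/L are absorbing", {
  coh <- simulate_cohort(ref_model(), 400, seed = 31, horizon_cycles = 6)
  S <- assign_states(coh)$states
  nc <- assign_states(coh)$n_complete
  for (i in seq_len(nrow(S))) {
    row <- S[i, seq_len(min(nc[i], ncol(S)))]
    expect_true(all(row %in% c("D", "L", "H", "O", "N")))
    for (ab in c("D", "L")) {
      hit <- which(row == ab)
      if (length(hit)) expect_true(all(row[min(hit):length(row)] == ab))
    }
  }
})

test_that("diagnostic classification follows the LVEF / NT-proBNP thresholds", {
  lv <- c(33, 55, 55, 40, 55, 55, 41, 40.5)
  bnp <- c(1752, 60, NA, NA, 400, 399, 125, 124)
  got <- classify_diagnosis(lv, bnp)
  expect_equal(as.character(got),
               c("HeFREF", "Control", "NoNTproBNP", "HeFREF",
                 "HeFPEF_ge400", "HeFPEF_125_399", "HeFPEF_125_399",
                 "Control"))
  expect_warning(out <- classify_diagnosis(NA_real_, 500), "without LVEF")
  expect_true(is.na(out))
  # categories are exhaustive whenever LVEF is present
  set.seed(5)
  lv <- runif(200, 10, 75)
  bnp <- ifelse(runif(200) < 0.2, NA, rlnorm(200, 6, 1.5))
  expect_false(anyNA(classify_diagnosis(lv, bnp)))
})

test_that("state sequences round-trip through the CSV writer", {
  coh <- simulate_cohort(ref_model(), 50, seed = 8, horizon_cycles = 6)
  s <- assign_states(coh, K = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_states(s, path)
  back <- read_states(path)
  expect_equal(unname(back$states), unname(s$states))
  expect_equal(back$patient_id, s$patient_id)
})
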