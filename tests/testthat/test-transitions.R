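# Transition counting, estimation, assembly, repair.

test_that("transition-1 counts put all mass in the OPD origin row", {
  tally <- reference_tally
  S <- matrix(rep(names(tally), tally), ncol = 1)
  counts <- count_transitions(make_seq(S), 1)
  expect_equal(unname(counts["O", ]), unname(as.integer(tally)))
  expect_equal(sum(counts), sum(tally))
  expect_equal(sum(counts[c("D", "L", "H", "N"), ]), 0L)
})

test_that("transition-2 counts match a hand tally", {
  S <- rbind(c("H", "H"), c("H", "D"))
  counts <- count_transitions(make_seq(S), 2)
  expect_equal(counts["H", "H"], 1L)
  expect_equal(counts["H", "D"], 1L)
  expect_equal(sum(counts), 2L)
})

test_that("absorbed patients contribute only diagonal mass in absorbing rows", {
  S <- rbind(c("D", "D"), c("L", "L"), c("L", "L"))
  counts <- count_transitions(make_seq(S), 2)
  expect_equal(counts["D", "D"], 1L)
  expect_equal(counts["L", "L"], 2L)
  expect_equal(sum(counts), 3L)
})

test_that("censored patient-cycles are excluded from counting", {
  S <- rbind(c("O", "O"), c("O", NA))
  counts <- count_transitions(make_seq(S), 2)
  expect_equal(sum(counts), 1L)
  S_all_na <- rbind(c(NA, NA))
  expect_error(count_transitions(make_seq(S_all_na), 2), "no patient")
})

test_that("row normalization reproduces the reference first-transition probabilities at 2 dp", {
  tally <- reference_tally
  S <- matrix(rep(names(tally), tally), ncol = 1)
  counts <- count_transitions(make_seq(S), 1)
  # at transition 1 only the OPD origin row is populated; the other
  # transient rows need the self-loop fallback
  m <- suppressWarnings(estimate_matrix(counts, zero_row = "self_loop"))
  expect_equal(round2(unname(m$P["O", ])), c(0.06, 0.25, 0.21, 0.30, 0.19))
  expect_equal(unname(rowSums(m$P)), rep(1, 5))
})

test_that("a single observed transition gives a degenerate row; random counts normalize exactly", {
  counts <- matrix(0L, 5, 5, dimnames = list(names(amc_states()),
                                             names(amc_states())))
  counts["H", "D"] <- 1L
  counts["O", "O"] <- 3L
  counts["O", "D"] <- 1L
  counts["N", "N"] <- 2L
  counts["N", "L"] <- 1L
  m <- estimate_matrix(counts)
  expect_equal(unname(m$P["H", "D"]), 1)
  expect_equal(unname(m$P["O", "O"]), 0.75)
  # degenerate data can estimate a chain without certain absorption; that
  # is flagged rather than silently accepted
  counts["O", "D"] <- 0L
  expect_warning(estimate_matrix(counts), "absorption")
  set.seed(17)
  for (rep in 1:10) {
    rc <- matrix(rpois(25, 20) + 1L, 5, 5)
    m <- estimate_matrix(rc)
    expect_true(all(abs(rowSums(m$P) - 1) < 1e-12))
    expect_true(all(m$P >= 0 & m$P <= 1))
  }
})

test_that("an unobserved transient row errors by default and self-loops under the fallback policy", {
  counts <- matrix(0L, 5, 5)
  counts[3, 1] <- 5L
  counts[4, 4] <- 5L # N row empty
  expect_error(estimate_matrix(counts), "no observed transitions")
  expect_warning(m <- estimate_matrix(counts, zero_row = "self_loop"),
                 "self-loop")
  expect_equal(m$P[5, 5], 1)
})

test_that("pooled assembly equals the row-count-weighted average of per-transition estimates", {
  set.seed(3)
  c1 <- matrix(rpois(25, 15) + 1L, 5, 5)
  c2 <- matrix(rpois(25, 25) + 1L, 5, 5)
  m1 <- estimate_matrix(c1)$P
  m2 <- estimate_matrix(c2)$P
  pooled <- assemble_model(c1, c2, pooling = "pooled")$P
  for (i in 3:5) {
    n1 <- sum(c1[i, ]); n2 <- sum(c2[i, ])
    expect_equal(unname(pooled[i, ]),
                 unname((n1 * m1[i, ] + n2 * m2[i, ]) / (n1 + n2)),
                 tolerance = 1e-12)
  }
  # identical counts: both pooling modes agree exactly
  expect_equal(assemble_model(c1, c1, pooling = "pooled")$P,
               assemble_model(c1, c1, pooling = "second")$P)
})

test_that("repair completes a single unspecified entry by the unit-row-sum complement", {
  P <- rbind(cbind(diag(2), matrix(0, 2, 3)),
             cbind(matrix(c(0.07, 0.17, 0.02, NA, 0.05, 0), 3, 2, byrow = TRUE),
                   ref_Q()))
  m <- repair_matrix(P)
  expect_equal(unname(m$R[2, 2]), 0.09)
  expect_equal(m$repair_log$action, "complement")
  expect_equal(m$repair_log$row, "O")
  # a perfectly stochastic matrix comes back unchanged with an empty log
  m2 <- repair_matrix(ref_model()$P)
  expect_equal(m2$P, ref_model()$P)
  expect_equal(nrow(m2$repair_log), 0L)
})

test_that("repair rejects rows that cannot be fixed", {
  P <- ref_model()$P
  P[3, 3] <- P[3, 3] + 0.2 # row sums to 1.20, all entries specified
  expect_error(repair_matrix(P), "more than tolerance")
  P <- ref_model()$P
  P[4, 2] <- NA
  P[4, 3] <- NA
  expect_error(repair_matrix(P), "at most one")
})

test_that("canonical validation enforces block structure and certain absorption", {
  P <- ref_model()$P
  P[1, ] <- c(0.9, 0.1, 0, 0, 0)
  expect_error(canonical_amc(P = P), "unit vector")
  expect_error(canonical_amc(R = matrix(0, 3, 2), Q = diag(3)),
               "not certain")
  P <- ref_model()$P
  P[5, 5] <- 0.7
  expect_error(canonical_amc(P = P), "stochastic")
})

test_that("models round-trip through the JSON format with their repair log", {
  ref <- chf_reference()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model(ref$model, path, metadata = list(source = "reference"))
  back <- read_model(path)
  expect_equal(back$P, ref$model$P)
  expect_equal(back$repair_log$value, ref$model$repair_log$value)
})
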