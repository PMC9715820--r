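# Shared fixtures and independent oracles, all built in code.

# Reference transient blocks (2-dp quoted values; O->L completed by unit
# row sum). Built here independently of the shipped JSON fixture.
ref_Q <- function() {
  matrix(c(0.24, 0.14, 0.38,
           0.12, 0.22, 0.55,
           0.19, 0.13, 0.63), 3, 3, byrow = TRUE)
}
ref_R <- function() {
  matrix(c(0.07, 0.17,
           0.02, 0.09,
           0.05, 0.00), 3, 2, byrow = TRUE)
}
ref_model <- function() canonical_amc(R = ref_R(), Q = ref_Q())

reference_tally <- c(D = 427, L = 1842, H = 1559, O = 2254, N = 1414)

# Round half away from zero, matching how 2-dp report values are printed.
round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# Independent oracle for the fundamental matrix: truncated Neumann series
# sum_{k=0..K} Q^k.
neumann_F <- function(Q, K = 2000L) {
  S <- diag(nrow(Q))
  Pk <- diag(nrow(Q))
  for (k in seq_len(K)) {
    Pk <- Pk %*% Q
    S <- S + Pk
  }
  S
}

# Random strictly substochastic transient block (rows sum < max_row).
random_subQ <- function(max_row = 0.95) {
  Q <- matrix(runif(9), 3, 3)
  Q * runif(3, 0.3, max_row) / rowSums(Q)
}

# Wrap a plain state matrix (rows = patients, cols = cycles) as a fully
# uncensored state_seq.
make_seq <- function(S) {
  structure(list(states = S,
                 patient_id = sprintf("P%04d", seq_len(nrow(S))),
                 n_complete = rep(ncol(S), nrow(S)),
                 K = ncol(S), cycle_length = 4L),
            class = "state_seq")
}

# One-patient cohort: baseline 2005-01-01; windows are then
# [2005-01-01, 2005-05-01), [2005-05-01, 2005-09-01), ... and the study end
# is chosen to close `complete_cycles` windows.
one_patient <- function(events = NULL, complete_cycles = 6,
                        baseline = as.Date("2005-01-01")) {
  if (!is.null(events)) {
    events <- data.frame(patient_id = "P1", date = as.Date(events$date),
                         event_kind = events$event_kind,
                         stringsAsFactors = FALSE)
  }
  end <- hfamc:::add_months(baseline, 4L * complete_cycles)
  hf_cohort(data.frame(patient_id = "P1", baseline_date = baseline,
                       stringsAsFactors = FALSE),
            events, end)
}

states_of <- function(cohort, K = 6) as.vector(assign_states(cohort, K = K)$states)

# Analytic distribution over cycles for a chain started in OPD, with an
# optional separate first-transition law (computed here, independent of
# iterate_distribution()).
analytic_cycle_dist <- function(P, K, first_transition = NULL) {
  d <- c(0, 0, 0, 1, 0)
  out <- matrix(NA_real_, K, 5)
  for (k in seq_len(K)) {
    d <- if (k == 1 && !is.null(first_transition)) first_transition
    else as.numeric(d %*% P)
    out[k, ] <- d
  }
  colnames(out) <- c("D", "L", "H", "O", "N")
  out
}
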