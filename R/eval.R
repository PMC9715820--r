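#' Observed per-cycle state distributions
#'
#' Tallies the fraction of the cohort in each of the five states at every
#' cycle. Absorbed patients remain counted in their absorbing state at
#' every later cycle, so each cycle's fractions sum to 1 over the baseline
#' cohort; patient-cycles that are administratively censored are dropped
#' from that cycle's denominator.
#'
#' @param sequences A `state_seq` from [assign_states()].
#' @param K Number of cycles; truncated with a warning if it exceeds the
#'   assigned cycles.
#' @return An `amc_trajectory` with cycles 1..K.
#' @export
observed_distributions <- function(sequences, K = sequences$K) {
  stopifnot(inherits(sequences, "state_seq"))
  if (length(sequences$patient_id) == 0L) stop("empty cohort")
  K <- as.integer(K)
  if (K > sequences$K) {
    warning("K = ", K, " exceeds available cycles; truncating to ", sequences$K)
    K <- sequences$K
  }
  dist <- matrix(NA_real_, K, 5L, dimnames = list(1:K, .STATES))
  for (k in seq_len(K)) {
    st <- sequences$states[, k]
    st <- st[!is.na(st)]
    if (!length(st)) stop("all patients censored at cycle ", k)
    dist[k, ] <- as.numeric(table(factor(st, levels = .STATES))) / length(st)
  }
  structure(list(cycles = 1:K, dist = dist), class = "amc_trajectory")
}

#' Predicted versus observed state distributions with signed errors
#'
#' Reproduces the model-validation table: predictions for cycles 3..K are
#' obtained by iterating the one-step chain forward from the *observed*
#' cycle-2 distribution (the model is constructed from the first two
#' transitions, so it makes no prediction for cycles 1-2), and the signed
#' error is predicted minus observed — negative values indicate
#' underestimation. Full precision is kept internally; rounding to 2
#' decimal places happens only in the print method.
#'
#' @param x A fitted [fit_amc()] object, or a [canonical_amc()] together
#'   with an `observed` trajectory.
#' @param K Last cycle tabulated (default 6, i.e. 2 years).
#' @param observed An `amc_trajectory` of observed distributions covering
#'   at least cycle 2; defaults to the distributions stored in a fitted
#'   model. Cycles beyond its reach get `NA` observed/error rows.
#' @return Object of class `amc_prediction`: list with `cycles` (3..K),
#'   `predicted`, `observed`, `error` (matrices over cycles 3..K) and
#'   `observed_head` (observed cycles 1..2).
#' @examples
#' ref <- chf_reference()
#' prediction_table(ref$model, observed = ref$observed, K = 6)
#' @export
prediction_table <- function(x, K = 6L, observed = NULL) {
  K <- as.integer(K)
  if (K < 3L) stop("K must be at least 3: cycles 1-2 carry no prediction")
  if (inherits(x, "amc") && is.null(observed)) observed <- x$observed
  model <- as_canonical_amc(x)
  if (is.null(observed)) stop("supply 'observed' distributions")
  stopifnot(inherits(observed, "amc_trajectory"))
  if (!2L %in% observed$cycles) stop("cannot predict: no observed cycle-2 distribution")
  d2 <- observed$dist[match(2L, observed$cycles), ]
  pred <- iterate_distribution(model, d2, n_cycles = K - 2L, from_cycle = 2L)
  predicted <- pred$dist[-1L, , drop = FALSE] # cycles 3..K
  obs <- matrix(NA_real_, K - 2L, 5L, dimnames = list(3:K, .STATES))
  have <- intersect(3:K, observed$cycles)
  obs[as.character(have), ] <- observed$dist[match(have, observed$cycles), ]
  err <- predicted - obs
  head_cycles <- intersect(1:2, observed$cycles)
  structure(list(cycles = 3:K,
                 predicted = predicted, observed = obs, error = err,
                 observed_head = observed$dist[match(head_cycles,
                                                     observed$cycles), ,
                                               drop = FALSE]),
            class = "amc_prediction")
}

#' @export
print.amc_prediction <- function(x, digits = 2, ...) {
  fmt <- function(m) {
    out <- matrix(sprintf(paste0("%.", digits, "f"), m), nrow(m), ncol(m))
    out[is.na(m)] <- "-"
    out
  }
  wide <- cbind(fmt(x$predicted), fmt(x$observed), fmt(x$error))
  head <- cbind(matrix("-", nrow(x$observed_head), 5L),
                fmt(x$observed_head),
                matrix("-", nrow(x$observed_head), 5L))
  tab <- rbind(head, wide)
  dimnames(tab) <- list(
    cycle = c(rownames(x$observed_head), x$cycles),
    paste(rep(c("pred", "obs", "err"), each = 5L), .STATES, sep = "."))
  cat("Predicted vs observed state distributions",
      "(error = predicted - observed):\n")
  print(tab, quote = FALSE)
  invisible(x)
}

.subset_cohort <- function(cohort, keep) {
  p <- cohort$patients[keep, , drop = FALSE]
  ev <- cohort$events[cohort$events$patient_id %in% p$patient_id, ,
                      drop = FALSE]
  hf_cohort(p, ev, cohort$study_end_date)
}

#' Fit subgroup chains by sex or age band
#'
#' Splits the cohort by a baseline stratifier — `sex`, or `age_band` with a
#' 65-year threshold — and runs the full estimation pipeline independently
#' in each stratum. The summary table compares one-step death risks,
#' absorption probabilities and expected cycles to absorption across
#' strata. An empty stratum (or one where estimation fails) is skipped with
#' a warning.
#'
#' @param cohort An [hf_cohort()].
#' @param by `"sex"` or `"age_band"`.
#' @param age_threshold Age cut for `age_band` (default 65 years).
#' @param K,pooling,zero_row Passed to [fit_amc()].
#' @return Object of class `amc_subgroups`: list with `models` (named list
#'   of fitted `amc` objects), `by` and `table` (per-stratum comparison).
#' @examples
#' ref <- chf_reference()
#' coh <- simulate_cohort(ref$model, 3000, seed = 11)
#' fit_subgroup_models(coh, by = "sex")
#' @export
fit_subgroup_models <- function(cohort, by = c("sex", "age_band"),
                                age_threshold = 65, K = 6L,
                                pooling = c("second", "pooled"),
                                zero_row = c("error", "self_loop")) {
  by <- match.arg(by)
  stopifnot(inherits(cohort, "hf_cohort"))
  g <- switch(by,
              sex = cohort$patients$sex,
              age_band = ifelse(cohort$patients$age_years >= age_threshold,
                                paste0(">=", age_threshold),
                                paste0("<", age_threshold)))
  levels <- sort(unique(g[!is.na(g)]))
  models <- list()
  for (lev in levels) {
    keep <- which(!is.na(g) & g == lev)
    if (!length(keep)) {
      warning("stratum '", lev, "' is empty; skipped")
      next
    }
    fit <- tryCatch(
      fit_amc(.subset_cohort(cohort, keep), K = K, pooling = pooling,
              zero_row = zero_row),
      error = function(e) {
        warning("stratum '", lev, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) models[[lev]] <- fit
  }
  if (!length(models)) stop("no stratum could be fitted")
  tab <- do.call(rbind, lapply(names(models), function(lev) {
    fit <- models[[lev]]
    ab <- absorption_summary(fit$transition)
    data.frame(stratum = lev, n = fit$n,
               p_death_from_H = ab$B["H", "D"],
               p_death_from_O = ab$B["O", "D"],
               p_death_from_N = ab$B["N", "D"],
               cycles_from_H = ab$expected_cycles["H"],
               cycles_from_O = ab$expected_cycles["O"],
               cycles_from_N = ab$expected_cycles["N"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(models = models, by = by, table = tab),
            class = "amc_subgroups")
}

#' @export
print.amc_subgroups <- function(x, digits = 2, ...) {
  cat("Subgroup absorbing chains by", x$by, "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-cycle survival, overall or by stratum
#'
#' Tabulates survival probabilities S(k) = 1 - P(Dead at cycle k) for
#' cycles 1..K: observed survival for cycles 1-2 and model-predicted
#' survival (iterated from the observed cycle-2 distribution) thereafter.
#'
#' @param x A fitted `amc`, an `amc_subgroups` object, or a named list of
#'   fitted `amc` objects.
#' @param K Last cycle (default 9).
#' @return data.frame with columns `cycle`, `stratum`, `survival`.
#' @export
survival_report <- function(x, K = 9L) {
  models <- if (inherits(x, "amc")) list(overall = x)
  else if (inherits(x, "amc_subgroups")) x$models
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "amc"))) x
  else stop("'x' must be a fitted amc, amc_subgroups, or list of amc")
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  out <- do.call(rbind, lapply(names(models), function(nm) {
    fit <- models[[nm]]
    s_obs <- survival_curve(fit$observed)
    s_obs <- s_obs[names(s_obs) %in% c("1", "2")]
    s_pred <- survival_curve(predict(fit, K = K))
    s_pred <- s_pred[!names(s_pred) %in% c("2")]
    s <- c(s_obs, s_pred)
    data.frame(cycle = as.integer(names(s)), stratum = nm,
               survival = unname(s), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out[order(out$stratum, out$cycle), , drop = FALSE]
}
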