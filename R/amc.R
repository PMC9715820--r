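#' Fit an absorbing Markov chain to a cohort
#'
#' The canonical workflow: discretize the cohort's event histories into
#' cycle states ([assign_states()]), count the first two transitions
#' ([count_transitions()]), and assemble the one-step chain
#' ([assemble_model()]). By construction the model uses only the first 8
#' months of follow-up: the second transition supplies the one-step
#' dynamics and the first transition the initial state distribution.
#' Observed per-cycle state distributions up to `K` are retained for
#' validation via [predict()], [residuals()] and [prediction_table()].
#'
#' @param x An [hf_cohort()] or a `state_seq` from [assign_states()].
#' @param K Number of cycles retained for prediction and validation
#'   (default 6, i.e. 2 years of 4-month cycles).
#' @param pooling Passed to [assemble_model()]: `"second"` (default) or
#'   `"pooled"`.
#' @param zero_row Passed to [estimate_matrix()].
#' @param cycle_length Cycle length in calendar months.
#' @param ... Passed between methods.
#' @return An object of class `amc`: list with `transition` (the
#'   [canonical_amc()]), `counts` (transition-1 and -2 count matrices),
#'   `initial` (observed cycle-1 distribution), `observed` (an
#'   `amc_trajectory` of observed distributions, cycles 1..K), `n`, `K`,
#'   `pooling`, `call`.
#' @examples
#' ref <- chf_reference()
#' coh <- simulate_cohort(ref$model, 2000, seed = 42)
#' fit <- fit_amc(coh)
#' fit
#' coef(fit)["H", "D"] # one-step P(Hosp -> Dead)
#' @export
fit_amc <- function(x, ...) UseMethod("fit_amc")

#' @rdname fit_amc
#' @export
fit_amc.hf_cohort <- function(x, K = 6L, pooling = c("second", "pooled"),
                              zero_row = c("error", "self_loop"),
                              cycle_length = 4L, ...) {
  seqs <- assign_states(x, K = max(as.integer(K), 2L),
                        cycle_length = cycle_length)
  fit <- fit_amc(seqs, K = K, pooling = pooling, zero_row = zero_row)
  fit$call <- match.call()
  fit
}

#' @rdname fit_amc
#' @export
fit_amc.state_seq <- function(x, K = 6L, pooling = c("second", "pooled"),
                              zero_row = c("error", "self_loop"), ...) {
  pooling <- match.arg(pooling)
  K <- as.integer(K)
  if (x$K < 2L) stop("need at least 2 assigned cycles to fit the chain")
  c1 <- count_transitions(x, 1L)
  c2 <- count_transitions(x, 2L)
  model <- assemble_model(c1, c2, pooling = pooling, zero_row = zero_row)
  initial <- as.numeric(c1["O", ]) / sum(c1["O", ])
  names(initial) <- .STATES
  observed <- observed_distributions(x, K = min(K, x$K))
  structure(list(transition = model, counts = list(t1 = c1, t2 = c2),
                 initial = initial, observed = observed,
                 n = length(x$patient_id), K = K, pooling = pooling,
                 call = match.call()),
            class = "amc")
}

#' @export
print.amc <- function(x, digits = 2, ...) {
  cat("Absorbing Markov chain fitted from the first two transitions\n")
  cat("  n =", x$n, "patients; one-step matrix from",
      if (x$pooling == "second") "transition 2" else "pooled transitions 1-2",
      "\n")
  cat("  observed cycle-1 distribution (D, L, H, O, N):",
      paste(sprintf("%.2f", x$initial), collapse = " "), "\n")
  print(round(x$transition$P, digits))
  invisible(x)
}

#' @export
coef.amc <- function(object, ...) object$transition$P

#' @export
summary.amc <- function(object, ...) {
  structure(list(fit = object,
                 absorption = absorption_summary(object$transition)),
            class = "summary.amc")
}

#' @export
print.summary.amc <- function(x, digits = 2, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$absorption, digits = digits)
  invisible(x)
}

#' @describeIn fit_amc forward predictions: iterate the one-step matrix from
#'   the observed distribution at cycle `from_cycle` (default 2, the last
#'   cycle used in model construction) out to cycle `K`.
#' @param object,from_cycle See details.
#' @export
predict.amc <- function(object, K = object$K, from_cycle = 2L, ...) {
  from_cycle <- as.integer(from_cycle)
  if (from_cycle > max(object$observed$cycles)) {
    stop("no observed distribution at cycle ", from_cycle)
  }
  init <- object$observed$dist[match(from_cycle, object$observed$cycles), ]
  iterate_distribution(object$transition, init, n_cycles = K - from_cycle,
                       from_cycle = from_cycle)
}

#' @describeIn fit_amc signed prediction errors (predicted minus observed)
#'   for cycles 3..K, as in [prediction_table()].
#' @export
residuals.amc <- function(object, K = object$K, ...) {
  prediction_table(object, K = K)$error
}

#' @describeIn fit_amc simulate a synthetic cohort from the fitted chain:
#'   cycle 1 is drawn from the fitted first-transition distribution and
#'   later cycles from the one-step matrix (arguments forwarded to
#'   [simulate_cohort()]).
#' @param nsim Number of patients to simulate.
#' @param seed Optional integer seed.
#' @export
simulate.amc <- function(object, nsim = object$n, seed = NULL, ...) {
  simulate_cohort(object$transition, n_patients = nsim, seed = seed,
                  first_transition = object$initial, ...)
}

#' @describeIn fit_amc plot observed versus model-predicted survival
#'   (1 minus the Dead component) by cycle.
#' @export
plot.amc <- function(x, K = x$K, ...) {
  obs <- survival_curve(x$observed)
  pred <- survival_curve(predict(x, K = K))
  plot(as.integer(names(obs)), obs, type = "b", pch = 16,
       xlim = c(0, K), ylim = c(min(obs, pred) * 0.95, 1),
       xlab = "cycle (4 months each)", ylab = "survival probability", ...)
  lines(as.integer(names(pred)), pred, type = "b", lty = 2, pch = 1)
  legend("bottomleft", c("observed", "predicted"), lty = c(1, 2),
         pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Fundamental matrix, time to absorption and absorption probabilities
#'
#' For a canonical absorbing chain with transient block `Q` and
#' transient-to-absorbing block `R`, computes the fundamental matrix
#' \eqn{F = (I - Q)^{-1}} — entry (i, j) is the expected number of cycles
#' spent in transient state j before absorption when starting from
#' transient state i — together with the expected total cycles to
#' absorption (row sums of F), the absorption-probability matrix
#' \eqn{B = F R} (rows: starting transient state; columns: Dead, Left), and
#' the 5x5 limiting matrix embedding B with identity absorbing rows and
#' zero transient columns. Computations use linear solves of \eqn{(I - Q)}.
#'
#' @param model A [canonical_amc()], fitted [fit_amc()] object, or 5x5
#'   canonical matrix. Absorption must be certain (spectral radius of `Q`
#'   below 1); otherwise an error is raised.
#' @return `absorption_summary`: object of class `amc_absorption` with
#'   elements `F`, `expected_cycles`, `B`, `limiting`. `fundamental_matrix`
#'   and `absorption_probabilities` return the `F` and `B` components
#'   directly.
#' @examples
#' s <- absorption_summary(chf_reference()$model)
#' round(s$F, 2)
#' round(s$expected_cycles, 2)
#' round(s$B, 2)
#' @export
absorption_summary <- function(model) {
  model <- as_canonical_amc(model)
  Q <- model$Q
  rho <- max(Mod(eigen(Q, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12) {
    stop("absorption impossible: spectral radius of Q is ", format(rho))
  }
  IQ <- diag(3L) - Q
  Fmat <- solve(IQ, diag(3L))
  dimnames(Fmat) <- list(.STATES[.TRANSIENT], .STATES[.TRANSIENT])
  expected <- rowSums(Fmat)
  B <- solve(IQ, model$R)
  dimnames(B) <- list(.STATES[.TRANSIENT], .STATES[.ABSORBING])
  limiting <- matrix(0, 5L, 5L, dimnames = list(.STATES, .STATES))
  limiting[.ABSORBING, .ABSORBING] <- diag(2L)
  limiting[.TRANSIENT, .ABSORBING] <- B
  structure(list(F = Fmat, expected_cycles = expected, B = B,
                 limiting = limiting),
            class = "amc_absorption")
}

#' @rdname absorption_summary
#' @export
fundamental_matrix <- function(model) absorption_summary(model)$F

#' @rdname absorption_summary
#' @export
absorption_probabilities <- function(model) absorption_summary(model)$B

#' @export
print.amc_absorption <- function(x, digits = 2, ...) {
  cat("Fundamental matrix F = (I - Q)^-1 (expected cycles in each",
      "transient state):\n")
  print(round(cbind(x$F, total = x$expected_cycles), digits))
  cat("Absorption probabilities B = F R:\n")
  print(round(x$B, digits))
  invisible(x)
}

#' Iterate a state distribution forward through the chain
#'
#' Computes the marginal state distribution after each of `n_cycles`
#' one-step transitions: \eqn{d_k = d_0 P^k}. The absorbing components are
#' non-decreasing and every distribution sums to 1.
#'
#' @param model A [canonical_amc()] (or coercible).
#' @param initial 5-vector over (D, L, H, O, N); must be nonnegative and
#'   sum to 1 within 1e-9.
#' @param n_cycles Number of one-step iterations (>= 0).
#' @param from_cycle Cycle index attached to `initial` (labels only).
#' @return An object of class `amc_trajectory`: list with `cycles` (integer
#'   vector, `from_cycle` .. `from_cycle + n_cycles`) and `dist` (matrix,
#'   one row per cycle, columns D, L, H, O, N).
#' @examples
#' ref <- chf_reference()
#' d2 <- ref$observed$dist[2, ] # observed cycle-2 distribution
#' iterate_distribution(ref$model, d2, 4, from_cycle = 2)
#' @export
iterate_distribution <- function(model, initial, n_cycles, from_cycle = 0L) {
  model <- as_canonical_amc(model)
  initial <- as.numeric(initial)
  if (length(initial) != 5L || any(initial < -1e-12) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("'initial' must be a nonnegative 5-vector summing to 1")
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 0L) stop("'n_cycles' must be >= 0")
  dist <- matrix(NA_real_, n_cycles + 1L, 5L,
                 dimnames = list(NULL, .STATES))
  dist[1L, ] <- pmax(initial, 0)
  d <- dist[1L, ]
  if (n_cycles > 0L) {
    for (k in seq_len(n_cycles)) {
      d <- as.numeric(d %*% model$P)
      dist[k + 1L, ] <- d
    }
  }
  cycles <- from_cycle + 0:n_cycles
  rownames(dist) <- cycles
  structure(list(cycles = cycles, dist = dist), class = "amc_trajectory")
}

#' @export
print.amc_trajectory <- function(x, digits = 2, ...) {
  cat("State distribution by cycle:\n")
  print(round(x$dist, digits))
  invisible(x)
}

#' @export
as.data.frame.amc_trajectory <- function(x, ...) {
  data.frame(cycle = x$cycles, x$dist, row.names = NULL)
}

#' Per-cycle survival probabilities
#'
#' The survival probability at cycle k is one minus the Dead component of
#' the state distribution at cycle k; it is non-increasing in k.
#'
#' @param trajectory An `amc_trajectory` (from [iterate_distribution()],
#'   [observed_distributions()] or [predict.amc()]).
#' @return Named numeric vector of survival probabilities, names = cycles.
#' @export
survival_curve <- function(trajectory) {
  stopifnot(inherits(trajectory, "amc_trajectory"))
  setNames(1 - trajectory$dist[, "D"], trajectory$cycles)
}

#' Monte-Carlo random walks to absorption
#'
#' Simulates independent walks of the chain from a given transient origin
#' until absorption, as a stochastic cross-check of the analytic absorption
#' probabilities and expected cycle counts.
#'
#' @param model A [canonical_amc()] (or coercible).
#' @param n Number of walks.
#' @param origin Starting transient state: `"H"`, `"O"` or `"N"`.
#' @param seed Optional integer seed.
#' @param max_cycles Cap on walk length.
#' @return List with `state` (factor over `D`, `L`: absorbing state
#'   reached) and `cycles` (integer vector: number of steps to absorption,
#'   counting the origin cycle as occupied — comparable to the row sums of
#'   the fundamental matrix).
#' @examples
#' w <- simulate_walks(chf_reference()$model, 1000, "H", seed = 1)
#' mean(w$state == "D") # compare absorption_probabilities()["H", "D"]
#' @export
simulate_walks <- function(model, n, origin = c("H", "O", "N"), seed = NULL,
                           max_cycles = 10000L) {
  model <- as_canonical_amc(model)
  origin <- match.arg(origin)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cp <- t(apply(model$P, 1L, cumsum))
  state <- rep(match(origin, .STATES), n)
  steps <- rep(0L, n)
  active <- state > 2L
  k <- 0L
  while (any(active) && k < max_cycles) {
    k <- k + 1L
    idx <- which(active)
    steps[idx] <- steps[idx] + 1L
    state[idx] <- .step_states(state[idx], cp)
    active[idx] <- state[idx] > 2L
  }
  if (any(active)) warning(sum(active), " walk(s) not absorbed by max_cycles")
  list(state = factor(.STATES[state], levels = c("D", "L")),
       cycles = steps)
}
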