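# Transition counting, row-stochastic estimation, and the canonical
# absorbing-chain container [I 0; R Q] over the fixed order (D, L, H, O, N).

as_canonical_amc <- function(x) {
  if (inherits(x, "canonical_amc")) return(x)
  if (inherits(x, "amc")) return(x$transition)
  if (is.matrix(x)) return(canonical_amc(P = x))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a canonical transition matrix")
}

#' Canonical absorbing Markov chain transition matrix
#'
#' Builds and validates a 5x5 row-stochastic transition matrix in canonical
#' block form \eqn{[I\ 0; R\ Q]} over the ordered states (Dead, Left, Hosp,
#' OPD, NoEvent): the two absorbing rows are exact unit vectors, `R` is the
#' 3x2 transient-to-absorbing block and `Q` the 3x3 transient-to-transient
#' block. Validation checks that every entry lies in \[0, 1\], every row sums
#' to 1 within 1e-9, and (unless `require_absorbing = FALSE`) that the
#' spectral radius of `Q` is below 1 so absorption is certain.
#'
#' @param P Full 5x5 matrix; alternatively supply `R` and `Q`.
#' @param R 3x2 transient-to-absorbing block (rows H, O, N; columns D, L).
#' @param Q 3x3 transient-to-transient block.
#' @param repair_log Optional data.frame documenting repairs applied to a
#'   near-stochastic source matrix (see [repair_matrix()]).
#' @param require_absorbing If `TRUE` (default), reject chains from which
#'   absorption is not certain.
#' @return An object of class `canonical_amc`: list with elements `P`, `R`,
#'   `Q`, `states`, `repair_log`.
#' @examples
#' ref <- chf_reference()
#' m <- canonical_amc(R = ref$model$R, Q = ref$model$Q)
#' m
#' @export
canonical_amc <- function(P = NULL, R = NULL, Q = NULL, repair_log = NULL,
                          require_absorbing = TRUE) {
  if (is.null(P)) {
    if (is.null(R) || is.null(Q)) stop("supply either P or both R and Q")
    R <- as.matrix(R); Q <- as.matrix(Q)
    if (!all(dim(R) == c(3L, 2L)) || !all(dim(Q) == c(3L, 3L))) {
      stop("R must be 3x2 and Q 3x3")
    }
    P <- rbind(cbind(diag(2), matrix(0, 2L, 3L)), cbind(R, Q))
  }
  P <- as.matrix(P)
  if (!all(dim(P) == c(5L, 5L))) stop("P must be a 5x5 matrix")
  dimnames(P) <- list(.STATES, .STATES)
  if (anyNA(P)) stop("P contains missing entries; use repair_matrix()")
  if (any(P < -1e-12 | P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  P <- pmin(pmax(P, 0), 1)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("rows not stochastic (sum != 1 within 1e-9): ",
         paste(.STATES[abs(rs - 1) > 1e-9], collapse = ", "))
  }
  for (i in .ABSORBING) {
    if (any(abs(P[i, ] - as.numeric(seq_len(5L) == i)) > 1e-9)) {
      stop("absorbing row ", .STATES[i], " must be a unit vector")
    }
    P[i, ] <- as.numeric(seq_len(5L) == i)
  }
  Q <- P[.TRANSIENT, .TRANSIENT, drop = FALSE]
  R <- P[.TRANSIENT, .ABSORBING, drop = FALSE]
  if (require_absorbing) {
    rho <- max(Mod(eigen(Q, only.values = TRUE)$values))
    if (rho >= 1 - 1e-12) {
      stop("absorption is not certain: spectral radius of Q is ",
           format(rho), " (>= 1)")
    }
  }
  structure(list(P = P, R = R, Q = Q, states = .STATES,
                 repair_log = repair_log),
            class = "canonical_amc")
}

#' @export
print.canonical_amc <- function(x, digits = 2, ...) {
  cat("Canonical absorbing Markov chain over (D, L, H, O, N)\n")
  print(round(x$P, digits))
  if (!is.null(x$repair_log) && nrow(x$repair_log)) {
    cat("Repairs applied to source matrix:\n")
    print(x$repair_log, row.names = FALSE)
  }
  invisible(x)
}

#' Count state transitions at a given transition index
#'
#' Tallies the 5x5 matrix of one-step transitions at transition `t`:
#' origin = state at cycle `t - 1`, destination = state at cycle `t`.
#' Transition 1 runs from baseline to the end of cycle 1, and every patient
#' starts in the OPD pseudo-state at baseline (the baseline assessment is a
#' clinic contact), so for `t = 1` all mass lies in the OPD origin row.
#' Patient-cycles that are administratively censored at either end of the
#' transition are excluded.
#'
#' @param sequences A `state_seq` from [assign_states()].
#' @param t Transition index (>= 1).
#' @return An integer 5x5 matrix of class `transition_counts` (origin rows,
#'   destination columns, order D, L, H, O, N) with attribute `transition`.
#' @examples
#' coh <- simulate_cohort(chf_reference()$model, 300, seed = 2)
#' count_transitions(assign_states(coh, K = 2), 1)
#' @export
count_transitions <- function(sequences, t) {
  stopifnot(inherits(sequences, "state_seq"))
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("'t' must be a positive transition index")
  if (t > sequences$K) stop("transition ", t, " exceeds available cycles (K = ",
                            sequences$K, ")")
  S <- sequences$states
  from <- if (t == 1L) rep("O", nrow(S)) else S[, t - 1L]
  to <- S[, t]
  ok <- !is.na(from) & !is.na(to)
  if (!any(ok)) stop("no patient contributes an uncensored transition at t = ", t)
  tab <- table(factor(from[ok], levels = .STATES),
               factor(to[ok], levels = .STATES))
  counts <- matrix(as.integer(tab), 5L, 5L, dimnames = list(.STATES, .STATES))
  structure(counts, class = "transition_counts", transition = t)
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts, transition t =", attr(x, "transition"), "\n")
  print(matrix(as.integer(x), 5L, 5L, dimnames = dimnames(x)))
  invisible(x)
}

#' Estimate a canonical transition matrix from counts
#'
#' Maximum-likelihood row normalization: \eqn{\hat p_{ij} = n_{ij} / n_{i+}}
#' for the transient origin rows; the absorbing rows are forced to exact
#' unit vectors. A transient row with no observations is an error by
#' default; the `"self_loop"` policy instead assigns it a unit self-loop
#' with a warning (the resulting chain no longer guarantees absorption and
#' is flagged as such).
#'
#' @param counts A `transition_counts` matrix (or plain nonnegative 5x5
#'   matrix in state order).
#' @param zero_row Policy for transient rows with zero observations:
#'   `"error"` (default) or `"self_loop"`.
#' @return A [canonical_amc()].
#' @export
estimate_matrix <- function(counts, zero_row = c("error", "self_loop")) {
  zero_row <- match.arg(zero_row)
  m <- matrix(as.numeric(counts), 5L, 5L)
  if (any(m < 0)) stop("negative transition counts")
  P <- matrix(0, 5L, 5L)
  P[1L, 1L] <- 1
  P[2L, 2L] <- 1
  fallback <- FALSE
  for (i in .TRANSIENT) {
    rs <- sum(m[i, ])
    if (rs == 0) {
      if (zero_row == "error") {
        stop("transient origin row ", .STATES[i],
             " has no observed transitions (set zero_row = \"self_loop\" to fall back)")
      }
      warning("transient row ", .STATES[i],
              " has no observations; assigning a unit self-loop")
      P[i, i] <- 1
      fallback <- TRUE
    } else {
      P[i, ] <- m[i, ] / rs
    }
  }
  out <- canonical_amc(P = P, require_absorbing = FALSE)
  if (!fallback) {
    rho <- max(Mod(eigen(out$Q, only.values = TRUE)$values))
    if (rho >= 1 - 1e-12) {
      warning("estimated chain does not guarantee absorption ",
              "(spectral radius of Q is ", format(rho), ")")
    }
  }
  out
}

#' Assemble the working model from the first two transition counts
#'
#' The chain is built from the first two observed transitions. The default
#' (`"second"`) estimates the one-step matrix from the second transition
#' only, with the first transition supplying the initial state distribution
#' — the construction that reproduces the reference predictions. The
#' `"pooled"` alternative sums both count matrices before normalizing,
#' which weights each origin row's estimate by its per-transition counts.
#'
#' @param counts_t1,counts_t2 `transition_counts` for transitions 1 and 2.
#' @param pooling `"second"` (default) or `"pooled"`.
#' @param zero_row Passed to [estimate_matrix()].
#' @return A [canonical_amc()].
#' @export
assemble_model <- function(counts_t1, counts_t2,
                           pooling = c("second", "pooled"),
                           zero_row = c("error", "self_loop")) {
  pooling <- match.arg(pooling)
  if (pooling == "second") {
    estimate_matrix(counts_t2, zero_row)
  } else {
    pooled <- matrix(as.numeric(counts_t1), 5L, 5L) +
      matrix(as.numeric(counts_t2), 5L, 5L)
    dimnames(pooled) <- list(.STATES, .STATES)
    estimate_matrix(pooled, zero_row)
  }
}

#' Repair a near-stochastic matrix quoted at limited precision
#'
#' Ingests transition matrices transcribed from reports, where entries are
#' rounded (typically to 2 decimal places) and occasionally one entry per
#' row is unavailable or inconsistent. Per row: exactly one `NA` entry is
#' replaced by its unit-row-sum complement (clamped at 0); a fully
#' specified row whose sum deviates from 1 by no more than `tolerance` is
#' rescaled; a larger deviation is an error naming the offending rows.
#' Every change is recorded in the returned repair log.
#'
#' @param P 5x5 numeric matrix in state order (D, L, H, O, N), possibly
#'   containing `NA` entries (at most one per row).
#' @param tolerance Maximum tolerated row-sum deviation for rescaling
#'   (default 0.01, half a unit in the second decimal place on a 5-entry
#'   row).
#' @return A [canonical_amc()] whose `repair_log` lists each repaired row.
#' @examples
#' ref_R <- matrix(c(0.07, 0.17, 0.02, NA, 0.05, 0), 3, 2, byrow = TRUE)
#' ref_Q <- matrix(c(0.24, 0.14, 0.38, 0.12, 0.22, 0.55, 0.19, 0.13, 0.63),
#'                 3, 3, byrow = TRUE)
#' P <- rbind(cbind(diag(2), matrix(0, 2, 3)), cbind(ref_R, ref_Q))
#' repair_matrix(P)$R # OPD-to-Left completed as 0.09
#' @export
repair_matrix <- function(P, tolerance = 0.01) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(5L, 5L))) stop("P must be a 5x5 matrix")
  dimnames(P) <- list(.STATES, .STATES)
  log_rows <- list()
  offending <- character(0)
  for (i in seq_len(5L)) {
    nas <- which(is.na(P[i, ]))
    if (length(nas) > 1L) {
      stop("row ", .STATES[i], " has ", length(nas),
           " unspecified entries; at most one is repairable")
    }
    if (length(nas) == 1L) {
      comp <- max(0, 1 - sum(P[i, -nas]))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        row = .STATES[i], column = .STATES[nas], action = "complement",
        value = comp, stringsAsFactors = FALSE)
      P[i, nas] <- comp
    }
    s <- sum(P[i, ])
    if (abs(s - 1) > 1e-9) {
      if (abs(s - 1) <= tolerance) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          row = .STATES[i], column = "*", action = "rescale",
          value = s, stringsAsFactors = FALSE)
        P[i, ] <- P[i, ] / s
      } else {
        offending <- c(offending, sprintf("%s (sum %.4f)", .STATES[i], s))
      }
    }
  }
  if (length(offending)) {
    stop("rows deviate from unit sum by more than tolerance = ", tolerance,
         ": ", paste(offending, collapse = ", "))
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(row = character(), column = character(), action = character(),
               value = numeric(), stringsAsFactors = FALSE)
  canonical_amc(P = P, repair_log = log_df)
}

#' Write / read a canonical transition matrix as JSON
#'
#' Serializes the blocks `R` and `Q`, the state order, and any repair log,
#' plus free-form metadata. `read_model` re-validates on load.
#'
#' @param model A [canonical_amc()] (or object coercible to one).
#' @param path File path.
#' @param metadata Optional named list stored verbatim.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `canonical_amc`.
#' @export
write_model <- function(model, path, metadata = NULL) {
  model <- as_canonical_amc(model)
  payload <- list(states = model$states,
                  R = unname(model$R), Q = unname(model$Q),
                  repair_log = model$repair_log, metadata = metadata)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(j$states), .STATES)) {
    stop("model file states must be D, L, H, O, N in order")
  }
  rl <- j$repair_log
  if (!is.null(rl) && !nrow(as.data.frame(rl))) rl <- NULL
  canonical_amc(R = matrix(unlist(j$R), 3L, 2L, byrow = !is.matrix(j$R)),
                Q = matrix(unlist(j$Q), 3L, 3L, byrow = !is.matrix(j$Q)),
                repair_log = if (is.null(rl)) NULL else as.data.frame(rl))
}
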