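#' Assign cycle-indexed health states to a cohort
#'
#' Discretizes each patient's event history into consecutive half-open
#' 4-calendar-month windows from their baseline assessment and assigns one
#' of five mutually exclusive states per cycle:
#'
#' * `D` (Dead) if the death date falls in or before the window's end —
#'   death takes precedence over any other event in the same window and is
#'   absorbing;
#' * `H` (Hosp) if at least one heart failure hospitalization falls in the
#'   window (with or without a clinic visit);
#' * `O` (OPD) if at least one clinic visit falls in the window without an
#'   admission or death;
#' * `N` (NoEvent) if the window is event-free but some event of any kind
#'   occurs in a later window — temporary non-attendance;
#' * `L` (Left) if the window and all later follow-up are event-free and the
#'   patient is alive: disengagement from the service, absorbing and
#'   backdated to the first fully event-free cycle.
#'
#' Windows whose end crosses the study end date are administratively
#' censored (`NA`), except that death, once dated, determines the state of
#' every later cycle.
#'
#' @param cohort An [hf_cohort()].
#' @param K Number of cycles to assign; defaults to the maximum number of
#'   complete cycles over the cohort.
#' @param cycle_length Cycle length in calendar months (default 4).
#' @return An object of class `state_seq`: list with `states` (character
#'   matrix, patients x `K`, `NA` = censored), `patient_id`, `n_complete`
#'   (complete cycles within the administrative window, per patient), `K`
#'   and `cycle_length`.
#' @examples
#' coh <- simulate_cohort(chf_reference()$model, 50, seed = 7)
#' s <- assign_states(coh, K = 6)
#' table(s$states[, 1])
#' @export
assign_states <- function(cohort, K = NULL, cycle_length = 4L) {
  stopifnot(inherits(cohort, "hf_cohort"))
  p <- cohort$patients
  ev <- cohort$events
  n <- nrow(p)
  n_complete <- if (n) {
    months_between(p$baseline_date, cohort$study_end_date) %/% cycle_length
  } else integer(0)
  if (is.null(K)) K <- max(n_complete, 0L)
  K <- as.integer(K)
  if (n == 0L || K < 1L) {
    return(structure(list(states = matrix(NA_character_, n, max(K, 0L)),
                          patient_id = p$patient_id,
                          n_complete = n_complete, K = max(K, 0L),
                          cycle_length = cycle_length),
                     class = "state_seq"))
  }

  idx <- match(ev$patient_id, p$patient_id)
  ecyc <- if (nrow(ev)) {
    months_between(p$baseline_date[idx], ev$date) %/% cycle_length + 1L
  } else integer(0)

  S <- matrix(NA_character_, n, K)
  sel <- which(ev$event_kind == "clinic_visit" & ecyc <= K)
  S[cbind(idx[sel], ecyc[sel])] <- "O"
  sel <- which(ev$event_kind == "hf_hospitalization" & ecyc <= K)
  S[cbind(idx[sel], ecyc[sel])] <- "H"

  dcyc <- rep(NA_integer_, n)
  dsel <- which(ev$event_kind == "death")
  dcyc[idx[dsel]] <- ecyc[dsel]

  # last cycle containing any event (death included), counting events beyond K
  lastc <- rep(0L, n)
  if (nrow(ev)) {
    agg <- tapply(ecyc, idx, max)
    lastc[as.integer(names(agg))] <- as.integer(agg)
  }

  has_death <- !is.na(dcyc)
  for (k in seq_len(K)) {
    S[has_death & dcyc <= k, k] <- "D"
    undef <- is.na(S[, k])
    S[undef & lastc > k, k] <- "N"
    S[undef & lastc <= k, k] <- "L"
    # administrative censoring: incomplete windows are excluded, but death
    # (dated on or before the window end) still determines the state
    cens <- k > n_complete & S[, k] != "D"
    S[cens, k] <- NA_character_
  }
  colnames(S) <- paste0("cycle", seq_len(K))
  structure(list(states = S, patient_id = p$patient_id,
                 n_complete = n_complete, K = K, cycle_length = cycle_length),
            class = "state_seq")
}

#' @export
print.state_seq <- function(x, ...) {
  cat("<state_seq> ", length(x$patient_id), " patients x ", x$K,
      " cycles (", x$cycle_length, "-month)\n", sep = "")
  if (x$K >= 1L && length(x$patient_id)) {
    tab <- table(factor(x$states[, min(x$K, 1L)], levels = .STATES))
    cat("cycle 1: ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify patients into diagnostic categories
#'
#' Applies the LVEF / NT-proBNP classification for suspected heart failure:
#' LVEF <= 40% is HeFREF regardless of NT-proBNP; otherwise NT-proBNP >= 400
#' ng/L is HeFPEF (>= 400), 125-399 ng/L is HeFPEF (125-399), < 125 ng/L is
#' a control, and an absent NT-proBNP result leaves the diagnosis uncertain
#' (NoNTproBNP). Patients without a baseline LVEF cannot be classified and
#' are returned as `NA` with a warning (an exclusion signal, not a
#' category).
#'
#' @param lvef_percent Numeric vector of LVEF values (%); `NA` = missing.
#' @param ntprobnp_ng_per_l Numeric vector of NT-proBNP values (ng/L);
#'   `NA` = no result.
#' @return Factor with levels `HeFREF`, `HeFPEF_ge400`, `HeFPEF_125_399`,
#'   `Control`, `NoNTproBNP`.
#' @examples
#' classify_diagnosis(c(33, 55, 55, 40), c(1752, 60, NA, NA))
#' @export
classify_diagnosis <- function(lvef_percent, ntprobnp_ng_per_l = NULL) {
  n <- length(lvef_percent)
  if (is.null(ntprobnp_ng_per_l)) ntprobnp_ng_per_l <- rep(NA_real_, n)
  if (length(ntprobnp_ng_per_l) != n) {
    stop("'lvef_percent' and 'ntprobnp_ng_per_l' lengths differ")
  }
  out <- rep(NA_character_, n)
  has_l <- !is.na(lvef_percent)
  out[has_l & lvef_percent <= 40] <- "HeFREF"
  pef <- has_l & lvef_percent > 40
  bnp <- ntprobnp_ng_per_l
  out[pef & !is.na(bnp) & bnp >= 400] <- "HeFPEF_ge400"
  out[pef & !is.na(bnp) & bnp >= 125 & bnp < 400] <- "HeFPEF_125_399"
  out[pef & !is.na(bnp) & bnp < 125] <- "Control"
  out[pef & is.na(bnp)] <- "NoNTproBNP"
  if (any(!has_l)) {
    warning(sum(!has_l), " patient(s) without LVEF cannot be classified (NA)")
  }
  factor(out, levels = c("HeFREF", "HeFPEF_ge400", "HeFPEF_125_399",
                         "Control", "NoNTproBNP"))
}

#' Write / read state sequences as CSV
#'
#' Long format: one row per patient-cycle with columns `patient_id`,
#' `cycle_index` (1-based), `state` (one of `D,L,H,O,N`, empty when
#' censored) and `censored` flag.
#'
#' @param sequences A `state_seq` from [assign_states()].
#' @param path File path.
#' @return `write_states` returns `path` invisibly; `read_states` a
#'   `state_seq`.
#' @export
write_states <- function(sequences, path) {
  stopifnot(inherits(sequences, "state_seq"))
  n <- length(sequences$patient_id)
  df <- data.frame(patient_id = rep(sequences$patient_id, each = sequences$K),
                   cycle_index = rep(seq_len(sequences$K), times = n),
                   state = as.vector(t(sequences$states)),
                   stringsAsFactors = FALSE)
  df$censored <- is.na(df$state)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character"))
  bad <- !df$state %in% .STATES & !(is.na(df$state) | df$state == "")
  if (any(bad)) {
    stop("line ", which(bad)[1L] + 1L, ": unknown state '",
         df$state[which(bad)[1L]], "'")
  }
  pid <- unique(df$patient_id)
  K <- max(df$cycle_index)
  S <- matrix(NA_character_, length(pid), K,
              dimnames = list(NULL, paste0("cycle", seq_len(K))))
  st <- df$state
  st[st == "" | df$censored] <- NA_character_
  S[cbind(match(df$patient_id, pid), df$cycle_index)] <- st
  n_complete <- apply(S, 1L, function(r) {
    nc <- which(is.na(r))
    if (!length(nc)) K else min(nc) - 1L
  })
  structure(list(states = S, patient_id = pid,
                 n_complete = as.integer(n_complete), K = K,
                 cycle_length = 4L),
            class = "state_seq")
}
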