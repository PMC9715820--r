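#' Construct a patient cohort of dated events
#'
#' A cohort bundles one row per patient (baseline assessment date and
#' baseline covariates) with a long table of dated events and a common
#' administrative study end date. The baseline assessment itself counts as a
#' clinic contact and is not repeated in the event table.
#'
#' @param patients data.frame with columns `patient_id`, `baseline_date`
#'   (Date), and optionally `age_years`, `sex` (`"male"`/`"female"`),
#'   `lvef_percent`, `ntprobnp_ng_per_l`. Missing covariate columns are
#'   filled with `NA`.
#' @param events data.frame with columns `patient_id`, `date` (Date) and
#'   `event_kind`, one of `"clinic_visit"`, `"hf_hospitalization"`,
#'   `"death"`. May have zero rows.
#' @param study_end_date Date; administrative end of follow-up, shared by
#'   the whole cohort.
#'
#' @details Validation enforces the event-log invariants: every event
#' belongs to a known patient, event dates lie in
#' `[baseline_date, study_end_date]`, each patient has at most one death and
#' the death is their last event.
#'
#' @return An object of class `hf_cohort`: a list with elements `patients`,
#'   `events` (sorted by patient then date) and `study_end_date`.
#' @seealso [simulate_cohort()], [read_cohort()], [assign_states()]
#' @export
hf_cohort <- function(patients, events = NULL, study_end_date) {
  stopifnot(is.data.frame(patients))
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), date = as.Date(character()),
                         event_kind = character(), stringsAsFactors = FALSE)
  }
  study_end_date <- as.Date(study_end_date)
  if (length(study_end_date) != 1L || is.na(study_end_date)) {
    stop("'study_end_date' must be a single valid date")
  }
  req <- c("patient_id", "baseline_date")
  if (!all(req %in% names(patients))) {
    stop("'patients' needs columns: ", paste(req, collapse = ", "))
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$baseline_date <- as.Date(patients$baseline_date)
  for (cv in c("age_years", "lvef_percent", "ntprobnp_ng_per_l")) {
    if (is.null(patients[[cv]])) patients[[cv]] <- rep(NA_real_, nrow(patients))
  }
  if (is.null(patients$sex)) patients$sex <- rep(NA_character_, nrow(patients))
  patients$sex <- as.character(patients$sex)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in 'patients'")
  }
  if (any(is.na(patients$baseline_date))) stop("missing baseline_date")
  if (any(patients$baseline_date > study_end_date)) {
    stop("baseline_date after study_end_date")
  }

  events$patient_id <- as.character(events$patient_id)
  events$date <- as.Date(events$date)
  events$event_kind <- as.character(events$event_kind)
  bad_kind <- setdiff(unique(events$event_kind),
                      c("clinic_visit", "hf_hospitalization", "death"))
  if (length(bad_kind)) stop("unknown event_kind: ", paste(bad_kind, collapse = ", "))
  idx <- match(events$patient_id, patients$patient_id)
  if (anyNA(idx)) {
    stop("events refer to unknown patient_id: ",
         paste(unique(events$patient_id[is.na(idx)]), collapse = ", "))
  }
  if (any(is.na(events$date))) stop("missing event date")
  if (any(events$date < patients$baseline_date[idx])) {
    bad <- events$patient_id[events$date < patients$baseline_date[idx]]
    stop("event before baseline for patient(s): ", paste(unique(bad), collapse = ", "))
  }
  if (any(events$date > study_end_date)) stop("event after study_end_date")
  is_death <- events$event_kind == "death"
  if (any(is_death)) {
    ndeath <- table(events$patient_id[is_death])
    if (any(ndeath > 1L)) {
      stop("more than one death event for patient(s): ",
           paste(names(ndeath)[ndeath > 1L], collapse = ", "))
    }
    dd <- setNames(events$date[is_death], events$patient_id[is_death])
    later <- !is_death & !is.na(dd[events$patient_id]) &
      events$date > dd[events$patient_id]
    if (any(later)) {
      stop("event after death for patient(s): ",
           paste(unique(events$patient_id[later]), collapse = ", "))
    }
  }
  ord <- order(idx, events$date, events$event_kind)
  events <- events[ord, c("patient_id", "date", "event_kind"), drop = FALSE]
  rownames(events) <- NULL
  rownames(patients) <- NULL
  structure(list(patients = patients, events = events,
                 study_end_date = study_end_date),
            class = "hf_cohort")
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat("<hf_cohort> ", nrow(x$patients), " patients, ", nrow(x$events),
      " events, study end ", format(x$study_end_date), "\n", sep = "")
  invisible(x)
}

#' Baseline covariate distributions for the synthetic generator
#'
#' Marginal distributions used by [simulate_cohort()] to draw baseline
#' covariates, parameterized to resemble an elderly chronic heart failure
#' clinic population: age roughly normal around the mid-70s, a small male
#' excess, LVEF spread across preserved and reduced function, and NT-proBNP
#' approximately log-normal with a configurable assay missingness fraction.
#'
#' @param age_mean,age_sd,age_min,age_max Age (years): normal mean/sd and
#'   truncation bounds.
#' @param male_frac Proportion of male patients.
#' @param lvef_mean,lvef_sd,lvef_min,lvef_max LVEF (%): normal mean/sd and
#'   truncation bounds.
#' @param lvef_missing Fraction of patients with missing LVEF (default 0:
#'   patients without a baseline LVEF are excluded upstream of modelling).
#' @param ntprobnp_meanlog,ntprobnp_sdlog NT-proBNP (ng/L) log-normal
#'   parameters.
#' @param ntprobnp_missing Bernoulli fraction of patients with no NT-proBNP
#'   result (default 0.15, emulating introduction of the assay mid-study).
#' @return A list of class `cov_spec`.
#' @export
cov_spec <- function(age_mean = 73.5, age_sd = 10.5, age_min = 18, age_max = 102,
                     male_frac = 0.58,
                     lvef_mean = 47, lvef_sd = 14, lvef_min = 10, lvef_max = 78,
                     lvef_missing = 0,
                     ntprobnp_meanlog = 6.68, ntprobnp_sdlog = 1.7,
                     ntprobnp_missing = 0.15) {
  spec <- list(age_mean = age_mean, age_sd = age_sd, age_min = age_min,
               age_max = age_max, male_frac = male_frac, lvef_mean = lvef_mean,
               lvef_sd = lvef_sd, lvef_min = lvef_min, lvef_max = lvef_max,
               lvef_missing = lvef_missing,
               ntprobnp_meanlog = ntprobnp_meanlog,
               ntprobnp_sdlog = ntprobnp_sdlog,
               ntprobnp_missing = ntprobnp_missing)
  stopifnot(spec$male_frac >= 0, spec$male_frac <= 1,
            spec$ntprobnp_missing >= 0, spec$ntprobnp_missing <= 1,
            spec$lvef_missing >= 0, spec$lvef_missing <= 1)
  class(spec) <- "cov_spec"
  spec
}

.draw_covariates <- function(n, spec) {
  age <- round(pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd),
                         spec$age_min), spec$age_max), 1)
  sex <- ifelse(runif(n) < spec$male_frac, "male", "female")
  lvef <- round(pmin(pmax(rnorm(n, spec$lvef_mean, spec$lvef_sd),
                          spec$lvef_min), spec$lvef_max))
  if (spec$lvef_missing > 0) {
    lvef[runif(n) < spec$lvef_missing] <- NA_real_
  }
  bnp <- round(rlnorm(n, spec$ntprobnp_meanlog, spec$ntprobnp_sdlog))
  bnp[runif(n) < spec$ntprobnp_missing] <- NA_real_
  data.frame(age_years = age, sex = sex, lvef_percent = lvef,
             ntprobnp_ng_per_l = bnp, stringsAsFactors = FALSE)
}

# Draw next states for current states `st` (integer codes) under cumulative
# row matrix `cp` (5x5, rows cumulative probabilities).
.step_states <- function(st, cp) {
  u <- runif(length(st))
  1L + rowSums(matrix(u, length(st), 5L) > cp[st, , drop = FALSE])
}

#' Simulate a synthetic cohort from a ground-truth absorbing chain
#'
#' Generates reproducible registry-style event logs whose latent cycle-state
#' dynamics follow a known absorbing Markov chain. Every patient starts with
#' a baseline clinic assessment in the OPD state; the latent state path is
#' then drawn cycle by cycle from the ground-truth chain until an absorbing
#' state (Dead or Left) is reached, and each latent state is realized as a
#' dated event strictly inside its 4-month window (Hosp: one hospitalization,
#' OPD: one clinic visit, Dead: one death; NoEvent and Left leave no trace).
#'
#' @param model Ground-truth chain: a [canonical_amc()] object, a fitted
#'   [fit_amc()] model, or a 5x5 canonical transition matrix.
#' @param n_patients Number of patients (>= 1).
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @param horizon_cycles Minimum number of complete 4-month cycles every
#'   patient is observed for (>= 3). The study end date is placed so that
#'   both this horizon and every patient's absorption cycle fall inside
#'   complete windows.
#' @param first_transition Optional 5-vector of state probabilities for the
#'   first transition (baseline to cycle 1). When supplied, cycle 1 is drawn
#'   from it instead of the chain's OPD row — this is how a two-phase model
#'   (separate first-transition distribution, common later dynamics) is
#'   emulated. Must be nonnegative and sum to 1 within 1e-9.
#' @param covariates A [cov_spec()] describing baseline covariate marginals.
#' @param strata Optional list coupling covariates to different ground-truth
#'   chains for subgroup studies. Each element is a list with components
#'   `p` (sampling proportion), `model` (chain for that stratum) and
#'   optionally `covariates` (a [cov_spec()] override) and `label`. The
#'   proportions must sum to 1.
#' @param enrol_start,enrol_days Baseline dates are drawn uniformly from
#'   `enrol_start` over `enrol_days` days.
#' @param cycle_length Cycle length in calendar months (default 4).
#' @param max_cycles Safety cap on the latent simulation length; patients
#'   not absorbed by then (vanishingly rare for any chain with certain
#'   absorption) are truncated with a warning.
#'
#' @return An `hf_cohort`. The latent state paths are attached as attribute
#'   `"latent"` (a character matrix, patients x cycles, states repeated after
#'   absorption) and the stratum assignment as attribute `"stratum"`; these
#'   are simulation ground truth, not observables, and are not written by
#'   [write_cohort()].
#' @examples
#' ref <- chf_reference()
#' coh <- simulate_cohort(ref$model, 200, seed = 1)
#' coh
#' @export
simulate_cohort <- function(model, n_patients, seed = NULL,
                            horizon_cycles = 12L, first_transition = NULL,
                            covariates = cov_spec(), strata = NULL,
                            enrol_start = as.Date("2000-01-01"),
                            enrol_days = 365L, cycle_length = 4L,
                            max_cycles = 500L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stop("'n_patients' must be >= 1")
  horizon_cycles <- as.integer(horizon_cycles)
  if (is.na(horizon_cycles) || horizon_cycles < 3L) {
    stop("'horizon_cycles' must be >= 3")
  }
  if (!is.null(first_transition)) {
    first_transition <- as.numeric(first_transition)
    if (length(first_transition) != 5L || any(first_transition < 0) ||
        abs(sum(first_transition) - 1) > 1e-9) {
      stop("'first_transition' must be a nonnegative 5-vector summing to 1")
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(strata)) {
    strata <- list(list(p = 1, model = model, covariates = covariates,
                        label = "all"))
  }
  pr <- vapply(strata, function(s) as.numeric(s$p), numeric(1))
  if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
    stop("stratum proportions must be nonnegative and sum to 1")
  }
  cps <- lapply(strata, function(s) {
    m <- as_canonical_amc(if (is.null(s$model)) model else s$model)
    t(apply(m$P, 1L, cumsum))
  })
  labels <- vapply(seq_along(strata), function(i) {
    if (is.null(strata[[i]]$label)) paste0("stratum", i) else
      as.character(strata[[i]]$label)
  }, character(1))

  stratum <- sample.int(length(strata), n_patients, replace = TRUE, prob = pr)

  baseline <- enrol_start + floor(runif(n_patients) * max(1L, enrol_days))
  covs <- .draw_covariates(n_patients, covariates)
  for (i in seq_along(strata)) {
    ov <- strata[[i]]$covariates
    if (!is.null(ov) && any(stratum == i)) {
      sel <- which(stratum == i)
      covs[sel, ] <- .draw_covariates(length(sel), ov)
    }
  }

  # Latent path: start in OPD at cycle 0, step until absorbed.
  state <- rep(4L, n_patients) # O
  absorbed_at <- rep(NA_integer_, n_patients)
  path_cols <- vector("list", 0L)
  k <- 0L
  cp_first <- if (!is.null(first_transition)) {
    matrix(cumsum(first_transition), 1L, 5L)
  } else NULL
  while (anyNA(absorbed_at) && k < max_cycles) {
    k <- k + 1L
    active <- which(is.na(absorbed_at))
    if (k == 1L && !is.null(cp_first)) {
      u <- runif(length(active))
      nxt <- 1L + rowSums(matrix(u, length(active), 5L) >
                            cp_first[rep(1L, length(active)), , drop = FALSE])
    } else {
      nxt <- integer(length(active))
      for (i in seq_along(strata)) {
        sel <- stratum[active] == i
        if (any(sel)) nxt[sel] <- .step_states(state[active[sel]], cps[[i]])
      }
    }
    state[active] <- nxt
    newly <- active[nxt <= 2L]
    absorbed_at[newly] <- k
    path_cols[[k]] <- state
  }
  if (anyNA(absorbed_at)) {
    warning(sum(is.na(absorbed_at)), " patient(s) not absorbed within ",
            max_cycles, " cycles; truncating their latent paths")
    absorbed_at[is.na(absorbed_at)] <- k
  }
  latent <- matrix(.STATES[do.call(cbind, path_cols)], n_patients, k,
                   dimnames = list(NULL, paste0("cycle", seq_len(k))))

  # Events: one per realized H/O/D cycle, dated uniformly strictly inside
  # the half-open window (never on a boundary) so reconstruction is exact.
  pid <- sprintf("P%06d", seq_len(n_patients))
  a <- absorbed_at
  pid_long <- rep(seq_len(n_patients), a)
  cyc_long <- sequence(a)
  st_long <- match(latent[cbind(pid_long, cyc_long)], .STATES)
  keep <- st_long %in% c(1L, 3L, 4L)
  pid_long <- pid_long[keep]; cyc_long <- cyc_long[keep]
  st_long <- st_long[keep]
  kind <- c("death", NA, "hf_hospitalization", "clinic_visit", NA)[st_long]
  wstart <- add_months(baseline[pid_long], cycle_length * (cyc_long - 1L))
  wend <- add_months(baseline[pid_long], cycle_length * cyc_long)
  ndays <- as.integer(wend - wstart)
  offset <- 1L + as.integer(floor(runif(length(ndays)) * (ndays - 1L)))
  events <- data.frame(patient_id = pid[pid_long], date = wstart + offset,
                       event_kind = kind, stringsAsFactors = FALSE)

  need_cycles <- pmax(a, horizon_cycles)
  study_end <- max(add_months(baseline, cycle_length * need_cycles))

  patients <- data.frame(patient_id = pid, baseline_date = baseline,
                         covs, stringsAsFactors = FALSE)
  coh <- hf_cohort(patients, events, study_end)
  attr(coh, "latent") <- latent
  attr(coh, "stratum") <- labels[stratum]
  attr(coh, "config") <- list(n_patients = n_patients, seed = seed,
                              horizon_cycles = horizon_cycles,
                              first_transition = first_transition,
                              cycle_length = cycle_length)
  coh
}

#' Write / read a cohort as delimited text
#'
#' The on-disk format is a CSV with one baseline row per patient followed by
#' one row per event, preceded by a single comment line carrying the study
#' end date: `# study_end_date: YYYY-MM-DD`. Columns are `patient_id`,
#' `row_type` (`baseline`/`event`), `date` (ISO-8601), `event_kind`,
#' `age_years`, `sex`, `lvef_percent`, `ntprobnp_ng_per_l`; covariates are
#' only populated on baseline rows. The round trip
#' `read_cohort(write_cohort(x))` is lossless on all fields (simulation-only
#' attributes such as the latent paths are not serialized).
#'
#' @param cohort An `hf_cohort`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `hf_cohort`. Malformed rows abort with an error naming the offending
#'   file line.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hf_cohort"))
  p <- cohort$patients
  base <- data.frame(patient_id = p$patient_id,
                     row_type = rep("baseline", nrow(p)),
                     date = format(p$baseline_date),
                     event_kind = rep(NA_character_, nrow(p)),
                     age_years = p$age_years, sex = p$sex,
                     lvef_percent = p$lvef_percent,
                     ntprobnp_ng_per_l = p$ntprobnp_ng_per_l,
                     stringsAsFactors = FALSE)
  ev <- cohort$events
  evd <- data.frame(patient_id = ev$patient_id,
                    row_type = rep("event", nrow(ev)),
                    date = format(ev$date), event_kind = ev$event_kind,
                    age_years = rep(NA_real_, nrow(ev)),
                    sex = rep(NA_character_, nrow(ev)),
                    lvef_percent = rep(NA_real_, nrow(ev)),
                    ntprobnp_ng_per_l = rep(NA_real_, nrow(ev)),
                    stringsAsFactors = FALSE)
  df <- rbind(base, evd)
  df <- df[order(match(df$patient_id, p$patient_id),
                 df$row_type != "baseline", df$date), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# study_end_date: %s", format(cohort$study_end_date)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# study_end_date: ", lines[1L])) {
    stop("line 1: expected '# study_end_date: YYYY-MM-DD' header comment")
  }
  study_end <- as.Date(sub("^# study_end_date: ", "", lines[1L]))
  if (is.na(study_end)) stop("line 1: unparseable study_end_date")
  df <- read.csv(textConnection(lines[-1L]), stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", row_type = "character",
                                date = "character", event_kind = "character",
                                age_years = "numeric", sex = "character",
                                lvef_percent = "numeric",
                                ntprobnp_ng_per_l = "numeric"))
  lineno <- seq_len(nrow(df)) + 2L # 1 comment line + 1 header line
  fail <- function(i, msg) stop(sprintf("line %d: %s", lineno[i], msg))
  bad <- which(!df$row_type %in% c("baseline", "event"))
  if (length(bad)) fail(bad[1L], paste0("unknown row_type '", df$row_type[bad[1L]], "'"))
  dt <- as.Date(df$date)
  bad <- which(is.na(dt))
  if (length(bad)) fail(bad[1L], "unparseable date")
  is_base <- df$row_type == "baseline"
  bl_rows <- which(is_base)
  if (anyDuplicated(df$patient_id[bl_rows])) {
    i <- bl_rows[duplicated(df$patient_id[bl_rows])][1L]
    fail(i, paste0("duplicate baseline row for patient ", df$patient_id[i]))
  }
  baseline <- setNames(dt[bl_rows], df$patient_id[bl_rows])
  ev_rows <- which(!is_base)
  if (length(ev_rows)) {
    unknown <- ev_rows[!df$patient_id[ev_rows] %in% names(baseline)]
    if (length(unknown)) {
      fail(unknown[1L], paste0("event for patient ", df$patient_id[unknown[1L]],
                               " without a baseline row"))
    }
    bad <- ev_rows[!df$event_kind[ev_rows] %in%
                     c("clinic_visit", "hf_hospitalization", "death")]
    if (length(bad)) fail(bad[1L], paste0("unknown event_kind '",
                                          df$event_kind[bad[1L]], "'"))
    early <- ev_rows[dt[ev_rows] < baseline[df$patient_id[ev_rows]]]
    if (length(early)) {
      fail(early[1L], paste0(df$event_kind[early[1L]], " dated before baseline"))
    }
    late <- ev_rows[dt[ev_rows] > study_end]
    if (length(late)) fail(late[1L], "event after study_end_date")
    deaths <- ev_rows[df$event_kind[ev_rows] == "death"]
    if (anyDuplicated(df$patient_id[deaths])) {
      i <- deaths[duplicated(df$patient_id[deaths])][1L]
      fail(i, "second death event for one patient")
    }
  }
  patients <- data.frame(patient_id = df$patient_id[bl_rows],
                         baseline_date = dt[bl_rows],
                         age_years = df$age_years[bl_rows],
                         sex = df$sex[bl_rows],
                         lvef_percent = df$lvef_percent[bl_rows],
                         ntprobnp_ng_per_l = df$ntprobnp_ng_per_l[bl_rows],
                         stringsAsFactors = FALSE)
  patients$sex[patients$sex %in% ""] <- NA_character_
  events <- data.frame(patient_id = df$patient_id[ev_rows],
                       date = dt[ev_rows],
                       event_kind = df$event_kind[ev_rows],
                       stringsAsFactors = FALSE)
  hf_cohort(patients, events, study_end)
}
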