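#' Reference chronic heart failure chain shipped with the package
#'
#' Loads the package's built-in reference model: five-state transition
#' blocks for a large chronic heart-failure clinic population assessed at
#' 4-month intervals, quoted to 2 decimal places, together with the
#' observed first-transition tally (n = 7496) and the observed per-cycle
#' state distributions for cycles 1-5. The OPD-to-Left transition
#' probability is not usable as quoted (it breaks the unit row sum) and is
#' completed by its unit-row-sum complement (0.09) via [repair_matrix()];
#' the repair is recorded in the returned model's repair log.
#'
#' @return A list of class `chf_reference` with elements:
#'   \describe{
#'     \item{model}{the repaired [canonical_amc()];}
#'     \item{first_transition_counts}{named integer 5-vector of observed
#'       cycle-1 states;}
#'     \item{first_transition}{the same as probabilities;}
#'     \item{observed}{an `amc_trajectory` of observed distributions,
#'       cycles 1-5.}
#'   }
#' @examples
#' ref <- chf_reference()
#' ref$model
#' round(absorption_probabilities(ref$model), 2)
#' @export
chf_reference <- function() {
  path <- system.file("extdata", "chf_reference_model.json",
                      package = "hfamc", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- rbind(cbind(diag(2L), matrix(0, 2L, 3L)), cbind(j$R, j$Q))
  model <- repair_matrix(P)
  counts <- unlist(j$first_transition_counts)[.STATES]
  obs <- as.matrix(as.data.frame(j$observed)[, .STATES])
  rownames(obs) <- j$observed$cycle
  structure(list(model = model,
                 first_transition_counts = counts,
                 first_transition = counts / sum(counts),
                 observed = structure(list(cycles = as.integer(j$observed$cycle),
                                           dist = obs),
                                      class = "amc_trajectory")),
            class = "chf_reference")
}

#' @export
print.chf_reference <- function(x, ...) {
  cat("Reference chronic heart failure chain (4-month cycles, n = ",
      sum(x$first_transition_counts), ")\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Full analysis of the shipped reference model
#'
#' Recomputes, from the package's reference transition blocks alone, the
#' derived quantities of the reference analysis: the fundamental matrix and
#' expected cycles to absorption, the absorption-probability and limiting
#' matrices, the predicted-versus-observed table up to cycle `K`, and the
#' model survival curve out to `K_survival` cycles.
#'
#' @param K Last cycle of the prediction table (default 6).
#' @param K_survival Last cycle of the survival curve (default 9).
#' @return A list of class `reference_analysis` with elements `model`,
#'   `absorption`, `predictions`, `survival`.
#' @examples
#' ra <- reference_analysis()
#' ra$absorption
#' @export
reference_analysis <- function(K = 6L, K_survival = 9L) {
  ref <- chf_reference()
  absorption <- absorption_summary(ref$model)
  predictions <- prediction_table(ref$model, K = K, observed = ref$observed)
  d2 <- ref$observed$dist[match(2L, ref$observed$cycles), ]
  traj <- iterate_distribution(ref$model, d2, n_cycles = K_survival - 2L,
                               from_cycle = 2L)
  s_pred <- survival_curve(traj)
  surv <- c(survival_curve(ref$observed)[c("1", "2")],
            s_pred[names(s_pred) != "2"])
  structure(list(model = ref$model, absorption = absorption,
                 predictions = predictions,
                 survival = surv),
            class = "reference_analysis")
}

#' @export
print.reference_analysis <- function(x, digits = 2, ...) {
  print(x$model, digits = digits)
  cat("\n")
  print(x$absorption, digits = digits)
  cat("\n")
  print(x$predictions, digits = digits)
  cat("\nSurvival by cycle (observed cycles 1-2, model thereafter):\n")
  print(round(x$survival, digits))
  invisible(x)
}
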