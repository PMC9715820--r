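---
title: "Five-state absorbing Markov chains for heart failure service trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-state absorbing Markov chains for heart failure service trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfamc)
```

## The model

Patients referred to a heart failure service are assessed at baseline and
followed at roughly 4-month intervals. `hfamc` discretizes each patient's
follow-up into consecutive half-open windows of 4 calendar months from
their baseline date and assigns one of five mutually exclusive, exhaustive
states per cycle: Dead (`D`), Left (`L`), Hosp (`H`), OPD (`O`) and
NoEvent (`N`). `D` and `L` are absorbing — once dead or permanently
disengaged from the service, a patient stays so; `H`, `O` and `N` are
transient and freely interconnected.

The key modelling assumption is the Markov property at the cohort level:
the distribution of next-cycle states depends only on the current state,
not on how it was reached. Under it, the process is fully described by a
row-stochastic one-step transition matrix which, with absorbing states
ordered first, takes the canonical block form

$$P=\begin{pmatrix} I & 0 \\ R & Q \end{pmatrix},$$

with $Q$ the $3\times 3$ transient block and $R$ the $3\times 2$
transient-to-absorbing block. Certain absorption (spectral radius of $Q$
below 1) is enforced at validation. The derived quantities are classical:

* the fundamental matrix $F=(I-Q)^{-1}$, whose $(i,j)$ entry is the
  expected number of cycles spent in transient state $j$ before absorption
  starting from $i$, with row sums the expected total time in the system;
* the absorption-probability matrix $B=FR$ (columns: death vs
  disengagement), embedded in the limiting matrix $\bar P$;
* forward marginals $d_k = d_{k_0} P^{\,k-k_0}$ for predicting the
  cohort's state distribution at later cycles.

$F$ and $B$ are computed by linear solves of $(I-Q)$ rather than explicit
inversion; the exposed contract (matrices) is unchanged.

## Estimation: why only the first two transitions

The fitted chain deliberately uses the first 8 months of follow-up only.
Transition 1 (baseline to cycle 1) is special: every patient starts in the
OPD pseudo-state because the baseline assessment is itself a clinic
contact, so transition-1 counts populate a single origin row. It therefore
cannot identify the full matrix, and serves instead as the initial state
distribution. Transition 2 (cycle 1 to cycle 2) is the first one with all
five origin states populated, and the default model (`pooling = "second"`)
is its row-normalized maximum-likelihood estimate. A `"pooled"` variant
sums both count matrices first, which amounts to a row-count-weighted
average of the two per-transition estimates; it is provided for
sensitivity analysis but is not the default, because only the
transition-2 construction reproduces the packaged reference predictions.

Predictions start from the *observed* cycle-2 distribution, not from a
modelled one: the model is built from cycles 1–2 and makes no prediction
for them, and iterating from the observed cycle 2 is the construction
consistent with that statement. Signed errors are predicted minus
observed, so negative values mean underestimation.

Transient origin rows with zero observations are an error by default; the
optional `zero_row = "self_loop"` policy substitutes a unit self-loop with
a warning and flags that the estimated chain no longer guarantees
absorption. Absorbing rows are always forced to exact unit vectors, and
every estimated row sums to 1 exactly after normalization. Full precision
is kept internally everywhere; 2-decimal rounding (half away from zero)
happens only in print methods.

## The state engine's edge rules

The event-log-to-state mapping has several corners the data do not decide
by themselves; the package's choices are:

* **Half-open windows.** Cycle $k$ covers $[b+4(k-1), b+4k)$ months from
  baseline $b$; a boundary-dated event belongs to the later cycle, so no
  event can be counted twice. Calendar-month arithmetic clamps day-of-month
  overflow to the month end.
* **Within-cycle precedence `D > H > O`.** OPD explicitly excludes
  admission and death; hospitalization does not exclude death, so death
  dominates to keep states exclusive. State assignment is invariant to the
  ordering of events inside one window.
* **`N` versus `L`.** Both are service-free cycles; they differ only in
  retrospect. A cycle is `N` when *any* later event (including death)
  exists before the study end, and `L` otherwise — so `L` is backdated to
  the first fully event-free cycle with no later events, and a patient who
  dies after a gap has `N` cycles in the gap, never `L`.
* **Administrative censoring.** Cycles whose window crosses the study end
  date are marked censored (`NA`) and excluded from transition counts and
  observed distributions, rather than being coerced to `L` — enrolment
  near the study end is not disengagement. The one exception is death:
  once dated, it determines every later cycle's state.

## The synthetic cohort generator

The generator emulates the structure of a long-running clinic registry:
baseline dates drawn over an enrolment window, baseline covariates (age,
sex, LVEF, NT-proBNP) from configurable marginals, and an event log driven
by a latent state path drawn from a ground-truth chain, starting in OPD.
Default covariate marginals describe an elderly CHF clinic population: age
$\sim N(73.5, 10.5^2)$ years (truncated 18–102), 58% male, LVEF
$\sim N(47, 14^2)$% (truncated 10–78), NT-proBNP log-normal with meanlog
6.68 and sdlog 1.7 ng/L, and a 0.15 Bernoulli missingness fraction for
NT-proBNP emulating the assay's mid-study introduction. Covariates are
drawn independently of the trajectory by default; the `strata` hook
couples covariate ranges to different ground-truth chains when subgroup
recovery is being studied (the subgroup analysis fits separate chains per
stratum rather than a covariate model, so the generator mirrors that).

Each latent `H`, `O` or `D` cycle is realized as exactly one dated event
placed uniformly *strictly inside* its window (never on a boundary), so
that reassigning states from the realized events recovers the latent path
exactly. Two design points matter for that exactness:

* Latent paths are simulated **to absorption** (capped at `max_cycles`),
  and the study end date is placed after every patient's absorption
  window, with `horizon_cycles` (default 12, i.e. the 4-year long-term
  horizon) as a guaranteed minimum of complete cycles. A patient still
  transient at the study end would leave a trailing event-free run that
  the engine must label `L`, breaking round-trip exactness; running to
  absorption removes the case.
* A direct `N`→`L` transition is inherently unidentifiable from an event
  log (an event-free gap followed by nothing looks like `L` from the gap's
  start). The reference chain has $p(N\to L)=0$, so the round trip is
  exact there; for ground truths with $p(N\to L)>0$ the reconstructed path
  backdates `L` over the final `N` run, which is the correct reading of
  the event log.

What passing the generator-based tests shows — and what it does not: the
pipeline recovers known transition structure from event logs with the
registry's *shape* (dated visits, admissions, deaths, censoring). Real
registries additionally have within-cycle event multiplicity, admissions
spanning window boundaries, coding errors and covariate-dependent
dynamics, none of which the generator emulates; one event per realized
state is sufficient for the estimator, which tolerates many.

## The packaged reference model

`chf_reference()` ships transition blocks for a large CHF clinic
population (first-transition tally 427/1842/1559/2254/1414 over
n = 7496), quoted to 2 decimal places from an external clinical analysis,
together with observed per-cycle distributions for cycles 1–5 (the source
cycle-6 row is incomplete and is not shipped). Two numerical caveats are
disclosed rather than patched over:

* The quoted OPD→Left probability (0.18) is inconsistent: it makes the
  OPD row sum to 1.09 and contradicts the quoted limiting matrix. It is
  stored as missing and completed by the unit-row-sum complement 0.09 via
  `repair_matrix()`, which logs the repair on the model object.
* Quantities derived from 2-dp inputs can differ from their quoted
  counterparts in the second decimal, because the source derived them from
  unrounded estimates. Concretely, recomputing from the quoted blocks
  gives $F_{NN}=7.03$ (quoted 7.02), an expected 10.56 cycles from `N`
  (quoted 10.55), and death-absorption probabilities 0.438/0.461/0.522
  (quoted 0.43/0.46/0.51). The package reports recomputed values at full
  precision and treats agreement within one unit in the quoted decimal as
  reproduction; the test suite asserts exactly that and deliberately
  leaves the two non-reproducible fundamental-matrix entries failing
  rather than widening the tolerance.

`repair_matrix()` more generally accepts one missing entry per row
(completed by complement, clamped at zero) or row sums within a 0.01
tolerance (rescaled); anything worse is an error naming the offending
rows, since silently normalizing a badly transcribed matrix would hide
real defects.

## Problem sizes and tolerances used in validation

Deterministic identities are checked tightly: $F(I-Q)=I$ within $10^{-10}$,
$F$ against a truncated Neumann series $\sum_k Q^k$ within $10^{-8}$, row
sums within $10^{-9}$ (the validation tolerance for stochasticity
throughout). Stochastic properties use fixed seeds and 3-standard-error
bands: first-transition frequencies at n = 7496 (the reference cohort
size), cycle-distribution laws at n = 10⁴, Monte-Carlo absorption
frequencies at 10⁵ walks per origin, and parameter recovery plus
end-to-end self-consistency (max |predicted − observed| < 0.01 over
cycles 3–6) at n = 10⁵ — sizes at which binomial error is well below the
2-dp reporting resolution while the whole suite runs in well under a
minute.

## Known limitations

* The chain is time-homogeneous beyond the two-transition construction; no
  covariate-dependent or continuous-time dynamics.
* Hospitalizations are counted in the cycle of their admission date; long
  stays spanning windows contribute once.
* No confidence intervals on transition probabilities are produced.
* Subgroup machinery covers sex and a 65-year age band; other stratifiers
  (e.g. NT-proBNP-defined phenotypes, via `classify_diagnosis()`) can be
  fitted by subsetting cohorts manually but have no packaged comparison
  surface.
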