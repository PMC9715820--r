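# hfamc — absorbing Markov chain models of chronic heart failure trajectories

Chronic heart failure (CHF) services follow large populations of patients
whose risk of death and hospitalization changes continuously with the course
of the disease. `hfamc` implements dynamic risk stratification for such
populations: instead of scoring individual patients once, it describes the
whole cohort's clinical trajectory as a discrete-time **absorbing Markov
chain (AMC)** over five mutually exclusive health states, assessed every
4 months:

| state | meaning |
|---|---|
| `D` Dead | death from any cause (absorbing) |
| `L` Left | no further service contact for the rest of follow-up, alive (absorbing) |
| `H` Hosp | at least one heart failure hospitalization in the cycle |
| `O` OPD  | an out-patient clinic visit, without admission or death |
| `N` NoEvent | a service-free cycle that is followed by a later event |

With the absorbing states ordered first, the one-step transition matrix has
the canonical block form

    P = | I  0 |
        | R  Q |

where `Q` (3×3) holds transient-to-transient and `R` (3×2)
transient-to-absorbing probabilities. The package estimates `P` from only
the **first two observed transitions** of a cohort (baseline → 4 months,
4 → 8 months) and derives the long-run behaviour analytically:

* fundamental matrix `F = (I − Q)⁻¹` — expected cycles spent in each
  transient state before absorption; row sums are expected total cycles in
  the system;
* absorption probabilities `B = F·R` — probability of ending in Dead vs
  Left from each transient state;
* forward predictions `d_k = d_2 Pᵏ⁻²` from the observed cycle-2 state
  distribution, validated cycle by cycle against the observed distributions
  (signed error = predicted − observed).

A seeded synthetic cohort generator produces registry-style event logs
(baseline assessments, dated clinic visits, hospitalizations, deaths) from
any ground-truth chain, so estimation, prediction and validation are all
testable without access to clinical data. Intended users are biostatisticians
and health-service modellers working with longitudinal event registries.

## Worked example

Simulate a 2000-patient cohort from the packaged reference chain, refit the
model from the first two transitions of the simulated event log, and
inspect what it implies:

```r
library(hfamc)

ref <- chf_reference()                       # packaged reference chain
coh <- simulate_cohort(ref$model, 2000, seed = 42,
                       first_transition = ref$first_transition)
fit <- fit_amc(coh)                          # states -> counts -> chain
fit
#> Absorbing Markov chain fitted from the first two transitions
#>   n = 2000 patients; one-step matrix from transition 2
#>   observed cycle-1 distribution (D, L, H, O, N): 0.07 0.24 0.20 0.29 0.21
#>      D    L    H    O    N
#> D 1.00 0.00 0.00 0.00 0.00
#> L 0.00 1.00 0.00 0.00 0.00
#> H 0.04 0.17 0.25 0.18 0.36
#> O 0.02 0.07 0.12 0.24 0.55
#> N 0.05 0.00 0.23 0.10 0.63

summary(fit)$absorption
#> Fundamental matrix F = (I - Q)^-1 (expected cycles in each transient state):
#>      H    O    N total
#> H 3.07 1.42 5.03  9.52
#> O 2.29 2.71 6.18 11.19
#> N 2.48 1.60 7.39 11.47
#> Absorption probabilities B = F R:
#>      D    L
#> H 0.39 0.61
#> O 0.44 0.56
#> N 0.48 0.52
```

Reading the two tables together: a patient hospitalized in their first
cycle is expected to spend about 9.5 further cycles (≈ 3 years) in the
system, and has probability 0.39 of dying (rather than disengaging) before
leaving it. The signed prediction errors on cycles 3–6 (`residuals(fit)`)
stay within ±0.03 of the observed state fractions here — the model built
from 8 months of data tracks the simulated cohort's later course closely.

`reference_analysis()` prints the same quantities computed directly from
the packaged reference transition blocks, including the predicted-vs-
observed table up to cycle 6; `fit_subgroup_models()` and
`survival_report()` repeat the pipeline by sex or 65-year age band.

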