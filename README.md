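# stemfate

Multi-scale simulation of breast stem-cell fate decision: Wnt/Notch
signaling, E-cadherin adhesion, and quorum sensing by secreted Dkk1.

## What this package is for

Mammary tissues maintain a roughly fixed fraction of stem cells (SCs) at
confluence, and modulating the signaling pathways that control SC fate —
Wnt, Notch, E-cadherin — shifts the balance between self-renewal and
differentiation. `stemfate` implements a hybrid cellular automaton (HCA)
model of this system for researchers studying density-dependent fate
control and differentiation therapy *in silico*: every stem cell on a
40 × 20 toroidal honeycomb lattice (800 sites, six neighbors each) carries
a deterministic intracellular ODE system, and discrete tissue rules couple
the cells through space.

The intracellular model tracks seven species per stem cell — secreted Dkk1
*K*, activated LEF/TCF *L*, E-cadherin *E*, proliferation factor *P*,
Notch receptor *N*, HES *H*, and differentiation factor *D* — with
saturating (Hill) regulation:

```
W      = S_w(Wnt_ext) · I_d(Dkk_ext)            Wnt signal, Dkk1-inhibited
dK/dt  = a_K(L)  − δ_K K                        Dkk1 secretion (quorum signal)
dL/dt  = W · g_E(B) − δ_L L                     LEF/TCF, adhesion-gated
dE/dt  = a_E↓(L) − δ_E E                        E-cadherin
dP/dt  = a_P(L)  − δ_P P                        proliferation factor
dN/dt  = σ_N − d_N↓(L) · N                      Notch receptor
dH/dt  = a_H(N*) − δ_H H,   N* = min(N, Σ DSL)  juxtacrine HES induction
dD/dt  = a_D↓(H) − δ_D D                        differentiation factor
```

Bound E-cadherin is `B = Σ_i κ·min(E_self, E_i)` over the six directions;
`Dkk_ext` is the exogenous bath dose plus the secreted Dkk1 of the cell
and its stem-cell neighbors (2.01 ng/mL per model unit). A cell divides
symmetrically when `P ≥ C_P`, a vacant neighbor site exists and its cell
cycle (τ = 24 h) has elapsed; it differentiates irreversibly when
`D ≥ C_M`, occupies its site for Φ = 336 h and then dies; otherwise it is
quiescent. Only stem cells secrete Dkk1, so the local secreted level is a
stem-density sensor: the feedback holds the SC fraction at confluence
(quorum sensing) and exogenous Dkk1 above a threshold concentration drives
the whole tissue into differentiation.

The simulation core is compiled (Rcpp) and mirrors a pure-R reference
implementation bit-for-bit, so full three-month tissue simulations take
about a second each.

## Worked example

Simulate the dosing experiment: 36 stem cells seeded at random, exogenous
Dkk1 applied for 48 h, three months of tissue dynamics, SC count averaged
over the last three days, 10 replicates per dose:

```r
library(stemfate)

cfg <- experiment_config(n_replicates = 10,
                         doses = c(0, 5, 9, 11, 13, 15, 17, 25),
                         master_seed = 42)
sweep <- run_dose_sweep(cfg)
detect_threshold(sweep)
#> Dkk1 dose-response threshold: 13 ng/mL (baseline 268.8 SCs)

sweep$summary
#>   dose  n  mean_sc    sd_sc   sem_sc
#> 1    0 10 268.7692 12.87481 4.071372
#> 2    5 10 273.5385 16.34442 5.168559
#> 3    9 10 280.3154 14.96608 4.732689
#> 4   11 10 275.9846 10.44177 3.301979
#> 5   13 10 292.2692 19.03836 6.020459
#> 6   15 10   0.0000  0.00000 0.000000
#> 7   17 10   0.0000  0.00000 0.000000
#> 8   25 10   0.0000  0.00000 0.000000
```

The untreated tissue settles at roughly 270–290 stem cells among 800
sites. Doses up to 13 ng/mL leave the population at baseline (low doses
can even nudge it upward); at 15 ng/mL and above every replicate loses all
stem cells — the seeded cells cannot divide under the dose, never build
Notch-mediated contact protection, and differentiate before the exposure
ends. `detect_threshold()` reports the largest dose whose mean response
stays within 95% of the untreated mean.

Oncogenic defect scenarios scale one parameter each (Notch synthesis,
ambient Wnt, or the E-cadherin inhibition half-saturation):

```r
mut <- experiment_config(n_replicates = 10, doses = 0, master_seed = 42,
                         scenario = mutation_scenario(mu_notch = 0.2))
run_dose_sweep(mut)$summary$mean_sc / sweep$summary$mean_sc[1]
#> [1] 2.976531
```

A 20% increase in Notch receptor synthesis roughly triples the steady
stem-cell pool (the 2–4-fold range holds for all three scenarios), and the
dose threshold of mutated tissue shifts upward.

Single runs, lattice snapshots and the unit calibration are available as
`run_replicate()`, `as.data.frame()` on a lattice, and
`calibrate_dkk_unit()`; a command-line wrapper lives at
`system.file("cli", "stemfate.R", package = "stemfate")` with
`simulate`, `sweep`, `threshold` and `calibrate` subcommands.

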