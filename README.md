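# mechwtd

Waiting-time distributions of critical events in simulated osteoblast
mechanotransduction.

## What this package is for

Osteoblasts sense mechanical load through membrane integrins and relay it
through the RAF–MEK–ERK cascade to RUNX2-driven gene expression and
extracellular-matrix deposition. In a stochastic, spatially resolved
simulation of that network the molecular counts fluctuate incessantly, and
the *timing pattern* of the large, abrupt fluctuations carries information
about the dynamical state of the system that mean trajectories hide.

`mechwtd` is for computational biologists who want to (a) simulate such a
network as a discrete-time agent-based model and (b) extract event-timing
statistics from any molecular count time series, simulated or otherwise.

It implements:

* **Simulator** — agents (integrin, RAF, MEK, ERK, RUNX2, ribosome, mRNA,
  vesicle, ECM protein; 8890 by default) diffusing by constrained Brownian
  motion in nested spherical compartments; nearest-partner binding within
  an interaction range R_inter; timer-driven activation cycles,
  dissociations, transcription and translation; integrin activation
  switched by a square-wave load (magnitude M, period P, baseline
  100 μPa). Counts and interaction range rescale jointly (n·R³ constant)
  so reduced-size runs preserve average binding kinetics.
* **Inversion pipeline** — each count series y(t) is treated as a
  subordinated process x(t) = x(t*(t)) whose directing process t(t*) is
  the cumulative sum of waiting times between critical events. The
  pipeline de-trends with a moving average over τ₁, measures the local
  fluctuation amplitude σ(t) over τ₂, rectifies against the Hilbert
  envelope (yIII = max(ΔyI − |H ΔyI|, 0)), detects prominent peaks and
  quiet-region boundaries, weights each signal interim period (SIP) τ by
  the amplitude of its initiating event, and smooths the weighted SIPs
  with a unit-mass Epanechnikov kernel into the normalised waiting-time
  distribution ψ(τ), with epoch-resolved variants ψ_t(τ) and replicate
  confidence bands.
* **Ground-truth generator** — forward simulation of subordinated
  processes and spike-train signals with planted SIP distributions, used
  to validate the whole inversion (event recall/precision, recovered mode
  locations).

## A worked example

Simulate the default network at 1/8 scale for 3·10⁴ s with the RAF→MEK
activation timer set to 10 s, then estimate the waiting-time distribution
of the RAF-bound active-MEK state:

```r
library(mechwtd)

cfg <- default_config(magnitude = 10000, period = 1000, duration = 30000)
cfg <- apply_scale(cfg, 1 / 8)
cfg <- set_timer(cfg, "RAFact+MEKd->MEKact", 10)

x <- simulate_cell(cfg, seed = 1)
x
#> state_ts: 30000 steps x 30 state labels (dt = 1 s, seed 1)
#>   agents: 1111 initial, 5541 final (4430 produced, 0 degraded)
#>   largest pools: ECMprotein.inactive.none.extracellular, ribosome.inactive.none.cytoplasm, ...

w <- fit_wtd(state_series(x, species = "MEK", activation = "active",
                          partner = "RAF"))
w
#> wtd: psi(tau) from 609 critical events in epoch [0, 30000] s
#>   grid: [0, 252] s by 0.25 s; integral = 1.000000
#>   modes: 2.50 s (psi = 0.079), 5.50 s (psi = 0.023), 7.50 s (psi = 0.021), 21.25 s (psi = 0.019) (+17 minor)
```

Reading the output: the run produced 4430 new agents (mRNA, vesicles and
deposited ECM protein — the cell is secreting matrix under load), and the
RAF-bound active-MEK state produced 609 critical events whose recurrence
density ψ(τ) integrates to 1 and peaks at a ~2.5 s waiting time: under a
fast activation cycle, cohorts of MEK molecules leave this state in
rapid succession. `plot(w)` draws ψ with its modes;
`sweep_wtd()` repeats the whole protocol over 10 seeds and attaches a
pointwise confidence band; `cmd_simulate()` / `cmd_analyze()` /
`cmd_validate()` (or the CLI wrapper in `inst/cli/mechwtd.R`) run the same
steps from the shell with TSV/JSON outputs and a run manifest.

Validating the inversion against planted ground truth:

```r
rep <- recovery_experiment(list(name = "gamma-mixture", means = c(4, 9),
                                shape = 20, probs = c(0.5, 0.5)))
rep
#> recovery_report: 10 seeds (10 ok)
#>   recall 0.99 | precision 0.99 | modes 4.00 / 8.50 s (medians)
```

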