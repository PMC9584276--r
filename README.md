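# evoepi

Epidemic spreading with evolving pathogens on contact networks.

Classic epidemic theory reduces an outbreak to one control parameter, the
reproduction number `R0 = k̄ β0 / α0`: above 1 the pathogen spreads, below
1 it dies out. But a pathogen mutates as it spreads, and each transmission
can shift its *inter-host fitness* ψ — the ratio `(β/β0)/(α/α0)` — so that
a strain with fitness ψ has reproduction number `ψ · R0`. An initially
sub-pandemic pathogen (`R0 < 1`) can therefore break through by crossing
the **critical fitness `ψ_c = 1/R0`** before it goes extinct, provided its
mutation rate σ (the per-transmission standard deviation of Δψ) is large
enough to generate the critical mutation in time, yet small enough that
selection can lock the gains in. The package is built for quantitative
epidemiologists and statistical physicists who want to simulate and
analyse this interplay.

`evoepi` provides:

* **`intra-host`** — a strain-chain replicator–mutator engine
  (`build_strain_chain()`, `replicate_select()`, `sample_transmission()`,
  `estimate_effective_sigma()`) showing how intra-host mutation/selection
  reduces to an unbiased random walk of ψ with effective step scale σ;
* **`epinet`** — exact event-driven SIR/SIS on networks with one fitness
  jump per transmission (`run_sir()`, `run_sis()`, `psi_jump()`,
  `strain_rates()`, `apply_mitigation()`);
* **`theory`** — the closed forms: early prevalence
  `η(t) = η0 exp(ξ(t))` with
  `ξ(t) = −α0(1−R0)t + ½σ²α0²R0²t³`, the critical-mutation timescale
  `τ_c = sqrt(2(1−R0)/(3α0σ²R0²))`, `ψ_c = 1/R0`, the unit-line
  survival criterion, and both phase boundaries
  `σ_c ∝ sqrt(α0(1−R0)³)/(2R0 ln I0)` (infection-free ↔ mutation-driven)
  and `σ_c ∝ sqrt(α0/3)(ψ_max R0 − 1)^{3/2}/R0` (mutation-driven ↔
  volatile), with prefactor calibration;
* **`experiments`** — breakthrough-probability estimation
  (`estimate_P()`), (σ, R0) phase diagrams, the explosive transition
  curve, mitigation timing, SIS hysteresis sweeps;
* **`reinfection`** — a staged COVID-19-like disease cycle with
  immunity-evasion reinfection: genetic distance z walks per transmission
  and a variant at distance z evades wild-type immunity with probability
  `z^h/(z_r^h + z^h)` (`run_covid_cycle()`, `detect_second_wave()`,
  `risk_map()`);
* **`iokit`** — Erdős–Rényi generation, edge-list I/O, hierarchical
  seeding, run manifests with bit-identical replay, and a CLI
  (`inst/cli/evoepi.R`) with `simulate`, `sis`, `theory`,
  `phase-diagram`, `transition`, `mitigate`, `hysteresis`, `reinfect`,
  `risk-map` and `intra-host` subcommands.

## Worked example

A sub-pandemic wild-type (`R0 = 0.25`) with a fast mutation rate
(`σ = 2`) on the reference network:

```r
library(evoepi)
net  <- generate_er_network(5000, 15, seed = 1)
pars <- epi_params(alpha0 = 0.1, R0 = 0.25, kbar = 15, sigma = 2,
                   psi_max = 6, t_max = 4000)
run_sir(net, pars, seed = 11)
#> <epi_trajectory> SIR, t_end=184.1, r_inf=0.028, max psi seen=6.00
#>   mean fitness crossed psi_c=3.99 at t=88.50

psi_critical(0.25)
#> [1] 4
tau_c(0.1, 0.25, 2)
#> [1] 4.472136
unit_line_check(0.02, 5000, 0.1, 0.25, sigma = 2)
#> [1] TRUE
```

In this realization a critical mutation appeared early
(`first_critical_time` = 9.9, on the order of the predicted
`τ_c ≈ 4.5`), the fitness walk even reached the cap (`max psi seen =
6.00`) — and the epidemic still died (`r_inf = 0.028`): a single
supercritical strain must also survive demographic noise. The
breakthrough *probability* is the meaningful observable:

```r
pars <- epi_params(alpha0 = 0.1, R0 = 0.35, kbar = 15, sigma = 2,
                   psi_max = 6, t_max = 4000)
estimate_P(scenario(pars, N = 2000, kbar = 15, n_reps = 20,
                    epsilon = 0.2, seed = 7))
#> <breakthrough_estimate> P = 0.600 (se 0.110, 20 reps, epsilon 0.20)
```

so at `R0 = 0.35` a majority of realizations turn pandemic despite the
wild-type being far below threshold — the mutation-driven phase. The
`classify_phase()` function labels any (σ, R0) point with the calibrated
boundary formulas, and `phase_diagram_scan()` reproduces the full map.

See the vignette (`vignettes/evolving-pathogens.Rmd`) for the model's
assumptions, parameter defaults, calibration of the boundary prefactors,
and known limitations.

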