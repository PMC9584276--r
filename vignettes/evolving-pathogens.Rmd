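---
title: "Modelling epidemics of evolving pathogens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epidemics of evolving pathogens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`evoepi` simulates contagion on a contact network when the pathogen itself
evolves during the outbreak. Every strain is summarized by a single
*inter-host fitness* value $\psi \ge 0$, defined through its rates as
$\psi = (\beta/\beta_0)/(\alpha/\alpha_0)$, so that a strain with fitness
$\psi$ has reproduction number $R = \psi R_0$, where
$R_0 = \bar k \beta_0/\alpha_0$ is the wild-type reproduction number on a
network of mean degree $\bar k$. The wild-type has $\psi = 1$.

The simulation is an exact event-driven (Gillespie) realization of network
SIR (or SIS):

* every susceptible--infected edge fires at the infecting node's
  strain-specific rate $\beta_\mu$,
* every infected node recovers at its strain-specific rate $\alpha_\mu$,
* upon each transmission the offspring strain's fitness takes one random
  step, $\psi_{\text{child}} = \min(\max(\psi_{\text{parent}} +
  \Delta\psi,\, 0),\, \psi_{\max})$ with
  $\Delta\psi \sim \mathcal N(\text{drift}, \sigma^2)$.

With $\sigma = 0$ the model is the classic stochastic network SIR in law
(the test suite verifies this run-for-run against an implementation with no
fitness machinery, and in distribution against the exact percolation
representation of SIR final sizes). Which rate absorbs the fitness is set
by `mutation_mode`: under $\alpha$-mutations (the default, used for all
reference experiments) $\beta$ stays at $\beta_0$ and
$\alpha_\mu = \alpha_0/\psi$; under $\beta$-mutations
$\beta_\mu = \beta_0\psi$ at fixed $\alpha_0$. Both preserve the defining
ratio; the $\alpha$-mode divides by $\psi$ and therefore applies a floor
`psi_min` (default $10^{-3}$) so recovery rates stay finite.

## Intra-host microfoundation

The single parameter $\sigma$ stands in for a detailed intra-host process,
implemented in the `strain_chain` functions. Strains sit on a
one-dimensional lattice; per replication cycle a strain mutates into either
neighbour with probability $p$ (reflecting chain ends). Each strain carries
an intra-host replication fitness $\varphi \sim \mathcal N(1,
\sigma_\varphi^2)$ (drawn per host) and an inter-host fitness $\psi \sim
\mathcal N(1, \sigma_\psi^2)$ (drawn per chain), both clamped at zero.
`replicate_select()` applies the deterministic replicator--mutator update
(multiply by $\varphi$, mutate, renormalize); an agent-per-virion
simulation would produce the same marginals at far higher cost, and the
stochastic lineage picture is recovered by `sample_transmission()`.

Selection inside the host acts on $\varphi$ only. Since $\varphi$ and
$\psi$ are independent, the transmitted $\psi$ performs an unbiased random
walk across host passages: `estimate_effective_sigma()` simulates repeated
passages (infect with the centre strain, replicate, transmit) and returns
the standard deviation of the per-passage change $\Delta\psi$ — the
effective mutation rate of the reduced inter-host model. The tests verify
that $\Delta\psi$ is centred at zero, grows with $p$, and is approximately
normal (moment checks), which is what justifies collapsing the intra-host
machinery into the single jump kernel above.

## Closed-form theory

For a sub-pandemic wild-type ($R_0 < 1$) with mutations, the early-time
prevalence follows $\eta(t) = \eta_0 e^{\xi(t)}$ with
$$\xi(t) = -\alpha_0(1 - R_0)\,t + \tfrac12 \sigma^2 \alpha_0^2 R_0^2\,t^3 .$$
The linear term is the sub-critical decay of the wild-type; the cubic term
is the mutation-driven proliferation. The minimum of $\xi$,
$$\tau_c = \sqrt{\frac{2(1 - R_0)}{3\alpha_0\sigma^2 R_0^2}},$$
is the expected appearance time of the *critical mutation* — a strain with
fitness above $\psi_c = 1/R_0$, whose reproduction number exceeds one.

Whether that mutation arrives in time is a race against extinction: the
pathogen survives to $\tau_c$ only if $\eta(\tau_c)$ is still of the order
of $1/N$ (`unit_line_check()`). We read the unit line softly, with a
threshold `threshold_mult / N`: a pathogen carried by a couple of hosts
still goes extinct with high probability, so crossing strictly $1/N$ is
not enough. The default multiplier 6 is anchored so that the known
critical scenario ($R_0 = 0.25$, $\sigma = 0.16$, $\eta_0 = 0.02$,
$N = 5000$) sits exactly on the boundary; with a strict $1/N$ threshold
the same formulas would put the $\sigma = 0.1$ scenario marginally
*above* the line (by a factor 1.14), contradicting its observed
infection-free behaviour.

Two boundaries delimit the mutation-driven window in $\sigma$:

* the lower boundary $\sigma_c \propto \sqrt{\alpha_0 (1-R_0)^3}\,/\,
  (2 R_0 \ln \mathcal I_0)$, where $\mathcal I_0 = N\eta_0$ is the number
  of initially infected hosts (more initial carriers mean more
  evolutionary trials, hence a lower required mutation rate);
* the upper boundary $\sigma_c \propto \sqrt{\alpha_0/3}\,
  (\psi_{\max} R_0 - 1)^{3/2} / R_0$, above which fitness gains are lost
  to further mutations faster than inter-host selection can lock them in
  (the *volatile* regime).

Both are scaling laws, exposed with explicit multiplicative prefactors
`c_lower` and `c_upper`. `calibrate_prefactors()` fits them to a simulated
phase diagram by locating the $P = 0.5$ crossings of each sub-pandemic
$R_0$ column. The package defaults, `calibrated_prefactors()`, were fitted
once on the reference setting ($N = 5000$, $\bar k = 15$, $\alpha_0 =
0.1$, $\eta_0 = 0.02$, $\psi_{\max} = 6$; columns $R_0 \in \{0.35, 0.4,
0.6, 0.8\}$): `c_lower = 23`, `c_upper = 12`. The constants come out of
order 10 rather than of order 1. This is a property of the reduced
dynamics, not a fitting artefact: the formulas' derivation assumes fitness
variance accumulating continuously along an infection, whereas the reduced
simulator takes exactly *one* step of size $\sigma$ per transmission —
roughly $\alpha_0 R_0$ events per host per unit time — so the simulated
boundary sits at correspondingly larger $\sigma$. The acceptance checks
verify that, with these calibrated constants, the predicted boundaries
separate spreading from non-spreading grid points.

## Two definitions of "crossing the critical fitness"

A trajectory records both:

* `first_critical_time` — the first instant any circulating strain reaches
  $\psi_c$. This is the quantity $\tau_c$ predicts (in the reference
  mutation-driven scenario, $R_0 = 0.25$, $\sigma = 2$, the median over
  realizations lands within the predicted $\tau_c = 4.47$ window);
* `crossing_time` — the first instant the *mean* fitness over currently
  infected hosts exceeds $\psi_c$. This necessarily happens much later:
  just after $\tau_c$ the infected pool is still dominated by wild-type
  seeds, and the pool mean only crosses once the supercritical lineage has
  taken over (tens of time units later in the same scenario).

The acceptance machinery reports the first definition; both are kept
because the second is the natural online monitoring statistic.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `alpha0` | 0.1 /day | wild-type recovery rate (10-day infectious period) |
| `kbar` | 15 | mean contact degree of the Erdős–Rényi substrate |
| `beta0` | $\alpha_0 R_0/\bar k$ | wild-type per-edge infection rate |
| `eta0` | 0.02 | initial infected fraction (100 seeds at $N = 5000$) |
| `sigma` | scenario | per-transmission fitness step scale |
| `psi_max` | 6 | maximal attainable inter-host fitness |
| `psi_min` | $10^{-3}$ | floor for $\alpha_0/\psi$ in $\alpha$-mode |
| `epsilon` | 0.2 | final-size threshold defining a breakthrough |
| `record_dt` | 0.5 day | trajectory recording grid |
| `n_strains`, `rho` | 201, 25000 | chain length / replication cycles per passage |
| `z_r`, `h` | 0.4, 8 | immune-evasion sigmoid midpoint and steepness |

**Why `psi_max = 6`.** The cap is the maximal fitness over all attainable
strains; the reduced walk needs it to be finite for a volatile regime to
exist at all. At the cap, an offspring's expected fitness under jumps of
scale $\sigma \gg \psi_{\max}$ is $\approx \psi_{\max}/2$ (half the jumps
clamp at the cap, the rest scatter downward), so saturating mutation rates
extinguish the pathogen only when $R_0\psi_{\max}/2 \lesssim 1$. The cap
must also comfortably exceed $\psi_c = 1/R_0$ at the reference
sub-pandemic point $R_0 = 0.25$, or no breakthrough is possible there.
$\psi_{\max} = 6$ satisfies both ($6 > 4$ and $6/2 \cdot 0.25 < 1$); with
a cap of 10 the volatile phase does not exist anywhere in the scanned
range, because even under saturating mutations the fittest neighbourhood
remains supercritical. A corollary worth knowing: with this cap the
volatile phase exists only for $R_0 \lesssim 1/3$ — at larger
sub-pandemic $R_0$ the breakthrough probability is monotone in $\sigma$.

**Mitigation.** `apply_mitigation(params, t_R, R_R)` rescales $\beta_0$ at
time $t_R$ so the wild-type reproduction number becomes $R_R$ (we rescale
$\beta$, the social-distancing reading; circulating strains keep their
$\psi$). Because all rates are piecewise constant, the switch is handled
exactly by truncating the current waiting time at $t_R$ and redrawing.
Reemergence is assessed by two criteria — reaching the post-mitigation
critical fitness $1/R_R$, or an ever-infected increment above `epsilon`
after $t_R$ — which the tests check against each other.

## The reinfection module

The immune-evasion model replaces the $\psi$ walk by a walk of the
normalized genetic distance $z \in [0,1]$ from the wild-type (one
$\mathcal N(0, \sigma_z^2)$ step per transmission, reflected at 0, capped
at 1) on top of a staged disease cycle: exposure (no shedding, 3 d mean),
pre-symptomatic shedding (2 d mean; i.e. shedding starts about 3 days into
a 5-day pre-symptomatic period), then either an asymptomatic shedding
course (30 %, ~7 d) or mild/severe/critical symptomatic courses
(0.81/0.14/0.05 split) that isolate on onset, with deaths possible from
the severe and critical stages. The severity split and death
probabilities are adjustable placeholders in the reported SARS-CoV-2
range; nothing downstream depends on their exact values. A strain at
distance $z$ reinfects wild-type-recovered hosts at rate $\beta_0
\phi(z)$ with $\phi(z) = z^h/(z_r^h + z^h)$.

Only evasion of *wild-type* immunity is modelled: a host recovering from a
reinfection is terminally immune. Without that closure recovered hosts
would be reinfected indefinitely and no distinct second wave could be
observed; with it, at most two macroscopic waves can arise, which is the
intended scope. The midpoint default $z_r = 0.4$ was chosen once so that
a genuinely two-wave regime exists: the variant must accumulate a
substantial fraction of the maximal genetic distance before escaping
immunity, so escape typically happens in the tail of the first wave and
ignites a separated second wave. With a much smaller $z_r$ escape occurs
mid-wave and the two waves merge; with very large $\sigma_z$ the same
merging happens from the other side. `detect_second_wave()` operationalizes
"double-peaked": moving-average smoothing, then at least two local maxima
above 10 % of the global peak separated by a trough below half the smaller
one. `risk_map()` tabulates the probability of a detected second wave over
$(R_0, \sigma_z)$.

The transmissibility fitness is frozen at $\psi = 1$ in this module: the
breakthrough channel under study is immune evasion, not transmissibility
gain, and mixing both walks would confound the attribution.

## What the generator emulates — and what it does not

All experiments run on Erdős–Rényi networks with mean degree 15 (fresh
network per realization by default; a fixed shared network is a flag), with
`round(eta0 * N)` uniformly seeded wild-type infections. This captures the
reference setting of the framework but deliberately omits: degree
heterogeneity (no scale-free tails — arbitrary edge lists are accepted as
input, but no heavy-tail-specific theory is applied), household/community
structure, non-exponential stage durations (except the staged disease
cycle, which is a chain of exponentials), host-to-host variation in the
mutation rate, and any correlation between intra- and inter-host fitness
beyond the optional `drift` bias. Passing tests therefore demonstrate
internal consistency with the model's own assumptions, not calibration to
surveillance data.

## Numerical choices

* Exact continuous-time event-driven simulation; no time-step artefacts.
  Per-event cost is $O(\#\text{infected} + \text{degree})$ using slot
  arrays with swap-removal; the running fitness sum is refreshed every
  $2^{14}$ events to cancel floating-point drift.
* Trajectories are recorded on a uniform grid (default 0.5 time units) as
  a right-continuous step function of the event state, plus a final record
  at the end time.
* Ties cannot occur (all clocks are continuous); degenerate inputs are
  rejected at the boundary (`p > 0.5`, empty seed set, conflicting
  `beta0`/`R0`, $\psi_{\max} R_0 < 1$ signalled as a distinct condition).
* The strain chain reflects at its ends; the replicator update renormalizes
  every cycle, and an all-zero post-selection composition (every reachable
  strain clamped to zero fitness) is an explicit error.
* Replicate-level seeds are drawn once from the master seed
  (`derive_seeds()`), so increasing the replicate count never perturbs
  earlier replicates, and any output can be regenerated bit-identically
  from its run manifest.

## Problem sizes

The default experiment scale mirrors the reference setting ($N = 5000$,
$\bar k = 15$, 50 realizations, $\sigma \in [10^{-3}, 10]$ in log steps).
The shipped test-suite and acceptance checks run reduced versions chosen
for desk-scale wall-clock times — networks of 300–5000 nodes, 10–50
realizations per point, and coarse $3\times3$ grids — with the full scan
available through `phase_diagram_scan()` and the command line. The
estimators are identical at every scale; only the binomial standard errors
change.

## Known limitations

* The per-transmission step kernel places the mutation-driven window at
  larger $\sigma$ than the boundary formulas' bare constants suggest
  (hence calibrated prefactors of order 10, see above). Comparisons with
  settings whose mutation step accumulates per replication cycle rather
  than per transmission need to rescale $\sigma$ accordingly.
* Network final sizes on $\bar k = 15$ Erdős–Rényi graphs sit visibly
  below the well-mixed final-size fixed point $r = 1 - e^{-R_0(r +
  \eta_0)}$ — the usual depression from finite neighbourhoods and
  exponential infectious periods. The engine is therefore validated
  against the exact percolation oracle, not against the well-mixed value.
* The volatile regime requires a finite fitness cap and, with the default
  cap, exists only at small $R_0$ (see above). The upper-boundary formula
  retains its scaling form but its fitted prefactor reflects this model's
  lock-in mechanism.
* In the reinfection module, stage durations are exponential and immune
  escape is binary per the sigmoid; no vaccination, waning, or
  variant-by-variant immunity matrix.
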