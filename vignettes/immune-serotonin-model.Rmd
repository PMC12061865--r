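---
title: "An immune-serotonin-cortical mean-field model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An immune-serotonin-cortical mean-field model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosero)
```

## The model

`immunosero` simulates a two-region cingulo-frontal circuit — prefrontal
cortex (PFC) and subcallosal cingulate cortex (SCC) — as a stochastic
dynamic mean-field model coupled to serotonin kinetics that are modulated by
peripheral inflammation. Each region $n \in \{\mathrm{PFC}, \mathrm{SCC}\}$
carries an excitatory and an inhibitory population whose synaptic gating
variables $S_E^n, S_I^n$ evolve as

$$\dot S_E = -S_E/\tau_\mathrm{NMDA} + (1 - S_E)\,\gamma\, r_E + \sigma v(t),
\qquad
\dot S_I = -S_I/\tau_\mathrm{GABA} + r_I + \sigma v(t),$$

with population rates given by the usual input-output nonlinearity
$r = H(I) = g (I - I_\mathrm{thr}) / \left(1 - e^{-d g (I - I_\mathrm{thr})}\right)$
applied to the population input currents. The excitatory current of a region
collects recurrent excitation, local feedback inhibition, the serotonergic
current, external drive, and long-range excitation from the other region:

$$I_E = w_+ J_\mathrm{NMDA} S_E - J S_I \pm W^{5HT}_E R\, M_{5HT}
  + W_E I_o + J_\mathrm{NMDA}\, C_\mathrm{in}\, S_E^\mathrm{other},$$

and analogously for $I_I$ (without the long-range term). The sign of the
serotonergic term is the model's central asymmetry: PFC is dominated by
excitatory 5HT2A receptors ($+$), SCC by inhibitory 5HT1A receptors ($-$).
The serotonergic current variable follows the extracellular serotonin
concentration $[5HT]$ through a first-order sigmoid filter

$$\tau_{5HT}\,\dot M_{5HT} = -M_{5HT} + \frac{J_{5HT}}{1 + e^{-\beta([5HT] + 1)}},$$

and the concentration itself obeys Michaelis-Menten kinetics with
activity-dependent synthesis and saturating transporter reuptake:

$$\dot{[5HT]} = \alpha\, C_{BR}\, r_E\, X_1
  - \frac{V_\mathrm{max}\,[5HT]}{K_m + [5HT]}\, X_2 .$$

Inflammation enters through the *degree of inflammation*
$\delta = [\mathrm{Cyt}]/[\mathrm{Cyt}]_b$, the fold-elevation of the
TNF-$\alpha$ cytokine concentration over its basal value. It attenuates
synthesis (tryptophan diverted into the kynurenine pathway) and boosts
reuptake (transporter upregulation):

$$X_1 = \frac{c_1^m}{c_1^m + \theta\, B\, \delta^m}, \qquad
  X_2 = 1 + c_2\, \theta\, B\, \delta,$$

where $\theta$ is a Heaviside gate that opens only when the cytokine level
exceeds the basal level ($\delta > 1$; at exactly $\delta = 1$ the gate is
closed, so the control condition gives $X_1 = X_2 = 1$ for every $B$), and
$B \in (0, 1]$ is the anti-inflammatory blocker factor. Drug treatments are
pure parameter edits: SSRIs lower transporter affinity ($K_m$: 170 to 200
nM), anti-inflammatory blockade sets $B = 0.55$, and the combined treatment
applies both.

The sigmoid argument $[5HT] + 1$ carries an additive offset of 1 nM. The
offset looks odd — at physiological concentrations of tens of nM it is
nearly irrelevant — but it is part of the published formulation and is
implemented exactly as printed. Likewise $B$ multiplies $\delta^m$ (not
$\delta$ before exponentiation) inside $X_1$, exactly as the treatment
equations print it, although the narrative gloss of $B$ as a "percentage
reduction of cytokine concentration" would suggest $(B\delta)^m$. Where
formula and narrative disagree, this package follows the formula.

## Units

All internal quantities use one consistent frame: time in seconds, rates in
Hz, concentrations in nM, currents in nA. The parameter tables of the
source model print time constants in ms and the NMDA kinetic parameter in a
per-ms convention ($\gamma = 0.641 \times 10^{-3}$); the package stores
$\tau_\mathrm{NMDA} = 0.1$ s, $\tau_\mathrm{GABA} = 0.01$ s and
$\gamma = 0.641$, so that the excitatory gating fixed point takes the
standard mean-field form $S_E^* = \gamma\tau r/(1 + \gamma\tau r)$ and
$V_\mathrm{max}$ (nM/s) needs no rescaling. A mixed ms/s frame is the
easiest way to acquire silent factor-1000 errors; the YAML config loader
(`read_param_config()`) accepts files in printed units and converts once at
the boundary.

## Stochastic integration

The coupled 8-dimensional system is integrated with the Euler-Maruyama
scheme at `dt = 0.1` ms. The noise term $\sigma v(t)$ with
$\mathrm{Cov}(v(t), v(t')) = \delta(t - t')$ enters only the two gating
equations; a $\delta$-correlated drive is only step-size-consistent with
the $\sqrt{dt}$ scaling, so each gating variable receives
$\sigma \sqrt{dt}\, z$ with $z \sim N(0,1)$ per step ($\sigma = 0.01$).
The serotonergic current and concentration equations are advanced
deterministically, as printed. After each step, clamps repair excursions
that noise can cause: $S_E \in [0, 1]$, $S_I \ge 0$, $[5HT] \ge 0$.

The production loop is compiled (Rcpp) and draws its normals from R's
session RNG, so a trajectory is fully determined by its seed;
`em_step()` is a plain-R reference implementation of the identical update,
and the test suite replays the RNG stream through both routes and checks
agreement to $10^{-10}$.

Default protocol, following the published one: 7 s of simulated time
(70,000 steps), the first 1 s (10,000 steps) discarded as transient, and
100 replicates per condition, replicate $r$ seeded with `base_seed + r`.
The replicate seeding follows the simple additive scheme because it is the
directly testable contract; all replicates of all conditions reuse the same
seed list, which also makes battery output invariant to the execution
order of conditions.

Initial conditions are random, as in the source protocol, which does not
state their distribution. The package draws $S_E, S_I \sim U(0, 0.5)$,
$M \sim U(0, 1)$, $[5HT] \sim U(40, 80)$ nM — ranges that bracket the
operating regime; the discarded transient absorbs the choice.

The reported observables are time-averages over the retained 6 s: the
extracellular serotonin concentration and the excitatory population rate
$r_E$ per region ("activity"; a rate model has no spectrum to peak, and the
published activity values are single Hz numbers of population-rate
magnitude). Whether the source reports time-averages or endpoint values is
unstated; time-averages are the lower-variance choice and are used
throughout.

## The deterministic oracle

`steady_state_oracle()` computes the noise-free fixed point of the full
8-dimensional drift: deterministic relaxation from a fixed interior state
provides the starting point, then a damped Newton iteration on a
finite-difference Jacobian polishes the root to residual $10^{-10}$. Two
independent scalar routes validate it: at the converged rate, the serotonin
component must equal the closed form
$[5HT]^* = K_m u/(1 - u)$, $u = \alpha C_{BR} r_E X_1 / (V_\mathrm{max} X_2)$,
and for a decoupled single region the rate must match brute-force bisection
on the 1-D self-consistency problem $r = H(I(r))$.

One numerical subtlety: the slowest relaxation eigenvalue at the control
fixed point corresponds to a ~0.42 s timescale. With initial serotonin
drawn from $U(40, 80)$ nM, a 1 s transient can leave a few tenths of a
percent of residual relaxation in a 6 s time-average. Stochastic runs keep
the published 7 s / 1 s protocol; the package's *noise-free* consistency
checks (trajectory vs. oracle, dt-halving) therefore use a 9 s run with a
3 s transient, after which the residual is below 0.01%.

## What "restored to control levels" means

The treatment analyses ask whether a drug returns serotonin or activity to
the control level. The obvious formalization — within $\pm 2$ sem of the
control mean — turns out to be unusable on both sides: the published
"restored" cases sit several printed sems away from control (e.g. SSRI
under mild inflammation raises PFC serotonin ~6% *above* control and is
described as restoration), and this package's replicate sems of
time-averaged observables are tighter still (~0.02 nM), because with the
$\sqrt{dt}$-consistent noise scaling the gating fluctuations average down
hard over 6 s.

`assess_restoration()` therefore operationalizes restoration with a
tolerance `max(2*(sem + sem_control), 5% of control)`:

* **serotonin** — one-sided: the deficit is corrected when the mean is not
  meaningfully below control; overshoot counts as restored (the
  deficiency-correction reading under which the published restoration
  narrative is internally consistent);
* **activity** — two-sided: hypo- and hyperactivity are both departures
  from control.

The 5% floor is a fixed scientific choice, not a fitted number; the
qualitative treatment pattern (monotherapy fails under severe inflammation,
the combination restores serotonin and activity at every degree) is robust
to halving or doubling it.

## Interventions and variants

* `apply_treatment()` rewrites $K_m$ (both regions) and $B$:
  `none` (170, 1), `ssri` (200, 1), `antiinflammatory` (170, 0.55),
  `combined` (200, 0.55).
* `apply_variant("nmda_excitotoxicity")` multiplies the SCC NMDA time
  constant by 1.05, the excitotoxic slowing of NMDA kinetics attributed to
  quinolinic acid under inflammation.
* `apply_variant("receptor_reduction")` multiplies the SCC receptor density
  $R$ by 0.92 ("about 8%" reduction, implemented as exactly 0.92 and
  configurable). The reduction is scoped to SCC: it models the lower
  postsynaptic 5HT1A density reported in the SCC of depressed individuals,
  and the source analysis reports PFC serotonin unaffected by the change.
  A network-wide reduction would contradict that observation in this model
  — the PFC excitatory serotonergic weight is large (0.48·R), and scaling
  it moves PFC serotonin by ~15% — whereas with the SCC scope the PFC
  responds only through the small long-range coupling term (<1%), which
  the test suite verifies.

The degrees of inflammation use the published grid values (1, 1.25, 1.4,
2.3) rather than the raw concentration ratios (1.245, 1.409, 2.301);
`degree_of_inflammation()` exists for the raw route and the test suite
checks that the ratios round to the grid.

## Known limitations and honest disagreements

The model is deliberately small: no spatial or laminar structure, no
spiking, no conduction delays, no somato-dendritic 5HT1A autoreceptor
dynamics, no dopamine, no pharmacokinetics (drug doses are provenance
labels, not inputs), and no continuous interval of inflammation degrees.
Simulated noise represents synaptic stochasticity only; real recordings
carry measurement noise, nonstationarity and inter-subject variability that
the generator does not emulate, so passing tests certify the model
mechanics, not clinical validity.

Two quantitative disagreements with the published summary values are
structural and worth understanding:

1. **PFC serotonin sits ~6% below the published control value.** At steady
   state the concentration is pinned to the rate by the closed form
   $K_m u/(1-u)$; at the published control rate (4.61 Hz) this gives
   61.6 nM, not the published 66.35 nM. The package reproduces its own
   self-consistent value (~62 nM); the comparison tolerance of 10% for
   mean values absorbs the gap, which presumably reflects unstated details
   of the original runs.

2. **SCC pairs are mutually inconsistent under the printed kinetics.** The
   published SCC control pair (3.79 Hz, 65.21 nM) cannot coexist: with the
   printed kinetic constants, a 3.79 Hz rate forces ~47.6 nM at steady
   state. Integrating the printed equations self-consistently, this package
   finds the SCC settling near 2.9 Hz and ~34 nM under control conditions.
   All SCC-valued comparisons against the published numbers therefore fail
   their 10% bands — and are left failing, clearly labelled, rather than
   papered over — while every *ordinal* SCC claim (activity rises with
   inflammation, treatments push it back, the receptor-reduction variant
   raises SCC serotonin at every inflamed degree) is reproduced. For the
   same reason the NMDA-excitotoxicity variant cannot lower SCC serotonin
   while raising SCC activity, as the source narrative describes: synthesis
   is proportional to $r_E$, so at steady state any manipulation that
   raises the SCC rate necessarily raises SCC serotonin.

## Problem sizes used in the shipped checks

The acceptance-style checks run the full published protocol: the
48-condition grid (4 degrees x 4 treatments x 3 variants) at 100
replicates of 7 s each, plus a noise-free 9 s trajectory and a Newton
fixed point per condition. The unit-test layer uses short coarse runs
(0.3-0.4 s at dt = 1-2 ms) wherever only shape, seeding or clamping
contracts are at stake, and reserves the fine protocol for accuracy
claims.

## A worked example

```{r example, eval = FALSE}
library(immunosero)

# severe inflammation, combined treatment
mp <- condition_params("severe", "combined")
steady_state_oracle(mp)         # noise-free fixed point
run_replicates(mp, simulation_settings(base_seed = 42))

# the full grid, scored against the published values
battery <- run_battery(battery_config(settings = simulation_settings()))
compare_to_reference(battery, rel_tol = 0.1)
assess_restoration(battery[battery$variant == "baseline", ])
```
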