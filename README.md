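# immunosero

A stochastic mean-field simulator of the interplay between peripheral
inflammation, extracellular serotonin and cortical activity in a two-region
cingulo-frontal circuit — the prefrontal cortex (PFC) and the subcallosal
cingulate cortex (SCC) — built for in-silico study of why antidepressant
monotherapy can fail under inflammation and why combining an SSRI with an
anti-inflammatory agent can succeed. The intended users are computational
neuroscientists and psychiatry researchers who want a small, fully
reproducible model of cytokine-serotonin-circuit coupling with drug
interventions expressed as parameter edits.

## The model

Each region carries an excitatory and an inhibitory population with NMDA and
GABA synaptic gating variables `S_E`, `S_I` driven through a saturating
transfer function `H(I) = g(I - I_thr) / (1 - exp(-d g (I - I_thr)))`:

    dS_E/dt = -S_E/tau_NMDA + (1 - S_E) * gamma * r_E + sigma * v(t)
    dS_I/dt = -S_I/tau_GABA + r_I + sigma * v(t)

A serotonergic current `M_5HT` follows the extracellular serotonin
concentration through a sigmoid and enters the regional currents with
opposite signs — excitatory in PFC (5HT2A-dominated), inhibitory in SCC
(5HT1A-dominated). Serotonin itself obeys Michaelis-Menten kinetics with
activity-dependent synthesis and transporter reuptake:

    d[5HT]/dt = alpha * C_BR * r_E * X1  -  Vmax * [5HT] / (Km + [5HT]) * X2

where the inflammation factors `X1 = c1^m / (c1^m + theta*B*degree^m)`
(synthesis attenuation) and `X2 = 1 + c2*theta*B*degree` (reuptake boost)
depend on the *degree of inflammation* — the fold-elevation of TNF-alpha
over its basal level (1, 1.25, 1.4, 2.3 for control, mild, moderate and
severe) — gated by a Heaviside `theta` that opens above the control level.
Treatments are parameter edits: an SSRI raises `Km` from 170 to 200 nM, an
anti-inflammatory blocker sets `B = 0.55`, the combined treatment does both.
Two mechanistic variants are included: NMDA excitotoxicity (SCC
`tau_NMDA` x 1.05) and postsynaptic receptor-density reduction (SCC
`R` x 0.92).

The system is integrated with Euler-Maruyama (0.1 ms step, noise on the
gating variables only, `sqrt(dt)` scaling), 7 s per trajectory with a 1 s
transient discarded, 100 replicates per condition. A deterministic Newton
solver (`steady_state_oracle()`) provides the noise-free fixed point used as
an independent oracle by the test suite. See the methods vignette
(`vignettes/immune-serotonin-model.Rmd`) for assumptions, units, numerical
choices and known limitations.

## A worked example

```r
library(immunosero)

mp <- condition_params("severe", "combined")   # degree 2.3, Km = 200, B = 0.55
fp <- steady_state_oracle(mp)                  # noise-free fixed point
round(fp[c("conc_pfc", "conc_scc")], 2)
#> conc_pfc conc_scc
#>    60.84    32.29

run_replicates(mp, simulation_settings(base_seed = 42))
#>   region observable      mean          sem   n
#> 1    PFC  serotonin 60.819692 0.0194796321 100
#> 2    SCC  serotonin 32.381102 0.0357316881 100
#> 3    PFC     rate_E  4.621911 0.0007859892 100
#> 4    SCC     rate_E  2.916340 0.0025421610 100
```

Reading: under severe inflammation with the combined SSRI +
anti-inflammatory treatment, PFC extracellular serotonin averages ~60.8 nM
across 100 stochastic replicates — back near its control level (~62.1 nM)
— and the PFC population rate (~4.62 Hz) is likewise restored. Running the
same condition untreated (`condition_params("severe")`) gives ~42.0 nM and
4.34 Hz: the inflammation-induced serotonin deficit and PFC hypoactivity
that the combined treatment corrects.

The full 48-condition battery (4 degrees x 4 treatments x 3 variants) with
tidy CSV/JSON output:

```r
battery <- run_battery(battery_config(settings = simulation_settings(),
                                      out_dir = "results"))
compare_to_reference(battery, rel_tol = 0.1)   # score against published values
assess_restoration(battery[battery$variant == "baseline", ])
```

A thin command-line front end ships in `inst/cli/immunosero`
(`simulate`, `battery`, `compare`, `oracle` subcommands).

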