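# mitonet

Mitochondria switch between fragmented populations of isolated organelles
and large fused networks, and the physiological payoff of the networked
state is still debated. `mitonet` is an R toolkit for exercising the main
quantitative hypotheses at desk scale, aimed at modellers and quantitative
cell biologists who want to reason about fission–fusion dynamics rather
than fit data. It implements five coherent models around a common
coordinate pair — the bond probability
`p = λ_fus / (λ_fus + λ_fis)` and the flicker relaxation time
`τ = 1 / (λ_fus + λ_fis)`:

1. **Fluctuating bond lattice** — mitochondrial units on an `L^d` lattice
   whose fusion links flicker on/off as independent two-state Markov
   processes; morphology classification (fragmented → microfused →
   mesofused → dynamic/static hyperfused) and connectivity statistics,
   with the percolation threshold `p_c = 1/2` of the 2D square lattice as
   the organising landmark.
2. **Tracer diffusion** — exact event-driven co-simulation of blind-ant
   walkers with the bond flicker, plus a dynamic effective-medium
   (mean-field) prediction `D(p, τ)` that reduces to the static EMA
   `(zp/2 − 1)/(z/2 − 1)` at `τ = ∞` and to `p·λ_dif/(2d)` for fast
   flicker. Near `p_c` a static network turns diffusion on switch-like;
   fast flicker linearises it.
3. **Quality control by blind surveillance** — an ODE model in which blind
   fission + selective fusion + size-selective (function-blind) mitophagy
   yield biased degradation of dysfunction; closed-form steady state
   `h* = [1 + (δ/μ)(λ_fis + s·λ_fus)/(λ_fis + λ_fus)]⁻¹` for the default
   configuration.
4. **Bioenergetics of fusion** — sigmoidal `r_ATP(Δψ)`; averaging
   potentials on fusion raises or lowers the summed synthesis rate with a
   sign set by Jensen's inequality between the two potentials.
5. **Calcium chains and robustness** — dilution of ER-derived matrix
   calcium along fused chains gives a unimodal net gain with an optimal
   chain length; a capacitor-leak model shows relative Δψ fluctuations
   shrinking with radius (`σ_rel ∝ 1/r`), and spin-coupled agents resist
   collective failure better than independent ones.

See `vignettes/mitonet-methods.Rmd` for the models, assumptions, parameter
meanings and numerical choices in detail.

## Worked example

```r
library(mitonet)
set.seed(42)

# a dynamic hyperfused lattice: p = 0.6 > p_c, fission still active
lat <- make_lattice(64, 2, lambda_fus = 1.2, lambda_fis = 0.8)
lat
#> network_lattice: 64^2 nodes, open boundaries
#>   p = 0.6, tau = 0.5 (lambda_fus = 1.2, lambda_fis = 0.8)
#>   8064 bonds, 59.9% on, time = 0
classify_morphology(lat$p, lat$lambda_fis)
#> morphology: dynamic_hyperfused (p_c = 0.5)
connectivity_stats(lat)
#> cluster_stats: 162 clusters, largest fraction 0.937, mean size 25.28, spanning: TRUE

# mean-field diffusion: switch-like when static, linear when fast-flickering
ema_diffusion(c(0.3, 0.5, 0.6, 0.8), tau = Inf)
#> [1] 0.00 0.00 0.05 0.15
ema_diffusion(c(0.3, 0.5, 0.6, 0.8), tau = 0.1)
#> [1] 0.0725 0.1221 0.1472 0.1981

# quality control: selective fusion (s = 0.2) makes h* grow with fusion rate
sweep_fusion(qc_params(s = 0.2, lambda_fis = 0.5, mu = 0.3, delta = 0.05),
             c(0.1, 1, 10))
#>   lambda_fus    h_star d_frag_share d_net_share
#> 1        0.1 0.8737864    0.1428571  0.03225806
#> 2        1.0 0.9278351    0.1428571  0.03225806
#> 3       10.0 0.9618321    0.1428571  0.03225806
```

The lattice at `p = 0.6` percolates (a spanning cluster holds 94% of the
units) while fission keeps turning over its bonds — the dynamic hyperfused
regime. The static mean-field diffusion coefficient is zero through
`p = 0.5` and switches on above it, while at `τ = 0.1` it is already close
to the annealed line `p/4`. In the sweep, the steady healthy fraction
climbs from 0.874 to 0.962 as fusion accelerates, and the fragmented pool
is five-fold enriched for dysfunction relative to the network (0.143
vs 0.032) — that enrichment is what lets function-blind mitophagy select
against dysfunction.

Fusion bioenergetics and the other modules follow the same pattern:

```r
sm <- sigmoid_response()   # psi_half = 150 mV, slope 10 mV
net_rate_change(energetics_unit(100), energetics_unit(120), sm)  # both convex
#> [1] -0.0181463
net_rate_change(energetics_unit(120), energetics_unit(190), sm)  # mixed
#> [1] 0.215479

optimal_chain_length(calcium_scenario())$n_star   # interior optimum
#> [1] 8

ens <- spin_ensemble(3, "complete", coupling = 1, bias = 0.3, horizon = 20)
group_vs_individual(ens)
#>          case         p se
#> 1       group 0.1202049 NA
#> 2 independent 0.7609783 NA
#> 3      single 0.9991640 NA
```

A coupled trio is six times less likely to fail collectively than the same
agents uncoupled.

Scenario files and CSV/JSON/GraphML reporting go through
`generate_fixtures()` / `run_scenario()`; a thin command-line dispatcher is
installed at `system.file("cli", "mitonet.R", package = "mitonet")` with
subcommands such as `simulate-diffusion`, `qc-sweep`, `calcium-sweep`,
`robustness-spin`.

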