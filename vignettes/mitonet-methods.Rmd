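---
title: "Models and methods in mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
set.seed(1)
```

mitonet implements five small quantitative models that probe why
mitochondria form fused networks rather than remaining fragmented. This
vignette documents each model, its assumptions, the parameters that matter,
the numerical choices made, and what the package's checks do and do not
establish. All models are deliberately coarse-grained: they are instruments
for reasoning about hypotheses, not fitted descriptions of any particular
cell type.

## The fluctuating bond lattice

Mitochondrial material is discretised into "units" occupying the nodes of an
`L^d` square or cubic lattice. A bond between neighbouring units is *on*
when the two units are lumenally continuous (fused). Each bond flickers
independently as a two-state Markov process with on-rate $\lambda_{fus}$ and
off-rate $\lambda_{fis}$, giving the stationary bond probability

$$p = \frac{\lambda_{fus}}{\lambda_{fus} + \lambda_{fis}}, \qquad
\tau = \frac{1}{\lambda_{fus} + \lambda_{fis}},$$

where $\tau$ is the relaxation time of the flicker (the decay time of a
bond's autocorrelation, i.e. the slow eigenvalue of the $2\times 2$ rate
matrix). Different rate pairs with the same ratio give the same connectivity
but different dynamics — this is why $(p, \tau)$ is the natural coordinate
pair throughout the package.

Morphological regimes are classified from $p$ and the fission rate:
fragmented ($p = 0$), microfused ($p \le \varepsilon$), mesofused
($\varepsilon < p < p_c$), dynamic hyperfused ($p_c \le p \le 1 -
\varepsilon$ with $\lambda_{fis} > 0$) and static hyperfused (essentially no
fission). The percolation threshold $p_c$ defaults to $1/2$, the exact
value for 2D square-lattice bond percolation; in 3D no closed form exists
and the user must supply a value (or estimate one with
`estimate_percolation_threshold()`). The cut-off $\varepsilon$ defaults to
0.05; no sharper value is implied by the biology, it merely fixes where
"$p \approx 0$" and "$p \approx 1$" begin.

Numerical choices:

* `step_bonds()` uses the exact two-state transition probability
  $P(\text{on at } t + \Delta t) = p + (s - p)e^{-\Delta t/\tau}$, so steps
  compose exactly and there is no Euler error; the test suite verifies that
  two half-steps and one full step have the same marginal law.
* Bonds are initialised from the stationary distribution, so ensembles have
  no burn-in transient.
* Connectivity (components, spanning, cluster sizes) is delegated to igraph
  and cross-checked against a hand-written breadth-first search on small
  lattices. "Spanning" means a component touches both faces along axis 0,
  the chain-across-the-cell criterion; it is well defined for open
  boundaries, which are therefore the default.

## Tracer diffusion and the mean-field surface

Fast-diffusing matrix species are modelled as continuous-time blind-ant
walkers: a walker attempts hops at total rate $\lambda_{dif}$, picks one of
its $2d$ neighbours uniformly, and moves iff the connecting bond is on. The
blind-ant convention (attempt, then reject) is chosen over the myopic ant
because it makes the fast-flicker limit exact: when bonds decorrelate
between attempts, each attempt independently succeeds with probability $p$
and $D \to p\,\lambda_{dif}/(2d)$.

Walker hops and bond flicker are co-simulated exactly. Because bonds are
independent Markov chains and a bond's state matters only when a walker
attempts to cross it, each bond is propagated lazily to the query time with
the exact transition law; queries are globally time-ordered across walkers,
so the bond history seen by all walkers is consistent. This is
statistically identical to simulating every bond flip event, at a fraction
of the cost, and has no time-step bias — important near the percolation
threshold where discretisation artefacts are largest. Diffusion runs use
periodic boundaries with unwrapped displacements; the apparent diffusion
coefficient is the late-time weighted least-squares slope of the MSD divided
by $2d$ (fit window defaults to the upper half of the recorded times, where
the crossover transient has decayed).

The mean-field prediction `ema_diffusion()` combines the frequency-dependent
single-bond effective-medium self-consistency for binary bonds,

$$\sum_w P(w)\,\frac{w - w_m}{w + (1/\gamma(s) - 1)\,w_m} = 0,
\qquad \gamma(s) = \frac{2}{z}\bigl(1 - s\tilde P(0, s)\bigr),$$

with the renewal closure of dynamic bond percolation, $s = 1/\tau$. Here
$\tilde P(0,s)$ is the Laplace-transformed return probability of the free
walk on the effective lattice, computed from
$P(0,t) = [e^{-2w_m t} I_0(2 w_m t)]^d$ by numerical quadrature, and
$z = 2d$. For a binary bond distribution the self-consistency reduces to a
scalar fixed point solved by bisection to $10^{-12}$. Three limits are exact
and unit-tested: $p = 1$ gives $\lambda_{dif}/(2d)$; $\tau = \infty$ gives
the classical static EMA $(zp/2 - 1)/(z/2 - 1)$ (so $2p - 1$ on the square
lattice, vanishing at $p \le 1/2$); $\tau \to 0$ gives the annealed limit
$p\,\lambda_{dif}/(2d)$.

Two points deserve honesty. First, the renewal closure treats the whole
lattice as rearranging at rate $1/\tau$, whereas the simulated bonds flicker
independently; independent flicker frees trapped walkers faster (any one
boundary bond opening suffices), so below the threshold at slow flicker the
mean field underestimates the simulated $D$ — the agreement checks in the
test suite find a deviation of roughly 15% at $(p, \tau) = (0.2, 10)$ and a
few percent elsewhere. Second, "the abrupt change at $p = 1/2$" is a
statement about the *onset* of long-range diffusion: the static mean-field
curve has its kink exactly at $p_c$, but the simulated static $D(p)$ is
convex above the threshold (the 2D conductivity exponent exceeds 1), so the
largest absolute finite-difference slope of the simulated curve sits above
$p_c$, not at it. The package's checks therefore locate the onset (threshold
estimate, mean-field kink, and the sharpening of the relative jump across
$[0.45, 0.55]$ as $\tau \to \infty$) rather than asserting a maximal
absolute gradient at $p_c$.

`kiss_and_run_range()` is a deliberate back-of-the-envelope: the RMS range
$\sqrt{2 d D t}$ of a matrix protein during a transient fusion contact.
With GFP-like mobility (20 µm²/s) and a 45 s mean contact it gives about
74 µm, far beyond any cell-crossing distance — matrix contents can
equilibrate through brief contacts, which is why the diffusion argument
matters most for slow species and membrane components.

## Quality control by blind surveillance

Populations of healthy (`h`) and dysfunctional (`d`) units are split into
fragmented (`_f`) and networked (`_n`) compartments. Fission is blind
(rate $\lambda_{fis}$ for both types); fusion is selective (healthy fuse at
$\lambda_{fus}$, dysfunctional at $s\lambda_{fus}$ with $s \le 1$);
mitophagy is size-selective but function-blind (rate $\mu$, fragmented
units only — this is the model's essential non-linearity); damage converts
healthy to dysfunctional at rate $\delta$; biogenesis replaces degraded mass
with fresh healthy fragments, so the total is conserved exactly (the
derivative components sum to zero identically).

Where the design was genuinely open, the package resolves it as follows and
exposes the alternative as a flag:

* **Damage scope.** By default damage manifests in the fragmented
  compartment only. This is the configuration in which the model behaves as
  the blind-surveillance argument requires: with $s = 1$ (blind fusion) the
  steady healthy fraction collapses to $\mu/(\mu + \delta)$ *independently
  of the fusion rate* — no selectivity, no surveillance benefit — while for
  $s < 1$ it increases monotonically with $\lambda_{fus}$. If damage also
  acts on networked units (`damage_networked = TRUE`), raising the fusion
  rate shelters dysfunctional units from mitophagy faster than it helps,
  and the healthy fraction *decreases* with $\lambda_{fus}$ for every $s$ —
  a useful sensitivity variant, but not the mechanism under study. One can
  read the default biologically as network residents being buffered by
  content exchange, with damage becoming consequential once a unit is
  isolated.
* **Biogenesis.** Default replacement is healthy (organelles built from
  fresh components). A `proportional` variant replaces in proportion to the
  current composition; it admits a second, all-dysfunctional fixed point,
  which the multi-start uniqueness check flags.

For the default configuration the steady state solves in closed form,

$$h^* = \left[1 + \frac{\delta}{\mu}\,
\frac{\lambda_{fis} + s\lambda_{fus}}{\lambda_{fis} + \lambda_{fus}}\right]^{-1},$$

which the solver (damped Newton on the simplex, residual tolerance
$10^{-10}$, long-integration fallback, multi-start uniqueness check) must
reproduce; the suite cross-checks Newton, ODE integration and the closed
form against each other at $10^{-8}$ or better. The selection mechanism is
visible directly in the steady state: the dysfunctional share among
fragmented units exceeds that among networked units exactly when $s < 1$
(in closed form, $d_f/h_f = \delta/\mu$ versus $d_n/h_n = s\,\delta/\mu$),
which is why even function-blind mitophagy removes dysfunction
preferentially.

## Bioenergetics of fusion

ATP synthesis rate responds sigmoidally to membrane potential; the package
uses the logistic parameterisation
$r_{ATP}(\Delta\psi) = \text{size} \cdot r_{max}\,\sigma((\Delta\psi -
\psi_{1/2})/k)$. The defaults $\psi_{1/2} = 150$ mV, $k = 10$ mV are
illustrative, chosen only so that the physiological 100–200 mV window
contains an exponential (convex) regime, a steep transition, and a plateau;
they are not fitted to data, and the region of the curve on which real
mitochondria sit is experimentally open. Only $\Delta\psi$ is modelled; the
proton-motive force's $\Delta$pH term is out of scope.

Fusion combines potentials either as a size-weighted mean or as a
charge-conserving capacitor combination with capacitances
$C_i = \text{size}_i \times \text{cristae}_i$, the cristae factor standing
in for inner-membrane surface amplification. Both rules are convex
combinations, so the fused potential can never leave the interval spanned by
the inputs — the property-based tests enforce this bound for random sizes
and cristae factors. The net rate change on fusion,
$\Delta r = r(\psi_{fused}, s_1 + s_2) - r(\psi_1, s_1) - r(\psi_2, s_2)$,
then has its sign governed by Jensen's inequality: negative when both
potentials lie in the convex tail, positive in mixed tail/plateau
situations, and zero (to machine precision) for equal potentials. The test
suite checks the full sign map on a $50 \times 50$ potential grid against an
independently coded logistic oracle. `superadditivity_check()` packages the
underlying criterion — fusion can only pay if usefulness is superadditive in
some mitochondrial property.

## Calcium chains

Only mitochondria at ER contact sites take up calcium efficiently; a fused
chain of $n$ units containing one saturated unit has matrix calcium
$(c_{high} + (n-1)c_{low})/n$ — averaging conserves total calcium exactly.
A sigmoidal activation curve (TCA-cycle enzyme stimulation) converts
concentration to per-unit output. The package evaluates both the gross
output $n\,a(\bar c(n))$ and the net gain over the unfused baseline; the
*optimal chain length maximises the net gain by default*. The distinction
matters: the gross output credits every added unit with its basal
activation, a contribution present whether or not the chain fuses, so
whenever basal activation is non-zero the gross curve turns upward again at
large $n$ and has no finite optimum. The net gain is cleanly unimodal in
the regime of interest ($c_{low} \ll c_{1/2} < c_{high}$; defaults 0.05, 1,
10 µM with slope 0.25 µM), rising while dilution recruits distal units and
falling once the chain calcium drops into the low-activity tail; ties break
toward shorter chains within a $10^{-9}$ relative tolerance, so flat
profiles (linear activation, or deep saturation everywhere) return $n^* =
1$. The optimum is verified against exhaustive scans for every scenario in
the test grid. The model is a snapshot: calcium transients are fast, so it
speaks to short timescales, and phosphate buffering is ignored.

## Robustness: fluctuation damping and coupled failure

**Capacitor-leak model.** A spherical mitochondrion of radius $r$ obeys
$C\,\dot\psi = I_{pump} - (G_{leak} + g_p N_{open}(t))\,\psi$ with every
baseline quantity proportional to membrane area $A = 4\pi r^2$:
$C = c_m y A$ (the invagination factor $y \ge 1$ models cristae area),
$I_{pump} = jA$, $G_{leak} = g_0 A$, and pore openings arriving as a Poisson
process of rate $\nu A$, each adding the *intensive* conductance $g_p$ for a
lifetime $t_p$. The baseline potential $j/g_0$ is therefore size-independent
while one pore's relative impact shrinks as $1/r^2$ and the event rate grows
as $r^2$; the resulting shot-noise scaling $\sigma_{rel} \propto 1/r$ is a
prediction of this reconstruction, which the radius sweep measures (fitted
log-log exponent near $-1$) rather than asserts. Integration is exact:
between events the trajectory is piecewise exponential, and the time
averages of $\psi$ and $\psi^2$ are accumulated from closed-form segment
integrals, so there is no step-size error. Defaults ($j/g_0 = 150$ mV-scale
baseline, unit leak and capacitance densities, $\nu = 0.2$ events per area
per time, $g_p = 0.5$, $t_p = 1$) put single-event depolarisations at a few
percent for $r$ in the 0.25–2 µm range — perturbations, not catastrophes.

**Spin-coupled agents.** Mitochondria as binary agents $s_i = \pm 1$
(functional/failed) with energy $E = -J\sum_{\text{edges}} s_i s_j -
h\sum_i s_i$: coupling $J \ge 0$ makes an agent prefer its neighbours'
state, the field $h > 0$ favours function, and $\theta$ (the `beta_inv`
noise parameter) scales the flip noise. Dynamics are continuous-time
single-flip Glauber heat-bath (Metropolis available; both satisfy detailed
balance, verified against Boltzmann weights by enumeration at $N = 4$).
"Catastrophic loss of function" is first passage to the all-failed state by
a horizon $T$, starting all-functional. The exact route builds the sparse
$2^N$ generator (capped at $N = 12$) and integrates the master equation;
the Monte Carlo route samples trajectories in compiled code. At $J = 0$ the
agents are exchangeable, so the number of failed agents is a birth–death
chain whose $(N+1)$-state first-passage problem provides an independent
closed-form check. Note one subtlety: because agents recover, the joint
first-passage probability at $J = 0$ is *smaller* than the product of
single-agent first-passage probabilities — "independent agents" are
compared through the same first-passage definition, not through that
product. Coupling is protective: the exact catastrophe probability is
non-increasing in $J$, and `group_vs_individual()` reports group,
uncoupled, and single-agent values side by side.

## Scenario tooling, reproducibility, and problem sizes

`generate_fixtures()` writes small seeded YAML scenarios (regeneration with
the same seed is byte-identical); `run_scenario()` validates them (unknown
keys are rejected), dispatches to the modules, and writes CSVs plus a
provenance record (config MD5, seed, package version). All randomness flows
through R's RNG — compiled code uses the R API — so a single `set.seed`
reproduces every output bitwise.

The suite's standing problem sizes were chosen to make each statistical
check decisive at desk scale: percolation threshold at $L = 128$ with 200
snapshots per probed $p$ (bisection to $\pm 0.02$ or better); diffusion
surfaces at $L = 64$ with $5\times4$ grids, 800–1500 walkers and 6 lattice
replicates per cell; fluctuation sweeps with 200 replicates per radius; spin
comparisons at $N = 3$ with 3000–4000 trajectories against exact values.

What the checks do *not* show: the lattice is a topological idealisation
(real mitochondria live on the cytoskeleton, off-lattice), bond rates are
homogeneous (no potential-dependent fusion within the lattice model), the
QC model is deterministic and non-spatial, the sigmoid parameters are
illustrative, and the calcium and robustness models are snapshots with
single-mechanism noise. Passing tests establish internal correctness of
each model and the stated qualitative behaviours, not quantitative
agreement with any measured cell.
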