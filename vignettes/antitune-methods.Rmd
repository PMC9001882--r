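---
title: "Models and methods: tuning antithetic pathway controllers by multiobjective optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antitune)
```

## The problem

Microbial cell factories that over-express a heterologous pathway are
exposed to fluctuations in shared precursors.  In a *merging* pathway
motif, one enzymatic step consumes both the dedicated precursor and an
essential host metabolite (for naringenin production in *E. coli*, the CHS
step consumes malonyl-CoA, a tightly regulated pool of roughly 4–40 µM
that the host also needs for fatty-acid synthesis).  A static design —
constitutive enzyme expression sized for nominal conditions — loses
production whenever that co-substrate dips.  Dynamic regulation closes a
feedback loop: a biosensor reads the product level and a biomolecular
controller adjusts enzyme expression to compensate.

`antitune` implements the model-based tuning workflow for such loops: two
deterministic kinetic models, a perturbation-rejection protocol, three
design objectives, a constrained multiobjective differential-evolution
(DE) optimizer with spherical pruning, and level-diagram decision support
over the resulting design library.

## The two models

### Simplified merging pathway

Six states (molecules per cell; population `X` in cells): substrate `S1`,
product `P`, enzyme `E`, controller species `sigma` and `asigma`, and
`X`.  Uptake of `S1` is constant (`K_S1`); the merging flux is
bisubstrate Michaelis–Menten in `S1` and the externally set pool
`S2_level`; every intracellular species is diluted at the growth rate
`mu`; `X` grows logistically to `Xmax`.

The controller is the antithetic motif: `sigma` is expressed
constitutively (`CN * k_sigma`, encoding the set point), the anti-sigma
factor is expressed through a product-responsive TF biosensor
(`biosensor_fraction()`), and the two annihilate at rate
`gamma * sigma * asigma`.  The annihilation imbalance integrates the
control error, which is what gives (quasi-)perfect adaptation; dilution
and degradation of the controller species leak that integral and
re-introduce steady-state error — the motivation for treating robustness
as an explicit objective rather than assuming it.

### Detailed naringenin pathway

Sixteen states: the five-step metabolic chain L-tyrosine → p-coumaric
acid → p-coumaroyl-CoA → naringenin chalcone → naringenin (the CHS step
merges in malonyl-CoA, `Ma_level`), the extended biosensor branch
naringenin → dihydrokaempferol → kaempferol read by the QdoR repressor,
the realistic controller (sigma, anti-sigma, an explicit sequestration
complex with unbinding `k_minus_c` and dissociation constant `kdc`,
promoter leakage `alpha`), the CHS actuator with a constitutive baseline
(`beta`-weighted) plus a sigma-activated part, and the AHL/LuxR reference
block with passive diffusion between each cell and the shared external
volume.  The population is homogeneous and deterministic: all `x` cells
share one intracellular state, so the total AHL returned to the medium is
`x * A`.

### Reading conventions fixed in one place

Three typeset promoter fractions admit several algebraic groupings; each
is isolated in a named kernel (`f_lux()`, `f_qdo()`, `f_p20()`,
`hill_activation()`) so that an alternative reading is a one-line,
centrally documented change.  The adopted groupings preserve every
qualitative property that matters for tuning: values in `[0, 1]`,
activation monotone in the inducer (AHL, sigma) and repression monotone
in the repressor (QdoR).  The Hill half-activation of the enzyme promoter
sits at `sigma = kd20 * CN`.  Similarly, the extracellular-AHL balance is
implemented as the mass-consistent counterpart of the per-cell diffusion
term: `dAe/dt = D*(x*A - x*Vc*Ae) - d_Ae*Ae` with `Vc = Vcell/Vext`, so
that what leaves the cells enters the medium.

Other conventions: amounts are molecules per cell throughout; µM-quoted
quantities (the 4.5 µM sigma constraint) are converted with
`molecules_from_uM()` at `Vcell = 1.1e-15` L; the transcription factor of
the simple biosensor is a constant pool `TF_total` (constitutive
expression reaches quasi-steady state much faster than the pathway);
`S2_level` and `Ma_level` are externally set inputs, not states, because
perturbations act on their *availability*; every species has its own
degradation constant even where defaults coincide.

## The parameter registry

The numeric parameter sets are shipped as YAML registry entries
(`merging-default`, `naringenin-default`), with units recorded per field.
These are package defaults calibrated once to reproduce the qualitative
operating regime the tuning methodology presumes, and they are not meant
to be revisited by users as part of optimization (the optimizer only
moves the decision variables):

* **Merging**: the closed loop reaches a steady product level before the
  perturbation and partially recovers after a 60 % step down in `S2`
  (default production loss ≈ 0.15, versus ≈ 0.42 for a titer-matched
  static design).  The basal enzyme strength is `a0 = 0` — the enzyme is
  purely sigma-driven — so that in the ideal controller limit (no
  controller degradation, negligible dilution) the loop genuinely
  settles instead of drifting past its set point on basal flux.
* **Naringenin**: the unperturbed design reaches 1.0 g/L at the default
  decision values, satisfies both controller constraints (sigma ≈ 66–70
  µM ≥ 4.5 µM, sigma ≫ anti-sigma), and after the 65 h / 60 %
  malonyl-CoA step shows the characteristic closed-loop signature: sigma
  rises, CHS transiently increases, and naringenin dips and partially
  recovers (production loss ≈ 0.026).  Two calibration choices deserve
  mention.  The AHL dose and promoter constants put the reference
  promoter deep into saturation, so slow depletion of the external AHL
  reservoir by cellular uptake and dilution does not drift the set point
  over the 130 h experiment.  And the biosensor branch operates
  sub-saturated (`Km_N`, `Km_Di` above the operating pools): a saturated
  readout enzyme would make the kaempferol signal blind to naringenin
  changes and silently open the loop.
* Culture scale: `xmax = 2e13` cells in `Vext = 1` L (a high-density
  fed-batch, OD ≈ 20), which makes the 1 g/L target correspond to about
  `1.1e8` naringenin molecules per cell through
  `K_Nar = mw * x(T) / (Av * Vext)`.

## Simulation protocol

`run_paired()` integrates the model once to the perturbation time
(`t_pert = 3900` min = 65 h by default), then continues twice from the
identical split state: unperturbed, and with the target pool stepped to
`(1 - reduction)` of nominal (default 60 %).  The two trajectories are
therefore exactly equal on `[0, t_pert]`.  The step-with-restart matches
a sudden availability change; no smoothing ramp is applied.  The horizon
`t_end = 7800` min (130 h) leaves the post-perturbation transient ample
time to settle; steady state before the perturbation is encouraged by
protocol length rather than enforced.

Integration uses `deSolve::ode` with `lsoda` (stiff-capable), `rtol =
1e-8`, `atol = 1e-6` molecules.  Solver probes may dip microscopically
below zero; states are clamped at zero before entering the strict
kinetic kernels, and output excursions below `1e-9` (relative) are
clipped.  Halving the tolerances moves default-protocol endpoints by
less than 0.01 %, which is the package's own regression bar.

## Objectives and constraints

For a paired run evaluated at the end of the experiment `T`:

* `J1 = |target - K * P_unp(T)|` — titer target error.  The norm bars
  are read as an absolute value so that `J1` is sign-free for
  minimization.  For naringenin, `K` is `knar_conversion()` (g/L); the
  default target is 1 g/L.
* `J2 = (P_unp(T) - P_pert(T)) / P_unp(T)` — production loss after the
  perturbation.  Kept signed: a negative value (production gain) is
  information, not an error, and the optimizer minimizes it either way.
* `J3` — oscillation count of the pre-perturbation sigma series: the
  clipped binary signal `X(k) = (sign(mean(sigma) - sigma(k)) + 1)/2`
  jumps at every mean-crossing and `J3 = 1/2 * sum (X(k) - X(k-1))^2`,
  so one full oscillation contributes 1.  Exact ties map to `X = 0.5`
  (they are measure-zero on real trajectories) and consecutive ties
  contribute nothing.

The naringenin MOP adds two feasibility constraints on the unperturbed
run, evaluated over the pre-perturbation window after a 10 % burn-in
(the window is a package choice; the burn-in excludes the start-up
transient from a cold start): free sigma at or above 4.5 µM, and sigma
at or above anti-sigma.  The total violation is the summed shortfall in
µM, and candidates are compared by Deb's feasibility rules.  Failed
integrations yield `+Inf` sentinel objectives rather than exclusion so
archive bookkeeping stays simple.

Decision variables follow the two bounds tables (`merging_bounds()`,
`naringenin_bounds()`); plasmid copy numbers are integers and proposals
are rounded before evaluation.  Two documented tensions in the source
tables are resolved in favor of the tables: the merging growth-rate
bounds `[0.005, 0.01]` min^-1 are used as printed even though prose
doubling times of 25–90 min would imply `[0.0077, 0.028]`, and `kd20` is
taken in molecules (`1e5`–`3.5e5`) with the µM quote left to the unit
helper.  The naringenin decision variable named for the controller
complex is mapped to the unbinding rate `k_minus_c`.  The 180 µM enzyme
ceiling is reported as a diagnostic (`E_max_uM`) rather than enforced,
since at the shipped defaults the enzyme stays far below it.

## The optimizer

`run_moea()` is DE/rand/1/bin with `F = 0.8`, `CR = 0.9` (standard
robust settings, exposed in `moea_config()`), reflection-then-clamp
bound repair, Deb-rule parent replacement, and an external archive of
mutually non-dominated solutions.  Archive members join the base-vector
pool with probability 0.5 (external-archive elitism).  Every evaluation
is cached on the decision vector rounded to 12 significant digits, so
identical candidates never re-trigger an ODE solve.  The seed is
mandatory and recorded in every output; identical seeds give
byte-identical archives.

Diversity is kept by *spherical pruning*: archive objective vectors are
min–max normalized to the archive's ideal/nadir box, mapped to
hyperspherical sectors (each of the `m - 1` angular coordinates binned
into `arcs` uniform divisions of `[0, π/2]`), and each sector keeps only
the member closest (Euclidean norm) to the ideal point.  Pruning fires
when the archive exceeds its capacity (defaults `arcs = 50`,
`capacity = 100`; the source method's internal constants are not
published, so these are package defaults).  Optional objective caps
(`obj_caps`) realize a pertinency bound in objective space.  Note that
pruning deliberately trades dominated hypervolume for spread: the
hypervolume-monotonicity property holds for archive *updates* and is
tested with pruning disabled (large capacity).

Infeasible-only archives keep the single least-violating candidate; the
first feasible arrival evicts them.

Desk-scale budgets are used throughout the package's own checks: the
merging MOP runs with a population of 20 for 14 generations (300
evaluations, about 2–3 minutes on one core) rather than the full
125-generation / 1000-evaluation study, and the analytic DE benchmark
uses 2000 evaluations.  These sizes are stated in the test and
acceptance code and were chosen so the whole suite runs in a few
minutes; the front structure (non-dominance, anti-monotone trade-off,
≥ 5 distinct designs) is already stable at this scale, and nothing in
the method depends on the budget beyond front density.

## Decision support

`pareto_table()` attaches level-diagram norms: objectives are min–max
normalized over the front and each solution is scored by the p-norm of
its normalized objective vector (`p = 2` by default; the norm used in
the original visualizations is not stated, and `p` is an argument).  A
solution has the same y-value in every level-diagram panel, which is
what makes the panels cross-readable.  `select_representatives()`
returns the per-objective extremes plus the minimum-norm compromise;
`tradeoff_stats()` reports Spearman correlations between objectives (on
a strictly non-dominated bi-objective front, exactly −1) and an optional
k-means regime labeling of the normalized front — a discussion aid,
never part of the optimization.

## What the shipped defaults do and do not show

The models are deterministic, single-compartment and host-agnostic: no
stochastic single-cell heterogeneity, no resource competition with the
host, no toxicity feedback from intermediate accumulation, and the
secondary pools are exogenous steps rather than mechanistic host
sub-models.  Passing the package's checks therefore demonstrates the
tuning machinery — correct model algebra against an independent symbolic
oracle, the dilution-sensitivity of antithetic adaptation, the dominance
structure of the Pareto libraries — not a quantitative prediction for
any particular strain.  The numeric registry is a calibrated stand-in
for unpublished kinetic tables and is documented as such; users with
measured parameters should load their own registry entry and re-run the
same workflow.

## A worked micro-example

```{r example, eval = FALSE}
# paired perturbation experiment at the registry defaults
p   <- merging_params()
pr  <- default_protocol("merging")
res <- run_paired("merging", p, pr)
j2_production_loss(endpoint(res$unperturbed)[["P"]],
                   endpoint(res$perturbed)[["P"]])
#> [1] 0.1496204

# scaled-down Pareto library for the merging MOP
opt <- optimize_merging(seed = 42)
tradeoff_stats(pareto_table(opt$archive))$spearman["J1", "J2"]
#> [1] -1
```
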