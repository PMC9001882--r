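# antitune

Model-based multiobjective tuning of biomolecular **antithetic feedback
controllers** for the dynamic regulation of merging metabolic pathways.

## The problem

In a merging pathway motif one enzymatic step consumes both a dedicated
precursor and an essential host metabolite. The canonical example shipped
here is naringenin production in *E. coli*: the chalcone synthase (CHS)
step merges p-coumaroyl-CoA with **malonyl-CoA**, a tightly regulated host
pool (4–40 µM) whose fluctuations act as a disturbance, and whose
over-accumulation is toxic — so the disturbance cannot be engineered away
at the source. A statically sized pathway loses production whenever the
pool dips. Dynamic regulation closes the loop instead: a biosensor reads
the product, and an antithetic controller (a σ factor annihilated
stoichiometrically by an anti-σ factor, the imbalance integrating the
control error) re-tunes enzyme expression.

Because growth dilution leaks the antithetic integrator, perfect
adaptation is lost *by construction* in vivo, and the design space becomes
a genuine trade-off between

* `J1` — titer target error, `|target − K·P_unp(T)|` (g/L for naringenin),
* `J2` — production loss after a perturbation,
  `(P_unp(T) − P_pert(T)) / P_unp(T)`,
* `J3` — oscillation count of the σ transient (a stability proxy),
  `½ Σ (X(k) − X(k−1))²` on the clipped binary mean-crossing signal,

subject (for the naringenin loop) to σ ≥ 4.5 µM and σ ≥ anti-σ. The
package tunes the accessible biological knobs — expression strengths,
plasmid copy numbers, dissociation constants, complex unbinding rate,
growth rate — by constrained multiobjective differential evolution with an
external non-dominated archive and spherical pruning, producing a **Pareto
library** of controller–biosensor designs plus level-diagram decision
support.

For whom: synthetic-biology / metabolic-engineering modelers choosing
gene-circuit parts for dynamic pathway regulation, and anyone needing a
compact, tested reference implementation of the antithetic-controller
tuning workflow.

## What is inside

| module | contents |
|---|---|
| models | `merging_rhs()`, `naringenin_rhs()` (6- and 16-state kinetic ODEs), shared kernels `mm_flux()`, `bisubstrate_flux()`, `hill_activation()`, `biosensor_fraction()`, `f_lux()/f_qdo()/f_p20()`; YAML parameter registry with units |
| simulate | `sim_protocol()`, `perturbation_spec()`, `integrate_model()` (deSolve/lsoda), `run_paired()` (shared pre-perturbation path), `endpoint()`, CSV export |
| objectives | `j1_titer_error()`, `j2_production_loss()`, `j3_count_oscillations()`, `knar_conversion()`, `evaluate_constraints()`, `evaluate_merging()`, `evaluate_naringenin()`, bounds tables |
| moea | `run_moea()` (DE/rand/1/bin + Deb rules + external archive), `spherical_prune()`, `hypervolume()`, `moea_config()` |
| analysis | `pareto_table()`, `pnorm_levels()`, `select_representatives()`, `tradeoff_stats()`, `level_diagram()`, `plot_front()` |
| cli | `cmd_simulate()/cmd_optimize()/cmd_analyze()` and the thin `inst/cli/antitune.R` script |

## Worked example

```r
library(antitune)

# 1. paired perturbation experiment at the registry defaults:
#    65 h of closed-loop production, then a 60% step down in S2
p   <- merging_params()
pr  <- default_protocol("merging")
res <- run_paired("merging", p, pr)
res$perturbed
#> <trajectory> 6 species x 1041 time points, t in [0, 7800] min
#>   event at t = 3900: S2_level reduced by 60% (to 4000)

j2_production_loss(endpoint(res$unperturbed)[["P"]],
                   endpoint(res$perturbed)[["P"]])
#> [1] 0.1496204
```

The closed loop loses 15 % of end-point product to the perturbation; the
titer-matched static design (`static_baseline_params()`) loses 42 % under
the same step — that difference is what the feedback buys.

```r
# 2. tune the controller/biosensor: scaled-down merging MOP
opt <- optimize_merging(seed = 42)
opt
#> <moea_result> 298 evaluations (seed 42), archive of 20 solutions

pt <- pareto_table(opt$archive)
select_representatives(pt)[, c("role", "solution_id", "J1", "J2")]
#>         role solution_id      J1      J2
#> 1     min_J1         150 0.02761 0.15222
#> 2     min_J2         135 3.22874 0.05042
#> 3 compromise         273 1.21024 0.09255
```

The library spans the expected trade-off: the design that nails the titer
target (`J1 = 0.028`) pays with a 15 % production loss, the most robust
design (`J2 = 0.050`) gives up titer, and the minimum-norm compromise sits
in between. Across the archive the J1–J2 Spearman correlation is exactly
−1 (`tradeoff_stats()`), the anti-monotonicity a true bi-objective Pareto
front must show. `level_diagram(pt, vars = c("a1", "kd20", "k_asigma",
"mu"))` plots each objective and decision variable against the common
normalized-norm axis.

The same workflow runs for the full naringenin loop
(`evaluate_naringenin()`, `mop_problem("naringenin")`); at the shipped
defaults the unperturbed design reaches 1.001 g/L with `J2 = 0.026`,
`J3 = 0.5`, and both controller constraints feasible.

A shell entry point wraps the three stages:

```sh
Rscript inst/cli/antitune.R simulate --config cfg.yaml --outdir out/
Rscript inst/cli/antitune.R optimize --config cfg.yaml --seed 1 --outdir out/
Rscript inst/cli/antitune.R analyze  --archive out/archive.csv --outdir out/
```

## Method notes

See the methods vignette (`vignettes/antitune-methods.Rmd`) for the model
equations and assumptions, the promoter-grouping and unit conventions, the
registry calibration rationale, optimizer internals and their defaults,
numerical tolerances, and known limitations (deterministic, homogeneous
population, host-agnostic).
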