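# crevo

Eco-evolutionary dynamics of metabolic allocation strategies under
non-linear tradeoffs.

## The problem

Classical consumer-resource theory caps the number of stably coexisting
species at the number of distinct resources `p` (competitive
exclusion). Models in which microbial uptake strategies trade off
*linearly* against a fixed metabolic budget seem to escape that cap and
sustain essentially unlimited diversity. `crevo` implements the
consumer-resource model that resolves this tension: strategies
`α = (α₁, …, α_p)` (per-capita uptake efforts) constrained to the
budget surface

```
Σⱼ αⱼ^γ = E,
```

with Monod resource uptake `rⱼ(c) = c/(Kⱼ+c)`, evolving by
mutation-selection dynamics in a chemostat or a serial-dilution
(batch-culture) ecology. The curvature `γ` of the tradeoff decides the
outcome:

* `γ < 1` (concave): the singular strategy
  `αⱼ* = (sⱼ/Σₖsₖ)^(1/γ)` is an evolutionary **branching point** — the
  population diversifies into at most `p` coexisting specialists, one
  per resource;
* `γ > 1` (convex): `α*` is a convergent-stable **ESS** — a single
  generalist, no diversification;
* `γ = 1` (linear): the invasion-fitness Hessian vanishes —
  **neutral**, diffusive diversification; unlimited coexistence is an
  artifact of this structurally unstable knife-edge.

The package provides the ecological integrators (compiled RHS via
`deSolve`), closed-form and numerical adaptive-dynamics analytics
(singular strategy, invasion fitness, selection gradient,
convergence/evolutionary stability), a mutation-selection evolution
engine, community observables (single-linkage phenotype clustering,
specialist classification, simplex projection), random-community
ecological assembly, scenario presets, and a small CLI (`exec/crevo`).

For whom: theoretical ecologists and evolution modellers who want a
tested, scriptable implementation of adaptive dynamics on non-linear
tradeoff surfaces — and a reference for how the linear special case
misleads.

## Worked example

```r
library(crevo)

spec <- tradeoff_spec(0.9, p = 3)                   # concave tradeoff
env  <- environment_spec(supply = c(1, 1, 1), monod_K = 1,
                         decay = 0.1, death_rate = 0.25)

# Analytics: the singular strategy and its classification
report <- classify_singular_point(
  environment_spec(supply = c(1, 1, 1), death_rate = 0.25), spec)
report
#> Singular strategy report  
#>   alpha* = 0.295029, 0.295029, 0.295029 
#>   classification: branching_point 
#>   Hessian eigenvalues: 0.09574, 0.09574 
#>   Jacobian eigenvalue real parts: -0.8617, -0.8617 
#>   branching directions: 1, 2, 3 

# Evolution from a single off-center ancestor
traj <- run_evolution(project_to_constraint(c(0.8, 0.15, 0.05), spec),
                      spec, env, evolution_params(rng_seed = 1))
cluster_phenotypes(traj$final, spec)
#> Phenotype clusters (single linkage, cutoff 0.2)
#>  cluster total_density n_strains specialist resource 1      2      3
#>        1      3.866738       285       TRUE        2 0 0.9999 0.0000
#>        2      3.866626       224       TRUE        1 1 0.0000 0.0000
#>        3      3.866594       164       TRUE        3 0 0.0000 0.9999
```

The population first converges to `α* ≈ (0.295, 0.295, 0.295)`
(distance shrinking below 0.05), then branches into three clusters,
each a specialist holding ≥ 0.9 of its budget share on a distinct
resource — the competitive-exclusion limit of 3 species on 3 resources.
Re-running with `tradeoff_spec(1.1, p = 3)` instead ends with a single
generalist cluster whose mean sits within ~10⁻³ of `α*`.

The same endpoints arise without mutation, from pure ecology:

```r
ecological_assembly(200, spec, env, seed = 1)$summary$clusters
#>   cluster total_density n_strains specialist resource
#> 1       1      4.057480         1       TRUE        2
#> 2       2      3.914263         1       TRUE        1
#> 3       3      3.612137         1       TRUE        3
```

Serial-dilution ecology (`ρ₀ = 10⁻³`, `c_fin = 10⁻⁸`,
`c(0) ∈ {0.1K, K, 10K}`) is available through
`dilution_protocol()` / `run_serial()`, or
`run_evolution(..., protocol = )`; presets for all scenarios ship with
the package (`crevo_presets()`), and the CLI mirrors them:

```sh
exec/crevo evolve --preset chemostat_gamma09 --seed 1 --out out/
exec/crevo classify-singular --preset chemostat_gamma11
```

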