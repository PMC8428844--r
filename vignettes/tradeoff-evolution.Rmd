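---
title: "Consumer-resource evolution under non-linear metabolic tradeoffs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-resource evolution under non-linear metabolic tradeoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crevo)
```

## The model

`crevo` simulates a well-mixed microbial community competing for `p`
substitutable resources. A strain is its metabolic allocation strategy
$\alpha = (\alpha_1, \dots, \alpha_p)$, $\alpha_j \ge 0$: the per-capita
effort invested in taking up resource $j$. Resource availability
saturates as a Monod function $r_j(c_j) = c_j / (K_j + c_j)$, and the
per-capita birth rate equals the total nutrient absorbed,
$\sum_j \alpha_j\, r_j(c_j)$.

Allocation is constrained by a metabolic budget with curvature
$\gamma$:

$$\sum_{j=1}^p \alpha_j^{\gamma_j} = E ,$$

concave for $\gamma < 1$, linear at $\gamma = 1$, convex for
$\gamma > 1$. All presets use $E = 1$; `budget` stays a parameter for
generality. The package supports a per-direction exponent vector
$\gamma_j$ and, independently, non-linear uptake
$\alpha_j^{q_j} r_j(c_j)$, because either non-linearity has the same
effect on the evolutionary outcome (see *Reparametrization* below).

Two ecologies share one integrator:

* **Chemostat** — supply $s_j$, resource decay $\mu_j$, death rate
  $\delta$:
  $\dot c_j = s_j - \big(\sum_a n_a \alpha_{aj}^{q_j}\big) r_j(c_j) - \mu_j c_j$,
  $\dot n_a = \big(\sum_j \alpha_{aj}^{q_j} r_j(c_j) - \delta\big) n_a$.
* **Serial dilution** — batches with $\delta = \mu = 0$: growth mirrored
  exactly by consumption, batch ends when $\sum_j c_j \le c_{fin}$, then
  dilution to total density $\rho_0$ into fresh medium $c_j(0)$. With
  $q = 1$ the quantity $\sum_a n_a + \sum_j c_j$ is conserved within a
  batch to solver precision, which the tests assert.

Reference parameterization (used throughout the tests and the
acceptance script): $p = 3$, $s_j = 1$, $\mu_j K_j = 0.1$, and
$\delta \in \{0.25, 1\}$; dilution runs use $\rho_0 = 10^{-3}$,
$c_{fin} = 10^{-8}$ and $c_j(0) \in \{0.1K, K, 10K\}$. The product
$\mu K$ only is fixed by the reference description; we realise it as
$K_j = 1$, $\mu_j = 0.1$, so that concentrations and half-saturation
constants share units — any other split with the same product is
equivalent after rescaling $c$.

### A note on the $\delta = 1$ linear-tradeoff reference case

With $E = 1$ and $\gamma = 1$, per-capita birth is bounded by
$\max_j r_j < 1$, so a death rate $\delta = 1$ exceeds every achievable
birth rate and the population decays to extinction. `run_evolution()`
detects the collapse and stops with a warning. The linear-case
demonstrations in this package therefore use $\delta = 0.25$; the
neutrality structure at $\gamma = 1$ (a vanishing fitness Hessian) does
not involve $\delta$.

## Adaptive dynamics

With $\mu = 0$ a monomorphic resident $\alpha$ has the closed-form
equilibrium

$$n^* = \frac{\sum_j s_j}{\delta}, \qquad
  r_j^* = \frac{s_j}{n^* \alpha_j^{q_j}}, \qquad
  c_j^* = \frac{K_j r_j^*}{1 - r_j^*},$$

feasible only while every $r_j^* < 1$ (the resident must be able to
absorb the full supply at a finite concentration; strongly asymmetric
supplies with concave $\gamma$ violate this, and the package signals
infeasibility rather than returning a spurious equilibrium). Invasion
fitness of a rare mutant $\alpha'$ is
$f(\alpha';\alpha) = \sum_j (\alpha'_j)^{q_j} r_j^* - \delta$, linear in
$(\alpha')^{q}$ — all curvature of the constrained fitness landscape
comes from the tradeoff surface itself.

The selection gradient vanishes at the singular strategy

$$\alpha_j^* = \left(\frac{E\, q_j s_j / \gamma_j}
  {\sum_k q_k s_k / \gamma_k}\right)^{1/\gamma_j},$$

which for uniform $\gamma$ and $q = E = 1$ reduces to the familiar
$\alpha_j^* = (s_j / \sum_k s_k)^{1/\gamma}$. The general form is the
tangency condition $\nabla f \parallel$ constraint normal; a naive
componentwise application of the uniform-$\gamma$ formula to
heterogeneous exponents does *not* satisfy it (the residual gradient is
of order $10^{-2}$ in the mixed case tested), which is why the package
solves the tangency condition instead.

`classify_singular_point()` computes, by central differences in an
orthonormal tangent basis with all probe mutants re-projected onto the
surface:

* the tangent-space **Hessian** of invasion fitness (evolutionary
  stability): all eigenvalues negative → ESS endpoint; any positive →
  branching point; all within $\pm 10^{-8}\delta$ → neutral;
* the **Jacobian** of the selection gradient with respect to the
  resident (convergence stability): negative real parts mean the
  singular strategy attracts monomorphic evolution.

The numerics satisfy the sign law
$\mathrm{sign}(\max \mathrm{eig}\, H) = \mathrm{sign}(1 - \gamma)$,
with convergence stability holding for every tested $\gamma$, and with
mixed exponents $(0.9, 1.1, 1.1)$ flagging exactly the concave
direction as branching.

**Finite-difference steps.** First derivatives use $h = 10^{-6}$.
Second derivatives default to $h = 10^{-3}$: the neutrality test at
$\gamma = 1$ must resolve a Hessian that is exactly zero against
round-off of order $\varepsilon / h^2$, which at $h = 10^{-3}$ is
$\sim 10^{-10}$ — two orders below the $10^{-8}\delta$ tolerance —
while truncation error $O(h^2)$ stays far below the smallest genuine
eigenvalue probed ($\gamma = 0.99$). Sign stability under halved and
doubled steps is part of the test suite. For uniform $\gamma$ the
surface projection uses an exact closed form, so no projection noise
enters the differences.

## The evolution engine

`run_evolution()` alternates ecological relaxation (100 time units of
chemostat integration, or 5 dilution cycles, per epoch) with mutation:
5 mutants per epoch, parents drawn proportionally to density, each
mutant an isotropic Gaussian step of s.d. $\sigma = 0.03$ clipped to
$\alpha_j \ge 0$ and re-projected onto the surface, seeded with 1% of
the parent's density. Strains below $10^{-6} \sum_j s_j / \delta$
(chemostat) or $10^{-9}\rho_0$ (post-dilution) are culled at epoch
boundaries.

These mutation parameters are the package's own choice; the relevant
physical regimes they respect are (i) timescale separation — a mutant's
establishment time is short compared with the epoch's ecological
relaxation — and (ii) locality, $\sigma \ll$ the inter-vertex distance.
They were set from a diagnostic of the branching timescale: escape from
a branching point is mutation-limited and scales roughly like
$\sigma^{-2}$, and weaker settings (e.g. $\sigma = 0.01$ with one
mutation per epoch) leave the population stuck in the pre-branching
cloud for tens of thousands of epochs without changing any endpoint.

**Stop rule.** The run ends when, over a 400-epoch window, the
single-linkage cluster count is constant, the density-weighted mean
phenotype drifts by at most 0.02, the total trait variance ranges over
at most $\max(0.002, 0.1 \cdot \mathrm{var})$, and the cluster
configuration is evolutionarily *final*. The last condition exists
because en route to full specialization the population passes through
quasi-stationary intermediates — a dimorphic state whose two-resource
generalist cluster must itself branch — that can sit flat in every
windowed statistic for many hundreds of epochs (escape from a
branching point is mutation-limited, with a seed-dependent waiting
time). Finality is read off the tradeoff geometry: along directions of
effective concave curvature ($\gamma_j / q_j < 1$) selection at a
singular configuration is disruptive, so a cluster whose budget is
still split across **two or more** concave directions (shares between
0.1 and 0.9) has a branching ahead of it and blocks the stop. One
interior concave share is allowed — a split along a single direction
cannot separate two viable daughters, and mixed-curvature endpoints
legitimately hold such a compromise share. Neutral ($\gamma = 1$) runs
never satisfy the variance guard and end at `max_epochs`, the intended
behaviour for a diffusively broadening cloud.

**Determinism.** All randomness flows from `rng_seed`; identical seeds
and parameters reproduce event logs and trajectories bitwise.

## Observables

Communities are summarised by single-linkage clustering in trait space
with cutoff 0.2 — far above a mutation-selection cloud width
($\sim \sigma$), far below the inter-vertex distance $\sqrt 2$. Cluster
centers are density-weighted means; a center is a *specialist* when one
budget share $\alpha_j^{\gamma_j}/E$ reaches 0.9. The simplex
projection $(\alpha_j^{\gamma_j}/E)_j$ is also the coordinate system
used for plotting three-resource communities.

`ecological_assembly()` seeds `n_species` random strategies (uniform on
the budget-share simplex — an unbiased choice; the sampling measure is
otherwise unconstrained) and runs plain ecology. Endpoints mirror the
evolutionary ones: $p$ specialist clusters for $\gamma < 1$, survivors
concentrated at $\alpha^*$ for $\gamma > 1$, and a large coexisting set
for $\gamma = 1$. For $\gamma > 1$ "concentrated" is measured as the
density-weighted mean simplex distance of the surviving community to
$\alpha^*$ (observed $\approx 0.02$–$0.05$, tested against 0.1): with
$p$ resources, a stationary survivor set may legitimately include a
low-density satellite strain at moderate distance (up to $p$ species
can coexist), so a maximum-distance criterion would reject genuine
ecological coexistence. The chemostat assembly budget is $2\times10^5$
time units because the final sorting near the singular strategy is
quasi-neutral, with decay rates of order $|H| d^2 \sim 10^{-4}$.

## Reparametrization

For uniform $\gamma$, `reparametrize()` maps $\beta_j = \alpha_j^\gamma$
onto the linear surface $\sum_j \beta_j = E$ with uptake exponents
$q' = 1/\gamma$; per-capita growth is identical for every resource
state, so full community trajectories of the two representations agree
to solver precision (tested at $10^{-8}$ relative). This is the formal
sense in which a tradeoff non-linearity and an uptake non-linearity are
the same thing, and why sub/super-linear uptake alone
(`uptake_exponent` $\ne 1$, effective curvature $\gamma/q$) restores
the competitive-exclusion outcome even under a linear budget.

## Numerical choices

* Right-hand sides are compiled (C, via `deSolve`'s compiled-code
  interface); an R mirror (`chemostat_derivatives()`) is the oracle in
  tests.
* Default integrator: fixed-order Adams (`lsode`, `mf = 10`) — the
  per-capita rates are bounded by the budget scale and Monod factors,
  so the system is non-stiff in the intended regimes and Adams is an
  order of magnitude faster than stiff-switching `lsoda` on large
  communities; `method = "lsoda"` remains available. Batch depletion
  uses `lsodar` root-finding (stopping residual $\sim 10^{-10}$ on
  $\sum_j c_j - c_{fin}$).
* Tolerances default to `rtol = 1e-8`, `atol = 1e-10`; negative solver
  undershoots contribute zero uptake inside the RHS and are clipped at
  checkpoints.
* Surface projection: closed form for uniform $\gamma$; bracketed root
  plus Newton polishing (to machine precision) otherwise. $0^\gamma$ is
  0; vertices are therefore valid phenotypes, and the clip-then-project
  mutation kernel can reach them exactly, which the $\gamma < 1$
  endpoint requires.

## Problem sizes used by the test-suite

Stochastic endpoint checks run 5 seeds for the $\gamma = 0.9$ chemostat
and the $c(0) = K$ dilution regime (passing in at least 4), and 2 seeds
each for the $c(0) = 10K$ and $0.1K$ regimes; $\gamma = 1.1$ endpoints
and the mixed-exponent run use one seed each, with observed margins
(distance to $\alpha^*$ $\approx 10^{-3}$ against a bound of 0.05) that
make seed-to-seed variation immaterial. Assemblies use 200 founder
species. These sizes are the package's own choices for a
routinely-runnable suite; nothing about the dynamics changes at larger
sizes.

## What the generator does and does not emulate

The synthetic communities emulate the model: fixed (non-plastic)
allocation strategies, substitutable resources, well-mixed batch or
chemostat environments, mutation as rare small phenotypic steps.
Passing tests therefore demonstrate properties of this model class, not
of real microbial data: there is no demography/drift beyond
deterministic densities plus mutational chipping, no cross-feeding, no
regulation of allocation within a lifetime, and no measurement noise.
The headline qualitative claim — diversification capped at $p$ species
unless the tradeoff is exactly linear — is in that sense a statement
about the structural instability of the linear case.

## Known limitations

* The $\mu = 0$ closed forms (equilibrium, invasion fitness, the
  analytics behind `classify_singular_point()`) require feasibility
  $r_j^* < 1$; classification under $\mu > 0$ is offered numerically
  and flagged approximate.
* Cluster counting is metric single-linkage with a fixed cutoff; it is
  deterministic and oracle-checkable but will chain together clouds
  that approach within the cutoff (this is why a uniform simplex sample
  counts as one cluster).
* The serial-dilution evolution engine treats an epoch as a fixed
  number of batches; batch-to-batch oscillations within an epoch are
  not resolved in the snapshots.
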