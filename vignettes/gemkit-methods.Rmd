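---
title: "Models and methods in gemkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gemkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemkit)
```

gemkit is a toolbox for building and interrogating genome-scale metabolic
models (GEMs). This vignette explains the models behind each component, the
parameters that matter, what the synthetic data emulate, and the design
choices made where more than one defensible option existed.

## The constraint-based model

A GEM is a stoichiometric matrix $S$ (metabolites × reactions) with flux
bounds $lb \le v \le ub$ in mmol/gDW/h inside a default ±1000 box. Steady
state imposes $S v = 0$ for every internal metabolite. Reversibility is
encoded solely through the bounds: a reaction is reversible iff $lb < 0$,
and the positive direction is left-to-right as the equation is written.
Exchange reactions connect single metabolites to the environment (positive
flux = excretion, negative = uptake). Exchange status is an explicit
attribute rather than a structural inference, because net stoichiometry
cannot distinguish an exchange from a mass-creating internal reaction such
as `B => 2 B`; in SBML it travels as the standard SBO term for exchange
reactions (SBO:0000627).

Metabolite instances are written `base[compartment]` (`glc[c]`). Formulas
are parsed in Hill notation; generic tokens (R-groups, polymer `(...)n`)
mark a metabolite composition-unknown so that KEGG-style generic formulas
never poison elemental balancing. Per-element balance tolerance is 1e-6,
loose enough for the floating coefficients of lipid and biomass
pseudo-reactions.

## The LP/MILP kernel

No linear-programming package is assumed to be installed, so the package
carries its own kernel: bounded-box LPs are rewritten into standard form
(shift to lower bounds, slack columns, an upper-bound row per variable) and
solved by a two-phase revised simplex with Bland's rule, re-factorizing the
basis at every pivot. That is asymptotically wasteful but numerically
docile, and the MILP diagnostics here operate on curation-scale networks
where robustness beats speed. The kernel is validated in the test suite
against hand-derived optima and against frozen reference values computed
with an independent solver (scipy's HiGHS interface) on randomly generated
instances.

Binary decisions use branch-and-bound with two safeguards worth noting:

* **Rounded re-solve.** A relaxation whose binaries look integral within
  tolerance is re-solved with the binaries pinned to their rounded values
  before being accepted. With big-M indicator rows ($|v| \le M y$,
  $M = 1000$), a $y$ of $10^{-6}$ still admits $10^{-3}$ of flux — exactly
  the production threshold — so "looks integral" must never be trusted.
* **Lexicographic tie-break.** Minimal-cardinality answers are generally
  non-unique. After the cardinality optimum $k^*$ is found, a second solve
  fixes $\sum y = k^*$ and minimizes the sum of reaction ranks, so reported
  minimal sets are reproducible across runs and platforms.

Quadratic steps (MoMA, exchange-flux fitting) go through quadprog; the
weighted least-squares objective of exchange fitting is made strictly
convex with a 1e-8 ridge on unmeasured fluxes.

## Gap diagnostics

Two distinct semantics of "net synthesis" are implemented deliberately:

* `make_something()` asks for a flux with $S v \ge 0$ elementwise and total
  production at least `production_epsilon` (default 1e-3), with all
  exchanges closed — a *free lunch*, possible only through unbalanced
  chemistry. The answer is the minimal reaction set supporting it.
* `can_produce()` asks whether an LP with a temporary sink demanding
  `production_epsilon` of one metabolite is feasible under the user's
  exchange bounds — ordinary producibility.

`production_epsilon` separates a real leak from numerical noise
(`flux_tolerance`, 1e-6); the invariant `big_m > epsilon > tolerance > 0`
is enforced by `gap_config()`. `check_production()` gates one artificial
synthesis reaction per non-producible metabolite behind a binary and
demands a sink for every metabolite simultaneously — valid because feasible
flux distributions add, so simultaneous production is equivalent to
per-metabolite production. `have_flux()` opens the exchanges the model
already has (it never invents new ones) and classifies blocked reactions by
whether a free product sink (downstream block), a free substrate source
(upstream block), or only both together (`blocked_both`, a class the
enum needed in practice) restores flux. `fill_gaps()` shares one set of
selection binaries across one flux block per goal component (metabolite to
produce, task to satisfy, reaction to unblock); reversible unblock targets
get a direction binary since $|v| \ge \epsilon$ is disjunctive.

## Draft reconstruction

Bidirectional best hits are computed best-first, filter-second: the best
hit (lowest E-value, ties by bitscore, all co-best kept) is determined
among all hits, and the thresholds then decide whether the reciprocal pair
is accepted. The alternative — filtering before picking the best —
violates monotonicity: relaxing a cutoff could promote a different best hit
and silently drop previously accepted orthologues. Defaults are E < 1e-30,
identity > 40%, coverage > 50%, alignment > 200 aa; the coverage criterion
is skipped with a warning when the hit table lacks the optional coverage
column, because query lengths are not part of the 12-column dialect.

For group-database drafts the default score cutoff is 1e-50, the
conservative choice for de-novo reconstruction of a poorly annotated
organism; 1e-30 suits re-annotation settings with abundant close homologs.
Both appear in practice and the tension is documented rather than resolved.
An infinite cutoff includes every group — even ones no gene scored against
— so that the no-filter draft reproduces the database exactly.

## Localization by simulated annealing

The connectivity predicate: every metabolite instance must be produced by
at least one reaction and consumed by at least one reaction in its
compartment, where reversible reactions (and the reversible passive
transports the method adds) count as both. Metabolites touched by exchange
reactions, and a user-supplied cofactor list, are exempt. For a candidate
assignment the minimal transport set is derived directly from the
predicate: a metabolite with $k$ deficient instances needs
$\lceil k/2 \rceil$ transports (one transport heals both endpoints). This
replaces a stated alternative — greedily searching for a small set of
reactions to move before adding a transport — because reaction moves are
already the annealer's proposal space; folding them into the repair step
would search the same neighborhood twice.

Proposals move one gene product (picked with probability proportional to
how poorly it is placed) to another compartment (picked proportionally to
its score there), with Metropolis acceptance under geometric cooling
(T ← 0.99·T per step, T₀ = 0.5, 10·|genes| steps by default — the
literature gives no schedule, so a conventional one is used). Scores are
normalized to per-gene probabilities before use; raw predictor outputs
differ wildly in scale between tools, and normalization makes the
transport-cost unit (default 0.1) meaningful across predictors. Seeds are
mandatory and reported with every solution. On fixtures small enough for
exhaustive search the annealer is required (and tested) to reach the global
optimum in at least 2 of 3 seeded runs.

## Simulation choices

Shadow prices follow the convention *positive = extra availability of the
metabolite increases the objective*. LP duals are reported, but they are
degenerate whenever the optimal basis is — dead-end metabolites are the
classic case — so `shadow_price_fd()` provides a finite-difference estimate
with an *optional* source (bounds [0, ε]); a fixed source would render the
LP infeasible for any metabolite the network cannot absorb.

Where auxiliary fluxes at an optimum are reported (e.g. a
transhydrogenation probe at a product optimum), `fba(pfba = TRUE)` first
fixes the objective and minimizes total absolute flux, collapsing
alternate-optima churn into a reproducible number.

Deletion screens prune supersets of combinations that already abolish the
objective — a genome-scale triple screen is otherwise on the order of 10⁸
LPs. Where a deletion's effect on a secondary product is reported, the
product is re-optimized at the fixed primary optimum in a chosen direction
(`coupling_mode = "max"` for best-case coupling, `"min"` for guaranteed
flux); both readings of "product increase when maximizing growth" are
available because the published setup does not pin one down.

Maintenance fitting regresses $q_{ATP} = m_{ATP} + K_{xATP}\,\mu$ across
chemostat dilution rates; when the table carries per-measurement
uncertainties the fit is weighted by $1/\sigma^2$, which matters because
chemostat rate errors are roughly relative, making high-rate points noisier
in absolute terms. P/O fitting grid-searches the ATP-synthase proton
stoichiometry (default grid 1–6 in steps of 0.05), re-running the model per
candidate; a flat error profile is flagged non-identifiable and a boundary
optimum warns that the truth may lie outside the grid.

Cofactor-cycle blocking adds the probe (NADH + NADP⁺ ⇌ NAD⁺ + NADPH),
closes carbon uptakes (exchanges of metabolites whose formula contains
carbon, or whose composition is unknown — erring safe), and while the probe
carries flux deletes the most active internal cycle member, ties broken by
reaction id for determinism.

## Sampling and omics integration

The flux polytope is sampled by hit-and-run on an orthonormal null-space
parameterization of $S$: a strictly interior start is found by maximizing
the minimal slack to the bounds, each step jumps to a uniform point on the
feasible chord along an isotropic random direction, with 1000 warm-up steps
and thinning 10 by default. Empty-interior polytopes (equality-constrained
points) return a single flagged point rather than pretending to mix.

Regulated-reaction calls are a deliberate conjunction: flux significantly
higher in condition B (one-sided rank-sum test on the sampled
distributions, p < 0.05 — rank-based because no parametric form for sampled
flux marginals is justified) *and* at least one associated gene
significantly up-regulated (p < 0.005, positive direction). For expression,
isozymes count if any gene passes. Ranking uses Fisher's combination of the
two p-values. Reporter Metabolites aggregate neighbor-gene evidence as
$Z_{met} = (1/\sqrt{k}) \sum \Phi^{-1}(1 - p)$ and are corrected by the
mean and standard deviation of the same statistic over random $k$-gene
sets, so corrected scores are standard normal under the null — a property
the acceptance suite checks at genome-like scale (1235 metabolites, 1006
genes, 10,000 background draws; sizes chosen to match a real fungal GEM).

## What the synthetic data emulate — and what they do not

The fixture generators are pure functions of their parameters and seed.

* The **toy networks** instantiate one failure mode each (free lunch, dead
  end, missing step with a worse bypass, plantable compartment split,
  closed-form yield, futile cofactor cycle) with fully specified formulas,
  so every MILP answer is checkable by exhaustive enumeration.
* The **chemostat series** plants $m_{ATP} = 4.14$ mmol ATP/gDW/h and
  $K_{xATP} = 104$ mmol ATP/gDW on dilution rates 0.025–0.2/h — the regime
  of glucose-limited cultures of an industrial filamentous fungus — with
  5% relative Gaussian noise as the realistic measurement error.
* The **respiration cartoon** pumps 10 protons per NADH and plants a
  synthase stoichiometry of 3.75 H⁺/ATP, making maximal ATP per NADH equal
  10/3.75.
* The **two-condition expression fixture** caps one branch of a forked
  uptake so the alternative branch's sampled flux genuinely shifts, and
  plants one strongly up-regulated gene on it.

A green test on these fixtures establishes that the algorithms are correct
on networks whose answers are provable — not that a specific published
organism-scale result is reproduced. Reproduction of the published
penicillin-producer numbers requires that model's supplementary dataset,
which cannot be redistributed here; the acceptance suite encodes that
pipeline and runs it whenever the file `inst/extdata/iAL1006.xml` is
supplied, and fails visibly otherwise.

## Known limitations

* The simplex kernel is dense and refactorizes per pivot: fine up to a few
  hundred rows, not intended for genome-scale FVA sweeps in tight loops.
* All transports created by the localization method are passive diffusion;
  active transport and membrane topology are out of scope.
* Workbook writing emits TSV sheets only (no xlsx writer is available);
  xlsx is read-only.
* The map parser targets the SBML layout subset (reaction/species glyph
  bounding boxes), not the full CellDesigner annotation dialect.
* Dual values at degenerate optima are basis-dependent; use the
  finite-difference cross-check where it matters.
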