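# gemkit

Reconstruction, quality control, simulation and omics integration of
genome-scale metabolic models (GEMs), in R.

A GEM collects every annotated metabolic reaction of an organism into a
stoichiometric matrix **S** (metabolites × reactions). At steady state the
flux vector **v** satisfies **S·v = 0** with box bounds **lb ≤ v ≤ ub**, and
flux balance analysis (FBA) maximizes an objective **cᵀv** over that
polytope. Around this core, gemkit covers the workflow a model builder
actually runs:

- **Draft reconstruction from homology** — transfer reactions from curated
  template models via bidirectional-best-hit orthology
  (`bidirectional_best_hits()`, `draft_from_templates()`; default cutoffs
  E < 1e-30, identity > 40%, coverage > 50%, alignment > 200 aa), or
  assemble a draft from an orthology-group (KO-style) reaction database
  with per-gene scores (`draft_from_group_db()`).
- **I/O** — SBML Level 3 + fbc writing, SBML L3/fbc and legacy L2 reading
  (`read_sbml()`, `write_sbml()`), and a tabular workbook dialect stored as
  TSV sheets (`read_tabular_model()`, `write_tabular_model()`; `.xlsx`
  workbooks with the same sheets are read via readxl).
- **Gap analysis (MILP)** — smallest reaction set creating mass from nothing
  (`make_something()` / `consume_something()`; a feasible answer means some
  reaction is unbalanced), iterative removal of such reactions
  (`remove_bad_reactions()`), producibility (`can_produce()`), minimal
  enabling metabolite sets with unlock maps (`check_production()`),
  dead-end classification into upstream/downstream blocks (`have_flux()`),
  connected subnetworks (`get_subnetworks()`), and minimal gap filling from
  template universes (`fill_gaps()`).
- **Compartment assignment** — simulated annealing that trades predictor
  scores (WoLF PSORT / CELLO dialects, `parse_predictor_output()`) against
  the number of transport reactions needed to keep every metabolite both
  produced and consumed in its compartment (`predict_localization()`,
  fitness = Σ score − transport_cost × #transports, default cost 0.1).
- **Simulation** — FBA with shadow prices (`fba()`, `shadow_prices()`,
  finite-difference cross-check `shadow_price_fd()`), MoMA (`moma()`),
  combinatorial deletion screens up to triple knockouts
  (`deletion_screen()`), task validation (`check_tasks()`), maintenance-ATP
  regression `q_ATP = m_ATP + K_xATP·µ` (`fit_maintenance()`), P/O-ratio
  fitting via the ATP-synthase proton stoichiometry (`fit_po_ratio()`),
  futile cofactor-cycle blocking (`block_cofactor_cycles()`), and maximal
  product yields under a defined medium (`theoretical_yield()`).
- **Omics integration** — quadratic fitting of exchange fluxes to measured
  rates (`fit_exchange_fluxes()`), hit-and-run sampling of the flux
  polytope (`sample_flux_space()`), transcriptionally regulated reactions
  across two conditions (`regulated_reactions()`), and Reporter Metabolite
  scoring `Z_met = (1/√k) Σ Φ⁻¹(1−p_gene)` with random-set background
  correction (`reporter_metabolites()`).
- **Visualization** — flux fold-change overlays on layout-annotated SBML
  maps, exported as SVG (`parse_map()`, `render_overlay()`).
- **Fixtures** — deterministic generators for every toy network and
  synthetic dataset used in the tests (`make_toy_models()`,
  `make_chemostat()`, `make_expression_and_fluxes()`, `biomass_table()`).

No LP/MILP solver package is assumed: the package ships a dense two-phase
simplex with branch-and-bound (`solve_lp()`, `solve_milp()`), sized for the
curation-scale problems the MILP diagnostics target; QP steps use quadprog.

## Worked example

```r
library(gemkit)
toys <- make_toy_models()

# FIX2 is a chain A -> B -> C with an illegal duplication B -> 2B.
make_something(toys$FIX2)
#> Gap report [make]: status optimal
#>   reactions: R4
```

With all exchanges closed, the smallest reaction set that still creates
mass is `{R4}` — the planted unbalanced reaction. On the clean chain the
same MILP is infeasible: the model conserves mass.

```r
fba(toys$FIX5)
#> Flux distribution (optimal)
#>   objective value: 2
#>   4 of 4 reactions carry flux
```

FIX5 caps substrate uptake at 1 mmol/gDW/h and each substrate yields two
product molecules, so the maximal product flux — and the molar yield — is
exactly 2.

```r
predict_localization(toys$FIX4, fix4_localization_scores(), c("c", "m"))
#> Localization solution (fitness 3.5, seed 1)
#>   c: 2 genes; m: 2 genes
#>   1 transport reaction(s) added
```

The annealer recovers the planted split (two cytosolic, two mitochondrial
gene products, fitness 4×0.9 − 0.1×1 = 3.5), matching the exhaustive search
over all 16 assignments.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gemkit.R qc --in model.xml --report qc.json
Rscript inst/cli/gemkit.R yield --in model.xml --substrate EX_glc --product EX_pen
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main pipeline from scratch against generated inputs — the QC
MILPs, gap filling, yield computation, maintenance and P/O fits, annealed
localization, flux-space sampling with regulated-reaction calls, and the
Reporter-Metabolite null calibration — logging each stage and writing the
results JSON to `--out`. All randomness derives from `--seed`.
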