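---
title: "From medium recipes to FBA constraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From medium recipes to FBA constraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfba)
```

## The modelling problem

Flux balance analysis (FBA) predicts a flux distribution `v` by solving the
linear program

```
maximise   c·v
subject to S·v = 0,   lb ≤ v ≤ ub
```

where `S` is the stoichiometric matrix and `c` selects the biomass
pseudo-reaction. The chemical environment enters exclusively through the
bounds of *exchange reactions* — pseudo-reactions with a single external
metabolite whose negative flux is uptake and positive flux is secretion.
`dietfba` addresses the step that precedes any such simulation: deriving
those bounds from a medium that is described, as real media are, at the
level of chemically complex components.

Two simulation regimes share the same mechanics but different units:

* **Yield mode** (the default): uptake bounds are concentrations in mmol
  per litre of medium. Because BiGG-convention biomass reactions are
  normalised so that unit flux produces 1 g of dry weight, the objective is
  then a biomass *yield* in gDW per litre of medium.
* **Rate mode**: uptake bounds are fluxes in mmol/gDW/h and the objective
  is a growth *rate* (hr⁻¹ scale). Converting concentrations to uptake
  fluxes requires compound- and organism-specific kinetics (e.g. Monod
  terms); that conversion is intentionally out of scope — the user supplies
  fluxes directly.

## The compilation pipeline

`compile_diet()` fixes the order of operations, because the operations do
not commute:

1. **Decomposition.** Each complex component of mass `A` g/L with a
   composition entry `(compound, mass fraction f)` contributes `A·f` g/L of
   that compound. Composition tables are validated so the fractions of a
   component never sum above 1 + 10⁻⁶: a component cannot yield more mass
   than itself. Fractions may sum below 1 (uncharacterised residue), which
   is the realistic case for hydrolysates.
2. **Mass → molar.** `conc = mass / MW × 1000` mmol/L. Molecular weights
   come from the user's compound registry; a missing weight is an error
   that names the compound rather than a silent drop.
3. **Merging.** The same molecule arriving from several components (e.g.
   glycine from both tryptone and yeast extract) is summed; each entry
   keeps the full list of transformation records, so every number in the
   final diet can be audited back to a recipe line. Entries are kept in
   lexicographic compound order, which makes compilation invariant to the
   order of recipe and composition rows.
4. **Speciation.** Formulation compounds are rewritten into the species a
   model represents. Four rule kinds cover the cases that occur in
   practice: `dissociation` (molar coefficients, e.g. 1:1:1 for NaCl),
   `oxidation_split` (fractions over oxidation states that must sum to 1),
   `polymer_substitution` (a molar coefficient to a model-supported unit),
   and `surrogate` (1:1 replacement, e.g. collapsing an acid/base pair to
   the single form the model knows). Rules chain (A→B then B→C) but cycles
   are rejected at validation time.
5. **Environment injection.** Aqueous media receive water at
   `1000 g/L / 18.015 g/mol = 5.55×10⁴ mmol/L` (density 1 g/cm³); the
   oxygen regime becomes a dissolved-O₂ entry (0 encodes anaerobiosis); pH
   becomes protons at `10^(-pH) × 1000` mmol/L. If the recipe already
   contains one of these compounds the compiler refuses rather than double
   count.

Zero-concentration entries are pruned throughout: in the downstream bound
application, *absence* of a compound is what closes its uptake, so a zero
entry and a missing entry must mean the same thing.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `oxygen_mmol_per_l` | mmol/L | 18.2 | dissolved-O₂ availability measured for aerobic *E. coli* cultures; 0 = anaerobic |
| `ph` | – | 7 | neutral media; protons injected as `10^(-pH)` M |
| Fe oxidation split | fraction | 0.5 / 0.5 | matches the measured intracellular Fe²⁺/Fe³⁺ ratio in *E. coli*; overridable per rule |
| `residue_mass` | flag | `FALSE` | manufacturer manuals report free-amino-acid masses; `TRUE` adds back one water (18.015 g/mol) per residue for residue-based tables |
| `policy` (mapper) | – | `surrogate` | try the alias table, then drop with a warning; `fail` for strict runs |
| repair `default_bound` | mmol/L | 10⁻³ | trace-level placeholder, explicitly flagged for replacement by a literature value |
| scan `delta` | mmol/L or fraction | 1 / 0.3 | absolute mode surfaces scarce-or-absent compounds, relative mode abundant ones |
| scan `cutoff` | relative difference | 10⁻⁶ | separates genuine growth effects from LP noise |

Hydrated salts are converted with the hydrate's molar mass and the water of
hydration is discarded — against 5.55×10⁴ mmol/L of solvent it is
negligible, and discarding is the conservative choice.

## Identifier mapping

Matching diet compounds to exchange reactions is exact-id only, after alias
expansion. Fuzzy string matching was deliberately rejected: a wrong
metabolite assignment silently corrupts every downstream flux, which is far
worse than an honest `dropped` status. The mapper supports the two BiGG
exchange dialects (`EX_x_e`, `EX_x(e)`), auto-detected by majority pattern,
and classifies each compound as `matched`, `surrogate` (alias table, e.g.
nicotinamide carried by the nicotinate exchange) or `dropped`. Extending
the model itself (adding exchanges/transporters) is model curation and out
of scope; the mapping report tells the user what curation would need.

## The LP backend

The solver behind `solve_fba()` is a dense two-phase primal simplex with
direct support for variable bounds (`lp_solve_bounded()`), written for the
package and exposed behind a minimal matrix-in/certificate-out interface so
another backend can be swapped in. Design points:

* **Certificates, not just optima.** Row duals and reduced costs are
  retained; the troubleshooter is built entirely on them. The sign
  convention is documented on `solve_fba()`: for a variable at its lower
  bound the reduced cost equals ∂objective/∂lb, so an uptake at bound with
  reduced cost −r gains r objective units per mmol/L of availability.
* **Tolerances.** Pivot/feasibility 10⁻⁹; phase-1 infeasibility threshold
  10⁻⁷; growth threshold 10⁻⁶ (the same cutoff the supplementation scan
  uses). Dantzig pricing with a Bland's-rule fallback after a fixed
  iteration count guards against cycling on degenerate vertices.
* **Degenerate optima.** FBA flux vectors are generally non-unique even
  when the objective is. `fixed_optimum_flux_range()` pins the objective
  within a relative tolerance (default 10⁻⁶) and minimises/maximises one
  reaction; any secretion claim should be checked as membership in that
  range, not equality with a point estimate. Note the reported width
  includes the slack granted by the pinning tolerance itself (about
  `optimum × 10⁻⁶`).
* **Failure modes.** Infeasible and unbounded are statuses, not errors —
  an infeasible diet is a diagnosis, not a crash.

The solver is validated against an independent brute-force vertex
enumeration (all basis/bound assignments) on every fixture small enough to
enumerate, against closed-form optima of the generated toy models, and
against LP strong duality.

## Troubleshooting zero growth

A zero or infeasible optimum under a freshly compiled diet has two
fundamentally different causes: a defective diet or a defective model.
`rank_missing_nutrients()` addresses the first: every exchange whose lower
bound is zero or binding is ranked by |reduced cost|, i.e. by the marginal
yield per mmol/L of availability. When maintenance demands (positive lower
bounds on internal reactions, e.g. ATP hydrolysis) make the LP infeasible
outright, those bounds are relaxed for the diagnosis and the relaxation is
reported. If the LP stays infeasible even then, the error message redirects
the user to model-side checks — no diet repair can fix a broken network,
and gap-filling is explicitly outside this package.

`repair_diet()` iterates: add the top suggestion at a user-supplied
concentration (or the trace-level placeholder), re-solve, log
before/after. With several jointly essential compounds the reduced cost of
a single addition can be zero while the LP basis prices exactly one of
them; iteration handles this naturally — each round surfaces the next
essential, and each round is weakly objective-improving. Suggested bounds
are deliberately *not* invented by the algorithm: concentrations are data,
and the audit trail flags placeholders as such.

## Supplementation scans

`scan_supplements()` re-solves once per compound with its uptake widened by
`+delta` mmol/L (absolute) or `+delta·conc` (relative), reporting
`(perturbed − baseline)/baseline`. Because relaxing one bound of a
maximisation LP cannot decrease the optimum, every relative difference is
non-negative up to solver tolerance — a property the test suite asserts.
Absolute mode also opens exchanges of compounds absent from the diet, which
is how carbohydrate supplementations of an amino-acid medium (the classic
glucose experiment) are expressed.

## What the synthetic fixtures do and do not show

`make_toy_model()` generates uptake–transport–biomass networks whose
optimal yield has the closed form `min_i conc_i / stoich_i` (with a
maintenance correction when enabled), plus options for infeasibility
(maintenance an empty diet cannot cover) and alternate optima (a redundant
parallel transporter). `make_toy_recipe_bundle()` is a miniature LB-like
medium exercising every compiler branch: decomposition, direct molecular
components, dissociation, an oxidation split, and the environment. Its
composition values are *synthetic and illustrative* — plausible for a
peptone medium but not measured; shipping a measured composition table is
the user's job, and the package refuses to invent one.

These fixtures validate the machinery exactly — unit bookkeeping, LP
optimality, reduced-cost logic, scan algebra. They do not probe what makes
genome-scale models hard: thousands of coupled pathways, cofactor balancing,
redundancy at scale, and identifier noise across model generations. The
test suite therefore demonstrates correctness of the pipeline, not
biological validity of any particular medium representation; the
genome-scale *E. coli* LB case study (BiGG iJO1366 + core model + a
measured LB composition) runs through the identical code path once those
external inputs are supplied. Problem sizes in the shipped tests were
chosen at toy scale (≤ 8 reactions for brute-force-verified LPs, ≤ 5
substrates for random stress toys, 20 seeded replicates in the acceptance
script) — large enough to hit every branch, small enough that the oracles
stay exact.

## Known limitations

* No kinetics: concentration→flux conversion for rate mode is the user's
  responsibility.
* No bioavailability or digestive transformation of nutrients; amounts in
  the recipe are assumed available at the cell boundary.
* No gap-filling or model curation; unmatched compounds are reported, not
  fixed.
* No combinatorial (multi-compound) supplementation search; the scan is
  one-at-a-time by design.
* ODS spreadsheets are not read directly; composition tables distributed in
  spreadsheet form must be exported to CSV/TSV first.
* The dense simplex trades speed for transparency (full certificates, no
  external dependency, no binary solver to install). It is comfortable at
  the scale of core models and below; genome-scale networks with thousands
  of reactions call for a sparse revised simplex or an industrial LP
  library, which the pluggable backend interface is designed to accommodate.
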