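# dietfba

**From a growth-medium recipe to quantitative nutritional constraints for
flux balance analysis.**

Constraint-based metabolic models predict growth by maximising a biomass
objective `c·v` subject to steady state `S·v = 0` and flux bounds
`lb ≤ v ≤ ub`. The quality of those predictions hinges on the part of the
problem that receives the least attention: the *nutritional input*. Most
real growth media are only defined at the level of chemically complex
components — tryptone, yeast extract, milk powder — while the model needs
one number per molecule: the uptake bound of its exchange reaction.

`dietfba` is a toolkit for microbial systems biologists that makes this
translation explicit, quantitative and reproducible, as a six-stage
workflow:

1. **Describe** the medium as components with amounts (g/L or mmol/L), pH
   and oxygen regime (`medium_recipe()`, `read_recipe()`).
2. **Decompose** complex components into molecules via mass-fraction
   composition tables, convert everything to mmol/L, and apply *speciation*
   rules — salt dissociation (NaCl → Na⁺ + Cl⁻), polymer substitution
   (cellulose → cellobiose), oxidation-state splits (Fe → 50% Fe²⁺ / 50%
   Fe³⁺) (`compile_diet()`, `apply_speciation()`).
3. **Inject** the environment: water at 5.55×10⁴ mmol/L for aqueous media,
   dissolved O₂ from the oxygen regime, protons at `10^(-pH)` M.
4. **Map** diet compounds to the model's exchange reactions across
   nomenclature dialects (`EX_glc__D(e)` vs `EX_glc__D_e`), with explicit
   drop/surrogate/fail policies for unmatched compounds
   (`build_exchange_index()`, `map_diet()`).
5. **Simulate**: apply uptake bounds (uptake = negative flux; lower bound =
   −concentration in yield mode) and solve the FBA linear program with the
   built-in bounded-variable simplex, returning fluxes, duals and reduced
   costs (`apply_diet_bounds()`, `solve_fba()`,
   `fixed_optimum_flux_range()`).
6. **Troubleshoot**: rank missing or limiting nutrients by the reduced
   costs of their uptake bounds and repair the diet iteratively
   (`rank_missing_nutrients()`, `repair_diet()`); then quantify the growth
   response to supplementations (`scan_supplements()`).

Models are read from BiGG-style JSON or SBML Level 3 FBC. Everything is
tibble-in/tibble-out and pipe-friendly; results have `tidy()`, `glance()`
and `autoplot()` methods. A shell interface (`inst/cli/dietfba`, or
`dietfba_cli()` from R) mirrors the stages as subcommands `compile`, `map`,
`simulate`, `troubleshoot`, `scan` and `roadmap`.

## Worked example

The package ships a deterministic miniature medium — one peptone-like
component that decomposes into three amino acids, a salt, an iron pool and
the aqueous aerobic environment — together with a toy model whose optimal
yield is known in closed form:

```r
library(dietfba)

bundle <- make_toy_recipe_bundle()
diet <- compile_diet(bundle$recipe, bundle$compositions, bundle$rules,
                     bundle$registry)
diet
#> <compiled_diet> 10 compound(s), mmol/L
#>    compound conc_mmol_per_l provenance
#>  1 ala__L           11.2    <chr [3]>
#>  2 cl              100      <chr [3]>
#>  3 fe2               0.05   <chr [2]>
#>  4 fe3               0.05   <chr [2]>
#>  5 glu__L            9.52   <chr [3]>
#>  6 gly              16.0    <chr [3]>
#>  7 h                 0.0001 <chr [1]>
#>  8 h2o           55509.     <chr [1]>
#>  9 na1             100      <chr [3]>
#> 10 o2               18.2    <chr [1]>
```

10 g/L NaCl-style salt became 100 mmol/L each of Na⁺ and Cl⁻; 4 g/L of
peptone became 11–16 mmol/L of free amino acids; the environment injected
water, oxygen (18.2 mmol/L, the aerobic *E. coli* culture value) and
protons (10⁻⁴ mmol/L at pH 7). Each row's `provenance` lists every
transformation that produced it.

```r
toy <- make_toy_bundle_model()
mapping <- map_diet(diet, build_exchange_index(toy$model), bundle$aliases)
#> Warning: 7 diet compound(s) have no exchange in the model ... (ions,
#> environment: the toy model only grows on the amino acids)

res <- toy$model |> apply_diet_bounds(mapping, diet) |> solve_fba()
glance(res)
#> # A tibble: 1 × 6
#>   status  objective mode  unit  biomass_id  max_residual
#> 1 optimal      5.61 yield gDW/L BIOMASS_toy            0
```

The predicted yield, 5.61 gDW per litre of medium, equals the closed-form
min-ratio optimum `min_i conc_i / stoich_i` — alanine is limiting
(11.2 mmol/L at 2 mmol per gDW). Supplementing it by +30% therefore gains
exactly 30% yield, while non-limiting compounds gain nothing:

```r
scan <- scan_supplements(toy$model, diet, mapping, mode = "relative",
                         delta = 0.3)
rank_report(scan)
#>   compound exchange_id baseline perturbed relative_difference effect
#> 1 ala__L   EX_ala__L_e     5.61      7.30                 0.3 TRUE
#> 2 glu__L   EX_glu__L_e     5.61      5.61                 0   FALSE
#> 3 gly      EX_gly_e        5.61      5.61                 0   FALSE
```

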