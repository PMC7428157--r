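#' Generate a toy metabolic model with a known optimum
#'
#' Builds a minimal uptake-transport-biomass network: each substrate `i` has
#' an external metabolite, an exchange reaction, a transporter, and enters a
#' single biomass reaction with stoichiometry `stoich[i]` (mmol of substrate
#' per unit of biomass). Under yield-mode bounds the optimal biomass is the
#' closed-form min-ratio `min_i conc_i / stoich_i`, which is returned
#' alongside the model as an independent oracle for solver tests. Options add
#' a maintenance demand (a lower-bounded drain on substrate 1, which shifts
#' the closed form to `(conc_1 - maintenance)/stoich_1` for that substrate
#' and makes the LP infeasible when the diet cannot cover it) and a redundant
#' parallel transporter for substrate 1 (creating alternate optima, visible
#' as a non-degenerate [fixed_optimum_flux_range()]).
#'
#' Fixtures are deterministic; see [make_random_toy_model()] for the seeded
#' stress-test variant.
#'
#' @param n_substrates number of substrates.
#' @param stoich positive vector of biomass stoichiometries (recycled).
#' @param maintenance non-negative lower-bounded drain flux on substrate 1.
#' @param redundant_pathway add a duplicate transporter for substrate 1.
#' @param substrate_ids compound ids (default `s1 ... sn`).
#' @param id model id.
#' @return List with `model` (a `metabolic_model`), `optimum` (function of a
#'   concentration vector returning the closed-form optimal yield, `NA` if
#'   infeasible), and `spec` (the generating parameters).
#' @examples
#' toy <- make_toy_model(2, stoich = c(1, 2))
#' toy$optimum(c(5, 4))   # 2: substrate 2 is limiting
#' @export
make_toy_model <- function(n_substrates = 2, stoich = 1, maintenance = 0,
                           redundant_pathway = FALSE, substrate_ids = NULL,
                           id = "toy") {
  stopifnot(n_substrates >= 1)
  stoich <- rep_len(as.numeric(stoich), n_substrates)
  if (any(stoich <= 0)) abort("biomass stoichiometries must be > 0")
  if (maintenance < 0) abort("maintenance must be >= 0")
  ids <- substrate_ids %||% paste0("s", seq_len(n_substrates))
  stopifnot(length(ids) == n_substrates)

  mets <- tibble(id = c(paste0(ids, "_e"), paste0(ids, "_c")),
                 compartment = rep(c("e", "c"), each = n_substrates))
  rxn_list <- list()
  add <- function(rid, sto, lb = 0, ub = 1000, objective = 0)
    rxn_list[[length(rxn_list) + 1L]] <<- list(id = rid, sto = sto, lb = lb,
                                               ub = ub, objective = objective)
  for (i in seq_len(n_substrates)) {
    add(paste0("EX_", ids[i], "_e"), setNames(-1, paste0(ids[i], "_e")))
    add(paste0("T_", ids[i]),
        setNames(c(-1, 1), paste0(ids[i], c("_e", "_c"))))
  }
  if (redundant_pathway)
    add(paste0("T_", ids[1], "_alt"),
        setNames(c(-1, 1), paste0(ids[1], c("_e", "_c"))))
  add("BIOMASS_toy", setNames(-stoich, paste0(ids, "_c")), objective = 1)
  if (maintenance > 0)
    add("MAINT", setNames(-1, paste0(ids[1], "_c")), lb = maintenance)

  rxns <- tibble(id = map_chr(rxn_list, "id"),
                 lb = map_dbl(rxn_list, "lb"),
                 ub = map_dbl(rxn_list, "ub"),
                 objective = map_dbl(rxn_list, "objective"))
  S <- matrix(0, nrow(mets), nrow(rxns))
  rownames(S) <- mets$id
  for (j in seq_along(rxn_list))
    S[names(rxn_list[[j]]$sto), j] <- rxn_list[[j]]$sto
  model <- metabolic_model(id, mets, rxns, S)

  optimum <- function(conc) {
    conc <- rep_len(as.numeric(conc), n_substrates)
    avail <- conc
    avail[1] <- avail[1] - maintenance
    if (avail[1] < 0) return(NA_real_)   # maintenance cannot be met
    min(avail / stoich)
  }
  list(model = model, optimum = optimum,
       spec = list(n_substrates = n_substrates, stoich = stoich,
                   maintenance = maintenance,
                   redundant_pathway = redundant_pathway,
                   substrate_ids = ids))
}

#' Open a toy model's uptakes at given concentrations
#'
#' Convenience used in examples and tests: sets the exchange lower bound of
#' substrate `i` to `-conc[i]` directly, bypassing the mapper.
#'
#' @param model toy `metabolic_model` from [make_toy_model()].
#' @param conc concentration vector (mmol/L), in substrate order or named by
#'   compound id.
#' @return The constrained model.
#' @export
constrain_toy <- function(model, conc) {
  ex <- exchange_reactions(model)
  if (!is.null(names(conc))) {
    ex_named <- paste0("EX_", names(conc), "_e")
    stopifnot(all(ex_named %in% ex))
    ex <- ex_named
  }
  conc <- rep_len(as.numeric(conc), length(ex))
  i <- match(ex, model$reactions$id)
  model$reactions$lb[i] <- -conc
  model
}

#' Seeded random toy models for stress tests
#'
#' Draws substrate counts, stoichiometries and diet concentrations from a
#' seeded generator; the closed-form optimum still holds, so these serve as
#' randomised oracles for the LP solver. The seed is recorded in the
#' returned `spec`.
#'
#' @param seed integer seed.
#' @param max_substrates upper bound on the substrate count.
#' @return As [make_toy_model()], plus `conc` (a drawn diet) in the list.
#' @export
make_random_toy_model <- function(seed, max_substrates = 5) {
  set.seed(seed)
  n <- sample(1:max_substrates, 1)
  stoich <- round(stats::runif(n, 0.2, 5), 3)
  maint <- if (stats::runif(1) < 0.3) round(stats::runif(1, 0, 2), 3) else 0
  toy <- make_toy_model(n, stoich, maintenance = maint,
                        redundant_pathway = stats::runif(1) < 0.3,
                        id = paste0("toy_seed", seed))
  toy$conc <- round(stats::runif(n, 0, 20), 3)
  toy$spec$seed <- seed
  toy
}

#' Generate a miniature LB-like recipe bundle
#'
#' A deterministic fixture exercising every branch of the diet compiler: one
#' chemically complex component (`peptone_mini`, decomposing into three
#' amino acids by mass fraction), one salt with a dissociation rule
#' (NaCl to Na+ + Cl-), one metal pool with a 50/50 oxidation-state split
#' (Fe to Fe2+/Fe3+), plus the aqueous/aerobic/pH-7 environment. The values
#' are synthetic — chosen to be plausible for a peptone-based medium, not
#' taken from any measured composition.
#'
#' @return A list with `recipe` (a `medium_recipe`), `compositions`,
#'   `rules`, `registry`, `aliases`, and `expected` — the analytically known
#'   compiled concentrations, for oracle testing.
#' @export
make_toy_recipe_bundle <- function() {
  registry <- compound_registry(tibble(
    id = c("gly", "ala__L", "glu__L", "nacl", "na1", "cl",
           "fe", "fe2", "fe3", "h2o", "o2", "h", "ncam", "nac"),
    name = c("glycine", "L-alanine", "L-glutamate", "sodium chloride",
             "sodium ion", "chloride ion", "iron pool", "Fe2+", "Fe3+",
             "water", "oxygen", "proton", "nicotinamide", "nicotinate"),
    molecular_weight = c(75.07, 89.09, 147.13, 58.44, 22.99, 35.45,
                         55.85, 55.85, 55.85, 18.015, 32.00, 1.008,
                         122.12, 123.11)))
  recipe <- medium_recipe(
    tibble(component = c("peptone_mini", "nacl", "fe"),
           amount = c(4, 5.844, 0.1),
           unit = c("g/L", "g/L", "mmol/L")),
    ph = 7, oxygen_mmol_per_l = 18.2, aqueous = TRUE)
  compositions <- composition_table(tibble(
    component = "peptone_mini",
    compound = c("gly", "ala__L", "glu__L"),
    mass_fraction = c(0.30, 0.25, 0.35),
    source = "synthetic illustrative composition"))
  rules <- speciation_rules(tibble(
    source = c("nacl", "nacl", "fe", "fe"),
    product = c("na1", "cl", "fe2", "fe3"),
    coefficient = c(1, 1, 0.5, 0.5),
    rule_kind = c("dissociation", "dissociation",
                  "oxidation_split", "oxidation_split")))
  aliases <- tibble(compound = "ncam", alias_of = "nac",
                    relationship = "amide of")
  expected <- c(
    ala__L = 4 * 0.25 / 89.09 * 1000,
    cl = 5.844 / 58.44 * 1000,
    fe2 = 0.05, fe3 = 0.05,
    glu__L = 4 * 0.35 / 147.13 * 1000,
    gly = 4 * 0.30 / 75.07 * 1000,
    h = 1e-4, h2o = 1000 / 18.015 * 1000,
    na1 = 5.844 / 58.44 * 1000, o2 = 18.2)
  list(recipe = recipe, compositions = compositions, rules = rules,
       registry = registry, aliases = aliases, expected = expected)
}

#' Toy model matching the LB-like bundle
#'
#' Uses the bundle's three amino acids as growable substrates so the bundle
#' can be driven end-to-end through compile, map, simulate, troubleshoot and
#' scan. Ions, metals and environment compounds deliberately have no
#' exchange in this model, exercising the drop policy.
#'
#' @param stoich biomass stoichiometries for (ala__L, glu__L, gly).
#' @param ... further arguments to [make_toy_model()].
#' @return As [make_toy_model()].
#' @export
make_toy_bundle_model <- function(stoich = c(2, 1, 1), ...) {
  make_toy_model(3, stoich = stoich,
                 substrate_ids = c("ala__L", "glu__L", "gly"),
                 id = "toy_lb", ...)
}

#' Write a toy bundle plus model to disk in the public formats
#'
#' Emits `recipe.csv`, `compositions.csv`, `rules.csv`, `compounds.csv`,
#' `aliases.csv` and `model.json` into `dir`, so the command-line interface
#' and file readers can be tested end-to-end on generated fixtures.
#'
#' @param dir output directory (created if needed).
#' @param bundle bundle from [make_toy_recipe_bundle()].
#' @param model a `metabolic_model`; default [make_toy_bundle_model()].
#' @return Named list of file paths, invisibly.
#' @export
write_toy_bundle <- function(dir, bundle = make_toy_recipe_bundle(),
                             model = make_toy_bundle_model()$model) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    recipe = file.path(dir, "recipe.csv"),
    compositions = file.path(dir, "compositions.csv"),
    rules = file.path(dir, "rules.csv"),
    compounds = file.path(dir, "compounds.csv"),
    aliases = file.path(dir, "aliases.csv"),
    model = file.path(dir, "model.json"))
  write_recipe(bundle$recipe, paths$recipe)
  readr::write_csv(as_tibble(bundle$compositions), paths$compositions)
  readr::write_csv(as_tibble(bundle$rules), paths$rules)
  readr::write_csv(as_tibble(bundle$registry), paths$compounds)
  readr::write_csv(bundle$aliases, paths$aliases)
  write_model_json(model, paths$model)
  invisible(paths)
}
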