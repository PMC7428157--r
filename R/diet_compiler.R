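#' Convert pH to proton concentration
#'
#' `10^(-pH)` mol/L expressed in mmol/L, the convention used to inject
#' protons into a compiled diet (pH 7 gives 1e-4 mmol/L).
#'
#' @param ph pH value(s) in \[0, 14\].
#' @return Proton concentration(s) in mmol/L.
#' @examples
#' ph_to_proton(7)   # 1e-4 mmol/L
#' @export
ph_to_proton <- function(ph) {
  ph <- as.numeric(ph)
  if (any(is.na(ph) | ph < 0 | ph > 14))
    abort("pH must lie in [0, 14]")
  10^(-ph) * 1000
}

#' Convert a mass concentration to a molar concentration
#'
#' @param mass_g_per_l mass concentration(s), g/L.
#' @param molecular_weight molecular weight(s), g/mol (> 0).
#' @return Concentration(s) in mmol/L (`mass / MW * 1000`).
#' @examples
#' mass_to_molar(1000, 18.015)   # pure water, ~5.55e4 mmol/L
#' @export
mass_to_molar <- function(mass_g_per_l, molecular_weight) {
  mw <- as.numeric(molecular_weight)
  if (any(is.na(mw) | mw <= 0))
    abort(paste0("molecular weight missing or <= 0; supply a positive ",
                 "molecular_weight (g/mol) for every compound that needs a ",
                 "mass-to-molar conversion"))
  as.numeric(mass_g_per_l) / mw * 1000
}

#' Concentration of water in pure water
#'
#' With density 1 g/cm^3 and MW 18.015 g/mol this is 5.551e4 mmol/L, the
#' value injected for the solvent in aqueous media.
#'
#' @param molecular_weight water MW, g/mol.
#' @param density_g_per_ml solvent density.
#' @return mmol/L.
#' @export
water_mmol_per_l <- function(molecular_weight = 18.015, density_g_per_ml = 1) {
  mass_to_molar(1000 * density_g_per_ml, molecular_weight)
}

#' Biomass yield from optical density
#'
#' Empirical conversion used to compare predicted yields with plate-reader
#' growth curves: one OD600 unit corresponds to roughly 0.3 g/L of bacterial
#' dry weight, so a stationary-phase culture at OD600 5 is ~1.5 g/L.
#'
#' @param od600 optical density at 600 nm.
#' @param gdw_per_od grams dry weight per litre per OD600 unit.
#' @return Yield in gDW/L.
#' @export
yield_from_od <- function(od600, gdw_per_od = 0.3) {
  as.numeric(od600) * as.numeric(gdw_per_od)
}

#' Decompose a complex component into constituent masses
#'
#' Applies a mass-fraction composition to an amount of a complex component:
#' each constituent receives `amount * mass_fraction` g/L. Because fractions
#' sum to at most 1, total output mass never exceeds the input mass.
#'
#' @param amount_g_per_l amount of the component, g/L.
#' @param composition a `composition_table` (rows for one component, or pass
#'   `component` to select).
#' @param component component id to select when `composition` covers several.
#' @return Tibble `compound`, `mass_g_per_l` (zero-mass rows pruned).
#' @export
decompose_component <- function(amount_g_per_l, composition, component = NULL) {
  comp <- composition_table(composition)
  if (!is.null(component)) comp <- comp[comp$component == component, ]
  if (length(unique(comp$component)) > 1)
    abort("composition covers several components; pass `component`")
  if (length(amount_g_per_l) != 1 || is.na(amount_g_per_l) || amount_g_per_l < 0)
    abort("amount must be a single value >= 0")
  out <- tibble(compound = comp$compound,
                mass_g_per_l = amount_g_per_l * comp$mass_fraction)
  out[out$mass_g_per_l > 0, ]
}

new_compiled_diet <- function(compound, conc, provenance) {
  df <- tibble(compound = as.character(compound),
               conc_mmol_per_l = as.numeric(conc),
               provenance = provenance)
  class(df) <- c("compiled_diet", class(df))
  df
}

#' @export
print.compiled_diet <- function(x, ...) {
  cat("<compiled_diet> ", nrow(x), " compound(s), mmol/L\n", sep = "")
  NextMethod()
}

## one normalisation pass: merge duplicates, prune zeros, stable order
normalise_diet <- function(diet) {
  df <- as_tibble(diet)[c("compound", "conc_mmol_per_l", "provenance")]
  df <- df |> group_by(.data$compound) |>
    summarise(conc_mmol_per_l = sum(.data$conc_mmol_per_l),
              provenance = list(sort(unlist(.data$provenance))),
              .groups = "drop") |>
    arrange(.data$compound)
  df <- df[df$conc_mmol_per_l > 0, ]
  new_compiled_diet(df$compound, df$conc_mmol_per_l, df$provenance)
}

#' Apply speciation rules to a compiled diet
#'
#' Rewrites diet entries into the species a metabolic model represents; see
#' [speciation_rules()] for the four rule kinds. Rules are applied until no
#' rule source remains in the diet (so a chain `A -> B`, `B -> C` resolves to
#' `C`); cyclic chains are rejected. Entries without a matching rule pass
#' through untouched, so the operation is the identity on rule-free diets.
#'
#' @param diet a `compiled_diet` (or tibble with `compound`,
#'   `conc_mmol_per_l`).
#' @param rules a `speciation_rules` tibble.
#' @param registry optional `compound_registry`; when present, rule products
#'   must exist in it and polymer substitutions are checked for mass
#'   conservation.
#' @param mass_tol relative tolerance for polymer mass conservation
#'   (condensation water makes exact conservation impossible).
#' @return A `compiled_diet`.
#' @export
apply_speciation <- function(diet, rules, registry = NULL, mass_tol = 0.07) {
  rules <- speciation_rules(rules)
  df <- as_tibble(diet)
  if (!"provenance" %in% names(df))
    df$provenance <- map(df$compound, ~ character())
  if (!nrow(rules)) return(normalise_diet(df))

  bad <- rules$rule_kind == "dissociation" & rules$coefficient <= 0
  if (any(bad))
    abort(paste0("dissociation coefficients must be positive: ",
                 paste(rules$source[bad], collapse = ", ")))
  ## cycle detection on the source -> product graph
  srcs <- unique(rules$source)
  reach <- function(from, seen = character()) {
    if (from %in% seen) abort(paste0("cyclic speciation rules involving '",
                                     from, "'"))
    for (p in rules$product[rules$source == from])
      if (p %in% srcs) reach(p, c(seen, from))
    invisible(NULL)
  }
  for (s in srcs) reach(s)
  if (!is.null(registry)) {
    unknown <- setdiff(c(rules$source, rules$product), registry$id)
    if (length(unknown))
      abort(paste0("speciation rules reference compound(s) absent from the ",
                   "registry: ", paste(unknown, collapse = ", ")))
    ## polymer substitutions must conserve mass within tolerance
    poly <- rules[rules$rule_kind == "polymer_substitution", ]
    for (i in seq_len(nrow(poly))) {
      mw_s <- registry$molecular_weight[match(poly$source[i], registry$id)]
      mw_p <- registry$molecular_weight[match(poly$product[i], registry$id)]
      if (is.na(mw_s) || is.na(mw_p)) next
      rel <- abs(poly$coefficient[i] * mw_p - mw_s) / mw_s
      if (rel > mass_tol)
        abort(sprintf(paste0("polymer_substitution %s -> %s (x%g) changes ",
                             "mass by %.1f%%, beyond the %g tolerance"),
                      poly$source[i], poly$product[i], poly$coefficient[i],
                      100 * rel, mass_tol))
    }
  }

  repeat {
    hit <- df$compound %in% srcs
    if (!any(hit)) break
    keep <- df[!hit, ]
    rewritten <- list()
    for (i in which(hit)) {
      rs <- rules[rules$source == df$compound[i], ]
      rewritten[[length(rewritten) + 1L]] <- tibble(
        compound = rs$product,
        conc_mmol_per_l = df$conc_mmol_per_l[i] * rs$coefficient,
        provenance = map2(rs$product, seq_len(nrow(rs)), function(p, k) {
          c(unlist(df$provenance[i]),
            sprintf("speciation[%s]: %s -> %s x%g", rs$rule_kind[k],
                    df$compound[i], p, rs$coefficient[k]))
        }))
    }
    df <- bind_rows(keep, bind_rows(rewritten))
  }
  normalise_diet(df)
}

#' Compile a medium recipe into a quantitative diet
#'
#' The full medium-to-molecules pipeline: complex components are decomposed
#' through their composition tables into constituent masses, every mass is
#' converted to mmol/L via the registry's molecular weights, contributions of
#' the same compound from different components are summed, speciation rules
#' rewrite formulation compounds into model species, and finally the
#' environmental compounds are injected (water at ~5.55e4 mmol/L for aqueous
#' media, dissolved oxygen from the recipe's oxygen regime, protons from its
#' pH). Every entry carries a provenance trail of the transformations that
#' produced it. Absence of a compound from the result later means a closed
#' uptake, so zero-concentration entries are pruned.
#'
#' @param recipe a `medium_recipe`.
#' @param compositions a `composition_table` covering every complex component
#'   (may be `NULL` when all components are already molecular).
#' @param rules optional `speciation_rules`.
#' @param registry a `compound_registry` with molecular weights for every
#'   compound that needs a mass conversion.
#' @param residue_mass if `TRUE`, composition mass fractions of decomposition
#'   products are residue-based (protein hydrolysate convention): one water
#'   mass (18.015 g/mol) is added back per residue when converting to moles.
#'   The default `FALSE` treats them as free-molecule masses, the
#'   manufacturer convention.
#' @param env_ids compound ids used for the injected environment.
#' @return A `compiled_diet` tibble: `compound`, `conc_mmol_per_l`,
#'   `provenance` (list column of transformation records).
#' @examples
#' bundle <- make_toy_recipe_bundle()
#' compile_diet(bundle$recipe, bundle$compositions, bundle$rules,
#'              bundle$registry)
#' @export
compile_diet <- function(recipe, compositions = NULL, rules = NULL, registry,
                         residue_mass = FALSE,
                         env_ids = c(water = "h2o", oxygen = "o2",
                                     proton = "h")) {
  stopifnot(inherits(recipe, "medium_recipe"))
  registry <- if (inherits(registry, "compound_registry")) registry
              else compound_registry(registry)
  comp_tab <- if (is.null(compositions)) composition_table(tibble())
              else composition_table(compositions)
  comps <- recipe$components
  entries <- list()
  water_mw <- 18.015

  for (i in seq_len(nrow(comps))) {
    id <- comps$component[i]; amt <- comps$amount[i]; unit <- comps$unit[i]
    if (unit == "mmol/L") {
      entries[[length(entries) + 1L]] <- tibble(
        compound = id, conc_mmol_per_l = amt,
        provenance = list(sprintf("recipe: %s %g mmol/L (direct)", id, amt)))
      next
    }
    ## mass-based entry: complex component or direct molecular compound
    rows <- comp_tab[comp_tab$component == id, ]
    if (nrow(rows)) {
      dec <- decompose_component(amt, rows)
      for (k in seq_len(nrow(dec))) {
        cid <- dec$compound[k]
        mw <- registry_mw(registry, cid)
        ## residue basis: reported mass lacks one water per peptide bond
        mw_eff <- if (residue_mass) mw - water_mw else mw
        if (mw_eff <= 0)
          abort(paste0("residue-mass conversion impossible for '", cid,
                       "': MW <= water"))
        moles <- dec$mass_g_per_l[k] / mw_eff * 1000
        frac <- rows$mass_fraction[match(cid, rows$compound)]
        entries[[length(entries) + 1L]] <- tibble(
          compound = cid, conc_mmol_per_l = moles,
          provenance = list(c(
            sprintf("recipe: %s %g g/L", id, amt),
            sprintf("decompose: %s x %g g/g -> %g g/L %s", id, frac,
                    dec$mass_g_per_l[k], cid),
            sprintf("mass_to_molar: MW %g%s -> %g mmol/L", mw,
                    if (residue_mass) " (residue basis)" else "", moles))))
      }
    } else if (id %in% registry$id) {
      mw <- registry_mw(registry, id)
      conc <- mass_to_molar(amt, mw)
      entries[[length(entries) + 1L]] <- tibble(
        compound = id, conc_mmol_per_l = conc,
        provenance = list(c(
          sprintf("recipe: %s %g g/L", id, amt),
          sprintf("mass_to_molar: MW %g -> %g mmol/L", mw, conc))))
    } else {
      abort(paste0("component '", id, "' is neither in the composition ",
                   "table nor a registry compound; cannot resolve it"))
    }
  }

  diet <- if (length(entries)) normalise_diet(bind_rows(entries))
          else new_compiled_diet(character(), numeric(), list())
  if (!is.null(rules)) diet <- apply_speciation(diet, rules, registry)

  ## environmental injection (water, oxygen, protons)
  clash <- intersect(diet$compound, unname(env_ids))
  if (length(clash))
    abort(paste0("environmental compound(s) already present in the recipe: ",
                 paste(clash, collapse = ", "),
                 "; remove them to avoid duplicate environmental injection"))
  env <- list()
  if (recipe$aqueous) {
    mw <- if (env_ids[["water"]] %in% registry$id)
      registry_mw(registry, env_ids[["water"]]) else water_mw
    env[[length(env) + 1L]] <- tibble(
      compound = env_ids[["water"]], conc_mmol_per_l = water_mmol_per_l(mw),
      provenance = list(sprintf(
        "environment: aqueous solvent, density 1 g/cm3, MW %g -> %g mmol/L",
        mw, water_mmol_per_l(mw))))
  }
  if (recipe$oxygen_mmol_per_l > 0)
    env[[length(env) + 1L]] <- tibble(
      compound = env_ids[["oxygen"]], conc_mmol_per_l = recipe$oxygen_mmol_per_l,
      provenance = list(sprintf("environment: dissolved oxygen %g mmol/L",
                                recipe$oxygen_mmol_per_l)))
  env[[length(env) + 1L]] <- tibble(
    compound = env_ids[["proton"]], conc_mmol_per_l = ph_to_proton(recipe$ph),
    provenance = list(sprintf("environment: pH %g -> %g mmol/L protons",
                              recipe$ph, ph_to_proton(recipe$ph))))
  normalise_diet(bind_rows(c(list(as_tibble(diet)), env)))
}

#' Write / read a compiled diet as TSV
#'
#' Serialises `compound`, `concentration_mmol_per_L` and the provenance trail
#' as a JSON array per row; `read_diet()` restores the `compiled_diet`.
#'
#' @param diet a `compiled_diet`.
#' @param path TSV path.
#' @return `path` invisibly (`write_diet`), a `compiled_diet` (`read_diet`).
#' @export
write_diet <- function(diet, path) {
  df <- tibble(compound = diet$compound,
               concentration_mmol_per_L = diet$conc_mmol_per_l,
               provenance_json = map_chr(diet$provenance, function(p)
                 as.character(jsonlite::toJSON(unlist(p) %||% character()))))
  ## JSON carries quotes; tabs/newlines cannot occur, so no TSV quoting
  readr::write_tsv(df, path, quote = "none", escape = "none")
  invisible(path)
}

#' @rdname write_diet
#' @export
read_diet <- function(path) {
  df <- read_table_auto(path)
  need <- c("compound", "concentration_mmol_per_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("diet file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  prov <- if ("provenance_json" %in% names(df))
    map(df$provenance_json, ~ as.character(jsonlite::fromJSON(.x)))
  else map(df$compound, ~ character())
  normalise_diet(tibble(compound = df$compound,
                        conc_mmol_per_l = df$concentration_mmol_per_L,
                        provenance = prov))
}
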