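#' Compound registries
#'
#' A compound registry is a tibble with one row per unique molecule or ion
#' that can appear in a compiled diet: short BiGG-style `id` (e.g. `glc__D`,
#' `na1`, `cl`), a human-readable `name`, the `molecular_weight` in g/mol
#' (required wherever a mass-to-molar conversion touches the compound), and
#' optional `formula`, `charge` and `aliases` (comma-separated alternative
#' names).
#'
#' @param compounds data frame with at least columns `id` and
#'   `molecular_weight`; `name`, `formula`, `charge`, `aliases` are optional.
#' @return A validated `compound_registry` tibble.
#' @examples
#' compound_registry(data.frame(id = c("gly", "h2o"),
#'                              molecular_weight = c(75.07, 18.015)))
#' @export
compound_registry <- function(compounds) {
  df <- as_tibble(compounds)
  need <- c("id", "molecular_weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("compound registry is missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (!"name" %in% names(df)) df$name <- df$id
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"charge" %in% names(df)) df$charge <- NA_integer_
  if (!"aliases" %in% names(df)) df$aliases <- NA_character_
  df$id <- as.character(df$id)
  df$molecular_weight <- as.numeric(df$molecular_weight)
  if (anyDuplicated(df$id))
    abort(paste0("duplicate compound id(s): ",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  bad <- !is.na(df$molecular_weight) & df$molecular_weight <= 0
  if (any(bad))
    abort(paste0("molecular_weight must be > 0; offending id(s): ",
                 paste(df$id[bad], collapse = ", ")))
  out <- df[c("id", "name", "molecular_weight", "formula", "charge", "aliases")]
  class(out) <- c("compound_registry", class(out))
  out
}

#' Read a compound registry from CSV/TSV
#'
#' @param path file with header `id,name,molecular_weight[,formula,charge,aliases]`.
#' @return A `compound_registry` tibble.
#' @export
read_compounds <- function(path) {
  compound_registry(read_table_auto(path))
}

registry_mw <- function(registry, id) {
  i <- match(id, registry$id)
  if (is.na(i))
    abort(paste0("compound '", id, "' is not in the registry"))
  mw <- registry$molecular_weight[i]
  if (is.na(mw) || mw <= 0)
    abort(paste0("compound '", id, "' has no usable molecular weight; ",
                 "supply one in the registry to convert mass to molar"))
  mw
}

recognised_units <- c("g/L", "mg/L", "mmol/L", "mol/L")

#' Construct a medium recipe
#'
#' A medium recipe is the user-facing description of a growth medium: a table
#' of components with amounts, plus the environmental settings that the diet
#' compiler turns into compound concentrations (pH into protons, oxygen
#' regime into dissolved oxygen, aqueous into water at 5.55e4 mmol/L).
#' Components may be chemically complex (resolved later through a composition
#' table, e.g. tryptone) or already molecular (e.g. NaCl), in which case no
#' composition entry is needed.
#'
#' @param components data frame with columns `component`, `amount`, `unit`
#'   (one of `r paste(recognised_units, collapse = ", ")`).
#' @param ph medium pH, in \[0, 14\].
#' @param oxygen_mmol_per_l dissolved oxygen concentration, mmol/L; 0 encodes
#'   an anaerobic culture. The default 18.2 mmol/L is the aerobic value
#'   measured for *E. coli* cultures.
#' @param aqueous logical; if `TRUE`, water is injected at compile time.
#' @return A `medium_recipe` object.
#' @examples
#' lb <- medium_recipe(
#'   data.frame(component = c("tryptone", "yeast_extract", "nacl"),
#'              amount = c(10, 5, 10), unit = "g/L"),
#'   ph = 7, oxygen_mmol_per_l = 18.2)
#' lb
#' @export
medium_recipe <- function(components, ph = 7, oxygen_mmol_per_l = 18.2,
                          aqueous = TRUE) {
  df <- as_tibble(components)
  need <- c("component", "amount", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("recipe is missing column(s): ", paste(miss, collapse = ", ")))
  df$component <- as.character(df$component)
  df$amount <- as.numeric(df$amount)
  df$unit <- as.character(df$unit)
  if (nrow(df)) {
    bad_unit <- !df$unit %in% recognised_units
    if (any(bad_unit))
      abort(paste0("unknown unit(s): ",
                   paste(unique(df$unit[bad_unit]), collapse = ", "),
                   "; recognised units are ",
                   paste(recognised_units, collapse = ", ")))
    if (any(is.na(df$amount)))
      abort("recipe amounts must be numeric")
    if (any(df$amount < 0))
      abort(paste0("negative amount for component(s): ",
                   paste(df$component[df$amount < 0], collapse = ", ")))
  }
  if (length(ph) != 1 || is.na(ph) || ph < 0 || ph > 14)
    abort("pH must be a single value in [0, 14]")
  if (length(oxygen_mmol_per_l) != 1 || is.na(oxygen_mmol_per_l) ||
      oxygen_mmol_per_l < 0)
    abort("oxygen_mmol_per_l must be a single value >= 0")
  ## canonicalise amounts: masses to g/L, molar to mmol/L
  if (nrow(df)) {
    fac <- c("g/L" = 1, "mg/L" = 1e-3, "mmol/L" = 1, "mol/L" = 1e3)
    canon <- c("g/L" = "g/L", "mg/L" = "g/L",
               "mmol/L" = "mmol/L", "mol/L" = "mmol/L")
    df$amount <- unname(df$amount * fac[df$unit])
    df$unit <- unname(canon[df$unit])
  }
  structure(list(components = df, ph = as.numeric(ph),
                 oxygen_mmol_per_l = as.numeric(oxygen_mmol_per_l),
                 aqueous = isTRUE(aqueous)),
            class = "medium_recipe")
}

#' @export
print.medium_recipe <- function(x, ...) {
  cat("<medium_recipe> ", nrow(x$components), " component(s), pH ", x$ph,
      ", O2 ", x$oxygen_mmol_per_l, " mmol/L",
      if (x$aqueous) ", aqueous" else "", "\n", sep = "")
  print(x$components)
  invisible(x)
}

read_table_auto <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a medium recipe from CSV/TSV
#'
#' Expects a header `component,amount,unit`; the environment may ride along
#' as extra columns `pH` and `oxygen_mmol_per_L` (first non-missing value is
#' used) or be passed through the arguments, which win over file columns.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`) recipe file.
#' @param ph,oxygen_mmol_per_l,aqueous override or supply environment
#'   settings; `NULL` means take from the file or the defaults of
#'   [medium_recipe()].
#' @return A `medium_recipe`.
#' @export
read_recipe <- function(path, ph = NULL, oxygen_mmol_per_l = NULL,
                        aqueous = NULL) {
  df <- read_table_auto(path)
  need <- c("component", "amount", "unit")
  miss <- setdiff(need, tolower(names(df)))
  if (length(miss))
    abort(paste0("recipe file ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")))
  names(df) <- tolower(names(df))
  amt <- suppressWarnings(as.numeric(df$amount))
  bad <- which(is.na(amt) & !is.na(df$amount) & df$amount != "")
  if (length(bad))
    abort(paste0("malformed amount in row ", bad[1], " of ", path, ": '",
                 df$amount[bad[1]], "'"))
  df$amount <- amt
  first_val <- function(col) {
    if (col %in% names(df) && any(!is.na(df[[col]]))) df[[col]][!is.na(df[[col]])][1]
    else NULL
  }
  ph <- ph %||% first_val("ph") %||% 7
  oxygen_mmol_per_l <- oxygen_mmol_per_l %||% first_val("oxygen_mmol_per_l") %||% 18.2
  aqueous <- aqueous %||% first_val("aqueous") %||% TRUE
  medium_recipe(df[c("component", "amount", "unit")], ph = as.numeric(ph),
                oxygen_mmol_per_l = as.numeric(oxygen_mmol_per_l),
                aqueous = as.logical(aqueous))
}

#' Write a medium recipe to CSV/TSV
#'
#' Inverse of [read_recipe()]: the environment settings are written as the
#' extra columns `ph`, `oxygen_mmol_per_l` and `aqueous` so that
#' `read_recipe(write_recipe(x, f))` round-trips the full data model.
#'
#' @param recipe a `medium_recipe`.
#' @param path output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "medium_recipe"))
  df <- recipe$components
  df$ph <- c(recipe$ph, rep(NA_real_, max(0, nrow(df) - 1)))[seq_len(nrow(df))]
  df$oxygen_mmol_per_l <-
    c(recipe$oxygen_mmol_per_l, rep(NA_real_, max(0, nrow(df) - 1)))[seq_len(nrow(df))]
  df$aqueous <- c(recipe$aqueous, rep(NA, max(0, nrow(df) - 1)))[seq_len(nrow(df))]
  if (!nrow(df))
    df <- tibble(component = character(), amount = numeric(), unit = character(),
                 ph = recipe$ph, oxygen_mmol_per_l = recipe$oxygen_mmol_per_l,
                 aqueous = recipe$aqueous)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read component composition tables
#'
#' A composition table resolves a chemically complex medium component (such
#' as tryptone or yeast extract) into molecular constituents by mass: each
#' row states that one gram of `component` contains `mass_fraction` grams of
#' `compound`, with a free-text `source` citation for provenance. Mass
#' fractions for one component may sum to less than 1 (uncharacterised
#' residue) but never more.
#'
#' @param path CSV/TSV with header `component,compound,mass_fraction,source`.
#' @return A `composition_table` tibble (one row per component-compound pair).
#' @export
read_composition_table <- function(path) {
  composition_table(read_table_auto(path))
}

#' @rdname read_composition_table
#' @param x data frame with columns `component`, `compound`, `mass_fraction`
#'   and optionally `source`.
#' @export
composition_table <- function(x) {
  df <- as_tibble(x)
  if (!nrow(df) && !length(names(df)))
    df <- tibble(component = character(), compound = character(),
                 mass_fraction = numeric(), source = character())
  need <- c("component", "compound", "mass_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("composition table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$component <- as.character(df$component)
  df$compound <- as.character(df$compound)
  df$mass_fraction <- as.numeric(df$mass_fraction)
  if (any(is.na(df$mass_fraction)))
    abort("mass_fraction must be numeric")
  if (any(df$mass_fraction < 0))
    abort("mass_fraction must be >= 0")
  sums <- df |> group_by(.data$component) |>
    summarise(total = sum(.data$mass_fraction), .groups = "drop")
  over <- sums$total > 1 + 1e-6
  if (any(over))
    abort(paste0("mass fractions exceed 1 g/g for component(s): ",
                 paste(sprintf("%s (%.4g)", sums$component[over],
                               sums$total[over]), collapse = ", "),
                 "; a component cannot yield more mass than itself"))
  dup <- duplicated(df[c("component", "compound")])
  if (any(dup))
    abort(paste0("duplicate composition entries for: ",
                 paste(unique(paste(df$component[dup], df$compound[dup],
                                    sep = "/")), collapse = ", ")))
  out <- df[c("component", "compound", "mass_fraction", "source")]
  class(out) <- c("composition_table", class(out))
  out
}

#' Read speciation rules from CSV/TSV
#'
#' Speciation rules rewrite a formulation compound into the species a model
#' actually represents: `dissociation` (salt to its ions, molar coefficients,
#' e.g. NaCl to Na+ + Cl-), `oxidation_split` (one pool split over oxidation
#' states by fractions summing to 1, e.g. 50% Fe2+ / 50% Fe3+),
#' `polymer_substitution` (polymer replaced by a model-supported unit such as
#' cellulose by cellobiose, molar coefficient chosen to conserve mass), and
#' `surrogate` (1:1 replacement by a related molecule the model knows, e.g.
#' conjugate acid collapsed to its base).
#'
#' @param path CSV/TSV with header `source,product,coefficient,rule_kind`.
#' @return A `speciation_rules` tibble.
#' @export
read_speciation_rules <- function(path) {
  speciation_rules(read_table_auto(path))
}

#' @rdname read_speciation_rules
#' @param x data frame with columns `source`, `product`, `coefficient`,
#'   `rule_kind`.
#' @export
speciation_rules <- function(x) {
  df <- as_tibble(x)
  if (!nrow(df) && !length(names(df)))
    df <- tibble(source = character(), product = character(),
                 coefficient = numeric(), rule_kind = character())
  need <- c("source", "product", "coefficient", "rule_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("speciation rules are missing column(s): ",
                 paste(miss, collapse = ", ")))
  df$source <- as.character(df$source)
  df$product <- as.character(df$product)
  df$coefficient <- as.numeric(df$coefficient)
  df$rule_kind <- as.character(df$rule_kind)
  kinds <- c("dissociation", "oxidation_split", "polymer_substitution",
             "surrogate")
  bad <- !df$rule_kind %in% kinds
  if (any(bad))
    abort(paste0("unknown rule_kind: ",
                 paste(unique(df$rule_kind[bad]), collapse = ", ")))
  if (any(is.na(df$coefficient) | df$coefficient < 0))
    abort("rule coefficients must be numeric and >= 0")
  ## oxidation splits must distribute the whole pool
  ox <- df[df$rule_kind == "oxidation_split", ]
  if (nrow(ox)) {
    s <- ox |> group_by(.data$source) |>
      summarise(total = sum(.data$coefficient), .groups = "drop")
    off <- abs(s$total - 1) > 1e-9
    if (any(off))
      abort(paste0("oxidation_split fractions must sum to 1 for source(s): ",
                   paste(s$source[off], collapse = ", ")))
  }
  out <- df[need]
  class(out) <- c("speciation_rules", class(out))
  out
}

#' Read an alias table from CSV/TSV
#'
#' Alias tables let the identifier mapper substitute a related molecule when
#' a diet compound has no exchange reaction in the model (the surrogate
#' policy), e.g. nicotinamide mapped onto nicotinate.
#'
#' @param path CSV/TSV with header `compound,alias_of[,relationship]`.
#' @return A tibble with columns `compound`, `alias_of`, `relationship`.
#' @export
read_alias_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("compound", "alias_of")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("alias table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (!"relationship" %in% names(df)) df$relationship <- NA_character_
  as_tibble(df[c("compound", "alias_of", "relationship")])
}
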