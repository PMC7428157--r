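#' Index a model's exchange reactions by compound
#'
#' Exchange reactions follow the convention `EX_` + metabolite id + external
#' compartment suffix (`"_e"` or `"(e)"` depending on the model's dialect).
#' The index strips the suffix so diet compounds (bare BiGG-style ids such as
#' `glc__D`) can be matched directly. Only true exchange pseudo-reactions —
#' one external metabolite, no other participants — enter the index.
#'
#' @param model a `metabolic_model`.
#' @param dialect `"auto"` (majority pattern among exchange metabolite ids),
#'   `"_e"` or `"(e)"`.
#' @return Tibble `compound`, `metabolite`, `exchange_id`.
#' @export
build_exchange_index <- function(model, dialect = c("auto", "_e", "(e)")) {
  dialect <- match.arg(dialect)
  ex <- exchange_reactions(model)
  if (!length(ex))
    abort(paste0("no exchange reactions detected in model '", model$id,
                 "'; if its external compartment uses a non-standard tag, ",
                 "override the dialect or fix the compartment annotation"))
  met_of <- vapply(ex, function(r) {
    model$metabolites$id[which(model$S[, r] != 0)]
  }, character(1))
  if (dialect == "auto") {
    n_par <- sum(grepl("\\(e\\)$|\\[e\\]$", met_of))
    n_us <- sum(grepl("_e$", met_of))
    dialect <- if (n_par > n_us) "(e)" else "_e"
  }
  strip <- function(x) {
    if (dialect == "(e)") sub("\\(e\\)$|\\[e\\]$", "", x)
    else sub("_e$", "", x)
  }
  tibble(compound = unname(strip(met_of)), metabolite = unname(met_of),
         exchange_id = unname(ex)) |>
    arrange(.data$compound)
}

#' Map a compiled diet onto a model's exchange reactions
#'
#' Every diet compound ends up in exactly one of three states: `matched`
#' (its id names an external metabolite with an exchange reaction),
#' `surrogate` (no direct match, but an alias table pointed to a related
#' model compound — e.g. nicotinamide carried by the nicotinate exchange), or
#' `dropped` (no representation in the model; its nutrients are simply
#' unavailable *in silico*). Matching is by exact id after alias expansion —
#' no fuzzy matching, since a wrong assignment corrupts every downstream
#' simulation.
#'
#' @param diet a `compiled_diet`.
#' @param index exchange index from [build_exchange_index()].
#' @param aliases optional alias tibble (`compound`, `alias_of`,
#'   `relationship`), see [read_alias_table()].
#' @param policy what to do with unmatched compounds: `"surrogate"` (try the
#'   alias table, then drop with a warning), `"drop"` (drop with a warning,
#'   ignoring aliases), or `"fail"` (error listing every unmatched compound).
#' @return Tibble `compound`, `status`, `exchange_id`, `note`; one row per
#'   diet compound, `matched + surrogate + dropped == nrow(diet)`.
#' @export
map_diet <- function(diet, index, aliases = NULL,
                     policy = c("surrogate", "drop", "fail")) {
  policy <- match.arg(policy)
  if (!nrow(index)) abort("exchange index is empty")
  compounds <- sort(unique(diet$compound))
  rows <- map(compounds, function(cpd) {
    i <- match(cpd, index$compound)
    if (!is.na(i))
      return(tibble(compound = cpd, status = "matched",
                    exchange_id = index$exchange_id[i],
                    note = paste0("exact match on metabolite ",
                                  index$metabolite[i])))
    if (policy == "surrogate" && !is.null(aliases)) {
      a <- match(cpd, aliases$compound)
      if (!is.na(a)) {
        tgt <- aliases$alias_of[a]
        k <- match(tgt, index$compound)
        if (!is.na(k))
          return(tibble(compound = cpd, status = "surrogate",
                        exchange_id = index$exchange_id[k],
                        note = paste0("surrogate via alias -> ", tgt,
                                      if (!is.na(aliases$relationship[a]))
                                        paste0(" (", aliases$relationship[a], ")")
                                      else "")))
      }
    }
    tibble(compound = cpd, status = "dropped", exchange_id = NA_character_,
           note = "no exchange reaction in the model")
  })
  out <- bind_rows(rows)
  if (!nrow(out))
    out <- tibble(compound = character(), status = character(),
                  exchange_id = character(), note = character())
  unmatched <- out$compound[out$status == "dropped"]
  if (length(unmatched)) {
    if (policy == "fail")
      abort(paste0("unmatched diet compound(s): ",
                   paste(unmatched, collapse = ", "),
                   "; supply aliases, curate the model, or use policy ",
                   "'drop'/'surrogate'"))
    warn(paste0(length(unmatched), " diet compound(s) have no exchange in ",
                "the model and were dropped: ",
                paste(unmatched, collapse = ", ")))
  }
  out
}

#' Write a mapping report as TSV
#'
#' @param mapping tibble from [map_diet()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  readr::write_tsv(mapping, path)
  invisible(path)
}
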