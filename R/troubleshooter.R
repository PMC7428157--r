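#' Rank missing or limiting nutrients by reduced cost
#'
#' When a constrained model refuses to grow (or grows implausibly little),
#' the reduced costs of its uptake reactions say which closed or binding
#' bounds are throttling the objective: a reduced cost of magnitude `r` on an
#' exchange at its lower bound means the objective would gain `r` per mmol/L
#' of extra availability. This is the LP-native diagnosis of an erroneously
#' defined diet — distinct from model-side defects (missing reactions, bad
#' biomass definition), which no diet repair can fix.
#'
#' If maintenance demands (positive lower bounds on internal reactions) make
#' the LP outright infeasible, those bounds are temporarily relaxed to zero
#' for the diagnosis and the relaxation is reported in the result's
#' `relaxed` attribute.
#'
#' @param model a diet-constrained `metabolic_model`.
#' @param mapping optional mapping tibble; used to translate exchange ids
#'   back to diet compounds in the report.
#' @param tol reduced costs with magnitude below this are noise, not
#'   suggestions.
#' @param default_bound suggested uptake bound (mmol/L) attached to each
#'   suggestion when no candidate value is known; a trace-level placeholder
#'   that should be replaced by a literature value.
#' @return Tibble `exchange_id`, `compound`, `reduced_cost`,
#'   `reduced_cost_magnitude`, `suggested_bound`, `rationale`, sorted by
#'   descending magnitude (ties broken lexicographically by exchange id).
#'   Attribute `relaxed` lists any maintenance bounds relaxed for diagnosis.
#' @export
rank_missing_nutrients <- function(model, mapping = NULL, tol = 1e-8,
                                   default_bound = 1e-3) {
  stopifnot(inherits(model, "metabolic_model"))
  ex <- exchange_reactions(model)
  relaxed <- character()
  res <- solve_fba(model)
  if (res$status == "infeasible") {
    ## maintenance demands can exceed what the diet supplies; relax them to
    ## diagnose the diet rather than fail
    rx <- model$reactions
    maint <- which(!(rx$id %in% ex) & rx$lb > 0)
    if (length(maint)) {
      relaxed <- rx$id[maint]
      model$reactions$lb[maint] <- 0
      res <- solve_fba(model)
    }
    if (res$status == "infeasible")
      abort(paste0("LP infeasible even after relaxing maintenance bounds; ",
                   "a nil-growth solution here points to inconsistencies in ",
                   "the model itself (missing reactions, incorrect bounds, ",
                   "erroneous biomass definition), not the diet"))
  }
  fl <- res$fluxes
  i <- match(ex, fl$reaction)
  at_lb <- abs(fl$flux[i] - fl$lb[i]) <= 1e-9 | fl$lb[i] == 0
  cand <- tibble(exchange_id = ex,
                 reduced_cost = fl$reduced_cost[i],
                 at_lb = at_lb) |>
    filter(.data$at_lb, abs(.data$reduced_cost) > tol)
  cpd <- if (!is.null(mapping))
    mapping$compound[match(cand$exchange_id, mapping$exchange_id)]
  else NA_character_
  out <- tibble(
    exchange_id = cand$exchange_id,
    compound = if (nrow(cand)) as.character(cpd) else character(),
    reduced_cost = cand$reduced_cost,
    reduced_cost_magnitude = abs(cand$reduced_cost),
    suggested_bound = -default_bound,
    rationale = sprintf(
      "uptake bound binding; objective gains %.3g per mmol/L of availability (placeholder bound %.3g mmol/L, replace with a literature value)",
      abs(cand$reduced_cost), default_bound)) |>
    arrange(desc(.data$reduced_cost_magnitude), .data$exchange_id)
  attr(out, "relaxed") <- relaxed
  attr(out, "objective") <- res$objective
  out
}

#' Iteratively repair a non-growing diet
#'
#' Adds the top-ranked missing nutrient (by reduced-cost magnitude), re-runs
#' the optimisation, and repeats until the objective clears the growth
#' threshold or the iteration budget is spent. Concentrations for added
#' compounds come from `candidate_bounds` (named vector, mmol/L); compounds
#' without a candidate get `default_bound`. Every addition is logged with the
#' objective before and after.
#'
#' @param model a diet-constrained `metabolic_model`.
#' @param diet the `compiled_diet` the bounds came from; repaired entries are
#'   appended so the returned diet matches the returned model.
#' @param mapping optional mapping tibble (for compound names in the audit).
#' @param candidate_bounds named numeric vector: concentration (mmol/L,
#'   positive) per exchange id or compound id.
#' @param default_bound fallback concentration, mmol/L.
#' @param growth_threshold objective value that counts as growth.
#' @param max_iterations repair budget.
#' @return A list with `model`, `diet`, `grew` (logical), and `audit` — a
#'   tibble `iteration`, `exchange_id`, `compound`, `bound_mmol_per_l`,
#'   `objective_before`, `objective_after`.
#' @export
repair_diet <- function(model, diet, mapping = NULL, candidate_bounds = NULL,
                        default_bound = 1e-3, growth_threshold = 1e-6,
                        max_iterations = 10L) {
  stopifnot(inherits(model, "metabolic_model"))
  audit <- list()
  res <- solve_fba(model)
  obj <- if (res$status == "optimal") res$objective else 0
  it <- 0L
  while (obj <= growth_threshold && it < max_iterations) {
    it <- it + 1L
    sugg <- rank_missing_nutrients(model, mapping)
    if (!nrow(sugg)) break
    top <- sugg[1, ]
    ## compound id: from the mapping if known, else strip the exchange
    ## naming convention (EX_ prefix + external suffix)
    cpd_id <- if (!is.na(top$compound)) top$compound
              else sub("_e$|\\(e\\)$|\\[e\\]$", "",
                       sub("^EX_", "", top$exchange_id))
    cb_get <- function(key) {
      if (is.null(candidate_bounds) || is.na(key) ||
          !key %in% names(candidate_bounds)) NULL
      else candidate_bounds[[key]]
    }
    conc <- cb_get(top$exchange_id) %||% cb_get(cpd_id) %||% default_bound
    j <- match(top$exchange_id, model$reactions$id)
    model$reactions$lb[j] <- -abs(conc)
    res <- solve_fba(model)
    new_obj <- if (res$status == "optimal") res$objective else 0
    audit[[it]] <- tibble(iteration = it, exchange_id = top$exchange_id,
                          compound = cpd_id, bound_mmol_per_l = abs(conc),
                          objective_before = obj, objective_after = new_obj)
    diet <- normalise_diet(bind_rows(
      as_tibble(diet),
      tibble(compound = cpd_id, conc_mmol_per_l = abs(conc),
             provenance = list(sprintf(
               "repair: added via reduced-cost diagnosis (|rc| %.3g), bound %g mmol/L",
               top$reduced_cost_magnitude, abs(conc))))))
    obj <- new_obj
  }
  grew <- obj > growth_threshold
  if (!grew && it >= max_iterations)
    warn(paste0("no growth after ", it, " repair iterations; consider ",
                "model curation or gap-filling (outside this tool's scope)"))
  list(model = model, diet = diet, grew = grew,
       objective = obj,
       audit = if (length(audit)) bind_rows(audit) else
         tibble(iteration = integer(), exchange_id = character(),
                compound = character(), bound_mmol_per_l = numeric(),
                objective_before = numeric(), objective_after = numeric()))
}
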