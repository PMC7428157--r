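#' Construct a constraint-based metabolic model
#'
#' The in-memory model is a stoichiometric matrix `S` (metabolites x
#' reactions) with per-reaction bounds and objective coefficients — the
#' standard FBA data structure. Exchange pseudo-reactions (single external
#' metabolite, no other participants) are auto-detected and form the surface
#' on which a compiled diet is applied.
#'
#' @param id model identifier.
#' @param metabolites tibble with columns `id`, `compartment` (and optionally
#'   `name`).
#' @param reactions tibble with columns `id`, `lb`, `ub`, `objective` (and
#'   optionally `name`).
#' @param S stoichiometric matrix, metabolites x reactions (dense or sparse);
#'   dimnames are set from the id columns.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(id, metabolites, reactions, S) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites))
    metabolites$compartment <- NA_character_
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (nrow(S) != nrow(metabolites) || ncol(S) != nrow(reactions))
    abort("S dimensions do not match the metabolite/reaction tables")
  dimnames(S) <- list(metabolites$id, reactions$id)
  reactions$lb <- as.numeric(reactions$lb)
  reactions$ub <- as.numeric(reactions$ub)
  reactions$objective <- as.numeric(reactions$objective)
  if (any(reactions$lb > reactions$ub))
    abort(paste0("lb > ub for reaction(s): ",
                 paste(reactions$id[reactions$lb > reactions$ub],
                       collapse = ", ")))
  m <- structure(list(id = as.character(id), metabolites = metabolites,
                      reactions = reactions, S = S, mode = "yield"),
                 class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", nrow(x$metabolites),
      " metabolites x ", nrow(x$reactions), " reactions, ",
      length(exchange_reactions(x)), " exchange(s), biomass: ",
      biomass_reaction(x) %||% "<none>", "\n", sep = "")
  invisible(x)
}

is_external_metabolite <- function(model) {
  comp <- model$metabolites$compartment
  ids <- model$metabolites$id
  (!is.na(comp) & comp %in% c("e", "C_e", "extracellular")) |
    grepl("_e$|\\(e\\)$|\\[e\\]$", ids)
}

#' Exchange reactions of a model
#'
#' An exchange reaction is a pseudo-reaction with exactly one participating
#' metabolite, and that metabolite external: it imports (negative flux) or
#' exports (positive flux) a compound across the model boundary.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$S != 0)
  ext <- is_external_metabolite(model)
  single <- which(nz == 1)
  keep <- vapply(single, function(j) {
    i <- which(model$S[, j] != 0)
    ext[i]
  }, logical(1))
  model$reactions$id[single[keep]]
}

#' Biomass (objective) reaction of a model
#'
#' @param model a `metabolic_model`.
#' @return The id of the reaction carrying a nonzero objective coefficient,
#'   or `NULL` if none is annotated.
#' @export
biomass_reaction <- function(model) {
  ids <- model$reactions$id[model$reactions$objective != 0]
  if (!length(ids)) NULL else ids[[1]]
}

#' Read a constraint-based model
#'
#' Supports the two interchange formats of the BiGG ecosystem: BiGG-style
#' JSON and SBML Level 3 with the FBC package (flux bounds as parameters,
#' objective via `fbc:listOfObjectives`). SBML `M_`/`R_` id prefixes are
#' stripped so identifiers match the BiGG dialect used by the diet mapper.
#'
#' @param path model file.
#' @param format `"auto"` (by extension), `"bigg_json"` or `"sbml"`.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "bigg_json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "bigg_json"
              else "sbml"
  if (format == "bigg_json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    abort(paste0("cannot parse BiGG JSON model ", path, ": ",
                                 conditionMessage(e))))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    abort(paste0("file ", path, " lacks metabolites/reactions; ",
                 "not a BiGG JSON model"))
  mets <- tibble(
    id = map_chr(doc$metabolites, "id"),
    name = map_chr(doc$metabolites, ~ .x$name %||% .x$id),
    compartment = map_chr(doc$metabolites, ~ as.character(.x$compartment %||%
                                                            NA_character_)))
  rxns <- tibble(
    id = map_chr(doc$reactions, "id"),
    name = map_chr(doc$reactions, ~ .x$name %||% .x$id),
    lb = map_dbl(doc$reactions, ~ .x$lower_bound %||% -1000),
    ub = map_dbl(doc$reactions, ~ .x$upper_bound %||% 1000),
    objective = map_dbl(doc$reactions, ~ .x$objective_coefficient %||% 0))
  ii <- integer(); jj <- integer(); xx <- numeric()
  midx <- setNames(seq_len(nrow(mets)), mets$id)
  for (j in seq_along(doc$reactions)) {
    sto <- doc$reactions[[j]]$metabolites
    if (!length(sto)) next
    mi <- midx[names(sto)]
    if (anyNA(mi))
      abort(paste0("reaction ", rxns$id[j], " references unknown ",
                   "metabolite(s): ",
                   paste(names(sto)[is.na(mi)], collapse = ", ")))
    ii <- c(ii, unname(mi)); jj <- c(jj, rep(j, length(sto)))
    xx <- c(xx, vapply(sto, as.numeric, numeric(1)))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mets), nrow(rxns)))
  m <- metabolic_model(doc$id %||% basename(path), mets, rxns, S)
  if (is.null(biomass_reaction(m)))
    warn("model has no objective annotation; set one before solve_fba()")
  m
}

strip_sbml_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    abort(paste0("cannot parse SBML model ", path, ": ",
                                 conditionMessage(e))))
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (!length(sp)) abort(paste0("no species found in ", path))
  mets <- tibble(
    id = strip_sbml_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"))
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  pars <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (!length(rx)) abort(paste0("no reactions found in ", path))
  rid <- strip_sbml_prefix(xml2::xml_attr(rx, "id"), "R_")
  lbref <- xml2::xml_attr(rx, "lowerFluxBound")
  ubref <- xml2::xml_attr(rx, "upperFluxBound")
  rev <- xml2::xml_attr(rx, "reversible") %in% c("true", "1")
  lb <- unname(parval[lbref])
  lb[is.na(lb)] <- ifelse(rev[is.na(lb)], -1000, 0)
  ub <- unname(parval[ubref])
  ub[is.na(ub)] <- 1000
  ## fbc objective
  fo <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  obj_rxn <- strip_sbml_prefix(xml2::xml_attr(fo, "reaction"), "R_")
  obj_coef <- as.numeric(xml2::xml_attr(fo, "coefficient"))
  rxns <- tibble(id = rid, name = xml2::xml_attr(rx, "name"),
                 lb = lb, ub = ub,
                 objective = ifelse(rid %in% obj_rxn,
                                    obj_coef[match(rid, obj_rxn)], 0))
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]
  midx <- setNames(seq_len(nrow(mets)), mets$id)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        rx[[j]], paste0("./*[local-name()='", side,
                        "']/*[local-name()='speciesReference']"))
      if (!length(refs)) next
      sids <- strip_sbml_prefix(xml2::xml_attr(refs, "species"), "M_")
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      if (side == "listOfReactants") sto <- -sto
      mi <- midx[sids]
      if (anyNA(mi))
        abort(paste0("reaction ", rid[j], " references unknown species"))
      ii <- c(ii, unname(mi)); jj <- c(jj, rep(j, length(refs)))
      xx <- c(xx, sto)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mets), nrow(rxns)))
  m <- metabolic_model(xml2::xml_attr(
    xml2::xml_find_first(doc, "//*[local-name()='model']"), "id") %||%
      basename(path), mets, rxns, S)
  if (is.null(biomass_reaction(m)))
    warn("model has no objective annotation; set one before solve_fba()")
  m
}

#' Write a model as BiGG-style JSON
#'
#' Used by the synthetic fixtures so toy models travel through the same
#' public format the real pipeline reads.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  S <- model$S
  rl <- lapply(seq_len(nrow(model$reactions)), function(j) {
    nz <- which(S[, j] != 0)
    list(id = model$reactions$id[j], name = model$reactions$name[j],
         metabolites = as.list(setNames(as.numeric(S[nz, j]),
                                        model$metabolites$id[nz])),
         lower_bound = model$reactions$lb[j],
         upper_bound = model$reactions$ub[j],
         objective_coefficient = model$reactions$objective[j],
         gene_reaction_rule = "")
  })
  ml <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i], name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i]))
  jsonlite::write_json(list(id = model$id, metabolites = ml, reactions = rl,
                            genes = list(), version = "1"),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Apply a mapped diet as exchange-reaction bounds
#'
#' Implements the sign convention of constraint-based modelling: uptake is a
#' negative exchange flux, so each matched compound's exchange reaction gets
#' lower bound `-concentration` (yield mode, mmol per litre of medium) or
#' `-uptake flux` (rate mode, mmol/gDW/h). Every exchange reaction *not*
#' covered by the diet is closed for uptake (lower bound 0); secretion upper
#' bounds are never touched.
#'
#' @param model a `metabolic_model`.
#' @param mapping a mapping tibble from [map_diet()].
#' @param diet a `compiled_diet` (yield mode) or a tibble with `compound` and
#'   `conc_mmol_per_l` holding uptake fluxes (rate mode).
#' @param mode `"yield"` (bounds are concentrations; objective in gDW/L) or
#'   `"rate"` (bounds are fluxes; objective on the hr^-1 scale).
#' @return The constrained `metabolic_model`.
#' @export
apply_diet_bounds <- function(model, mapping, diet,
                              mode = c("yield", "rate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "metabolic_model"))
  ex <- exchange_reactions(model)
  if (!length(ex)) abort("model has no exchange reactions")
  rx <- model$reactions
  rx$lb[rx$id %in% ex & rx$lb < 0] <- 0       # close all uptakes first
  used <- mapping[mapping$status %in% c("matched", "surrogate"), ]
  if (nrow(used)) {
    bad <- setdiff(used$exchange_id, ex)
    if (length(bad))
      abort(paste0("mapping targets non-exchange reaction(s): ",
                   paste(bad, collapse = ", ")))
    conc <- diet$conc_mmol_per_l[match(used$compound, diet$compound)]
    if (anyNA(conc))
      abort(paste0("mapped compound(s) absent from the diet: ",
                   paste(used$compound[is.na(conc)], collapse = ", ")))
    ## several diet compounds may share one exchange (surrogates): sum them
    per_ex <- tibble(exchange_id = used$exchange_id, conc = conc) |>
      group_by(.data$exchange_id) |>
      summarise(conc = sum(.data$conc), .groups = "drop")
    i <- match(per_ex$exchange_id, rx$id)
    rx$lb[i] <- -per_ex$conc
  }
  dropped <- mapping$compound[mapping$status == "dropped"]
  if (length(dropped))
    warn(paste0("diet compound(s) without a model exchange left out: ",
                paste(dropped, collapse = ", ")))
  model$reactions <- rx
  model$mode <- mode
  model
}

#' Solve the flux balance analysis linear program
#'
#' Maximises the objective (biomass) flux `c'v` subject to steady state
#' `S v = 0` and the reaction bounds, using the built-in bounded-variable
#' simplex. The full optimality certificate is kept: per-reaction fluxes and
#' reduced costs, per-metabolite duals. With yield-mode bounds (mmol/L) and a
#' biomass reaction normalised to 1 gDW per unit flux, the objective value is
#' the biomass yield in grams dry weight per litre of medium.
#'
#' Reduced-cost sign convention: for a reaction resting at its lower bound
#' the reported value is the sensitivity of the objective to that bound
#' (`d objective / d lb`), so an uptake reaction with reduced cost `-r`
#' gains `r` objective units per mmol/L of extra nutrient.
#'
#' @param model a `metabolic_model` with >= 1 nonzero objective coefficient.
#' @param tol LP pivot tolerance.
#' @return An `fba_result`: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective`, `fluxes` (tibble `reaction`, `flux`,
#'   `reduced_cost`, `lb`, `ub`), `duals` (tibble `metabolite`, `dual`),
#'   `mode`, `biomass_id`.
#' @examples
#' toy <- make_toy_model(2, stoich = c(1, 2))
#' res <- solve_fba(constrain_toy(toy$model, c(5, 4)))
#' glance(res)
#' @export
solve_fba <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(biomass_reaction(model)))
    abort("model has no objective; set a nonzero objective coefficient")
  rx <- model$reactions
  sol <- lp_solve_bounded(model$S, rep(0, nrow(model$metabolites)),
                          rx$objective, rx$lb, rx$ub, maximize = TRUE,
                          tol = tol)
  status <- sol$status
  if (status %in% c("iteration_limit"))
    abort("LP solver hit its iteration limit; model may be ill-conditioned")
  res <- structure(list(
    status = status,
    objective = if (status == "optimal") sol$objective else NA_real_,
    fluxes = tibble(reaction = rx$id, flux = sol$x,
                    reduced_cost = sol$reduced_costs, lb = rx$lb, ub = rx$ub),
    duals = tibble(metabolite = model$metabolites$id, dual = sol$y),
    mode = model$mode %||% "yield",
    biomass_id = biomass_reaction(model),
    max_residual = if (status == "optimal")
      max(abs(as.numeric(model$S %*% sol$x))) else NA_real_),
    class = "fba_result")
  res
}

#' @export
print.fba_result <- function(x, ...) {
  unit <- if (x$mode == "yield") "gDW/L" else "hr^-1 scale"
  cat("<fba_result> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective, digits = 6), " (", unit, ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Flux range of one reaction at the fixed optimum
#'
#' Flux variability analysis for a single reaction: the objective is pinned
#' to its optimal value (within a relative tolerance) and the target
#' reaction's flux is minimised and maximised. A range wider than ~1e-6
#' signals alternate optima, so point estimates of e.g. secretion fluxes
#' should be read as any value inside the range.
#'
#' @param model a constrained `metabolic_model`.
#' @param reaction reaction id whose flux range is wanted.
#' @param optimum optimal objective value; solved for when `NULL`.
#' @param rel_tol relative slack allowed on the pinned optimum.
#' @return Tibble with `reaction`, `min_flux`, `max_flux`, `width`.
#' @export
fixed_optimum_flux_range <- function(model, reaction, optimum = NULL,
                                     rel_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- match(reaction, model$reactions$id)
  if (is.na(j)) abort(paste0("unknown reaction: ", reaction))
  if (is.null(optimum)) {
    base <- solve_fba(model)
    if (base$status != "optimal")
      abort(paste0("cannot fix the optimum: baseline solve is ",
                   base$status))
    optimum <- base$objective
  }
  rx <- model$reactions
  n <- nrow(rx)
  ## add row c'v - z = 0 with z >= optimum * (1 - rel_tol)
  A <- rbind(as.matrix(model$S), rx$objective)
  A <- cbind(A, c(rep(0, nrow(model$S)), -1))
  zmin <- optimum - abs(optimum) * rel_tol - 1e-12
  lb <- c(rx$lb, zmin); ub <- c(rx$ub, Inf)
  cobj <- c(rep(0, n), 0); cobj[j] <- 1
  b <- rep(0, nrow(A))
  lo <- lp_solve_bounded(A, b, cobj, lb, ub, maximize = FALSE)
  hi <- lp_solve_bounded(A, b, cobj, lb, ub, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    abort("flux range LP infeasible after fixing the optimum; the fixing tolerance may be too tight")
  tibble(reaction = reaction, min_flux = lo$objective,
         max_flux = hi$objective, width = hi$objective - lo$objective)
}
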