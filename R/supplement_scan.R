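#' Scan nutrient supplementations for growth effects
#'
#' Re-optimises the model once per compound with that compound's uptake
#' bound widened — either by an absolute amount (`mode = "absolute"`, e.g.
#' +1 mmol/L, which also opens the exchange of an absent compound) or by a
#' relative fraction of its current concentration (`mode = "relative"`, e.g.
#' +30%) — and reports the relative yield difference against the unperturbed
#' baseline. The two modes are complementary: absolute deltas surface
#' compounds that are scarce or absent (or heavy), relative deltas surface
#' abundant, light compounds. Effects below `cutoff` are retained in the raw
#' rows but excluded from the effect set.
#'
#' @param model a `metabolic_model` (unconstrained bounds are fine; the diet
#'   is applied internally).
#' @param diet a `compiled_diet`.
#' @param mapping mapping tibble from [map_diet()].
#' @param mode `"absolute"` or `"relative"`.
#' @param delta mmol/L for absolute mode, fraction (0.3 = +30%) for relative.
#' @param cutoff relative-difference threshold separating real effects from
#'   numerical noise.
#' @param extra_compounds compounds to supplement even though absent from the
#'   diet (absolute mode; e.g. glucose, arabinose). Must be resolvable in the
#'   exchange `index`.
#' @param index exchange index; recomputed from the model when `NULL`.
#' @return A `supplementation_report`: tibble `compound`, `exchange_id`,
#'   `baseline`, `perturbed`, `relative_difference`, `effect` with attributes
#'   `mode`, `delta`, `cutoff`, `baseline`.
#' @examples
#' toy <- make_toy_model(2, stoich = c(1, 2))
#' bundle_diet <- tibble::tibble(compound = c("s1", "s2"),
#'                               conc_mmol_per_l = c(5, 4),
#'                               provenance = list("x", "x"))
#' idx <- build_exchange_index(toy$model)
#' mp <- map_diet(bundle_diet, idx)
#' scan_supplements(toy$model, bundle_diet, mp, mode = "relative",
#'                  delta = 0.3)
#' @export
scan_supplements <- function(model, diet, mapping, mode = c("absolute",
                                                            "relative"),
                             delta = if (mode == "absolute") 1 else 0.3,
                             cutoff = 1e-6, extra_compounds = NULL,
                             index = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "metabolic_model"))
  if (delta < 0) abort("delta must be >= 0")
  if (is.null(index)) index <- build_exchange_index(model)
  base_model <- apply_diet_bounds(model, mapping, diet, mode = "yield")
  base <- solve_fba(base_model)
  if (base$status != "optimal" || base$objective <= 0)
    abort(paste0("baseline objective is ",
                 if (base$status == "optimal") "zero" else base$status,
                 "; diagnose the diet with rank_missing_nutrients() before ",
                 "scanning supplements"))
  b0 <- base$objective

  present <- mapping[mapping$status %in% c("matched", "surrogate"), ]
  targets <- tibble(compound = present$compound,
                    exchange_id = present$exchange_id,
                    conc = diet$conc_mmol_per_l[match(present$compound,
                                                      diet$compound)])
  if (length(extra_compounds)) {
    if (mode != "absolute")
      abort("extra_compounds (absent from the diet) need mode = 'absolute'")
    k <- match(extra_compounds, index$compound)
    if (anyNA(k))
      abort(paste0("extra compound(s) not in the model: ",
                   paste(extra_compounds[is.na(k)], collapse = ", ")))
    new <- !extra_compounds %in% targets$compound
    targets <- bind_rows(targets,
                         tibble(compound = extra_compounds[new],
                                exchange_id = index$exchange_id[k][new],
                                conc = 0))
  }
  targets <- targets |> arrange(.data$compound)

  rows <- map(seq_len(nrow(targets)), function(i) {
    new_conc <- if (mode == "absolute") targets$conc[i] + delta
                else targets$conc[i] * (1 + delta)
    m <- base_model
    j <- match(targets$exchange_id[i], m$reactions$id)
    m$reactions$lb[j] <- -new_conc
    r <- solve_fba(m)
    pert <- if (r$status == "optimal") r$objective else NA_real_
    tibble(compound = targets$compound[i],
           exchange_id = targets$exchange_id[i],
           baseline = b0, perturbed = pert,
           relative_difference = (pert - b0) / b0)
  })
  out <- bind_rows(rows)
  out$effect <- abs(out$relative_difference) >= cutoff
  structure(out, mode = mode, delta = delta, cutoff = cutoff, baseline = b0,
            class = c("supplementation_report", class(out)))
}

#' Order a supplementation report by effect size
#'
#' @param report a `supplementation_report`.
#' @param effects_only drop sub-cutoff rows.
#' @return The report rows sorted by descending relative difference, ties
#'   broken lexicographically by compound.
#' @export
rank_report <- function(report, effects_only = FALSE) {
  out <- report |>
    arrange(desc(.data$relative_difference), .data$compound)
  if (effects_only) out <- out[out$effect, ]
  out
}

#' @export
print.supplementation_report <- function(x, ...) {
  cat("<supplementation_report> mode ", attr(x, "mode"), ", delta ",
      attr(x, "delta"),
      if (attr(x, "mode") == "absolute") " mmol/L" else " (fraction)",
      ", baseline ", format(attr(x, "baseline"), digits = 6),
      ", ", sum(x$effect), "/", nrow(x), " compound(s) above cutoff ",
      format(attr(x, "cutoff")), "\n", sep = "")
  NextMethod()
}

#' Write a supplementation report as TSV
#'
#' @param report a `supplementation_report`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(report, path) {
  df <- as_tibble(report)
  df$mode <- attr(report, "mode")
  df$delta <- attr(report, "delta")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
autoplot.supplementation_report <- function(object, effects_only = TRUE,
                                            ...) {
  df <- rank_report(object, effects_only = effects_only)
  df$compound <- factor(df$compound, levels = rev(df$compound))
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$relative_difference,
                                   y = .data$compound)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "relative yield difference (%)", y = NULL,
      title = sprintf("Supplementation %s%s per compound",
                      if (attr(object, "mode") == "absolute") "+" else "+",
                      if (attr(object, "mode") == "absolute")
                        paste0(attr(object, "delta"), " mmol/L")
                      else paste0(100 * attr(object, "delta"), "%"))) +
    ggplot2::theme_minimal()
}
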