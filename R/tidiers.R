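#' Tidy an FBA result
#'
#' One row per reaction with its flux and reduced cost, broom-style.
#'
#' @param x an `fba_result`.
#' @param nonzero_only keep only reactions carrying flux or a reduced cost.
#' @param ... unused.
#' @return A tibble `reaction`, `flux`, `reduced_cost`, `lb`, `ub`.
#' @export
tidy.fba_result <- function(x, nonzero_only = FALSE, ...) {
  out <- x$fluxes
  if (nonzero_only)
    out <- out[abs(out$flux) > 1e-9 | abs(out$reduced_cost) > 1e-9, ]
  out
}

#' @rdname tidy.fba_result
#' @export
glance.fba_result <- function(x, ...) {
  tibble(status = x$status, objective = x$objective, mode = x$mode,
         unit = if (x$mode == "yield") "gDW/L" else "hr^-1 scale",
         biomass_id = x$biomass_id %||% NA_character_,
         max_residual = x$max_residual)
}

#' @export
tidy.supplementation_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.supplementation_report <- function(x, ...) {
  tibble(mode = attr(x, "mode"), delta = attr(x, "delta"),
         cutoff = attr(x, "cutoff"), baseline = attr(x, "baseline"),
         n_compounds = nrow(x), n_effects = sum(x$effect))
}

#' @export
autoplot.fba_result <- function(object, top = 20, ...) {
  df <- tidy(object, nonzero_only = TRUE)
  df <- df[order(-abs(df$flux)), ]
  df <- head(df, top)
  df$reaction <- factor(df$reaction, levels = rev(df$reaction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux, y = .data$reaction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = if (object$mode == "yield")
      "flux (mmol/L; biomass in gDW/L)" else "flux (mmol/gDW/h)",
      y = NULL, title = "Largest flux magnitudes at the FBA optimum") +
    ggplot2::theme_minimal()
}

#' Serialise an FBA result as a JSON report
#'
#' @param x an `fba_result`.
#' @param path output path.
#' @param flux_tol fluxes/reduced costs below this magnitude are omitted.
#' @return `path`, invisibly.
#' @export
write_fba_report <- function(x, path, flux_tol = 1e-9) {
  nz <- tidy(x, nonzero_only = TRUE)
  jsonlite::write_json(list(
    status = x$status, objective = x$objective, mode = x$mode,
    unit = if (x$mode == "yield") "gDW/L" else "hr^-1 scale",
    biomass_reaction = x$biomass_id,
    fluxes = setNames(as.list(nz$flux), nz$reaction),
    reduced_costs = setNames(as.list(nz$reduced_cost), nz$reaction)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
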