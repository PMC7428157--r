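# Independent oracles used across the suite. These deliberately share no
# code with the package's simplex: the LP oracle enumerates basic solutions
# (vertices of {Av=b, lb<=v<=ub}) by brute force, which is exact for the
# small fixtures it is used on (n <= 8 reactions).

brute_force_lp <- function(A, b, obj, lb, ub, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  best <- -Inf; best_x <- NULL; feasible <- FALSE
  check <- function(x) {
    if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) return()
    if (max(abs(A %*% x - b)) > 1e-7) return()
    feasible <<- TRUE
    val <- sum(obj * x)
    if (val > best) { best <<- val; best_x <<- x }
  }
  combos <- if (m == 0) matrix(integer(), 0, 1) else utils::combn(n, m)
  for (ci in seq_len(ncol(combos))) {
    B <- combos[, ci]
    AB <- A[, B, drop = FALSE]
    if (m > 0 && abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    n_free <- length(N)
    for (mask in seq_len(max(1L, 2L^n_free)) - 1L) {
      xN <- numeric(n_free)
      ok <- TRUE
      for (k in seq_len(n_free)) {
        at_ub <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L
        v <- if (at_ub) ub[N[k]] else lb[N[k]]
        if (!is.finite(v)) { ok <- FALSE; break }
        xN[k] <- v
      }
      if (!ok) next
      x <- numeric(n)
      x[N] <- xN
      if (m > 0) {
        rhs <- b - if (n_free) A[, N, drop = FALSE] %*% xN else b * 0
        xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
        if (is.null(xB)) next
        x[B] <- as.numeric(xB)
      }
      check(x)
    }
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_,
       x = best_x)
}

# exhaustive single-compound relaxation: which closed/binding exchange gains
# the objective most when relaxed by eps?
brute_force_best_relaxation <- function(model, eps = 1e-3) {
  ex <- exchange_reactions(model)
  base <- solve_fba(model)
  base_obj <- if (base$status == "optimal") base$objective else 0
  gains <- vapply(ex, function(r) {
    m2 <- model
    j <- match(r, m2$reactions$id)
    m2$reactions$lb[j] <- m2$reactions$lb[j] - eps
    r2 <- solve_fba(m2)
    (if (r2$status == "optimal") r2$objective else 0) - base_obj
  }, numeric(1))
  gains <- sort(gains, decreasing = TRUE)
  list(best = names(gains)[1], gains = gains)
}

# SBML L3 + FBC serialisation of the 2-substrate toy model, written from a
# literal template (independent of the package's JSON writer)
write_toy_sbml <- function(path) {
  xml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_s1_e" compartment="e" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="M_s2_e" compartment="e" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="M_s1_c" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="M_s2_c" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
      <parameter id="lb_s1" value="-5" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_s1_e" reversible="true" fast="false" fbc:lowerFluxBound="lb_s1" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="M_s1_e" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="R_EX_s2_e" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="M_s2_e" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="R_T_s1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="M_s1_e" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="M_s1_c" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R_T_s2" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="M_s2_e" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="M_s2_c" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R_BIOMASS_toy" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants>
          <speciesReference species="M_s1_c" stoichiometry="1" constant="true"/>
          <speciesReference species="M_s2_c" stoichiometry="2" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIOMASS_toy" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>'
  writeLines(xml, path)
  invisible(path)
}

lp_matrices <- function(model) {
  list(A = as.matrix(model$S), b = rep(0, nrow(model$metabolites)),
       obj = model$reactions$objective, lb = model$reactions$lb,
       ub = model$reactions$ub)
}
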