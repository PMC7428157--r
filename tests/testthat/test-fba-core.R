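test_that("BiGG JSON models round-trip through write/read", {
  toy <- make_toy_model(2, stoich = c(1, 2), maintenance = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  m2 <- read_model(path)
  expect_equal(m2$reactions$id, toy$model$reactions$id)
  expect_equal(m2$reactions$lb, toy$model$reactions$lb)
  expect_equal(m2$reactions$objective, toy$model$reactions$objective)
  expect_equal(as.matrix(m2$S), as.matrix(toy$model$S),
               ignore_attr = TRUE)
  expect_equal(biomass_reaction(m2), "BIOMASS_toy")
  expect_equal(sort(exchange_reactions(m2)),
               sort(exchange_reactions(toy$model)))
})

test_that("SBML L3 FBC models load with bounds, stoichiometry and objective", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_toy_sbml(path)
  m <- read_model(path)
  expect_equal(nrow(m$metabolites), 4)
  expect_equal(nrow(m$reactions), 5)
  expect_equal(biomass_reaction(m), "BIOMASS_toy")
  ## parameter-referenced bounds
  expect_equal(m$reactions$lb[m$reactions$id == "EX_s1_e"], -5)
  expect_equal(m$reactions$ub[m$reactions$id == "EX_s1_e"], 1000)
  ## stoichiometry: biomass consumes 1 s1_c + 2 s2_c
  expect_equal(as.numeric(m$S["s2_c", "BIOMASS_toy"]), -2)
  ## equivalent JSON toy gives the same FBA optimum
  res <- solve_fba(constrain_toy(m, c(s1 = 5, s2 = 4)))
  ref <- make_toy_model(2, stoich = c(1, 2))
  expect_equal(res$objective, ref$optimum(c(5, 4)), tolerance = 1e-9)
})

test_that("truncated model files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "broken", "metabolites": [', path)
  expect_error(read_model(path), "parse")
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", path2)
  expect_error(read_model(path2), "parse|species")
})

test_that("diet bounds follow the uptake sign convention", {
  toy <- make_toy_model(2, stoich = c(1, 1))
  diet <- tibble::tibble(compound = "s1", conc_mmol_per_l = 10,
                         provenance = list("r"))
  idx <- build_exchange_index(toy$model)
  mp <- suppressWarnings(map_diet(diet, idx))
  ## open s2 beforehand to confirm undieted exchanges are re-closed
  m0 <- toy$model
  m0$reactions$lb[m0$reactions$id == "EX_s2_e"] <- -99
  m <- apply_diet_bounds(m0, mp, diet)
  expect_equal(m$reactions$lb[m$reactions$id == "EX_s1_e"], -10)
  expect_equal(m$reactions$lb[m$reactions$id == "EX_s2_e"], 0)
  ## secretion (upper) bounds untouched
  expect_equal(m$reactions$ub, m0$reactions$ub)
  ## mapping to a non-exchange reaction errors
  bad <- tibble::tibble(compound = "s1", status = "matched",
                        exchange_id = "T_s1", note = "")
  expect_error(apply_diet_bounds(toy$model, bad, diet), "non-exchange")
})

test_that("toy FBA objectives equal the closed-form min-ratio optimum", {
  cases <- list(
    list(n = 1, stoich = 10, conc = 10),          # 10/10 = 1
    list(n = 2, stoich = c(1, 2), conc = c(5, 4)),# second limiting: 2
    list(n = 3, stoich = c(2, 1, 4), conc = c(10, 3, 100)))
  for (cs in cases) {
    toy <- make_toy_model(cs$n, stoich = cs$stoich)
    res <- solve_fba(constrain_toy(toy$model, cs$conc))
    expect_equal(res$status, "optimal")
    expect_equal(res$objective, toy$optimum(cs$conc), tolerance = 1e-7)
  }
  ## all uptakes closed: zero growth, not an error
  toy <- make_toy_model(2)
  res0 <- solve_fba(toy$model)
  expect_equal(res0$status, "optimal")
  expect_equal(res0$objective, 0)
})

test_that("objective scales linearly with the limiting diet bound", {
  toy <- make_toy_model(1, stoich = 10)
  r1 <- solve_fba(constrain_toy(toy$model, 10))
  r2 <- solve_fba(constrain_toy(toy$model, 20))
  expect_equal(r2$objective, 2 * r1$objective, tolerance = 1e-9)
})

test_that("relaxing any diet bound never decreases the optimum", {
  for (seed in c(2, 5, 13)) {
    toy <- make_random_toy_model(seed)
    m <- constrain_toy(toy$model, toy$conc)
    base <- solve_fba(m)
    if (base$status != "optimal") next
    ex <- exchange_reactions(m)
    for (r in ex) {
      m2 <- m
      j <- match(r, m2$reactions$id)
      m2$reactions$lb[j] <- m2$reactions$lb[j] - 1
      res <- solve_fba(m2)
      expect_gte(res$objective, base$objective - 1e-9)
    }
  }
})

test_that("flux ranges at the fixed optimum expose alternate optima", {
  ## unique optimum: range collapses to the FBA flux
  toy <- make_toy_model(2, stoich = c(1, 2))
  m <- constrain_toy(toy$model, c(5, 4))
  res <- solve_fba(m)
  fr <- fixed_optimum_flux_range(m, "T_s1")
  expect_lt(fr$width, 1e-4)   # only the 1e-6 relative slack on the optimum
  flux <- res$fluxes$flux[res$fluxes$reaction == "T_s1"]
  expect_equal(fr$min_flux, flux, tolerance = 1e-5)
  ## redundant parallel transporter: the range spans both alternatives
  toy2 <- make_toy_model(1, stoich = 1, redundant_pathway = TRUE)
  m2 <- constrain_toy(toy2$model, c(8, 0))
  fr2 <- fixed_optimum_flux_range(m2, "T_s1")
  expect_equal(fr2$min_flux, 0, tolerance = 1e-6)
  expect_equal(fr2$max_flux, 8, tolerance = 1e-6)
})

test_that("tidy/glance expose the optimality certificate", {
  toy <- make_toy_model(1, stoich = 2)
  res <- solve_fba(constrain_toy(toy$model, 10))
  td <- tidy(res)
  expect_true(all(c("reaction", "flux", "reduced_cost") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$unit, "gDW/L")
  expect_lt(gl$max_residual, 1e-9)
})
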