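test_that("worked unit conversions match hand arithmetic", {
  ## pure water, density 1 g/cm3: 5.551e4 mmol/L
  expect_equal(mass_to_molar(1000, 18.015), 55509.3, tolerance = 1e-6)
  expect_equal(water_mmol_per_l(), 55509.3, tolerance = 1e-6)
  expect_equal(mass_to_molar(0, 18.015), 0)
  ## glucose: 1.8016 g/L at MW 180.16 is 10 mmol/L
  expect_equal(mass_to_molar(1.8016, 180.16), 10, tolerance = 1e-12)
  expect_error(mass_to_molar(1, NA), "molecular weight")
})

test_that("pH converts to protons and is strictly decreasing", {
  expect_equal(ph_to_proton(7), 1e-4)
  expect_equal(ph_to_proton(0), 1000)
  expect_equal(ph_to_proton(14), 1e-8)
  expect_error(ph_to_proton(-0.1), "pH")
  expect_error(ph_to_proton(14.5), "pH")
  grid <- seq(0, 14, by = 0.5)
  expect_true(all(diff(ph_to_proton(grid)) < 0))
})

test_that("decomposition applies fractions and conserves mass", {
  comp <- composition_table(tibble::tibble(
    component = "tryptone", compound = "glu__L", mass_fraction = 0.05))
  out <- decompose_component(10, comp)
  expect_equal(out$mass_g_per_l, 0.5)
  expect_equal(out$compound, "glu__L")
  ## zero amount prunes to nothing
  expect_equal(nrow(decompose_component(0, comp)), 0)
  ## fractions summing to exactly 1 conserve the full mass
  full <- composition_table(tibble::tibble(
    component = "x", compound = c("a", "b", "c"),
    mass_fraction = c(0.2, 0.5, 0.3)))
  out2 <- decompose_component(5, full)
  expect_equal(sum(out2$mass_g_per_l), 5, tolerance = 1e-12)
})

test_that("mass bookkeeping holds for random fractions", {
  set.seed(42)
  for (k in 1:20) {
    nf <- sample(1:6, 1)
    fr <- stats::runif(nf); fr <- fr / sum(fr) * stats::runif(1, 0.3, 1)
    comp <- composition_table(tibble::tibble(
      component = "x", compound = paste0("c", seq_len(nf)),
      mass_fraction = fr))
    amt <- stats::runif(1, 0, 50)
    out <- decompose_component(amt, comp)
    expect_lte(sum(out$mass_g_per_l), amt * (1 + 1e-9))
  }
})

test_that("speciation handles dissociation, splits, identity and cycles", {
  b <- make_toy_recipe_bundle()
  diet <- tibble::tibble(compound = c("nacl", "fe"),
                         conc_mmol_per_l = c(171, 0.10),
                         provenance = list("x", "y"))
  out <- apply_speciation(diet, b$rules, b$registry)
  expect_equal(setNames(out$conc_mmol_per_l, out$compound),
               c(cl = 171, fe2 = 0.05, fe3 = 0.05, na1 = 171))
  ## molar conservation for 1:1 dissociation, total conservation for splits
  expect_equal(sum(out$conc_mmol_per_l[out$compound %in% c("fe2", "fe3")]),
               0.10)
  ## no matching rule: identity
  diet2 <- tibble::tibble(compound = "gly", conc_mmol_per_l = 5,
                          provenance = list("z"))
  out2 <- apply_speciation(diet2, b$rules, b$registry)
  expect_equal(out2$compound, "gly")
  expect_equal(out2$conc_mmol_per_l, 5)
  ## cycles are rejected
  cyc <- speciation_rules(tibble::tibble(
    source = c("a", "b"), product = c("b", "a"), coefficient = 1,
    rule_kind = "surrogate"))
  expect_error(apply_speciation(diet2, cyc), "cyclic")
  ## provenance records the applied rule
  expect_true(any(grepl("dissociation", unlist(
    out$provenance[out$compound == "na1"]))))
})

test_that("polymer substitution checks mass conservation when weights are known", {
  reg <- compound_registry(tibble::tibble(
    id = c("cellulose_unit", "cellb"),
    molecular_weight = c(162.14, 342.30)))
  ok <- speciation_rules(tibble::tibble(
    source = "cellulose_unit", product = "cellb", coefficient = 0.5,
    rule_kind = "polymer_substitution"))
  diet <- tibble::tibble(compound = "cellulose_unit", conc_mmol_per_l = 10,
                         provenance = list("r"))
  out <- apply_speciation(diet, ok, reg)   # +5.6% mass from hydration water
  expect_equal(out$conc_mmol_per_l, 5)
  bad <- speciation_rules(tibble::tibble(
    source = "cellulose_unit", product = "cellb", coefficient = 2,
    rule_kind = "polymer_substitution"))
  expect_error(apply_speciation(diet, bad, reg), "mass")
})

test_that("compile_diet runs the full pipeline with provenance", {
  b <- make_toy_recipe_bundle()
  d <- compile_diet(b$recipe, b$compositions, b$rules, b$registry)
  expect_s3_class(d, "compiled_diet")
  expect_equal(setNames(d$conc_mmol_per_l, d$compound), b$expected,
               tolerance = 1e-9)
  expect_true(all(d$conc_mmol_per_l > 0))
  expect_true(all(lengths(d$provenance) >= 1))
  ## environment present
  expect_true(all(c("h2o", "o2", "h") %in% d$compound))
  expect_equal(d$conc_mmol_per_l[d$compound == "o2"], 18.2)
  expect_equal(d$conc_mmol_per_l[d$compound == "h"], 1e-4)
})

test_that("empty recipe compiles to environment only", {
  r <- medium_recipe(tibble::tibble(component = character(),
                                    amount = numeric(), unit = character()),
                     ph = 7, oxygen_mmol_per_l = 18.2)
  reg <- compound_registry(tibble::tibble(id = "h2o",
                                          molecular_weight = 18.015))
  d <- compile_diet(r, registry = reg)
  expect_equal(sort(d$compound), c("h", "h2o", "o2"))
  ## anaerobic drops oxygen
  r2 <- medium_recipe(tibble::tibble(component = character(),
                                     amount = numeric(), unit = character()),
                      ph = 7, oxygen_mmol_per_l = 0)
  d2 <- compile_diet(r2, registry = reg)
  expect_equal(sort(d2$compound), c("h", "h2o"))
})

test_that("same compound from two components merges by summation", {
  reg <- compound_registry(tibble::tibble(
    id = c("gly", "h2o"), molecular_weight = c(75.07, 18.015)))
  comp <- composition_table(tibble::tibble(
    component = c("tryptone", "yeast_extract"), compound = "gly",
    mass_fraction = c(0.02, 0.03)))
  r <- medium_recipe(tibble::tibble(
    component = c("tryptone", "yeast_extract"), amount = c(10, 5),
    unit = "g/L"), ph = 7, oxygen_mmol_per_l = 0)
  d <- compile_diet(r, comp, registry = reg)
  gly <- d[d$compound == "gly", ]
  ## manual sum: (10*0.02 + 5*0.03) g/L / 75.07 * 1000
  expect_equal(gly$conc_mmol_per_l, (10 * 0.02 + 5 * 0.03) / 75.07 * 1000,
               tolerance = 1e-12)
  expect_equal(sum(grepl("decompose", unlist(gly$provenance))), 2)
})

test_that("compilation is order-independent", {
  b <- make_toy_recipe_bundle()
  d1 <- compile_diet(b$recipe, b$compositions, b$rules, b$registry)
  perm_recipe <- b$recipe
  perm_recipe$components <- perm_recipe$components[c(3, 1, 2), ]
  perm_comp <- b$compositions[rev(seq_len(nrow(b$compositions))), ]
  d2 <- compile_diet(perm_recipe, perm_comp, b$rules, b$registry)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("unresolvable components and duplicate environment injection error", {
  b <- make_toy_recipe_bundle()
  r <- medium_recipe(tibble::tibble(component = "mystery_powder", amount = 1,
                                    unit = "g/L"))
  expect_error(compile_diet(r, b$compositions, b$rules, b$registry),
               "mystery_powder")
  r2 <- medium_recipe(tibble::tibble(component = "o2", amount = 5,
                                     unit = "mmol/L"))
  expect_error(compile_diet(r2, registry = b$registry),
               "duplicate environmental injection")
})

test_that("residue-mass mode adds back one water per residue", {
  reg <- compound_registry(tibble::tibble(id = "gly",
                                          molecular_weight = 75.07))
  comp <- composition_table(tibble::tibble(
    component = "pept", compound = "gly", mass_fraction = 0.5))
  r <- medium_recipe(tibble::tibble(component = "pept", amount = 2,
                                    unit = "g/L"), oxygen_mmol_per_l = 0,
                     aqueous = FALSE)
  free <- compile_diet(r, comp, registry = reg)
  res <- compile_diet(r, comp, registry = reg, residue_mass = TRUE)
  expect_equal(free$conc_mmol_per_l[free$compound == "gly"],
               1 / 75.07 * 1000)
  expect_equal(res$conc_mmol_per_l[res$compound == "gly"],
               1 / (75.07 - 18.015) * 1000)
})

test_that("compiled diets round-trip through TSV with provenance", {
  b <- make_toy_recipe_bundle()
  d <- compile_diet(b$recipe, b$compositions, b$rules, b$registry)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diet(d, path)
  d2 <- read_diet(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))
})
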