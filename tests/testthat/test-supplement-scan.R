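scan_fixture <- function() {
  toy <- make_toy_model(2, stoich = c(1, 2))
  diet <- tibble::tibble(compound = c("s1", "s2"),
                         conc_mmol_per_l = c(50, 4),
                         provenance = list("r", "r"))
  idx <- build_exchange_index(toy$model)
  mp <- suppressWarnings(map_diet(diet, idx))
  list(toy = toy, diet = diet, idx = idx, mp = mp)
}

test_that("supplementing the limiting substrate by +30% gains exactly 30%", {
  fx <- scan_fixture()
  rep <- scan_supplements(fx$toy$model, fx$diet, fx$mp, mode = "relative",
                          delta = 0.3)
  r2 <- rep[rep$compound == "s2", ]           # s2 is limiting (4/2 < 50/1)
  expect_equal(r2$relative_difference, 0.3, tolerance = 1e-9)
  expect_true(r2$effect)
  ## non-limiting substrate: below cutoff, excluded from the effect set
  r1 <- rep[rep$compound == "s1", ]
  expect_lt(abs(r1$relative_difference), 1e-6)
  expect_false(r1$effect)
})

test_that("absolute mode opens exchanges of compounds absent from the diet", {
  fx <- scan_fixture()
  ## add an extra substrate the diet lacks; model can grow on it? no - it
  ## has no biomass route, so its effect is 0, but the row must exist
  rep <- scan_supplements(fx$toy$model, fx$diet, fx$mp, mode = "absolute",
                          delta = 1, extra_compounds = "s1")
  expect_true("s1" %in% rep$compound)
  ## present compound: +1 mmol/L on its concentration
  r2 <- rep[rep$compound == "s2", ][1, ]
  expect_equal(r2$perturbed, (4 + 1) / 2, tolerance = 1e-9)
  expect_error(scan_supplements(fx$toy$model, fx$diet, fx$mp,
                                mode = "absolute", extra_compounds = "nope"),
               "nope")
  expect_error(scan_supplements(fx$toy$model, fx$diet, fx$mp,
                                mode = "relative", extra_compounds = "s1"),
               "absolute")
})

test_that("supplementation never decreases an LP maximum and is order-independent", {
  for (seed in c(6, 17)) {
    toy <- make_random_toy_model(seed)
    conc <- pmax(toy$conc, 0.5)     # ensure growth
    if (toy$spec$maintenance >= conc[1]) conc[1] <- toy$spec$maintenance + 1
    diet <- tibble::tibble(compound = toy$spec$substrate_ids,
                           conc_mmol_per_l = conc,
                           provenance = rep(list("r"), length(conc)))
    idx <- build_exchange_index(toy$model)
    mp <- suppressWarnings(map_diet(diet, idx))
    rep <- scan_supplements(toy$model, diet, mp, mode = "absolute",
                            delta = 1)
    expect_true(all(rep$relative_difference >= -1e-9))
    dperm <- diet[rev(seq_len(nrow(diet))), ]
    mp2 <- suppressWarnings(map_diet(dperm, idx))
    rep2 <- scan_supplements(toy$model, dperm, mp2, mode = "absolute",
                             delta = 1)
    expect_equal(as.data.frame(rep), as.data.frame(rep2))
  }
})

test_that("zero-growth baselines direct the user to the troubleshooter", {
  toy <- make_toy_model(1)
  empty_mp <- tibble::tibble(compound = character(), status = character(),
                             exchange_id = character(), note = character())
  empty <- tibble::tibble(compound = character(),
                          conc_mmol_per_l = numeric(), provenance = list())
  expect_error(scan_supplements(toy$model, empty, empty_mp),
               "rank_missing_nutrients")
})

test_that("rank_report orders by effect then lexicographically", {
  fx <- scan_fixture()
  rep <- scan_supplements(fx$toy$model, fx$diet, fx$mp, mode = "relative",
                          delta = 0.3)
  rk <- rank_report(rep)
  expect_equal(rk$compound[1], "s2")
  ## all-zero effects: stable lexicographic order
  rep0 <- scan_supplements(fx$toy$model, fx$diet, fx$mp, mode = "absolute",
                           delta = 0)
  rk0 <- rank_report(rep0)
  expect_equal(rk0$compound, sort(rk0$compound))
  expect_equal(nrow(rank_report(rep0, effects_only = TRUE)), 0)
})

test_that("report accessors and plot scaffolding work", {
  fx <- scan_fixture()
  rep <- scan_supplements(fx$toy$model, fx$diet, fx$mp, mode = "relative",
                          delta = 0.3)
  gl <- glance(rep)
  expect_equal(gl$mode, "relative")
  expect_equal(gl$n_effects, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_report(rep, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep))
  expect_true(all(c("mode", "delta") %in% names(back)))
})
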