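test_that("generation is deterministic given scenario and seed", {
  sc <- site_scenario()
  a <- generate_site_data(sc, seed = 3)
  b <- generate_site_data(sc, seed = 3)
  expect_identical(a$plots, b$plots)
  expect_identical(a$isotope, b$isotope)
  expect_identical(a$water, b$water)
  expect_identical(a$fallow, b$fallow)
  c <- generate_site_data(sc, seed = 4)
  expect_false(identical(a$plots, c$plots))
})

test_that("noise-free data reproduce the closed-form truth exactly", {
  dat <- generate_site_data(noise_free_scenario(), seed = 1)
  fit <- fit_pipeline(dat)
  expect_equal(coef(fit), coef(dat$truth), tolerance = 1e-12)
  expect_equal(fit$ledger$se, rep(0, nrow(fit$ledger)))
})

test_that("closed-form truth of the default scenario matches the known chain", {
  truth <- closed_form_truth(site_scenario())
  q <- truth$quantities
  # uptake 185, residue ~1.9, surface water ~2.9, groundwater 61.7,
  # constants 6 + 25, NUE 0.5, fallow 3.4, C:N 14.4, residue C 1872
  expect_equal(q$peat_total_n$value, 149.2, tolerance = 1e-3)
  expect_equal(q$nmin_total$value, 301.8, tolerance = 1e-2)
  expect_equal(q$net_c_loss$value, 2474, tolerance = 1e-3)
  # doubling C:N doubles the C mineralized
  sc2 <- site_scenario(profile = soil_profile(2 * 14.4,
                                              bulk_density = 0.555))
  expect_equal(closed_form_truth(sc2)$quantities$c_mineralized$value,
               2 * q$c_mineralized$value)
})

test_that("a zero-source scenario with NUE 1 and full residue credit nets to zero", {
  sc <- noise_free_scenario(
    true_fndr = 0, water_conc_mean = 0, true_ndgw = 0,
    residue_n_spring_mean = 52, soil_no3_mean = 0,
    constants = budget_constants(nue = 1),
    residue_c_mean = (185 - 31) * 14.4)
  truth <- closed_form_truth(sc)
  expect_equal(truth$quantities$nmin_fallow$value, 0)
  expect_equal(truth$quantities$net_c_loss$value, 0, tolerance = 1e-9)
})

test_that("single-seed pipeline estimate lands within 3 analytic SEs of truth", {
  sc <- site_scenario()
  dat <- generate_site_data(sc, seed = 1)
  fit <- suppressWarnings(fit_pipeline(dat))
  truth <- dat$truth$quantities$net_c_loss$value
  expect_lt(abs(fit$quantities$net_c_loss$value - truth),
            3 * fit$quantities$net_c_loss$se)
})

test_that("estimated fNdr is unbiased for the true mixing fraction", {
  sc <- site_scenario()
  app <- sc$application
  grand <- mean(vapply(1:100, function(s) {
    d <- generate_site_data(sc, seed = s)
    mean(fraction_from_residue(d$isotope$atom_pct_15n,
                               app$atom_pct_unlabeled,
                               app$atom_pct_labeled))
  }, numeric(1)))
  # Monte-Carlo error of the grand mean: atom sd 0.1 over 400 tillers
  mc_se <- (sc$tiller_atom_sd / (app$atom_pct_labeled -
                                   app$atom_pct_unlabeled)) / sqrt(400)
  expect_lt(abs(grand - sc$true_fndr), 4 * mc_se)
})

test_that("scenario-implied analytic SEs match the noise model", {
  sc <- site_scenario()
  ses <- scenario_analytic_se(sc)
  expect_equal(unname(ses["uptake_0n"]), sc$uptake_0n_sd / 2)
  expect_equal(unname(ses["ndgw"]), sc$meso_sd * sqrt(2) / 2)
  expect_equal(unname(ses["peat_total_n"]),
               sqrt(ses[["uptake_0n"]]^2 + ses[["ndr"]]^2 +
                      ses[["ndsw"]]^2))
})
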