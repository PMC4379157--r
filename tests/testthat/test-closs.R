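prof1 <- soil_profile(cn_ratio = 14.4, bulk_density = 0.555)

test_that("C:N stoichiometry converts N mineralization to C", {
  cm <- c_mineralized(qn(301.8, 32.5), 14.4)
  expect_equal(cm$value, 4345.92)
  expect_equal(cm$se, 32.5 * 14.4)
  expect_identical(cm$units, "kg C ha-1")
  expect_equal(c_mineralized(qn(0), 14.4)$value, 0)
  expect_error(c_mineralized(qn(300), 0), "positive")
  # linear in the ratio
  expect_equal(c_mineralized(qn(301.8), 2 * 14.4)$value,
               2 * c_mineralized(qn(301.8), 14.4)$value)
})

test_that("net C loss credits the residue input", {
  expect_equal(net_c_loss(qc(4345), qc(1872))$value, 2473)
  expect_equal(net_c_loss(qc(1872), qc(1872))$value, 0)
  n <- net_c_loss(qc(4345, 596), qc(1872, 137))
  expect_equal(n$se, sqrt(596^2 + 137^2))
})

test_that("kg ha-1 to g cm-2 conversion is exact and round-trips", {
  # 2473 kg C ha-1 is 2.473e-2 g C cm-2
  expect_equal(2473 * 1e-5, 2.473e-2, tolerance = 1e-12)
  x <- c(1, 301.8, 4345.92, 1e6)
  expect_equal(x * 1e-5 * 1e5, x, tolerance = 1e-12)
})

test_that("subsidence is linear in net C loss and inverse in bulk density", {
  s1 <- subsidence_rate(qc(2473), prof1)
  expect_equal(s1$value, (2473e-5 / 0.58 / 0.555) / 0.67)
  expect_equal(subsidence_rate(qc(0), prof1)$value, 0)
  expect_equal(subsidence_rate(qc(2 * 2473), prof1)$value, 2 * s1$value)

  dbl_bd <- soil_profile(14.4, bulk_density = 2 * 0.555)
  expect_equal(subsidence_rate(qc(2473), dbl_bd)$value, s1$value / 2)

  half_fmin <- soil_profile(14.4, bulk_density = 0.555, f_min = 0.67 / 2)
  expect_equal(subsidence_rate(qc(2473), half_fmin)$value, 2 * s1$value)

  expect_error(soil_profile(14.4, bulk_density = 0), "positive")
  expect_error(soil_profile(14.4, bulk_density = 0.5, f_min = 0), "f_min")
})

test_that("NUE sensitivity curve is convex decreasing with matching endpoints", {
  fit <- n_budget(twitchell_site(1))
  sen <- nue_sensitivity(fit, nue_grid = seq(0.30, 0.90, 0.05))
  expect_true(all(diff(sen$net_c_loss) < 0))
  # marginally smaller reductions as NUE grows: differences shrink
  expect_true(all(diff(diff(sen$net_c_loss)) > 0))
  expect_error(nue_sensitivity(fit, nue_grid = c(0, 0.5)), "\\(0, 1\\]")

  # a one-point grid at the fitted NUE reproduces the main result
  one <- nue_sensitivity(fit, nue_grid = 0.5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$net_c_loss, fit$quantities$net_c_loss$value)
  expect_equal(one$subsidence, fit$quantities$subsidence$value)

  # sensitivity entry point also accepts raw site measurements
  sen2 <- nue_sensitivity(twitchell_site(1), nue_grid = c(0.5, 0.7))
  expect_equal(sen2$net_c_loss[1], fit$quantities$net_c_loss$value)
})
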