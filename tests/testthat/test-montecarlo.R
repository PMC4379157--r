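test_that("zero-SE inputs make every draw equal the analytic value", {
  site <- site_measurements(
    site = "exact", uptake_0n = qn(185), ndr = qn(1.9), ndsw = qn(2.9),
    ndgw = qn(61.7), residue_n_fall = qn(63.9), residue_n_spring = qn(47),
    soil_no3_at_flooding = qn(20.3), residue_c_input = qc(1872),
    profile = soil_profile(14.4, bulk_density = 0.555))
  mc <- monte_carlo_budget(site, n_draws = 50, seed = 1)
  expect_equal(mc$sd, rep(0, nrow(mc)))
  expect_equal(mc$mean, mc$value)
})

test_that("a fixed seed makes the Monte-Carlo run reproducible", {
  site <- twitchell_site(1)
  a <- monte_carlo_budget(site, n_draws = 500, seed = 99)
  b <- monte_carlo_budget(site, n_draws = 500, seed = 99)
  expect_identical(attr(a, "draws"), attr(b, "draws"))
  expect_identical(a$mean, b$mean)
  c <- monte_carlo_budget(site, n_draws = 500, seed = 100)
  expect_false(identical(a$mean, c$mean))
})

test_that("Monte-Carlo sd tracks the analytic SE on the linear chain", {
  mc <- monte_carlo_budget(twitchell_site(1), n_draws = 20000, seed = 2)
  linear <- c("surface_peat_n", "peat_total_n", "nmin_growing",
              "nmin_total", "c_mineralized", "net_c_loss", "subsidence")
  rel <- abs(mc[linear, "sd"] / mc[linear, "se"] - 1)
  expect_true(all(rel < 0.05))
  # means are centred on the analytic values
  z <- abs(mc[linear, "mean"] - mc[linear, "value"]) /
    (mc[linear, "se"] / sqrt(20000))
  expect_true(all(z < 4))
})

test_that("negative-draw truncation is optional and counted", {
  site <- twitchell_site(1)
  # surface-water SE (1.3 on 2.9) makes negative draws near-certain
  expect_warning(monte_carlo_budget(site, n_draws = 2000, seed = 4,
                                    truncate_negative = TRUE),
                 "truncated")
  expect_silent(monte_carlo_budget(site, n_draws = 200, seed = 4))
  expect_error(monte_carlo_budget(site, n_draws = 0), "n_draws")
})

test_that("simulate() draws from the fitted budget deterministically", {
  fit <- n_budget(twitchell_site(2))
  d1 <- simulate(fit, nsim = 100, seed = 7)
  d2 <- simulate(fit, nsim = 100, seed = 7)
  expect_identical(d1$net_c_loss, d2$net_c_loss)
  expect_equal(nrow(d1), 100L)
  expect_true(all(c("peat_total_n", "net_c_loss", "subsidence")
                  %in% names(d1)))
})
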