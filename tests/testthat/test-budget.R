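consts <- budget_constants() # deposition 6, fixation 25, NUE 0.5

test_that("surface-peat N is the uptake residual after known sources", {
  sp <- surface_peat_n(qn(185.0, 10.0), qn(1.9, 0.2), qn(2.9, 1.3),
                       qn(61.7, 9.0), consts)
  expect_equal(sp$value, 87.5)
  expect_equal(sp$se, sqrt(10^2 + 0.2^2 + 1.3^2 + 9^2))

  sp2 <- surface_peat_n(qn(167.0), qn(3.8), qn(3.0), qn(39.6), consts)
  expect_equal(sp2$value, 89.6)

  zero <- surface_peat_n(qn(95.5), qn(1.9), qn(2.9), qn(59.7), consts)
  expect_equal(zero$value, 0)
  expect_warning(surface_peat_n(qn(30), qn(1.9), qn(2.9), qn(61.7), consts),
                 "negative")
})

test_that("peat total adds groundwater back and NUE inflates to gross", {
  pt <- peat_total_n(qn(87.5, 13.5), qn(61.7, 9.0))
  expect_equal(pt$value, 149.2)
  expect_equal(pt$se, sqrt(13.5^2 + 9.0^2)) # 16.2
  expect_equal(peat_total_n(qn(89.6), qn(39.6))$value, 129.2)

  expect_equal(growing_season_mineralization(pt, 0.5)$value, 298.4)
  expect_equal(growing_season_mineralization(qn(129.2), 0.5)$value, 258.4)
  id <- growing_season_mineralization(pt, 1)
  expect_equal(id$value, pt$value)
  expect_error(growing_season_mineralization(pt, 0), "nue")

  # strictly decreasing in NUE
  grid <- seq(0.3, 0.9, 0.1)
  vals <- sapply(grid, function(nu)
    growing_season_mineralization(pt, nu)$value)
  expect_true(all(diff(vals) < 0))
})

test_that("fallow-season ledger subtracts residue mineralization from soil NO3", {
  rm1 <- residue_n_mineralized_fallow(qn(63.9, 1.3), qn(47))
  expect_equal(rm1$value, 16.9)
  expect_equal(residue_n_mineralized_fallow(qn(30), qn(30))$value, 0)

  expect_equal(fallow_peat_mineralization(qn(20.3), rm1)$value, 3.4)
  expect_equal(fallow_peat_mineralization(qn(42.1), qn(21.0))$value, 21.1)
  expect_equal(fallow_peat_mineralization(qn(16.9), qn(16.9))$value, 0)
  expect_warning(fallow_peat_mineralization(qn(10), qn(16.9)), "negative")

  expect_equal(annual_mineralization(qn(298.4), qn(3.4))$value, 301.8)
  expect_equal(annual_mineralization(qn(0), qn(0))$value, 0)
})

test_that("fitted ledger closes by construction", {
  for (s in 1:2) {
    fit <- n_budget(twitchell_site(s))
    q <- fit$quantities
    expect_equal(q$uptake_0n$value,
                 q$ndr$value + q$ndsw$value + q$ndgw$value +
                   q$n_deposition$value + q$n_fixation$value +
                   q$surface_peat_n$value,
                 tolerance = 1e-9)
    expect_equal(q$peat_total_n$value,
                 q$surface_peat_n$value + q$ndgw$value, tolerance = 1e-9)
    expect_equal(q$nmin_total$value,
                 q$nmin_growing$value + q$nmin_fallow$value,
                 tolerance = 1e-9)
    expect_equal(q$net_c_loss$value,
                 q$c_mineralized$value - q$residue_c_input$value,
                 tolerance = 1e-9)
  }
})

test_that("se modes agree on values and differ only in the peat-total SE", {
  site <- twitchell_site(1)
  paper <- n_budget(site, se_mode = "paper")
  cons <- n_budget(site, se_mode = "consistent")
  expect_equal(paper$ledger$value, cons$ledger$value)
  se_p <- paper$quantities$peat_total_n$se
  se_c <- cons$quantities$peat_total_n$se
  gw <- site$ndgw$se
  # the published convention counts the groundwater SE twice
  expect_equal(se_p, sqrt(se_c^2 + 2 * gw^2))
  expect_lt(se_c, se_p)
})

test_that("fit methods expose the ledger coherently", {
  fit <- n_budget(twitchell_site(1))
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf["peat_total_n"]), 149.2)

  # the summary shares of uptake account for the whole budget
  sh <- summary(fit)$uptake_shares_pct
  expect_equal(sum(sh), 100, tolerance = 1e-9)

  # predicting at the fitted NUE reproduces the main result
  pr <- predict(fit)
  expect_equal(pr$net_c_loss, fit$quantities$net_c_loss$value)
  expect_equal(pr$nue, fit$constants$nue)

  ci <- confint(fit, parm = "net_c_loss")
  q <- fit$quantities$net_c_loss
  expect_equal(unname(ci[1, ]),
               q$value + c(-1, 1) * qnorm(0.975) * q$se)

  expect_output(print(fit), "Peat N \\(total\\)")
  expect_output(print(summary(fit)), "NUE sensitivity")
})
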