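app <- residue_application() # labelled 1310 kg ha-1 at 9.0693 atom %,
                             # field residue 3700 kg ha-1 at 0.3673 atom %

test_that("isotope mixing fraction interpolates between background and input", {
  bg <- 0.3673
  inp <- 9.0693
  expect_equal(fraction_from_residue(bg, bg, inp), 0)
  expect_equal(fraction_from_residue(inp, bg, inp), 1)
  # sample enriched one tenth of the way: fNdr = 0.10
  expect_equal(fraction_from_residue(1.2375, bg, inp), 0.1000,
               tolerance = 1e-4)
})

test_that("mixing fraction round-trips through forward simulation", {
  bg <- 0.3673
  inp <- 9.0693
  set.seed(11)
  for (f_true in c(0, runif(20), 1)) {
    atom <- bg + f_true * (inp - bg)
    expect_equal(fraction_from_residue(atom, bg, inp), f_true,
                 tolerance = 1e-12)
  }
})

test_that("mixing fraction is strictly increasing in sample enrichment", {
  atom <- seq(0.4, 9, length.out = 50)
  f <- fraction_from_residue(atom, 0.3673, 9.0693)
  expect_true(all(diff(f) > 0))
})

test_that("degenerate and out-of-range tracer inputs are flagged", {
  expect_error(fraction_from_residue(0.5, 0.3673, 0.3673), "invalid tracer")
  expect_warning(f <- fraction_from_residue(0.30, 0.3673, 9.0693),
                 "outside")
  expect_lt(f, 0) # raw value preserved, not clamped
  expect_error(fraction_from_residue(101, 0.3673, 9.0693))
})

test_that("N derived from residue scales uptake by fraction and labelled share", {
  expect_equal(n_from_residue(0, 135, 0.2615), 0)
  expect_equal(app$proportion_labeled, 1310 / 5010)
  expect_equal(n_from_residue(0.10, 135, app$proportion_labeled), 3.53,
               tolerance = 1e-3) # 13.5 * 1310/5010
  expect_error(n_from_residue(0.1, -1, 0.5), "nonnegative")
  expect_error(n_from_residue(0.1, 135, 0), "proportion_labeled")
})

test_that("tracer recovery accounting closes exactly", {
  expect_equal(percent_recovered(0, 500, 12), 0)
  expect_equal(percent_recovered(0.10, 120, 12), 100)
  # half of the applied label found in the soil pool: inside the 50-70%
  # soil-recovery band typical of residue tracer studies
  expect_equal(percent_recovered(0.05, 120, 12), 50)
  expect_error(percent_recovered(0.1, 120, 0), "positive")

  expect_equal(percent_loss(0, 0), 100)
  expect_equal(percent_loss(30, 60), 10)
  expect_equal(percent_loss(16, 60), 24)
  expect_warning(neg <- percent_loss(60, 60), "negative loss")
  expect_equal(neg, -20)

  set.seed(5)
  for (i in 1:20) {
    fa <- runif(1, 0, 0.3)
    fb <- runif(1, 0, 0.6)
    above <- percent_recovered(fa, 120, 12)
    below <- percent_recovered(fb, 120, 12)
    loss <- suppressWarnings(percent_loss(above, below))
    expect_identical(above + below + loss, 100)
  }
})

test_that("per-replicate fNdr averaging preserves the replicate SE", {
  atom <- c(0.80, 0.85, 0.83, 0.86)
  uptake <- c(130, 140, 133, 137)
  est <- estimate_ndr(atom, uptake, app)
  f_each <- (atom - 0.3673) / (9.0693 - 0.3673)
  expect_equal(est$fndr, f_each)
  expect_equal(est$fndr_hat, mean(f_each))
  ndr_each <- f_each * uptake * app$proportion_labeled
  expect_equal(est$ndr$value, mean(ndr_each))
  expect_equal(est$ndr$se, sd(ndr_each) / 2)
})
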