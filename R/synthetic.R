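#' Scenario for synthetic site data
#'
#' True parameter values and replicate-level noise for a complete
#' synthetic field campaign: fertilizer-omission plots, labelled-residue
#' microplots, mesocosm pairs, inlet water sampling and fallow-season
#' residue/soil measurements.  Defaults emulate the Site-1 measurement
#' design — four plot/mesocosm replicates, five water sampling dates and
#' five fallow residue samples — with replicate-level noise calibrated so
#' the standard errors of the simulated means match the magnitudes the
#' study design reports (e.g. plot sd 20 gives SE 10 at n = 4).
#'
#' @param site site label.
#' @param uptake_0n_mean,uptake_0n_sd,n_plots fertilizer-omission plot
#'   uptake, kg N ha-1.
#' @param true_fndr true fraction of plant N derived from labelled
#'   residue.
#' @param resid_uptake_mean,resid_uptake_sd aboveground N uptake in the
#'   residue microplots, kg N ha-1.
#' @param tiller_atom_sd measurement sd of tiller atom % 15N.
#' @param application a [residue_application()].
#' @param meso_minus_mean true uptake in sealed (-groundwater) mesocosms.
#' @param true_ndgw true shallow-groundwater contribution, kg N ha-1.
#' @param meso_sd,n_meso mesocosm replicate noise and count.
#' @param water_conc_mean,water_conc_sd,n_dates inlet total mineral N,
#'   mg N L-1; concentrations are truncated at zero in generation
#'   (negative concentrations are unphysical).
#' @param et an [et_model()].
#' @param residue_n_fall_mean,residue_n_spring_mean,residue_sd,n_residue
#'   fallow residue N sampling, kg N ha-1.
#' @param soil_no3_mean,soil_no3_sd,n_soil late-spring soil NO3-N,
#'   kg N ha-1.
#' @param residue_c_mean,residue_c_sd residue C input at tillage,
#'   kg C ha-1.
#' @param profile a [soil_profile()].
#' @param constants a [budget_constants()].
#' @return object of class `"site_scenario"`.
#' @export
site_scenario <- function(site = "synthetic-1",
                          uptake_0n_mean = 185, uptake_0n_sd = 20,
                          n_plots = 4,
                          true_fndr = 0.0538,
                          resid_uptake_mean = 135, resid_uptake_sd = 10,
                          tiller_atom_sd = 0.1,
                          application = residue_application(),
                          meso_minus_mean = 127, true_ndgw = 61.7,
                          meso_sd = 12.7, n_meso = 4,
                          water_conc_mean = 0.4315, water_conc_sd = 0.43,
                          n_dates = 5,
                          et = et_model(),
                          residue_n_fall_mean = 52,
                          residue_n_spring_mean = 35.1,
                          residue_sd = 2.0, n_residue = 5,
                          soil_no3_mean = 20.3, soil_no3_sd = 1.4,
                          n_soil = 4,
                          residue_c_mean = 1872, residue_c_sd = 306,
                          profile = soil_profile(cn_ratio = 14.4,
                                                 bulk_density = 0.555),
                          constants = budget_constants()) {
  sc <- as.list(environment())
  with(sc, stopifnot(
    n_plots >= 2, n_meso >= 2, n_dates >= 1, n_residue >= 2, n_soil >= 2,
    uptake_0n_mean > 0, true_fndr >= 0, true_fndr <= 1,
    meso_minus_mean > 0, water_conc_mean >= 0,
    residue_n_fall_mean >= residue_n_spring_mean,
    inherits(application, "residue_application"),
    inherits(et, "et_model"), inherits(profile, "soil_profile"),
    inherits(constants, "budget_constants")))
  structure(sc, class = "site_scenario")
}

#' Exact budget implied by a scenario's true parameters
#'
#' Runs the deterministic budget on the scenario's true values (all SEs
#' zero) — the oracle against which estimates from noisy synthetic data
#' are judged.
#'
#' @param scenario a [site_scenario()].
#' @return an `"n_budget"` fit with zero SEs throughout.
#' @export
closed_form_truth <- function(scenario) {
  stopifnot(inherits(scenario, "site_scenario"))
  sc <- scenario
  ndr <- n_from_residue(sc$true_fndr, sc$resid_uptake_mean,
                        sc$application$proportion_labeled)
  ndsw <- surface_water_n(quantity(sc$water_conc_mean, 0, "mg N L-1"),
                          sc$et)
  site <- site_measurements(
    site = sc$site,
    uptake_0n = quantity(sc$uptake_0n_mean, 0, "kg N ha-1"),
    ndr = quantity(ndr, 0, "kg N ha-1"),
    ndsw = quantity(ndsw$value, 0, "kg N ha-1"),
    ndgw = quantity(sc$true_ndgw, 0, "kg N ha-1"),
    residue_n_fall = quantity(sc$residue_n_fall_mean, 0, "kg N ha-1"),
    residue_n_spring = quantity(sc$residue_n_spring_mean, 0, "kg N ha-1"),
    soil_no3_at_flooding = quantity(sc$soil_no3_mean, 0, "kg N ha-1"),
    residue_c_input = quantity(sc$residue_c_mean, 0, "kg C ha-1"),
    profile = sc$profile
  )
  n_budget(site, sc$constants)
}

#' Generate a synthetic site dataset
#'
#' Simulates every raw table the pipeline consumes.  Plot, mesocosm and
#' fallow measurements are Normal at the replicate level; tiller atom %
#' 15N is obtained by forward isotope mixing at the scenario's true fNdr
#' and jittered with instrument noise; water concentrations are Normal
#' truncated at zero.  Regeneration with the same scenario and seed is
#' identical.  The ground truth is stored alongside the data and is never
#' re-derived from the noisy tables.
#'
#' @param scenario a [site_scenario()].
#' @param seed integer seed.
#' @return object of class `"synthetic_site"`: list with data frames
#'   `plots`, `isotope`, `mesocosm`, `water`, `fallow`, the `scenario`,
#'   and `truth` (the [closed_form_truth()] fit).
#' @examples
#' dat <- generate_site_data(site_scenario(), seed = 1)
#' head(dat$plots)
#' @export
generate_site_data <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "site_scenario"))
  sc <- scenario
  set.seed(seed)

  plots <- data.frame(
    site = sc$site, treatment = "0N", replicate = seq_len(sc$n_plots),
    agb_n_uptake_kg_ha = stats::rnorm(sc$n_plots, sc$uptake_0n_mean,
                                      sc$uptake_0n_sd))

  # forward isotope mixing: sample atom % implied by the true fNdr,
  # plus instrument noise per replicate microplot
  app <- sc$application
  atom_true <- app$atom_pct_unlabeled +
    sc$true_fndr * (app$atom_pct_labeled - app$atom_pct_unlabeled)
  isotope <- data.frame(
    site = sc$site, treatment = "15N_residue",
    replicate = seq_len(sc$n_plots), pool = "tiller",
    atom_pct_15n = stats::rnorm(sc$n_plots, atom_true, sc$tiller_atom_sd),
    total_n_kg_ha = stats::rnorm(sc$n_plots, sc$resid_uptake_mean,
                                 sc$resid_uptake_sd))

  mesocosm <- data.frame(
    site = sc$site,
    treatment = rep(c("plus_gw", "minus_gw"), each = sc$n_meso),
    replicate = rep(seq_len(sc$n_meso), 2),
    agb_n_uptake_kg_ha = c(
      stats::rnorm(sc$n_meso, sc$meso_minus_mean + sc$true_ndgw, sc$meso_sd),
      stats::rnorm(sc$n_meso, sc$meso_minus_mean, sc$meso_sd)))

  conc <- pmax(0, stats::rnorm(sc$n_dates, sc$water_conc_mean,
                               sc$water_conc_sd))
  water <- data.frame(
    site = sc$site, date = seq_len(sc$n_dates), location = "inlet",
    nh4_n_mg_l = 0.8 * conc, no3_n_mg_l = 0.2 * conc)

  fallow <- rbind(
    data.frame(site = sc$site, measure = "residue_n_fall",
               replicate = seq_len(sc$n_residue), units = "kg N ha-1",
               value = stats::rnorm(sc$n_residue, sc$residue_n_fall_mean,
                                    sc$residue_sd)),
    data.frame(site = sc$site, measure = "residue_n_spring",
               replicate = seq_len(sc$n_residue), units = "kg N ha-1",
               value = stats::rnorm(sc$n_residue, sc$residue_n_spring_mean,
                                    sc$residue_sd)),
    data.frame(site = sc$site, measure = "soil_no3_at_flooding",
               replicate = seq_len(sc$n_soil), units = "kg N ha-1",
               value = stats::rnorm(sc$n_soil, sc$soil_no3_mean,
                                    sc$soil_no3_sd)),
    data.frame(site = sc$site, measure = "residue_c_input",
               replicate = seq_len(sc$n_residue), units = "kg C ha-1",
               value = stats::rnorm(sc$n_residue, sc$residue_c_mean,
                                    sc$residue_c_sd)))

  structure(list(plots = plots, isotope = isotope, mesocosm = mesocosm,
                 water = water, fallow = fallow, scenario = sc,
                 truth = closed_form_truth(sc), seed = seed),
            class = "synthetic_site")
}

#' Summarise raw measurement tables into budget inputs
#'
#' The estimation path from replicate-level tables (as produced by
#' [generate_site_data()] or read from CSV) to the summary quantities the
#' budget consumes: replicate means and SEs for plot uptake and fallow
#' measurements, per-replicate isotope mixing for the residue term, the
#' mesocosm contrast for groundwater, and the seasonal inlet mean scaled
#' by evapotranspiration for surface water.
#'
#' @param plots,isotope,mesocosm,water,fallow data frames in the schemas
#'   of [generate_site_data()] (see [measurement_schemas]).
#' @param application a [residue_application()].
#' @param et an [et_model()].
#' @param profile a [soil_profile()].
#' @param site site label; defaults to the one in `plots`.
#' @return a [site_measurements()] object.
#' @export
site_from_tables <- function(plots, isotope, mesocosm, water, fallow,
                             application = residue_application(),
                             et = et_model(),
                             profile, site = plots$site[1]) {
  uptake <- replicate_stats(
    plots$agb_n_uptake_kg_ha[plots$treatment == "0N"], "kg N ha-1")

  tiller <- isotope[isotope$pool == "tiller", ]
  ndr <- estimate_ndr(tiller$atom_pct_15n, tiller$total_n_kg_ha,
                      application)$ndr

  plus <- replicate_stats(
    mesocosm$agb_n_uptake_kg_ha[mesocosm$treatment == "plus_gw"],
    "kg N ha-1")
  minus <- replicate_stats(
    mesocosm$agb_n_uptake_kg_ha[mesocosm$treatment == "minus_gw"],
    "kg N ha-1")
  ndgw <- groundwater_n(plus, minus)

  inlet <- water[water$location == "inlet", ]
  ndsw <- surface_water_n(
    seasonal_mean_inlet_n(inlet$nh4_n_mg_l, inlet$no3_n_mg_l), et)

  fq <- function(measure, units) {
    v <- fallow$value[fallow$measure == measure]
    if (!length(v)) stop("fallow table has no rows for ", measure,
                         call. = FALSE)
    replicate_stats(v, units)
  }

  site_measurements(
    site = site, uptake_0n = uptake, ndr = ndr, ndsw = ndsw, ndgw = ndgw,
    residue_n_fall = fq("residue_n_fall", "kg N ha-1"),
    residue_n_spring = fq("residue_n_spring", "kg N ha-1"),
    soil_no3_at_flooding = fq("soil_no3_at_flooding", "kg N ha-1"),
    residue_c_input = fq("residue_c_input", "kg C ha-1"),
    profile = profile)
}

#' Analytic standard errors implied by a scenario's noise model
#'
#' Closed-form (delta-method) standard errors of the pipeline estimators
#' under the scenario's known replicate-level noise: the sampling SE each
#' estimate would carry on average.  Used as the reference scale in
#' parameter-recovery studies — bias is judged against it and
#' known-variance 95% intervals built from it attain nominal coverage,
#' which intervals built from per-dataset SEs estimated at n = 4 do not.
#' The zero-truncation of water concentrations is ignored here (its
#' effect on the SE is second-order at the default noise level).
#'
#' @param scenario a [site_scenario()].
#' @return named numeric vector of SEs (kg N ha-1) for `uptake_0n`,
#'   `ndr`, `ndsw`, `ndgw`, `surface_peat_n` and `peat_total_n` (the
#'   latter single-counted, matching `se_mode = "consistent"`).
#' @export
scenario_analytic_se <- function(scenario) {
  stopifnot(inherits(scenario, "site_scenario"))
  sc <- scenario
  app <- sc$application
  p <- app$proportion_labeled
  se_uptake <- sc$uptake_0n_sd / sqrt(sc$n_plots)
  dfda <- 1 / (app$atom_pct_labeled - app$atom_pct_unlabeled)
  sd_ndr_rep <- sqrt((sc$resid_uptake_mean * p * sc$tiller_atom_sd * dfda)^2 +
                       (sc$true_fndr * p * sc$resid_uptake_sd)^2)
  se_ndr <- sd_ndr_rep / sqrt(sc$n_plots)
  se_ndsw <- (sc$water_conc_sd / sqrt(sc$n_dates)) *
    sc$et$cumulative_et_m * .L_PER_HA_M * sc$et$crop_coefficient * 1e-6
  se_ndgw <- sc$meso_sd * sqrt(2 / sc$n_meso)
  c(uptake_0n = se_uptake, ndr = se_ndr, ndsw = se_ndsw, ndgw = se_ndgw,
    surface_peat_n = sqrt(se_uptake^2 + se_ndr^2 + se_ndsw^2 + se_ndgw^2),
    peat_total_n = sqrt(se_uptake^2 + se_ndr^2 + se_ndsw^2))
}
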