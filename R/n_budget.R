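#' Fit the annual peatland nitrogen budget
#'
#' Assembles the full annual ledger for one site from summary-level
#' measurements: partitions fertilizer-omission plant N uptake among
#' residue, surface water, shallow groundwater, deposition and fixation;
#' attributes the residual (plus the groundwater term) to peat
#' mineralization; inflates it by the N uptake efficiency; adds the
#' winter-fallow mineralization; and converts the annual N flux to gross
#' and net soil C loss and a subsidence rate via the soil profile.
#' Standard errors are propagated analytically through every line.
#'
#' @param site a [site_measurements()] (or [site_from_tables()]) object.
#' @param constants a [budget_constants()].
#' @param se_mode `"paper"` (default) reports the peat-total SE as the
#'   root-sum-of-squares of the surface-peat SE and the groundwater SE —
#'   the published convention, in which the groundwater SE is counted in
#'   both terms; `"consistent"` propagates the peat total directly from
#'   its independent components (the groundwater term cancels
#'   algebraically), giving a smaller, single-counted SE.  Values are
#'   identical in both modes.
#' @param nue_grid NUE values for the sensitivity scan stored in the fit
#'   (fractions in (0, 1]).
#' @return an object of class `"n_budget"`: a list with the input `site`
#'   and `constants`, the named `quantities` of every ledger line, a tidy
#'   `ledger` data frame (item, value, se, units, season), and the NUE
#'   `sensitivity` table.  Supports `print()`, `summary()`, `coef()`,
#'   `confint()`, `predict()`, `plot()` and `simulate()`.
#' @examples
#' fit <- n_budget(twitchell_site(1))
#' fit
#' coef(fit)["net_c_loss"]
#' @export
n_budget <- function(site, constants = budget_constants(),
                     se_mode = c("paper", "consistent"),
                     nue_grid = seq(0.30, 0.90, by = 0.05)) {
  stopifnot(inherits(site, "site_measurements"),
            inherits(constants, "budget_constants"))
  se_mode <- match.arg(se_mode)
  if (any(nue_grid <= 0) || any(nue_grid > 1))
    stop("nue_grid values must lie in (0, 1]", call. = FALSE)

  qn <- function(v) quantity(v, 0, "kg N ha-1")
  sp <- surface_peat_n(site$uptake_0n, site$ndr, site$ndsw, site$ndgw,
                       constants)
  peat_total <- switch(se_mode,
    paper = peat_total_n(sp, site$ndgw),
    consistent = q_combine(site$uptake_0n, site$ndr, site$ndsw,
                           qn(constants$n_deposition),
                           qn(constants$n_fixation),
                           signs = c(1, -1, -1, -1, -1)))
  nmin_growing <- growing_season_mineralization(peat_total, constants$nue)

  residue_min <- residue_n_mineralized_fallow(site$residue_n_fall,
                                              site$residue_n_spring)
  nmin_fallow <- fallow_peat_mineralization(site$soil_no3_at_flooding,
                                            residue_min)
  nmin_total <- annual_mineralization(nmin_growing, nmin_fallow)

  prof <- site$profile
  c_min <- c_mineralized(nmin_total, prof$cn_ratio)
  net_c <- net_c_loss(c_min, site$residue_c_input)
  subsidence <- subsidence_rate(net_c, prof)

  quantities <- list(
    uptake_0n = site$uptake_0n, ndr = site$ndr, ndsw = site$ndsw,
    ndgw = site$ndgw,
    n_deposition = qn(constants$n_deposition),
    n_fixation = qn(constants$n_fixation),
    surface_peat_n = sp, peat_total_n = peat_total,
    nmin_growing = nmin_growing,
    residue_min_fallow = residue_min,
    soil_no3_at_flooding = site$soil_no3_at_flooding,
    nmin_fallow = nmin_fallow, nmin_total = nmin_total,
    c_mineralized = c_min, residue_c_input = site$residue_c_input,
    net_c_loss = net_c, subsidence = subsidence
  )
  season <- c(rep("growing", 9), rep("fallow", 3), rep("annual", 5))
  ledger <- data.frame(
    item = names(quantities),
    value = vapply(quantities, function(q) q$value, numeric(1)),
    se = vapply(quantities, function(q) q$se, numeric(1)),
    units = vapply(quantities, function(q) q$units, character(1)),
    season = season,
    row.names = NULL
  )

  fit <- structure(list(site = site, constants = constants,
                        se_mode = se_mode, quantities = quantities,
                        ledger = ledger),
                   class = "n_budget")
  fit$sensitivity <- nue_sensitivity(fit, nue_grid)
  fit
}

# deterministic budget chain on plain numerics; vectorised over draws.
# `v` is a list/data.frame with elements uptake_0n, ndr, ndsw, ndgw,
# residue_n_fall, residue_n_spring, soil_no3, residue_c, cn_ratio.
.budget_chain <- function(v, consts, profile, nue = consts$nue) {
  sp <- v$uptake_0n - (v$ndr + v$ndsw + v$ndgw +
                         consts$n_deposition + consts$n_fixation)
  peat_total <- sp + v$ndgw
  nmin_growing <- peat_total / nue
  residue_min <- v$residue_n_fall - v$residue_n_spring
  nmin_fallow <- v$soil_no3 - residue_min
  nmin_total <- nmin_growing + nmin_fallow
  c_min <- nmin_total * v$cn_ratio
  net_c <- c_min - v$residue_c
  subsidence <- (net_c * .G_CM2_PER_KG_HA / profile$som_pct_c /
                   profile$bulk_density) / profile$f_min
  list(surface_peat_n = sp, peat_total_n = peat_total,
       nmin_growing = nmin_growing, residue_min_fallow = residue_min,
       nmin_fallow = nmin_fallow, nmin_total = nmin_total,
       c_mineralized = c_min, net_c_loss = net_c, subsidence = subsidence)
}

.site_values <- function(site) {
  list(uptake_0n = site$uptake_0n$value, ndr = site$ndr$value,
       ndsw = site$ndsw$value, ndgw = site$ndgw$value,
       residue_n_fall = site$residue_n_fall$value,
       residue_n_spring = site$residue_n_spring$value,
       soil_no3 = site$soil_no3_at_flooding$value,
       residue_c = site$residue_c_input$value,
       cn_ratio = site$profile$cn_ratio)
}

#' Sensitivity of the C-loss estimate to the NUE assumption
#'
#' Re-evaluates the full budget over a grid of N uptake efficiencies.
#' Lower NUE implies more gross mineralization behind the same plant
#' uptake, hence a larger C loss; the curve is convex decreasing in NUE
#' (successive increments buy progressively smaller reductions).
#'
#' @param fit an `"n_budget"` fit (or a [site_measurements()] object,
#'   in which case `constants` supplies the other assumptions).
#' @param nue_grid NUE values, fractions in (0, 1].
#' @param constants used only when `fit` is a `site_measurements`.
#' @return data frame with one row per NUE: `nmin_total`, `net_c_loss`
#'   and `subsidence` values and SEs.
#' @examples
#' nue_sensitivity(twitchell_site(1), nue_grid = c(0.5, 0.7))
#' @export
nue_sensitivity <- function(fit, nue_grid = seq(0.30, 0.90, by = 0.05),
                            constants = budget_constants()) {
  if (inherits(fit, "site_measurements"))
    fit <- n_budget(fit, constants, nue_grid = range(nue_grid))
  stopifnot(inherits(fit, "n_budget"))
  if (any(nue_grid <= 0) || any(nue_grid > 1))
    stop("nue values must lie in (0, 1]", call. = FALSE)
  q <- fit$quantities
  prof <- fit$site$profile
  rows <- lapply(nue_grid, function(nu) {
    nmg <- growing_season_mineralization(q$peat_total_n, nu)
    nmt <- annual_mineralization(nmg, q$nmin_fallow)
    net <- net_c_loss(c_mineralized(nmt, prof$cn_ratio),
                      fit$site$residue_c_input)
    sub <- subsidence_rate(net, prof)
    data.frame(nue = nu,
               nmin_total = nmt$value, nmin_total_se = nmt$se,
               net_c_loss = net$value, net_c_loss_se = net$se,
               subsidence = sub$value, subsidence_se = sub$se)
  })
  do.call(rbind, rows)
}
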