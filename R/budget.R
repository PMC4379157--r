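#' Fixed constants of the growing-season N budget
#'
#' Literature-based terms treated as exact (SE = 0) in the analytic error
#' propagation: atmospheric N deposition, biological N2 fixation by
#' free-living cyanobacteria, and the N uptake efficiency (NUE) used to
#' inflate plant-captured peat N to gross mineralization.
#'
#' @param n_deposition annual atmospheric N deposition, kg N ha-1
#'   (default 6, a regional wet+dry estimate).
#' @param n_fixation biological N2 fixation, kg N ha-1 (default 25, the
#'   middle of the 20-30 range commonly reported for paddies).
#' @param nue N uptake efficiency, fraction in (0, 1] (default 0.50, the
#'   commonly reported fertilizer-N value for rice).
#' @return object of class `"budget_constants"`.
#' @export
budget_constants <- function(n_deposition = 6, n_fixation = 25, nue = 0.50) {
  if (nue <= 0 || nue > 1) stop("nue must lie in (0, 1]", call. = FALSE)
  if (n_deposition < 0 || n_fixation < 0)
    stop("deposition and fixation must be >= 0", call. = FALSE)
  structure(list(n_deposition = n_deposition, n_fixation = n_fixation,
                 nue = nue),
            class = "budget_constants")
}

#' Soil profile for C-loss and subsidence conversion
#'
#' @param cn_ratio soil C:N mass ratio (kg C per kg N) to 30 cm.
#' @param som_pct_c carbon fraction of soil organic matter, g C per g SOM
#'   (default 0.58).
#' @param bulk_density bulk density of the upper profile, g cm-3.
#' @param f_min fraction of land-surface subsidence attributable to SOM
#'   oxidation rather than compaction, in (0, 1] (default 0.67).
#' @return object of class `"soil_profile"`.
#' @export
soil_profile <- function(cn_ratio, som_pct_c = 0.58, bulk_density,
                         f_min = 0.67) {
  if (cn_ratio <= 0 || som_pct_c <= 0 || bulk_density <= 0)
    stop("soil profile values must be positive", call. = FALSE)
  if (f_min <= 0 || f_min > 1)
    stop("f_min must lie in (0, 1]", call. = FALSE)
  structure(list(cn_ratio = cn_ratio, som_pct_c = som_pct_c,
                 bulk_density = bulk_density, f_min = f_min),
            class = "soil_profile")
}

#' Summary-level measurements for one site
#'
#' Gathers the per-site measured quantities the annual budget consumes,
#' each as a mean +/- SE [quantity()].  Build it directly from published
#' or summarised values, or derive it from raw replicate tables with
#' [site_from_tables()].
#'
#' @param site site label.
#' @param uptake_0n total aboveground N uptake in fertilizer-omission
#'   plots, kg N ha-1.
#' @param ndr N derived from the previous crop's residue (tracer
#'   estimate), kg N ha-1.
#' @param ndsw N derived from surface irrigation water, kg N ha-1.
#' @param ndgw N derived from shallow groundwater (mesocosm contrast),
#'   kg N ha-1.
#' @param residue_n_fall,residue_n_spring total residue N before and
#'   after winter-fallow decomposition, kg N ha-1.
#' @param soil_no3_at_flooding soil NO3-N accumulated by late spring,
#'   assumed denitrified on flooding, kg N ha-1.
#' @param residue_c_input C returned to the soil in residue at tillage,
#'   kg C ha-1.
#' @param profile a [soil_profile()].
#' @return object of class `"site_measurements"`.
#' @export
site_measurements <- function(site, uptake_0n, ndr, ndsw, ndgw,
                              residue_n_fall, residue_n_spring,
                              soil_no3_at_flooding, residue_c_input,
                              profile) {
  qn <- function(x) as_quantity(x, "kg N ha-1")
  qc <- function(x) as_quantity(x, "kg C ha-1")
  stopifnot(inherits(profile, "soil_profile"))
  structure(list(
    site = site,
    uptake_0n = qn(uptake_0n), ndr = qn(ndr), ndsw = qn(ndsw),
    ndgw = qn(ndgw),
    residue_n_fall = qn(residue_n_fall),
    residue_n_spring = qn(residue_n_spring),
    soil_no3_at_flooding = qn(soil_no3_at_flooding),
    residue_c_input = qc(residue_c_input),
    profile = profile
  ), class = "site_measurements")
}

# ---- ledger operations (growing season) -----------------------------------

#' Surface-peat N uptake
#'
#' The residual of the growing-season ledger: total uptake in
#' fertilizer-omission plots minus every other known source (residue,
#' surface water, shallow groundwater, deposition, fixation).  Deposition
#' and fixation enter as exact constants; the SE combines the measured
#' terms by root sum of squares.
#'
#' @param uptake_0n,ndr,ndsw,ndgw `quantity` objects, kg N ha-1.
#' @param consts a [budget_constants()].
#' @return a `quantity`; negative values (implying a soil N sink) are
#'   returned with a warning.
#' @export
surface_peat_n <- function(uptake_0n, ndr, ndsw, ndgw,
                           consts = budget_constants()) {
  stopifnot(inherits(consts, "budget_constants"))
  out <- q_combine(uptake_0n, ndr, ndsw, ndgw,
                   quantity(consts$n_deposition, 0, "kg N ha-1"),
                   quantity(consts$n_fixation, 0, "kg N ha-1"),
                   signs = c(1, -1, -1, -1, -1, -1))
  if (out$value < -1e-9) # tolerate float residue of an exactly-zero balance
    warning("surface-peat N is negative: known sources exceed uptake",
            call. = FALSE)
  out
}

#' Total peat-derived N uptake
#'
#' Adds the shallow-groundwater term back onto the surface-peat residual:
#' groundwater N in this system is itself attributed to subsurface peat
#' mineralization.  The reported SE combines the surface-peat SE (which
#' already contains the groundwater SE) with the groundwater SE again,
#' mirroring the published propagation; see [n_budget()]'s `se_mode` for a
#' single-counted alternative.
#'
#' @param surface_peat,ndgw `quantity` objects, kg N ha-1.
#' @return a `quantity`, kg N ha-1.
#' @export
peat_total_n <- function(surface_peat, ndgw) {
  surface_peat + ndgw
}

#' Growing-season SOM-N mineralization
#'
#' Peat-derived plant N divided by the N uptake efficiency: plants capture
#' only a fraction `nue` of mineralized N, so gross mineralization is the
#' captured amount inflated by 1/nue (SE scaled by the same exact factor).
#'
#' @param peat_total `quantity`, total peat-derived N uptake, kg N ha-1.
#' @param nue N uptake efficiency, fraction in (0, 1].
#' @return a `quantity`, kg N ha-1.
#' @export
growing_season_mineralization <- function(peat_total, nue) {
  if (nue <= 0 || nue > 1) stop("nue must lie in (0, 1]", call. = FALSE)
  q_scale(peat_total, 1 / nue)
}

# ---- ledger operations (winter fallow) ------------------------------------

#' N mineralized from crop residue over the winter fallow
#'
#' Difference between residue N at fall harvest and residue N remaining
#' at spring sampling.
#'
#' @param residue_n_fall,residue_n_spring `quantity` objects, kg N ha-1.
#' @return a `quantity`, kg N ha-1.
#' @export
residue_n_mineralized_fallow <- function(residue_n_fall, residue_n_spring) {
  residue_n_fall - residue_n_spring
}

#' Fallow-season peat N mineralization
#'
#' Soil NO3-N accumulated by late spring indexes total fallow
#' mineralization (it is assumed denitrified on flooding); subtracting the
#' residue-derived share leaves the peat contribution.
#'
#' @param soil_no3_at_flooding,residue_min `quantity` objects, kg N ha-1.
#' @return a `quantity`; negative values returned with a warning.
#' @export
fallow_peat_mineralization <- function(soil_no3_at_flooding, residue_min) {
  out <- soil_no3_at_flooding - residue_min
  if (out$value < 0)
    warning("fallow peat mineralization is negative: residue mineralization ",
            "exceeds accumulated soil NO3-N", call. = FALSE)
  out
}

#' Annual SOM-N mineralization
#'
#' @param growing,fallow `quantity` objects, kg N ha-1.
#' @return their sum, SE by root sum of squares.
#' @export
annual_mineralization <- function(growing, fallow) {
  growing + fallow
}
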