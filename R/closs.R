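#' Soil C mineralized from annual N mineralization
#'
#' Converts annual SOM-N mineralization to C via the soil C:N mass ratio,
#' treated as an exact stoichiometric factor in the analytic path (attach
#' an SE through the Monte-Carlo path if C:N uncertainty matters).
#'
#' @param nmin_total annual SOM-N mineralization, `quantity`, kg N ha-1.
#' @param cn_ratio soil C:N ratio, kg C per kg N (> 0).
#' @return a `quantity`, kg C ha-1.
#' @export
c_mineralized <- function(nmin_total, cn_ratio) {
  if (cn_ratio <= 0) stop("C:N ratio must be positive", call. = FALSE)
  q_scale(nmin_total, cn_ratio, units = "kg C ha-1")
}

#' Net annual soil C loss
#'
#' Gross C mineralized less the C credit returned in crop residue at
#' tillage.  The residue input enters as a positive credit and is
#' subtracted — the published tables and text net it out of the loss.
#'
#' @param c_min gross C mineralized, `quantity`, kg C ha-1.
#' @param residue_c_input residue C input, `quantity`, kg C ha-1.
#' @return a `quantity`, kg C ha-1.
#' @export
net_c_loss <- function(c_min, residue_c_input) {
  c_min - residue_c_input
}

# kg ha-1 -> g cm-2: 1 kg/ha = 1000 g / 1e8 cm2; exact
.G_CM2_PER_KG_HA <- 1e-5

#' Annual subsidence implied by net soil C loss
#'
#' Net C loss is converted to a depth of oxidised organic soil per year:
#' \deqn{S = \frac{(C_{net}/f_C)/\rho_b}{f_{min}}}
#' where \eqn{C_{net}} is in g C cm-2 yr-1 (1 kg ha-1 = 1e-5 g cm-2,
#' exact), \eqn{f_C} the carbon fraction of SOM, \eqn{\rho_b} the bulk
#' density, and \eqn{f_{min}} the fraction of observed subsidence
#' attributable to SOM oxidation (the remainder being compaction and
#' consolidation).
#'
#' @param net_c net soil C loss, `quantity`, kg C ha-1 yr-1.
#' @param profile a [soil_profile()].
#' @return a `quantity`, cm yr-1.
#' @examples
#' subsidence_rate(quantity(2473, 0, "kg C ha-1"),
#'                 soil_profile(cn_ratio = 14.4, bulk_density = 0.555))
#' @export
subsidence_rate <- function(net_c, profile) {
  stopifnot(inherits(profile, "soil_profile"))
  factor <- .G_CM2_PER_KG_HA / profile$som_pct_c / profile$bulk_density /
    profile$f_min
  q_scale(as_quantity(net_c, "kg C ha-1"), factor, units = "cm yr-1")
}
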