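#' Twitchell Island 2012 published site inputs
#'
#' Summary-level measurements (mean +/- SE) for the two Twitchell Island
#' rice fields, as published: fertilizer-omission uptake, the three
#' measured source terms, the fallow-season lines and the soil profile.
#' These are the inputs from which every published ledger value is
#' reproducible, and the packaged fixture the acceptance checks run on.
#'
#' Site 1: uptake 185.0 +/- 10.0, residue 1.9 +/- 0.2, surface water
#' 2.9 +/- 1.3, groundwater 61.7 +/- 9.0 kg N ha-1; residue-N mineralized
#' over the fallow 16.9 +/- 1.3 against soil NO3-N 20.3 +/- 0.7; C:N 14.4,
#' bulk density 0.555 g cm-3, residue C input 1872 +/- 137 kg C ha-1.
#' Site 2: uptake 167.0 +/- 7.7, residue 3.8 +/- 1.1, surface water
#' 3.0 +/- 1.3, groundwater 39.6 +/- 6.7; fallow residue 21.0 +/- 2.1
#' against soil NO3-N 42.1 +/- 0.5; C:N 14.8, bulk density 0.782,
#' residue C 1894 +/- 189.
#'
#' The fallow residue lines are published only as the fall-minus-spring
#' difference; the fixture anchors the spring value at the residue-mixture
#' N content (47 kg N ha-1) and carries the full SE of the difference on
#' the fall line, which leaves every derived ledger line and its SE
#' unchanged.
#'
#' @param site 1 or 2.
#' @return a [site_measurements()] object.
#' @examples
#' n_budget(twitchell_site(1))
#' @export
twitchell_site <- function(site = 1) {
  site <- match.arg(as.character(site), c("1", "2"))
  qn <- function(v, se = 0) quantity(v, se, "kg N ha-1")
  if (site == "1") {
    site_measurements(
      site = "Twitchell-1",
      uptake_0n = qn(185.0, 10.0),
      ndr = qn(1.9, 0.2),
      ndsw = qn(2.9, 1.3),
      ndgw = qn(61.7, 9.0),
      residue_n_fall = qn(47 + 16.9, 1.3),
      residue_n_spring = qn(47, 0),
      soil_no3_at_flooding = qn(20.3, 0.7),
      residue_c_input = quantity(1872, 137, "kg C ha-1"),
      profile = soil_profile(cn_ratio = 14.4, bulk_density = 0.555)
    )
  } else {
    site_measurements(
      site = "Twitchell-2",
      uptake_0n = qn(167.0, 7.7),
      ndr = qn(3.8, 1.1),
      ndsw = qn(3.0, 1.3),
      ndgw = qn(39.6, 6.7),
      residue_n_fall = qn(47 + 21.0, 2.1),
      residue_n_spring = qn(47, 0),
      soil_no3_at_flooding = qn(42.1, 0.5),
      residue_c_input = quantity(1894, 189, "kg C ha-1"),
      profile = soil_profile(cn_ratio = 14.8, bulk_density = 0.782)
    )
  }
}
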