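# shorthand constructors used across test files
qn <- function(v, se = 0) quantity(v, se, "kg N ha-1")
qc <- function(v, se = 0) quantity(v, se, "kg C ha-1")

# a scenario with all replicate-level noise switched off: the pipeline
# estimate must then equal the closed-form truth exactly
noise_free_scenario <- function(...) {
  site_scenario(uptake_0n_sd = 0, resid_uptake_sd = 0, tiller_atom_sd = 0,
                meso_sd = 0, water_conc_sd = 0, residue_sd = 0,
                soil_no3_sd = 0, residue_c_sd = 0, ...)
}

fit_pipeline <- function(dat, se_mode = "consistent") {
  site <- site_from_tables(dat$plots, dat$isotope, dat$mesocosm,
                           dat$water, dat$fallow,
                           profile = dat$scenario$profile)
  n_budget(site, dat$scenario$constants, se_mode = se_mode)
}
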