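# Independent flat-arithmetic transcription of every process equation,
# written as one expression per flux (no shared helpers with the package
# code path). Conversion conventions: gram-denominated activity
# coefficients x gas carbon ratio x 1e-6 g->t; stock-proportional
# expressions inherit the stock's tC scale, gas ratio only.
oracle_fluxes <- function(cfg, pools = cfg$init) {
  p <- cfg$params
  f <- cfg$forcings
  pr <- cfg$profile
  sd <- pr$sd
  co2g <- 12 / 44 * 1e-6
  ch4g <- 12 / 16 * 1e-6
  ad <- f$nv * (1 * sd[1] + 2 * sd[2] + 3 * sd[3] + 4 * sd[4] + 5 * sd[5])
  ni_days <- 365 * f$ni
  lin <- max(0, 20 - f$temp)
  c(
    shopping = ad * p$ce_shopping * co2g,
    wa = ad * p$ce_wa * co2g,
    visiting = ad * p$ce_visiting * co2g,
    fishing = ad * p$ce_fishing * co2g,
    hotel = f$nv * (0 * sd[1] + 1 * sd[2] + 2 * sd[3] + 3 * sd[4] +
                      4 * sd[5]) * pr$hotel_r * p$ce_hotel * co2g,
    ph = f$nv * (0 * sd[1] + 1 * sd[2] + 2 * sd[3] + 3 * sd[4] +
                   4 * sd[5]) * p$ce_ph * pr$ph_r * co2g,
    rm = ad * pr$moto_r * pr$pd_moto * p$ce_moto * co2g,
    car = ad * pr$pd_pc * pr$pc_r * p$ce_pc * co2g,
    ssb = ad * pr$pd_ssd * pr$ssd_r * p$ce_ssb * co2g,
    pc = p$car_r * f$ni * p$ce_car * co2g,
    desalination = (ad + ni_days) * p$per_wc * p$ce_desalination * co2g,
    ferry = f$nv * p$dis_ferry * p$ce_ferry * co2g,
    waste = (ad + ni_days) * p$per_waste * p$pch4_waste * ch4g,
    aquaculture = p$aqu_frac * f$inshore_area * p$ce_aqu * co2g,
    sg = p$aqu_frac * f$inshore_area * 1e6 * p$growth_r * p$shell_c_r /
      0.27 * 1e-6,
    w_pho = pools[["wetland_c"]] * p$w_growth_r *
      (p$tidal_frac * f$land_area) * 1.05^(20 - f$temp) *
      (f$rade / (f$rade + 6) * 690) * 12 / 44,
    f_pho = pools[["forest_c"]] * p$f_growth_r *
      (p$forest_frac * f$land_area) * 1.05^(20 - f$temp) *
      (f$rade / (f$rade + 6) * 690) * 12 / 44,
    w_res = p$w_re_r * (p$tidal_frac * f$land_area) * lin *
      pools[["wetland_c"]] * 12 / 44,
    f_res = pools[["forest_c"]] * (p$forest_frac * f$land_area) *
      p$f_re_r * lin * 12 / 44,
    adsorption = pools[["soil_c"]] * p$ads_r * lin * 12 / 44,
    decomposition = pools[["forest_c"]] * p$dec_r * lin,
    litter_to_sea = 0.5 * pools[["wetland_c"]],
    wet_ch4_release = 0.1 * pools[["wetland_c"]] * lin * 12 / 16,
    unused_ch4 = pools[["waste_ch4"]] * p$ch4_use_r
  )
}

# flux tibble -> named vector, restricted to the oracle's flux set
flux_vec <- function(fl) {
  stats::setNames(fl$value, fl$flux)
}

expect_fluxes_match_oracle <- function(cfg, pools = cfg$init,
                                       tol = 1e-9) {
  got <- flux_vec(compute_fluxes(cfg, pools))
  want <- oracle_fluxes(cfg, pools)
  expect_equal(got[names(want)], want, tolerance = tol)
}
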