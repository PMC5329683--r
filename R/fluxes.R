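#' Visitor activity-days and lodging-nights
#'
#' A visitor staying k days generates k activity-days and k - 1 lodging
#' nights, so the annual totals are `nv * sum(k * sd_k)` and
#' `nv * sum((k - 1) * sd_k)` over the stay-duration distribution.
#'
#' @param profile a [tourist_profile()].
#' @param nv visitors per year (>= 0).
#' @return person-days (resp. person-nights) per year.
#' @export
#' @examples
#' visitor_activity_days(tourist_profile(), 1e6) # 2.9 million person-days
#' lodging_nights(tourist_profile(), 1e6)        # 1.9 million person-nights
visitor_activity_days <- function(profile, nv) {
  validate_profile(profile)
  stopifnot_scalar(nv, "nv", min = 0)
  nv * sum(seq_len(5) * profile$sd)
}

#' @rdname visitor_activity_days
#' @export
lodging_nights <- function(profile, nv) {
  validate_profile(profile)
  stopifnot_scalar(nv, "nv", min = 0)
  nv * sum((seq_len(5) - 1) * profile$sd)
}

# Temperature response factors. The linear (20 - temp) factor drives
# respiration, decomposition, soil adsorption and wetland methane release;
# the exponential 1.05^(20 - temp) factor scales photosynthesis. Above the
# 20 degC reference the linear factor is clamped at zero (with a warning),
# or raises in strict mode.
temp_factors <- function(temp, temp_mode = "clamp") {
  k <- island_constants()
  lin <- k$ref_temp - temp
  if (lin < 0) {
    if (identical(temp_mode, "strict")) {
      rlang::abort(sprintf(
        "temp = %g degC is at/above the %g degC reference; linear factor undefined in strict mode",
        temp, k$ref_temp), class = "islandcarbon_domain_error")
    }
    rlang::warn(sprintf(
      "temp = %g degC exceeds the %g degC reference; linear temperature factor clamped to 0",
      temp, k$ref_temp))
    lin <- 0
  } else if (identical(temp_mode, "strict") && lin == 0) {
    rlang::abort(sprintf(
      "temp = %g degC is at/above the %g degC reference; linear factor undefined in strict mode",
      temp, k$ref_temp), class = "islandcarbon_domain_error")
  }
  list(lin = lin, q = k$q_base^(k$ref_temp - temp))
}

flux_tbl <- function(...) {
  v <- c(...)
  roles <- flux_roles()
  tibble::tibble(flux = names(v), role = unname(roles[names(v)]),
                 value = unname(v))
}

#' Tourism activity and accommodation fluxes
#'
#' The nine tourist-driven emissions: shopping, water activity, sightseeing
#' and offshore angling scale with activity-days; hotel and private-home
#' accommodation scale with lodging-nights and the lodging split; rental
#' motorcycle, tourist private car and small shuttle bus scale with
#' activity-days, modal share, daily distance and a per-km coefficient.
#' All coefficients are g CO2 per unit; values are returned in tC yr-1.
#'
#' @param profile a [tourist_profile()].
#' @param forcings an [island_forcings()].
#' @param params an [island_parameters()].
#' @return a tibble with columns `flux`, `role`, `value` (tC yr-1).
#' @export
#' @examples
#' tourism_fluxes(tourist_profile(), island_forcings(), island_parameters())
tourism_fluxes <- function(profile, forcings, params) {
  ad <- visitor_activity_days(profile, forcings$nv)
  ln <- lodging_nights(profile, forcings$nv)
  p <- params
  flux_tbl(
    shopping = g_gas_to_tc(ad * p$ce_shopping, "co2"),
    wa       = g_gas_to_tc(ad * p$ce_wa, "co2"),
    visiting = g_gas_to_tc(ad * p$ce_visiting, "co2"),
    fishing  = g_gas_to_tc(ad * p$ce_fishing, "co2"),
    hotel    = g_gas_to_tc(ln * profile$hotel_r * p$ce_hotel, "co2"),
    ph       = g_gas_to_tc(ln * profile$ph_r * p$ce_ph, "co2"),
    rm       = g_gas_to_tc(ad * profile$moto_r * profile$pd_moto *
                             p$ce_moto, "co2"),
    car      = g_gas_to_tc(ad * profile$pd_pc * profile$pc_r * p$ce_pc,
                           "co2"),
    ssb      = g_gas_to_tc(ad * profile$pd_ssd * profile$ssd_r * p$ce_ssb,
                           "co2")
  )
}

#' Infrastructure and waste fluxes
#'
#' Resident private cars, seawater desalination, the ferry link to the
#' mainland, and landfill methane generation. Desalination and waste are
#' driven by total person-days (visitor activity-days plus 365 days per
#' resident); the ferry scales with visitors and the per-visitor ferry
#' distance. `waste` is methane and is returned as CH4 carbon (12/16).
#'
#' @inheritParams tourism_fluxes
#' @return a tibble with columns `flux`, `role`, `value` (tC yr-1).
#' @export
infrastructure_fluxes <- function(profile, forcings, params) {
  k <- island_constants()
  ad <- visitor_activity_days(profile, forcings$nv)
  person_days <- ad + k$days_per_year * forcings$ni
  p <- params
  flux_tbl(
    pc = g_gas_to_tc(p$car_r * forcings$ni * p$ce_car, "co2"),
    desalination = g_gas_to_tc(person_days * p$per_wc * p$ce_desalination,
                               "co2"),
    ferry = g_gas_to_tc(forcings$nv * p$dis_ferry * p$ce_ferry, "co2"),
    waste = g_gas_to_tc(person_days * p$per_waste * p$pch4_waste, "ch4")
  )
}

#' Forest, wetland and soil ecosystem fluxes
#'
#' Stock-proportional ecosystem processes. Photosynthesis combines the
#' exponential temperature factor `1.05^(20 - temp)` with the
#' Michaelis-Menten light factor `rade / (rade + 6) * 690`; respiration,
#' litter decomposition and soil adsorption use the linear `(20 - temp)`
#' factor; wetland litter export is a fixed 0.5 fraction of wetland carbon
#' and wetland methane release a 0.1 fraction times the linear factor.
#' CO2-denominated processes are converted to carbon by 12/44 and the
#' methane release by 12/16; the area term enters as its km2 value, as the
#' process equations are written.
#'
#' @param pools a [carbon_pools()] vector.
#' @inheritParams tourism_fluxes
#' @param temp_mode `"clamp"` or `"strict"`, see [island_config()].
#' @return a tibble with columns `flux`, `role`, `value` (tC yr-1).
#' @export
ecosystem_fluxes <- function(pools, forcings, params, temp_mode = "clamp") {
  k <- island_constants()
  tf <- temp_factors(forcings$temp, temp_mode)
  light <- forcings$rade / (forcings$rade + k$light_half_sat) * k$light_scale
  forest_area <- params$forest_frac * forcings$land_area
  tidal_area <- params$tidal_frac * forcings$land_area
  w <- pools[["wetland_c"]]
  f <- pools[["forest_c"]]
  s <- pools[["soil_c"]]
  flux_tbl(
    w_pho = k$co2_to_c * w * params$w_growth_r * tidal_area * tf$q * light,
    f_pho = k$co2_to_c * f * params$f_growth_r * forest_area * tf$q * light,
    w_res = k$co2_to_c * params$w_re_r * tidal_area * tf$lin * w,
    f_res = k$co2_to_c * f * forest_area * params$f_re_r * tf$lin,
    adsorption = k$co2_to_c * s * params$ads_r * tf$lin,
    decomposition = f * params$dec_r * tf$lin,
    litter_to_sea = k$litter_to_sea_frac * w,
    wet_ch4_release = k$ch4_to_c * k$wetland_ch4_frac * w * tf$lin
  )
}

#' Mussel aquaculture fluxes
#'
#' The culture-area emission of aquaculture operations and the
#' shell-carbonate sink. Shellfish fix dissolved bicarbonate into calcium
#' carbonate shell (Ca2+ + 2HCO3- -> CaCO3 + CO2 + H2O); the sink is
#' area x mussel growth rate x shell carbon fraction / 0.27, with the
#' growth rate per m2 so the area enters in m2.
#'
#' @inheritParams tourism_fluxes
#' @return a tibble with columns `flux`, `role`, `value` (tC yr-1).
#' @export
aquaculture_fluxes <- function(forcings, params) {
  k <- island_constants()
  aqu_area_km2 <- params$aqu_frac * forcings$inshore_area
  flux_tbl(
    aquaculture = g_gas_to_tc(aqu_area_km2 * params$ce_aqu, "co2"),
    sg = g_gas_to_tc(
      aqu_area_km2 * k$m2_per_km2 * params$growth_r * params$shell_c_r /
        k$shell_carbon_divisor, "c")
  )
}

#' Methane pool fluxes
#'
#' Release of the landfill methane-carbon pool (at fraction `ch4_use_r`,
#' the uncollected share) and wetland methane release. Both are returned as
#' CH4 carbon in tC yr-1; `wet_ch4_release` duplicates the value computed
#' in [ecosystem_fluxes()] for convenience when only the methane routing is
#' needed.
#'
#' @param pools a [carbon_pools()] vector.
#' @param params an [island_parameters()].
#' @param temp a temperature (degC); default the reference fixture's 8.
#' @param temp_mode `"clamp"` or `"strict"`.
#' @return a tibble with columns `flux`, `role`, `value` (tC yr-1).
#' @export
ch4_fluxes <- function(pools, params, temp = 8, temp_mode = "clamp") {
  k <- island_constants()
  tf <- temp_factors(temp, temp_mode)
  flux_tbl(
    unused_ch4 = pools[["waste_ch4"]] * params$ch4_use_r,
    wet_ch4_release = k$ch4_to_c * k$wetland_ch4_frac *
      pools[["wetland_c"]] * tf$lin
  )
}

#' Compute all process fluxes for one state
#'
#' Evaluates the full set of named process fluxes (tC yr-1) from the current
#' stocks, the configuration's parameters, forcings and tourist profile,
#' applies any calibration multipliers (`flux_scale`), and tags each flux
#' with its budget role: `emission` (human activity releasing carbon),
#' `sink` (removal from the atmospheric exchange pool) or `internal`
#' (transfer between stocks).
#'
#' @param config an [island_config()].
#' @param pools a [carbon_pools()] vector; defaults to `config$init`.
#' @return a tibble with one row per flux: `flux`, `role`, `value` (tC yr-1).
#' @export
#' @examples
#' compute_fluxes(config_as_printed()) |>
#'   dplyr::filter(role == "emission")
compute_fluxes <- function(config, pools = config$init) {
  validate_pools(pools)
  f <- config$forcings
  p <- config$params
  eco <- ecosystem_fluxes(pools, f, p, config$temp_mode)
  ch4 <- ch4_fluxes(pools, p, temp = f$temp, temp_mode = config$temp_mode)
  out <- dplyr::bind_rows(
    tourism_fluxes(config$profile, f, p),
    infrastructure_fluxes(config$profile, f, p),
    aquaculture_fluxes(f, p),
    eco,
    dplyr::filter(ch4, .data$flux == "unused_ch4"),
    flux_tbl(food_import = p$food_import,
             residential_electricity = p$residential_electricity)
  )
  if (length(config$flux_scale)) {
    sc <- config$flux_scale
    out <- dplyr::mutate(
      out,
      value = .data$value *
        dplyr::coalesce(unname(sc[.data$flux]), 1))
  }
  out[match(flux_names(), out$flux), , drop = FALSE]
}
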