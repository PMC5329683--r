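#' Carbon stocks of the island model
#'
#' Constructs the vector of the seven carbon stocks, all in tonnes of carbon
#' (tC): the cumulative atmospheric CO2 exchange (signed; positive means net
#' carbon released to the atmosphere), forest biomass carbon, wetland plant
#' carbon, mussel-shell carbonate carbon, soil carbon, the landfill methane
#' carbon pool, and cumulative methane carbon released.
#'
#' @param co2_exchange,forest_c,wetland_c,shell_c,soil_c,waste_ch4,total_ch4
#'   stock values in tC. All but `co2_exchange` must be non-negative.
#' @return a named numeric vector of class `carbon_pools`.
#' @export
#' @examples
#' carbon_pools(forest_c = 240, wetland_c = 1800, soil_c = 19600)
carbon_pools <- function(co2_exchange = 0, forest_c = 0, wetland_c = 0,
                         shell_c = 0, soil_c = 0, waste_ch4 = 0,
                         total_ch4 = 0) {
  pools <- c(
    co2_exchange = co2_exchange, forest_c = forest_c, wetland_c = wetland_c,
    shell_c = shell_c, soil_c = soil_c, waste_ch4 = waste_ch4,
    total_ch4 = total_ch4
  )
  validate_pools(pools)
  structure(pools, class = "carbon_pools")
}

validate_pools <- function(pools) {
  missing <- setdiff(pool_names(), names(pools))
  if (length(missing)) {
    abort_config(paste("missing stocks:", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(pools))) {
    abort_config("all stocks must be finite")
  }
  nonneg <- setdiff(pool_names(), "co2_exchange")
  bad <- nonneg[pools[nonneg] < 0]
  if (length(bad)) {
    abort_config(paste("negative stock(s):", paste(bad, collapse = ", ")),
                 field = bad[1])
  }
  invisible(pools)
}

#' Forcing functions (external drivers)
#'
#' The externally prescribed drivers of the model: annual mean temperature
#' and solar radiation, annual visitor and resident counts, and the island's
#' land and managed inshore sea areas. Forcings are not altered by the
#' model state.
#'
#' @param temp mean temperature (degC).
#' @param rade mean solar radiation (MJ m-2 yr-1), > 0.
#' @param nv visitors per year (count, >= 0).
#' @param ni inhabitants (count, >= 0).
#' @param land_area island land area (km2, > 0).
#' @param inshore_area managed sea area (km2, > 0).
#' @return a named list of class `island_forcings`.
#' @export
island_forcings <- function(temp = 8, rade = 1.2, nv = 1e6, ni = 1e4,
                            land_area = 6.62, inshore_area = 1500) {
  f <- list(temp = temp, rade = rade, nv = nv, ni = ni,
            land_area = land_area, inshore_area = inshore_area)
  validate_forcings(f)
  structure(f, class = "island_forcings")
}

validate_forcings <- function(f) {
  stopifnot_scalar(f$temp, "temp")
  stopifnot_scalar(f$rade, "rade", min = 0, strict_min = TRUE)
  stopifnot_scalar(f$nv, "nv", min = 0)
  stopifnot_scalar(f$ni, "ni", min = 0)
  stopifnot_scalar(f$land_area, "land_area", min = 0, strict_min = TRUE)
  stopifnot_scalar(f$inshore_area, "inshore_area", min = 0,
                   strict_min = TRUE)
  invisible(f)
}

#' Tourist behaviour profile
#'
#' Stay-duration distribution and on-island behaviour of visitors: the
#' fractions of tourists staying 1, 2, 3, 4 and 5-or-more days (`sd`, summing
#' to 1), lodging-choice fractions (hotel vs private home), island-transport
#' modal fractions (rental motorcycle, private car, small shuttle bus) and
#' the corresponding daily travel distances.
#'
#' A visitor staying k days generates k activity-days and k - 1 lodging
#' nights; see [visitor_activity_days()] and [lodging_nights()].
#'
#' @param sd numeric length 5; stay-duration fractions, each in \[0, 1\],
#'   summing to 1 (tolerance 1e-9).
#' @param hotel_r,ph_r lodging split fractions in \[0, 1\].
#' @param moto_r,pc_r,ssd_r modal fractions in \[0, 1\].
#' @param pd_moto,pd_pc,pd_ssd daily travel distances (km day-1, >= 0).
#' @return a named list of class `tourist_profile`.
#' @export
#' @examples
#' tourist_profile() # the surveyed profile: most visitors stay three days
tourist_profile <- function(sd = c(0.1, 0.2, 0.5, 0.1, 0.1),
                            hotel_r = 0.3, ph_r = 0.7,
                            moto_r = 0.2, pc_r = 0.1, ssd_r = 0.7,
                            pd_moto = 6, pd_pc = 20, pd_ssd = 14) {
  p <- list(sd = sd, hotel_r = hotel_r, ph_r = ph_r, moto_r = moto_r,
            pc_r = pc_r, ssd_r = ssd_r, pd_moto = pd_moto, pd_pc = pd_pc,
            pd_ssd = pd_ssd)
  validate_profile(p)
  structure(p, class = "tourist_profile")
}

validate_profile <- function(p) {
  if (!is.numeric(p$sd) || length(p$sd) != 5L || any(!is.finite(p$sd))) {
    abort_config("`sd` must be 5 finite stay-duration fractions",
                 field = "sd")
  }
  if (any(p$sd < 0) || any(p$sd > 1)) {
    abort_config("stay-duration fractions `sd` must lie in [0, 1]",
                 field = "sd")
  }
  if (abs(sum(p$sd) - 1) > 1e-9) {
    abort_config(sprintf(
      "stay-duration fractions sd1..sd5 must sum to 1 (got %.12g)",
      sum(p$sd)), field = "sd")
  }
  for (nm in c("hotel_r", "ph_r", "moto_r", "pc_r", "ssd_r")) {
    stopifnot_scalar(p[[nm]], nm, min = 0, max = 1)
  }
  for (nm in c("pd_moto", "pd_pc", "pd_ssd")) {
    stopifnot_scalar(p[[nm]], nm, min = 0)
  }
  invisible(p)
}

#' Island model parameters
#'
#' Every rate constant and per-unit emission coefficient of the model, with
#' the unit each was reported in (see [config_units()]). Emission
#' coefficients `ce_*` are gram-scale masses per activity unit and are
#' converted to tC at the flux boundary; ecosystem rates act per unit stock
#' per year with the habitat area entering as its km2 value, exactly as the
#' model's process equations are written.
#'
#' @param w_growth_r,f_growth_r wetland/forest photosynthetic growth rates.
#' @param w_re_r,f_re_r wetland/forest respiration rates.
#' @param dec_r forest litter decomposition rate.
#' @param ads_r soil carbon adsorption rate.
#' @param forest_frac,tidal_frac fractions of land area under forest and
#'   tidal wetland.
#' @param aqu_frac fraction of inshore area under mussel culture.
#' @param growth_r mussel growth rate (g C m-2 yr-1).
#' @param shell_c_r carbon fraction of shell material, in \[0, 1\].
#' @param ce_aqu aquaculture operations emission (g CO2 km-2 yr-1).
#' @param ce_car resident private-car emission (g CO2 car-1 yr-1).
#' @param ce_desalination desalination emission (g CO2 per t freshwater).
#' @param ce_ferry ferry emission (g CO2 km-1).
#' @param ce_fishing,ce_visiting,ce_wa tourist activity emissions
#'   (g CO2 per activity-day).
#' @param ce_shopping shopping emission (g CO2 per visitor-day).
#' @param ce_hotel,ce_ph lodging emissions (g CO2 per night).
#' @param ce_moto,ce_pc,ce_ssb island-transport emissions (g CO2 km-1).
#' @param dis_ferry annual ferry distance per visitor (km).
#' @param per_wc freshwater use (t person-1 day-1).
#' @param per_waste solid waste generation (kg person-1 day-1).
#' @param pch4_waste methane yield of landfilled waste (g CH4 kg-1).
#' @param ch4_use_r landfill methane release fraction, in \[0, 1\].
#' @param car_r resident car-ownership fraction, in \[0, 1\].
#' @param food_import,residential_electricity optional pass-through
#'   emission terms (tC yr-1), default 0; placeholders for the imported-food
#'   and residential-electricity arrows of the conceptual model, which carry
#'   no measured coefficient.
#' @return a named list of class `island_parameters`.
#' @export
island_parameters <- function(w_growth_r = 0.1, f_growth_r = 0.1,
                              w_re_r = 0.2, f_re_r = 0.2, dec_r = 0.15,
                              ads_r = 0.1,
                              forest_frac = 0.53, tidal_frac = 0.14,
                              aqu_frac = 0.005,
                              growth_r = 1500, shell_c_r = 0.95,
                              ce_aqu = 50000, ce_car = 5.4e6,
                              ce_desalination = 2784, ce_ferry = 106,
                              ce_fishing = 1670, ce_hotel = 7900,
                              ce_moto = 0, ce_pc = 63, ce_ph = 1619,
                              ce_shopping = 344, ce_ssb = 40,
                              ce_visiting = 417, ce_wa = 15300,
                              dis_ferry = 140, per_wc = 1.2,
                              per_waste = 1.1, pch4_waste = 80000,
                              ch4_use_r = 1, car_r = 0.1,
                              food_import = 0,
                              residential_electricity = 0) {
  p <- as.list(environment())
  validate_parameters(p)
  structure(p, class = "island_parameters")
}

validate_parameters <- function(p) {
  fracs <- c("forest_frac", "tidal_frac", "aqu_frac", "shell_c_r",
             "ch4_use_r", "car_r")
  for (nm in fracs) stopifnot_scalar(p[[nm]], nm, min = 0, max = 1)
  rest <- setdiff(parameter_names(), fracs)
  for (nm in rest) stopifnot_scalar(p[[nm]], nm, min = 0)
  invisible(p)
}

parameter_names <- function() names(formals(island_parameters))

#' Assemble a full model configuration
#'
#' Bundles parameters, forcings, tourist profile, initial stocks and run
#' settings into one validated configuration, the single object every other
#' function in the package consumes.
#'
#' @param params an [island_parameters()] list.
#' @param forcings an [island_forcings()] list.
#' @param profile a [tourist_profile()] list.
#' @param init a [carbon_pools()] vector of initial stocks.
#' @param horizon run length in years (> 0).
#' @param dt time step in years (> 0, <= horizon).
#' @param flux_scale optional named numeric vector of per-flux multipliers
#'   applied after flux computation (names must be flux names); used by the
#'   calibrated fixture to close the documented gaps between the raw
#'   coefficients and the reported 2014 budget rows.
#' @param extra_sinks tibble with columns `name`, `area_km2`, `rate_tc_km2`
#'   describing added area-based sink terms (e.g. macroalgae farming);
#'   default empty.
#' @param temp_mode `"clamp"` (default) clamps the linear `(20 - temp)`
#'   temperature factor to zero with a warning when `temp` exceeds 20 degC;
#'   `"strict"` raises an error at or above the reference temperature.
#' @param name label for the configuration (used in logs and reports).
#' @return a list of class `island_config`.
#' @seealso [config_as_printed()], [config_calibrated()], [config_random()]
#' @export
#' @examples
#' cfg <- island_config(horizon = 1, dt = 1 / 12)
#' cfg$forcings$nv
island_config <- function(params = island_parameters(),
                          forcings = island_forcings(),
                          profile = tourist_profile(),
                          init = carbon_pools(),
                          horizon = 1, dt = 1 / 12,
                          flux_scale = numeric(),
                          extra_sinks = NULL,
                          temp_mode = c("clamp", "strict"),
                          name = "custom") {
  temp_mode <- match.arg(temp_mode)
  validate_parameters(params)
  validate_forcings(forcings)
  validate_profile(profile)
  validate_pools(init)
  stopifnot_scalar(horizon, "horizon", min = 0, strict_min = TRUE)
  stopifnot_scalar(dt, "dt", min = 0, strict_min = TRUE)
  if (dt > horizon + 1e-12) {
    abort_config("`dt` must not exceed `horizon`", field = "dt")
  }
  if (length(flux_scale)) {
    bad <- setdiff(names(flux_scale), flux_names())
    if (length(bad)) {
      abort_config(paste("flux_scale names are not fluxes:",
                         paste(bad, collapse = ", ")), field = "flux_scale")
    }
    if (any(flux_scale < 0)) {
      abort_config("flux_scale multipliers must be >= 0",
                   field = "flux_scale")
    }
  }
  if (is.null(extra_sinks)) {
    extra_sinks <- tibble::tibble(name = character(), area_km2 = numeric(),
                                  rate_tc_km2 = numeric())
  } else {
    extra_sinks <- tibble::as_tibble(extra_sinks)
    need <- c("name", "area_km2", "rate_tc_km2")
    if (!all(need %in% names(extra_sinks))) {
      abort_config("extra_sinks needs columns name, area_km2, rate_tc_km2",
                   field = "extra_sinks")
    }
    if (any(extra_sinks$rate_tc_km2 < 0) || any(extra_sinks$area_km2 < 0)) {
      abort_config("extra sink areas and rates must be >= 0",
                   field = "extra_sinks")
    }
  }
  structure(
    list(params = params, forcings = forcings, profile = profile,
         init = init, horizon = horizon, dt = dt, flux_scale = flux_scale,
         extra_sinks = extra_sinks, temp_mode = temp_mode, name = name),
    class = "island_config"
  )
}

#' @export
print.island_config <- function(x, ...) {
  cat("<island_config> ", x$name, "\n", sep = "")
  cat("  visitors/yr: ", format(x$forcings$nv, big.mark = ","),
      "  residents: ", format(x$forcings$ni, big.mark = ","), "\n", sep = "")
  cat("  horizon: ", x$horizon, " yr  dt: ", signif(x$dt, 4), " yr\n",
      sep = "")
  if (length(x$flux_scale)) {
    cat("  calibration multipliers on: ",
        paste(names(x$flux_scale), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$extra_sinks)) {
    cat("  extra sinks: ", paste(x$extra_sinks$name, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Canonical unit strings, used by the YAML schema (units are validated,
# never guessed).
config_units <- function() {
  c(
    temp = "degC", rade = "MJ m-2 yr-1", nv = "visitor yr-1", ni = "person",
    land_area = "km2", inshore_area = "km2",
    sd = "1", hotel_r = "1", ph_r = "1", moto_r = "1", pc_r = "1",
    ssd_r = "1", pd_moto = "km day-1", pd_pc = "km day-1",
    pd_ssd = "km day-1",
    w_growth_r = "stock-1 yr-1", f_growth_r = "stock-1 yr-1",
    w_re_r = "stock-1 yr-1 degC-1", f_re_r = "stock-1 yr-1 degC-1",
    dec_r = "stock-1 yr-1 degC-1", ads_r = "stock-1 yr-1 degC-1",
    forest_frac = "1", tidal_frac = "1", aqu_frac = "1",
    growth_r = "g C m-2 yr-1", shell_c_r = "1",
    ce_aqu = "g CO2 km-2 yr-1", ce_car = "g CO2 car-1 yr-1",
    ce_desalination = "g CO2 t-1", ce_ferry = "g CO2 km-1",
    ce_fishing = "g CO2 day-1", ce_hotel = "g CO2 night-1",
    ce_moto = "g CO2 km-1", ce_pc = "g CO2 km-1",
    ce_ph = "g CO2 night-1", ce_shopping = "g CO2 day-1",
    ce_ssb = "g CO2 km-1", ce_visiting = "g CO2 day-1",
    ce_wa = "g CO2 day-1",
    dis_ferry = "km", per_wc = "t person-1 day-1",
    per_waste = "kg person-1 day-1", pch4_waste = "g CH4 kg-1",
    ch4_use_r = "1", car_r = "1",
    food_import = "tC yr-1", residential_electricity = "tC yr-1",
    horizon = "yr", dt = "yr"
  )
}
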