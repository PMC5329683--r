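# Inflow/outflow membership of each stock, exactly as the model's stock
# equations are written. Emission fluxes enter the atmospheric exchange
# pool from outside the stock system; litter_to_sea leaves it; everything
# else is a transfer between stocks.
stock_flows <- function() {
  list(
    co2_exchange = list(
      inflow = c("w_res", "f_res", "aquaculture", "pc", "desalination",
                 "shopping", "wa", "visiting", "fishing", "hotel", "ph",
                 "ferry", "rm", "car", "ssb", "food_import",
                 "residential_electricity"),
      outflow = c("w_pho", "f_pho", "adsorption", "sg")
    ),
    forest_c = list(inflow = "f_pho",
                    outflow = c("f_res", "decomposition")),
    wetland_c = list(inflow = "w_pho",
                     outflow = c("w_res", "litter_to_sea",
                                 "wet_ch4_release")),
    shell_c = list(inflow = "sg", outflow = character()),
    soil_c = list(inflow = c("adsorption", "decomposition"),
                  outflow = character()),
    waste_ch4 = list(inflow = "waste", outflow = "unused_ch4"),
    total_ch4 = list(inflow = c("wet_ch4_release", "unused_ch4"),
                     outflow = character())
  )
}

#' Advance the stocks one time step
#'
#' Applies the explicit fixed-step update `stock + (inflows - outflows) * dt`
#' to every stock, using the inflow/outflow membership of the model's stock
#' equations. Stocks other than the signed atmospheric exchange pool are
#' floored at zero (with a warning naming the stock) if an outflow would
#' overdraw them within the step; with `on_overdraft = "error"` an error is
#' raised instead.
#'
#' @param pools a [carbon_pools()] vector.
#' @param fluxes a flux tibble from [compute_fluxes()] (columns `flux`,
#'   `value` in tC yr-1).
#' @param dt step length in years (> 0).
#' @param on_overdraft `"floor"` (default) or `"error"`.
#' @return the updated [carbon_pools()] vector.
#' @export
#' @examples
#' p <- carbon_pools(wetland_c = 10)
#' f <- compute_fluxes(config_as_printed(), p)
#' step_pools(p, f, dt = 1 / 12)
step_pools <- function(pools, fluxes, dt, on_overdraft = c("floor", "error")) {
  on_overdraft <- match.arg(on_overdraft)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort_config("`dt` must be a single positive number", field = "dt")
  }
  validate_pools(pools)
  v <- stats::setNames(fluxes$value, fluxes$flux)
  flows <- stock_flows()
  out <- pools
  for (stock in names(flows)) {
    net <- sum(v[flows[[stock]]$inflow]) - sum(v[flows[[stock]]$outflow])
    newval <- pools[[stock]] + net * dt
    if (stock != "co2_exchange" && newval < 0) {
      if (on_overdraft == "error") {
        rlang::abort(sprintf(
          "stock `%s` overdrawn within step (would reach %.6g tC)",
          stock, newval), class = "islandcarbon_overdraft_error")
      }
      rlang::warn(sprintf(
        "stock `%s` overdrawn within step; floored at 0 (was %.6g tC)",
        stock, newval))
      newval <- 0
    }
    out[[stock]] <- newval
  }
  out
}

#' Run the stock-and-flow simulation
#'
#' Iterates flux evaluation and the explicit stock update over the
#' configured horizon with a fixed step. The year is the model's natural
#' unit: forcings are annual means and all fluxes annual rates, so the
#' default horizon is one year and the default step one month (dt = 1/12).
#'
#' @param config an [island_config()].
#' @param on_overdraft passed to [step_pools()].
#' @return an `island_trajectory` object: a list with `times` (step-end
#'   times, yr), `states` (tibble of stocks per recorded time, including
#'   t = 0), `fluxes` (tibble of per-step fluxes with the step start time),
#'   `config`, and `config_hash`. Non-finite states abort with a diagnostic
#'   naming the offending flux.
#' @export
#' @examples
#' run_model(config_calibrated()) |> glance()
run_model <- function(config, on_overdraft = c("floor", "error")) {
  on_overdraft <- match.arg(on_overdraft)
  stopifnot(inherits(config, "island_config"))
  n_steps <- round(config$horizon / config$dt)
  if (abs(n_steps * config$dt - config$horizon) > 1e-9) {
    abort_config("`horizon` must be an integer multiple of `dt`",
                 field = "horizon")
  }
  pools <- config$init
  states <- vector("list", n_steps + 1L)
  fluxes <- vector("list", n_steps)
  states[[1L]] <- c(time = 0, unclass(pools))
  for (i in seq_len(n_steps)) {
    fl <- compute_fluxes(config, pools)
    if (any(!is.finite(fl$value))) {
      bad <- fl$flux[!is.finite(fl$value)][1L]
      rlang::abort(sprintf(
        "non-finite flux `%s` at t = %.6g yr", bad, (i - 1L) * config$dt),
        class = "islandcarbon_numeric_error")
    }
    pools <- step_pools(pools, fl, config$dt, on_overdraft)
    fluxes[[i]] <- dplyr::mutate(fl, time = (i - 1L) * config$dt,
                                 .before = 1L)
    states[[i + 1L]] <- c(time = i * config$dt, unclass(pools))
  }
  structure(
    list(
      times = seq_len(n_steps) * config$dt,
      states = tibble::as_tibble(do.call(rbind, states)),
      fluxes = dplyr::bind_rows(fluxes),
      config = config,
      config_hash = rlang::hash(config)
    ),
    class = "island_trajectory"
  )
}

#' @export
print.island_trajectory <- function(x, ...) {
  cat("<island_trajectory> config: ", x$config$name,
      "  (hash ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("  ", length(x$times), " step(s) of ", signif(x$config$dt, 4),
      " yr over ", x$config$horizon, " yr\n", sep = "")
  final <- x$states[nrow(x$states), ]
  cat("  final co2_exchange: ", signif(final$co2_exchange, 6), " tC\n",
      sep = "")
  invisible(x)
}

#' Annual flux totals of a trajectory
#'
#' Time-integrates each per-step flux over the trajectory
#' (`sum(value * dt)`), giving the totals the budget is built from.
#'
#' @param trajectory an `island_trajectory`.
#' @return a tibble `flux`, `role`, `total` (tC over the run).
#' @export
flux_totals <- function(trajectory) {
  dt <- trajectory$config$dt
  trajectory$fluxes |>
    dplyr::group_by(.data$flux, .data$role) |>
    dplyr::summarise(total = sum(.data$value) * dt, .groups = "drop")
}

#' Tidy a trajectory into long format
#'
#' One row per time x variable, with `type` distinguishing stocks (tC,
#' recorded at step ends including t = 0) from fluxes (tC yr-1, recorded at
#' step starts). This is the layout [write_trajectory_csv()] exports.
#'
#' @param x an `island_trajectory`.
#' @param ... unused.
#' @return a tibble with columns `time`, `name`, `type`, `value`, `unit`.
#' @method tidy island_trajectory
#' @export
tidy.island_trajectory <- function(x, ...) {
  stocks <- x$states |>
    tidyr::pivot_longer(-"time", names_to = "name") |>
    dplyr::mutate(type = "stock", unit = "tC")
  fl <- x$fluxes |>
    dplyr::select("time", name = "flux", "value") |>
    dplyr::mutate(type = "flux", unit = "tC yr-1")
  dplyr::bind_rows(stocks, fl) |>
    dplyr::select("time", "name", "type", "value", "unit") |>
    dplyr::arrange(.data$time, .data$type, .data$name)
}

#' One-row summary of a trajectory
#'
#' @param x an `island_trajectory`.
#' @param ... unused.
#' @return a tibble with the horizon, step, step count, final atmospheric
#'   exchange and the final total of all stocks.
#' @method glance island_trajectory
#' @export
glance.island_trajectory <- function(x, ...) {
  final <- x$states[nrow(x$states), ]
  tibble::tibble(
    horizon = x$config$horizon,
    dt = x$config$dt,
    n_steps = length(x$times),
    final_co2_exchange = final$co2_exchange,
    final_total_stock = sum(final[pool_names()]),
    config = x$config$name
  )
}
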