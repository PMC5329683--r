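#' Default flux-to-budget-row mapping
#'
#' Assigns every process flux to a named budget row (with a sign, so
#' ecosystem rows are net: photosynthesis minus respiration, litter and
#' methane losses) and a column (`emission` or `sink`), or marks it
#' `internal` (excluded from the budget). The default reproduces the
#' structure of the island's reported 2014 budget:
#' * `private_car` aggregates resident cars (`pc`) and tourist cars (`car`);
#'   rental motorcycles stay a separate row.
#' * `soil_respiration` is populated from the soil-uptake (`adsorption`)
#'   magnitude but classified as an emission, following the reported table;
#'   pass `soil_respiration_as = "sink"` for the flux's mechanistic sign.
#' * `forest_ecosystem` = f_pho - f_res - decomposition;
#'   `wetland_ecosystem` = w_pho - w_res - wet_ch4_release - litter_to_sea.
#' * `unused_ch4` is internal (methane routing; the generation flux `waste`
#'   carries the solid-waste row).
#'
#' @param soil_respiration_as `"emission"` (default, as reported) or
#'   `"sink"`.
#' @return a tibble with columns `flux`, `row`, `sign`, `column` (`column`
#'   is `NA` for internal fluxes).
#' @export
default_mapping <- function(soil_respiration_as = c("emission", "sink")) {
  soil_respiration_as <- match.arg(soil_respiration_as)
  tibble::tribble(
    ~flux,            ~row,                 ~sign, ~column,
    "ferry",           "ferry",                 1, "emission",
    "ssb",             "small_shuttle_bus",     1, "emission",
    "pc",              "private_car",           1, "emission",
    "car",             "private_car",           1, "emission",
    "rm",              "rental_motorcycle",     1, "emission",
    "fishing",         "fishing",               1, "emission",
    "visiting",        "visiting",              1, "emission",
    "wa",              "water_activity",        1, "emission",
    "shopping",        "shopping",              1, "emission",
    "hotel",           "hotel",                 1, "emission",
    "ph",              "private_home",          1, "emission",
    "desalination",    "desalination",          1, "emission",
    "aquaculture",     "mussel_aquaculture",    1, "emission",
    "adsorption",      "soil_respiration",      1, soil_respiration_as,
    "waste",           "solid_waste",           1, "emission",
    "food_import",     "food_import",           1, "emission",
    "residential_electricity", "residential_electricity", 1, "emission",
    "sg",              "shell_aquaculture",     1, "sink",
    "f_pho",           "forest_ecosystem",      1, "sink",
    "f_res",           "forest_ecosystem",     -1, "sink",
    "decomposition",   "forest_ecosystem",     -1, "sink",
    "w_pho",           "wetland_ecosystem",     1, "sink",
    "w_res",           "wetland_ecosystem",    -1, "sink",
    "wet_ch4_release", "wetland_ecosystem",    -1, "sink",
    "litter_to_sea",   "wetland_ecosystem",    -1, "sink",
    "unused_ch4",      NA_character_,           1, NA_character_
  )
}

#' Aggregate a simulated year into a carbon budget
#'
#' Time-integrates the trajectory's fluxes and maps them into a two-column
#' annual budget (emissions | sinks) with totals and the carbon credit
#' (total emission minus total sink; negative means net removal). Every
#' flux must be covered by the mapping; an unmapped flux is an error, never
#' silently dropped. Extra area-based sinks configured on the run (e.g. a
#' macroalgae farming project) are appended as sink rows.
#'
#' @param trajectory an `island_trajectory` covering exactly one year, from
#'   [run_model()].
#' @param mapping a mapping tibble, see [default_mapping()].
#' @return a `carbon_budget`: a tibble with columns `row`, `column`,
#'   `value` (tC yr-1), carrying attributes `total_emission`, `total_sink`,
#'   `carbon_credit`, `mapping` and `config_name`.
#' @export
#' @examples
#' config_calibrated() |> run_model() |> aggregate_budget()
aggregate_budget <- function(trajectory, mapping = default_mapping()) {
  stopifnot(inherits(trajectory, "island_trajectory"))
  if (abs(trajectory$config$horizon - 1) > 1e-9) {
    abort_config("budget aggregation needs a trajectory of exactly 1 year",
                 field = "horizon")
  }
  totals <- flux_totals(trajectory)
  unmapped <- setdiff(totals$flux, mapping$flux)
  if (length(unmapped)) {
    rlang::abort(paste0("flux(es) not covered by the budget mapping: ",
                        paste(unmapped, collapse = ", ")),
                 class = "islandcarbon_mapping_error")
  }
  rows <- mapping |>
    dplyr::filter(!is.na(.data$row)) |>
    dplyr::inner_join(totals, by = "flux") |>
    dplyr::group_by(.data$row, .data$column) |>
    dplyr::summarise(value = sum(.data$sign * .data$total),
                     .groups = "drop")
  extra <- trajectory$config$extra_sinks
  if (nrow(extra)) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(row = extra$name, column = "sink",
                     value = extra$area_km2 * extra$rate_tc_km2))
  }
  rows <- dplyr::arrange(rows, dplyr::desc(.data$column == "emission"),
                         dplyr::desc(.data$value))
  new_carbon_budget(rows, config_name = trajectory$config$name,
                    mapping = mapping)
}

new_carbon_budget <- function(rows, config_name = "manual",
                              mapping = NULL) {
  e <- sum(rows$value[rows$column == "emission"])
  s <- sum(rows$value[rows$column == "sink"])
  structure(
    rows,
    class = c("carbon_budget", class(tibble::tibble())),
    total_emission = e,
    total_sink = s,
    carbon_credit = carbon_credit(e, s),
    mapping = mapping,
    config_name = config_name
  )
}

#' Build a budget directly from row values
#'
#' Wraps a plain row table (columns `row`, `column`, `value`) into a
#' `carbon_budget` with totals and credit, e.g. to analyse a reported
#' budget table without running the model.
#'
#' @param rows a data frame with columns `row`, `column` (`"emission"` or
#'   `"sink"`) and `value` (tC yr-1).
#' @return a `carbon_budget`.
#' @export
#' @examples
#' as_carbon_budget(reported_budget_2014()) |> glance()
as_carbon_budget <- function(rows) {
  rows <- tibble::as_tibble(rows)[, c("row", "column", "value")]
  stopifnot(all(rows$column %in% c("emission", "sink")))
  new_carbon_budget(rows)
}

#' Carbon credit of an annual budget
#'
#' The island's net annual carbon balance: total emission minus total sink
#' (tC yr-1). Negative means the island removes more carbon than it emits.
#'
#' @param total_emission,total_sink annual totals (tC yr-1, >= 0).
#' @return the carbon credit (tC yr-1).
#' @export
#' @examples
#' carbon_credit(36780, 51240) # -14460: net removal
carbon_credit <- function(total_emission, total_sink) {
  stopifnot_scalar(total_emission, "total_emission", min = 0)
  stopifnot_scalar(total_sink, "total_sink", min = 0)
  total_emission - total_sink
}

#' Percentage shares of budget rows
#'
#' Each row's percent of its column total, reported to 0.1 % (half-up).
#' With `headline_mode = TRUE` the denominators are the island's reported
#' 2014 headline totals (36780 tC emitted, 51240 tC captured) instead of
#' the model's own column sums — the reported rows sum to less than the
#' reported headline, so the published percentages are only reproducible
#' against the headline denominators.
#'
#' @param budget a `carbon_budget`.
#' @param headline_mode logical; use the reported 2014 totals as
#'   denominators.
#' @return the budget tibble with an added `share` column (percent).
#' @export
#' @examples
#' as_carbon_budget(reported_budget_2014()) |>
#'   budget_shares(headline_mode = TRUE)
budget_shares <- function(budget, headline_mode = FALSE) {
  stopifnot(inherits(budget, "carbon_budget"))
  if (headline_mode) {
    denom <- c(emission = reported_totals_2014()$emission,
               sink = reported_totals_2014()$sink)
  } else {
    denom <- c(emission = attr(budget, "total_emission"),
               sink = attr(budget, "total_sink"))
  }
  used <- unique(budget$column)
  if (any(denom[used] <= 0)) {
    rlang::abort("shares undefined: a column total is zero",
                 class = "islandcarbon_share_error")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(budget),
    share = round_half_up(100 * .data$value /
                            unname(denom[.data$column]), 1))
  for (a in c("total_emission", "total_sink", "carbon_credit", "mapping",
              "config_name")) {
    attr(out, a) <- attr(budget, a)
  }
  class(out) <- class(budget)
  out
}

#' The island's reported 2014 budget rows
#'
#' The published annual carbon budget of the island for 2014 (tC yr-1,
#' values reported to the nearest 10): thirteen emission rows and three
#' sink rows. Used as the calibration target of [config_calibrated()] and
#' for regression tests.
#'
#' @return a tibble with columns `row`, `column`, `value`.
#' @export
reported_budget_2014 <- function() {
  tibble::tribble(
    ~row,                  ~column,    ~value,
    "ferry",               "emission", 11070,
    "small_shuttle_bus",   "emission",   310,
    "private_car",         "emission",  1560,
    "fishing",             "emission",  1300,
    "visiting",            "emission",   320,
    "water_activity",      "emission",  1200,
    "shopping",            "emission",   270,
    "hotel",               "emission",  1220,
    "private_home",        "emission",   600,
    "desalination",        "emission",  6870,
    "mussel_aquaculture",  "emission",  2100,
    "soil_respiration",    "emission",  6430,
    "solid_waste",         "emission",   700,
    "shell_aquaculture",   "sink",     41620,
    "forest_ecosystem",    "sink",      3750,
    "wetland_ecosystem",   "sink",      5870
  )
}

#' Reported 2014 headline totals
#'
#' The headline annual totals of the island's published 2014 assessment:
#' 36780 tC emitted, 51240 tC captured, carbon credit -14460 tC yr-1. Note
#' the published emission rows sum to 33950 tC yr-1; the ~2830 tC gap to
#' the headline is unexplained in the source assessment and deliberately
#' surfaced, not reconciled (see the methods vignette).
#'
#' @return a list with elements `emission`, `sink`, `credit` (tC yr-1).
#' @export
reported_totals_2014 <- function() {
  list(emission = 36780, sink = 51240, credit = 36780 - 51240)
}

#' @method tidy carbon_budget
#' @export
tidy.carbon_budget <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "total_emission") <- NULL
  out
}

#' @method glance carbon_budget
#' @export
glance.carbon_budget <- function(x, ...) {
  tibble::tibble(
    total_emission = attr(x, "total_emission"),
    total_sink = attr(x, "total_sink"),
    carbon_credit = attr(x, "carbon_credit"),
    n_rows = nrow(x),
    config = attr(x, "config_name") %||% NA_character_
  )
}

#' @export
print.carbon_budget <- function(x, digits_to = 10, ...) {
  cat("Annual island carbon budget (tC yr-1)",
      if (!is.null(attr(x, "config_name")))
        paste0("  [", attr(x, "config_name"), "]"),
      "\n", sep = "")
  cat(format_budget(x, digits_to = digits_to), sep = "\n")
  invisible(x)
}

#' Render a budget as an aligned two-column text table
#'
#' Mirrors the reported table's layout: one line per row with the value in
#' the emission or the sink column, then totals and the carbon credit.
#' Values are rounded to the nearest 10 tC yr-1 (half-up) by default, the
#' precision the island's budget is reported at.
#'
#' @param budget a `carbon_budget`.
#' @param digits_to round to this nearest multiple (10 by default; use
#'   `NULL` for unrounded values).
#' @return a character vector of lines.
#' @export
format_budget <- function(budget, digits_to = 10) {
  rnd <- function(v) {
    if (is.null(digits_to)) v else round_half_up(v / digits_to) * digits_to
  }
  rows <- tibble::as_tibble(budget)
  w <- max(nchar(rows$row), nchar("carbon_credit")) + 2L
  line <- function(name, e, s) {
    sprintf("%-*s %12s %12s", w, name,
            ifelse(is.na(e), "", format(e, big.mark = "")),
            ifelse(is.na(s), "", format(s, big.mark = "")))
  }
  header <- line("item", "emission", "sink")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    v <- rnd(rows$value[i])
    if (rows$column[i] == "emission") line(rows$row[i], v, NA)
    else line(rows$row[i], NA, v)
  }, character(1))
  c(header,
    strrep("-", nchar(header)),
    body,
    strrep("-", nchar(header)),
    line("total", rnd(attr(budget, "total_emission")),
         rnd(attr(budget, "total_sink"))),
    line("carbon_credit", rnd(attr(budget, "carbon_credit")), NA))
}
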