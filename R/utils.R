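#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported budget rows (nearest
#' 10 tC yr-1) and percentage shares (one decimal). Base `round()` rounds
#' half to even, which does not reproduce conventionally reported tables.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (negative rounds to tens, etc.).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)    # 1, not 0
#' round_half_up(315, -1) # 320
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Convert between flux mass units
#'
#' Converts a carbon flux in tC yr-1 to the gas mass it was reported in
#' (g CO2, g CH4 or g C per year), and back. Conversions use the molar mass
#' ratios 12/44 (CO2) and 12/16 (CH4).
#'
#' @param x numeric flux value(s).
#' @param gas one of `"co2"`, `"ch4"`, `"c"`.
#' @return converted numeric vector.
#' @export
#' @examples
#' g_gas_to_tc(1.1368e9, "co2") # small-shuttle-bus example, ~310 tC
#' tc_to_g_gas(g_gas_to_tc(42, "ch4"), "ch4")
tc_to_g_gas <- function(x, gas = c("co2", "ch4", "c")) {
  gas <- match.arg(gas)
  k <- island_constants()
  ratio <- switch(gas, co2 = k$co2_to_c, ch4 = k$ch4_to_c, c = 1)
  x * k$g_per_tonne / ratio
}

#' @rdname tc_to_g_gas
#' @export
g_gas_to_tc <- function(x, gas = c("co2", "ch4", "c")) {
  gas <- match.arg(gas)
  k <- island_constants()
  ratio <- switch(gas, co2 = k$co2_to_c, ch4 = k$ch4_to_c, c = 1)
  x * ratio / k$g_per_tonne
}

# internal: stop with a classed validation error
abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "islandcarbon_config_error", field = field)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf,
                             strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name),
                 field = name)
  }
  if (strict_min && x <= min) {
    abort_config(sprintf("`%s` must be > %g", name, min), field = name)
  }
  if (!strict_min && x < min) {
    abort_config(sprintf("`%s` must be >= %g", name, min), field = name)
  }
  if (x > max) {
    abort_config(sprintf("`%s` must be <= %g", name, max), field = name)
  }
  invisible(x)
}
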