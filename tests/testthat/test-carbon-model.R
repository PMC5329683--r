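test_that("activity-days and lodging-nights weight the stay distribution", {
  pr <- tourist_profile()
  expect_equal(visitor_activity_days(pr, 1e6), 2.9e6)
  expect_equal(lodging_nights(pr, 1e6), 1.9e6)
  # zero visitors and degenerate distributions
  expect_equal(visitor_activity_days(pr, 0), 0)
  expect_equal(lodging_nights(pr, 0), 0)
  day_trippers <- tourist_profile(sd = c(1, 0, 0, 0, 0))
  expect_equal(visitor_activity_days(day_trippers, 1234), 1234)
  expect_equal(lodging_nights(day_trippers, 1234), 0)
})

test_that("profile validation rejects malformed stay distributions", {
  expect_error(tourist_profile(sd = c(0.5, 0.5, 0.5, 0, 0)),
               "sum to 1", class = "islandcarbon_config_error")
  expect_error(tourist_profile(sd = c(-0.1, 0.4, 0.5, 0.1, 0.1)),
               class = "islandcarbon_config_error")
  expect_error(visitor_activity_days(tourist_profile(), -1),
               class = "islandcarbon_config_error")
  expect_error(tourist_profile(hotel_r = 1.2),
               class = "islandcarbon_config_error")
})

test_that("small-shuttle-bus flux reproduces the reported 310 tC/yr", {
  fl <- flux_vec(tourism_fluxes(tourist_profile(), island_forcings(),
                                island_parameters()))
  expect_equal(round_half_up(fl[["ssb"]] / 10) * 10, 310)
  # and exactly equals the flat transcription
  expect_equal(fl[["ssb"]], 2.9e6 * 14 * 0.7 * 40 * 12 / 44 * 1e-6)
})

test_that("zero coefficients and zero stocks kill their fluxes", {
  cfg <- config_as_printed()
  fl <- flux_vec(compute_fluxes(cfg, carbon_pools()))
  # published motorcycle coefficient is zero
  expect_equal(fl[["rm"]], 0)
  # every stock-proportional flux vanishes with its stock
  expect_equal(unname(fl[c("w_pho", "f_pho", "w_res", "f_res",
                           "adsorption", "decomposition",
                           "litter_to_sea", "wet_ch4_release",
                           "unused_ch4")]),
               rep(0, 9))
})

test_that("infrastructure fluxes vanish without people and scale with nv", {
  p <- island_parameters()
  pr <- tourist_profile()
  empty <- island_forcings(nv = 0, ni = 0)
  fl0 <- flux_vec(infrastructure_fluxes(pr, empty, p))
  expect_equal(unname(fl0[c("pc", "desalination", "ferry", "waste")]),
               rep(0, 4))
  # doubling visitors doubles the ferry and the visitor part of desalination
  f1 <- island_forcings(nv = 1e6, ni = 0)
  f2 <- island_forcings(nv = 2e6, ni = 0)
  fl1 <- flux_vec(infrastructure_fluxes(pr, f1, p))
  fl2 <- flux_vec(infrastructure_fluxes(pr, f2, p))
  expect_equal(fl2[["ferry"]], 2 * fl1[["ferry"]])
  expect_equal(fl2[["desalination"]], 2 * fl1[["desalination"]])
})

test_that("desalination from published coefficients is ~5968 tC/yr", {
  fl <- flux_vec(infrastructure_fluxes(tourist_profile(),
                                       island_forcings(),
                                       island_parameters()))
  want <- (2.9e6 + 3.65e6) * 1.2 * 2784 * 12 / 44 * 1e-6
  expect_equal(fl[["desalination"]], want)
  expect_equal(round_half_up(want), 5968)
})

test_that("ecosystem fluxes follow the light and temperature responses", {
  p <- island_parameters()
  f <- island_forcings() # temp 8, rade 1.2
  pools <- carbon_pools(wetland_c = 100)
  fl <- flux_vec(ecosystem_fluxes(pools, f, p))
  want_raw <- 100 * 0.1 * (0.14 * 6.62) * 1.05^12 * (1.2 / 7.2 * 690)
  expect_equal(fl[["w_pho"]], want_raw * 12 / 44)
  # at the reference temperature the exponential factor is 1 and every
  # linear factor is 0
  f20 <- island_forcings(temp = 20)
  fl20 <- flux_vec(ecosystem_fluxes(carbon_pools(wetland_c = 100,
                                                 forest_c = 50,
                                                 soil_c = 10), f20, p))
  expect_equal(unname(fl20[c("w_res", "f_res", "adsorption",
                             "decomposition", "wet_ch4_release")]),
               rep(0, 5))
  expect_gt(fl20[["w_pho"]], 0)
})

test_that("above-reference temperatures clamp with warning or error", {
  p <- island_parameters()
  pools <- carbon_pools(wetland_c = 100, forest_c = 50, soil_c = 10)
  hot <- island_forcings(temp = 25)
  expect_warning(fl <- ecosystem_fluxes(pools, hot, p), "clamped")
  expect_equal(flux_vec(fl)[["f_res"]], 0)
  expect_error(ecosystem_fluxes(pools, hot, p, temp_mode = "strict"),
               class = "islandcarbon_domain_error")
  expect_error(
    ecosystem_fluxes(pools, island_forcings(temp = 20), p,
                     temp_mode = "strict"),
    class = "islandcarbon_domain_error")
})

test_that("aquaculture fluxes scale linearly with culture area", {
  p <- island_parameters()
  f <- island_forcings()
  fl <- flux_vec(aquaculture_fluxes(f, p))
  # shell sink at the m2 convention: ~3.96e4 tC/yr
  expect_equal(fl[["sg"]], 7.5e6 * 1500 * 0.95 / 0.27 * 1e-6)
  expect_equal(round_half_up(fl[["sg"]] / 1e3), 40) # ~4e4 tC/yr
  # zero area kills both; doubling the fraction doubles both
  p0 <- island_parameters(aqu_frac = 0)
  expect_equal(unname(flux_vec(aquaculture_fluxes(f, p0))), c(0, 0))
  p2 <- island_parameters(aqu_frac = 0.01)
  expect_equal(flux_vec(aquaculture_fluxes(f, p2)),
               2 * flux_vec(aquaculture_fluxes(f, p)))
})

test_that("methane fluxes follow the landfill pool and release fraction", {
  p <- island_parameters() # ch4_use_r = 1
  expect_equal(
    flux_vec(ch4_fluxes(carbon_pools(waste_ch4 = 50), p))[["unused_ch4"]],
    50)
  p0 <- island_parameters(ch4_use_r = 0)
  expect_equal(
    flux_vec(ch4_fluxes(carbon_pools(waste_ch4 = 50), p0))[["unused_ch4"]],
    0)
  expect_equal(
    unname(flux_vec(ch4_fluxes(carbon_pools(), p))), c(0, 0))
  expect_error(island_parameters(ch4_use_r = 1.5),
               class = "islandcarbon_config_error")
})

test_that("scaling a driver scales exactly the fluxes that cite it", {
  cfg <- config_random(11)
  pools <- cfg$init
  base <- flux_vec(compute_fluxes(cfg, pools))
  # lambda on a single emission coefficient
  cfg2 <- cfg
  cfg2$params$ce_ferry <- 3 * cfg$params$ce_ferry
  scaled <- flux_vec(compute_fluxes(cfg2, pools))
  expect_equal(scaled[["ferry"]], 3 * base[["ferry"]])
  others <- setdiff(names(base), "ferry")
  expect_equal(scaled[others], base[others])
  # lambda on visitors scales exactly the visitor-driven fluxes
  cfg3 <- cfg
  cfg3$forcings$nv <- 2 * cfg$forcings$nv
  doubled <- flux_vec(compute_fluxes(cfg3, pools))
  visitor_driven <- c("shopping", "wa", "visiting", "fishing", "hotel",
                      "ph", "rm", "car", "ssb", "ferry")
  expect_equal(doubled[visitor_driven], 2 * base[visitor_driven])
  untouched <- c("pc", "aquaculture", "sg", "w_pho", "f_pho", "w_res",
                 "f_res", "adsorption", "decomposition", "litter_to_sea",
                 "wet_ch4_release", "unused_ch4")
  expect_equal(doubled[untouched], base[untouched])
})

test_that("flux values equal the flat-arithmetic oracle on random draws", {
  for (seed in 1:25) {
    cfg <- config_random(seed)
    expect_fluxes_match_oracle(cfg)
  }
})

test_that("tC to gas mass conversion round-trips to 1e-12", {
  x <- c(310.03, 5967.9, 0.007, 41620)
  for (gas in c("co2", "ch4", "c")) {
    expect_equal(g_gas_to_tc(tc_to_g_gas(x, gas), gas), x,
                 tolerance = 1e-12)
  }
})

test_that("all fluxes are non-negative for valid random inputs", {
  for (seed in c(3, 101, 977)) {
    cfg <- config_random(seed)
    expect_true(all(compute_fluxes(cfg)$value >= 0))
  }
})
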