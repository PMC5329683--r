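zero_fluxes <- function() {
  fl <- compute_fluxes(config_as_printed(), carbon_pools())
  fl$value <- 0
  fl
}

test_that("a zero flux set leaves the stocks unchanged", {
  p <- carbon_pools(forest_c = 10, wetland_c = 20, soil_c = 30)
  expect_equal(unclass(step_pools(p, zero_fluxes(), dt = 0.5)), unclass(p))
})

test_that("a single constant inflow integrates to r * n * dt", {
  fl <- zero_fluxes()
  fl$value[fl$flux == "sg"] <- 7 # tC/yr into the shell pool
  p <- carbon_pools()
  dt <- 1 / 12
  for (i in 1:24) p <- step_pools(p, fl, dt)
  expect_equal(p[["shell_c"]], 7 * 24 * dt, tolerance = 1e-12)
})

test_that("stepping matches a cumulative-sum oracle over random fluxes", {
  set.seed(42)
  fl <- zero_fluxes()
  p <- carbon_pools(co2_exchange = 0, forest_c = 1e4, wetland_c = 1e4,
                    shell_c = 1e4, soil_c = 1e4, waste_ch4 = 1e4,
                    total_ch4 = 0)
  dt <- 0.05
  sums <- stats::setNames(numeric(length(fl$flux)), fl$flux)
  for (step in 1:20) {
    fl$value <- stats::runif(nrow(fl), 0, 50)
    sums <- sums + fl$value * dt
    p <- step_pools(p, fl, dt)
  }
  # independent oracle: initial + (sum of inflows - outflows) per stock
  expect_equal(p[["shell_c"]], 1e4 + sums[["sg"]], tolerance = 1e-9)
  expect_equal(p[["soil_c"]],
               1e4 + sums[["adsorption"]] + sums[["decomposition"]],
               tolerance = 1e-9)
  expect_equal(p[["waste_ch4"]],
               1e4 + sums[["waste"]] - sums[["unused_ch4"]],
               tolerance = 1e-9)
  expect_equal(p[["total_ch4"]],
               sums[["wet_ch4_release"]] + sums[["unused_ch4"]],
               tolerance = 1e-9)
  expect_equal(p[["wetland_c"]],
               1e4 + sums[["w_pho"]] - sums[["w_res"]] -
                 sums[["litter_to_sea"]] - sums[["wet_ch4_release"]],
               tolerance = 1e-9)
  emis <- c("w_res", "f_res", "aquaculture", "pc", "desalination",
            "shopping", "wa", "visiting", "fishing", "hotel", "ph",
            "ferry", "rm", "car", "ssb", "food_import",
            "residential_electricity")
  expect_equal(p[["co2_exchange"]],
               sum(sums[emis]) - sums[["w_pho"]] - sums[["f_pho"]] -
                 sums[["adsorption"]] - sums[["sg"]],
               tolerance = 1e-9)
})

test_that("overdrawing a stock floors at zero with warning, or errors", {
  fl <- zero_fluxes()
  fl$value[fl$flux == "unused_ch4"] <- 100
  p <- carbon_pools(waste_ch4 = 1)
  expect_warning(p2 <- step_pools(p, fl, dt = 1), "waste_ch4")
  expect_equal(p2[["waste_ch4"]], 0)
  expect_error(step_pools(p, fl, dt = 1, on_overdraft = "error"),
               class = "islandcarbon_overdraft_error")
  expect_error(step_pools(p, fl, dt = 0),
               class = "islandcarbon_config_error")
})

test_that("zero published initial stocks keep ecosystem fluxes at zero", {
  traj <- run_model(config_as_printed())
  eco <- c("w_pho", "f_pho", "w_res", "f_res", "adsorption",
           "decomposition", "litter_to_sea", "wet_ch4_release")
  vals <- traj$fluxes$value[traj$fluxes$flux %in% eco]
  expect_equal(vals, rep(0, length(vals)))
  final <- traj$states[nrow(traj$states), ]
  expect_equal(final$forest_c, 0)
  expect_equal(final$wetland_c, 0)
  expect_equal(final$soil_c, 0)
  # person-driven pools still accumulate
  expect_gt(final$shell_c, 0)
  expect_gt(final$waste_ch4 + final$total_ch4, 0)
})

test_that("total stock change equals integrated external sources minus removals", {
  for (seed in c(5, 19, 404)) {
    cfg <- config_random(seed, horizon = 1, dt = 1 / 12)
    traj <- run_model(cfg)
    totals <- flux_totals(traj)
    external_in <- sum(totals$total[totals$role == "emission"])
    external_out <- totals$total[totals$flux == "litter_to_sea"]
    first <- unlist(traj$states[1, pool_names()])
    last <- unlist(traj$states[nrow(traj$states), pool_names()])
    delta <- sum(last) - sum(first)
    expect_equal(delta, external_in - external_out,
                 tolerance = 1e-9)
  }
})

test_that("identical configs give identical serialized trajectories", {
  t1 <- run_model(config_random(77))
  t2 <- run_model(config_random(77))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(t1, f1)
  write_trajectory_csv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$config_hash, t2$config_hash)
})

test_that("halving dt leaves person-driven totals unchanged and shrinks stock-flux error", {
  cfg <- config_calibrated(check = FALSE)
  cfg$name <- "refine"
  # damp the photosynthetic growth so rate * dt stays well below 1 and the
  # first-order error term dominates at the step sizes compared
  cfg$params$f_growth_r <- 0.005
  cfg$params$w_growth_r <- 0.02
  totals_at <- function(dt) {
    cfg$dt <- dt
    tt <- flux_totals(run_model(cfg))
    stats::setNames(tt$total, tt$flux)
  }
  a <- totals_at(1 / 8)
  b <- totals_at(1 / 16)
  c_ <- totals_at(1 / 32)
  person <- c("ferry", "ssb", "desalination", "pc", "hotel", "waste")
  expect_equal(a[person], b[person], tolerance = 1e-9)
  # stock-proportional totals converge at first order: successive
  # differences roughly halve
  d1 <- abs(b[["f_pho"]] - a[["f_pho"]])
  d2 <- abs(c_[["f_pho"]] - b[["f_pho"]])
  expect_lt(d2, d1)
})

test_that("run_model validates horizon/dt compatibility and finiteness", {
  cfg <- config_as_printed()
  cfg$dt <- 0.3
  expect_error(run_model(cfg), "multiple",
               class = "islandcarbon_config_error")
  bad <- config_as_printed()
  bad$params$ce_ferry <- Inf
  expect_error(run_model(bad), "ferry",
               class = "islandcarbon_numeric_error")
})

test_that("tidy and glance expose the trajectory in long and summary form", {
  traj <- run_model(config_calibrated())
  td <- tidy(traj)
  expect_setequal(names(td), c("time", "name", "type", "value", "unit"))
  expect_setequal(unique(td$type), c("stock", "flux"))
  g <- glance(traj)
  expect_equal(g$n_steps, 1)
  expect_equal(g$horizon, 1)
})
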