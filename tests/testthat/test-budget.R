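test_that("a single nonzero flux yields a one-sided budget", {
  cfg <- config_as_printed()
  # zero everything except the ferry
  for (nm in grep("^ce_", parameter_names(), value = TRUE)) {
    cfg$params[[nm]] <- 0
  }
  cfg$params$ce_ferry <- 106
  cfg$params$pch4_waste <- 0
  cfg$params$growth_r <- 0
  b <- carbon_budget_of(cfg)
  fl <- compute_fluxes(cfg)
  ferry <- fl$value[fl$flux == "ferry"]
  expect_equal(attr(b, "total_emission"), ferry)
  expect_equal(attr(b, "total_sink"), 0)
  expect_equal(attr(b, "carbon_credit"), ferry)
})

test_that("the reported 2014 rows reproduce the reported totals", {
  b <- as_carbon_budget(reported_budget_2014())
  expect_equal(attr(b, "total_sink"), 41620 + 3750 + 5870)
  expect_equal(attr(b, "total_sink"), 51240)
  # emission rows sum below the reported headline: surfaced, not hidden
  expect_equal(attr(b, "total_emission"), 33950)
  expect_lt(attr(b, "total_emission"), reported_totals_2014()$emission)
})

test_that("carbon credit is emission minus sink with its symmetries", {
  expect_equal(carbon_credit(36780, 51240), -14460)
  expect_equal(carbon_credit(123.4, 123.4), 0)
  expect_equal(carbon_credit(0, 77), -77)
  for (i in 1:10) {
    e <- stats::runif(1, 0, 1e5)
    s <- stats::runif(1, 0, 1e5)
    expect_equal(carbon_credit(e, s), -carbon_credit(s, e))
  }
  expect_error(carbon_credit(-1, 0), class = "islandcarbon_config_error")
})

test_that("row aggregation equals a flat-sum oracle on random flux sets", {
  set.seed(99)
  for (rep in 1:5) {
    cfg <- config_random(sample.int(1e6, 1), horizon = 1, dt = 1)
    # a full-year step may overdraw a fast-turnover stock; flooring only
    # affects later states, not the step-start fluxes the budget uses
    traj <- suppressWarnings(run_model(cfg))
    b <- aggregate_budget(traj)
    v <- stats::setNames(traj$fluxes$value, traj$fluxes$flux)
    rows <- stats::setNames(b$value, b$row)
    expect_equal(rows[["private_car"]], v[["pc"]] + v[["car"]])
    expect_equal(rows[["forest_ecosystem"]],
                 v[["f_pho"]] - v[["f_res"]] - v[["decomposition"]])
    expect_equal(rows[["wetland_ecosystem"]],
                 v[["w_pho"]] - v[["w_res"]] - v[["wet_ch4_release"]] -
                   v[["litter_to_sea"]])
    expect_equal(attr(b, "total_emission"),
                 sum(b$value[b$column == "emission"]))
  }
})

test_that("unmapped fluxes are an error naming the flux", {
  traj <- run_model(config_calibrated())
  broken <- dplyr::filter(default_mapping(), .data$flux != "ferry")
  expect_error(aggregate_budget(traj, broken), "ferry",
               class = "islandcarbon_mapping_error")
  # a non-annual trajectory cannot be aggregated
  cfg <- config_calibrated(check = FALSE)
  cfg$horizon <- 2
  expect_error(aggregate_budget(run_model(cfg)),
               class = "islandcarbon_config_error")
})

test_that("shares divide rows by column totals at 0.1% precision", {
  b <- budget_shares(as_carbon_budget(reported_budget_2014()),
                     headline_mode = TRUE)
  sh <- stats::setNames(b$share, b$row)
  expect_equal(sh[["shell_aquaculture"]], 81.2)
  expect_equal(sh[["desalination"]], 18.7)
  # single-row column is 100% of itself (own-total mode, sinks collapsed)
  one <- as_carbon_budget(tibble::tibble(
    row = c("x", "s"), column = c("emission", "sink"), value = c(5, 3)))
  sh1 <- budget_shares(one)
  expect_equal(sh1$share, c(100, 100))
  # zero column total -> undefined shares
  zero <- as_carbon_budget(tibble::tibble(
    row = "x", column = "emission", value = 0))
  expect_error(budget_shares(zero), class = "islandcarbon_share_error")
})

test_that("shares within each column normalise to 100 +/- 0.2", {
  for (b in list(carbon_budget_of(config_calibrated()),
                 suppressWarnings(carbon_budget_of(config_random(8, dt = 1))))) {
    sh <- budget_shares(b)
    sums <- tapply(sh$share, sh$column, sum)
    expect_true(all(abs(sums - 100) <= 0.2))
  }
})

test_that("soil respiration classification is configurable", {
  traj <- run_model(config_calibrated())
  as_emission <- aggregate_budget(traj)
  as_sink <- aggregate_budget(traj, default_mapping("sink"))
  i <- which(as_emission$row == "soil_respiration")
  j <- which(as_sink$row == "soil_respiration")
  expect_equal(as_emission$column[i], "emission")
  expect_equal(as_sink$column[j], "sink")
  expect_equal(as_emission$value[i], as_sink$value[j])
  expect_equal(attr(as_sink, "total_sink") - attr(as_emission, "total_sink"),
               as_sink$value[j])
})

test_that("budget text rendering matches the reported two-column layout", {
  lines <- format_budget(as_carbon_budget(reported_budget_2014()))
  expect_true(any(grepl("shell_aquaculture\\s+41620", lines)))
  expect_true(any(grepl("total\\s+33950\\s+51240", lines)))
  expect_true(any(grepl("carbon_credit\\s+-17290", lines)))
})
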