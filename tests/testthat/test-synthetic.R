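test_that("degenerate configurations produce degenerate landscapes", {
  cfg0 <- small_config(type_mix = c(deforestation = 0, maintenance = 0.5,
                                    forest = 0.5),
                       defor_front_fraction = 0)
  land <- generate_landscape(cfg0)
  expect_true(all(land$annual_rate == 0))
  expect_true(all(land$cum_defor == 0))

  cfg1 <- small_config(tree_cover_mix = c(high = 1, low = 0),
                       type_mix = c(deforestation = 0.1, maintenance = 0,
                                    forest = 0.9))
  land1 <- generate_landscape(cfg1)
  expect_true(all(land1$pixels$tree_cover_2000 >= 70))
})

test_that("landscape invariants hold: bounded percentages, monotone cumulative clearing", {
  land <- generate_landscape(small_config(seed = 3))
  expect_true(all(land$pixels$tree_cover_2000 >= 0 &
                    land$pixels$tree_cover_2000 <= 100))
  expect_true(all(land$annual_rate >= 0 & land$annual_rate <= 100))
  expect_true(all(land$cum_defor >= 0 & land$cum_defor <= 100))
  expect_true(all(apply(land$cum_defor, 1L, function(x) all(diff(x) >= 0))))
})

test_that("active clearing fraction per year tracks defor_front_fraction within binomial bounds", {
  f <- 0.02
  cfg <- synthetic_config(grid_rows = 50L, grid_cols = 50L,
                          defor_front_fraction = f, seed = 11)
  land <- generate_landscape(cfg)
  npix <- 2500L
  lo <- qbinom(0.005, npix, f) / npix
  hi <- qbinom(0.995, npix, f) / npix
  frac <- colMeans(land$annual_rate >= 5)
  expect_true(all(frac >= lo & frac <= hi))
})

test_that("pure maintenance seasons have exactly one detection day per pixel-year", {
  cfg <- small_config(type_mix = c(deforestation = 0, maintenance = 1,
                                   forest = 0))
  land <- generate_landscape(cfg)
  sim <- generate_fire_seasons(cfg, land)
  py <- persistence(sim$detections)
  expect_true(all(py$n_days == 1L))
})

test_that("per-type day-count and landscape preconditions hold for every generated detection", {
  cfg <- small_config(seed = 5)
  land <- generate_landscape(cfg)
  sim <- generate_fire_seasons(cfg, land)
  py <- persistence(sim$detections)
  d <- sim$detections
  d$year <- as.integer(format(d$date, "%Y"))
  key <- paste(d$pixel_row, d$pixel_col, d$year)
  pyk <- paste(py$pixel_row, py$pixel_col, py$year)
  d$n_days <- py$n_days[match(key, pyk)]
  pid <- (d$pixel_row - 1L) * land$grid_cols + d$pixel_col
  ycol <- match(as.character(d$year), colnames(land$annual_rate))
  rate <- land$annual_rate[cbind(pid, ycol)]
  cum <- land$cum_defor[cbind(pid, ycol)]
  cover <- land$pixels$tree_cover_2000[pid]
  defo <- d$true_type == "deforestation"
  fore <- d$true_type == "forest"
  main <- d$true_type == "maintenance"
  expect_true(all(d$n_days[defo] >= 2L & rate[defo] >= 5))
  expect_true(all(d$n_days[fore] <= 3L & cover[fore] >= 70 & cum[fore] <= 20))
  expect_true(all(d$n_days[main] == 1L))
  months <- as.integer(format(d$date, "%m"))
  expect_true(all(months %in% cfg$season_months))
})

test_that("truth-label shares converge to the configured type mix", {
  cfg <- synthetic_config(grid_rows = 120L, grid_cols = 120L,
                          mean_annual_detections = 6000,
                          annual_trend = 0,
                          drought_multiplier_by_type =
                            c(deforestation = 1, maintenance = 1,
                              forest = 1),
                          seed = 2)
  land <- generate_landscape(cfg)
  sim <- generate_fire_seasons(cfg, land)
  n <- nrow(sim$detections)
  expect_gt(n, 9e4)
  shares <- table(sim$detections$true_type)[names(cfg$type_mix)] / n
  expect_true(all(abs(shares - cfg$type_mix) < 0.015))
})

test_that("without drought amplification the expected totals sit exactly on the trend line", {
  cfg <- small_config(drought_multiplier_by_type =
                        c(deforestation = 1, maintenance = 1, forest = 1))
  land <- generate_landscape(cfg)
  sim <- generate_fire_seasons(cfg, land)
  tot <- sim$truth$expected_totals$total
  line <- cfg$mean_annual_detections *
    (1 + cfg$annual_trend)^(seq_along(cfg$years) - 1)
  expect_equal(tot, line, tolerance = 1e-12)
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- small_config(seed = 99)
  a <- generate_fire_seasons(cfg, generate_landscape(cfg))
  b <- generate_fire_seasons(cfg, generate_landscape(cfg))
  expect_identical(a, b)
})

test_that("an infeasible type request names the offending type", {
  cfg <- small_config(defor_front_fraction = 0)
  land <- generate_landscape(cfg)
  expect_error(generate_fire_seasons(cfg, land),
               "deforestation",
               class = "amazonfire_infeasible_error")
})

test_that("[CO] generator: exact coupling, decoupling, and positivity", {
  cfg <- small_config(co_coupling = list(intercept = 80, slope = 0.004,
                                         sd = 0))
  totals <- data.frame(year = 2003:2019,
                       total = seq(4000, 800, length.out = 17))
  co <- generate_co_series(cfg, totals)
  fit <- suppressWarnings(ols_regression(totals$total, co$co))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.004, tolerance = 1e-12)
  expect_true(all(co$co > 0))

  # slope 0: regression slope estimate centered on 0 across seeds
  est <- vapply(1:200, function(s) {
    cfgs <- small_config(seed = s,
                         co_coupling = list(intercept = 100, slope = 0,
                                            sd = 2))
    ols_regression(totals$total,
                   generate_co_series(cfgs, totals)$co)$slope
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 4 * se + 1e-6)
})

test_that("a coupled [CO] series inherits a detectable decreasing trend (simulation power)", {
  totals <- data.frame(year = 2003:2015,
                       total = 4000 * (1 - 0.08)^(0:12))
  hits <- vapply(1:500, function(s) {
    cfgs <- small_config(seed = s,
                         co_coupling = list(intercept = 80, slope = 0.01,
                                            sd = 2))
    co <- generate_co_series(cfgs, totals)
    mk <- mann_kendall(co$year, co$co, alpha = 0.05)
    mk$significant && mk$S < 0
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
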