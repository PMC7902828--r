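test_that("Mann-Kendall handles constant, monotone, and tied series", {
  const <- mann_kendall(2003:2010, rep(5, 8))
  expect_equal(const$S, 0L)
  expect_equal(const$p_value, 1)
  expect_true(const$degenerate)
  expect_false(const$significant)

  inc <- mann_kendall(2003:2006, c(1, 2, 3, 4))
  expect_equal(inc$S, 6L)
  expect_equal(inc$p_exact, 2 / 24, tolerance = 1e-12)

  # tie correction shrinks the variance relative to the tie-free formula
  tied <- mann_kendall(2003:2010, c(1, 2, 2, 3, 4, 4, 5, 6))
  n <- 8
  expect_lt(tied$var_S, n * (n - 1) * (2 * n + 5) / 18)
  expect_true(abs(tied$S) <= n * (n - 1) / 2)
})

test_that("Mann-Kendall agrees with cor.test's Kendall machinery", {
  set.seed(42)
  for (i in 1:5) {
    y <- rnorm(9)
    mk <- mann_kendall(2003:2011, y)
    ct <- suppressWarnings(stats::cor.test(2003:2011, y,
                                           method = "kendall"))
    # same S statistic (tau * n(n-1)/2) and comparable p
    expect_equal(mk$S, unname(ct$estimate) * 9 * 8 / 2, tolerance = 1e-9)
    expect_equal(mk$p_exact, unname(ct$p.value), tolerance = 1e-9)
  }
})

test_that("normal-approximation and exact p agree closely for tie-free data, n >= 10", {
  set.seed(7)
  for (n in c(10, 14, 17, 25)) {
    for (i in 1:10) {
      y <- rnorm(n)
      mk <- mann_kendall(seq_len(n), y)
      expect_lt(abs(mk$p_value - mk$p_exact), 0.02)
    }
  }
})

test_that("Theil-Sen slope matches hand enumeration and is shift invariant", {
  ts1 <- theil_sen(1:5, 3 * (1:5) + 2)
  expect_equal(ts1$slope, 3, tolerance = 1e-12)
  expect_equal(ts1$intercept, 2, tolerance = 1e-12)

  # pairwise slopes of {0,0,10} at years 1..3: (0, 5, 10) -> median 5
  expect_equal(theil_sen(1:3, c(0, 0, 10))$slope, 5, tolerance = 1e-12)

  y <- c(4, 8, 1, 9, 3, 7)
  expect_equal(theil_sen(1:6, y + 100)$slope, theil_sen(1:6, y)$slope,
               tolerance = 1e-12)
})

test_that("Theil-Sen resists outlier contamination below the breakdown point", {
  t <- 1:10
  y <- 2 * t + 1
  y[c(3, 8)] <- y[c(3, 8)] + 500   # 20% gross contamination
  expect_equal(theil_sen(t, y)$slope, 2, tolerance = 1e-12)
})

test_that("OLS matches the normal-equations oracle and flags degenerate x", {
  x <- c(1, 2, 4, 7, 9); y <- c(2.2, 2.8, 5.1, 8.3, 9.9)
  f <- ols_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$intercept, beta[1L], tolerance = 1e-12)
  expect_equal(f$slope, beta[2L], tolerance = 1e-12)
  sse <- sum((y - X %*% beta)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(f$r_squared, 1 - sse / sst, tolerance = 1e-12)

  fe <- suppressWarnings(ols_regression(x, 2 * x))
  expect_equal(fe$r_squared, 1, tolerance = 1e-12)
  expect_equal(fe$slope, 2, tolerance = 1e-12)

  expect_error(ols_regression(rep(3, 5), y),
               class = "amazonfire_degenerate_error")
})

test_that("null OLS p-values are uniform", {
  set.seed(11)
  p <- vapply(1:1000, function(i)
    ols_regression(1:12, rnorm(12))$p_value, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("fires per deforested area is a plain homogeneous ratio", {
  fires <- data.frame(year = 2010:2012, total = c(100, 60, 90))
  defor <- data.frame(year = 2010:2012, defor_km2 = c(50, 30, 30))
  r <- fires_per_area_ratio(fires, defor)
  expect_equal(r$fires_per_km2, c(2, 2, 3))

  fires2 <- fires; defor2 <- defor
  fires2$total <- fires2$total * 4; defor2$defor_km2 <- defor2$defor_km2 * 4
  expect_equal(fires_per_area_ratio(fires2, defor2)$fires_per_km2,
               r$fires_per_km2)

  defor$defor_km2[2] <- 0
  expect_error(fires_per_area_ratio(fires, defor), "2011",
               class = "amazonfire_degenerate_error")
})

test_that("phase regressions decompose into manual per-phase OLS", {
  set.seed(5)
  years <- 2003:2019
  defor <- data.frame(year = years,
                      defor_km2 = 25000 * 0.88^(years - 2003) + rnorm(17, 0, 200))
  fires <- data.frame(year = years,
                      total = 8 * defor$defor_km2 + rnorm(17, 0, 5000))
  ph <- phase_regressions(fires, defor)
  expect_setequal(ph$name, c("I", "II", "III", "IV", "full"))
  for (nm in c("I", "II", "III", "IV")) {
    row <- ph[ph$name == nm, ]
    sub <- merge(fires, defor, by = "year")
    sub <- sub[sub$year >= row$start & sub$year <= row$end, ]
    man <- ols_regression(sub$defor_km2, sub$total)
    expect_equal(row$r_squared, man$r_squared, tolerance = 1e-12)
    expect_equal(row$p_value, man$p_value, tolerance = 1e-12)
  }
  expect_true(ph$low_n[ph$name == "II"])       # 3-year phase
  expect_false(ph$low_n[ph$name == "full"])

  # noise-free affine series: full-period R^2 = 1
  fires0 <- data.frame(year = years, total = 5 * defor$defor_km2 + 100)
  ph0 <- suppressWarnings(phase_regressions(fires0, defor))
  expect_equal(ph0$r_squared[ph0$name == "full"], 1, tolerance = 1e-9)

  expect_error(phase_regressions(fires, defor,
                                 data.frame(name = "X", start = 1990L,
                                            end = 1995L)),
               "span")
})

test_that("Sen slope confidence limits bracket the point estimate", {
  set.seed(3)
  y <- -4 * (1:15) + rnorm(15, 0, 3)
  ts <- theil_sen(1:15, y)
  expect_true(ts$lower <= ts$slope && ts$slope <= ts$upper)
})
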