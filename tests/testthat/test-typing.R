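test_that("persistence counts distinct days, not detections", {
  det <- make_det(rep(1, 3), rep(1, 3),
                  c("2010-08-01", "2010-08-15", "2010-09-02"))
  expect_equal(persistence(det)$n_days, 3L)

  det2 <- make_det(rep(2, 5), rep(2, 5), rep("2010-08-01", 5))
  py <- persistence(det2)
  expect_equal(py$n_days, 1L)
  expect_equal(py$n_detections, 5L)
})

test_that("persistence equals a brute-force set-of-dates oracle on a seeded season", {
  cfg <- small_config(seed = 21)
  det <- generate_fire_seasons(cfg, generate_landscape(cfg))$detections
  py <- persistence(det)
  yr <- as.integer(format(det$date, "%Y"))
  key <- paste(det$pixel_row, det$pixel_col, yr)
  oracle <- tapply(as.integer(det$date), key,
                   function(d) length(unique(d)))
  expect_equal(py$n_days,
               as.integer(oracle[paste(py$pixel_row, py$pixel_col,
                                       py$year)]))
  expect_equal(sum(py$n_detections), nrow(det))
})

test_that("seasonal persistence windows drop out-of-season detections", {
  det <- make_det(rep(1, 3), rep(1, 3),
                  c("2010-03-01", "2010-08-15", "2010-09-02"))
  expect_equal(persistence(det, window = "year")$n_days, 3L)
  expect_equal(persistence(det, window = "season")$n_days, 2L)
})

test_that("threshold boundaries classify as stated", {
  # persistent fire on an active clearing: deforestation even at the 5% edge
  expect_equal(classify_pixel_year(2L, 5, 40, 30), "deforestation")
  # single-day fire under high cover and limited clearing: forest at both edges
  expect_equal(classify_pixel_year(1L, 0, 70, 20), "forest")
  # persistent fire without clearing, too many days for forest: maintenance
  expect_equal(classify_pixel_year(4L, 0, 90, 0), "maintenance")
  # single-day fire on low cover: maintenance
  expect_equal(classify_pixel_year(1L, 0, 50, 0), "maintenance")
  expect_error(classify_pixel_year(0L, 0, 50, 0),
               class = "amazonfire_nofire_error")
})

test_that("the full boundary truth table reproduces the three-rule logic", {
  lands <- data.frame(rate = c(5, 4.9, 5, 4.9),
                      cover = c(40, 70, 70, 70),
                      cum = c(30, 20, 20, 20.1))
  # expected labels by applying the rule order by hand
  expected <- rbind(
    c("maintenance", "deforestation", "deforestation", "deforestation"),
    c("forest", "forest", "forest", "maintenance"),
    c("forest", "deforestation", "deforestation", "deforestation"),
    c("maintenance", "maintenance", "maintenance", "maintenance"))
  for (li in 1:4) for (nd in 1:4)
    expect_equal(classify_pixel_year(nd, lands$rate[li], lands$cover[li],
                                     lands$cum[li]),
                 expected[li, nd],
                 label = sprintf("landscape %d, n_days %d", li, nd))
})

test_that("raising the deforestation-rate threshold never increases deforestation counts", {
  cfg <- small_config(seed = 31)
  land <- generate_landscape(cfg)
  det <- generate_fire_seasons(cfg, land)$detections
  counts <- vapply(c(5, 5.3, 5.6, 6, 10), function(r) {
    th <- classification_thresholds(min_defor_rate = r)
    sum(classify_all(det, land, th)$detections$fire_type == "deforestation")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classification recovers truth exactly on disjoint synthetic strata", {
  cfg <- small_config(seed = 17)
  land <- generate_landscape(cfg)
  sim <- generate_fire_seasons(cfg, land)
  cl <- classify_all(sim$detections, land)
  expect_identical(cl$detections$fire_type, sim$detections$true_type)
  # shares in the tabulation equal truth shares exactly
  tot <- colSums(cl$annual_counts[c("deforestation", "maintenance",
                                    "forest")])
  expect_equal(as.numeric(tot),
               as.numeric(table(sim$truth$labels)[c("deforestation",
                                                    "maintenance",
                                                    "forest")]))
})

test_that("precedence order only moves the documented overlap cells", {
  # overlap: pixel-years satisfying both deforestation (n_days >= 2,
  # rate >= 5) and forest (n_days <= 3, cover >= 70, cum <= 20) conditions
  land <- make_landscape(1, 2, 2010, tree_cover = c(90, 90),
                         rate = c(8, 0), cum = c(10, 10))
  det <- make_det(c(1, 1, 1), c(1, 1, 2),
                  c("2010-08-01", "2010-08-05", "2010-08-01"))
  a <- classify_all(det, land, precedence = c("deforestation", "forest"))
  b <- classify_all(det, land, precedence = c("forest", "deforestation"))
  expect_equal(a$pixel_years$fire_type, c("deforestation", "forest"))
  expect_equal(b$pixel_years$fire_type, c("forest", "forest"))
  # the non-overlap pixel (col 2) never moves
  expect_equal(a$pixel_years$fire_type[2], b$pixel_years$fire_type[2])
})

test_that("detections on unknown pixels error by default and can fall back", {
  land <- make_landscape(2, 2, 2010, tree_cover = 50, rate = 0, cum = 0)
  det <- make_det(3, 1, "2010-08-01")
  expect_error(classify_all(det, land),
               class = "amazonfire_missing_landscape_error")
  expect_warning(cl <- classify_all(det, land, on_missing = "maintenance"),
                 "maintenance")
  expect_equal(cl$detections$fire_type, "maintenance")
})

test_that("annual tabulation yields shares summing to 100 and sensible ratios", {
  det <- rbind(make_det(1, 1, "2010-08-01"), make_det(1, 2, "2010-08-01"),
               make_det(2, 1, "2010-08-03"), make_det(2, 2, "2010-08-04"))
  det$fire_type <- c("deforestation", "forest", "forest", "maintenance")
  tab <- annual_type_counts(det)
  expect_equal(tab$total, 4)
  expect_equal(tab$share_deforestation + tab$share_maintenance +
                 tab$share_forest, 100, tolerance = 1e-9)
  expect_equal(tab$ratio_defor_forest, 50)
  expect_equal(tab$ratio_defor_maintenance, 100)
})
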