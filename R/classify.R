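#' Fire-type classification thresholds
#'
#' The rule set separating deforestation, maintenance, and forest
#' (understory) fires. Defaults: persistence of 2 or more detection days
#' and an annual deforestation rate of at least 5 percent mark
#' deforestation fires (5 percent being the smallest clearing the annual
#' deforestation product resolves); at most 3 detection days with year-2000
#' tree cover of at least 70 percent and cumulative deforestation since
#' 2001 of at most 20 percent mark forest fires; everything else is a
#' maintenance (pasture/cropland) fire.
#'
#' @param min_persistent_days minimum distinct detection days for the
#'   deforestation rule (default 2).
#' @param max_forest_days maximum distinct detection days for the forest
#'   rule (default 3).
#' @param min_defor_rate minimum annual deforestation rate, percent
#'   (default 5).
#' @param min_tree_cover minimum year-2000 tree cover, percent (default 70).
#' @param max_cum_defor maximum cumulative deforestation since 2001,
#'   percent (default 20).
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(min_persistent_days = 2L,
                                      max_forest_days = 3L,
                                      min_defor_rate = 5,
                                      min_tree_cover = 70,
                                      max_cum_defor = 20) {
  th <- list(min_persistent_days = as.integer(min_persistent_days),
             max_forest_days = as.integer(max_forest_days),
             min_defor_rate = min_defor_rate,
             min_tree_cover = min_tree_cover,
             max_cum_defor = max_cum_defor)
  if (th$min_persistent_days < 1L || th$max_forest_days < 1L)
    stop_af("day thresholds must be >= 1")
  pct <- c(th$min_defor_rate, th$min_tree_cover, th$max_cum_defor)
  if (any(pct < 0 | pct > 100))
    stop_af("percentage thresholds must lie in [0, 100]")
  structure(th, class = "classification_thresholds")
}

#' Persistence: distinct detection days per pixel and year
#'
#' Persistence is counted in days, not detections: several same-day
#' detections of one fire (multiple overpasses) count once. Two or more
#' days of fire on a pixel within a year signal repeated burning of piled
#' slash, the signature of active deforestation.
#'
#' @param detections validated detections data frame.
#' @param window `"year"` (calendar-year counting, the default) or
#'   `"season"` to restrict counting to `season_months`.
#' @param season_months months used when `window = "season"`.
#' @return data frame with one row per pixel-year carrying detections:
#'   `pixel_row`, `pixel_col`, `year`, `n_days`, `n_detections`.
#' @export
persistence <- function(detections, window = c("year", "season"),
                        season_months = 7:11) {
  window <- match.arg(window)
  d <- detections
  if (window == "season")
    d <- d[as.integer(format(d$date, "%m")) %in% season_months, ,
           drop = FALSE]
  if (!nrow(d))
    return(data.frame(pixel_row = integer(), pixel_col = integer(),
                      year = integer(), n_days = integer(),
                      n_detections = integer()))
  key <- data.frame(pixel_row = d$pixel_row, pixel_col = d$pixel_col,
                    year = as.integer(format(d$date, "%Y")))
  dup_day <- duplicated(cbind(key, day = d$date))
  agg_n <- stats::aggregate(list(n_detections = rep(1L, nrow(key))),
                            key, FUN = sum)
  agg_d <- stats::aggregate(list(n_days = rep(1L, nrow(key))[!dup_day]),
                            key[!dup_day, ], FUN = sum)
  out <- merge(agg_d, agg_n, sort = TRUE)
  out[order(out$year, out$pixel_row, out$pixel_col), ] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Classify one pixel-year by the persistence + landscape rules
#'
#' Rules are applied in a fixed precedence (deforestation first by
#' default): a pixel-year is a deforestation fire iff it has at least
#' `min_persistent_days` distinct detection days and an annual
#' deforestation rate of at least `min_defor_rate`; otherwise a forest
#' fire iff it has at most `max_forest_days` days, tree cover of at least
#' `min_tree_cover`, and cumulative deforestation of at most
#' `max_cum_defor`; otherwise a maintenance fire. Pixel-years with 2--3
#' detection days can satisfy both the deforestation and forest
#' conditions; precedence resolves the overlap and is configurable for
#' sensitivity analysis.
#'
#' @param n_days distinct detection days (integer >= 1); vectorized.
#' @param defor_rate annual deforestation rate, percent; vectorized.
#' @param tree_cover year-2000 tree cover, percent; vectorized.
#' @param cum_defor cumulative deforestation since 2001, percent.
#' @param thresholds a [classification_thresholds()].
#' @param precedence order in which the deforestation and forest rules are
#'   tried; maintenance is always the residual class.
#' @return character vector of labels.
#' @export
classify_pixel_year <- function(n_days, defor_rate, tree_cover, cum_defor,
                                thresholds = classification_thresholds(),
                                precedence = c("deforestation", "forest")) {
  if (any(n_days < 1L))
    stop_af("n_days must be >= 1 (no-fire pixel-years must not be classified)",
            class = "amazonfire_nofire_error")
  precedence <- match.arg(precedence, c("deforestation", "forest"),
                          several.ok = TRUE)
  th <- thresholds
  is_defor <- n_days >= th$min_persistent_days &
    defor_rate >= th$min_defor_rate
  is_forest <- n_days <= th$max_forest_days &
    tree_cover >= th$min_tree_cover & cum_defor <= th$max_cum_defor
  lab <- rep("maintenance", length(n_days))
  if (precedence[1L] == "deforestation") {
    lab[is_forest] <- "forest"
    lab[is_defor] <- "deforestation"
  } else {
    lab[is_defor] <- "deforestation"
    lab[is_forest] <- "forest"
  }
  lab
}

#' Classify every detection and tabulate annual type counts
#'
#' The unit of classification is the pixel-year (matching the persistence
#' definition): all detections of one pixel in one year share a label.
#'
#' @param detections validated detections data frame.
#' @param landscape a `pixel_landscape` covering every detection pixel.
#' @param thresholds a [classification_thresholds()].
#' @param precedence passed to [classify_pixel_year()].
#' @param window,season_months passed to [persistence()].
#' @param on_missing what to do with detections on pixels lacking landscape
#'   data for their year: `"error"` (default) or `"maintenance"` (label and
#'   warn).
#' @return list with `detections` (input plus `fire_type`), `pixel_years`
#'   (the classified pixel-year table) and `annual_counts` (an
#'   [annual_type_counts()] table).
#' @export
classify_all <- function(detections, landscape,
                         thresholds = classification_thresholds(),
                         precedence = c("deforestation", "forest"),
                         window = "year", season_months = 7:11,
                         on_missing = c("error", "maintenance")) {
  on_missing <- match.arg(on_missing)
  py <- persistence(detections, window = window,
                    season_months = season_months)
  nc <- landscape$grid_cols
  pid <- pixel_id(py$pixel_row, py$pixel_col, nc)
  ycol <- match(as.character(py$year), colnames(landscape$annual_rate))
  in_grid <- py$pixel_row >= 1L & py$pixel_row <= landscape$grid_rows &
    py$pixel_col >= 1L & py$pixel_col <= landscape$grid_cols & !is.na(ycol)
  if (any(!in_grid)) {
    if (on_missing == "error")
      stop_af("%d pixel-year(s) lack landscape records (first: pixel %d,%d year %d)",
              sum(!in_grid), py$pixel_row[!in_grid][1L],
              py$pixel_col[!in_grid][1L], py$year[!in_grid][1L],
              class = "amazonfire_missing_landscape_error")
    warning(sprintf("classify_all: %d pixel-year(s) without landscape labeled maintenance",
                    sum(!in_grid)))
  }
  rate <- cover <- cum <- rep(NA_real_, nrow(py))
  rate[in_grid] <- landscape$annual_rate[cbind(pid[in_grid], ycol[in_grid])]
  cum[in_grid] <- landscape$cum_defor[cbind(pid[in_grid], ycol[in_grid])]
  cover[in_grid] <- landscape$pixels$tree_cover_2000[pid[in_grid]]
  py$fire_type <- "maintenance"
  py$fire_type[in_grid] <- classify_pixel_year(
    py$n_days[in_grid], rate[in_grid], cover[in_grid], cum[in_grid],
    thresholds, precedence)

  dyear <- as.integer(format(detections$date, "%Y"))
  mkey <- paste(detections$pixel_row, detections$pixel_col, dyear)
  pkey <- paste(py$pixel_row, py$pixel_col, py$year)
  det <- detections
  det$fire_type <- py$fire_type[match(mkey, pkey)]
  # detections excluded from a seasonal counting window carry no label
  list(detections = det,
       pixel_years = py,
       annual_counts = annual_type_counts(det, years = landscape$years))
}

#' Annual fire counts, shares, and ratios by type
#'
#' @param labeled_detections detections with a `fire_type` column.
#' @param years years to tabulate (zero-filled when absent from the data);
#'   default: the years present.
#' @return data frame with per-year counts by type, total, percent shares,
#'   and the deforestation:forest and deforestation:maintenance ratios
#'   (percent).
#' @export
annual_type_counts <- function(labeled_detections, years = NULL) {
  d <- labeled_detections[!is.na(labeled_detections$fire_type), ,
                          drop = FALSE]
  yr <- as.integer(format(d$date, "%Y"))
  years <- years %||% sort(unique(yr))
  tab <- table(factor(yr, levels = years),
               factor(d$fire_type, levels = fire_types()))
  out <- data.frame(year = as.integer(years),
                    deforestation = as.numeric(tab[, "deforestation"]),
                    maintenance = as.numeric(tab[, "maintenance"]),
                    forest = as.numeric(tab[, "forest"]))
  out$total <- out$deforestation + out$maintenance + out$forest
  tot <- ifelse(out$total > 0, out$total, NA_real_)
  for (ty in fire_types())
    out[[paste0("share_", ty)]] <- 100 * out[[ty]] / tot
  out$ratio_defor_forest <-
    100 * out$deforestation / ifelse(out$forest > 0, out$forest, NA_real_)
  out$ratio_defor_maintenance <-
    100 * out$deforestation /
    ifelse(out$maintenance > 0, out$maintenance, NA_real_)
  out
}
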