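#' Recompute one year's annual mean [CO] over a shifted 12-month window
#'
#' Used to account for a late-onset fire season: e.g. the 2015 season
#' extended into early 2016, so the 2015 annual mean is recomputed over
#' April 2015 -- March 2016. Only the target year changes; re-applying
#' with the January--December window restores the original value.
#'
#' @param series data frame `year`, `co` (annual means).
#' @param monthly data frame `year`, `month`, `value` of monthly [CO].
#' @param target_year the year whose mean is recomputed.
#' @param start_month first month of the shifted window (in
#'   `target_year`).
#' @param end_month last month; when `end_month < start_month` the window
#'   wraps into `target_year + 1`.
#' @return the series with the target year's value replaced; attribute
#'   `window_adjustments` records the applied windows.
#' @export
window_adjust <- function(series, monthly, target_year,
                          start_month = 4L, end_month = 3L) {
  stopifnot(all(c("year", "co") %in% names(series)),
            all(c("year", "month", "value") %in% names(monthly)))
  if (!target_year %in% series$year)
    stop_af("target year %d not in series", target_year)
  if (end_month >= start_month) {
    want <- data.frame(year = target_year, month = start_month:end_month)
  } else {
    want <- rbind(
      data.frame(year = target_year, month = start_month:12L),
      data.frame(year = target_year + 1L, month = 1L:end_month))
  }
  if (nrow(want) != 12L)
    stop_af("window must span exactly 12 months (got %d)", nrow(want))
  key_m <- paste(monthly$year, monthly$month)
  hit <- match(paste(want$year, want$month), key_m)
  if (anyNA(hit))
    stop_af("missing monthly values: %s",
            paste(sprintf("%d-%02d", want$year[is.na(hit)],
                          want$month[is.na(hit)]), collapse = ", "),
            class = "amazonfire_io_error")
  out <- series
  out$co[out$year == target_year] <- mean(monthly$value[hit])
  adj <- rbind(attr(series, "window_adjustments"),
               data.frame(year = target_year, start_month = start_month,
                          end_month = end_month))
  attr(out, "window_adjustments") <- adj
  out
}

#' Increment-based [CO] reduction sensitivity scan
#'
#' Quantifies how much the anomalously high imported emissions of selected
#' years (2007 and 2010 in the biome analysis, when neighbouring-savanna
#' burning exported CO into the basin) would need to be discounted for the
#' [CO]-on-time trend to become significant. For reductions
#' k = 0, step, 2*step, ... the target years' values are multiplied by
#' (1 - k/100), the OLS regression of [CO] on year is refit, and the
#' smallest k with p < alpha is reported (NA when never reached).
#'
#' @param series data frame `year`, `co`.
#' @param target_years years whose values are reduced (default 2007 and
#'   2010).
#' @param step increment in percent (> 0; default 5).
#' @param alpha significance level (default 0.05).
#' @param max_reduction largest reduction scanned, percent.
#' @return object of class `sensitivity_scan`: `profile` (data frame `k`,
#'   `slope`, `p_value`, `r_squared`), `minimal_reduction` (percent or
#'   NA), `alpha`, `monotone` (whether p decreased weakly along the
#'   profile).
#' @export
sensitivity_scan <- function(series, target_years = c(2007L, 2010L),
                             step = 5, alpha = 0.05, max_reduction = 50) {
  stopifnot(all(c("year", "co") %in% names(series)))
  if (step <= 0) stop_af("step must be > 0")
  if (!all(target_years %in% series$year))
    stop_af("target years outside the series")
  ks <- seq(0, max_reduction, by = step)
  hit <- series$year %in% target_years
  prof <- lapply(ks, function(k) {
    v <- series$co
    v[hit] <- v[hit] * (1 - k / 100)
    f <- ols_regression(series$year, v)
    data.frame(k = k, slope = f$slope, p_value = f$p_value,
               r_squared = f$r_squared)
  })
  prof <- do.call(rbind, prof)
  ok <- prof$k[prof$p_value < alpha]
  structure(list(profile = prof,
                 minimal_reduction = if (length(ok)) min(ok) else NA_real_,
                 target_years = target_years, step = step, alpha = alpha,
                 monotone = !is.unsorted(rev(prof$p_value))),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  if (is.na(x$minimal_reduction)) {
    cat(sprintf("Sensitivity scan: no reduction up to %g%% reaches p < %g\n",
                max(x$profile$k), x$alpha))
  } else {
    row <- x$profile[x$profile$k == x$minimal_reduction, ]
    cat(sprintf("Sensitivity scan: %g%% reduction of %s yields p = %.3g, R^2 = %.2f\n",
                x$minimal_reduction,
                paste(x$target_years, collapse = "/"),
                row$p_value, row$r_squared))
  }
  invisible(x)
}

#' Regression of annual [CO] on annual deforestation rates
#'
#' Delegates to [ols_regression()] with deforestation as the predictor;
#' a significant positive slope ties pyrogenic emissions back to
#' clearing activity.
#'
#' @param co data frame `year`, `co`.
#' @param defor data frame `year`, `defor_km2`.
#' @return an `ols_fit`.
#' @export
co_on_deforestation <- function(co, defor) {
  m <- merge(co[c("year", "co")], defor[c("year", "defor_km2")],
             by = "year")
  if (!nrow(m)) stop_af("no overlapping years between [CO] and deforestation")
  ols_regression(m$defor_km2, m$co)
}
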