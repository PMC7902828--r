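#' Generate synthetic multi-year fire seasons with known ground truth
#'
#' Places active-fire detections on a landscape so that every detection's
#' true type is recoverable by the persistence + landscape rules:
#'
#' * deforestation fires land on `clearing` pixels (annual rate >= 5
#'   percent) as pixel-year clusters with at least 2 distinct detection
#'   days -- slash piles burn repeatedly;
#' * maintenance fires land on `pasture` pixels with exactly 1 detection
#'   day per pixel-year -- light fuels are consumed in one burn;
#' * forest (understory) fires land on `intact` pixels (tree cover >= 70
#'   percent, cumulative deforestation <= 20 percent) with at most 3
#'   distinct days.
#'
#' Expected annual totals follow the configured geometric trend, scaled in
#' drought years by the per-type drought multipliers; realized counts are
#' Poisson around those expectations. FRP values are drawn per type from
#' the configured lognormal parameters, and dates fall within the
#' configured fire-season months.
#'
#' @param config a [synthetic_config()].
#' @param landscape the [generate_landscape()] output for the same config.
#' @return a list with `detections` (data frame: `pixel_row`, `pixel_col`,
#'   `lon`, `lat`, `date`, `frp`, `true_type`) and `truth` (class
#'   `synthetic_truth`: per-detection labels, per-pixel classes, the
#'   injected trend, and per-year expected totals by type).
#' @export
generate_fire_seasons <- function(config, landscape) {
  config <- validate_synthetic_config(config)
  stopifnot(inherits(landscape, "pixel_landscape"))
  if (landscape$grid_rows != config$grid_rows ||
      landscape$grid_cols != config$grid_cols ||
      !identical(landscape$years, config$years))
    stop_af("landscape does not match config (grid or years differ)")
  set.seed(child_seed(config$seed, 2L))

  years <- config$years
  mix <- config$type_mix
  mult <- config$drought_multiplier_by_type
  cls <- landscape$pixels$class
  eligible <- list(deforestation = which(cls == "clearing"),
                   maintenance   = which(cls == "pasture"),
                   forest        = which(cls == "intact"))
  # mean cluster sizes used to convert expected detections into clusters
  mean_size <- c(deforestation = 5, maintenance = 2.5, forest = 3)

  for (ty in fire_types()) {
    if (mix[[ty]] > 0 && length(eligible[[ty]]) == 0L)
      stop_af("no pixel eligible for fire type '%s' (nonzero mix share)",
              ty, class = "amazonfire_infeasible_error")
  }

  expected <- expand.grid(year = years, type = fire_types(),
                          stringsAsFactors = FALSE)
  base <- config$mean_annual_detections *
    (1 + config$annual_trend)^(match(expected$year, years) - 1)
  dm <- ifelse(expected$year %in% config$drought_years,
               mult[expected$type], 1)
  expected$expected_count <- base * mix[expected$type] * dm

  # multiplicative FRP time signal: log-linear decline to the breakpoint
  # year, log-linear rise after it (a V in log intensity)
  frp_mult <- rep(1, length(years))
  if (!is.null(config$frp_breakpoint)) {
    bp <- config$frp_breakpoint
    ch <- config$frp_annual_change
    frp_mult <- exp(ifelse(years <= bp,
                           ch[["pre"]] * (years - years[1L]),
                           ch[["pre"]] * (bp - years[1L]) +
                             ch[["post"]] * (years - bp)))
  }

  out <- vector("list", nrow(expected))
  for (k in seq_len(nrow(expected))) {
    ty <- expected$type[k]; yr <- expected$year[k]
    m <- expected$expected_count[k]
    if (m <= 0) next
    ncl <- stats::rpois(1L, m / mean_size[[ty]])
    if (ncl == 0L) next
    elig <- eligible[[ty]]
    if (ty == "deforestation") {
      px <- elig[sample.int(length(elig), ncl, replace = TRUE)]
      sizes <- 2L + stats::rpois(ncl, 3)
      dmax <- pmin(sizes, 6L)
      ndays <- 2L + floor(stats::runif(ncl) * (dmax - 1L))
    } else {
      if (ncl > length(elig))
        stop_af(paste0("fire season %d saturated: %d %s clusters requested ",
                       "but only %d eligible pixels; enlarge the grid or ",
                       "lower mean_annual_detections"),
                yr, ncl, ty, length(elig),
                class = "amazonfire_saturation_error")
      px <- elig[sample.int(length(elig), ncl, replace = FALSE)]
      if (ty == "maintenance") {
        sizes <- 1L + stats::rpois(ncl, 1.5)
        ndays <- rep(1L, ncl)
      } else {
        sizes <- 1L + stats::rpois(ncl, 2)
        dmax <- pmin(sizes, 3L)
        ndays <- 1L + floor(stats::runif(ncl) * dmax)
      }
    }
    season <- season_days(yr, config$season_months)
    days <- vector("list", ncl)
    for (j in seq_len(ncl))
      days[[j]] <- sort(season[sample.int(length(season), ndays[j])])
    idx <- rep(seq_len(ncl), sizes)
    within <- sequence(sizes)
    # detection i of a cluster burns on day ((i-1) mod n_days)+1, so every
    # sampled day carries at least one detection
    days_vec <- unlist(days)
    day_off <- cumsum(c(0L, ndays))[idx]
    det_day <- days_vec[day_off + ((within - 1L) %% ndays[idx]) + 1L]
    pars <- config$frp_params_by_type[[ty]]
    out[[k]] <- data.frame(
      pixel = px[idx],
      date = as.Date(det_day, origin = "1970-01-01"),
      frp = stats::rlnorm(length(idx), pars[["meanlog"]], pars[["sdlog"]]) *
        frp_mult[match(yr, years)],
      true_type = ty,
      stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(det))
    det <- data.frame(pixel = integer(), date = as.Date(character()),
                      frp = numeric(), true_type = character())
  nc <- config$grid_cols
  det$pixel_row <- ((det$pixel - 1L) %/% nc) + 1L
  det$pixel_col <- ((det$pixel - 1L) %% nc) + 1L
  det$lon <- config$origin_lon + (det$pixel_col - 0.5) * config$cell_deg
  det$lat <- config$origin_lat +
    (config$grid_rows - det$pixel_row + 0.5) * config$cell_deg
  ord <- order(det$date, det$pixel_row, det$pixel_col, det$frp)
  det <- det[ord, c("pixel_row", "pixel_col", "lon", "lat",
                    "date", "frp", "true_type")]
  rownames(det) <- NULL

  truth <- structure(list(
    labels = det$true_type,
    pixel_class = cls,
    injected_trend = config$annual_trend,
    frp_breakpoint = config$frp_breakpoint,
    expected_totals = stats::reshape(
      expected, direction = "wide", idvar = "year",
      timevar = "type", v.names = "expected_count")),
    class = "synthetic_truth")
  names(truth$expected_totals) <- sub("expected_count\\.", "",
                                      names(truth$expected_totals))
  truth$expected_totals$total <- rowSums(truth$expected_totals[fire_types()])
  rownames(truth$expected_totals) <- NULL

  list(detections = det, truth = truth)
}

# all calendar dates of `year` whose month lies in `months`
season_days <- function(year, months) {
  d <- seq(as.Date(sprintf("%d-01-01", year)),
           as.Date(sprintf("%d-12-31", year)), by = "day")
  as.numeric(d[as.integer(format(d, "%m")) %in% months])
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d labeled detections, injected trend %+.1f%%/yr\n",
              length(x$labels), 100 * x$injected_trend))
  print(round(x$expected_totals, 1))
  invisible(x)
}

#' Generate an annual carbon monoxide series coupled to fire totals
#'
#' Emits an annual mean [CO] series (800 hPa level, instrument units carried
#' opaquely) as an affine function of total annual detections plus Gaussian
#' noise: `co = intercept + slope * total + N(0, sd)`. Non-positive draws
#' are resampled so the emitted series is strictly positive.
#'
#' @param config a [synthetic_config()]; `config$co_coupling` supplies
#'   `intercept`, `slope` and `sd`.
#' @param annual_totals data frame with `year` and `total` (detections per
#'   year), or a named numeric vector (names = years).
#' @return an `emission_series` data frame with `year` and `co`.
#' @export
generate_co_series <- function(config, annual_totals) {
  config <- validate_synthetic_config(config)
  if (is.numeric(annual_totals) && !is.null(names(annual_totals)))
    annual_totals <- data.frame(year = as.integer(names(annual_totals)),
                                total = as.numeric(annual_totals))
  stopifnot(is.data.frame(annual_totals),
            all(c("year", "total") %in% names(annual_totals)))
  if (anyDuplicated(annual_totals$year))
    stop_af("annual_totals must have one total per year")
  set.seed(child_seed(config$seed, 3L))
  cc <- config$co_coupling
  n <- nrow(annual_totals)
  co <- cc$intercept + cc$slope * annual_totals$total +
    stats::rnorm(n, 0, cc$sd)
  for (i in which(co <= 0)) {
    tries <- 0L
    while (co[i] <= 0 && tries < 100L) {
      co[i] <- cc$intercept + cc$slope * annual_totals$total[i] +
        stats::rnorm(1L, 0, cc$sd)
      tries <- tries + 1L
    }
    if (co[i] <= 0) co[i] <- .Machine$double.eps
  }
  structure(data.frame(year = annual_totals$year, co = co),
            class = c("emission_series", "data.frame"))
}
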