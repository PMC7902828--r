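#' Configuration for the synthetic Amazon fire-season generator
#'
#' Builds and validates the parameter set used by [generate_landscape()],
#' [generate_fire_seasons()] and [generate_co_series()]. The defaults emulate
#' the study conditions of the Brazilian Amazon biome (BAMZ) analyses:
#' 2003--2019 study years, drought years 2005/2007/2010/2015, a declining
#' multi-year trend in detections, a fire-type mix of 8/39/53 percent for
#' deforestation, maintenance and forest fires, and a heavy-tailed fire
#' radiative power (FRP) distribution for deforestation fires.
#'
#' One root seed drives the generator through fixed child streams (stream 1:
#' landscape, stream 2: fire seasons, stream 3: CO series), so regenerating
#' any product with the same root seed is bit-identical.
#'
#' @param grid_rows,grid_cols grid dimensions; each pixel represents 1 km^2.
#' @param years ordered calendar years of the simulated record.
#' @param seed integer root RNG seed.
#' @param type_mix named fractions (deforestation, maintenance, forest)
#'   summing to 1; expected shares of detections by true fire type.
#' @param mean_annual_detections expected number of detections in the first
#'   year, before trend and drought scaling.
#' @param annual_trend relative change in expected total detections per year
#'   (e.g. -0.08 for an 8 percent annual decline).
#' @param drought_years subset of `years` treated as drought years.
#' @param drought_multiplier_by_type named factors (>= 1) applied to the
#'   expected per-type totals in drought years; droughts amplify forest and
#'   maintenance fires more than deforestation fires.
#' @param frp_params_by_type per-type lognormal parameters `meanlog`,`sdlog`
#'   for FRP (MW); deforestation fires have the heaviest upper tail.
#' @param frp_breakpoint year at which the multiplicative FRP time signal
#'   turns from decline to rise (the fire-intensity V, mirroring the
#'   observed fall of intensity to 2013 and rise after); NULL disables the
#'   temporal FRP signal.
#' @param frp_annual_change named log-scale annual rates `pre`, `post` of
#'   the FRP multiplier before/after `frp_breakpoint`.
#' @param tree_cover_mix fractions of high-cover (>= 70 percent tree cover in
#'   2000) versus low-cover pixels.
#' @param defor_front_fraction fraction of pixels undergoing active clearing
#'   (annual deforestation rate >= 5 percent) in any given year.
#' @param co_coupling list with `intercept`, `slope`, `sd` linking annual
#'   mean carbon monoxide concentration at 800 hPa to total detections.
#' @param season_months months (integers) of the fire season within which
#'   detection dates are drawn; default July--November (dry season).
#' @param origin_lon,origin_lat,cell_deg geographic anchoring of the grid
#'   (lower-left corner and cell size in degrees), used only to attach
#'   plausible lon/lat values to detections.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(grid_rows = 60L,
                             grid_cols = 60L,
                             years = 2003:2019,
                             seed = 1L,
                             type_mix = c(deforestation = 0.08,
                                          maintenance  = 0.39,
                                          forest       = 0.53),
                             mean_annual_detections = 2000,
                             annual_trend = -0.08,
                             drought_years = c(2005L, 2007L, 2010L, 2015L),
                             drought_multiplier_by_type =
                               c(deforestation = 1.1,
                                 maintenance  = 1.8,
                                 forest       = 2.2),
                             frp_params_by_type = list(
                               deforestation = c(meanlog = log(20), sdlog = 1.2),
                               maintenance   = c(meanlog = log(12), sdlog = 0.7),
                               forest        = c(meanlog = log(10), sdlog = 0.7)),
                             frp_breakpoint = 2013L,
                             frp_annual_change = c(pre = -0.05, post = 0.05),
                             tree_cover_mix = c(high = 0.55, low = 0.45),
                             defor_front_fraction = 0.02,
                             co_coupling = list(intercept = 80,
                                                slope = 0.004,
                                                sd = 2),
                             season_months = 7:11,
                             origin_lon = -73,
                             origin_lat = -13,
                             cell_deg = 0.01) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              years = assert_years(years),
              seed = seed,
              type_mix = type_mix,
              mean_annual_detections = mean_annual_detections,
              annual_trend = annual_trend,
              drought_years = as.integer(drought_years),
              drought_multiplier_by_type = drought_multiplier_by_type,
              frp_params_by_type = frp_params_by_type,
              frp_breakpoint = if (is.null(frp_breakpoint)) NULL
                               else as.integer(frp_breakpoint),
              frp_annual_change = frp_annual_change,
              tree_cover_mix = tree_cover_mix,
              defor_front_fraction = defor_front_fraction,
              co_coupling = co_coupling,
              season_months = as.integer(season_months),
              origin_lon = origin_lon, origin_lat = origin_lat,
              cell_deg = cell_deg)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

fire_types <- function() c("deforestation", "maintenance", "forest")

#' @rdname synthetic_config
#' @param cfg a `synthetic_config` object to validate.
#' @export
validate_synthetic_config <- function(cfg) {
  if (cfg$grid_rows < 1L || cfg$grid_cols < 1L)
    stop_af("grid dimensions must be positive (got %d x %d)",
            cfg$grid_rows, cfg$grid_cols, class = "amazonfire_dim_error")
  if (cfg$grid_rows * cfg$grid_cols < 4L)
    stop_af("grid must have at least 4 pixels",
            class = "amazonfire_dim_error")
  ty <- fire_types()
  if (!all(ty %in% names(cfg$type_mix)))
    stop_af("type_mix must be named with %s", paste(ty, collapse = ", "))
  cfg$type_mix <- cfg$type_mix[ty]
  if (any(cfg$type_mix < 0) || abs(sum(cfg$type_mix) - 1) > 1e-12)
    stop_af("type_mix must be nonnegative and sum to 1 (got %.15f)",
            sum(cfg$type_mix))
  if (!all(ty %in% names(cfg$drought_multiplier_by_type)))
    stop_af("drought_multiplier_by_type must be named with %s",
            paste(ty, collapse = ", "))
  cfg$drought_multiplier_by_type <- cfg$drought_multiplier_by_type[ty]
  if (any(cfg$drought_multiplier_by_type < 1))
    stop_af("drought multipliers must all be >= 1")
  if (!all(ty %in% names(cfg$frp_params_by_type)))
    stop_af("frp_params_by_type must be named with %s",
            paste(ty, collapse = ", "))
  if (length(cfg$tree_cover_mix) != 2L || any(cfg$tree_cover_mix < 0) ||
      abs(sum(cfg$tree_cover_mix) - 1) > 1e-12)
    stop_af("tree_cover_mix must be two nonnegative fractions summing to 1")
  if (cfg$defor_front_fraction < 0 || cfg$defor_front_fraction > 1)
    stop_af("defor_front_fraction must be in [0, 1]")
  if (!all(cfg$drought_years %in% cfg$years))
    stop_af("drought_years must be a subset of years")
  if (!all(cfg$season_months %in% 1:12))
    stop_af("season_months must be calendar months 1..12")
  if (!is.null(cfg$frp_breakpoint)) {
    if (!cfg$frp_breakpoint %in% cfg$years)
      stop_af("frp_breakpoint must be one of the study years")
    if (!all(c("pre", "post") %in% names(cfg$frp_annual_change)))
      stop_af("frp_annual_change must be named 'pre' and 'post'")
  }
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic Amazon fire-season configuration\n")
  cat(sprintf("  grid: %d x %d pixels (1 km), years %d-%d\n",
              x$grid_rows, x$grid_cols, min(x$years), max(x$years)))
  cat(sprintf("  type mix: %s\n",
              paste(sprintf("%s %.0f%%", names(x$type_mix),
                            100 * x$type_mix), collapse = ", ")))
  cat(sprintf("  annual trend: %+.1f%%/yr; drought years: %s\n",
              100 * x$annual_trend,
              paste(x$drought_years, collapse = ", ")))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}
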