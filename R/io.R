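#' Grid specification for the 1-km fire grid
#'
#' Defines the study grid onto which detections and land products are
#' placed. Indexing is 1-based and row-major with row 1 at the northern
#' edge; cell membership is half-open, so a coordinate on a cell's
#' western/southern edge belongs to that cell.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param origin_lon,origin_lat lower-left corner, degrees.
#' @param cell_deg cell size in degrees.
#' @param crs free-text CRS name (carried as metadata only).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(grid_rows, grid_cols, origin_lon = -73,
                      origin_lat = -13, cell_deg = 0.01,
                      crs = "EPSG:4326") {
  if (grid_rows < 1 || grid_cols < 1)
    stop_af("grid dimensions must be positive",
            class = "amazonfire_dim_error")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_deg = cell_deg, crs = crs), class = "grid_spec")
}

grid_spec_from_config <- function(config) {
  grid_spec(config$grid_rows, config$grid_cols, config$origin_lon,
            config$origin_lat, config$cell_deg)
}

lonlat_to_index <- function(lon, lat, gs) {
  col <- floor((lon - gs$origin_lon) / gs$cell_deg) + 1L
  row <- gs$grid_rows - floor((lat - gs$origin_lat) / gs$cell_deg)
  list(row = as.integer(row), col = as.integer(col))
}

#' Read an active-fire detection table
#'
#' Reads a CSV of detections (columns `pixel_row`/`pixel_col` or
#' `lon`/`lat`, `date` in ISO-8601, `frp` in MW; extra columns are
#' preserved), validates every record, and converts lon/lat to grid
#' indices when indices are absent. Invalid rows -- negative FRP,
#' unparseable dates, coordinates outside the grid extent -- are rejected
#' and counted in the `n_rejected` attribute. Missing FRP is allowed:
#' those detections are retained for counting and excluded from FRP
#' analyses downstream.
#'
#' @param path CSV path.
#' @param grid_spec a [grid_spec()]; required when only lon/lat are given,
#'   used for bounds checking otherwise.
#' @param study_years optional year range; detections outside it are
#'   rejected.
#' @return validated detections data frame with attributes `n_rejected`
#'   and `grid_spec`.
#' @export
read_detections <- function(path, grid_spec = NULL, study_years = NULL) {
  if (!file.exists(path))
    stop_af("detection file not found: %s", path,
            class = "amazonfire_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_idx <- all(c("pixel_row", "pixel_col") %in% names(df))
  has_ll <- all(c("lon", "lat") %in% names(df))
  if (!has_idx && !has_ll)
    stop_af("schema error in %s: need pixel_row/pixel_col or lon/lat", path,
            class = "amazonfire_schema_error")
  if (!"date" %in% names(df))
    stop_af("schema error in %s: missing column 'date'", path,
            class = "amazonfire_schema_error")
  df$date <- as.Date(df$date)
  if (!"frp" %in% names(df)) df$frp <- NA_real_
  df$frp <- as.numeric(df$frp)
  if (!has_idx) {
    if (is.null(grid_spec))
      stop_af("grid_spec required to convert lon/lat to grid indices")
    ix <- lonlat_to_index(df$lon, df$lat, grid_spec)
    df$pixel_row <- ix$row; df$pixel_col <- ix$col
  }
  bad <- is.na(df$date) | (!is.na(df$frp) & df$frp < 0)
  if (!is.null(grid_spec))
    bad <- bad | df$pixel_row < 1L | df$pixel_row > grid_spec$grid_rows |
      df$pixel_col < 1L | df$pixel_col > grid_spec$grid_cols |
      is.na(df$pixel_row) | is.na(df$pixel_col)
  if (!is.null(study_years))
    bad <- bad | !(as.integer(format(df$date, "%Y")) %in% study_years)
  n_rej <- sum(bad, na.rm = TRUE)
  if (n_rej > 0)
    message(sprintf("read_detections: rejected %d invalid row(s)", n_rej))
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rej
  attr(df, "grid_spec") <- grid_spec
  df
}

#' Write detections to CSV
#'
#' Columns: `pixel_row`, `pixel_col`, `lon`, `lat`, `date` (ISO-8601),
#' `frp_mw`, plus `fire_type`/`true_type` when present. [read_detections()]
#' of the written file round-trips the collection.
#'
#' @param detections detections data frame.
#' @param path output CSV path.
#' @export
write_detections <- function(detections, path) {
  out <- detections
  names(out)[names(out) == "frp"] <- "frp_mw"
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# read back the dialect written by write_detections
#' @rdname write_detections
#' @inheritParams read_detections
#' @export
read_detections_csv <- function(path, grid_spec = NULL) {
  df <- read_detections(path, grid_spec)
  names(df)[names(df) == "frp_mw"] <- "frp"
  df
}

#' Aggregate a fine-resolution raster to the 1-km fire grid
#'
#' Block-aggregates a fine matrix (e.g. 30-m tree cover) whose resolution
#' divides the coarse cell evenly. Each coarse cell is the statistic of its
#' covered fine cells, excluding nodata (`NA`); cells whose fine block is
#' entirely nodata are masked (`NA`).
#'
#' @param fine numeric matrix; `NA` is nodata.
#' @param factor integer block size: each coarse cell covers
#'   `factor x factor` fine cells.
#' @param statistic `"mean"` or `"fraction_above"`.
#' @param threshold required for `fraction_above`: the fraction of valid
#'   fine cells strictly above this value.
#' @return coarse matrix of dimension `dim(fine)/factor`.
#' @export
aggregate_to_grid <- function(fine, factor,
                              statistic = c("mean", "fraction_above"),
                              threshold = NULL) {
  statistic <- match.arg(statistic)
  factor <- as.integer(factor)
  if (factor < 1L) stop_af("aggregation factor must be >= 1")
  if (nrow(fine) %% factor != 0L || ncol(fine) %% factor != 0L)
    stop_af("fine raster (%d x %d) is not divisible by factor %d",
            nrow(fine), ncol(fine), factor,
            class = "amazonfire_dim_error")
  if (statistic == "fraction_above" && is.null(threshold))
    stop_af("threshold required for statistic = 'fraction_above'")
  nr <- nrow(fine) %/% factor; nc <- ncol(fine) %/% factor
  f <- if (statistic == "mean") identity else function(v) v > threshold
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- fine[((i - 1L) * factor + 1L):(i * factor),
                  ((j - 1L) * factor + 1L):(j * factor)]
    v <- block[!is.na(block)]
    if (length(v)) out[i, j] <- mean(f(v))
  }
  out
}

#' Rasterize detection counts onto the grid for one year
#'
#' Cell value is the number of detections in that pixel and year or, with
#' `distinct_days = TRUE`, the number of distinct detection days -- the
#' persistence count used by the fire-type rules (same-day multi-overpass
#' detections collapse to one day).
#'
#' @param detections validated detections data frame.
#' @param year calendar year to rasterize.
#' @param grid a [grid_spec()] or any object with `grid_rows`/`grid_cols`.
#' @param distinct_days count distinct days instead of raw detections.
#' @return numeric matrix `grid_rows x grid_cols` with attribute `year`.
#' @export
rasterize_counts <- function(detections, year, grid, distinct_days = FALSE) {
  nr <- grid$grid_rows; nc <- grid$grid_cols
  yr <- as.integer(format(detections$date, "%Y"))
  d <- detections[yr == year, , drop = FALSE]
  m <- matrix(0, nr, nc)
  if (nrow(d)) {
    if (distinct_days)
      d <- d[!duplicated(d[c("pixel_row", "pixel_col", "date")]), ,
             drop = FALSE]
    tab <- table(factor(pixel_id(d$pixel_row, d$pixel_col, nc),
                        levels = seq_len(nr * nc)))
    m <- matrix(as.numeric(tab), nr, nc, byrow = TRUE)
  }
  attr(m, "year") <- year
  m
}

#' Stack annual count grids into a years x pixels array
#'
#' @inheritParams rasterize_counts
#' @param years years to stack (one grid per year).
#' @return 3-D array `[grid_rows, grid_cols, years]` with year dimnames.
#' @export
count_stack <- function(detections, years, grid, distinct_days = FALSE) {
  arr <- array(0, dim = c(grid$grid_rows, grid$grid_cols, length(years)),
               dimnames = list(NULL, NULL, as.character(years)))
  for (i in seq_along(years))
    arr[, , i] <- rasterize_counts(detections, years[i], grid, distinct_days)
  arr
}

#' Write / read a pixel landscape as plain CSV
#'
#' The landscape dialect is one row per pixel with `tree_cover_2000`,
#' `class`, and wide per-year columns `rate_<year>` and `cum_<year>`
#' (percent). This keeps the product in a text format any consumer can
#' verify without the package.
#'
#' @param landscape a `pixel_landscape`.
#' @param path CSV path.
#' @export
write_landscape <- function(landscape, path) {
  wide <- cbind(landscape$pixels,
                stats::setNames(as.data.frame(landscape$annual_rate),
                                paste0("rate_", landscape$years)),
                stats::setNames(as.data.frame(landscape$cum_defor),
                                paste0("cum_", landscape$years)))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  if (!file.exists(path))
    stop_af("landscape file not found: %s", path,
            class = "amazonfire_io_error")
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  rate_cols <- grep("^rate_", names(wide), value = TRUE)
  cum_cols <- grep("^cum_", names(wide), value = TRUE)
  years <- as.integer(sub("rate_", "", rate_cols))
  nr <- max(wide$pixel_row); nc <- max(wide$pixel_col)
  ord <- order(pixel_id(wide$pixel_row, wide$pixel_col, nc))
  wide <- wide[ord, ]
  structure(list(
    grid_rows = nr, grid_cols = nc, years = years,
    pixels = wide[c("pixel_row", "pixel_col", "tree_cover_2000", "class")],
    annual_rate = stats::setNames(as.matrix(wide[rate_cols]), NULL) |>
      `dimnames<-`(list(NULL, as.character(years))),
    cum_defor = stats::setNames(as.matrix(wide[cum_cols]), NULL) |>
      `dimnames<-`(list(NULL, as.character(years)))),
    class = "pixel_landscape")
}
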