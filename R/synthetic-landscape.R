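#' Generate a synthetic deforestation landscape
#'
#' Builds the per-pixel landscape inputs that the fire-type classifier
#' consumes: tree cover in the year 2000, annual deforestation rates, and
#' cumulative deforestation from 2001. Pixels fall into exactly one stratum:
#'
#' * `clearing`: an active deforestation front; each such pixel clears at an
#'   annual rate >= 5 percent in every study year (drawn once per pixel and
#'   bounded so cumulative deforestation stays <= 100 percent).
#' * `intact`: no clearing, tree cover drawn from the high-cover stratum
#'   (>= 70 percent), cumulative deforestation 0 -- eligible for forest
#'   (understory) fires.
#' * `pasture`: no clearing, low tree cover (< 70 percent) -- eligible for
#'   maintenance fires.
#'
#' Membership in the clearing stratum is an independent Bernoulli draw with
#' probability `defor_front_fraction`, so the per-year fraction of pixels
#' with rate >= 5 percent matches that parameter up to binomial noise.
#' Tree cover of non-clearing pixels follows `tree_cover_mix`; clearing
#' pixels also draw their cover from the same mix (their classification never
#' depends on it, because persistent fire on a >= 5 percent clearing rate
#' dominates the rule order).
#'
#' @param config a [synthetic_config()] object.
#' @return an object of class `pixel_landscape`: a list with `grid_rows`,
#'   `grid_cols`, `years`, a `pixels` data frame (`pixel_row`, `pixel_col`,
#'   `tree_cover_2000`, `class`), and matrices `annual_rate` and `cum_defor`
#'   (pixels x years, percent).
#' @export
generate_landscape <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(child_seed(config$seed, 1L))
  nr <- config$grid_rows; nc <- config$grid_cols
  npix <- nr * nc
  ny <- length(config$years)

  front <- stats::runif(npix) < config$defor_front_fraction
  high  <- stats::runif(npix) < config$tree_cover_mix[[1L]]
  cover <- ifelse(high, stats::runif(npix, 70, 100), stats::runif(npix, 0, 60))

  cls <- ifelse(front, "clearing", ifelse(high, "intact", "pasture"))

  annual_rate <- matrix(0, npix, ny,
                        dimnames = list(NULL, as.character(config$years)))
  if (any(front)) {
    # per pixel-year clearing rates: >= 5% every study year (the front is
    # persistently active) and bounded so cumulative clearing stays <= 100%
    upper <- max(5 + 1e-9, min(15, 100 / ny))
    annual_rate[front, ] <- stats::runif(sum(front) * ny, 5, upper)
  }
  cum <- t(apply(annual_rate, 1L, cumsum))
  if (ny == 1L) cum <- matrix(annual_rate, npix, 1L)
  cum <- pmin(cum, 100)
  dimnames(cum) <- dimnames(annual_rate)

  structure(list(
    grid_rows = nr, grid_cols = nc, years = config$years,
    pixels = data.frame(
      pixel_row = rep(seq_len(nr), each = nc),
      pixel_col = rep(seq_len(nc), times = nr),
      tree_cover_2000 = cover,
      class = cls,
      stringsAsFactors = FALSE),
    annual_rate = annual_rate,
    cum_defor = cum), class = "pixel_landscape")
}

# linear pixel id used throughout: row-major, 1-based
pixel_id <- function(row, col, grid_cols) (row - 1L) * grid_cols + col

#' @export
print.pixel_landscape <- function(x, ...) {
  tab <- table(x$pixels$class)
  cat(sprintf("Pixel landscape: %d x %d km grid, years %d-%d\n",
              x$grid_rows, x$grid_cols, min(x$years), max(x$years)))
  cat("  strata:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Annual biome-level deforestation series implied by a landscape
#'
#' Sums per-pixel annual deforestation fractions into a km^2-per-year series
#' (each pixel is 1 km^2, so a rate of 5 percent contributes 0.05 km^2).
#'
#' @param landscape a `pixel_landscape`.
#' @return data frame with `year` and `defor_km2`.
#' @export
landscape_defor_series <- function(landscape) {
  data.frame(year = landscape$years,
             defor_km2 = as.numeric(colSums(landscape$annual_rate) / 100))
}
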