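#' Standardize annual count grids into per-pixel anomaly fields
#'
#' For every pixel, subtracts the reference-period mean of annual fire
#' counts and divides by the reference-period standard deviation, yielding
#' z-score fields. Pixels whose reference series has zero variance
#' (including pixels with no fire in any reference year) are masked and
#' counted; they cannot carry an anomaly.
#'
#' @param stack 3-D array `[rows, cols, years]` from [count_stack()], with
#'   year dimnames.
#' @param reference_years years defining the climatology (default: all
#'   years in the stack; at least 2).
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return object of class `anomaly_fields`: `z` (same shape as `stack`),
#'   `mask` (logical rows x cols, TRUE = valid), `years`,
#'   `n_zero_variance`.
#' @export
standardize <- function(stack, reference_years = NULL,
                        sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  years <- as.integer(dimnames(stack)[[3L]])
  reference_years <- reference_years %||% years
  if (!all(reference_years %in% years))
    stop_af("reference window %d-%d outside the stacked years",
            min(reference_years), max(reference_years))
  if (length(reference_years) < 2L)
    stop_af("need at least 2 reference years")
  ref <- stack[, , as.character(reference_years), drop = FALSE]
  mu <- apply(ref, c(1L, 2L), mean)
  sdv <- apply(ref, c(1L, 2L), stats::sd)
  if (sd_denominator == "population") {
    nref <- length(reference_years)
    sdv <- sdv * sqrt((nref - 1) / nref)
  }
  mask <- is.finite(sdv) & sdv > 0
  z <- stack
  for (k in seq_along(years)) {
    zi <- (stack[, , k] - mu) / sdv
    zi[!mask] <- NA_real_
    z[, , k] <- zi
  }
  structure(list(z = z, mask = mask, years = years,
                 reference_years = as.integer(reference_years),
                 n_zero_variance = sum(!mask)),
            class = "anomaly_fields")
}

#' Percent of area with anomalies above a threshold, per year
#'
#' The fire-season severity index: the share of valid area whose
#' standardized annual fire count strictly exceeds `threshold` standard
#' deviations. Because the reference denominator is ambiguous in
#' biome-scale work, two percentages are reported side by side: over the
#' valid (fire-varying) pixels and over the whole grid.
#'
#' @param fields an `anomaly_fields` object from [standardize()].
#' @param threshold exceedance threshold in SD units (> 0; default 2).
#' @return an `extent_series` data frame: `year`, `n_exceed`, `n_valid`,
#'   `percent` (of valid pixels), `percent_of_grid`.
#' @export
extent_above <- function(fields, threshold = 2) {
  stopifnot(inherits(fields, "anomaly_fields"))
  if (threshold <= 0) stop_af("threshold must be > 0")
  nvalid <- sum(fields$mask)
  if (nvalid == 0L)
    stop_af("no valid pixels (all zero-variance)",
            class = "amazonfire_degenerate_error")
  ngrid <- length(fields$mask)
  n_ex <- vapply(seq_along(fields$years), function(k)
    sum(fields$z[, , k][fields$mask] > threshold), numeric(1))
  structure(data.frame(year = fields$years, n_exceed = n_ex,
                       n_valid = nvalid,
                       percent = 100 * n_ex / nvalid,
                       percent_of_grid = 100 * n_ex / ngrid),
            class = c("extent_series", "data.frame"))
}
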