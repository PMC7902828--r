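# shared fixtures and small independent oracles

# a small, fast study configuration (same study conditions, smaller grid)
small_config <- function(seed = 1, ...) {
  synthetic_config(grid_rows = 40L, grid_cols = 40L,
                   mean_annual_detections = 800, seed = seed, ...)
}

# flat-trend configuration used for drought-effect isolation: the
# generator's deforestation front is constant across years, so the
# matched condition for ratio-separation checks is a flat count trend
drought_iso_config <- function(seed = 1, ...) {
  synthetic_config(grid_rows = 30L, grid_cols = 30L,
                   mean_annual_detections = 400,
                   annual_trend = 0,
                   drought_multiplier_by_type =
                     c(deforestation = 1, maintenance = 1.8, forest = 2.2),
                   frp_breakpoint = NULL,
                   seed = seed, ...)
}

# brute-force Mann-Kendall S statistic
brute_S <- function(v) {
  n <- length(v); s <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    s <- s + sign(v[j] - v[i])
  s
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exact two-tailed MK p by full enumeration over orderings of the values
enum_mk_p <- function(v) {
  n <- length(v)
  P <- all_perms(n)
  s_obs <- brute_S(v)
  s_all <- apply(P, 1L, function(p) brute_S(v[p]))
  mean(abs(s_all) >= abs(s_obs))
}

# detections data frame builder for hand-made cases
make_det <- function(row, col, date, frp = 10) {
  data.frame(pixel_row = row, pixel_col = col,
             lon = NA_real_, lat = NA_real_,
             date = as.Date(date), frp = frp)
}

# hand-rolled landscape with explicit per-pixel values (single stratum set)
make_landscape <- function(grid_rows, grid_cols, years, tree_cover,
                           rate, cum, class = "manual") {
  npix <- grid_rows * grid_cols
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols, years = as.integer(years),
    pixels = data.frame(
      pixel_row = rep(seq_len(grid_rows), each = grid_cols),
      pixel_col = rep(seq_len(grid_cols), times = grid_rows),
      tree_cover_2000 = rep_len(tree_cover, npix),
      class = rep_len(class, npix)),
    annual_rate = matrix(rep_len(rate, npix * length(years)), npix,
                         length(years),
                         dimnames = list(NULL, as.character(years))),
    cum_defor = matrix(rep_len(cum, npix * length(years)), npix,
                       length(years),
                       dimnames = list(NULL, as.character(years)))),
    class = "pixel_landscape")
}

# wrap a years x pixels matrix as anomaly fields on an r x c grid
as_fields <- function(X, grid_rows, grid_cols, years,
                      mask = matrix(TRUE, grid_rows, grid_cols)) {
  stopifnot(nrow(X) == length(years), ncol(X) == sum(mask))
  z <- array(NA_real_, c(grid_rows, grid_cols, length(years)),
             dimnames = list(NULL, NULL, as.character(years)))
  for (k in seq_along(years)) {
    m <- matrix(NA_real_, grid_rows, grid_cols)
    m[mask] <- X[k, ]
    z[, , k] <- m
  }
  structure(list(z = z, mask = mask, years = as.integer(years),
                 reference_years = as.integer(years),
                 n_zero_variance = sum(!mask)),
            class = "anomaly_fields")
}

# [CO]-style series where the minimal significant reduction of the target
# years is a chosen multiple of `step`: the boundary inflation `delta` is
# found by inverting the closed-form OLS t-test (via uniroot on its
# p-value) so that reducing the inflated years by `k_lo` stays above
# alpha while `k_hi = k_lo + step` crosses below it.
make_sensitivity_fixture <- function(years = 2003:2015,
                                     target_years = c(2007L, 2010L),
                                     alpha = 0.05, step = 5,
                                     k_lo = 5, k_hi = 10) {
  base <- 120 - 1.2 * (years - years[1L])
  resid <- rep(c(3, -4, 2, -1, 4, -3, 1), length.out = length(years))
  hit <- years %in% target_years
  p_at <- function(delta, k) {
    v <- base + resid
    v[hit] <- (v[hit] + delta) * (1 - k / 100)
    ols_regression(years, v)$p_value
  }
  # inflating the target years weakens the downward trend, raising p
  d_lo <- stats::uniroot(function(d) p_at(d, k_lo) - alpha,
                         c(0, 200))$root   # p(k_lo) = alpha at d_lo
  d_hi <- stats::uniroot(function(d) p_at(d, k_hi) - alpha,
                         c(0, 200))$root   # p(k_hi) = alpha at d_hi
  delta <- (d_lo + d_hi) / 2               # p(k_lo) > alpha > p(k_hi)
  stopifnot(p_at(delta, k_lo) > alpha, p_at(delta, k_hi) < alpha)
  v <- base + resid
  v[hit] <- v[hit] + delta
  data.frame(year = years, co = v)
}
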