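#' Two-tailed Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test on an annual series. The statistic is
#' `S = sum_{i<j} sign(x_j - x_i)`; its null variance uses the standard
#' tie correction, the normalized statistic applies the +/-1 continuity
#' correction, and the two-tailed p-value comes from the normal
#' approximation. For tie-free series up to n = 25 the exact permutation
#' p-value `P(|S| >= |s_obs|)` is also computed via the inversion-count
#' distribution and, when available, drives the significance flag (an
#' exact test at typical study-series lengths).
#'
#' @param years ordered time points (no duplicates).
#' @param values series values, same length.
#' @param alpha two-tailed significance level (0.01 for the fire-count
#'   trend convention, 0.05 elsewhere).
#' @return object of class `mk_test`: `S`, `var_S`, `z`, `p_value`
#'   (normal), `p_exact` (NA when unavailable), `alpha`, `significant`,
#'   `degenerate`, `n`.
#' @export
mann_kendall <- function(years, values, alpha = 0.05) {
  stopifnot(length(years) == length(values))
  if (anyDuplicated(years)) stop_af("duplicate years in series")
  n <- length(values)
  if (n < 2L) stop_af("Mann-Kendall needs n >= 2")
  values <- values[order(years)]
  S <- 0L
  for (i in seq_len(n - 1L))
    S <- S + sum(sign(values[(i + 1L):n] - values[i]))
  ties <- table(values)
  tp <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tp * (tp - 1) * (2 * tp + 5))) / 18
  degenerate <- var_S <= 0
  z <- if (degenerate || S == 0) 0 else (S - sign(S)) / sqrt(var_S)
  p <- if (degenerate) 1 else 2 * (1 - stats::pnorm(abs(z)))
  p <- min(p, 1)
  p_exact <- NA_real_
  if (n <= 25L && length(tp) == 0L)   # enumeration distribution is cheap here
    p_exact <- mk_exact_p(S, n)
  if (degenerate) p_exact <- 1
  structure(list(S = S, var_S = var_S, z = z, p_value = p,
                 p_exact = p_exact, alpha = alpha,
                 significant = (if (is.na(p_exact)) p else p_exact) < alpha,
                 degenerate = degenerate, n = n),
            class = "mk_test")
}

# Exact two-tailed p for tie-free data: P(|S| >= |s|) under uniform random
# orderings. The null distribution of S follows from the inversion-count
# generating polynomial prod_{j=1}^{n-1} (1 + x + ... + x^j); a permutation
# with k inversions has S = n(n-1)/2 - 2k.
mk_exact_p <- function(S, n) {
  N <- n * (n - 1) / 2
  counts <- 1
  for (j in seq_len(n - 1L)) {
    new <- numeric(length(counts) + j)
    for (i in 0:j)
      new[seq_along(counts) + i] <- new[seq_along(counts) + i] + counts
    counts <- new                   # counts[k+1] = #perms with k inversions
  }
  s_vals <- N - 2 * (seq_along(counts) - 1L)
  sum(counts[abs(s_vals) >= abs(S)]) / sum(counts)
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d, z = %.3f, p = %.4g%s (n = %d)\n",
              x$S, x$z, x$p_value,
              if (!is.na(x$p_exact)) sprintf(" [exact %.4g]", x$p_exact)
              else "", x$n))
  cat(sprintf("  %s at alpha = %g%s\n",
              if (x$significant) "significant" else "not significant",
              x$alpha, if (x$degenerate) " (degenerate series)" else ""))
  invisible(x)
}

#' Theil-Sen robust slope
#'
#' Slope is the median of all pairwise slopes `(x_j - x_i)/(t_j - t_i)`,
#' `i < j`; the intercept follows the `median(y - slope * t)` convention.
#' Rank-based confidence limits for the slope (default 95 percent) are
#' reported using the Mann-Kendall variance.
#'
#' @inheritParams mann_kendall
#' @param conf confidence level for the slope limits.
#' @return object of class `sen_slope`: `slope`, `intercept`, `lower`,
#'   `upper`, `conf`, `n`.
#' @export
theil_sen <- function(years, values, conf = 0.95) {
  stopifnot(length(years) == length(values))
  if (anyDuplicated(years)) stop_af("duplicate years in series")
  n <- length(values)
  if (n < 2L) stop_af("Theil-Sen needs n >= 2")
  o <- order(years); t <- as.numeric(years[o]); y <- values[o]
  ij <- utils::combn(n, 2L)
  slopes <- (y[ij[2L, ]] - y[ij[1L, ]]) / (t[ij[2L, ]] - t[ij[1L, ]])
  slope <- stats::median(slopes)
  intercept <- stats::median(y - slope * t)
  ties <- table(y); tp <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tp * (tp - 1) * (2 * tp + 5))) / 18
  ss <- sort(slopes); Np <- length(ss)
  C <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(var_S)
  lo <- max(1L, floor((Np - C) / 2))
  hi <- min(Np, ceiling((Np + C) / 2) + 1L)
  structure(list(slope = slope, intercept = intercept,
                 lower = ss[lo], upper = ss[hi], conf = conf, n = n),
            class = "sen_slope")
}

#' @export
print.sen_slope <- function(x, ...) {
  cat(sprintf("Theil-Sen slope: %.6g per year (%.0f%% limits %.6g to %.6g, n = %d)\n",
              x$slope, 100 * x$conf, x$lower, x$upper, x$n))
  invisible(x)
}

#' Ordinary least-squares regression with R-squared and p-value
#'
#' Thin wrapper over [stats::lm()] reporting the slope, intercept,
#' `R^2 = 1 - SSE/SST` and the two-sided t-test p-value on the slope --
#' the reporting convention used throughout the decoupling diagnostics.
#'
#' @param x,y equal-length numeric vectors (n >= 3 for a p-value).
#' @return object of class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, and the residuals.
#' @export
ols_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_af("OLS needs n >= 3")
  if (stats::var(x) == 0)
    stop_af("zero variance in x; slope undefined",
            class = "amazonfire_degenerate_error")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n = n, residuals = unname(stats::resid(fit))),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: slope %.6g, intercept %.6g, R^2 = %.3f, p = %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Annual fires per square kilometre deforested
#'
#' The decoupling index: the ratio of annual active-fire counts to annual
#' deforested area. High values flag fire activity beyond what clearing
#' alone explains.
#'
#' @param fires data frame with `year` and `total` (counts).
#' @param defor data frame with `year` and `defor_km2` (km^2/yr, > 0).
#' @return data frame `year`, `fires_per_km2`.
#' @export
fires_per_area_ratio <- function(fires, defor) {
  m <- merge(fires[c("year", "total")], defor[c("year", "defor_km2")],
             by = "year")
  if (nrow(m) != nrow(fires) || nrow(m) != nrow(defor))
    stop_af("fires and deforestation series have mismatched years")
  bad <- which(m$defor_km2 <= 0)
  if (length(bad))
    stop_af("non-positive deforested area in year %d", m$year[bad[1L]],
            class = "amazonfire_degenerate_error")
  data.frame(year = m$year, fires_per_km2 = m$total / m$defor_km2)
}

#' PPCDAm policy phases
#'
#' The deforestation-control plan phases used to stratify the
#' fire-deforestation regressions: I 2004-2008, II 2009-2011,
#' III 2012-2015, IV 2016-2019.
#'
#' @param include_iv include Phase IV (study-period extension).
#' @return data frame with `name`, `start`, `end`.
#' @export
ppcdam_phases <- function(include_iv = TRUE) {
  ph <- data.frame(name = c("I", "II", "III", "IV"),
                   start = c(2004L, 2009L, 2012L, 2016L),
                   end = c(2008L, 2011L, 2015L, 2019L),
                   stringsAsFactors = FALSE)
  if (!include_iv) ph <- ph[ph$name != "IV", ]
  ph
}

#' Fire-deforestation regressions per policy phase
#'
#' Regresses annual fire counts on deforestation rates within each phase
#' and over the full period. Phases with fewer than 3 usable years are
#' flagged non-testable (results NA) rather than dropped; 3-year phases
#' carry a low-n flag since their p-values have almost no power.
#'
#' @param fires data frame `year`, `total`.
#' @param defor data frame `year`, `defor_km2`.
#' @param phases data frame `name`, `start`, `end` (default
#'   [ppcdam_phases()]); a `full` row spanning the common years is always
#'   appended.
#' @return data frame: one row per phase plus `full`, with `slope`,
#'   `r_squared`, `p_value`, `n`, `testable`, `low_n`.
#' @export
phase_regressions <- function(fires, defor, phases = ppcdam_phases()) {
  m <- merge(fires[c("year", "total")], defor[c("year", "defor_km2")],
             by = "year")
  span <- range(m$year)
  if (any(phases$start > span[2L] | phases$end < span[1L]))
    stop_af("phase outside the data span %d-%d", span[1L], span[2L])
  phases <- rbind(phases,
                  data.frame(name = "full", start = span[1L],
                             end = span[2L]))
  res <- lapply(seq_len(nrow(phases)), function(i) {
    sub <- m[m$year >= phases$start[i] & m$year <= phases$end[i], ]
    n <- nrow(sub)
    if (n < 3L)
      return(data.frame(name = phases$name[i], start = phases$start[i],
                        end = phases$end[i], slope = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = n, testable = FALSE, low_n = TRUE))
    f <- ols_regression(sub$defor_km2, sub$total)
    data.frame(name = phases$name[i], start = phases$start[i],
               end = phases$end[i], slope = f$slope,
               r_squared = f$r_squared, p_value = f$p_value,
               n = n, testable = TRUE, low_n = n <= 3L)
  })
  do.call(rbind, res)
}
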