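#' Empirical FRP percentile by group
#'
#' Computes the empirical percentile of fire radiative power per group
#' (fire type or year) under the linear-interpolation convention between
#' order statistics ([stats::quantile()] type 7): for values 1..10 the
#' 90th percentile is 9.1. High percentiles -- FRP90 by convention --
#' discriminate fire types far better than means or medians, because the
#' heavy upper tail of deforestation fires is what sets them apart.
#'
#' @param frp numeric FRP values (MW); `NA` dropped.
#' @param by grouping vector (same length) or NULL for one group.
#' @param level percentile in (0, 100); default 90.
#' @return data frame `group`, `level`, `value`, `n`.
#' @export
frp_percentile <- function(frp, by = NULL, level = 90) {
  if (level <= 0 || level > 100)
    stop_af("percentile level must lie in (0, 100]")   # 100 = the maximum
  by <- by %||% rep("all", length(frp))
  keep <- !is.na(frp)
  frp <- frp[keep]; by <- by[keep]
  if (!length(frp)) stop_af("no FRP values",
                            class = "amazonfire_degenerate_error")
  groups <- split(frp, by)
  if (any(!lengths(groups)))
    stop_af("empty FRP group", class = "amazonfire_degenerate_error")
  data.frame(group = names(groups),
             level = level,
             value = vapply(groups, function(v)
               unname(stats::quantile(v, level / 100, type = 7)),
               numeric(1)),
             n = lengths(groups),
             row.names = NULL)
}

#' FRP probability density per group
#'
#' Kernel density of FRP per group, estimated on the log scale (FRP is
#' strictly positive and heavy-tailed) with the default data-driven
#' bandwidth rule, then transformed back (`f_X(x) = f_logX(log x)/x`) and
#' renormalized so each emitted density integrates to exactly 1 by the
#' trapezoid rule. Groups with fewer than 30 values fall back to a
#' histogram estimate with a warning. Densities are descriptive only.
#'
#' @inheritParams frp_percentile
#' @param n number of evaluation points.
#' @return data frame `group`, `x` (MW), `density`, `method`.
#' @export
frp_density <- function(frp, by = NULL, n = 512L) {
  by <- by %||% rep("all", length(frp))
  keep <- !is.na(frp)
  frp <- frp[keep]; by <- by[keep]
  groups <- split(frp, by)
  if (any(!lengths(groups)))
    stop_af("empty FRP group", class = "amazonfire_degenerate_error")
  out <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (any(v <= 0)) stop_af("FRP must be positive for density estimation")
    if (length(v) >= 30L && stats::sd(v) > 0) {
      dl <- stats::density(log(v), n = n)
      x <- exp(dl$x); dens <- dl$y / x
      method <- "kde_log"
    } else {
      if (length(v) < 30L)
        warning(sprintf("frp_density: group '%s' has %d < 30 values; histogram-only estimate",
                        g, length(v)))
      h <- graphics::hist(v, plot = FALSE)
      x <- h$mids; dens <- h$density
      if (length(x) < 2L) { x <- c(x - 1e-6, x + 1e-6); dens <- rep(dens, 2L) }
      method <- "histogram"
    }
    integral <- sum(diff(x) * (dens[-1L] + dens[-length(dens)]) / 2)
    data.frame(group = g, x = x, density = dens / integral,
               method = method)
  })
  do.call(rbind, out)
}

#' Continuous single-breakpoint ("broken stick") trend fit
#'
#' For every candidate breakpoint year `b` in the search range, fits the
#' continuous two-segment least-squares model
#' `y = a + c1 * t + c2 * max(t - b, 0)` and keeps the candidate with the
#' smallest SSE. Each branch (inclusive of the knot year on both sides, as
#' is conventional when reporting the two sub-periods) is then tested with
#' the two-tailed Mann-Kendall test. A discontinuous mode -- two
#' independent lines sharing the knot year -- is available behind a flag.
#' Candidates leaving fewer than 3 points on either side are skipped.
#'
#' @param years ordered time points.
#' @param values series values (e.g. annual FRP90, MW).
#' @param candidates candidate breakpoint years (default 2005:2017).
#' @param alpha significance level for the branch trend tests.
#' @param continuous constrain the two segments to meet at the knot.
#' @return object of class `breakpoint_fit`: `breakpoint`, `pre_slope`,
#'   `post_slope`, `sse`, `sse_single` (one-line fit), `no_break` flag,
#'   `candidates` (searched years with SSE), `mk_pre`, `mk_post`,
#'   `fitted`.
#' @export
breakpoint_fit <- function(years, values, candidates = 2005:2017,
                           alpha = 0.05, continuous = TRUE) {
  stopifnot(length(years) == length(values))
  o <- order(years); t <- as.numeric(years[o]); y <- values[o]
  usable <- candidates[vapply(candidates, function(b)
    sum(t <= b) >= 3L && sum(t >= b) >= 3L, logical(1))]
  if (!length(usable))
    stop_af("no candidate breakpoint leaves >= 3 points on each side",
            class = "amazonfire_degenerate_error")
  fits <- lapply(usable, function(b) {
    if (continuous) {
      hinge <- pmax(t - b, 0)
      fit <- stats::lm(y ~ t + hinge)
      co <- stats::coef(fit)
      list(b = b, sse = sum(stats::resid(fit)^2),
           pre = unname(co[2L]), post = unname(co[2L] + co[3L]),
           fitted = unname(stats::fitted(fit)))
    } else {
      # disjoint partition (knot year with the pre-branch) so each point
      # contributes once; the branch MK tests below still include the knot
      # on both sides, which is a reporting convention only
      li <- t <= b; ri <- t > b
      f1 <- stats::lm(y[li] ~ t[li]); f2 <- stats::lm(y[ri] ~ t[ri])
      fv <- numeric(length(t))
      fv[li] <- stats::fitted(f1); fv[ri] <- stats::fitted(f2)
      list(b = b, sse = sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2),
           pre = unname(stats::coef(f1)[2L]),
           post = unname(stats::coef(f2)[2L]), fitted = fv)
    }
  })
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  best <- which.min(sse)          # ties break to the earliest candidate
  tol <- 1e-9 * max(1, max(sse))
  no_break <- diff(range(sse)) <= tol
  if (no_break) best <- 1L
  bf <- fits[[best]]
  single <- stats::lm(y ~ t)
  structure(list(breakpoint = bf$b, pre_slope = bf$pre,
                 post_slope = bf$post, sse = bf$sse,
                 sse_single = sum(stats::resid(single)^2),
                 no_break = no_break,
                 candidates = data.frame(year = usable, sse = sse),
                 mk_pre = mann_kendall(t[t <= bf$b], y[t <= bf$b], alpha),
                 mk_post = mann_kendall(t[t >= bf$b], y[t >= bf$b], alpha),
                 years = t, values = y, fitted = bf$fitted,
                 continuous = continuous),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$no_break)
    cat("Breakpoint fit: no break detected (all candidate SSE equal)\n")
  cat(sprintf("Breakpoint at %d: slopes %.4g (pre) / %.4g (post) per year, SSE %.4g\n",
              x$breakpoint, x$pre_slope, x$post_slope, x$sse))
  cat(sprintf("  branch Mann-Kendall p: pre %.4g%s, post %.4g%s (alpha %g)\n",
              x$mk_pre$p_value,
              if (x$mk_pre$significant) "*" else "",
              x$mk_post$p_value,
              if (x$mk_post$significant) "*" else "",
              x$mk_pre$alpha))
  invisible(x)
}
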