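#' EOF / principal-component decomposition of standardized fire grids
#'
#' Decomposes the years x valid-pixels matrix of standardized annual fire
#' counts by singular value decomposition (the temporal-covariance
#' orientation, natural when years are few and pixels many). Explained
#' variance fractions come from the squared singular values; the PC of
#' mode k is the projection of the year series onto EOF k. Sign
#' convention: each EOF is flipped so its loading of largest absolute
#' value is positive, making results deterministic across platforms.
#'
#' @param fields an `anomaly_fields` object from [standardize()] (the
#'   valid-pixel mask is constant across years by construction).
#' @param n_modes number of modes to retain (clipped with a warning to
#'   `min(n_years, n_valid_pixels)`).
#' @return object of class `eof_decomposition`: `eofs` (valid-pixels x
#'   modes, orthonormal columns), `pcs` (years x modes), `lambda`
#'   (percent variance per mode), `cumulative`, `mask`, `years`,
#'   `total_variance`.
#' @export
eof_decompose <- function(fields, n_modes = NULL) {
  stopifnot(inherits(fields, "anomaly_fields"))
  ny <- length(fields$years)
  nv <- sum(fields$mask)
  if (nv == 0L) stop_af("no valid pixels to decompose",
                        class = "amazonfire_degenerate_error")
  X <- t(vapply(seq_len(ny),
                function(k) fields$z[, , k][fields$mask],
                numeric(nv)))
  if (nv == 1L) X <- matrix(X, nrow = ny)
  kmax <- min(dim(X))
  n_modes <- n_modes %||% kmax
  if (n_modes > kmax) {
    warning(sprintf("n_modes clipped from %d to %d", n_modes, kmax))
    n_modes <- kmax
  }
  sv <- svd(X, nu = kmax, nv = kmax)
  lambda <- 100 * sv$d^2 / sum(sv$d^2)
  eofs <- sv$v
  pcs <- sv$u %*% diag(sv$d, kmax, kmax)
  for (k in seq_len(kmax)) {
    j <- which.max(abs(eofs[, k]))
    if (eofs[j, k] < 0) {
      eofs[, k] <- -eofs[, k]
      pcs[, k] <- -pcs[, k]
    }
  }
  structure(list(eofs = eofs[, seq_len(n_modes), drop = FALSE],
                 pcs = pcs[, seq_len(n_modes), drop = FALSE],
                 lambda = lambda[seq_len(n_modes)],
                 lambda_all = lambda,
                 cumulative = cumsum(lambda)[seq_len(n_modes)],
                 singular_values = sv$d,
                 mask = fields$mask, years = fields$years,
                 total_variance = sum(sv$d^2), n_modes = n_modes),
            class = "eof_decomposition")
}

#' @export
print.eof_decomposition <- function(x, ...) {
  cat(sprintf("EOF decomposition: %d modes over %d years x %d valid pixels\n",
              x$n_modes, length(x$years), sum(x$mask)))
  k <- seq_len(min(6L, x$n_modes))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", x$lambda[k]), collapse = ", "),
      sprintf("(first %d cumulative %.1f%%)\n", max(k), x$cumulative[max(k)]))
  invisible(x)
}

#' Reconstruct the standardized matrix from retained modes
#'
#' @param decomp an `eof_decomposition`.
#' @param modes which modes to use (default: all retained).
#' @return years x valid-pixels matrix.
#' @export
eof_reconstruct <- function(decomp, modes = seq_len(decomp$n_modes)) {
  decomp$pcs[, modes, drop = FALSE] %*%
    t(decomp$eofs[, modes, drop = FALSE])
}

#' Per-mode EOF sign maps
#'
#' Reduces each spatial pattern to its loading sign per pixel (-1, 0, +1;
#' zero only at exactly-zero loadings), the reading that highlights the
#' north/south and core/edge contrasts of fire activity.
#'
#' @param decomp an `eof_decomposition`.
#' @param modes modes to map.
#' @return list of rows x cols matrices (NA outside the valid mask), one
#'   per requested mode.
#' @export
eof_sign_maps <- function(decomp, modes = 1:3) {
  if (any(modes > decomp$n_modes))
    stop_af("requested mode beyond the %d retained", decomp$n_modes)
  lapply(modes, function(k) {
    m <- matrix(NA_real_, nrow(decomp$mask), ncol(decomp$mask))
    m[decomp$mask] <- sign(decomp$eofs[, k])
    m
  })
}

#' Tidy explained-variance table across fire types
#'
#' @param decomps named list of `eof_decomposition` objects (one per fire
#'   type).
#' @return data frame `fire_type`, `mode`, `lambda` (percent),
#'   `cumulative`.
#' @export
variance_table <- function(decomps) {
  stopifnot(length(names(decomps)) == length(decomps))
  do.call(rbind, lapply(names(decomps), function(ty) {
    d <- decomps[[ty]]
    data.frame(fire_type = ty, mode = seq_len(d$n_modes),
               lambda = d$lambda, cumulative = d$cumulative)
  }))
}
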