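#' Kirkwood-Irving surface tension of a slab
#'
#' For a two-interface slab with the interface normal along z, the
#' surface tension is the integrated anisotropy of the pressure tensor,
#'
#'   gamma = (L_z / 2) < P_zz - (P_xx + P_yy) / 2 >
#'
#' with the 1/2 prefactor sharing the anisotropy between the two
#' interfaces.  (Note the common equivalent form with the normal first,
#' gamma = (L_z/2)<P_N - P_T>, here P_N = P_zz.)  In real units the
#' bar-angstrom result is converted to mN/m (1 bar A = 0.01 mN/m);
#' reduced units pass through.  The uncertainty is the block-average
#' standard error of the per-sample integrand.
#'
#' @param series a [pressure_series()].
#' @param kind `"air-monolayer-water"` (gamma_m) or `"air-water"`
#'   (gamma_w); metadata only.
#' @param n_blocks blocks for the uncertainty estimate.
#' @return list of class `surface_tension` with `gamma`, `uncertainty`,
#'   `kind`, `units`.
#' @export
kirkwood_irving <- function(series, kind = c("air-monolayer-water",
                                             "air-water"),
                            n_blocks = 5) {
  stopifnot(inherits(series, "pressure_series"))
  kind <- match.arg(kind)
  if (!length(series$times)) stop("empty pressure series")
  g <- (series$box_lz / 2) *
    (series$pzz - (series$pxx + series$pyy) / 2)
  gamma <- .tension_out(mean(g), series$units)
  unc <- if (length(g) >= n_blocks)
    .tension_out(block_uncertainty(g, n_blocks), series$units)
  else NA_real_
  structure(list(gamma = gamma, uncertainty = unc, kind = kind,
                 units = series$units),
            class = "surface_tension")
}

#' @export
print.surface_tension <- function(x, ...) {
  u <- if (x$units == "real") "mN/m" else "eps/sigma^2"
  cat(sprintf("gamma(%s) = %.4g +- %.2g %s\n", x$kind, x$gamma,
              x$uncertainty, u))
  invisible(x)
}

#' Surface pressure as a tension difference
#'
#' The classical route: `Pi = gamma_w - gamma_m`, the reduction of the
#' clean air-water surface tension caused by the monolayer.
#' Uncertainties are combined in quadrature.  Negative values are
#' allowed and flagged as metastable (slightly negative surface
#' pressures at large molecular areas indicate a metastable bare-like
#' interface, not an error).
#'
#' @param gamma_w `surface_tension` of the bare air-water interface.
#' @param gamma_m `surface_tension` of the air-monolayer-water
#'   interface.
#' @return list of class `surface_pressure` with `value`, `uncertainty`,
#'   `units`, `metastable`.
#' @export
surface_pressure <- function(gamma_w, gamma_m) {
  stopifnot(inherits(gamma_w, "surface_tension"),
            inherits(gamma_m, "surface_tension"))
  if (!identical(gamma_w$units, gamma_m$units))
    stop("unit mismatch: gamma_w is in ", gamma_w$units, " units, gamma_m in ",
         gamma_m$units)
  value <- gamma_w$gamma - gamma_m$gamma
  unc <- sqrt(sum(c(gamma_w$uncertainty, gamma_m$uncertainty)^2, na.rm = TRUE))
  structure(list(value = value, uncertainty = unc, units = gamma_w$units,
                 metastable = value < 0),
            class = "surface_pressure")
}

#' @export
print.surface_pressure <- function(x, ...) {
  u <- if (x$units == "real") "mN/m" else "eps/sigma^2"
  cat(sprintf("Pi = %.4g +- %.2g %s%s\n", x$value, x$uncertainty, u,
              if (isTRUE(x$metastable)) "  [negative: metastable]" else ""))
  invisible(x)
}
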