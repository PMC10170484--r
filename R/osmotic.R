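#' Specify a semipermeable virtual wall pair
#'
#' Two planar walls at `x = -x_wall` and `x = +x_wall` act as the mobile
#' barriers of a Langmuir trough: solvent crosses freely, while beads of
#' the restrained species that stray beyond a wall feel an inward
#' restoring force.  Two force laws are available for the flat-bottom
#' restraint, both zero for `|x| <= x_wall` and acting on the
#' penetration depth `d = |x| - x_wall`:
#'
#' * `"quadratic"`: `F = k d^2`, with `k` in kcal mol^-1 A^-3 (real
#'   units; the default, `k = 20`, is stiff enough to confine without
#'   perturbing the film) or epsilon/sigma^3 (reduced);
#' * `"linear"`: `F = k d`, the flat-bottom harmonic restraint, `k` in
#'   kcal mol^-1 A^-2 or epsilon/sigma^2.
#'
#' The force estimator downstream is agnostic to which law generated
#' the data.
#'
#' @param x_wall positive wall position (walls at +-x_wall).
#' @param k positive force constant.
#' @param force_law `"quadratic"` or `"linear"`.
#' @param restrained_species species tags the walls act on; must be
#'   non-empty and must not include the solvent (the wall is an osmotic
#'   membrane).
#' @param solvent_species the solvent tag, used only for the exclusion
#'   check.
#' @return list of class `wall_spec`.
#' @export
wall_spec <- function(x_wall, k = 20, force_law = c("quadratic", "linear"),
                      restrained_species = c("H", "T"),
                      solvent_species = "W") {
  force_law <- match.arg(force_law)
  if (!is.numeric(x_wall) || x_wall <= 0) stop("x_wall must be > 0")
  if (!is.numeric(k) || k <= 0) stop("k must be > 0")
  if (!length(restrained_species)) stop("restrained_species must be non-empty")
  if (any(solvent_species %in% restrained_species))
    stop("the solvent must not be restrained (the wall is semipermeable)")
  structure(list(x_wall = x_wall, k = k, force_law = force_law,
                 restrained_species = restrained_species),
            class = "wall_spec")
}

#' @export
print.wall_spec <- function(x, ...) {
  cat(sprintf("wall_spec: x_wall = %.4g, k = %.4g (%s law), restrains %s\n",
              x$x_wall, x$k, x$force_law,
              paste(x$restrained_species, collapse = ", ")))
  invisible(x)
}

#' Accumulate virtual-wall restoring forces over a trajectory
#'
#' For every saved frame, sums the restoring-force magnitude over all
#' restrained beads with `|x_i| > x_wall` (both walls contribute) and
#' returns the arithmetic mean over the N frames -- the osmotic force
#' `<F_wall>`.  Beads are summed in index order so the result is
#' bitwise reproducible.
#'
#' @param traj a [trajectory].
#' @param wall a [wall_spec()].
#' @param sanity_distance penetrations deeper than this trigger an
#'   escaped-surfactant warning (default 5 length units).
#' @return list of class `wall_force_record` with `per_frame_force`,
#'   `mean_force`, `n_frames`, `per_species_force` (named means summing
#'   to the total) and `times`.
#' @export
wall_force <- function(traj, wall, sanity_distance = 5) {
  stopifnot(inherits(traj, "trajectory"), inherits(wall, "wall_spec"))
  nf <- n_frames(traj)
  if (nf < 1) stop("no frames in trajectory")
  mask <- traj$species %in% wall$restrained_species
  if (!any(mask))
    stop("no restrained species (", paste(wall$restrained_species,
         collapse = ", "), ") present in the trajectory")
  x <- traj$coords[mask, 1, , drop = FALSE]
  x <- matrix(x, nrow = sum(mask), ncol = nf)
  pen <- pmax(abs(x) - wall$x_wall, 0)
  if (any(pen > sanity_distance))
    warning("bead(s) beyond the wall by more than ", sanity_distance,
            " length units: escaped surfactant?")
  f <- if (wall$force_law == "quadratic") wall$k * pen^2 else wall$k * pen
  per_frame <- colSums(f)
  sp <- traj$species[mask]
  per_species <- vapply(
    sort(unique(sp)),
    function(s) mean(colSums(f[sp == s, , drop = FALSE])),
    0.0)
  structure(list(per_frame_force = per_frame, mean_force = mean(per_frame),
                 n_frames = nf, per_species_force = per_species,
                 times = traj$times),
            class = "wall_force_record")
}

#' @export
print.wall_force_record <- function(x, ...) {
  cat(sprintf("wall_force_record: <F_wall> = %.6g over %d frames\n",
              x$mean_force, x$n_frames))
  invisible(x)
}

#' Ideal 2D surface pressure from the osmotic wall force
#'
#' Converts the mean wall force to the uncorrected film pressure
#' `Pi_ideal = <F_wall> / (4 L_y)`.  The divisor 4 accounts for the
#' four intersections of the two virtual walls with the two
#' air-monolayer-water interfaces of the slab.  In real units the
#' result (kcal mol^-1 A^-2) is converted to mN/m.
#'
#' When `per_species_depths` is supplied, the per-species decomposition
#' is evaluated instead: each species' 3D osmotic pressure
#' `Pi_os,a = <F_a> / (L_y tau_za)` is formed from its share of the
#' wall force and its interfacial depth `tau_za`, and the 2D pressure
#' is `sum_a Pi_os,a tau_za / 4`.  The depths cancel algebraically, so
#' this route must (and does) equal the total-force route for any
#' decomposition; both are computed and cross-checked.
#'
#' @param record a `wall_force_record`, or a bare numeric `<F_wall>`.
#' @param l_y box length along y (> 0).
#' @param units `"real"` or `"reduced"`.
#' @param per_species_depths optional named numeric of depths `tau_za`
#'   per restrained species; names must match the record's
#'   `per_species_force`.
#' @return surface pressure as a single number (mN/m in real units,
#'   epsilon/sigma^2 in reduced units).
#' @export
pi_ideal <- function(record, l_y, units = "reduced",
                     per_species_depths = NULL) {
  units <- .check_units(units)
  if (!is.numeric(l_y) || l_y <= 0) stop("l_y must be > 0")
  if (is.numeric(record)) {
    f_mean <- record
    per_species <- NULL
  } else {
    stopifnot(inherits(record, "wall_force_record"))
    f_mean <- record$mean_force
    per_species <- record$per_species_force
  }
  pi_total <- f_mean / (4 * l_y)
  if (!is.null(per_species_depths)) {
    if (is.null(per_species))
      stop("per-species path needs a wall_force_record with species shares")
    if (!all(names(per_species) %in% names(per_species_depths)))
      stop("per_species_depths must name every restrained species")
    tau <- per_species_depths[names(per_species)]
    if (any(tau <= 0)) stop("depths tau_za must be > 0")
    pi_os <- per_species / (l_y * tau)     # per-species 3D osmotic pressure
    pi_sum <- sum(pi_os * tau) / 4          # back to the 2D film pressure
    stopifnot(isTRUE(all.equal(pi_sum, pi_total)))
    pi_total <- pi_sum
  }
  .surface_pressure_out(pi_total, units)
}

#' Corrected surface pressure
#'
#' Applies the semi-empirical correction `Pi_real = Pi_ideal * xi`,
#' where xi is the ratio of the infinite-dilution interfacial thickness
#' to the thickness at the current molecular area (see
#' [xi_coefficient()]).  At wide spreading xi is close to 1 and the
#' correction vanishes; as the monolayer packs and the inhomogeneous
#' surface zone deepens, xi < 1 scales the ideal pressure down.
#'
#' @param pi_ideal_value surface pressure from [pi_ideal()].
#' @param xi a [xi_coefficient()] object or a bare number.
#' @return corrected surface pressure, same units as the input.
#' @export
pi_real <- function(pi_ideal_value, xi) {
  if (inherits(xi, "xi_coefficient")) xi <- xi$xi
  if (!is.finite(pi_ideal_value)) stop("pi_ideal must be finite")
  if (!is.numeric(xi) || !is.finite(xi)) stop("xi must be a finite number")
  pi_ideal_value * xi
}

#' Block-average standard error
#'
#' Standard error of the mean of a correlated series, estimated from
#' the scatter of contiguous equal-length block means.  The series is
#' cut into `n_blocks` blocks of `floor(n / n_blocks)` values; remainder
#' values past the last block boundary are dropped.
#'
#' @param x numeric series (e.g. per-frame wall forces or the
#'   tension integrand).
#' @param n_blocks number of blocks, `2 <= n_blocks <= length(x)`.
#' @return standard error of the mean.
#' @export
block_uncertainty <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (n < n_blocks) stop("series shorter than the number of blocks")
  bl <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks),
                  function(b) mean(x[((b - 1) * bl + 1):(b * bl)]), 0.0)
  stats::sd(means) / sqrt(n_blocks)
}
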