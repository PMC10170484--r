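#' Per-species density profile along the interface normal
#'
#' Bins particle z-coordinates into uniform slices spanning the box and
#' averages over frames, yielding a number density (counts per bin
#' volume).  Restricting `region` to the between-the-walls x-range
#' excludes the clean-interface margin, so the profile reflects only the
#' monolayer-covered strip; the bin cross-section is then
#' `region_width x L_y` instead of `L_x x L_y`.
#'
#' The requested bin width is adjusted to the nearest value that tiles
#' `L_z` exactly (an integer number of bins), so bins are uniform.
#'
#' Because a Langevin thermostat does not conserve momentum, the whole
#' slab performs a slow random walk along z over long runs; averaging
#' the raw histogram over such a run smears both interfaces and
#' overestimates the interfacial thickness.  With `center = TRUE`
#' (the default for thickness work, see [reference_thickness()]) each
#' frame is shifted so the circular-mean z of the `center_species`
#' particles sits at zero before binning, removing the drift without
#' touching the interfacial structure.
#'
#' @param traj a [trajectory].
#' @param species character vector of species to include; `NULL` means
#'   all species present.
#' @param bin_width requested bin width along z.
#' @param region optional length-2 numeric `c(xmin, xmax)`; only
#'   particles with `xmin <= x <= xmax` contribute.
#' @param center recentre each frame on the slab's centre of mass
#'   before binning.
#' @param center_species species used to locate the slab centre
#'   (default `"W"`, the solvent).
#' @return object of class `density_profile` with `bin_centers`,
#'   `density` (matrix, one column per species), `bin_width`, `units`.
#' @export
density_profile <- function(traj, species = NULL, bin_width, region = NULL,
                            center = FALSE, center_species = "W") {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1) stop("empty trajectory")
  box <- traj$box[1, ]
  lz <- box[3]
  if (bin_width <= 0) stop("bin width must be > 0")
  if (bin_width > lz) stop("bin width larger than the box")
  if (is.null(species)) species <- sort(unique(traj$species))
  if (!length(species)) stop("empty species selection")
  missing_sp <- setdiff(species, unique(traj$species))
  if (length(missing_sp))
    stop("species not present in trajectory: ",
         paste(missing_sp, collapse = ", "))
  lx_eff <- box[1]
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] < region[2])
    if (region[1] < -box[1] / 2 - 1e-9 || region[2] > box[1] / 2 + 1e-9)
      stop("region lies outside the box")
    lx_eff <- region[2] - region[1]
  }
  nbins <- max(1L, as.integer(round(lz / bin_width)))
  width <- lz / nbins
  nf <- n_frames(traj)
  z_shift <- rep(0, nf)
  if (center) {
    cmask <- traj$species %in% center_species
    if (!any(cmask)) stop("no '", paste(center_species, collapse = ","),
                          "' particles to centre on")
    zc <- matrix(traj$coords[cmask, 3, , drop = FALSE], ncol = nf)
    theta <- zc * (2 * pi / lz)   # circular mean handles wrapped slabs
    z_shift <- atan2(colMeans(sin(theta)), colMeans(cos(theta))) * lz / (2 * pi)
  }
  dens <- matrix(0, nbins, length(species), dimnames = list(NULL, species))
  for (s in seq_along(species)) {
    pmask <- traj$species == species[s]
    zz <- traj$coords[pmask, 3, , drop = FALSE]
    zz <- sweep(zz, 3, z_shift)
    if (!is.null(region)) {
      xx <- traj$coords[pmask, 1, , drop = FALSE]
      keep <- xx >= region[1] & xx <= region[2]
    } else keep <- rep(TRUE, length(zz))
    z <- zz[keep]
    # wrap into [-lz/2, lz/2)
    z <- z - lz * floor(z / lz + 0.5)
    idx <- pmin(nbins, pmax(1L, as.integer(floor((z / lz + 0.5) * nbins)) + 1L))
    dens[, s] <- tabulate(idx, nbins)
  }
  bin_vol <- width * lx_eff * box[2]
  dens <- dens / (nf * bin_vol)
  structure(list(bin_centers = -lz / 2 + (seq_len(nbins) - 0.5) * width,
                 density = dens, bin_width = width, units = traj$units,
                 region = region),
            class = "density_profile")
}

#' Build a density profile from precomputed values
#'
#' Useful for analytic test profiles and for re-importing profiles
#' exported as CSV.
#'
#' @param bin_centers numeric, uniformly spaced, increasing.
#' @param density numeric vector (single species) or matrix with one
#'   named column per species.
#' @param units `"real"` or `"reduced"`.
#' @param species species name used when `density` is a bare vector.
#' @return a `density_profile`.
#' @export
as_density_profile <- function(bin_centers, density, units = "reduced",
                               species = "W") {
  if (is.null(dim(density)))
    density <- matrix(density, ncol = 1, dimnames = list(NULL, species))
  if (any(density < 0)) stop("densities must be >= 0")
  w <- diff(bin_centers)
  if (length(w) && (any(w <= 0) || diff(range(w)) > 1e-6 * mean(w)))
    stop("bins must be uniform and ordered")
  structure(list(bin_centers = bin_centers, density = density,
                 bin_width = if (length(w)) mean(w) else 1,
                 units = .check_units(units), region = NULL),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile:", length(x$bin_centers), "bins of width",
      signif(x$bin_width, 4), "| species:",
      paste(colnames(x$density), collapse = ", "), "\n")
  invisible(x)
}

#' Export a density profile as CSV
#' @param profile a `density_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_density_profile <- function(profile, path) {
  df <- data.frame(bin_center = profile$bin_centers, profile$density,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# locate the outermost crossing of `level` in a density vector, scanning
# from `from` towards `to` (the bulk).  Returns the interpolated z and the
# number of crossings seen (for the non-monotonicity warning).
.outermost_crossing <- function(z, rho, level, from, to) {
  idx <- if (from < to) seq(from, to) else seq(from, to, by = -1L)
  r <- rho[idx]
  below <- r < level
  cross <- which(below[-length(below)] & !below[-1])
  if (!length(cross)) return(list(z = NA_real_, n = 0L))
  i <- idx[cross[1]]
  j <- idx[cross[1] + 1L]
  frac <- (level - rho[i]) / (rho[j] - rho[i])
  list(z = z[i] + frac * (z[j] - z[i]), n = length(cross))
}

#' Interfacial thickness by the 90-10% density rule
#'
#' The inhomogeneous-zone thickness `L_z;int` is the distance along z
#' over which the solvent density drops from `hi_frac` (default 90%) to
#' `lo_frac` (default 10%) of its bulk value.  The bulk reference is the
#' mean solvent density over the central 50% of the slab (the region
#' where the density exceeds half its maximum), not the single highest
#' bin, so a noisy maximum does not bias the crossings.  Crossings are
#' located by linear interpolation between adjacent bins; when a
#' non-monotonic tail produces several crossings the outermost one is
#' used and a warning is emitted.  A slab has two interfaces; both are
#' measured and their mean is the value used downstream.  A profile
#' whose density is still above `hi_frac` at a box edge (a half-infinite
#' plateau, as in single-interface test profiles) contributes only its
#' decaying side.
#'
#' @param profile a `density_profile`.
#' @param solvent_species column of the profile to analyse.
#' @param lo_frac,hi_frac dimensionless thresholds, `0 < lo < hi < 1`.
#' @return list of class `interfacial_thickness` with `lz_int` (the
#'   mean), `per_interface` (lower-z, upper-z), `rho_ref`, `lo_frac`,
#'   `hi_frac`.
#' @export
interfacial_thickness <- function(profile, solvent_species = "W",
                                  lo_frac = 0.10, hi_frac = 0.90) {
  stopifnot(inherits(profile, "density_profile"))
  if (!(lo_frac > 0 && lo_frac < hi_frac && hi_frac < 1))
    stop("need 0 < lo_frac < hi_frac < 1")
  if (!solvent_species %in% colnames(profile$density))
    stop("species '", solvent_species, "' not in profile")
  rho <- profile$density[, solvent_species]
  z <- profile$bin_centers
  n <- length(z)
  rmax <- max(rho)
  if (rmax <= 0) stop("degenerate profile: density is identically zero")
  # slab extent: region where density >= half max; bulk ref = mean over
  # the central 50% of that extent
  in_slab <- which(rho >= 0.5 * rmax)
  zl <- z[min(in_slab)]; zr <- z[max(in_slab)]
  zc <- (zl + zr) / 2; qw <- (zr - zl) / 4
  central <- z >= zc - qw & z <= zc + qw
  rho_ref <- mean(rho[central])
  hi <- hi_frac * rho_ref
  lo <- lo_frac * rho_ref
  if (rmax < hi)
    stop("degenerate profile: density never reaches ", hi_frac,
         " of the bulk reference")
  ic <- which.min(abs(z - zc))
  sides <- list(lower = c(1L, ic), upper = c(n, ic))
  th <- c(lower = NA_real_, upper = NA_real_)
  ncross <- 0L
  for (s in names(sides)) {
    from <- sides[[s]][1]; to <- sides[[s]][2]
    if (rho[from] >= hi) next  # plateau runs into the box edge: no interface
    chi <- .outermost_crossing(z, rho, hi, from, to)
    clo <- .outermost_crossing(z, rho, lo, from, to)
    if (chi$n == 0L) next
    if (clo$n == 0L)  # density never falls below lo on this side
      next
    th[s] <- abs(chi$z - clo$z)
    ncross <- max(ncross, chi$n, clo$n)
  }
  if (all(is.na(th)))
    stop("degenerate profile: no interface with a ", hi_frac, "-",
         lo_frac, " transition found")
  if (ncross > 1L)
    warning("non-monotonic interfacial tail: using outermost crossings")
  structure(list(lz_int = mean(th, na.rm = TRUE), per_interface = th,
                 rho_ref = rho_ref, lo_frac = lo_frac, hi_frac = hi_frac),
            class = "interfacial_thickness")
}

#' @export
print.interfacial_thickness <- function(x, ...) {
  cat(sprintf("L_z;int = %.4g (lower %.4g, upper %.4g), %d-%d%% rule\n",
              x$lz_int, x$per_interface[1], x$per_interface[2],
              round(100 * x$hi_frac), round(100 * x$lo_frac)))
  invisible(x)
}

#' Semi-empirical correction coefficient xi
#'
#' `xi = lz_ref / lz_at_area`: the interfacial thickness of the bare
#' (infinite-dilution) interface divided by the thickness at the current
#' molecular area.  It is close to 1 when the surfactants are widely
#' spread out and falls below 1 as they pack and the inhomogeneous zone
#' deepens.  `xi > 1` (thickness below the bare-interface value) is
#' physically unexpected and triggers a warning.
#'
#' @param lz_at_area interfacial thickness at the current area (> 0).
#' @param lz_ref infinite-dilution reference thickness (> 0).
#' @return list of class `xi_coefficient` with `xi`, `lz_ref`,
#'   `lz_at_area`.
#' @export
xi_coefficient <- function(lz_at_area, lz_ref) {
  if (inherits(lz_at_area, "interfacial_thickness"))
    lz_at_area <- lz_at_area$lz_int
  if (inherits(lz_ref, "interfacial_thickness")) lz_ref <- lz_ref$lz_int
  if (!is.numeric(lz_at_area) || lz_at_area <= 0 ||
      !is.numeric(lz_ref) || lz_ref <= 0)
    stop("both thicknesses must be positive numbers")
  xi <- lz_ref / lz_at_area
  if (xi > 1 + 1e-9)
    warning("xi = ", signif(xi, 4), " > 1: interface thinner than the ",
            "bare reference (physically unexpected)")
  structure(list(xi = xi, lz_ref = lz_ref, lz_at_area = lz_at_area),
            class = "xi_coefficient")
}

#' @export
print.xi_coefficient <- function(x, ...) {
  cat(sprintf("xi = %.4f (L_ref = %.4g / L_area = %.4g)\n", x$xi, x$lz_ref,
              x$lz_at_area))
  invisible(x)
}

#' Infinite-dilution reference thickness from a clean solvent slab
#'
#' Computes `L_z;int` of a surfactant-free interface with the same bins
#' and thresholds as the monolayer analysis.  The trajectory must be a
#' clean slab: if the fraction of non-solvent particles exceeds
#' `surfactant_tol` the call errors, instructing the use of a clean
#' slab, since a contaminated reference would bias xi for every point of
#' the isotherm.
#'
#' @param traj a [trajectory] of the bare solvent slab.
#' @param solvent_species solvent tag (default `"W"`).
#' @param bin_width profile bin width; defaults per unit system.
#' @param surfactant_tol maximum tolerated fraction of non-solvent
#'   particles.
#' @param lo_frac,hi_frac thresholds passed to
#'   [interfacial_thickness()].
#' @return an `interfacial_thickness` for the bare interface.
#' @export
reference_thickness <- function(traj, solvent_species = "W",
                                bin_width = if (traj$units == "real") 0.5 else 0.1,
                                surfactant_tol = 0.01,
                                lo_frac = 0.10, hi_frac = 0.90) {
  stopifnot(inherits(traj, "trajectory"))
  frac_other <- mean(traj$species != solvent_species)
  if (frac_other > surfactant_tol)
    stop("trajectory contains ", signif(100 * frac_other, 3),
         "% non-solvent particles; the infinite-dilution reference must ",
         "be computed from a clean solvent slab")
  prof <- density_profile(traj, species = solvent_species,
                          bin_width = bin_width, center = TRUE,
                          center_species = solvent_species)
  interfacial_thickness(prof, solvent_species, lo_frac, hi_frac)
}
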