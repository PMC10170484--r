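#' Specify a toy monolayer model
#'
#' Defines a minimal coarse-grained air-monolayer-water slab in reduced
#' Lennard-Jones units (epsilon = sigma = m = kB = 1): a solvent slab
#' centred at z = 0 and periodic in x and y, a vacuum region along z,
#' and surfactants made of one head bead plus a short tail, with heads
#' bound to the solvent surface and tails pointing into the vacuum.
#' Semipermeable virtual walls at x = +-x_wall confine the surfactants
#' while the solvent passes freely, and a clean solvent margin extends
#' beyond each wall.
#'
#' Species tags are `"W"` (solvent), `"H"` (head), `"T"` (tail).  All
#' pair interactions are truncated force-shifted Lennard-Jones.
#' Solvent-solvent and head-solvent are attractive; tail-solvent is
#' attractive but markedly weaker than solvent-solvent, making the
#' tails mildly hydrophobic: the film floats on the slab, yet a
#' compressed, thickening tail mat imbibes some solvent into its
#' interstices.  That partial wetting reproduces the hallmark of real
#' monolayers at low molecular area -- an inhomogeneous surface zone of
#' solvent, head groups and chain segments that deepens as the film
#' packs -- so the 90-10 interfacial thickness grows monotonically
#' under compression while the bare-slab thickness stays the
#' infinite-dilution asymptote.  Tail-tail attraction condenses the
#' film; bonds along each chain are harmonic.
#'
#' The defaults define the reference study conditions used throughout
#' the package's tests: T = 0.75 (between the triple and critical
#' points of the truncated LJ fluid, so the slab coexists with a dilute
#' vapour), friction 1.0/tau, timestep 0.005 tau, slab number density
#' 0.8/sigma^3, clean-interface margin 4.5 sigma (the 18 angstrom
#' margin under the real-units mapping sigma = 4 angstrom).
#'
#' @param n_solvent requested solvent particle count (rounded to fill
#'   complete lattice layers at the slab density).
#' @param n_per_leaflet surfactants per leaflet (0 gives a bare slab).
#' @param tail_beads tail beads per surfactant.
#' @param box numeric `(L_x, L_y, L_z)` in sigma; L_z must leave a
#'   vacuum region above the film.
#' @param wall a [wall_spec()] in reduced units (`k` in
#'   epsilon/sigma^3 for the quadratic law), or `NULL` for a fully
#'   periodic system without walls.
#' @param temperature,friction,dt thermostat target, Langevin friction
#'   and timestep (reduced units).
#' @param slab_density target solvent number density.
#' @param margin clean-interface margin required beyond each wall.
#' @param eps,sigma,cutoff optional 3x3 matrices (species order W, H,
#'   T) overriding the pair interaction table.
#' @param bond_k,bond_r0 harmonic bond constant and rest length.
#' @param seed integer seed; every stochastic stage (placement jitter,
#'   velocity draw, thermostat noise) derives from it.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(n_solvent = 840, n_per_leaflet = 4, tail_beads = 2,
                     box = c(20, 7.5, 28),
                     wall = wall_spec(x_wall = 16 / 3, k = 50),
                     temperature = 0.75, friction = 1.0, dt = 0.005,
                     slab_density = 0.8, margin = 4.5,
                     eps = NULL, sigma = NULL, cutoff = NULL,
                     bond_k = 100, bond_r0 = 1.0, seed = 1L) {
  stopifnot(n_solvent > 0, n_per_leaflet >= 0, tail_beads >= 0,
            length(box) == 3, all(box > 0), dt > 0, temperature > 0,
            friction >= 0, slab_density > 0, margin >= 0)
  sp_names <- c("W", "H", "T")
  if (is.null(eps)) {
    eps <- matrix(c(1.00, 1.30, 0.45,
                    1.30, 1.00, 0.80,
                    0.45, 0.80, 0.60), 3, 3,
                  dimnames = list(sp_names, sp_names))
  }
  if (is.null(sigma))
    sigma <- matrix(1.0, 3, 3, dimnames = list(sp_names, sp_names))
  if (is.null(cutoff))
    cutoff <- matrix(2.5, 3, 3, dimnames = list(sp_names, sp_names))
  if (any(cutoff < sigma & eps > 0)) stop("cutoffs must be >= sigma")
  if (!is.null(wall)) {
    stopifnot(inherits(wall, "wall_spec"))
    if (wall$x_wall + margin > box[1] / 2)
      stop("walls too close to the box edge: x_wall + margin must be <= ",
           "L_x / 2 so a clean solvent margin remains beyond each wall")
  }
  structure(list(n_solvent = as.integer(n_solvent),
                 n_per_leaflet = as.integer(n_per_leaflet),
                 tail_beads = as.integer(tail_beads), box = box, wall = wall,
                 temperature = temperature, friction = friction, dt = dt,
                 slab_density = slab_density, margin = margin, eps = eps,
                 sigma = sigma, cutoff = cutoff, bond_k = bond_k,
                 bond_r0 = bond_r0, seed = as.integer(seed)),
            class = "toy_spec")
}

#' @export
print.toy_spec <- function(x, ...) {
  cat(sprintf(paste0("toy_spec: %d solvent + 2 x %d surfactants ",
                     "(%d tail beads), box %s, T = %.3g\n"),
              x$n_solvent, x$n_per_leaflet, x$tail_beads,
              paste(signif(x$box, 4), collapse = " x "), x$temperature))
  if (!is.null(x$wall)) print(x$wall)
  invisible(x)
}

#' Build the initial configuration of a toy system
#'
#' Deterministic for a given spec seed.  Solvent particles fill a cubic
#' lattice at the slab density spanning the full xy cross-section,
#' centred at z = 0 (the lattice layer count is rounded, so the actual
#' solvent count can differ slightly from the request).  Surfactants
#' are laid on a grid strictly between the walls on both z-surfaces of
#' the slab, heads at the surface and tails stacked outward into the
#' vacuum; solvent sites overlapping a surfactant bead (within 0.8
#' sigma) are removed.  Errors if the walls leave no clean margin or
#' the surfactant grid cannot fit between the walls.
#'
#' @param spec a [toy_spec()].
#' @return list of class `toy_state` with `coords`, `species`, `box`,
#'   `bonds` (two-column index matrix), `velocities` (`NULL`: drawn by
#'   the integrator) and `time`.
#' @export
build_system <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  box <- spec$box
  set.seed(spec$seed)
  a <- (1 / spec$slab_density)^(1 / 3)
  nx <- max(1L, floor(box[1] / a))
  ny <- max(1L, floor(box[2] / a))
  nz <- max(1L, round(spec$n_solvent / (nx * ny)))
  h <- nz * a                      # slab thickness
  if (h > 0.8 * box[3])
    stop("construction error: solvent slab (", signif(h, 3),
         " sigma) leaves no vacuum region in L_z = ", box[3])
  gx <- (seq_len(nx) - (nx + 1) / 2) * (box[1] / nx)
  gy <- (seq_len(ny) - (ny + 1) / 2) * (box[2] / ny)
  gz <- (seq_len(nz) - (nz + 1) / 2) * a
  sol <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sol <- sol + matrix(stats::runif(length(sol), -0.05 * a, 0.05 * a),
                      ncol = 3)
  surf <- NULL
  bonds <- NULL
  nbead <- 1L + spec$tail_beads
  if (spec$n_per_leaflet > 0) {
    if (is.null(spec$wall))
      xr <- c(-box[1] / 2 + 0.5, box[1] / 2 - 0.5)
    else
      xr <- c(-spec$wall$x_wall + 0.4, spec$wall$x_wall - 0.4)
    nsx <- ceiling(sqrt(spec$n_per_leaflet * diff(xr) / box[2]))
    nsy <- ceiling(spec$n_per_leaflet / nsx)
    if (nsx < 1 || diff(xr) <= 0)
      stop("construction error: no room for surfactants between the walls")
    px <- xr[1] + (rep(seq_len(nsx), each = nsy)[seq_len(spec$n_per_leaflet)] -
                     0.5) * diff(xr) / nsx
    py <- -box[2] / 2 +
      (rep(seq_len(nsy), times = nsx)[seq_len(spec$n_per_leaflet)] - 0.5) *
      box[2] / nsy
    one_leaflet <- function(side) {
      z_head <- side * (h / 2)
      do.call(rbind, lapply(seq_len(spec$n_per_leaflet), function(i) {
        zs <- z_head + side * spec$bond_r0 * (0:spec$tail_beads)
        cbind(px[i], py[i], zs)
      }))
    }
    surf <- rbind(one_leaflet(+1), one_leaflet(-1))
    nmol <- 2L * spec$n_per_leaflet
    if (spec$tail_beads > 0) {
      bonds <- do.call(rbind, lapply(seq_len(nmol), function(m) {
        o <- (m - 1L) * nbead
        cbind(o + seq_len(spec$tail_beads), o + seq_len(spec$tail_beads) + 1L)
      }))
    }
    # carve solvent sites that overlap surfactant beads
    keep <- rep(TRUE, nrow(sol))
    for (b in seq_len(nrow(surf))) {
      d2 <- (sol[, 1] - surf[b, 1])^2 + (sol[, 2] - surf[b, 2])^2 +
        (sol[, 3] - surf[b, 3])^2
      keep <- keep & d2 > 0.8^2
    }
    sol <- sol[keep, , drop = FALSE]
  }
  coords <- rbind(surf, sol)
  species <- c(rep(c("H", rep("T", spec$tail_beads)),
                   times = if (is.null(surf)) 0 else 2L * spec$n_per_leaflet),
               rep("W", nrow(sol)))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  structure(list(coords = unname(coords), species = species, box = box,
                 bonds = bonds, velocities = NULL, time = 0,
                 slab_thickness = h),
            class = "toy_state")
}

#' Run Langevin dynamics on a toy system
#'
#' Integrates the system with the BAOAB Langevin scheme and logs, every
#' `sample_every` steps: the frame, the instantaneous wall restoring
#' force (total and per species), the instantaneous pressure-tensor
#' diagonals (kinetic plus pair, bond and wall virial, over the full
#' box volume), the kinetic temperature and the potential energy.
#' Runs are bitwise reproducible for a given seed.  Chaining runs is
#' done by passing the returned `final_state` back in as `state`.
#'
#' @param spec a [toy_spec()].
#' @param state a `toy_state` from [build_system()] or a previous run's
#'   `final_state`; `NULL` builds a fresh system.
#' @param n_steps number of integration steps.
#' @param sample_every sampling stride in steps.
#' @param seed RNG seed for this run (defaults to the spec seed).
#' @param units_out `"reduced"` (default) or `"real"`: with `"real"`,
#'   outputs are mapped to real units with sigma = 4 angstrom,
#'   epsilon = 0.3 kcal/mol, tau = 1 ps (lengths in angstrom, forces
#'   in kcal/mol/angstrom, pressures in bar).
#' @return list of class `toy_run` with `trajectory`, `wall_force`
#'   (data frame `time, f_total, f_H, f_T`), `pressure` (a
#'   [pressure_series()]), `energy` (data frame `time, temperature,
#'   potential`), `final_state` and `spec`.
#' @export
run_toysim <- function(spec, state = NULL, n_steps, sample_every = 100L,
                       seed = spec$seed, units_out = "reduced") {
  stopifnot(inherits(spec, "toy_spec"), n_steps >= 1, sample_every >= 1)
  units_out <- .check_units(units_out)
  if (is.null(state)) state <- build_system(spec)
  sp_int <- match(state$species, c("W", "H", "T")) - 1L
  if (anyNA(sp_int)) stop("unknown species tag in state")
  has_wall <- !is.null(spec$wall)
  restrained <- if (has_wall) c("W", "H", "T") %in% spec$wall$restrained_species
                else rep(FALSE, 3)
  res <- .sim_run_cpp(
    coords = state$coords, species = sp_int, box = state$box,
    velocities = state$velocities, eps = unname(spec$eps),
    sigma = unname(spec$sigma), rcut = unname(spec$cutoff),
    bonds = state$bonds, bond_k = spec$bond_k, bond_r0 = spec$bond_r0,
    has_wall = has_wall,
    x_wall = if (has_wall) spec$wall$x_wall else 0,
    wall_k = if (has_wall) spec$wall$k else 0,
    wall_pow = if (has_wall && spec$wall$force_law == "quadratic") 2L else 1L,
    restrained = restrained, temperature = spec$temperature,
    friction = spec$friction, dt = spec$dt, n_steps = as.integer(n_steps),
    sample_every = as.integer(sample_every), t0 = state$time,
    seed = as.numeric(seed),
    relax_steps = if (is.null(state$velocities)) 200L else 0L)
  u <- .toy_unit_scale(units_out)
  traj <- trajectory(res$traj * u$length, state$species,
                     state$box * u$length, res$times * u$time,
                     units = units_out)
  wall_df <- data.frame(time = res$times * u$time,
                        f_total = res$wall_total * u$force,
                        f_H = res$wall_by_species[, 2] * u$force,
                        f_T = res$wall_by_species[, 3] * u$force)
  pres <- pressure_series(res$times * u$time, res$pxx * u$pressure,
                          res$pyy * u$pressure, res$pzz * u$pressure,
                          box_lz = state$box[3] * u$length, units = units_out)
  energy <- data.frame(time = res$times * u$time,
                       temperature = res$temperature,
                       potential = res$potential * u$energy)
  final_state <- state
  final_state$coords <- res$coords_final
  final_state$velocities <- res$velocities_final
  final_state$time <- if (length(res$times)) res$times[length(res$times)]
                      else state$time + n_steps * spec$dt
  structure(list(trajectory = traj, wall_force = wall_df, pressure = pres,
                 energy = energy, final_state = final_state, spec = spec,
                 units = units_out),
            class = "toy_run")
}

# conversion factors from reduced toy units to the output unit system
.toy_unit_scale <- function(units_out, sigma_A = 4, eps_kcal = 0.3) {
  if (units_out == "reduced")
    return(list(length = 1, time = 1, force = 1, energy = 1, pressure = 1))
  # 1 kcal/mol/A^3 in bar
  kcal_A3_bar <- 4184 / 6.02214076e23 / 1e-30 / 1e5
  list(length = sigma_A, time = 1, force = eps_kcal / sigma_A,
       energy = eps_kcal, pressure = eps_kcal / sigma_A^3 * kcal_A3_bar)
}

#' @export
print.toy_run <- function(x, ...) {
  cat("toy_run:", n_frames(x$trajectory), "sampled frames,",
      n_particles(x$trajectory), "particles\n")
  cat(sprintf("  <T> = %.4g, <F_wall> = %.4g\n",
              mean(x$energy$temperature), mean(x$wall_force$f_total)))
  invisible(x)
}

#' Generate a deterministic test fixture
#'
#' Canned inputs used by the test-suite and by examples:
#'
#' * `"penetration-frames"`: a hand-built 2-frame trajectory whose wall
#'   forces are computable by hand.  Frame 1 has a single head bead
#'   exactly 1 length unit beyond the +x wall (`x_wall = 10`,
#'   `k = 20`, quadratic law: instantaneous force `20 * 1^2 = 20`);
#'   frame 2 has every bead inside, so the 2-frame mean is 10 and the
#'   frame-1-only mean is exactly 20.
#' * `"clean-slab"`: a short seeded run of a bare solvent slab (the
#'   infinite-dilution reference for xi).
#' * `"dilute-monolayer"`: a short seeded run with widely spread
#'   surfactants (xi close to 1 by construction).
#' * `"compressed-monolayer"`: a short seeded run near full surface
#'   coverage.
#'
#' @param kind fixture name, see above.
#' @param seed integer seed.
#' @param n_steps,sample_every run length for the simulated kinds.
#' @return for `"penetration-frames"`, a list with `traj`, `wall` and
#'   `expected_mean_force`; otherwise a `toy_run`.
#' @export
generate_fixture <- function(kind = c("clean-slab", "dilute-monolayer",
                                      "compressed-monolayer",
                                      "penetration-frames"),
                             seed = 1L, n_steps = 20000L,
                             sample_every = 50L) {
  kind <- match.arg(kind)
  if (kind == "penetration-frames") {
    # 4 beads: 2 solvent (free to be anywhere), 1 head, 1 tail
    f1 <- rbind(c(11, 0, 5), c(-3, 1, 4),    # H beyond +x wall by 1, T inside
                c(12, 2, -2), c(0, 0, 0))    # solvent: ignored by the wall
    f2 <- rbind(c(9.5, 0, 5), c(-3, 1, 4), c(12, 2, -2), c(0, 0, 0))
    coords <- array(c(f1, f2), dim = c(4, 3, 2))
    traj <- trajectory(coords, c("H", "T", "W", "W"), c(30, 10, 30),
                       times = c(0, 1))
    return(list(traj = traj,
                wall = wall_spec(x_wall = 10, k = 20,
                                 force_law = "quadratic"),
                expected_mean_force = 10,        # 2-frame mean
                expected_frame1_force = 20))     # single-frame value
  }
  spec <- switch(kind,
    "clean-slab" = toy_spec(n_solvent = 840, n_per_leaflet = 0,
                            wall = NULL, seed = seed),
    # defaults: x_wall = 16/3 with 4 per leaflet -> A = 20 sigma^2
    "dilute-monolayer" = toy_spec(seed = seed),
    # x_wall = 1 with 4 per leaflet -> A = 3.75 sigma^2
    "compressed-monolayer" = toy_spec(wall = wall_spec(x_wall = 1, k = 50),
                                      seed = seed))
  run_toysim(spec, n_steps = n_steps, sample_every = sample_every,
             seed = seed)
}
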