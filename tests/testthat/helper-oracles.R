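# Independent reference implementations and analytic fixtures used as
# oracles.  These deliberately avoid the package's vectorized code paths.

# naive per-frame, per-bead double loop over the wall force law
naive_wall_force <- function(traj, wall) {
  nf <- n_frames(traj)
  per_frame <- numeric(nf)
  for (f in seq_len(nf)) {
    contrib <- numeric(0)
    for (i in seq_len(n_particles(traj))) {
      if (!(traj$species[i] %in% wall$restrained_species)) next
      d <- abs(traj$coords[i, 1, f]) - wall$x_wall
      if (d > 0)
        contrib <- c(contrib,
                     if (wall$force_law == "quadratic") wall$k * d^2
                     else wall$k * d)
    }
    per_frame[f] <- sum(contrib)   # bead-index order
  }
  list(per_frame = per_frame, mean = mean(per_frame))
}

# random penetration-frames trajectory for oracle comparisons
random_penetration_traj <- function(n = 12, nf = 5, x_wall = 8) {
  species <- sample(c("W", "H", "T"), n, replace = TRUE)
  coords <- array(stats::runif(n * 3 * nf, -12, 12), dim = c(n, 3, nf))
  trajectory(coords, species, box = c(30, 10, 30), times = seq_len(nf))
}

# single-interface hyperbolic-tangent density profile
tanh_profile <- function(w = 1, rho0 = 0.8, bin = w / 20, z0 = 0,
                         half_span = 12 * w) {
  z <- seq(z0 - half_span, z0 + half_span, by = bin)
  rho <- rho0 / 2 * (1 - tanh((z - z0) / w))
  as_density_profile(z, rho)
}

# one bead penetrating one wall by depth d, plus inert particles
single_penetration_traj <- function(d = 1, x_wall = 10) {
  f1 <- rbind(c(x_wall + d, 0, 5), c(0, 0, 4), c(11.5, 2, -2))
  trajectory(array(f1, dim = c(3, 3, 1)), c("H", "T", "W"), c(30, 10, 30))
}
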