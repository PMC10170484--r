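test_that("a uniform lattice gives a flat profile at the exact density", {
  # 10 particles per z-level, 10 levels aligned with the bin grid
  box <- c(5, 2, 10)
  z <- rep(seq(-4.5, 4.5, by = 1), each = 10)
  xy <- matrix(stats::runif(200, -0.9, 0.9), ncol = 2)
  coords <- array(c(xy[, 1] * 2.5, xy[, 2], z), dim = c(100, 3, 1))
  traj <- trajectory(coords, rep("W", 100), box)
  prof <- density_profile(traj, bin_width = 1)
  expect_equal(unname(prof$density[, "W"]),
               rep(100 / prod(box), 10))
})

test_that("particles on a single plane occupy a single bin", {
  coords <- array(c(runif(20, -3, 3), runif(20, -1, 1), rep(2.05, 20)),
                  dim = c(20, 3, 1))
  traj <- trajectory(coords, rep("W", 20), c(8, 2, 12))
  prof <- density_profile(traj, bin_width = 0.5)
  expect_equal(sum(prof$density > 0), 1)
})

test_that("multi-frame profiles equal the average of per-frame histograms", {
  set.seed(31)
  box <- c(6, 4, 15)
  c1 <- cbind(runif(40, -3, 3), runif(40, -2, 2), runif(40, -7, 7))
  c2 <- c1
  c2[, 3] <- c2[, 3] + 0.25   # displaced by half a bin
  traj <- trajectory(array(c(c1, c2), dim = c(40, 3, 2)), rep("W", 40),
                     box, times = c(0, 1))
  prof <- density_profile(traj, bin_width = 0.5)
  # brute-force per-frame oracle
  one <- function(cc) {
    prof1 <- density_profile(trajectory(cc, rep("W", 40), box),
                             bin_width = 0.5)
    prof1$density[, "W"]
  }
  expect_equal(unname(prof$density[, "W"]), unname((one(c1) + one(c2)) / 2))
})

test_that("selection and region arguments are validated", {
  coords <- array(stats::rnorm(30), dim = c(10, 3, 1))
  traj <- trajectory(coords, rep(c("W", "H"), 5), c(10, 10, 10))
  expect_error(density_profile(traj, species = "X", bin_width = 0.5),
               "not present")
  expect_error(density_profile(traj, bin_width = 11), "larger than the box")
  expect_error(density_profile(traj, bin_width = 0.5, region = c(-9, 2)),
               "outside the box")
})

test_that("tanh interface thickness matches the closed form within 1%", {
  w <- 1.3
  prof <- tanh_profile(w = w, bin = w / 20)
  th <- interfacial_thickness(prof)
  expect_equal(th$lz_int, 2 * atanh(0.8) * w, tolerance = 0.01)
})

test_that("linear-ramp thickness is 80% of the ramp length", {
  # plateau, then a linear drop from rho0 to 0 over L = 5
  z <- seq(0, 20, by = 0.05)
  rho <- ifelse(z < 10, 0.8, ifelse(z < 15, 0.8 * (15 - z) / 5, 0))
  th <- interfacial_thickness(as_density_profile(z, rho))
  expect_lt(abs(th$lz_int - 0.8 * 5), 0.05 + 1e-9)  # within one bin width
})

test_that("a step profile has thickness of at most one bin", {
  z <- seq(-10, 10, by = 0.25)
  rho <- ifelse(abs(z) < 5, 0.9, 0)
  th <- interfacial_thickness(as_density_profile(z, rho))
  expect_lte(th$lz_int, 0.25 + 1e-9)
})

test_that("thickness is invariant under density rescaling and scales with z", {
  prof <- tanh_profile(w = 0.9, bin = 0.05)
  th <- interfacial_thickness(prof)
  scaled <- as_density_profile(prof$bin_centers, prof$density[, 1] * 7.3)
  expect_equal(interfacial_thickness(scaled)$lz_int, th$lz_int)
  # tolerance covers boundary-bin inclusion flips in the bulk window
  stretched <- as_density_profile(prof$bin_centers * 2.5, prof$density[, 1])
  expect_equal(interfacial_thickness(stretched)$lz_int, 2.5 * th$lz_int,
               tolerance = 1e-4)
})

test_that("halving the bin width moves the thickness by less than a bin", {
  w <- 1.1
  t1 <- interfacial_thickness(tanh_profile(w = w, bin = 0.2))$lz_int
  t2 <- interfacial_thickness(tanh_profile(w = w, bin = 0.1))$lz_int
  expect_lt(abs(t1 - t2), 0.2)
})

test_that("non-monotonic tails warn and use the outermost crossing", {
  z <- seq(0, 30, by = 0.1)
  rho <- 0.4 * (1 - tanh((z - 10) / 1))
  bump <- 0.15 * exp(-(z - 14)^2 / 0.5)  # vapour blob above the 10% level
  expect_warning(th <- interfacial_thickness(as_density_profile(z, rho + bump)),
                 "outermost")
  clean <- interfacial_thickness(as_density_profile(z, rho))
  expect_gt(th$lz_int, clean$lz_int)
})

test_that("profiles that never reach the upper threshold are rejected", {
  z <- seq(0, 10, by = 0.1)
  expect_error(interfacial_thickness(as_density_profile(z, rep(0, 101))),
               "degenerate")
  # a fully liquid box has no interface on either side
  expect_error(interfacial_thickness(as_density_profile(z, rep(0.8, 101))),
               "no interface")
})

test_that("xi follows the thickness ratio and guards its domain", {
  expect_equal(xi_coefficient(3.2, 3.2)$xi, 1)
  expect_equal(xi_coefficient(6.4, 3.2)$xi, 0.5)
  expect_warning(xi <- xi_coefficient(2, 3), "physically unexpected")
  expect_equal(xi$xi, 1.5)
  expect_error(xi_coefficient(-1, 3), "positive")
  expect_error(xi_coefficient(3, 0), "positive")
})

test_that("reference_thickness refuses monolayer-contaminated input", {
  pen <- generate_fixture("penetration-frames")
  expect_error(reference_thickness(pen$traj), "clean solvent slab")
})
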