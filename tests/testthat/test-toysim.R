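test_that("system construction is deterministic and respects composition", {
  spec <- toy_spec(seed = 17)
  s1 <- build_system(spec)
  s2 <- build_system(spec)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$species, s2$species)
  expect_equal(sum(s1$species == "H"), 2 * spec$n_per_leaflet)
  expect_equal(sum(s1$species == "T"),
               2 * spec$n_per_leaflet * spec$tail_beads)

  bare <- build_system(toy_spec(n_per_leaflet = 0, wall = NULL, seed = 17))
  expect_true(all(bare$species == "W"))
  expect_equal(nrow(bare$bonds), 0)
})

test_that("surfactants are placed at the solvent surfaces, between the walls", {
  spec <- toy_spec(seed = 3)
  st <- build_system(spec)
  heads <- st$coords[st$species == "H", , drop = FALSE]
  h <- st$slab_thickness
  expect_true(all(abs(heads[, 3]) <= h / 2 + 1))   # at the surfaces
  expect_true(all(abs(heads[, 3]) >= h / 2 - 1.5))
  expect_true(all(abs(heads[, 1]) < spec$wall$x_wall))  # between the walls
  tails <- st$coords[st$species == "T", , drop = FALSE]
  expect_true(all(abs(tails[, 3]) > h / 2 - 1))    # pointing into the vacuum
})

test_that("impossible geometries raise construction errors", {
  expect_error(toy_spec(wall = wall_spec(x_wall = 9, k = 50)),
               "clean solvent margin")
  expect_error(build_system(toy_spec(n_solvent = 5000, wall = NULL,
                                     n_per_leaflet = 0)),
               "vacuum")
})

test_that("seeded runs are bitwise reproducible", {
  spec <- toy_spec(n_solvent = 260, n_per_leaflet = 2, box = c(12, 7.5, 20),
                   wall = wall_spec(x_wall = 1.5, k = 50), seed = 9)
  r1 <- run_toysim(spec, n_steps = 2000, sample_every = 100, seed = 9)
  r2 <- run_toysim(spec, n_steps = 2000, sample_every = 100, seed = 9)
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)
  expect_identical(r1$pressure$pzz, r2$pressure$pzz)
  expect_identical(r1$wall_force$f_total, r2$wall_force$f_total)
  r3 <- run_toysim(spec, n_steps = 2000, sample_every = 100, seed = 10)
  expect_false(identical(r1$trajectory$coords, r3$trajectory$coords))
})

test_that("with zero friction and no walls, momentum is conserved", {
  spec <- toy_spec(n_solvent = 216, n_per_leaflet = 0, box = c(9, 7.5, 15),
                   wall = NULL, friction = 0, seed = 11)
  st <- build_system(spec)
  set.seed(11)
  v <- matrix(rnorm(nrow(st$coords) * 3, sd = sqrt(0.75)), ncol = 3)
  v <- sweep(v, 2, colMeans(v))
  st$velocities <- v
  out <- run_toysim(spec, st, n_steps = 1000, sample_every = 1000)
  expect_lt(max(abs(colSums(out$final_state$velocities) - colSums(v))),
            1e-9)
})

test_that("the thermostat holds the target temperature within 2%", {
  spec <- toy_spec(n_solvent = 500, n_per_leaflet = 0, box = c(12, 7.5, 20),
                   wall = NULL, seed = 21)
  st <- build_system(spec)
  out <- run_toysim(spec, st, n_steps = 50000, sample_every = 25)
  expect_equal(mean(out$energy$temperature), spec$temperature,
               tolerance = 0.02)
})

test_that("with interactions off the pressure is the ideal-gas value", {
  eps0 <- matrix(0, 3, 3)
  spec <- toy_spec(n_solvent = 400, n_per_leaflet = 0, box = c(10, 10, 10),
                   wall = NULL, eps = eps0, seed = 2)
  st <- build_system(spec)
  out <- run_toysim(spec, st, n_steps = 50000, sample_every = 10)
  p_mean <- mean((out$pressure$pxx + out$pressure$pyy + out$pressure$pzz) / 3)
  n <- nrow(st$coords)
  expect_equal(p_mean, n * spec$temperature / prod(spec$box),
               tolerance = 0.01)
})

test_that("solvent crosses the walls freely while surfactants stay confined", {
  run <- cached("semiperm", {
    run_toysim(toy_spec(seed = 4010), n_steps = 30000, sample_every = 50,
               seed = 4010)
  })
  xw <- 16 / 3
  x <- run$trajectory$coords[, 1, ]
  is_w <- run$trajectory$species == "W"
  w_beyond <- mean(abs(x[is_w, ]) > xw)
  s_beyond <- mean(abs(x[!is_w, ]) > xw)
  expect_gt(w_beyond, 0.1)    # the margin region holds free solvent
  expect_lt(s_beyond, 0.02)   # surfactant excursions are transient
  # solvent flux through the wall planes is balanced: the margin
  # population stays steady instead of draining or accumulating
  frac_t <- colMeans(abs(x[is_w, , drop = FALSE]) > xw)
  nf <- length(frac_t)
  drift <- mean(frac_t[seq(nf / 2)]) - mean(frac_t[-seq(nf / 2)])
  expect_lt(abs(drift), 0.05)
})

test_that("divergent dynamics stop with an informative error", {
  spec <- toy_spec(n_solvent = 50, n_per_leaflet = 0, box = c(10, 10, 10),
                   wall = NULL, friction = 0, seed = 1)
  st <- build_system(spec)
  st$velocities <- matrix(1e7, nrow(st$coords), 3)
  expect_error(run_toysim(spec, st, n_steps = 200, sample_every = 10),
               "diverged at step")
})

test_that("fixture kinds are validated and documented values hold", {
  expect_error(generate_fixture("no-such-kind"))
  pen <- generate_fixture("penetration-frames")
  expect_identical(wall_force(subset_frames(pen$traj, 1),
                              pen$wall)$mean_force, 20)
  clean <- cached("fix_clean", generate_fixture("clean-slab", seed = 5,
                                                n_steps = 10000))
  th <- reference_thickness(clean$trajectory)
  expect_gt(th$lz_int, 1)
  expect_identical(mean(clean$wall_force$f_total), 0)
})

test_that("real-units output applies the sigma/epsilon mapping", {
  spec <- toy_spec(n_solvent = 260, n_per_leaflet = 2, box = c(12, 7.5, 20),
                   wall = wall_spec(x_wall = 1.5, k = 50), seed = 9)
  red <- run_toysim(spec, n_steps = 500, sample_every = 100, seed = 9)
  real <- run_toysim(spec, n_steps = 500, sample_every = 100, seed = 9,
                     units_out = "real")
  expect_equal(real$trajectory$coords, red$trajectory$coords * 4)
  expect_equal(real$wall_force$f_total, red$wall_force$f_total * 0.3 / 4)
  expect_equal(real$trajectory$units, "real")
  kcal_A3_bar <- 4184 / 6.02214076e23 / 1e-30 / 1e5
  expect_equal(real$pressure$pzz,
               red$pressure$pzz * 0.3 / 64 * kcal_A3_bar)
})
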