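test_that("trajectory constructor enforces its invariants", {
  coords <- array(stats::rnorm(4 * 3 * 2), dim = c(4, 3, 2))
  traj <- trajectory(coords, c("W", "W", "H", "T"), c(10, 10, 20),
                     times = c(0, 1))
  expect_equal(n_frames(traj), 2)
  expect_equal(n_particles(traj), 4)
  expect_error(trajectory(coords, c("W", "W"), c(10, 10, 20)),
               "species count")
  expect_error(trajectory(coords, c("W", "W", "H", "T"), c(10, -1, 20)),
               "positive")
  expect_error(trajectory(coords, c("W", "W", "H", "T"), c(10, 10, 20),
                          times = c(1, 1)), "strictly increasing")
})

test_that("extended-XYZ write/read round trip is the identity", {
  set.seed(42)
  coords <- array(round(stats::rnorm(5 * 3 * 3, sd = 4), 6),
                  dim = c(5, 3, 3))
  traj <- trajectory(coords, c("W", "W", "H", "T", "T"), c(12, 8, 25),
                     times = c(0, 10, 20))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path, format = "xyz-ext")
  back <- read_trajectory(path, format = "xyz-ext")
  expect_equal(back$coords, traj$coords)
  expect_identical(back$species, traj$species)
  expect_equal(back$box, traj$box)
  expect_equal(back$times, traj$times)
})

test_that("the two dialects store identical coordinates", {
  set.seed(7)
  coords <- array(round(stats::runif(4 * 3 * 2, -6, 6), 6),
                  dim = c(4, 3, 2))
  traj <- trajectory(coords, c("H", "T", "W", "W"), c(14, 9, 30),
                     times = c(0, 1))
  p1 <- withr::local_tempfile(fileext = ".xyz")
  p2 <- withr::local_tempfile(fileext = ".dump")
  write_trajectory(traj, p1, "xyz-ext")
  write_trajectory(traj, p2, "lammps-dump")
  t1 <- read_trajectory(p1, "xyz-ext")
  t2 <- read_trajectory(p2, "lammps-dump",
                        species_map = c("1" = "H", "2" = "T", "3" = "W"))
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$species, t2$species)
  expect_equal(t1$box, t2$box)
})

test_that("a frame with a missing atom is a structural error", {
  lines <- c("3",
             'Lattice="10 0 0 0 10 0 0 0 10" Time=0',
             "W 1 1 1", "W 2 2 2", "H 3 3 3",
             "3",
             'Lattice="10 0 0 0 10 0 0 0 10" Time=1',
             "W 1 1 1", "W 2 2 2")
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, path)
  expect_error(read_trajectory(path, "xyz-ext"), "structural|parse")
})

test_that("malformed records name the offending line", {
  lines <- c("2", 'Lattice="10 0 0 0 10 0 0 0 10" Time=0',
             "W 1 1 1", "W 2 nope 2")
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, path)
  expect_error(read_trajectory(path, "xyz-ext"), "non-numeric")
  lines2 <- c("2", "no lattice here", "W 1 1 1", "W 2 2 2")
  writeLines(lines2, path)
  expect_error(read_trajectory(path, "xyz-ext"), "line 2")
})

test_that("pressure series CSV round trips and enforces its schema", {
  ps <- pressure_series(times = c(0, 1, 2), pxx = c(1, 2, 3),
                        pyy = c(1.5, 2.5, 3.5), pzz = c(0.5, 0.25, 0.125),
                        box_lz = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pressure_series(ps, path)
  back <- read_pressure_series(path)
  expect_equal(back$pzz, ps$pzz)
  expect_equal(back$box_lz, 25)
  expect_equal(length(back$times), 3)

  df <- utils::read.csv(path, comment.char = "#")
  df$pzz <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_pressure_series(path, box_lz = 25), "schema.*pzz")

  expect_error(pressure_series(1:3, 1:3, 1:3, 1:2, 25), "equal length")
  expect_error(pressure_series(1:3, 1:3, 1:3, 1:3, -1), "positive")
})

test_that("wall-force logs round trip", {
  log <- data.frame(time = c(0, 1), f_total = c(3, 0), f_H = c(2, 0),
                    f_T = c(1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wall_force_log(log, path)
  expect_equal(read_wall_force_log(path), log)
})

test_that("isotherm JSON round trips, with null for absent tensor values", {
  pts <- data.frame(area_per_lipid = c(20, 10, 5),
                    pi_ideal = c(0.03, 0.08, 0.2),
                    pi_ideal_se = c(0.005, 0.006, 0.01),
                    xi = c(0.98, 0.9, 0.85), lz_int = c(3.4, 3.7, 3.9),
                    pi_real = c(0.03, 0.08, 0.2) * c(0.98, 0.9, 0.85),
                    pi_real_se = c(0.005, 0.005, 0.009),
                    pi_tensor = c(0.028, NA, NA),
                    pi_tensor_se = c(0.02, NA, NA),
                    flagged = c(FALSE, FALSE, TRUE))
  iso <- isotherm_points(pts, units = "reduced", temperature = 0.75,
                         direction = "compression")
  path <- withr::local_tempfile(fileext = ".json")
  write_isotherm(iso, path)
  expect_match(paste(readLines(path), collapse = ""), "null")
  back <- read_isotherm(path)
  expect_equal(back$pi_real, iso$pi_real)
  expect_equal(back$pi_tensor, iso$pi_tensor)
  expect_equal(attr(back, "direction"), "compression")
  expect_error(write_isotherm(iso[0, ], path))
})

test_that("run configuration loads from YAML and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: reduced", "bin_width: 0.2", "n_blocks: 4",
               "margin: 5", "wall:", "  x_wall: 6", "  k: 50"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$bin_width, 0.2)
  expect_equal(cfg$wall$x_wall, 6)
  expect_error(run_config(n_blocks = 1), "block count")
  expect_error(run_config(margin = -1), "margin")
  expect_error(run_config(bin_width = 0), "bin width")
})
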