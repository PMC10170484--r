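test_that("area per lipid follows the wall geometry", {
  expect_equal(area_per_lipid(40, 40, 64), 50)
  expect_equal(area_per_lipid(40, 40, 128), 25)  # doubling n halves A
  expect_equal(area_per_lipid(16 / 3, 7.5, 4), 20)  # reduced units pass through
  expect_error(area_per_lipid(40, 40, 0), "at least one lipid")
  expect_error(area_per_lipid(-1, 40, 64), "x_wall")
})

test_that("isotherm assembly validates ordering and internal consistency", {
  pts <- data.frame(area_per_lipid = c(10, 20), pi_ideal = c(0.1, 0.05),
                    xi = c(0.9, 1), pi_real = c(0.09, 0.05))
  iso <- isotherm_points(pts)
  expect_equal(iso$area_per_lipid, c(20, 10))  # ordered by descending area
  bad <- pts
  bad$pi_real[1] <- 0.2
  expect_error(isotherm_points(bad), "pi_real must equal")
  dup <- pts
  dup$area_per_lipid <- c(10, 10)
  expect_error(isotherm_points(dup), "strictly monotone")
  expect_error(isotherm_points(pts[0, ]))
})

test_that("plateau detection finds flat stretches and nothing else", {
  mk <- function(a, p) isotherm_points(
    data.frame(area_per_lipid = a, pi_ideal = p, xi = 1, pi_real = p))
  # strictly steep isotherm: no plateau
  steep <- mk(c(80, 70, 60, 50), c(1, 11, 21, 31))
  expect_null(plateau_detect(steep, slope_threshold = 0.5))
  # three consecutive equal pressures: that interval
  flat <- mk(c(80, 70, 60, 55, 50, 45), c(2, 10, 10, 10, 20, 30))
  expect_equal(plateau_detect(flat, slope_threshold = 0.1), c(55, 70))
  # zero threshold never qualifies on noisy data
  set.seed(8)
  noisy <- mk(seq(80, 45, by = -5), cumsum(runif(8)))
  expect_null(plateau_detect(noisy, slope_threshold = 0))
  expect_error(plateau_detect(mk(c(80, 70), c(1, 2))), "at least 4")
})

test_that("a single-area sweep equals the direct per-area analysis", {
  ref <- sweep_clean()
  spec <- toy_spec(seed = 4321)
  iso <- sweep_isotherm(spec, areas = 20, direction = "compression",
                        per_area_steps = 4000, sample_every = 50,
                        burn_in = 0.25, lz_ref = ref$lz_ref$lz_int,
                        equil_steps = 1000, seed = 4321)
  # reproduce the same run by hand
  spec_i <- spec
  spec_i$wall$x_wall <- 20 * spec$n_per_leaflet / (2 * spec$box[2])
  st <- build_system(spec_i)
  eq <- run_toysim(spec_i, st, n_steps = 1000, sample_every = 1000,
                   seed = 4321)
  run <- run_toysim(spec_i, eq$final_state, n_steps = 4000,
                    sample_every = 50, seed = 4322)
  keep <- seq(21, 80)
  prod <- run
  prod$trajectory <- subset_frames(run$trajectory, keep)
  row <- isotherm_point(prod, spec_i$wall, ref$lz_ref$lz_int,
                        spec$n_per_leaflet)
  expect_equal(iso$pi_ideal, row$pi_ideal)
  expect_equal(iso$xi, row$xi)
  expect_equal(iso$pi_real, row$pi_real)
})

test_that("sweeps demand a consistent area ordering and wall margin", {
  ref_lz <- 3.4
  spec <- toy_spec(seed = 1)
  expect_error(sweep_isotherm(spec, c(5, 10), direction = "compression",
                              lz_ref = ref_lz), "decreasing")
  expect_error(sweep_isotherm(spec, c(5, 10, 80), direction = "expansion",
                              lz_ref = ref_lz), "clean margin")
})

test_that("isotherm JSON output is a pure function of the points", {
  pts <- data.frame(area_per_lipid = c(20, 10), pi_ideal = c(0.05, 0.1),
                    pi_ideal_se = c(0.01, 0.01), xi = c(1, 0.9),
                    lz_int = c(3.4, 3.8), pi_real = c(0.05, 0.09),
                    pi_real_se = c(0.01, 0.009),
                    pi_tensor = c(NA, NA), pi_tensor_se = c(NA, NA),
                    flagged = c(FALSE, FALSE))
  iso <- isotherm_points(pts, temperature = 0.75)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_isotherm(iso, p1)
  write_isotherm(iso, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("replicate isotherms combine by inverse-variance weighting", {
  mk <- function(p, se) isotherm_points(data.frame(
    area_per_lipid = c(20, 10), pi_ideal = p, pi_ideal_se = se,
    xi = 1, lz_int = c(3.4, 3.6), pi_real = p, pi_real_se = se,
    pi_tensor = NA_real_, pi_tensor_se = NA_real_,
    flagged = c(FALSE, TRUE)))
  i1 <- mk(c(0.04, 0.10), c(0.01, 0.02))
  i2 <- mk(c(0.06, 0.08), c(0.02, 0.01))
  comb <- combine_isotherms(i1, i2)
  # hand-computed inverse-variance means
  w <- 1 / c(0.01, 0.02)^2
  expect_equal(comb$pi_real[1], sum(c(0.04, 0.06) * w) / sum(w))
  expect_equal(comb$pi_real_se[1], sqrt(1 / sum(w)))
  expect_equal(comb$pi_real[2], sum(c(0.10, 0.08) * rev(w)) / sum(w))
  expect_equal(comb$lz_int, c(3.4, 3.6))  # identical in both replicates
  expect_true(comb$flagged[2])
  expect_false(comb$flagged[1])
  # stored xi stays consistent with the combined pressures
  expect_equal(comb$pi_real, comb$pi_ideal * comb$xi)
  i3 <- mk(c(0.04, 0.1), c(0.01, 0.02))
  attr(i3, "units") <- "reduced"
  i3$area_per_lipid <- c(20, 11)
  expect_error(combine_isotherms(i1, isotherm_points(i3)), "same area grid")
})
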