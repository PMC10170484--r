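#' Area per lipid between the walls
#'
#' With the surfactant count held constant, the molecular area is set
#' by the wall separation: `A = 2 x_wall L_y / n_per_leaflet`, the
#' interfacial area between the walls divided by the surfactants in one
#' leaflet.
#'
#' @param x_wall wall position (walls at +-x_wall), > 0.
#' @param l_y box length along y, > 0.
#' @param n_per_leaflet surfactants per leaflet, > 0.
#' @return area per lipid (square angstrom or sigma^2).
#' @export
area_per_lipid <- function(x_wall, l_y, n_per_leaflet) {
  if (!is.numeric(x_wall) || any(x_wall <= 0)) stop("x_wall must be > 0")
  if (!is.numeric(l_y) || l_y <= 0) stop("l_y must be > 0")
  if (!is.numeric(n_per_leaflet) || n_per_leaflet <= 0)
    stop("need at least one lipid per leaflet")
  2 * x_wall * l_y / n_per_leaflet
}

# wall position that realizes a target area per lipid
.x_wall_for_area <- function(area, l_y, n_per_leaflet) {
  area * n_per_leaflet / (2 * l_y)
}

#' Assemble an isotherm data frame from per-point values
#'
#' Validates the point set (positive, strictly monotone areas;
#' `pi_real = pi_ideal * xi` consistency) and attaches metadata.
#' Points are kept ordered by descending area.
#'
#' @param points data frame with columns `area_per_lipid`, `pi_ideal`,
#'   `pi_ideal_se`, `xi`, `lz_int`, `pi_real`, `pi_real_se`,
#'   `pi_tensor`, `pi_tensor_se`, `flagged`.
#' @param units `"real"` or `"reduced"`.
#' @param temperature simulation temperature (metadata).
#' @param direction `"compression"`, `"expansion"` or `"independent"`.
#' @return the points as a data frame of class `isotherm`.
#' @export
isotherm_points <- function(points, units = "reduced", temperature = NA,
                            direction = "independent") {
  stopifnot(is.data.frame(points), nrow(points) >= 1)
  need <- c("area_per_lipid", "pi_ideal", "xi", "pi_real")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols))
    stop("missing isotherm column(s): ", paste(missing_cols, collapse = ", "))
  if (any(points$area_per_lipid <= 0)) stop("areas must be > 0")
  points <- points[order(-points$area_per_lipid), , drop = FALSE]
  if (anyDuplicated(points$area_per_lipid))
    stop("areas must be strictly monotone within a sweep")
  ok <- is.na(points$pi_real) | is.na(points$xi) |
    abs(points$pi_real - points$pi_ideal * points$xi) <=
      1e-9 * (1 + abs(points$pi_real))
  if (!all(ok))
    stop("inconsistent point(s): pi_real must equal pi_ideal * xi")
  rownames(points) <- NULL
  structure(points, class = c("isotherm", "data.frame"), units = units,
            temperature = temperature, direction = direction)
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("isotherm: %d area points, %s sweep (%s units), T = %s\n",
              nrow(x), attr(x, "direction"), attr(x, "units"),
              format(attr(x, "temperature"))))
  print(as.data.frame(lapply(x, function(col)
    if (is.numeric(col)) signif(col, 5) else col)))
  invisible(x)
}

#' Analyse one static-wall segment into an isotherm point
#'
#' Runs the full osmotic analysis on a sampled run at one molecular
#' area: wall-force accumulation, ideal pressure, between-the-walls
#' density profile, interfacial thickness, xi and the corrected
#' pressure, plus (optionally) the tensor-route pressure from the same
#' run's pressure log, and an equilibration drift flag (first-half vs
#' second-half mean wall force beyond 3x their combined block standard
#' errors).
#'
#' @param run a `toy_run` (or any list with `trajectory`, `wall_force`,
#'   `pressure` in those formats).
#' @param wall the [wall_spec()] in force during the run.
#' @param lz_ref infinite-dilution reference thickness (number or
#'   [interfacial_thickness()]).
#' @param n_per_leaflet surfactants per leaflet.
#' @param gamma_w optional bare-interface [kirkwood_irving()] tension;
#'   when given, the tensor-route `pi_tensor` is evaluated too.
#' @param bin_width density-profile bin width.
#' @param n_blocks blocks for uncertainties.
#' @return one-row data frame (see [isotherm_points()]).
#' @export
isotherm_point <- function(run, wall, lz_ref, n_per_leaflet, gamma_w = NULL,
                           bin_width = 0.1, n_blocks = 5) {
  traj <- run$trajectory
  units <- traj$units
  l_y <- traj$box[1, 2]
  rec <- wall_force(traj, wall)
  conv <- 1 / (4 * l_y)
  pi_id <- pi_ideal(rec, l_y, units = units)
  pi_id_se <- .surface_pressure_out(
    block_uncertainty(rec$per_frame_force, n_blocks) * conv, units)
  prof <- density_profile(traj, species = "W", bin_width = bin_width,
                          region = c(-wall$x_wall, wall$x_wall),
                          center = TRUE)
  th <- interfacial_thickness(prof)
  xi <- xi_coefficient(th, lz_ref)
  p_real <- pi_real(pi_id, xi)
  pi_t <- pi_t_se <- NA_real_
  if (!is.null(gamma_w)) {
    gm <- kirkwood_irving(run$pressure, kind = "air-monolayer-water",
                          n_blocks = n_blocks)
    pt <- surface_pressure(gamma_w, gm)
    pi_t <- pt$value
    pi_t_se <- pt$uncertainty
  }
  # burn-in drift test on the wall-force series
  f <- rec$per_frame_force
  half <- length(f) %/% 2
  flagged <- FALSE
  if (half >= n_blocks) {
    m1 <- mean(f[seq_len(half)]); m2 <- mean(f[(half + 1):(2 * half)])
    s1 <- block_uncertainty(f[seq_len(half)], n_blocks)
    s2 <- block_uncertainty(f[(half + 1):(2 * half)], n_blocks)
    flagged <- abs(m1 - m2) > 3 * sqrt(s1^2 + s2^2)
  }
  data.frame(area_per_lipid = area_per_lipid(wall$x_wall, l_y,
                                             n_per_leaflet),
             pi_ideal = pi_id, pi_ideal_se = pi_id_se, xi = xi$xi,
             lz_int = th$lz_int, pi_real = p_real,
             pi_real_se = pi_id_se * xi$xi, pi_tensor = pi_t,
             pi_tensor_se = pi_t_se, flagged = flagged)
}

#' Sweep molecular areas and assemble a surface pressure-area isotherm
#'
#' Emulates a Langmuir-trough compression or expansion: the surfactant
#' count stays fixed while the walls are repositioned to each target
#' area in turn.  Repositioning is instantaneous, followed by a burn-in
#' segment that is discarded; production sampling then proceeds with
#' static walls, and each point carries the osmotic-route pressures
#' (ideal and corrected), xi, the interfacial thickness and optionally
#' the tensor-route pressure from the same run.  A point whose wall
#' force still drifts after burn-in (first-half vs second-half mean
#' difference beyond 3x combined block errors) is flagged, never
#' silently included.
#'
#' @param spec a [toy_spec()]; its wall's `x_wall` is overridden per
#'   area point.
#' @param areas target areas per lipid; must be ordered consistently
#'   with `direction` (decreasing for compression, increasing for
#'   expansion).
#' @param direction `"compression"` or `"expansion"`.
#' @param per_area_steps integration steps spent at each area.
#' @param sample_every sampling stride in steps.
#' @param burn_in fraction of each per-area segment discarded before
#'   analysis.
#' @param lz_ref infinite-dilution reference thickness for xi (from
#'   [reference_thickness()] on a clean slab).
#' @param gamma_w optional bare-interface tension; enables the
#'   tensor-route column.
#' @param equil_steps extra equilibration steps before the first area
#'   point (discarded entirely).
#' @param bin_width,n_blocks analysis parameters.
#' @param seed base RNG seed; each area segment uses `seed + point
#'   index`.
#' @param state optional starting `toy_state`; the natural way to run a
#'   hysteresis loop is to hand the compression sweep's
#'   `attr(iso, "final_state")` to the matching expansion sweep, so the
#'   expansion retraces the same film instead of starting from a
#'   freshly packed construction.
#' @return an `isotherm` data frame (class `isotherm`), points ordered
#'   by descending area, with the last segment's `toy_state` attached
#'   as attribute `final_state`.
#' @export
sweep_isotherm <- function(spec, areas,
                           direction = c("compression", "expansion"),
                           per_area_steps = 40000L, sample_every = 50L,
                           burn_in = 0.2, lz_ref, gamma_w = NULL,
                           equil_steps = 10000L, bin_width = 0.1,
                           n_blocks = 5, seed = spec$seed, state = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "toy_spec"), !is.null(spec$wall),
            all(areas > 0), length(areas) >= 1, burn_in >= 0, burn_in < 1)
  ordered <- if (direction == "compression") !is.unsorted(rev(areas))
             else !is.unsorted(areas)
  if (!ordered)
    stop("areas must be ordered ", if (direction == "compression")
         "decreasing" else "increasing", " for a ", direction, " sweep")
  l_y <- spec$box[2]
  x_walls <- .x_wall_for_area(areas, l_y, spec$n_per_leaflet)
  if (max(x_walls) + spec$margin > spec$box[1] / 2)
    stop("largest area needs x_wall = ", signif(max(x_walls), 4),
         " which leaves no clean margin in L_x = ", spec$box[1])
  rows <- vector("list", length(areas))
  fresh <- is.null(state)
  for (i in seq_along(areas)) {
    spec_i <- spec
    spec_i$wall$x_wall <- x_walls[i]
    if (i == 1L) {
      if (fresh) state <- build_system(spec_i)
      if (equil_steps > 0) {
        eq <- run_toysim(spec_i, state, n_steps = equil_steps,
                         sample_every = equil_steps, seed = seed)
        state <- eq$final_state
      }
    }
    run <- run_toysim(spec_i, state, n_steps = per_area_steps,
                      sample_every = sample_every, seed = seed + i)
    state <- run$final_state
    nf <- n_frames(run$trajectory)
    keep <- seq.int(floor(burn_in * nf) + 1L, nf)
    prod <- run
    prod$trajectory <- subset_frames(run$trajectory, keep)
    prod$pressure <- pressure_series(run$pressure$times[keep],
                                     run$pressure$pxx[keep],
                                     run$pressure$pyy[keep],
                                     run$pressure$pzz[keep],
                                     run$pressure$box_lz, run$units)
    rows[[i]] <- isotherm_point(prod, spec_i$wall, lz_ref,
                                spec$n_per_leaflet, gamma_w = gamma_w,
                                bin_width = bin_width, n_blocks = n_blocks)
  }
  iso <- isotherm_points(do.call(rbind, rows), units = "reduced",
                         temperature = spec$temperature,
                         direction = direction)
  attr(iso, "final_state") <- state
  iso
}

#' Detect a coexistence plateau in an isotherm
#'
#' Liquid-expanded/liquid-condensed phase coexistence shows up as a
#' plateau: a stretch of areas over which the surface pressure barely
#' changes.  The detector computes the finite-difference slope
#' `|dPi/dA|` of each segment between adjacent area points (the
#' centred estimate at the segment midpoint) and returns the longest
#' contiguous run of at least two qualifying segments, as an area
#' interval.  It is a convenience diagnostic; the threshold is in
#' pressure per area units (default 0.1, i.e. mN m^-1 A^-2 in real
#' units).
#'
#' @param isotherm an `isotherm` with at least 4 points.
#' @param slope_threshold maximum `|dPi/dA|` counted as flat.
#' @param pressure_column which pressure to scan (default `pi_real`).
#' @return numeric `c(area_min, area_max)` of the plateau, or `NULL` if
#'   none.
#' @export
plateau_detect <- function(isotherm, slope_threshold = 0.1,
                           pressure_column = "pi_real") {
  stopifnot(inherits(isotherm, "isotherm"))
  if (nrow(isotherm) < 4) stop("need at least 4 isotherm points")
  a <- isotherm$area_per_lipid
  p <- isotherm[[pressure_column]]
  slope <- abs(diff(p) / diff(a))
  flat <- slope < slope_threshold
  if (!any(flat)) return(NULL)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 2L)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  seg <- starts[best]:ends[best]           # segment indices
  range(a[c(seg, max(seg) + 1L)])
}

#' Combine replicate isotherms by inverse-variance weighting
#'
#' Replicate sweeps (different seeds over the same area grid) are
#' merged per area point: pressures are averaged with weights
#' `1 / se^2`, combined standard errors follow from the weight sums,
#' the interfacial thickness is averaged unweighted, and the combined
#' xi is re-derived as `pi_real / pi_ideal` so the stored fields stay
#' internally consistent.  A point flagged in any replicate stays
#' flagged.
#'
#' @param ... two or more `isotherm` objects over identical area grids.
#' @return a combined `isotherm` with direction `"independent"`.
#' @export
combine_isotherms <- function(...) {
  isos <- list(...)
  if (length(isos) < 2) stop("need at least two isotherms to combine")
  a <- isos[[1]]$area_per_lipid
  for (iso in isos) {
    stopifnot(inherits(iso, "isotherm"))
    if (length(iso$area_per_lipid) != length(a) ||
        any(abs(iso$area_per_lipid - a) > 1e-9 * (1 + abs(a))))
      stop("isotherms must share the same area grid")
  }
  wmean <- function(x, se) {
    w <- 1 / se^2
    ok <- is.finite(w) & is.finite(x)
    if (!any(ok)) return(c(NA_real_, NA_real_))
    c(sum(x[ok] * w[ok]) / sum(w[ok]), sqrt(1 / sum(w[ok])))
  }
  rows <- lapply(seq_along(a), function(i) {
    pick <- function(col) vapply(isos, function(iso) iso[[col]][i], 0.0)
    pi_id <- wmean(pick("pi_ideal"), pick("pi_ideal_se"))
    pi_re <- wmean(pick("pi_real"), pick("pi_real_se"))
    pi_te <- wmean(pick("pi_tensor"), pick("pi_tensor_se"))
    data.frame(area_per_lipid = a[i], pi_ideal = pi_id[1],
               pi_ideal_se = pi_id[2],
               xi = pi_re[1] / pi_id[1],
               lz_int = mean(pick("lz_int")),
               pi_real = pi_re[1], pi_real_se = pi_re[2],
               pi_tensor = pi_te[1], pi_tensor_se = pi_te[2],
               flagged = any(vapply(isos,
                                    function(iso) isTRUE(iso$flagged[i]),
                                    TRUE)))
  })
  isotherm_points(do.call(rbind, rows), units = attr(isos[[1]], "units"),
                  temperature = attr(isos[[1]], "temperature"),
                  direction = "independent")
}
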