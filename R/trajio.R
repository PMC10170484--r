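#' Construct a trajectory object
#'
#' A trajectory holds per-frame particle coordinates, a fixed species
#' label per particle, per-frame orthogonal box lengths and frame times.
#' Coordinates are taken as stored in the source file (wrapped or
#' unwrapped); no re-imaging is ever performed, because wall-penetration
#' distances along x and density binning along z must see the raw
#' coordinates.
#'
#' @param coords numeric array `n_particles x 3 x n_frames`, or a
#'   `n x 3` matrix for a single frame.
#' @param species character vector of per-particle species tags
#'   (constant across frames).
#' @param box numeric length-3 vector `(L_x, L_y, L_z)` or an
#'   `n_frames x 3` matrix of per-frame box lengths.
#' @param times numeric vector of frame times, strictly increasing.
#' @param units `"real"` (angstrom, ps) or `"reduced"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, species, box, times = NULL, units = "reduced") {
  units <- .check_units(units)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[1]
  nf <- dim(coords)[3]
  if (length(species) != n)
    stop("coordinate count (", n, ") must equal species count (",
         length(species), ")")
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf)
    stop("need one time per frame")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3)
    stop("box must be length 3 or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("all box lengths must be positive")
  structure(
    list(coords = coords, species = as.character(species), box = box,
         times = as.numeric(times), units = units),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_particles(x), "particles,", n_frames(x), "frames (",
      x$units, "units )\n")
  cat("  species:", paste(sprintf("%s=%d", names(table(x$species)),
                                  table(x$species)), collapse = ", "), "\n")
  cat("  box (first frame):", paste(signif(x$box[1, ], 6), collapse = " x "),
      "\n")
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj a [trajectory] object.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[1]

#' Subset frames of a trajectory
#' @param traj a [trajectory] object.
#' @param idx integer frame indices to keep (in order).
#' @return a [trajectory] with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$coords[, , idx, drop = FALSE], traj$species,
             traj$box[idx, , drop = FALSE], traj$times[idx], traj$units)
}

#' Read a trajectory from a text file
#'
#' Two textual dialects are supported: extended XYZ (a count line, a
#' comment line carrying `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` and
#' `Time=...`, then one `species x y z` line per particle) and a minimal
#' LAMMPS-dump subset (orthogonal boxes, `ITEM: ATOMS id type x y z`,
#' unscaled coordinates).  Parsers are strict: malformed headers or
#' records raise an error naming the offending line, and a change in
#' particle count across frames is a structural error, never a silent
#' drop.
#'
#' @param path file path.
#' @param format `"xyz-ext"` or `"lammps-dump"`.
#' @param species_map for LAMMPS dumps, an optional named character
#'   vector mapping numeric type to species label, e.g.
#'   `c("1" = "W", "2" = "H")`.  Unmapped types keep their numeric
#'   label as a character string.
#' @param units unit system tag to attach, `"real"` or `"reduced"`.
#' @return a [trajectory].
#' @export
read_trajectory <- function(path, format = c("xyz-ext", "lammps-dump"),
                            species_map = NULL, units = "reduced") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "xyz-ext") .read_xyz_ext(lines, units)
  else .read_lammps_dump(lines, species_map, units)
}

.read_xyz_ext <- function(lines, units) {
  pos <- 1L
  frames <- list()
  boxes <- list()
  times <- c()
  species0 <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0)
      stop("parse error at line ", pos, ": expected particle count, got '",
           lines[pos], "'")
    if (pos + 1L > length(lines))
      stop("parse error at line ", pos + 1L, ": missing comment line")
    comment <- lines[pos + 1L]
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) < 2)
      stop("parse error at line ", pos + 1L, ": no Lattice=\"...\" box")
    lat <- suppressWarnings(as.numeric(strsplit(trimws(m[2]), "[ \t]+")[[1]]))
    if (length(lat) != 9 || anyNA(lat))
      stop("parse error at line ", pos + 1L, ": Lattice needs 9 numbers")
    box <- lat[c(1, 5, 9)]
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    t_frame <- if (length(tm) >= 2) as.numeric(tm[2]) else length(times)
    if (pos + 1L + n > length(lines))
      stop("structural error: frame starting at line ", pos, " declares ", n,
           " particles but the file ends early")
    rec <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(rec), "[ \t]+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop("parse error at line ", pos + 1L + bad[1],
           ": expected 'species x y z'")
    sp <- vapply(parts, `[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(parts, function(p) p[2:4])))), ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop("parse error in frame starting at line ", pos,
           ": non-numeric coordinate")
    if (is.null(species0)) species0 <- sp
    else if (length(sp) != length(species0) || any(sp != species0))
      stop("structural error: frame ", length(frames) + 1L,
           " particle list differs from frame 1")
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    times <- c(times, t_frame)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("no frames found")
  coords <- array(unlist(frames), dim = c(length(species0), 3, length(frames)))
  trajectory(coords, species0, do.call(rbind, boxes), times, units)
}

.read_lammps_dump <- function(lines, species_map, units) {
  pos <- 1L
  frames <- list(); boxes <- list(); times <- c(); species0 <- NULL
  expect <- function(tag, at) {
    if (at > length(lines) || !startsWith(lines[at], tag))
      stop("parse error at line ", at, ": expected '", tag, "'")
  }
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    expect("ITEM: TIMESTEP", pos)
    step <- suppressWarnings(as.numeric(lines[pos + 1L]))
    if (is.na(step)) stop("parse error at line ", pos + 1L, ": bad timestep")
    expect("ITEM: NUMBER OF ATOMS", pos + 2L)
    n <- suppressWarnings(as.integer(lines[pos + 3L]))
    if (is.na(n) || n <= 0)
      stop("parse error at line ", pos + 3L, ": bad atom count")
    expect("ITEM: BOX BOUNDS", pos + 4L)
    bl <- matrix(NA_real_, 3, 2)
    for (d in 1:3) {
      v <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[pos + 4L + d]), "[ \t]+")[[1]]))
      if (length(v) < 2 || anyNA(v[1:2]))
        stop("parse error at line ", pos + 4L + d, ": bad box bounds")
      bl[d, ] <- v[1:2]
    }
    hdr <- pos + 8L
    expect("ITEM: ATOMS", hdr)
    cols <- strsplit(trimws(sub("ITEM: ATOMS", "", lines[hdr])), "[ \t]+")[[1]]
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% cols))
      stop("parse error at line ", hdr, ": ATOMS columns must include ",
           paste(need, collapse = " "))
    ci <- match(need, cols)
    if (hdr + n > length(lines))
      stop("structural error: frame starting at line ", pos, " declares ", n,
           " atoms but the file ends early")
    rec <- strsplit(trimws(lines[(hdr + 1L):(hdr + n)]), "[ \t]+")
    bad <- which(lengths(rec) < length(cols))
    if (length(bad))
      stop("parse error at line ", hdr + bad[1], ": short atom record")
    mat <- matrix(suppressWarnings(as.numeric(unlist(
      lapply(rec, function(p) p[ci])))), ncol = 5, byrow = TRUE)
    if (anyNA(mat))
      stop("parse error in frame starting at line ", pos,
           ": non-numeric atom field")
    ord <- order(mat[, 1])
    mat <- mat[ord, , drop = FALSE]
    sp <- as.character(as.integer(mat[, 2]))
    if (!is.null(species_map)) {
      mapped <- species_map[sp]
      sp <- ifelse(is.na(mapped), sp, unname(mapped))
    }
    if (is.null(species0)) species0 <- sp
    else if (length(sp) != length(species0) || any(sp != species0))
      stop("structural error: frame ", length(frames) + 1L,
           " particle list differs from frame 1")
    frames[[length(frames) + 1L]] <- mat[, 3:5, drop = FALSE]
    boxes[[length(boxes) + 1L]] <- bl[, 2] - bl[, 1]
    times <- c(times, step)
    pos <- hdr + n + 1L
  }
  if (!length(frames)) stop("no frames found")
  coords <- array(unlist(frames), dim = c(length(species0), 3, length(frames)))
  trajectory(coords, species0, do.call(rbind, boxes), times, units)
}

#' Write a trajectory to a text file
#'
#' Inverse of [read_trajectory()]; a write-then-read round trip is the
#' identity up to the textual precision (`%.10g`).  For the LAMMPS-dump
#' dialect, box bounds are written centred (`-L/2 .. L/2`) so that the
#' stored coordinates are identical to the extended-XYZ writer's, and
#' frame times must be integer-valued (they go into `ITEM: TIMESTEP`).
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @param format `"xyz-ext"` or `"lammps-dump"`.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("xyz-ext", "lammps-dump")) {
  format <- match.arg(format)
  nf <- n_frames(traj)
  n <- n_particles(traj)
  out <- character(0)
  if (format == "xyz-ext") {
    out <- vector("list", nf)
    for (f in seq_len(nf)) {
      b <- traj$box[f, ]
      hdr <- c(as.character(n),
               sprintf(paste0('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" ',
                              'Properties=species:S:1:pos:R:3 Time=%.10g'),
                       b[1], b[2], b[3], traj$times[f]))
      rows <- sprintf("%s %.10g %.10g %.10g", traj$species,
                      traj$coords[, 1, f], traj$coords[, 2, f],
                      traj$coords[, 3, f])
      out[[f]] <- c(hdr, rows)
    }
    writeLines(unlist(out), path)
  } else {
    steps <- traj$times
    if (any(abs(steps - round(steps)) > 1e-9))
      stop("lammps-dump stores integer timesteps; trajectory times are not ",
           "integer-valued")
    types <- as.integer(factor(traj$species, levels = sort(unique(traj$species))))
    out <- vector("list", nf)
    for (f in seq_len(nf)) {
      b <- traj$box[f, ]
      hdr <- c("ITEM: TIMESTEP", sprintf("%d", as.integer(round(steps[f]))),
               "ITEM: NUMBER OF ATOMS", as.character(n),
               "ITEM: BOX BOUNDS pp pp pp",
               sprintf("%.10g %.10g", -b[1] / 2, b[1] / 2),
               sprintf("%.10g %.10g", -b[2] / 2, b[2] / 2),
               sprintf("%.10g %.10g", -b[3] / 2, b[3] / 2),
               "ITEM: ATOMS id type x y z")
      rows <- sprintf("%d %d %.10g %.10g %.10g", seq_len(n), types,
                      traj$coords[, 1, f], traj$coords[, 2, f],
                      traj$coords[, 3, f])
      out[[f]] <- c(hdr, rows)
    }
    writeLines(unlist(out), path)
  }
  invisible(path)
}

#' Construct a pressure-tensor time series
#'
#' Holds the diagonal components of the instantaneous pressure tensor of
#' a slab system plus the box length along the interface normal, the
#' inputs to the Kirkwood-Irving surface tension.
#'
#' @param times numeric, frame times.
#' @param pxx,pyy,pzz numeric, diagonal pressure components (bar in real
#'   units, epsilon/sigma^3 in reduced units).
#' @param box_lz box length along z (angstrom or sigma); must be > 0.
#' @param units `"real"` or `"reduced"`.
#' @return object of class `pressure_series`.
#' @export
pressure_series <- function(times, pxx, pyy, pzz, box_lz, units = "reduced") {
  units <- .check_units(units)
  nlen <- length(times)
  if (length(pxx) != nlen || length(pyy) != nlen || length(pzz) != nlen)
    stop("times, pxx, pyy, pzz must have equal length")
  if (!is.numeric(box_lz) || length(box_lz) != 1 || box_lz <= 0)
    stop("box_lz must be a single positive number")
  structure(list(times = as.numeric(times), pxx = as.numeric(pxx),
                 pyy = as.numeric(pyy), pzz = as.numeric(pzz),
                 box_lz = box_lz, units = units),
            class = "pressure_series")
}

#' @export
print.pressure_series <- function(x, ...) {
  cat("pressure_series:", length(x$times), "samples, L_z =", x$box_lz,
      "(", x$units, "units )\n")
  invisible(x)
}

#' Read / write a pressure-tensor series as CSV
#'
#' The CSV must have a header with columns `time, pxx, pyy, pzz`.  The
#' box length along z is taken from the `box_lz` argument or, failing
#' that, from a `# box_lz: <value>` comment line that [write_pressure_series()]
#' emits.
#'
#' @param path file path.
#' @param box_lz optional box length along z, overriding the header
#'   comment.
#' @param units `"real"` or `"reduced"`.
#' @return a [pressure_series].
#' @export
read_pressure_series <- function(path, box_lz = NULL, units = "reduced") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(box_lz) && grepl("^#\\s*box_lz:", first))
    box_lz <- as.numeric(sub("^#\\s*box_lz:\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "pxx", "pyy", "pzz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (is.null(box_lz))
    stop("box_lz must be given (argument or '# box_lz:' header comment)")
  pressure_series(df$time, df$pxx, df$pyy, df$pzz, box_lz, units)
}

#' @rdname read_pressure_series
#' @param series a [pressure_series] to write.
#' @export
write_pressure_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box_lz: %.12g", series$box_lz), con)
  utils::write.csv(
    data.frame(time = series$times, pxx = series$pxx, pyy = series$pyy,
               pzz = series$pzz),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a wall-force log as CSV
#'
#' Columns: `time`, `f_total`, then one `f_<species>` column per
#' restrained species.  Forces are the instantaneous total inward
#' restoring-force magnitudes summed over both walls.
#'
#' @param path file path.
#' @return a data frame with the same columns.
#' @export
read_wall_force_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "f_total") %in% names(df)))
    stop("schema error: wall-force log needs columns time, f_total")
  df
}

#' @rdname read_wall_force_log
#' @param log data frame with columns `time`, `f_total`, `f_<species>...`.
#' @export
write_wall_force_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Defaults for a whole analysis run, loadable from YAML.  The clean
#' interface margin is the surfactant-free solvent region that must
#' extend beyond each wall so solvent exchanges freely across the
#' barriers; 18 angstrom in real units, 4.5 sigma in reduced units.
#'
#' @param units `"real"` or `"reduced"`.
#' @param bin_width density-profile bin width (0.5 A real, 0.1 sigma
#'   reduced by default).
#' @param n_blocks number of blocks for block-average uncertainties.
#' @param margin clean-interface margin beyond each wall.
#' @param sample_every analysis sampling stride (frames).
#' @param wall optional list with `x_wall`, `k`, `force_law`,
#'   `restrained_species` (see [wall_spec()]).
#' @return a list of class `run_config`.
#' @export
run_config <- function(units = "reduced",
                       bin_width = if (units == "real") 0.5 else 0.1,
                       n_blocks = 5,
                       margin = if (units == "real") 18 else 4.5,
                       sample_every = 1L, wall = NULL) {
  units <- .check_units(units)
  if (margin < 0) stop("margin must be >= 0")
  if (n_blocks < 2) stop("block count must be >= 2")
  if (bin_width <= 0) stop("bin width must be > 0")
  if (!is.null(wall))
    wall <- do.call(wall_spec, wall[intersect(names(wall),
      c("x_wall", "k", "force_law", "restrained_species"))])
  structure(list(units = units, bin_width = bin_width, n_blocks = n_blocks,
                 margin = margin, sample_every = as.integer(sample_every),
                 wall = wall),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals),
                    c("units", "bin_width", "n_blocks", "margin",
                      "sample_every", "wall"))
  do.call(run_config, vals[keep])
}

#' Write an isotherm to JSON / read it back
#'
#' One record per area point with fields `area_per_lipid`, `pi_ideal`,
#' `pi_real`, `pi_tensor` (null when the tensor route was not run),
#' their uncertainties, `xi`, `lz_int` and a `flagged` equilibration
#' marker, plus a metadata object (units, temperature, sweep direction).
#' A write-then-read round trip reproduces the numeric values exactly
#' (full double precision is serialized).
#'
#' @param isotherm an `isotherm` data frame from [sweep_isotherm()] or
#'   [isotherm_points()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_isotherm <- function(isotherm, path) {
  if (!inherits(isotherm, "isotherm")) stop("not an isotherm object")
  if (!nrow(isotherm)) stop("empty isotherm")
  meta <- list(units = attr(isotherm, "units"),
               temperature = attr(isotherm, "temperature"),
               direction = attr(isotherm, "direction"),
               method = "osmotic+tensor")
  jsonlite::write_json(
    list(metadata = meta, points = as.data.frame(isotherm)),
    path, auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- as.data.frame(obj$points)
  for (cn in names(pts))
    if (cn != "flagged") pts[[cn]] <- as.numeric(pts[[cn]])
  isotherm_points(pts, units = obj$metadata$units,
                  temperature = obj$metadata$temperature,
                  direction = obj$metadata$direction)
}
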