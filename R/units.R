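#' Unit conventions and conversion constants
#'
#' The package supports two unit systems, chosen once per analysis:
#'
#' * `"real"`: lengths in angstrom, time in ps, energies in kcal/mol,
#'   pressures in bar.  Surface pressures and tensions are reported in
#'   mN/m.
#' * `"reduced"`: Lennard-Jones reduced units (epsilon = sigma = m =
#'   kB = 1).  Surface pressures and tensions are reported in
#'   epsilon/sigma^2 and no conversion is applied.
#'
#' The two conversion constants used are exported for transparency:
#' a line tension of 1 kcal mol^-1 A^-2 equals
#' `4184 / 6.02214076e23 / 1e-20 * 1000` = 694.7695 mN/m, and
#' 1 bar A = 1e5 Pa x 1e-10 m = 0.01 mN/m.
#'
#' @name isopress-units
#' @keywords internal
NULL

# 1 kcal mol^-1 A^-2 expressed in mN/m
KCAL_PER_MOL_A2_TO_MN_M <- 4184 / 6.02214076e23 / 1e-20 * 1000

# 1 bar * A expressed in mN/m
BAR_A_TO_MN_M <- 0.01

.check_units <- function(units) {
  match.arg(units, c("real", "reduced"))
}

# convert an energy/length^2 quantity to the reporting unit for `units`
.surface_pressure_out <- function(value, units) {
  if (units == "real") value * KCAL_PER_MOL_A2_TO_MN_M else value
}

# convert a bar*length tension integrand to the reporting unit
.tension_out <- function(value, units) {
  if (units == "real") value * BAR_A_TO_MN_M else value
}
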