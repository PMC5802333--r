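#' Physical constants for stopping-power calculations
#'
#' Bundle of the constants entering the Bethe-Bloch stopping-power ratio:
#' the electron rest energy \eqn{m_e c^2}, the proton rest energy
#' \eqn{m_p c^2} (used to obtain \eqn{\beta = v/c} from kinetic energy),
#' and the mean excitation energy of water \eqn{I_w}.
#'
#' @param electron_rest_energy_mev Electron rest energy in MeV.
#' @param proton_rest_energy_mev Proton rest energy in MeV.
#' @param water_ionisation_ev Mean excitation energy (I-value) of water in eV.
#'   The conventional value 75 eV is the default and may be overridden.
#' @return A list of class `physical_constants`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(electron_rest_energy_mev = 0.511,
                               proton_rest_energy_mev = 938.272,
                               water_ionisation_ev = 75) {
  stopifnot(electron_rest_energy_mev > 0,
            proton_rest_energy_mev > 0,
            water_ionisation_ev > 0)
  structure(list(electron_rest_energy_mev = electron_rest_energy_mev,
                 proton_rest_energy_mev = proton_rest_energy_mev,
                 water_ionisation_ev = water_ionisation_ev),
            class = "physical_constants")
}

#' Squared relative velocity of a proton
#'
#' Computes \eqn{\beta^2 = 1 - (m_p c^2 / (m_p c^2 + E))^2} for a proton of
#' kinetic energy `energy` MeV. Vectorised over `energy`.
#'
#' @param energy Proton kinetic energy in MeV (non-negative).
#' @param constants A [physical_constants()] object.
#' @return \eqn{\beta^2}, dimensionless, in `[0, 1)`.
#' @export
#' @examples
#' beta_squared(0)        # at rest
#' beta_squared(938.272)  # gamma = 2, beta^2 = 0.75
beta_squared <- function(energy, constants = physical_constants()) {
  if (any(!is.finite(energy)) || any(energy < 0)) {
    stop("'energy' must be finite and non-negative (MeV)")
  }
  mp <- constants$proton_rest_energy_mev
  1 - (mp / (mp + energy))^2
}

# Bethe-Bloch bracket ln(2 m_e c^2 beta^2 / (I (1 - beta^2))) - beta^2,
# with I in eV. Errors when the logarithm's argument makes the bracket
# non-positive (pathologically large I or very low energy).
.bb_bracket <- function(beta2, ionisation_ev, constants, label) {
  two_mec2_ev <- 2 * constants$electron_rest_energy_mev * 1e6
  arg <- two_mec2_ev * beta2 / (ionisation_ev * (1 - beta2))
  if (any(arg <= 0)) {
    stop("non-positive logarithm argument in the ", label,
         " stopping-power bracket (energy too low?)")
  }
  br <- log(arg) - beta2
  if (any(br <= 0)) {
    stop("non-positive Bethe-Bloch bracket for the ", label,
         " term (I = ", ionisation_ev, " eV too large for this energy)")
  }
  br
}

#' Relative proton stopping power of a material
#'
#' Stopping power relative to water from the Bethe-Bloch ratio
#' \deqn{S_{rel} = \frac{\rho_e}{\rho_{e,w}} \cdot
#'   \frac{\ln\!\left(\frac{2 m_e c^2 \beta^2}{I (1-\beta^2)}\right) - \beta^2}
#'        {\ln\!\left(\frac{2 m_e c^2 \beta^2}{I_w (1-\beta^2)}\right) - \beta^2}}
#' where \eqn{\rho_e/\rho_{e,w}} is the electron density relative to water,
#' \eqn{I} the material's mean excitation energy and \eqn{I_w} water's.
#' A material with zero electron density (air) has zero stopping power
#' regardless of `ionisation_ev`.
#'
#' @param rho_e_rel Electron density relative to water (dimensionless, >= 0).
#' @param ionisation_ev Mean excitation energy I of the material, eV.
#' @param energy Proton kinetic energy in MeV (> 0).
#' @param constants A [physical_constants()] object (holds \eqn{I_w}).
#' @return Relative stopping power (dimensionless, >= 0).
#' @export
#' @examples
#' relative_stopping_power(1.0, 75, 150)   # water: exactly 1
#' relative_stopping_power(1.69, 87, 150)  # cortical-bone substitute
relative_stopping_power <- function(rho_e_rel, ionisation_ev, energy,
                                    constants = physical_constants()) {
  if (any(rho_e_rel < 0)) stop("'rho_e_rel' must be >= 0")
  if (all(rho_e_rel == 0)) return(rho_e_rel * 0)
  if (any(ionisation_ev <= 0)) stop("'ionisation_ev' must be > 0 (eV)")
  if (any(energy <= 0)) stop("'energy' must be > 0 (MeV)")
  b2 <- beta_squared(energy, constants)
  num <- .bb_bracket(b2, ionisation_ev, constants, "material")
  den <- .bb_bracket(b2, constants$water_ionisation_ev, constants, "water")
  rho_e_rel * num / den
}

#' Proton range in water from kinetic energy
#'
#' Power-law range-energy relationship \eqn{R = \alpha E^p} used to justify
#' treating the stopping-power ratio as energy independent over the
#' therapeutic window.
#'
#' @param energy Proton kinetic energy in MeV (>= 0). Vectorised.
#' @param params List with elements `alpha` (cm MeV^-p) and `p`
#'   (dimensionless); defaults to [range_energy_params()].
#' @return Range in cm.
#' @export
range_from_energy <- function(energy, params = range_energy_params()) {
  if (any(energy < 0)) stop("'energy' must be >= 0 (MeV)")
  stopifnot(params$alpha > 0, params$p > 0)
  params$alpha * energy^params$p
}

#' Default power-law range-energy parameters
#'
#' Standard water values for the range-energy power law \eqn{R = \alpha E^p}:
#' \eqn{\alpha = 0.0022} cm, \eqn{p = 1.77}.
#'
#' @param alpha Coefficient, cm MeV^-p.
#' @param p Exponent, dimensionless.
#' @return List with `alpha` and `p`.
#' @export
range_energy_params <- function(alpha = 0.0022, p = 1.77) {
  stopifnot(alpha > 0, p > 0)
  list(alpha = alpha, p = p)
}

#' Energy (in)dependence of the stopping-power ratio
#'
#' Percentage change of the relative stopping power between two proton
#' energies, \eqn{100 |S_{rel}(E_1) - S_{rel}(E_2)| / S_{rel}(E_1)}.
#' Identically zero when the material's I-value equals water's. The defaults
#' evaluate the worst case relevant to megavoltage-CT calibration: a
#' cortical-bone substitute (relative electron density 1.69, I = 87 eV)
#' between 90 and 310 MeV, the extremes of the therapeutic energy window.
#'
#' @param rho_e_rel Electron density relative to water.
#' @param ionisation_ev Mean excitation energy of the material, eV.
#' @param energy_low,energy_high The two proton kinetic energies, MeV.
#' @param constants A [physical_constants()] object.
#' @return Percentage difference (non-negative).
#' @export
#' @examples
#' energy_independence_check()  # cortical bone, 90 vs 310 MeV
energy_independence_check <- function(rho_e_rel = 1.69, ionisation_ev = 87,
                                      energy_low = 90, energy_high = 310,
                                      constants = physical_constants()) {
  s_lo <- relative_stopping_power(rho_e_rel, ionisation_ev, energy_low, constants)
  s_hi <- relative_stopping_power(rho_e_rel, ionisation_ev, energy_high, constants)
  100 * abs(s_lo - s_hi) / s_lo
}

#' Calibration table mapping CT number to relative stopping power
#'
#' An ordered set of (HU, stopping power) knots defining a piecewise-linear
#' conversion curve.
#'
#' @param hu Numeric vector of Hounsfield units, strictly increasing.
#' @param sp Numeric vector of relative stopping powers, non-negative, same
#'   length as `hu`.
#' @return A data frame of class `calibration_table` with columns `hu`, `sp`.
#' @export
#' @examples
#' calibration_table(c(-1000, 0, 1000), c(0, 1, 1.8))
calibration_table <- function(hu, sp) {
  if (length(hu) != length(sp) || length(hu) < 2) {
    stop("need at least 2 (hu, sp) knots of equal length")
  }
  if (anyDuplicated(hu)) stop("duplicate HU values in calibration knots")
  o <- order(hu)
  hu <- hu[o]; sp <- sp[o]
  if (any(diff(hu) <= 0)) stop("HU knots must be strictly increasing")
  if (any(sp < 0)) stop("stopping-power knots must be non-negative")
  structure(data.frame(hu = hu, sp = sp),
            class = c("calibration_table", "data.frame"))
}

#' Insert specifications of the default megavoltage-CT calibration phantom
#'
#' The density-insert set used to calibrate a TomoTherapy megavoltage CT:
#' physical density, electron density relative to water, assumed mean
#' excitation energy, and measured HU for each tissue substitute. The
#' I-values are not manufacturer-published figures: they were derived by
#' inverting the Bethe-Bloch ratio at 150 MeV so that the computed stopping
#' powers reproduce the reference calibration's published stopping-power
#' column to better than 0.001, and are documented as such.
#'
#' @return Data frame with columns `name`, `density`,
#'   `rel_electron_density`, `ionisation_ev`, `hu`.
#' @export
default_inserts <- function() {
  path <- system.file("extdata", "mvct_inserts.csv", package = "rangewepl")
  read_insert_table(path)
}

#' Build a calibration table from phantom inserts
#'
#' Evaluates the Bethe-Bloch relative stopping power of each insert at a
#' single reference energy and pairs it with the insert's measured HU.
#' The reference energy defaults to 150 MeV (mid-therapeutic); because the
#' stopping-power ratio varies by less than 0.6% across 90-310 MeV the
#' choice is immaterial at calibration accuracy, but it is fixed for
#' reproducibility.
#'
#' @param inserts Data frame with columns `rel_electron_density`,
#'   `ionisation_ev`, `hu` (and optionally `name`), e.g. [default_inserts()].
#' @param energy Reference proton kinetic energy, MeV.
#' @param constants A [physical_constants()] object.
#' @return A [calibration_table()].
#' @export
#' @examples
#' build_calibration(default_inserts())
build_calibration <- function(inserts = default_inserts(), energy = 150,
                              constants = physical_constants()) {
  req <- c("rel_electron_density", "ionisation_ev", "hu")
  if (!all(req %in% names(inserts))) {
    stop("'inserts' must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(inserts) < 2) stop("need at least 2 inserts")
  if (anyDuplicated(inserts$hu)) stop("duplicate HU values among inserts")
  sp <- vapply(seq_len(nrow(inserts)), function(i) {
    if (inserts$rel_electron_density[i] == 0) return(0)
    relative_stopping_power(inserts$rel_electron_density[i],
                            inserts$ionisation_ev[i], energy, constants)
  }, numeric(1))
  calibration_table(inserts$hu, sp)
}

#' Default HU to stopping power calibration
#'
#' The piecewise-linear calibration curve whose knots are the reference
#' megavoltage-CT insert measurements (HU) paired with their published
#' relative stopping powers, from air (-970 HU, sp 0) to cortical bone
#' (673 HU, sp 1.622) with water at 9.5 HU, sp 1.00.
#'
#' @return A [calibration_table()].
#' @export
default_calibration <- function() {
  path <- system.file("extdata", "mvct_calibration.csv", package = "rangewepl")
  read_calibration(path)
}

#' Convert Hounsfield units to relative stopping power
#'
#' Piecewise-linear interpolation between calibration knots. Below the
#' lowest knot the value is clamped to 0 (nothing stops less than nothing);
#' above the highest knot the last segment is extrapolated linearly so
#' metal-bright pixels are handled conservatively. Negative interpolated
#' values are clamped to 0. Vectorised over `hu`; `NA` inputs map to 0 with
#' a warning (unreconstructed or corrupt voxels).
#'
#' @param hu Numeric vector (or matrix) of Hounsfield units.
#' @param table A [calibration_table()].
#' @return Relative stopping power, same shape as `hu`.
#' @export
#' @examples
#' hu_to_sp(c(-2000, 9.5, 673), default_calibration())
hu_to_sp <- function(hu, table = default_calibration()) {
  stopifnot(inherits(table, "calibration_table"))
  dims <- dim(hu)
  x <- as.numeric(hu)
  if (anyNA(x)) {
    warning("NA Hounsfield units encountered; converted to stopping power 0")
    x[is.na(x)] <- -Inf
  }
  kh <- table$hu; ks <- table$sp; n <- length(kh)
  out <- stats::approx(kh, ks, xout = x, rule = 2, ties = "ordered")$y
  # linear extrapolation above the top knot from the last segment's slope
  hi <- x > kh[n]
  if (any(hi)) {
    slope <- (ks[n] - ks[n - 1]) / (kh[n] - kh[n - 1])
    out[hi] <- ks[n] + slope * (x[hi] - kh[n])
  }
  out[x < kh[1]] <- 0
  out <- pmax(out, 0)
  dim(out) <- dims
  out
}
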