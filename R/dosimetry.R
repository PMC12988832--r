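# Laser and dye dosimetry arithmetic: per-pulse fluence through an optical
# fiber face, ratio to the ANSI skin maximum permissible exposure (MPE),
# intraluminal dye concentration, and renal biomarker range checks.

#' Laser exposure description
#'
#' @param pulse_energy Per-pulse energy in mJ (> 0 allowed to be 0 for the
#'   degenerate no-light case).
#' @param fiber_diameter Optical fiber (bundle) diameter in mm.
#' @param wavelength Wavelength in nm (default 750).
#' @param pulse_duration Pulse duration in ns (default 5).
#' @param repetition_rate Pulse repetition frequency in Hz (default 10).
#' @param mpe_limit ANSI skin maximum permissible exposure in mJ/cm^2 at
#'   this wavelength (default 25.2).
#' @return A `pa_exposure` object.
#' @export
laser_exposure <- function(pulse_energy, fiber_diameter = 5,
                           wavelength = 750, pulse_duration = 5,
                           repetition_rate = 10, mpe_limit = 25.2) {
  stopifnot(pulse_energy >= 0, fiber_diameter > 0, mpe_limit > 0)
  structure(list(pulse_energy = pulse_energy,
                 fiber_diameter = fiber_diameter,
                 wavelength = wavelength, pulse_duration = pulse_duration,
                 repetition_rate = repetition_rate, mpe_limit = mpe_limit),
            class = "pa_exposure")
}

#' Per-pulse fluence at the fiber face
#'
#' Assumes a uniform (top-hat) beam over the circular fiber face:
#' `pulse_energy / (pi * (fiber_diameter / 2)^2)` with the area in cm^2.
#'
#' @param exposure A [laser_exposure()] object.
#' @return Fluence in mJ/cm^2.
#' @examples
#' fluence(laser_exposure(6.78, fiber_diameter = 5))  # 34.53 mJ/cm^2
#' @export
fluence <- function(exposure) {
  stopifnot(inherits(exposure, "pa_exposure"))
  radius_cm <- exposure$fiber_diameter / 2 / 10
  exposure$pulse_energy / (pi * radius_cm^2)
}

#' Ratio of fluence to the MPE safety limit
#'
#' @param exposure A [laser_exposure()] object.
#' @return `fluence(exposure) / mpe_limit`; values above 1 exceed the
#'   ANSI skin limit.
#' @examples
#' mpe_ratio(laser_exposure(15.89))  # about 3.2
#' @export
mpe_ratio <- function(exposure) {
  fluence(exposure) / exposure$mpe_limit
}

#' Dye dose description
#'
#' @param injected_volume Injected volume in mL.
#' @param vial_concentration Dye strength in mg/mL (default 5, i.e. a
#'   10-mL vial containing 50 mg).
#' @param lumen_volume Assumed ureter lumen volume in mL (default 22.2).
#' @param molar_mass Dye molar mass in g/mol (default 319.85, methylene
#'   blue).
#' @return A `pa_dose` object.
#' @export
dye_dose <- function(injected_volume, vial_concentration = 5,
                     lumen_volume = 22.2, molar_mass = 319.85) {
  stopifnot(injected_volume >= 0, vial_concentration > 0,
            lumen_volume > 0, molar_mass > 0)
  structure(list(injected_volume = injected_volume,
                 vial_concentration = vial_concentration,
                 lumen_volume = lumen_volume, molar_mass = molar_mass),
            class = "pa_dose")
}

#' Intraluminal dye concentration
#'
#' Injected mass diluted into the assumed lumen volume, converted to molar
#' units: `(injected_volume * vial_concentration) / lumen_volume /
#' molar_mass`, expressed in micromolar.
#'
#' @param dose A [dye_dose()] object.
#' @return Concentration in uM.
#' @examples
#' intraluminal_concentration(dye_dose(0.5))  # about 352 uM
#' @export
intraluminal_concentration <- function(dose) {
  stopifnot(inherits(dose, "pa_dose"))
  mg_per_ml <- dose$injected_volume * dose$vial_concentration /
    dose$lumen_volume
  # mg/mL = g/L; divide by g/mol -> mol/L; *1e6 -> uM
  mg_per_ml / dose$molar_mass * 1e6
}

#' Systemic concentration helper
#'
#' Dye mass distributed into a user-supplied distribution volume; no
#' default volume is assumed.
#'
#' @param total_mg Total injected dye mass in mg.
#' @param distribution_volume_ml Assumed distribution volume in mL.
#' @param molar_mass Dye molar mass in g/mol.
#' @return Concentration in uM.
#' @export
systemic_concentration <- function(total_mg, distribution_volume_ml,
                                   molar_mass = 319.85) {
  stopifnot(total_mg >= 0, distribution_volume_ml > 0, molar_mass > 0)
  total_mg / distribution_volume_ml / molar_mass * 1e6
}

#' Renal biomarker range flags
#'
#' Flags blood urea nitrogen (BUN), serum creatinine (SC), and their ratio
#' against reference intervals (inclusive bounds): BUN 2--13 mg/dL, SC
#' 0.6--1.8 mg/dL, BUN/SC 3.33--7.22. The ratio bounds default to the exact
#' fractions `2/0.6` and `13/1.8` (printed as 3.33 and 7.22), so boundary
#' biomarker values are consistently in range.
#'
#' @param bun BUN in mg/dL.
#' @param sc SC in mg/dL (> 0 for the ratio).
#' @param bun_range,sc_range,ratio_range Reference intervals.
#' @return One-row tibble: `bun`, `sc`, `bun_sc_ratio`, and logical
#'   `bun_in_range`, `sc_in_range`, `ratio_in_range`.
#' @examples
#' biomarker_flags(bun = 10, sc = 2.0)  # SC out of range
#' @export
biomarker_flags <- function(bun, sc, bun_range = c(2, 13),
                            sc_range = c(0.6, 1.8),
                            ratio_range = c(2 / 0.6, 13 / 1.8)) {
  stopifnot(bun >= 0, sc >= 0)
  if (sc == 0) stop("serum creatinine must be > 0 to form the BUN/SC ratio")
  ratio <- bun / sc
  tibble::tibble(
    bun = bun, sc = sc, bun_sc_ratio = ratio,
    bun_in_range = bun >= bun_range[1] & bun <= bun_range[2],
    sc_in_range = sc >= sc_range[1] & sc <= sc_range[2],
    ratio_in_range = ratio >= ratio_range[1] & ratio <= ratio_range[2])
}
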