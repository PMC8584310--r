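#' Fit a spectrophotometric standard (calibration) curve
#'
#' Ordinary least-squares line absorbance = slope * concentration + intercept,
#' the standard-curve method used to infer unknown drug concentrations from
#' UV-Vis absorbance readings.
#'
#' @param concentrations Known concentrations (ug/mL), at least 2 distinct.
#' @param absorbances Measured absorbances, same length.
#' @param wavelength_nm Metadata: wavelength of the reading (default 484 nm,
#'   the doxorubicin absorbance maximum).
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `wavelength_nm`.
#' @examples
#' fit_calibration(c(0, 10), c(0, 1))   # slope 0.1, intercept 0
#' @export
fit_calibration <- function(concentrations, absorbances, wavelength_nm = 484) {
  stopifnot(length(concentrations) == length(absorbances))
  if (length(unique(concentrations)) < 2L) {
    stop("need >= 2 distinct concentrations", call. = FALSE)
  }
  co <- stats::coef(stats::lm(absorbances ~ concentrations))
  if (!is.finite(co[2]) || co[2] <= 0) {
    stop("calibration slope must be positive", call. = FALSE)
  }
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         wavelength_nm = wavelength_nm),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: A = %.6g * conc + %.6g  (%g nm)\n",
              x$slope, x$intercept, x$wavelength_nm))
  invisible(x)
}

#' Concentration from absorbance via a calibration curve
#'
#' Inverts the standard curve: conc = (A - intercept) / slope. Absorbances
#' below the intercept would give negative concentrations; these are clipped
#' to zero with a warning.
#'
#' @param cal A [fit_calibration()] result.
#' @param absorbance Numeric vector of absorbance readings.
#' @return Concentrations in the calibration units (ug/mL).
#' @export
conc_from_absorbance <- function(cal, absorbance) {
  stopifnot(inherits(cal, "calibration_curve"))
  conc <- (absorbance - cal$intercept) / cal$slope
  if (any(conc < 0)) {
    warning("absorbance below calibration intercept; concentration clipped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Drug loading record
#'
#' Captures a loading (adsorption) experiment: a known mass of carrier
#' suspended in a drug solution, with the solution concentration measured
#' before and after contact. Concentration units are explicit (`"mg/mL"` or
#' `"ug/mL"`) and may differ between the two readings; they are converted
#' internally. This guards against the classic mistake of mixing mg/mL and
#' ug/mL silently.
#'
#' @param carrier_mass_mg Carrier (nanotube) mass in mg.
#' @param solution_volume_mL Solution volume in mL.
#' @param initial_conc,final_conc Drug concentration before/after loading.
#' @param initial_unit,final_unit `"mg/mL"` or `"ug/mL"`.
#' @return An object of class `loading_record` (concentrations stored in
#'   ug/mL).
#' @export
loading_record <- function(carrier_mass_mg, solution_volume_mL,
                           initial_conc, final_conc,
                           initial_unit = c("mg/mL", "ug/mL"),
                           final_unit = c("mg/mL", "ug/mL")) {
  initial_unit <- match.arg(initial_unit)
  final_unit <- match.arg(final_unit)
  to_ug <- function(x, unit) if (unit == "mg/mL") x * 1000 else x
  initial <- to_ug(initial_conc, initial_unit)
  final <- to_ug(final_conc, final_unit)
  stopifnot(carrier_mass_mg > 0, solution_volume_mL > 0, initial > 0,
            final >= 0)
  if (final > initial) {
    stop("final concentration exceeds initial concentration", call. = FALSE)
  }
  structure(
    list(carrier_mass_mg = carrier_mass_mg,
         solution_volume_mL = solution_volume_mL,
         initial_conc_ug_mL = initial, final_conc_ug_mL = final),
    class = "loading_record"
  )
}

#' Percent of drug adsorbed (generic)
#'
#' For a [loading_record()]: the percentage of drug removed from solution,
#' 100 (1 - C_final / C_initial). For a [configuration()] with a cluster
#' assignment: the percentage of ligand molecules in the nanotube-containing
#' cluster (see [cluster_molecules()]).
#'
#' @param x A `loading_record` or a `configuration`.
#' @param ... Method arguments.
#' @return Percentage in [0, 100].
#' @export
percent_adsorbed <- function(x, ...) UseMethod("percent_adsorbed")

#' @rdname percent_adsorbed
#' @export
percent_adsorbed.loading_record <- function(x, ...) {
  100 * (1 - x$final_conc_ug_mL / x$initial_conc_ug_mL)
}

#' Drug-to-carrier mass ratio of a loading protocol
#'
#' Mass of drug offered (volume x concentration) divided by the carrier mass.
#' For 100 mg of carrier in 10 mL of 40 mg/mL drug solution this is 4,
#' i.e. a 4:1 drug:carrier ratio.
#'
#' @param carrier_mass_mg Carrier mass (mg).
#' @param solution_volume_mL Solution volume (mL).
#' @param conc_mg_mL Drug concentration (mg/mL).
#' @return Dimensionless mass ratio m_drug / m_carrier.
#' @export
loading_mass_ratio <- function(carrier_mass_mg = 100, solution_volume_mL = 10,
                               conc_mg_mL = 40) {
  stopifnot(carrier_mass_mg > 0, solution_volume_mL > 0, conc_mg_mL > 0)
  conc_mg_mL * solution_volume_mL / carrier_mass_mg
}

#' Percent of loaded drug released
#'
#' 100 * released_mass / loaded_mass, where released mass is usually the
#' measured medium concentration times the buffer volume. Released mass
#' exceeding the loaded mass by more than 5% indicates a calibration or
#' bookkeeping inconsistency and raises an error.
#'
#' @param released_mass_ug Released drug mass (ug), >= 0.
#' @param loaded_mass_ug Loaded drug mass (ug), > 0.
#' @return Percentage released.
#' @examples
#' percent_released(882, 1000)  # 88.2
#' @export
percent_released <- function(released_mass_ug, loaded_mass_ug) {
  stopifnot(all(released_mass_ug >= 0), loaded_mass_ug > 0)
  if (any(released_mass_ug > 1.05 * loaded_mass_ug)) {
    stop("released mass exceeds loaded mass by more than 5%: calibration inconsistency",
         call. = FALSE)
  }
  100 * released_mass_ug / loaded_mass_ug
}

#' Release curve from per-time medium concentrations
#'
#' Converts concentrations measured in the release medium at each sampling
#' time into a fraction-scale [release_curve()]:
#' fraction = conc * volume / loaded_mass. Sampling-volume depletion is not
#' modelled (no withdrawal-replacement correction).
#'
#' @param concs_ug_mL Measured concentrations (ug/mL), one per time.
#' @param volume_mL Release-medium volume (mL).
#' @param loaded_mass_ug Drug mass initially loaded on the carrier (ug).
#' @param times Sampling times (minutes), strictly increasing.
#' @return A fraction-scale `release_curve`.
#' @export
timecourse_from_concs <- function(concs_ug_mL, volume_mL, loaded_mass_ug,
                                  times) {
  stopifnot(length(concs_ug_mL) == length(times), volume_mL > 0,
            loaded_mass_ug > 0)
  frac <- percent_released(concs_ug_mL * volume_mL, loaded_mass_ug) / 100
  release_curve(times, frac, value_kind = "fraction")
}
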