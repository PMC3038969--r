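#' Construct a lumen area curve
#'
#' Cross-sectional area of the ascending aorta over one cardiac cycle, from
#' cine segmentation. The systolic and diastolic areas are the global
#' maximum and minimum of the curve.
#'
#' @param times Sample times in ms, strictly increasing.
#' @param areas Lumen areas in mm^2, all positive.
#' @param rr_interval Cardiac cycle length in ms.
#' @return An object of class `area_curve`.
#' @export
area_curve <- function(times, areas, rr_interval) {
  times <- as.numeric(times); areas <- as.numeric(areas)
  if (length(times) != length(areas)) stop("times and areas must match in length")
  if (length(times) < 2L) stop("an area curve needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("areas must be finite and positive")
  structure(list(times = times, areas = areas,
                 rr_interval = as.numeric(rr_interval)),
            class = "area_curve")
}

#' Ascending-aorta strain from an area curve
#'
#' Strain is the relative systolic-diastolic area change,
#' `(Ss - Sd) / Sd`, with `Ss`/`Sd` the maximum/minimum of the lumen area
#' curve over the cardiac cycle.
#'
#' @param a An [area_curve()].
#' @return List with `strain` (dimensionless), `Ss` and `Sd` (mm^2).
#' @export
compute_strain <- function(a) {
  stopifnot(inherits(a, "area_curve"))
  Ss <- max(a$areas)
  Sd <- min(a$areas)
  list(strain = (Ss - Sd) / Sd, Ss = Ss, Sd = Sd)
}

#' Calibrate a tonometric carotid waveform to mmHg
#'
#' Applanation tonometry records the carotid pressure waveform in arbitrary
#' units. Assuming the mean-minus-diastolic pressure difference is conserved
#' along the arterial tree, the waveform is rescaled by the unique positive
#' affine map whose output has mean equal to the brachial mean pressure and
#' minimum equal to the brachial diastolic pressure; the carotid pulse
#' pressure is then the max-min range of the rescaled waveform. The result is
#' invariant to any positive gain or offset of the raw recording.
#'
#' @param raw Numeric vector, raw carotid waveform samples (arbitrary units).
#' @param brachial_mean,brachial_diastolic Brachial mean and diastolic
#'   pressures in mmHg, `brachial_mean > brachial_diastolic`.
#' @return List with `carotid_pp` (mmHg), the map `gain` and `offset`, and
#'   the rescaled waveform `calibrated` (mmHg).
#' @export
calibrate_carotid_pressure <- function(raw, brachial_mean, brachial_diastolic) {
  raw <- as.numeric(raw)
  if (length(raw) < 2L || any(!is.finite(raw)))
    stop("raw carotid waveform must contain at least 2 finite samples")
  if (!(brachial_mean > brachial_diastolic))
    stop("brachial mean pressure must exceed diastolic pressure")
  m <- mean(raw); lo <- min(raw)
  if (m - lo < 1e-12)
    stop("raw carotid waveform is constant (or mean equals minimum); cannot calibrate")
  gain <- (brachial_mean - brachial_diastolic) / (m - lo)
  offset <- brachial_diastolic - gain * lo
  cal <- gain * raw + offset
  list(carotid_pp = gain * (max(raw) - lo), gain = gain, offset = offset,
       calibrated = cal)
}

#' Distensibility from strain and pulse pressure
#'
#' `Distensibility = strain / pulse pressure`, in mmHg^-1. Using the carotid
#' pulse pressure yields the carotid-calibrated index, using the brachial
#' pulse pressure the brachial one.
#'
#' @param strain Dimensionless area strain.
#' @param pp Pulse pressure in mmHg, positive.
#' @return Distensibility in mmHg^-1.
#' @export
compute_distensibility <- function(strain, pp) {
  if (!(pp > 0)) stop("pulse pressure must be positive")
  strain / pp
}

#' Bramwell-Hill pulse wave velocity from distensibility
#'
#' The Bramwell-Hill model for a compliant vessel filled with an
#' incompressible, non-viscous fluid gives
#' `PWV = sqrt(1 / (rho * D))` with `D` the distensibility in SI units.
#' Distensibility is supplied in clinical units (mmHg^-1) and converted via
#' 1 mmHg = 133.322 Pa.
#'
#' @param d Distensibility in mmHg^-1, positive.
#' @param rho Blood density in kg m^-3 (default 1059).
#' @return Pulse wave velocity in m/s.
#' @export
pwv_from_distensibility <- function(d, rho = DEFAULT_BLOOD_DENSITY) {
  if (any(d <= 0)) stop("distensibility must be positive")
  if (!(rho > 0)) stop("blood density must be positive")
  sqrt(1 / (rho * d / MMHG_TO_PA))
}

#' Distensibility from pulse wave velocity (inverse Bramwell-Hill)
#'
#' @param pwv Pulse wave velocity in m/s, positive.
#' @param rho Blood density in kg m^-3 (default 1059).
#' @return Distensibility in mmHg^-1.
#' @export
distensibility_from_pwv <- function(pwv, rho = DEFAULT_BLOOD_DENSITY) {
  if (any(pwv <= 0)) stop("pwv must be positive")
  if (!(rho > 0)) stop("blood density must be positive")
  MMHG_TO_PA / (rho * pwv^2)
}

#' Regional arch pulse wave velocity from length and transit time
#'
#' `Arch_PWV = arch length / transit time`; with the length in mm and the
#' time in ms the ratio is numerically in m/s.
#'
#' @param arch_length_mm Centerline arch length between the slice-plane
#'   intersections, mm.
#' @param transit_time_ms Transit time, ms, positive.
#' @param boundary_flag If `TRUE` (transit-time argmin at the search
#'   boundary) a warning is emitted.
#' @return Pulse wave velocity in m/s.
#' @export
compute_arch_pwv <- function(arch_length_mm, transit_time_ms,
                             boundary_flag = FALSE) {
  if (!(arch_length_mm > 0)) stop("arch length must be positive")
  if (!(transit_time_ms > 0)) stop("transit time must be positive (a zero transit time gives an infinite PWV)")
  if (isTRUE(boundary_flag))
    warning("transit time lies at the search-range boundary; Arch_PWV may be unreliable")
  arch_length_mm / transit_time_ms
}

#' Mean arterial pressure (one-third rule)
#'
#' Fallback when the oscillometric device does not report a mean pressure:
#' `MAP = diastolic + (systolic - diastolic) / 3`.
#'
#' @param systolic,diastolic Brachial pressures in mmHg, `systolic > diastolic`.
#' @return Mean arterial pressure in mmHg.
#' @export
mean_arterial_pressure <- function(systolic, diastolic) {
  if (!all(systolic > diastolic)) stop("systolic pressure must exceed diastolic")
  diastolic + (systolic - diastolic) / 3
}

#' Construct a pressure record
#'
#' Brachial cuff pressures plus optional tonometric carotid data. A measured
#' mean pressure takes precedence; the one-third rule is used only when no
#' mean is supplied.
#'
#' @param brachial_systolic,brachial_diastolic Brachial pressures, mmHg.
#' @param brachial_mean Optional measured mean pressure, mmHg; defaults to
#'   [mean_arterial_pressure()].
#' @param carotid_raw Optional raw carotid tonometry waveform (arbitrary
#'   units).
#' @param carotid_pp Optional carotid pulse pressure, mmHg; if absent and
#'   `carotid_raw` is present it is computed by
#'   [calibrate_carotid_pressure()].
#' @return An object of class `pressure_record` with `brachial_pp` and
#'   (possibly `NA`) `carotid_pp`.
#' @export
pressure_record <- function(brachial_systolic, brachial_diastolic,
                            brachial_mean = NULL, carotid_raw = NULL,
                            carotid_pp = NULL) {
  if (!(brachial_systolic > brachial_diastolic))
    stop("systolic pressure must exceed diastolic")
  if (is.null(brachial_mean))
    brachial_mean <- mean_arterial_pressure(brachial_systolic, brachial_diastolic)
  if (!(brachial_mean > brachial_diastolic && brachial_mean < brachial_systolic))
    stop("mean pressure must lie strictly between diastolic and systolic")
  if (is.null(carotid_pp) && !is.null(carotid_raw))
    carotid_pp <- calibrate_carotid_pressure(carotid_raw, brachial_mean,
                                             brachial_diastolic)$carotid_pp
  structure(list(brachial_systolic = brachial_systolic,
                 brachial_diastolic = brachial_diastolic,
                 brachial_mean = brachial_mean,
                 brachial_pp = brachial_systolic - brachial_diastolic,
                 carotid_raw = carotid_raw,
                 carotid_pp = if (is.null(carotid_pp)) NA_real_ else carotid_pp),
            class = "pressure_record")
}
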