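#' Parameters of the synthetic cohort generator
#'
#' The generator emulates the per-subject data a CMR stiffness study
#' produces: a delayed pair of phase-contrast velocity waveforms, an
#' ascending-aorta lumen-area curve, 3D arch centerline markers, cuff and
#' tonometric pressures, and an external carotid-femoral PWV. Every subject
#' is built Bramwell-Hill-consistent before noise, so ground truth is known
#' for all downstream quantities.
#'
#' Defaults mirror a healthy-volunteer cohort: true distensibility is
#' log-normal with marginal mean 5.86e-3 and SD 3.23e-3 mmHg^-1, ages are
#' uniform on 20-70 years with log-distensibility declining with age,
#' velocity waveforms are sampled every 18 ms (view-shared phase contrast),
#' area curves every 33 ms (cine inter-phase), and the brachial pulse
#' pressure exceeds the carotid one by 9.5 mmHg on average.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param blood_density Blood density, kg m^-3.
#' @param distensibility_log_mean,distensibility_log_sd Marginal mean/SD of
#'   log true distensibility (mmHg^-1 scale).
#' @param age_range Years, uniform draw.
#' @param age_log_slope Decline of log-distensibility per year of age; the
#'   residual SD is reduced so the marginal SD stays at
#'   `distensibility_log_sd`.
#' @param brachial_minus_carotid_pp_offset Mean brachial - carotid pulse
#'   pressure difference, mmHg.
#' @param pp_noise_sd SD of the brachial-carotid offset noise, mmHg.
#' @param waveform_sample_interval Velocity sampling step, ms.
#' @param area_sample_interval Area-curve sampling step, ms.
#' @param rr_interval Cardiac cycle length, ms.
#' @param velocity_noise_sd Additive velocity noise, cm/s.
#' @param area_noise_sd Additive area noise, mm^2.
#' @param marker_jitter_sd Isotropic 3D marker jitter, mm.
#' @param arch_radius_range Arch-top radius draw range, mm.
#' @param limb_length Straight ascending/descending limb length, mm.
#' @param plane_height Height of the phase-contrast slice plane above the
#'   limb bases, mm (must be below `limb_length`).
#' @param cf_pwv_noise_sd SD of the carotid-femoral PWV around its
#'   PWV-linked mean, m/s.
#' @param seed Integer seed; the cohort is a pure function of these
#'   parameters including the seed.
#' @return An object of class `synth_params` (a validated list).
#' @export
synth_params <- function(n_subjects = 46L,
                         blood_density = DEFAULT_BLOOD_DENSITY,
                         distensibility_log_mean =
                           log(5.86e-3) - 0.5 * log(1 + (3.23 / 5.86)^2),
                         distensibility_log_sd =
                           sqrt(log(1 + (3.23 / 5.86)^2)),
                         age_range = c(20, 70),
                         age_log_slope = 0.025,
                         brachial_minus_carotid_pp_offset = 9.5,
                         pp_noise_sd = 3,
                         waveform_sample_interval = 18,
                         area_sample_interval = 33,
                         rr_interval = 900,
                         velocity_noise_sd = 1,
                         area_noise_sd = 2,
                         marker_jitter_sd = 1,
                         arch_radius_range = c(20, 30),
                         limb_length = 25,
                         plane_height = 5,
                         cf_pwv_noise_sd = 2.3,
                         seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            blood_density = blood_density,
            distensibility_log_mean = distensibility_log_mean,
            distensibility_log_sd = distensibility_log_sd,
            age_range = age_range,
            age_log_slope = age_log_slope,
            brachial_minus_carotid_pp_offset = brachial_minus_carotid_pp_offset,
            pp_noise_sd = pp_noise_sd,
            waveform_sample_interval = waveform_sample_interval,
            area_sample_interval = area_sample_interval,
            rr_interval = rr_interval,
            velocity_noise_sd = velocity_noise_sd,
            area_noise_sd = area_noise_sd,
            marker_jitter_sd = marker_jitter_sd,
            arch_radius_range = arch_radius_range,
            limb_length = limb_length,
            plane_height = plane_height,
            cf_pwv_noise_sd = cf_pwv_noise_sd,
            seed = as.integer(seed))
  sds <- c(p$pp_noise_sd, p$velocity_noise_sd, p$area_noise_sd,
           p$marker_jitter_sd, p$cf_pwv_noise_sd, p$distensibility_log_sd)
  if (any(sds < 0)) stop("all noise SDs must be >= 0")
  if (p$waveform_sample_interval <= 0 || p$area_sample_interval <= 0)
    stop("sample intervals must be positive")
  if (p$rr_interval <= 4 * p$waveform_sample_interval)
    stop("rr_interval must exceed 4 sampling intervals")
  if (p$blood_density <= 0) stop("blood density must be positive")
  if (p$plane_height < 0 || p$plane_height > p$limb_length)
    stop("plane_height must lie in [0, limb_length]")
  age_var <- diff(p$age_range)^2 / 12
  if (p$distensibility_log_sd^2 < p$age_log_slope^2 * age_var)
    stop("distensibility_log_sd too small for the given age trend")
  class(p) <- "synth_params"
  p
}

#' Zero out all noise sources of a parameter set
#'
#' Convenience for ground-truth identity checks: returns the same parameters
#' with every noise SD set to 0 (the age trend is kept).
#'
#' @param params A [synth_params()] object.
#' @return A `synth_params` object with all noise SDs zero.
#' @export
noise_free <- function(params) {
  params$pp_noise_sd <- 0
  params$velocity_noise_sd <- 0
  params$area_noise_sd <- 0
  params$marker_jitter_sd <- 0
  params$cf_pwv_noise_sd <- 0
  params
}

# Smooth unimodal velocity template (cm/s): half-cosine upstroke from flow
# onset to the peak, slower cosine decay back to zero, zero-flow diastole.
velocity_template <- function(t, onset_ms, upslope_ms, downslope_ms,
                              peak_velocity) {
  tt <- t - onset_ms
  v <- numeric(length(t))
  up <- tt >= 0 & tt <= upslope_ms
  v[up] <- peak_velocity * 0.5 * (1 - cos(pi * tt[up] / upslope_ms))
  dn <- tt > upslope_ms & tt <= upslope_ms + downslope_ms
  v[dn] <- peak_velocity * 0.5 * (1 + cos(pi * (tt[dn] - upslope_ms) / downslope_ms))
  v
}

#' Generate a delayed ascending/descending velocity waveform pair
#'
#' The descending waveform is the ascending template delayed by exactly
#' `transit_time` in continuous time (the delay is applied before sampling,
#' so the true shift is not quantized to the acquisition grid), optionally
#' amplitude-scaled and noise-corrupted.
#'
#' @param transit_time True delay in ms, within `[0, 100]`.
#' @param params A [synth_params()] object (sampling grid and noise).
#' @param upslope_ms,downslope_ms Template upstroke/decay durations, ms.
#' @param peak_velocity Template peak velocity, cm/s.
#' @param onset_ms Flow-onset time of the ascending template, ms.
#' @param desc_scale Amplitude scale of the descending waveform.
#' @return List with `ascending` and `descending` [velocity_waveform()]s on
#'   the same grid covering one cardiac cycle.
#' @export
generate_velocity_pair <- function(transit_time, params = synth_params(),
                                   upslope_ms = 90, downslope_ms = 220,
                                   peak_velocity = 100, onset_ms = 60,
                                   desc_scale = 1) {
  if (transit_time < 0 || transit_time > 100)
    stop("transit_time must lie in [0, 100] ms (the shift search range)")
  rr <- params$rr_interval
  if (onset_ms + transit_time + upslope_ms + downslope_ms >= rr)
    stop("waveform support (onset + transit + upstroke + decay) must fit in one cycle")
  times <- seq(0, by = params$waveform_sample_interval,
               length.out = floor(rr / params$waveform_sample_interval))
  n <- length(times)
  va <- velocity_template(times, onset_ms, upslope_ms, downslope_ms, peak_velocity)
  vd <- desc_scale * velocity_template(times - transit_time, onset_ms,
                                       upslope_ms, downslope_ms, peak_velocity)
  if (params$velocity_noise_sd > 0) {
    va <- va + stats::rnorm(n, 0, params$velocity_noise_sd)
    vd <- vd + stats::rnorm(n, 0, params$velocity_noise_sd)
  }
  list(ascending = velocity_waveform(times, va, rr),
       descending = velocity_waveform(times, vd, rr))
}

#' Generate a lumen-area curve with known strain
#'
#' A smooth periodic curve whose minimum is the diastolic area and whose
#' maximum is `diastolic_area * (1 + strain)`. The systolic peak is placed on
#' a sample instant so the discrete extrema equal the continuous ones and the
#' built-in strain is recovered exactly at zero noise.
#'
#' @param diastolic_area Diastolic lumen area, mm^2, positive.
#' @param strain Dimensionless area strain, > -1.
#' @param rr_interval Cardiac cycle length, ms.
#' @param params A [synth_params()] object (sampling step and noise).
#' @param peak_time_ms Nominal systolic peak time; snapped to the sampling
#'   grid.
#' @param width_ms Half-width of the systolic bump, ms.
#' @return An [area_curve()].
#' @export
generate_area_curve <- function(diastolic_area, strain,
                                rr_interval = synth_params()$rr_interval,
                                params = synth_params(),
                                peak_time_ms = 200, width_ms = 170) {
  if (!(diastolic_area > 0)) stop("diastolic_area must be positive")
  if (!(strain > -1)) stop("strain must exceed -1")
  times <- seq(0, by = params$area_sample_interval,
               length.out = floor(rr_interval / params$area_sample_interval))
  t_pk <- times[which.min(abs(times - peak_time_ms))]
  bump <- numeric(length(times))
  inb <- abs(times - t_pk) <= width_ms
  bump[inb] <- 0.5 * (1 + cos(pi * (times[inb] - t_pk) / width_ms))
  areas <- diastolic_area * (1 + strain * bump)
  if (params$area_noise_sd > 0)
    areas <- areas + stats::rnorm(length(times), 0, params$area_noise_sd)
  area_curve(times, pmax(areas, 1e-6), rr_interval)
}

# Rotation about the x axis by `deg` degrees; applied to markers and the
# slice plane so tilt leaves the geometry rigidly moved.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3L, 3L, byrow = TRUE)
}

#' Generate 3D arch centerline markers with analytic length
#'
#' The reference arch is two straight vertical limbs of length `limb_length`
#' separated by `separation`, joined by a semi-elliptic top with horizontal
#' semi-axis `separation / 2` and vertical semi-axis `radius` (a semicircle
#' when `separation == 2 * radius`); the whole shape may be tilted out of
#' plane. Markers are placed evenly along each limb and at the quarter
#' points of the top; `radius = Inf` degenerates to a straight line of
#' collinear markers. The analytic length between the two limb base planes
#' is returned together with the slice plane `plane_height` mm above the
#' bases.
#'
#' @param radius Arch-top vertical semi-axis, mm (`Inf` for the collinear
#'   degenerate mode).
#' @param separation Ascending-descending limb separation, mm.
#' @param tilt Out-of-plane tilt, degrees (rotation about the x axis).
#' @param n_asc,n_top,n_desc Marker counts: 6-8 per limb, 3 on the top
#'   (counts outside these ranges draw a warning but are honored).
#' @param params A [synth_params()] object (limb length, plane height,
#'   marker jitter).
#' @return List with `markers` ([centerline_markers()]), `true_length` (mm,
#'   analytic, between the limb base planes, jitter-free), `clipped_length`
#'   (mm, between the slice-plane crossings) and `plane`
#'   ([slice_plane()]).
#' @export
generate_arch_markers <- function(radius, separation = 2 * radius, tilt = 0,
                                  n_asc = 7L, n_top = 3L, n_desc = 7L,
                                  params = synth_params()) {
  if (!(radius > 0)) stop("radius must be positive")
  if (n_asc < 6L || n_asc > 8L || n_desc < 6L || n_desc > 8L)
    warning("limb marker counts outside the usual 6-8 range")
  if (n_top != 3L)
    warning("arch-top marker count differs from the usual 3")
  L <- params$limb_length
  R <- rot_x(tilt)
  if (is.infinite(radius)) {
    # Degenerate collinear mode: all markers on one straight line.
    total <- 2 * L + separation
    z <- seq(0, total, length.out = n_asc + n_top + n_desc)
    pts <- cbind(0, 0, z)
    true_len <- total
    clip_len <- total - 2 * params$plane_height
  } else if (L <= 0) {
    # No straight limbs: all markers lie on the (semi-elliptic) top itself.
    a <- separation / 2
    b <- radius
    th <- seq(0, pi, length.out = n_asc + n_top + n_desc)
    pts <- cbind(-a * cos(th), 0, b * sin(th))
    ell_speed <- function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
    true_len <- stats::integrate(ell_speed, 0, pi, rel.tol = 1e-10)$value
    clip_len <- true_len
  } else {
    a <- separation / 2
    b <- radius
    z_asc <- seq(0, L, length.out = n_asc)
    asc <- cbind(-a, 0, z_asc)
    th <- seq(0, pi, length.out = n_top + 2L)[2:(n_top + 1L)]
    top <- cbind(-a * cos(th), 0, L + b * sin(th))
    z_desc <- seq(L, 0, length.out = n_desc)
    desc <- cbind(a, 0, z_desc)
    pts <- rbind(asc, top, desc)
    ell_speed <- function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
    arc <- stats::integrate(ell_speed, 0, pi, rel.tol = 1e-10)$value
    true_len <- 2 * L + arc
    clip_len <- true_len - 2 * params$plane_height
  }
  pts <- pts %*% t(R)
  if (params$marker_jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, params$marker_jitter_sd),
                        ncol = 3L)
  seg <- c(rep("ascending", n_asc), rep("arch_top", n_top),
           rep("descending", n_desc))
  plane <- slice_plane(drop(R %*% c(0, 0, params$plane_height)),
                       drop(R %*% c(0, 0, 1)))
  list(markers = centerline_markers(pts, seg),
       true_length = true_len,
       clipped_length = clip_len,
       plane = plane)
}

# Solve for the exponent gamma such that the raised-cosine tonometric pulse
# shape s^gamma has the sample mean required for the mean/diastolic
# calibration to reproduce the target carotid pulse pressure exactly.
carotid_raw_waveform <- function(target_pp, brachial_mean, brachial_diastolic,
                                 rr_interval, n_samples = 128L) {
  t <- seq(0, rr_interval, length.out = n_samples + 1L)[seq_len(n_samples)]
  f <- 0.7  # systolic fraction of the cycle carrying the pulse
  s <- numeric(n_samples)
  inp <- t <= f * rr_interval
  s[inp] <- 0.5 * (1 - cos(2 * pi * t[inp] / (f * rr_interval)))
  # Calibration maps (mean, min) onto the brachial values, so the pulse
  # pressure it returns is (mean_b - dia_b) * (max - min) / (mean - min).
  # Solve the shape exponent so the *sampled* mean/max ratio hits the target.
  m_target <- (brachial_mean - brachial_diastolic) / target_pp
  # Feasible ratios run from ~0 (gamma large) to the positive-support
  # fraction of the pulse (gamma -> 0).
  if (m_target <= 1e-3 || m_target >= mean(s > 0) - 1e-3)
    stop("carotid pulse pressure target incompatible with the pulse shape")
  smax <- max(s)
  g <- stats::uniroot(function(g) mean(s^g) / smax^g - m_target,
                      interval = c(0.02, 50), tol = 1e-14)$root
  s^g
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_subjects` subjects whose true distensibility, Bramwell-Hill PWV,
#' arch geometry, transit time, strain and pressures are mutually consistent
#' before noise: `true_pwv` is the Bramwell-Hill transform of
#' `true_distensibility`, `true_transit_time = clipped arch length /
#' true_pwv`, and `true_strain = true_distensibility * carotid pulse
#' pressure`. Log-distensibility declines with age so that an age-grouped
#' summary shows higher PWV in the older group. The carotid-femoral PWV is
#' generated around a linear function of the true PWV. The cohort is a pure
#' function of the parameter set, including its seed; ages are redrawn for
#' one subject if needed so that both the `<= 50` and `> 50` year groups are
#' populated when `n_subjects >= 10`.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   per-subject inputs + truth), `truth` (data frame), `params`.
#' @export
generate_cohort <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (params$n_subjects < 3L) stop("a cohort needs at least 3 subjects")
  set.seed(params$seed)
  n <- params$n_subjects
  age <- stats::runif(n, params$age_range[1L], params$age_range[2L])
  if (n >= 10L) {
    if (!any(age > 50)) age[n] <- stats::runif(1L, 50.5, params$age_range[2L])
    if (!any(age <= 50)) age[n] <- stats::runif(1L, params$age_range[1L], 50)
  }
  age_mid <- mean(params$age_range)
  age_var <- diff(params$age_range)^2 / 12
  resid_sd <- sqrt(params$distensibility_log_sd^2 -
                     params$age_log_slope^2 * age_var)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    logd <- params$distensibility_log_mean -
      params$age_log_slope * (age[i] - age_mid) +
      stats::rnorm(1L, 0, resid_sd)
    d_true <- exp(logd)
    pwv_true <- pwv_from_distensibility(d_true, params$blood_density)
    radius <- stats::runif(1L, params$arch_radius_range[1L],
                           params$arch_radius_range[2L])
    tilt <- stats::runif(1L, -15, 15)
    geo <- generate_arch_markers(radius, 2 * radius, tilt, params = params)
    tt_true <- geo$clipped_length / pwv_true  # mm / (m/s) = ms
    if (tt_true > 100)
      stop("true transit time exceeds the 100 ms search range; ",
           "check geometry/distensibility parameters")
    cpp <- -1
    while (cpp < 18) cpp <- stats::rnorm(1L, 35.9, 10.6)
    strain_true <- d_true * cpp
    # offset noise truncated at 3 SD: keeps the brachial PP physiological
    # and the tonometric shape solve feasible for every subject
    e <- stats::rnorm(1L, 0, params$pp_noise_sd)
    e <- max(min(e, 3 * params$pp_noise_sd), -3 * params$pp_noise_sd)
    ppb <- cpp + params$brachial_minus_carotid_pp_offset + e
    dia <- stats::rnorm(1L, 70, 8)
    sys <- dia + ppb
    map <- dia + ppb / 3
    peak_vel <- stats::runif(1L, 70, 110)
    pair <- generate_velocity_pair(tt_true, params,
                                   peak_velocity = peak_vel,
                                   desc_scale = 0.8)
    pair2 <- generate_velocity_pair(tt_true, params,
                                    peak_velocity = peak_vel,
                                    desc_scale = 0.8)
    sd_area <- 0
    while (sd_area < 300) sd_area <- stats::rnorm(1L, 600, 80)
    area <- generate_area_curve(sd_area, strain_true, params$rr_interval,
                                params)
    raw <- carotid_raw_waveform(cpp, map, dia, params$rr_interval)
    # Second-operator marker picks: same true geometry, independent jitter.
    geo2 <- generate_arch_markers(radius, 2 * radius, tilt, params = params)
    cf <- -0.35 + 1.71 * pwv_true + stats::rnorm(1L, 0, params$cf_pwv_noise_sd)
    pres <- pressure_record(sys, dia, brachial_mean = map, carotid_raw = raw)
    subjects[[i]] <- list(
      subject_id = sprintf("subj_%03d", i),
      age = age[i],
      true_distensibility = d_true,
      true_pwv = pwv_true,
      true_transit_time = tt_true,
      true_arch_length = geo$clipped_length,
      true_strain = strain_true,
      true_carotid_pp = cpp,
      cf_pwv = cf,
      pressures = pres,
      ascending = pair$ascending,
      descending = pair$descending,
      ascending_op2 = pair2$ascending,
      descending_op2 = pair2$descending,
      area = area,
      markers = geo$markers,
      markers_op2 = geo2$markers,
      plane = geo$plane)
  }
  truth <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1L), "subject_id"),
    age = age,
    true_distensibility = vapply(subjects, `[[`, numeric(1L), "true_distensibility"),
    true_pwv = vapply(subjects, `[[`, numeric(1L), "true_pwv"),
    true_transit_time_ms = vapply(subjects, `[[`, numeric(1L), "true_transit_time"),
    true_arch_length_mm = vapply(subjects, `[[`, numeric(1L), "true_arch_length"),
    true_strain = vapply(subjects, `[[`, numeric(1L), "true_strain"),
    cf_pwv = vapply(subjects, `[[`, numeric(1L), "cf_pwv"))
  structure(list(subjects = subjects, truth = truth, params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (seed %d)\n",
              length(x$subjects), x$params$seed))
  cat(sprintf("  true distensibility %.3g +/- %.3g mmHg^-1, true PWV %.3g +/- %.3g m/s\n",
              mean(x$truth$true_distensibility), stats::sd(x$truth$true_distensibility),
              mean(x$truth$true_pwv), stats::sd(x$truth$true_pwv)))
  invisible(x)
}
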