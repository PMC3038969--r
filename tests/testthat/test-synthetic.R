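test_that("parameter validation enforces the generator invariants", {
  expect_s3_class(synth_params(), "synth_params")
  expect_error(synth_params(velocity_noise_sd = -1), ">= 0")
  expect_error(synth_params(waveform_sample_interval = 0), "positive")
  expect_error(synth_params(rr_interval = 60), "4 sampling intervals")
  expect_error(synth_params(blood_density = 0), "positive")
  p <- noise_free(synth_params())
  expect_identical(p$velocity_noise_sd, 0)
  expect_identical(p$marker_jitter_sd, 0)
})

test_that("a zero transit time with zero noise gives identical waveforms", {
  p0 <- noise_free(synth_params())
  pr <- generate_velocity_pair(0, p0)
  expect_identical(pr$ascending$velocities, pr$descending$velocities)
  expect_error(generate_velocity_pair(150, p0), "\\[0, 100\\]")
  expect_error(generate_velocity_pair(-2, p0), "\\[0, 100\\]")
})

test_that("the estimator recovers the generator's continuous-time delay", {
  p0 <- noise_free(synth_params())
  pr <- generate_velocity_pair(25, p0)
  expect_lte(abs(estimate_transit_time(pr$ascending, pr$descending)$delta_t - 25), 1)
  # amplitude scaling of the descending limb must not bias the estimate
  pr2 <- generate_velocity_pair(30, p0, desc_scale = 0.7)
  expect_lte(abs(estimate_transit_time(pr2$ascending, pr2$descending)$delta_t - 30), 1)
})

test_that("area curves attain the requested extrema exactly at zero noise", {
  p0 <- noise_free(synth_params())
  a <- generate_area_curve(400, 0.25, 900, p0)
  expect_equal(max(a$areas), 500)
  expect_equal(min(a$areas), 400)
  # zero strain gives a constant curve and zero recovered strain
  a0 <- generate_area_curve(450, 0, 900, p0)
  expect_equal(max(a0$areas), min(a0$areas))
  expect_equal(compute_strain(a0)$strain, 0)
  expect_error(generate_area_curve(-5, 0.2, 900, p0), "positive")
})

test_that("noisy area curves recover the built-in strain within the MC band", {
  p <- synth_params()  # area noise SD 2 mm^2
  set.seed(100)
  st <- replicate(100, compute_strain(generate_area_curve(450, 0.2, 900, p))$strain)
  expect_true(all(abs(st - 0.2) < 0.03))
})

test_that("arch markers carry the analytic arc length", {
  p0 <- noise_free(synth_params())
  # semicircle of radius 50, no limbs
  ps <- noise_free(synth_params(limb_length = 0, plane_height = 0))
  g <- generate_arch_markers(50, 100, params = ps)
  expect_equal(g$true_length, pi * 50, tolerance = 1e-8)
  cv <- fit_centerline(g$markers)
  expect_equal(arc_length(cv), pi * 50, tolerance = 5e-3)
  # collinear degenerate mode: length is the end-to-end distance
  gl <- generate_arch_markers(Inf, 50, params = p0)
  pts <- gl$markers$points
  expect_equal(gl$true_length, sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)))
  # tilt does not change the analytic or fitted length
  gt <- generate_arch_markers(25, 50, tilt = 15, params = p0)
  cvt <- fit_centerline(gt$markers)
  uu <- clip_to_plane(cvt, gt$plane)
  fitted <- arc_length(cvt, uu[["u_asc"]], uu[["u_desc"]])
  expect_equal(fitted, gt$clipped_length, tolerance = 5e-3)
  expect_warning(generate_arch_markers(25, 50, n_asc = 5, params = p0), "6-8")
})

test_that("every generated subject is Bramwell-Hill consistent before noise", {
  co <- generate_cohort(synth_params(n_subjects = 15, seed = 9))
  for (s in co$subjects) {
    expect_equal(s$true_pwv,
                 pwv_from_distensibility(s$true_distensibility,
                                         co$params$blood_density),
                 tolerance = 1e-12)
    expect_equal(s$true_transit_time * s$true_pwv, s$true_arch_length,
                 tolerance = 1e-9)
    expect_equal(s$true_strain, s$true_distensibility * s$true_carotid_pp,
                 tolerance = 1e-12)
    # the calibrated carotid PP reproduces the generating value
    cal <- calibrate_carotid_pressure(s$pressures$carotid_raw,
                                      s$pressures$brachial_mean,
                                      s$pressures$brachial_diastolic)
    expect_equal(cal$carotid_pp, s$true_carotid_pp, tolerance = 1e-6)
  }
})

test_that("cohort generation is deterministic in the seed and guards its preconditions", {
  p <- synth_params(n_subjects = 6, seed = 123)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- synth_params(n_subjects = 6, seed = 124)
  expect_false(identical(generate_cohort(p)$truth, generate_cohort(p2)$truth))
  expect_error(generate_cohort(synth_params(n_subjects = 2)), "3 subjects")
})

test_that("both age groups are populated for cohorts of 10 or more", {
  for (seed in 1:5) {
    co <- generate_cohort(synth_params(n_subjects = 10, seed = seed))
    g <- table(age_groups(co$truth$age))
    expect_true(all(g >= 1))
  }
})

test_that("added noise degrades the cohort correlation, never improves it", {
  r_of <- function(vn, seeds) {
    mean(vapply(seeds, function(s) {
      co <- generate_cohort(synth_params(n_subjects = 20, seed = s,
                                         velocity_noise_sd = vn))
      tab <- analyze_synthetic_cohort(co)
      bramwell_hill_consistency(tab)$regressions$aa_distc_vs_inv_arch_pwv2$pearson_r
    }, numeric(1)))
  }
  seeds <- 1:12
  r_clean <- r_of(0, seeds)
  r_noisy <- r_of(2, seeds)
  expect_gt(r_clean, r_noisy - 0.005)  # weak decrease up to MC error
})
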