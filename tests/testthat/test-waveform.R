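test_that("resampling to 1 ms is an interpolation: idempotent and exact at knots", {
  t18 <- seq(0, 882, by = 18)
  w <- velocity_waveform(t18, test_pulse(t18), 900)
  r <- resample_to_1ms(w)
  expect_equal(r$times, seq(0, 882, by = 1))
  expect_equal(r$velocities[r$times %in% t18], w$velocities)
  # already on a 1 ms grid -> unchanged
  expect_identical(resample_to_1ms(r), r)
})

test_that("cubic resampling reproduces a cubic polynomial", {
  t18 <- seq(0, 882, by = 18)
  f <- function(t) 2 + 0.03 * t - 4e-5 * t^2 + 1.2e-8 * t^3
  w <- velocity_waveform(t18, f(t18), 900)
  r <- resample_to_1ms(w)
  interior <- r$times > 18 & r$times < 864
  expect_lt(max(abs(r$velocities[interior] - f(r$times[interior])) /
                  pmax(abs(f(r$times[interior])), 1)), 1e-9)
})

test_that("resampling rejects inputs with fewer than 4 samples", {
  expect_error(velocity_waveform(c(0, 18, 36), c(0, 1, 2), 900), "4 samples")
})

test_that("normalization maps to [0,1] and is invariant to positive affine maps", {
  t <- seq(0, 882, by = 18)
  w <- velocity_waveform(t, test_pulse(t, peak = 80), 900)
  nw <- normalize_waveform(w)
  expect_equal(min(nw$velocities), 0)
  expect_equal(max(nw$velocities), 1)
  # gain x0.7 and offset +5 give the identical normalized curve
  w2 <- velocity_waveform(t, 0.7 * w$velocities + 5, 900)
  expect_equal(normalize_waveform(w2)$velocities, nw$velocities)
  # idempotence
  expect_equal(normalize_waveform(nw)$velocities, nw$velocities)
  # constant waveform has no amplitude
  expect_error(normalize_waveform(velocity_waveform(t, rep(3, length(t)), 900)),
               "constant")
})

test_that("up-slope extraction follows the onset threshold and first-peak rule", {
  # linear ramp 0 -> 1 over 0..200 ms, then flat: onset at the last sample
  # with value <= 0.05 (t = 10), peak at the first maximum (t = 200)
  t <- 0:399
  v <- pmin(t / 200, 1)
  w <- velocity_waveform(t, v, 450)
  up <- extract_systolic_upslope(w, onset_fraction = 0.05)
  expect_equal(up$onset_time, 10)
  expect_equal(up$peak_time, 200)
  expect_equal(up$n_samples, 191L)
  expect_equal(up$samples[1], 0.05)
  expect_equal(up$samples[up$n_samples], 1)

  # onset_fraction = 0 with leading zeros: onset is the last zero before the rise
  v0 <- c(rep(0, 21), seq(0, 1, length.out = 180), rep(0.2, 199))
  w0 <- velocity_waveform(0:399, v0, 450)
  up0 <- extract_systolic_upslope(w0, onset_fraction = 0)
  expect_equal(up0$onset_time, 21)

  # peak at the first sample leaves no up-slope
  wbad <- velocity_waveform(0:199, seq(1, 0, length.out = 200), 450)
  expect_error(extract_systolic_upslope(wbad), "first sample")
})

test_that("two equal maxima resolve to the first", {
  v <- c(seq(0, 1, length.out = 101), seq(1, 0.5, length.out = 50)[-1],
         seq(0.5, 1, length.out = 50), seq(1, 0, length.out = 101)[-1])
  w <- velocity_waveform(seq_along(v) - 1, v, 400)
  expect_equal(extract_systolic_upslope(w)$peak_time, 100)
})

test_that("a waveform matched against itself gives zero shift and zero error", {
  pr <- test_pair(0)
  res <- estimate_transit_time(pr$asc, pr$asc)
  expect_equal(res$delta_t, 0)
  expect_equal(res$error_profile[1], 0)
})

test_that("noiseless continuous-time shifts of 5-60 ms are recovered within 1 ms", {
  for (s in seq(5, 60, by = 5)) {
    pr <- test_pair(s, scale = 0.8)
    res <- estimate_transit_time(pr$asc, pr$desc)
    expect_lte(abs(res$delta_t - s), 1)
  }
})

test_that("the estimate is invariant to positive affine transforms of either input", {
  pr <- test_pair(27, scale = 0.8)
  ref <- estimate_transit_time(pr$asc, pr$desc)
  asc2 <- velocity_waveform(pr$asc$times, 3.1 * pr$asc$velocities + 12,
                            pr$asc$rr_interval)
  desc2 <- velocity_waveform(pr$desc$times, 0.4 * pr$desc$velocities - 2,
                             pr$desc$rr_interval)
  res <- estimate_transit_time(asc2, desc2)
  expect_equal(res$delta_t, ref$delta_t)
  expect_equal(res$error_profile, ref$error_profile)
})

test_that("shifts beyond the search range clamp to 100 ms with the boundary flag", {
  pr <- test_pair(120)
  res <- estimate_transit_time(pr$asc, pr$desc)
  expect_equal(res$delta_t, 100)
  expect_true(res$boundary_flag)
})

test_that("waveforms with different cycle lengths are rejected", {
  a <- test_pair(10)$asc
  t2 <- seq(0, by = 18, length.out = 44)
  b <- velocity_waveform(t2, test_pulse(t2), 800)
  expect_error(estimate_transit_time(a, b), "rr_interval")
})

test_that("the error profile matches a naive double-loop of its definition", {
  for (seed in 1:10) {
    pr <- random_pair(seed)
    res <- estimate_transit_time(pr$asc, pr$desc)
    a <- normalize_waveform(resample_to_1ms(pr$asc))
    d <- normalize_waveform(resample_to_1ms(pr$desc))
    up <- extract_systolic_upslope(a)
    er <- oracle_er_profile(up$samples, seq(up$onset_time, up$peak_time),
                            d$times, d$velocities, d$rr_interval)
    expect_equal(res$error_profile, er, tolerance = 1e-12)
    expect_equal(res$delta_t, which.min(er) - 1L)
  }
})

test_that("the minimum of the error profile is attained at the reported shift", {
  pr <- test_pair(33, scale = 0.7)
  res <- estimate_transit_time(pr$asc, pr$desc)
  expect_true(all(res$error_profile >= 0))
  expect_equal(min(res$error_profile), res$error_profile[res$delta_t + 1L])
})
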