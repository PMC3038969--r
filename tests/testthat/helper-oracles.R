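# Independent oracles used across the suite.

# Naive O(N*K) double-loop of the quadratic error profile
# Er(k) = (1/N) sum_i (EA*(i) - ED(i + k))^2,
# computed directly from the definitions on already-normalized 1 ms curves.
# Kept loop-by-loop and scalar so it shares no code path with the
# vectorized estimator.
oracle_er_profile <- function(ea, t_up, d_times, d_values, rr, k_max = 100L) {
  td <- c(d_times, rr)
  vd <- c(d_values, d_values[1L])
  ed_at <- function(t) {
    tm <- t %% rr
    stats::approx(td, vd, xout = tm, rule = 2)$y
  }
  er <- numeric(k_max + 1L)
  for (k in 0:k_max) {
    s <- 0
    for (i in seq_along(ea)) {
      s <- s + (ea[i] - ed_at(t_up[i] + k))^2
    }
    er[k + 1L] <- s / length(ea)
  }
  er
}

# Piecewise half-cosine systolic pulse, used to build waveform fixtures
# without going through the package's generator.
test_pulse <- function(t, onset = 60, up = 90, down = 220, peak = 100) {
  tt <- t - onset
  v <- numeric(length(t))
  i1 <- tt >= 0 & tt <= up
  v[i1] <- peak * 0.5 * (1 - cos(pi * tt[i1] / up))
  i2 <- tt > up & tt <= up + down
  v[i2] <- peak * 0.5 * (1 + cos(pi * (tt[i2] - up) / down))
  v
}

# A sampled waveform pair with a continuous-time delay, built directly from
# the pulse above (independent of generate_velocity_pair).
test_pair <- function(shift, step = 18, rr = 900, scale = 1, ...) {
  times <- seq(0, by = step, length.out = floor(rr / step))
  list(asc = velocity_waveform(times, test_pulse(times, ...), rr),
       desc = velocity_waveform(times, scale * test_pulse(times - shift, ...), rr))
}

# Random smooth-ish waveform pair for the estimator-vs-oracle equivalence
# checks: random pulse timing/amplitude plus mild noise.
random_pair <- function(seed) {
  set.seed(seed)
  onset <- runif(1, 30, 90)
  up <- runif(1, 60, 130)
  down <- runif(1, 150, 280)
  peak <- runif(1, 50, 150)
  shift <- runif(1, 0, 60)
  rr <- round(runif(1, 700, 1100))
  times <- seq(0, by = 18, length.out = floor(rr / 18))
  asc <- test_pulse(times, onset, up, down, peak) + rnorm(length(times), 0, 2)
  desc <- 0.8 * test_pulse(times - shift, onset, up, down, peak) +
    rnorm(length(times), 0, 2)
  list(asc = velocity_waveform(times, asc, rr),
       desc = velocity_waveform(times, desc, rr))
}

# Markers on a semicircle of radius r in the x-z plane, spaced by `step_deg`.
semicircle_markers <- function(r = 50, step_deg = 22.5) {
  th <- seq(0, pi, by = step_deg * pi / 180)
  n <- length(th)
  k <- n %/% 3
  seg <- c(rep("ascending", k), rep("arch_top", n - 2 * k), rep("descending", k))
  centerline_markers(cbind(-r * cos(th), 0, r * sin(th)), seg)
}

# Random well-separated 3D markers for property tests.
random_markers <- function(seed, n = 8L) {
  set.seed(seed)
  base <- cbind(cumsum(runif(n, 5, 15)), cumsum(rnorm(n, 0, 3)),
                cumsum(rnorm(n, 0, 3)))
  seg <- c(rep("ascending", 3), rep("arch_top", 3), rep("descending", n - 6))
  centerline_markers(base, seg)
}

random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(M))
}
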