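make_ramp_trace <- function(x, f) {
  load_trace(seq_along(x) * 0.01, f, x)
}

test_that("segmentation reads labels verbatim and recovers boundaries without them", {
  p <- noise_free(default_material_params()$Col)
  proto <- loading_protocol(preload_duration = 4, cycle_count = 8, sampling_rate = 50)
  sim <- generate_load_trace(p, proto, seed = 11)
  seg <- segment_phases(sim$trace, proto)
  expect_equal(seg$preload_end, sim$truth$preload_end)
  expect_equal(seg$ramp_start, sim$truth$ramp_start)
  expect_equal(seg$cycle_boundaries, sim$truth$cycle_boundaries, ignore_attr = TRUE)
  # strip the labels: boundaries must agree within one sample
  bare <- sim$trace
  bare$phase <- NULL
  seg2 <- segment_phases(bare, proto)
  expect_lte(abs(seg2$preload_end - sim$truth$preload_end), 1)
  expect_lte(abs(seg2$ramp_start - sim$truth$ramp_start), 1)
  expect_lte(max(abs(seg2$cycle_boundaries - sim$truth$cycle_boundaries)), 1)
})

test_that("zero-cycle protocols yield an empty cycle list with touching phases", {
  p <- noise_free(default_material_params()$C)
  proto <- loading_protocol(preload_duration = 2, cycle_count = 0, sampling_rate = 50)
  sim <- generate_load_trace(p, proto, seed = 2)
  seg <- segment_phases(sim$trace, proto)
  expect_identical(seg$preload_end, seg$ramp_start)
  expect_null(seg$cycle_boundaries)
})

test_that("segmentation errors on truncated traces", {
  p <- noise_free(default_material_params()$C)
  proto <- loading_protocol(preload_duration = 4, cycle_count = 8, sampling_rate = 50)
  sim <- generate_load_trace(p, proto, seed = 3)
  bare <- sim$trace
  bare$phase <- NULL
  short <- load_trace(bare$time_s[1:100], bare$force_N[1:100], bare$displacement_mm[1:100])
  expect_error(segment_phases(short, proto), "preload")
  mid <- load_trace(bare$time_s[1:300], bare$force_N[1:300], bare$displacement_mm[1:300])
  expect_error(segment_phases(mid, proto), "ramp|cycles")
})

test_that("ultimate point takes the earliest global force maximum", {
  tr <- make_ramp_trace(c(0, 1, 2), c(1, 5, 3))
  up <- ultimate_point(tr)
  expect_equal(up$force, 5)
  expect_equal(up$index, 2)
  expect_equal(up$displacement, 1)
  flat <- make_ramp_trace(c(0, 1, 2), c(2, 2, 2))
  expect_equal(ultimate_point(flat)$index, 1)
  expect_error(ultimate_point(NULL), "empty")
})

test_that("stress and strain are geometry quotients with guarded inputs", {
  expect_equal(ultimate_stress(100, 25), 4)
  expect_equal(ultimate_stress(0, 10), 0)
  expect_equal(ultimate_stress(633, 28.5), 22.21, tolerance = 1e-3)
  expect_error(ultimate_stress(10, 0), "csa")
  expect_equal(strain_at_failure(9, 45), 0.2)
  expect_equal(strain_at_failure(0, 45), 0)
  expect_error(strain_at_failure(9, 0), "gauge")
  expect_equal(elastic_modulus(100, 30, 45), 150)
  expect_equal(elastic_modulus(123.4, 45, 45), 123.4)
  expect_error(elastic_modulus(1, -1, 45), "> 0")
})

test_that("max-gradient stiffness matches exact and brute-force references", {
  # exactly linear: the window width must not matter
  x <- seq(0, 10, by = 0.05)
  tr <- make_ramp_trace(x, 12 * x)
  for (w in c(3, 10, 50)) {
    expect_equal(stiffness_max_gradient(tr, ramp_only_seg(), window = w), 12,
                 tolerance = 1e-10)
  }
  # quadratic force: compare with an exhaustive per-window OLS
  trq <- make_ramp_trace(x, x^2)
  for (w in c(5, 17, 40)) {
    got <- stiffness_max_gradient(trq, ramp_only_seg(), window = w)
    ref <- brute_force_max_slope(x[1:which.max(trq$force_N)],
                                 trq$force_N[1:which.max(trq$force_N)], w)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # too little data for the window
  tiny <- make_ramp_trace(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_error(stiffness_max_gradient(tiny, ramp_only_seg(), window = 5), "shorter")
  expect_error(stiffness_max_gradient(tiny, ramp_only_seg(), window = 2), "at least 3")
  # zero displacement variance
  const <- load_trace(1:10 * 0.1, c(1:9, 5), rep(1, 10))
  expect_error(stiffness_max_gradient(const, ramp_only_seg(), window = 5), "variance")
})

test_that("work to failure integrates force over displacement", {
  x <- seq(0, 4, by = 0.01)
  expect_equal(work_to_failure(make_ramp_trace(x, 10 * x), ramp_only_seg()), 80,
               tolerance = 1e-9)
  x2 <- seq(0, 10, by = 0.1)
  f2 <- rep(5, length(x2))
  f2[1] <- 5 + 1e-9  # earliest-max tie break keeps the full range
  expect_equal(work_to_failure(make_ramp_trace(x2, rev(f2)), ramp_only_seg()), 50,
               tolerance = 1e-6)
  # integration stops at the ultimate point
  x3 <- c(0, 1, 2, 3)
  f3 <- c(0, 2, 4, 1)
  expect_equal(work_to_failure(make_ramp_trace(x3, f3), ramp_only_seg()), 4)
})

test_that("trapezoidal work agrees with a 100x oversampled integral", {
  fun <- function(x) 150 * (1 - exp(-x / 2)) + 25 * x
  x_coarse <- seq(0, 6, length.out = 200)
  x_fine <- seq(0, 6, length.out = 200 * 100)
  coarse <- work_to_failure(make_ramp_trace(x_coarse, fun(x_coarse)), ramp_only_seg())
  fine <- sum(diff(x_fine) * (fun(x_fine)[-1] + fun(x_fine)[-length(x_fine)]) / 2)
  expect_lt(abs(coarse - fine) / fine, 1e-3)
})

test_that("relative stress relaxation is the first-to-last peak change", {
  proto <- fast_protocol()
  p <- noise_free(default_material_params()$C)
  sim <- generate_load_trace(p, proto, seed = 4)
  seg <- segment_phases(sim$trace, proto)
  # hand-built peaks via the truth boundaries
  cb <- sim$truth$cycle_boundaries
  peaks <- vapply(seq_len(nrow(cb)),
                  function(i) max(sim$trace$force_N[cb[i, 1]:cb[i, 2]]), numeric(1))
  expect_equal(relative_stress_relaxation(sim$trace, seg),
               (peaks[length(peaks)] - peaks[1]) / peaks[1])
  # constructed: 100 N -> 50 N
  x <- rep(c(0, 1, 2, 1), 2)
  f <- c(0, 50, 100, 50, 0, 25, 50, 25)
  tr <- load_trace(seq_along(x) * 0.1, f, x)
  seg2 <- structure(list(preload_end = 1L,
                         cycle_boundaries = cbind(start = c(1L, 5L), end = c(4L, 8L)),
                         ramp_start = 9L),
                    class = "phase_segmentation")
  expect_equal(relative_stress_relaxation(tr, seg2), -0.5)
  seg1 <- seg2
  seg1$cycle_boundaries <- seg2$cycle_boundaries[1, , drop = FALSE]
  expect_error(relative_stress_relaxation(tr, seg1), "two cycles")
})

test_that("relaxation converges to relaxation_fraction - 1 for fast decay", {
  p <- tendon_material_params(120, 0.2, 0.3, 25, relaxation_time_constant = 5,
                              failure_strain_spread = 0, csa_spread = 0, noise_sd = 0)
  proto <- loading_protocol(preload_duration = 2, cycle_count = 40, sampling_rate = 50)
  sim <- generate_load_trace(p, proto, seed = 6)
  seg <- segment_phases(sim$trace, proto)
  expect_lt(abs(relative_stress_relaxation(sim$trace, seg) - (0.3 - 1)), 1e-3)
})

test_that("extract_all preserves the unit identities and scales correctly", {
  proto <- fast_protocol()
  sim <- generate_load_trace(default_material_params()$GP, proto, seed = 12)
  sp <- specimen("s1", "GP", sim$truth$csa, proto$gauge_length)
  pr <- extract_all(sim$trace, sp, proto)
  expect_equal(pr$ultimate_stress_MPa * pr$csa_mm2, pr$ultimate_force_N)
  expect_equal(pr$elastic_modulus_MPa * pr$csa_mm2 / sp$gauge_length, pr$stiffness_N_mm)
  # force scaling: x2 scales force-like metrics, leaves ratios unchanged
  tr2 <- sim$trace
  tr2$force_N <- 2 * tr2$force_N
  pr2 <- extract_all(tr2, sp, proto)
  expect_equal(pr2$ultimate_force_N, 2 * pr$ultimate_force_N)
  expect_equal(pr2$stiffness_N_mm, 2 * pr$stiffness_N_mm, tolerance = 1e-10)
  expect_equal(pr2$work_to_failure_mJ, 2 * pr$work_to_failure_mJ, tolerance = 1e-10)
  expect_equal(pr2$strain_at_failure, pr$strain_at_failure)
  expect_equal(pr2$relative_stress_relaxation, pr$relative_stress_relaxation)
})

test_that("the packaged fixture trace reproduces its snapshot properties", {
  path <- system.file("extdata", "demo_trace_synthetic.csv", package = "tendonmech")
  proto <- fast_protocol()
  tr <- read_trace_csv(path)
  sp <- specimen("DEMO_GP_001", "GP", 26.3004589271, proto$gauge_length)
  pr <- extract_all(tr, sp, proto)
  expect_equal(pr$ultimate_force_N, 866.00940649, tolerance = 1e-6)
  expect_equal(pr$ultimate_stress_MPa, 32.92753974, tolerance = 1e-6)
  expect_equal(pr$stiffness_N_mm, 225.45127883, tolerance = 1e-6)
  expect_equal(pr$elastic_modulus_MPa, 385.74640752, tolerance = 1e-6)
  expect_equal(pr$work_to_failure_mJ, 1764.50837160, tolerance = 1e-6)
  expect_equal(pr$strain_at_failure, 0.10312393, tolerance = 1e-6)
  expect_equal(pr$relative_stress_relaxation, -0.02563250, tolerance = 1e-6)
})
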