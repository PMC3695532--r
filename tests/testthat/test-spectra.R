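test_that("1D processing follows spectrometer conventions", {
  # single-point fid: flat spectrum
  sp <- process_1d(1 + 0i, dwell_s = 1e-4)
  expect_equal(nrow(sp), 1024)
  expect_lt(diff(range(sp$intensity)), 1e-12)
  # constant fid with 30 Hz broadening: Lorentzian of FWHM 30 Hz at 0
  dw <- 2e-4
  fid <- rep(1 + 0i, 4096)
  sp <- process_1d(fid, dw, lb_hz = 30, zerofill = 8192)
  pk <- which.max(sp$intensity)
  expect_equal(sp$freq_khz[pk], 0, tolerance = 1e-6)
  half <- max(sp$intensity) / 2
  above <- range(sp$freq_khz[sp$intensity > half]) * 1e3
  expect_equal(diff(above), 30, tolerance = 0.1)
  expect_error(process_1d(fid, dw, zerofill = 10), "at least")
})

test_that("zero filling only interpolates: peak integral invariant", {
  dw <- 1e-4
  fid <- exp(2i * pi * 800 * (0:255) * dw) * exp(-(0:255) * dw * pi * 120)
  int_of <- function(zf) {
    sp <- process_1d(fid, dw, zerofill = zf)
    sum(sp$intensity) * (1 / (zf * dw)) / 1e0
  }
  expect_equal(int_of(512), int_of(2048), tolerance = 1e-3)
})

test_that("ppm referencing uses the ammonium chloride scale", {
  expect_equal(to_ppm(0), 35.9)
  expect_equal(to_ppm(43.5e-3), 36.9)            # +43.5 Hz = +1 ppm
  expect_equal(to_ppm(10) - 35.9, 229.9, tolerance = 0.1)  # ~250 ppm scale
  expect_equal(to_ppm(1.5, "C13"), 10)
  expect_error(to_ppm(1, "H1"))
})

test_that("States recombination discriminates the sign of the frequency", {
  nu <- 3e3
  dt1 <- 40e-6                     # 25 kHz MAS: indirect width 25 kHz
  t1 <- (0:63) * dt1
  sp <- process_2d_states(cos(2 * pi * nu * t1), sin(2 * pi * nu * t1),
                          dwell1_s = dt1, lb1_hz = 100, zerofill1 = 512)
  expect_equal(attr(sp, "sw1_khz"), 25)
  pk <- sp$f1_khz[which.max(sp$intensity)]
  expect_equal(pk, 3, tolerance = 0.1)
  at <- function(f) max(abs(sp$intensity[abs(sp$f1_khz - f) < 1]))
  expect_gt(at(3) / at(-3), 50)    # no mirror image
  expect_error(process_2d_states(1:4 + 0i, 1:5 + 0i, dwell1_s = dt1),
               "shape")
})

test_that("slices are nearest-column and unit normalised", {
  nu <- 3e3; dt1 <- 40e-6; t1 <- (0:31) * dt1
  cosm <- cbind(cos(2 * pi * nu * t1), 0.3 * cos(2 * pi * nu * t1))
  sinm <- cbind(sin(2 * pi * nu * t1), 0.3 * sin(2 * pi * nu * t1))
  sp <- process_2d_states(cosm, sinm, dwell1_s = dt1, dwell2_s = 1e-4,
                          zerofill1 = 256, zerofill2 = 8)
  f2 <- sort(unique(sp$f2_khz))
  sl <- extract_slice(sp, f2[3] + 0.1 * diff(f2[1:2]))   # between grid points
  expect_equal(max(sl$intensity), 1)
  expect_equal(sl$f1_khz[which.max(sl$intensity)], 3, tolerance = 0.2)
  expect_error(extract_slice(sp, 1e5), "outside")
})

test_that("the amide indirect lineshape has second-order character", {
  # transmitter near the shifted amide resonance; spread of the simulated
  # line is on the hundreds-of-ppm scale and collapses without second order
  ex <- hnc_experiment(tau_n_ms = 1.2, nu1_n_khz = 50, offset_n_khz = 16.8,
                       t1_increments = 32, n_steps = 100L)
  z <- run_hnc_2d(amide(), ex, zcw_scheme(144))
  sl <- extract_slice(process_2d_states(z, lb1_hz = 200), 0)
  supp <- range(sl$f1_ppm[sl$intensity > 0.1])
  expect_gt(diff(supp), 80)       # hundreds of ppm, not a sharp line
  expect_lt(diff(supp), 600)
  pk <- sl$f1_ppm[which.max(sl$intensity)]
  expect_gt(pk, 250)              # in the strongly shifted amide region
  expect_lt(pk, 520)
})
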