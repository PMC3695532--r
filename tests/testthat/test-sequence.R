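test_that("no rf or zero pulse length produces no filtered signal", {
  pw <- fast_powder()
  r0 <- run_hnc_1d(glycine(), fast_exp(nu1_n_khz = 0), pw)
  expect_lt(abs(r0$efficiency), 1e-10)
  expect_lt(r0$selected_amplitude, 1e-10)
  for (sel in c("SQ", "DQ")) {
    rt <- run_hnc_1d(glycine(), fast_exp(tau_n_ms = 0, selection = sel), pw)
    expect_lt(abs(rt$efficiency), 1e-12)
  }
})

test_that("non-rotor-synchronised pulses are rejected", {
  expect_error(run_hnc_1d(glycine(), fast_exp(tau_n_ms = 0.41), fast_powder()),
               "rotor-synchronised")
})

test_that("coherence amplitudes are norm-conserving under the pulse", {
  rho0 <- embed_operator(spin_matrices(1 / 2)$Ix, "C13")
  a0 <- coherence_amplitudes(rho0)
  expect_equal(a0$amplitude[a0$order == 0], 1, tolerance = 1e-12)
  expect_equal(sum(a0$amplitude^2), 1, tolerance = 1e-12)
  U <- pulse_propagator_cached(glycine(), c(25, 55, 140), 10, nu1_n_khz = 35)
  a1 <- coherence_amplitudes(evolve(rho0, U))
  expect_equal(sum(a1$amplitude^2), 1, tolerance = 1e-10)
  expect_true(all(a1$amplitude >= 0))
  expect_gt(sum(a1$amplitude[abs(a1$order) == 1]), 0)   # SQ terms generated
})

test_that("phase cycling reproduces the projection filter", {
  pw <- fast_powder()
  for (sel in c("SQ", "DQ")) {
    ex <- fast_exp(selection = sel)
    e_proj <- run_hnc_1d(glycine(), ex, pw)$efficiency
    e_cyc <- phase_cycle_run(glycine(), ex, pw)$efficiency
    expect_lt(abs(e_proj - e_cyc), 1e-8)
  }
  # a two-step cycle keeps all even orders: differs from pure DQ projection
  exd <- fast_exp(selection = "DQ")
  e_dq <- run_hnc_1d(glycine(), exd, pw)$efficiency
  e_bad <- phase_cycle_run(glycine(), exd, pw, n_phases = 8,
                           receiver = rep(c(0.5, 0, 0, 0), 2))$efficiency
  expect_gt(abs(e_bad - e_dq), 1e-6)
  # insufficient phases are rejected
  expect_error(phase_cycle_run(glycine(), exd, pw, n_phases = 4), "separate")
})

test_that("order-0 'selection' reproduces the unfiltered echo", {
  pw <- fast_powder()
  ex <- fast_exp()
  e0 <- phase_cycle_run(glycine(), ex, pw, p_select = 0,
                        n_phases = 1)$efficiency
  # independent reconstruction with the propagation primitives
  sys <- glycine()
  Sx <- embed_operator(spin_matrices(1 / 2)$Ix, "C13")
  Upi <- kronecker(matrix(c(0, -1i, -1i, 0), 2, 2), diag(3))
  acc <- 0
  for (i in seq_len(nrow(pw))) {
    o <- c(pw$alpha[i], pw$beta[i], pw$gamma[i])
    U <- propagator(sys, o, 0, 0.4e-3, nu1_n_khz = 35, steps_per_period = 100)
    rho <- evolve(evolve(evolve(Sx, U), Upi), U)
    acc <- acc + pw$weight[i] * Re(sum(rho * Sx)) / 1.5
  }
  expect_equal(e0, acc, tolerance = 1e-8)
})

test_that("the pi pulse refocuses 13C shifts", {
  pw <- fast_powder()
  e_on <- run_hnc_1d(glycine(), fast_exp(), pw)$efficiency
  e_off <- run_hnc_1d(glycine(offset_c_khz = 5), fast_exp(), pw)$efficiency
  expect_lt(abs(e_on - e_off), 1e-10)
})

test_that("offset asymmetry arises only from the second-order terms", {
  pw <- fast_powder()
  eff_at <- function(off, so) {
    run_hnc_1d(glycine(), fast_exp(tau_n_ms = 0.8, offset_n_khz = off), pw,
               second_order = so)$efficiency
  }
  expect_lt(abs(eff_at(4, FALSE) - eff_at(-4, FALSE)), 1e-8)
  expect_gt(abs(eff_at(4, TRUE) - eff_at(-4, TRUE)), 1e-5)
})

test_that("the 2D acquisition matches the 1D limit and refocusing rules", {
  pw <- fast_powder()
  ex <- fast_exp(t1_increments = 6)
  z <- run_hnc_2d(glycine(), ex, pw)
  e1 <- run_hnc_1d(glycine(), ex, pw)$efficiency
  expect_equal(Re(z$cos[1]), e1, tolerance = 1e-10)
  expect_equal(z$delta_t1_s, 40e-6, tolerance = 1e-12)
  # with second order disabled (on resonance) nothing evolves in t1:
  # rotor synchronisation refocuses the first-order quadrupole exactly
  z0 <- run_hnc_2d(glycine(), ex, pw, second_order = FALSE)
  expect_lt(max(Mod(z0$cos - z0$cos[1])), 1e-5)
  # with second order on, the indirect dimension does evolve
  expect_gt(max(Mod(z$cos - z$cos[1])), 1e-3)
})

test_that("filters only ever reduce the deviation norm", {
  U <- pulse_propagator_cached(glycine(), c(25, 55, 140), 10, nu1_n_khz = 35)
  Sx <- embed_operator(spin_matrices(1 / 2)$Ix, "C13")
  rho1 <- evolve(Sx, U)
  expect_equal(frob(rho1), frob(Sx), tolerance = 1e-10)
  comp <- coherence_decompose(rho1)
  rho_f <- comp[["1"]] + comp[["-1"]]
  expect_lt(frob(rho_f), frob(rho1))
})
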