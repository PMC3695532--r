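test_that("rank-2 rotations preserve the norm and match closed forms", {
  expect_equal(wigner_d2(0), diag(5), tolerance = 1e-12)
  expect_equal(wigner_d2(pi / 2)[3, 3], -1 / 2, tolerance = 1e-12)
  A <- complex(real = rnorm(5, 0, 2), imaginary = rnorm(5))
  expect_equal(rotate_rank2(A, c(0, 0, 0)), A, tolerance = 1e-12)
  for (eul in list(c(10, 20, 30), c(123, 87, 201))) {
    expect_equal(sum(Mod(rotate_rank2(A, eul))^2), sum(Mod(A)^2),
                 tolerance = 1e-12)
  }
  # axial tensor at beta = 90 deg picks up d2_00 = -1/2
  ax <- c(0, 0, 1, 0, 0) + 0i
  expect_equal(Re(rotate_rank2(ax, c(0, 90, 0))[3]), -0.5, tolerance = 1e-12)
})

test_that("quadrupole PAS components follow the documented convention", {
  expect_equal(quad_pas_components(1.18, 0)[c(1, 5)], c(0i, 0i))
  expect_equal(quad_pas_components(0, 0.5), rep(0i, 5))
  A <- quad_pas_components(1.18, 0.54)
  expect_equal(Mod(A[5] / A[3]), 0.54 / sqrt(6), tolerance = 1e-12)
  expect_equal(A[2], 0i)
  expect_error(quad_pas_components(1, 1.2), "eta")
})

test_that("MAS Fourier coefficients null the average at the magic angle", {
  ax <- c(0, 0, 1, 0, 0) + 0i
  co <- mas_fourier_coefficients(ax, mas_khz = 25)
  expect_equal(nrow(co), 5)
  expect_lt(Mod(co$coeff[co$m == 0]), 1e-12)   # P2(cos theta_m) = 0
  # mis-set axis: c0 proportional to P2(cos theta)
  th <- magic_angle_deg() + 0.05
  co2 <- mas_fourier_coefficients(ax, 25, rotor_angle_deg = th)
  p2 <- (3 * cos(th * pi / 180)^2 - 1) / 2
  expect_equal(Re(co2$coeff[co2$m == 0]), p2, tolerance = 1e-9)
  expect_gt(Mod(co2$coeff[co2$m == 0]), 1e-4)
})

test_that("the Hamiltonian assembles the expected interaction terms", {
  sys0 <- spin_system(cq_mhz = 0, eta_q = 0, dipole_khz = -0.716, j_hz = 11,
                      mas_khz = 25)
  H <- hamiltonian_at(3e-6, sys0, c(40, 70, 10), second_order = FALSE)
  expect_lt(frob(H - Conj(t(H))), 1e-9)
  # with no quadrupole and no rf only dipole + J survive: pure IzSz form
  IzSz <- embed_operator(spin_matrices(1)$Iz, "N14") %*%
    embed_operator(spin_matrices(1 / 2)$Iz, "C13")
  coef <- sum(diag(H %*% IzSz)) / sum(diag(IzSz %*% IzSz))
  expect_lt(frob(H - coef[1] * IzSz) / frob(H), 1e-9)
  # rotor periodicity
  sys <- glycine()
  H1 <- hamiltonian_at(1.3e-6, sys, c(40, 70, 10), nu1_n_khz = 35)
  H2 <- hamiltonian_at(1.3e-6 + 1 / 25e3, sys, c(40, 70, 10), nu1_n_khz = 35)
  expect_lt(frob(H1 - H2) / frob(H1), 1e-10)
  # second-order terms require the Larmor frequency
  sysbad <- glycine()
  sysbad$larmor_14n_mhz <- NA_real_
  expect_error(hamiltonian_at(0, sysbad, c(0, 30, 0)), "Larmor")
})

test_that("second-order terms scale as 1 / larmor frequency", {
  o <- c(37, 64, 112)
  h2part <- function(lar) {
    sys <- glycine(larmor_14n_mhz = lar)
    hamiltonian_at(0, sys, o) - hamiltonian_at(0, sys, o, second_order = FALSE)
  }
  expect_lt(frob(h2part(87) - h2part(43.5) / 2) / frob(h2part(43.5)), 1e-10)
})

test_that("static first-order frequencies match the analytic spin-1 formula", {
  sys <- spin_system(cq_mhz = 1.18, eta_q = 0.54, dipole_khz = 0,
                     euler_qd_deg = c(25, 40, 70), mas_khz = 25)
  grid <- expand.grid(a = seq(0, 300, 60), b = seq(10, 170, 40))
  err <- scale <- numeric(0)
  for (k in seq_len(nrow(grid))) {
    ornt <- c(grid$a[k], grid$b[k], 33)
    H <- hamiltonian_at(0, sys, ornt, second_order = FALSE)
    d <- Re(diag(H))[1:3] / (2 * pi)
    ang <- field_in_quad_pas(sys, ornt)
    fan <- analytic_first_order_hz(sys$cq_mhz, sys$eta_q,
                                   ang["phi_deg"], ang["theta_deg"])
    err <- c(err, (d[1] - d[2]) - fan[1], (d[2] - d[3]) - fan[2])
    scale <- c(scale, fan)
  }
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(scale^2)), 0.01)
})

test_that("second-order terms match exact full-Zeeman diagonalisation", {
  # residuals are third order, ~ (wQ/w0)^3 * w0; allow three times that scale
  for (ornt in list(c(37, 64, 112), c(200, 130, 15))) {
    sys <- glycine()
    H2 <- hamiltonian_at(0, sys, ornt)
    third <- 3 * (2 * pi * sys$cq_mhz * 1e6 / 4)^3 /
      (2 * pi * sys$larmor_14n_mhz * 1e6)^2
    expect_lt(max(abs(oracle_impl_levels(H2) - oracle_rot_levels(sys, ornt))),
              3 * third)
    # and the residual dipolar splitting (difference between 13C manifolds)
    lev <- oracle_impl_levels(H2)
    lev_or <- oracle_rot_levels(sys, ornt)
    split_impl <- lev[c(2, 4, 6)] - lev[c(1, 3, 5)]
    split_or <- lev_or[c(2, 4, 6)] - lev_or[c(1, 3, 5)]
    expect_equal(split_impl, split_or, tolerance = 0.05)
  }
})

test_that("powder-averaged second-order shift matches the closed form", {
  # isotropic second-order quadrupolar shift of both spin-1 SQ transitions:
  # 3 CQ^2 (1 + eta^2/3) / (40 nu0), towards higher shift
  sys <- spin_system(cq_mhz = 1.18, eta_q = 0.54, dipole_khz = 0, mas_khz = 25)
  pw <- zcw_scheme(300)
  sh <- c(0, 0)
  for (i in seq_len(nrow(pw))) {
    o <- c(pw$alpha[i], pw$beta[i], pw$gamma[i])
    d <- Re(diag(hamiltonian_at(0, sys, o) -
                   hamiltonian_at(0, sys, o, second_order = FALSE)))[1:3]
    sh <- sh + pw$weight[i] * c(d[1] - d[2], d[2] - d[3])
  }
  closed <- 3 * (sys$cq_mhz * 1e6)^2 * (1 + sys$eta_q^2 / 3) /
    (40 * sys$larmor_14n_mhz * 1e6)
  expect_equal(abs(sh) / (2 * pi), rep(closed, 2), tolerance = 0.005)
})

test_that("powder spectra are insensitive to the dipolar sign", {
  # first-order static frequencies, powder-averaged moments
  pw <- zcw_scheme(144)
  moments <- function(dip) {
    sys <- spin_system(cq_mhz = 1.18, eta_q = 0.54, dipole_khz = dip,
                       mas_khz = 25)
    f <- numeric(0)
    for (i in seq_len(nrow(pw))) {
      d <- Re(diag(hamiltonian_at(0, sys, c(pw$alpha[i], pw$beta[i],
                                            pw$gamma[i]),
                                  second_order = FALSE)))
      f <- c(f, sort(d[1:3] - d[4:6]))
    }
    c(mean(f), mean(f^2))
  }
  expect_equal(moments(-0.716), moments(0.716), tolerance = 1e-10)
})
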