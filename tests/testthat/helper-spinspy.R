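# Shared fixtures and independent oracles for the test suite.

# small, fast study conditions
fast_powder <- function(n = 50) zcw_scheme(n)
fast_exp <- function(...) {
  args <- modifyList(list(tau_n_ms = 0.4, nu1_n_khz = 35, n_steps = 100L),
                     list(...))
  do.call(hnc_experiment, args)
}
glycine <- function(...) preset_system("glycine_amine", ...)
amide <- function(...) preset_system("triglycine_amide", ...)

frob <- function(m) sqrt(sum(Mod(m)^2))

random_hermitian6 <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  (m + Conj(t(m))) / 2
}

# ---- independent full-Zeeman oracle (Cartesian operator construction) ----
# Builds the static laboratory-frame Hamiltonian of the pair at the
# instantaneous t = 0 orientation from Cartesian forms, with full Zeeman
# terms on both spins, and returns its exact eigenvalues. Completely
# independent of the spherical-tensor/Wigner machinery in the package.

.rot_about <- function(ang, M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(exp(-1i * ang * e$values)) %*% Conj(t(e$vectors))
}

.euler_op <- function(a, b, g, ops) {
  .rot_about(a * pi / 180, ops$Iz) %*% .rot_about(b * pi / 180, ops$Iy) %*%
    .rot_about(g * pi / 180, ops$Iz)
}

oracle_full_zeeman_levels <- function(sys, ornt) {
  n1 <- spin_matrices(1)
  s1 <- spin_matrices(1 / 2)
  rot <- function(O, U) Conj(t(U)) %*% O %*% U
  # operator conjugation composes opposite to the spatial chain
  UN <- .euler_op(sys$euler_qd_deg[1], sys$euler_qd_deg[2],
                  sys$euler_qd_deg[3], n1) %*%
    .euler_op(ornt[1], ornt[2], ornt[3], n1) %*%
    .euler_op(0, sys$rotor_angle_deg, 0, n1)
  dQ <- 2 * pi * sys$cq_mhz * 1e6 / 4
  # PAS x/y labelling matching the package convention (eta term sign)
  HQ <- dQ * (3 * rot(n1$Iz, UN) %*% rot(n1$Iz, UN) - 2 * diag(3) +
                sys$eta_q * (rot(n1$Iy, UN) %*% rot(n1$Iy, UN) -
                               rot(n1$Ix, UN) %*% rot(n1$Ix, UN)))
  UDn <- .euler_op(ornt[1], ornt[2], ornt[3], n1) %*%
    .euler_op(0, sys$rotor_angle_deg, 0, n1)
  UDs <- .euler_op(ornt[1], ornt[2], ornt[3], s1) %*%
    .euler_op(0, sys$rotor_angle_deg, 0, s1)
  Izr <- embed_operator(rot(n1$Iz, UDn), "N14")
  Szr <- embed_operator(rot(s1$Iz, UDs), "C13")
  IS <- embed_operator(n1$Ix, "N14") %*% embed_operator(s1$Ix, "C13") +
    embed_operator(n1$Iy, "N14") %*% embed_operator(s1$Iy, "C13") +
    embed_operator(n1$Iz, "N14") %*% embed_operator(s1$Iz, "C13")
  b <- 2 * pi * sys$dipole_khz * 1e3
  HD <- b * (3 * Izr %*% Szr - IS)
  w0N <- 2 * pi * sys$larmor_14n_mhz * 1e6
  w0C <- 2 * pi * sys$larmor_13c_mhz * 1e6
  Hfull <- -w0N * embed_operator(n1$Iz, "N14") -
    w0C * embed_operator(s1$Iz, "C13") +
    embed_operator(HQ, "N14") + HD
  eigen(Hfull, symmetric = TRUE, only.values = TRUE)$values
}

# rotating-frame level set of the oracle, grouped by mN (+1, 0, -1), each
# sorted within the group, matching oracle_impl_levels()
oracle_rot_levels <- function(sys, ornt) {
  ev <- oracle_full_zeeman_levels(sys, ornt)
  w0N <- 2 * pi * sys$larmor_14n_mhz * 1e6
  w0C <- 2 * pi * sys$larmor_13c_mhz * 1e6
  zeeman <- rep(-w0N * c(1, 0, -1), times = 2) +
    rep(-w0C * c(0.5, -0.5), each = 3)
  ord <- order(zeeman)
  rot <- (sort(ev) - zeeman[ord])[order(ord)]
  mN <- rep(c(1, 0, -1), times = 2)
  unlist(lapply(c(1, 0, -1), function(m) sort(rot[mN == m])))
}

# same grouping for an implementation Hamiltonian (block-diagonal in mN)
oracle_impl_levels <- function(H) {
  mN <- rep(c(1, 0, -1), times = 2)
  unlist(lapply(c(1, 0, -1), function(m) {
    idx <- which(mN == m)
    sort(Re(eigen(H[idx, idx], symmetric = TRUE, only.values = TRUE)$values))
  }))
}

# analytic first-order spin-1 frequencies (Hz) for polar angles of the lab
# field in the quadrupole PAS, expressed through the package Euler chain:
# crystallite (alpha, beta, gamma) with zero rotor tilt
analytic_first_order_hz <- function(cq_mhz, eta, alpha_deg, beta_deg) {
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  f <- (3 * cos(b)^2 - 1) - eta * sin(b)^2 * cos(2 * a)
  c(3 * cq_mhz * 1e6 / 8 * f, -3 * cq_mhz * 1e6 / 8 * f)
}

# Cartesian geometry: direction of the lab field in the quadrupole PAS for
# the package's Euler chain (independent 3x3 rotation matrices)
.rz3 <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE)
}
.ry3 <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE)
}
.r3 <- function(e) .rz3(e[1] * pi / 180) %*% .ry3(e[2] * pi / 180) %*%
  .rz3(e[3] * pi / 180)

field_in_quad_pas <- function(sys, ornt) {
  n <- .r3(sys$euler_qd_deg) %*% .r3(ornt) %*%
    .r3(c(0, sys$rotor_angle_deg, 0)) %*% c(0, 0, 1)
  c(theta_deg = acos(n[3]) * 180 / pi,
    phi_deg = atan2(n[2], n[1]) * 180 / pi)
}
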