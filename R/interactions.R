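# Spin-system definition, spatial tensor conventions and the rotating-frame
# Hamiltonian for one 13C-14N pair under MAS.
#
# Spatial tensor convention (ascending m = -2..2, angular frequency units):
#   A_PAS = (-(eta/2) delta, 0, sqrt(3/2) delta, 0, -(eta/2) delta)
# with, for the quadrupole of a spin-1 (2I(2I-1) = 2),
#   delta_Q = 2*pi * C_Q / 2           (C_Q = e^2 q Q / h in Hz)
# which places the static first-order transitions of an axial tensor at
# +/- (3 C_Q / 8) (3 cos^2 beta - 1 - eta sin^2 beta cos 2 alpha) Hz,
# and, for the axially symmetric dipole (b = b_IS / 2pi printed in kHz),
#   delta_D = 2 * (2*pi*b), eta_D = 0
# so the static aligned secular coupling is b * 2 IzSz.
#
# Frame chain (all rotations active ZYZ, see rotate_rank2()):
#   quadrupole PAS --(alpha,beta,gamma of the system)--> dipolar PAS
#     --(crystallite alpha,beta,gamma)--> rotor frame
#     --(w_r t, rotor-axis angle, 0)--> lab frame.

#' Quadrupole tensor components in its principal axis system
#'
#' @param cq_mhz Quadrupole coupling constant `C_Q = e^2 q Q / h` in MHz.
#' @param eta_q Asymmetry parameter, in `[0, 1]`.
#' @return Complex vector of length 5 (`m = -2 ... 2`), rad/s.
#' @examples
#' quad_pas_components(1.18, 0.54)
#' @export
quad_pas_components <- function(cq_mhz, eta_q) {
  if (eta_q < 0 || eta_q > 1) abort("`eta_q` must lie in [0, 1].")
  delta <- 2 * pi * cq_mhz * 1e6 / 2
  complex(real = c(-eta_q / 2, 0, sqrt(3 / 2), 0, -eta_q / 2) * delta)
}

#' Dipolar tensor components in its principal axis system
#'
#' @param dipole_khz Dipolar coupling `b_IS / 2pi` in kHz (signed).
#' @return Complex vector of length 5 (`m = -2 ... 2`), rad/s.
#' @export
dipole_pas_components <- function(dipole_khz) {
  delta <- 2 * (2 * pi * dipole_khz * 1e3)
  complex(real = c(0, 0, sqrt(3 / 2), 0, 0) * delta)
}

#' Define a 13C-14N spin system
#'
#' Collects the interaction parameters and static/spinning field conditions
#' for one 13C-14N spin pair. Defaults (Larmor frequencies, MAS rate) match
#' a 14.1 T spectrometer spinning at 25 kHz.
#'
#' @param cq_mhz 14N quadrupole coupling constant in MHz.
#' @param eta_q Quadrupole asymmetry, `[0, 1]`.
#' @param dipole_khz 13C-14N dipolar coupling `b/2pi` in kHz (signed).
#' @param euler_qd_deg Euler angles (degrees) rotating the quadrupole PAS
#'   into the dipolar frame, active ZYZ.
#' @param j_hz Scalar 13C-14N J coupling in Hz.
#' @param larmor_13c_mhz,larmor_14n_mhz Larmor frequencies in MHz. The 14N
#'   value sets the scale of the second-order terms.
#' @param mas_khz MAS rate in kHz (> 0).
#' @param rotor_angle_deg Rotor-axis angle, degrees; defaults to the magic
#'   angle and may be mis-set deliberately (e.g. `magic_angle_deg() + 0.05`).
#' @param offset_n_khz 14N resonance offset from the carrier (taken at the
#'   ammonium chloride reference position), kHz.
#' @param offset_c_khz 13C resonance offset from its carrier, kHz.
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(cq_mhz = 1.18, eta_q = 0.54, dipole_khz = -0.716)
#' sys
#' @export
spin_system <- function(cq_mhz, eta_q, dipole_khz,
                        euler_qd_deg = c(0, 0, 0), j_hz = 0,
                        larmor_13c_mhz = 150, larmor_14n_mhz = 43.5,
                        mas_khz = 25, rotor_angle_deg = magic_angle_deg(),
                        offset_n_khz = 0, offset_c_khz = 0) {
  if (cq_mhz < 0) abort("`cq_mhz` must be >= 0 (sign is carried by the tensor orientation).")
  if (eta_q < 0 || eta_q > 1) abort("`eta_q` must lie in [0, 1].")
  if (mas_khz <= 0) abort("`mas_khz` must be > 0.")
  if (length(euler_qd_deg) != 3) abort("`euler_qd_deg` must have length 3.")
  if (abs(rotor_angle_deg - magic_angle_deg()) > 5) {
    abort("`rotor_angle_deg` must be near the magic angle (within 5 degrees).")
  }
  structure(
    list(
      cq_mhz = cq_mhz, eta_q = eta_q, dipole_khz = dipole_khz,
      euler_qd_deg = as.numeric(euler_qd_deg), j_hz = j_hz,
      larmor_13c_mhz = larmor_13c_mhz, larmor_14n_mhz = larmor_14n_mhz,
      mas_khz = mas_khz, rotor_angle_deg = rotor_angle_deg,
      offset_n_khz = offset_n_khz, offset_c_khz = offset_c_khz
    ),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> 13C-14N pair\n")
  cat(sprintf("  C_Q = %.3f MHz, eta = %.2f, quad->dipole Euler (%g, %g, %g) deg\n",
              x$cq_mhz, x$eta_q, x$euler_qd_deg[1], x$euler_qd_deg[2],
              x$euler_qd_deg[3]))
  cat(sprintf("  dipole b/2pi = %.3f kHz, J = %g Hz\n", x$dipole_khz, x$j_hz))
  cat(sprintf("  Larmor 13C %.1f MHz / 14N %.1f MHz, MAS %.1f kHz, rotor axis %.4f deg\n",
              x$larmor_13c_mhz, x$larmor_14n_mhz, x$mas_khz, x$rotor_angle_deg))
  invisible(x)
}

# Named parameter presets (literature values for the two limiting cases:
# a fast-rotating amine NH3 with a small, dipole-collinear quadrupole, and a
# rigid sp2 peptide amide with a 3 MHz quadrupole tilted from the N-C bond).
.spinspy_presets <- list(
  glycine_amine = list(
    cq_mhz = 1.18, eta_q = 0.54, dipole_khz = -0.716,
    euler_qd_deg = c(0, 0, 0)
  ),
  triglycine_amide = list(
    cq_mhz = 3.01, eta_q = 0.48, dipole_khz = -0.928,
    euler_qd_deg = c(0, 90, 120)
  )
)

#' Built-in spin-system presets
#'
#' `preset_names()` lists the shipped parameter sets; `preset_system()`
#' builds a [spin_system()] from one, with experiment conditions
#' overridable through `...`.
#'
#' @param name Preset name, one of `preset_names()`.
#' @param ... Passed on to [spin_system()] (e.g. `mas_khz`,
#'   `rotor_angle_deg`, offsets).
#' @return `preset_system()`: a `spin_system`; `preset_names()`: character.
#' @examples
#' preset_names()
#' preset_system("glycine_amine")
#' @export
preset_system <- function(name, ...) {
  if (!name %in% names(.spinspy_presets)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(names(.spinspy_presets), collapse = ", ")))
  }
  do.call(spin_system, c(.spinspy_presets[[name]], list(...)))
}

#' @rdname preset_system
#' @export
preset_names <- function() names(.spinspy_presets)

# Per-crystallite precomputation: rotor-frame tensors and fixed scalars.
.orient_pre <- function(system, orientation_deg) {
  AQ_dip <- rotate_rank2(quad_pas_components(system$cq_mhz, system$eta_q),
                         system$euler_qd_deg)
  AQ_rot <- rotate_rank2(AQ_dip, orientation_deg)
  AD_rot <- rotate_rank2(dipole_pas_components(system$dipole_khz),
                         orientation_deg)
  list(
    AQrot = AQ_rot,
    ADrot = AD_rot,
    d2ra = wigner_d2(system$rotor_angle_deg * pi / 180),
    wr = 2 * pi * system$mas_khz * 1e3,
    w0N = 2 * pi * system$larmor_14n_mhz * 1e6,
    Jw = 2 * pi * system$j_hz,
    # sign: a resonance at higher ppm evolves at +f1 on the spectrum axis,
    # which for the m-ordered basis means an Iz coefficient of -2*pi*offset
    offN = -2 * pi * system$offset_n_khz * 1e3,
    offC = -2 * pi * system$offset_c_khz * 1e3
  )
}

#' Rotating-frame Hamiltonian at a point in time
#'
#' Assembles the full rotating-frame Hamiltonian of the 13C-14N pair for one
#' crystallite at time `t_s` under MAS: first-order secular quadrupole,
#' second-order quadrupole self terms and quadrupole-dipole cross terms
#' (instantaneous perturbation theory, scaling as `1/omega_0(14N)`), secular
#' heteronuclear dipole, J coupling, resonance offsets and rf fields.
#'
#' @param t_s Time in seconds (rotor phase zero at `t_s = 0`).
#' @param system A [spin_system()].
#' @param orientation_deg Crystallite Euler angles `c(alpha, beta, gamma)`
#'   in degrees (dipolar frame to rotor frame).
#' @param nu1_n_khz,phase_n_deg 14N rf nutation (kHz) and phase (degrees).
#' @param nu1_c_khz,phase_c_deg 13C rf nutation (kHz) and phase (degrees).
#' @param transmitter_n_khz 14N transmitter displacement from the reference
#'   carrier, kHz, positive towards higher ppm; the effective 14N offset is
#'   `offset_n_khz - transmitter_n_khz`.
#' @param second_order Include the second-order terms? Requires a finite
#'   14N Larmor frequency.
#' @return Hermitian 6x6 complex matrix, rad/s.
#' @examples
#' sys <- preset_system("glycine_amine")
#' H <- hamiltonian_at(1e-6, sys, c(10, 60, 120), nu1_n_khz = 35)
#' max(Mod(H - Conj(t(H))))    # Hermitian
#' @export
hamiltonian_at <- function(t_s, system, orientation_deg,
                           nu1_n_khz = 0, phase_n_deg = 0,
                           nu1_c_khz = 0, phase_c_deg = 0,
                           transmitter_n_khz = 0,
                           second_order = TRUE) {
  stopifnot(inherits(system, "spin_system"))
  if (second_order &&
      (!is.finite(system$larmor_14n_mhz) || system$larmor_14n_mhz <= 0)) {
    abort("second-order terms require a finite 14N Larmor frequency (`larmor_14n_mhz`).")
  }
  if (nu1_n_khz < 0 || nu1_c_khz < 0) abort("rf nutation must be >= 0.")
  pre <- .orient_pre(system, orientation_deg)
  cpp_ham_at(t_s, pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
             2 * pi * nu1_n_khz * 1e3, phase_n_deg * pi / 180,
             2 * pi * nu1_c_khz * 1e3, phase_c_deg * pi / 180,
             pre$offN + 2 * pi * transmitter_n_khz * 1e3, pre$offC,
             pre$Jw, second_order)
}
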