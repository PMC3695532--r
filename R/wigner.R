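# Rank-2 Wigner rotations for spatial tensors.
#
# Active ZYZ convention: a rotation by Euler angles (alpha, beta, gamma)
# transports the components of a rank-2 irreducible spherical tensor as
#   A'_m = sum_{m'} A_{m'} exp(-i m' alpha) d2_{m',m}(beta) exp(-i m gamma)
# with d2 the reduced Wigner matrix <m'| exp(-i beta Jy) |m>.
# Component vectors are stored ascending, index 1..5 <-> m = -2..2.

#' Reduced Wigner matrix of rank 2
#'
#' `d^2_{m',m}(beta) = <m'|exp(-i beta Jy)|m>`, evaluated exactly from the
#' spin-2 angular-momentum matrix, returned with ascending row/column order
#' `m = -2 ... 2` (element `[m' + 3, m + 3]`).
#'
#' @param beta_rad Rotation angle about y, radians.
#' @return Real orthogonal 5x5 matrix.
#' @examples
#' wigner_d2(0)                      # identity
#' wigner_d2(pi / 2)[3, 3]           # d2_00(90 deg) = -1/2
#' @export
wigner_d2 <- function(beta_rad) {
  ops <- .ladder_ops(2)            # basis m = +2..-2
  e <- eigen(ops$Iy, symmetric = TRUE)
  d <- Re(e$vectors %*% diag(exp(-1i * beta_rad * e$values)) %*%
            Conj(t(e$vectors)))
  d[5:1, 5:1]                      # reorder to ascending m
}

#' Rotate rank-2 spherical tensor components
#'
#' Applies an active ZYZ rotation to the five components of a rank-2
#' spherical tensor. The Euclidean norm `sum(|A_m|^2)` is preserved.
#'
#' @param components Complex vector of length 5, `m = -2 ... 2` ascending.
#' @param euler_deg Euler angles `c(alpha, beta, gamma)` in degrees.
#' @return Rotated complex vector of length 5.
#' @examples
#' A <- c(0, 0, 1, 0, 0)
#' rotate_rank2(A, c(0, 90, 0))[3]   # axial tensor at 90 deg: -1/2
#' @export
rotate_rank2 <- function(components, euler_deg) {
  stopifnot(length(components) == 5, length(euler_deg) == 3)
  ang <- euler_deg * pi / 180
  m <- -2:2
  d <- wigner_d2(ang[2])
  pre <- components * exp(-1i * m * ang[1])
  out <- as.vector(t(d) %*% pre)          # out_m = sum_m' pre_m' d[m', m]
  out * exp(-1i * m * ang[3])
}

#' MAS Fourier coefficients of the secular spatial component
#'
#' Under magic-angle spinning the lab-frame secular component of a rank-2
#' interaction is a five-term Fourier series,
#' `A_lab(t) = sum_m c_m exp(i m w_r t)`, with
#' `c_m = A_rotor[-m] * d2_{-m,0}(theta)`. At the exact magic angle
#' (`54.7356` deg) the constant term of a traceless tensor vanishes because
#' `d2_00(theta_m) = P2(cos theta_m) = 0`; a rotor-axis mis-set leaves a
#' residual `c_0` proportional to `P2(cos theta)`.
#'
#' @param rotor_components Complex vector of length 5 (`m = -2 ... 2`),
#'   tensor components in the rotor frame.
#' @param mas_khz Spinning rate in kHz (> 0).
#' @param rotor_angle_deg Angle between rotor axis and field, degrees.
#' @return A tibble with columns `m`, `freq_khz` (`= m * mas_khz`) and the
#'   complex coefficient `coeff` (same units as the input components).
#' @export
mas_fourier_coefficients <- function(rotor_components, mas_khz,
                                     rotor_angle_deg = magic_angle_deg()) {
  stopifnot(length(rotor_components) == 5, mas_khz > 0)
  d <- wigner_d2(rotor_angle_deg * pi / 180)
  m <- -2:2
  cm <- vapply(m, function(k) rotor_components[-k + 3] * d[-k + 3, 3],
               complex(1))
  tibble(m = m, freq_khz = m * mas_khz, coeff = cm)
}

#' The magic angle in degrees
#'
#' `acos(1/sqrt(3)) = 54.7356...` degrees, the rotor-axis angle at which
#' `P2(cos theta)` vanishes and rank-2 anisotropies are averaged by MAS.
#'
#' @return Scalar, degrees.
#' @export
magic_angle_deg <- function() acos(1 / sqrt(3)) * 180 / pi
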