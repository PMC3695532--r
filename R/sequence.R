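# The indirect-detection experiment: a long rotor-synchronised CW 14N pulse
# converts initial 13C transverse magnetisation into mixed 13C-14N
# coherences; the selected 14N coherence order (SQ or DQ) evolves during a
# rotor-synchronised t1 split symmetrically around an ideal 13C pi pulse,
# and an identical 14N pulse reconverts it into observable 13C signal.
#
# The pi pulse refocuses 13C isotropic/anisotropic shifts; rotor
# synchronisation of t1 refocuses the first-order quadrupole, so the
# indirect dimension evolves only under the second-order terms and offsets.

#' Define an indirect-detection experiment
#'
#' @param tau_n_ms 14N excitation/reconversion pulse duration in ms; must
#'   correspond to a whole number of rotor periods (see [run_hnc_1d()]).
#' @param nu1_n_khz 14N rf nutation frequency in kHz.
#' @param offset_n_khz 14N transmitter displacement from the reference
#'   carrier, kHz (0 = on the ammonium chloride position).
#' @param selection Coherence-order selection, `"SQ"` (p = +/-1) or `"DQ"`
#'   (p = +/-2).
#' @param delta_t1_periods Indirect-dimension increment in rotor periods
#'   (`dt1 = n tau_r`).
#' @param t1_increments Number of t1 points for 2D acquisition.
#' @param n_steps Integration steps per rotor period.
#' @return An object of class `hnc_experiment`.
#' @examples
#' hnc_experiment(tau_n_ms = 2, nu1_n_khz = 35)
#' @export
hnc_experiment <- function(tau_n_ms = 2, nu1_n_khz = 35, offset_n_khz = 0,
                           selection = c("SQ", "DQ"),
                           delta_t1_periods = 1L, t1_increments = 1L,
                           n_steps = 200L) {
  selection <- match.arg(selection)
  if (tau_n_ms < 0) abort("`tau_n_ms` must be >= 0.")
  if (nu1_n_khz < 0) abort("`nu1_n_khz` must be >= 0.")
  if (delta_t1_periods < 1 || delta_t1_periods != round(delta_t1_periods)) {
    abort("`delta_t1_periods` must be a positive integer (dt1 = n tau_r).")
  }
  if (t1_increments < 1) abort("`t1_increments` must be >= 1.")
  structure(
    list(tau_n_ms = tau_n_ms, nu1_n_khz = nu1_n_khz,
         offset_n_khz = offset_n_khz, selection = selection,
         delta_t1_periods = as.integer(delta_t1_periods),
         t1_increments = as.integer(t1_increments),
         n_steps = as.integer(n_steps)),
    class = "hnc_experiment"
  )
}

#' @export
print.hnc_experiment <- function(x, ...) {
  cat(sprintf(
    "<hnc_experiment> tau_N = %g ms at nu1 = %g kHz, offset %g kHz, %s selection\n",
    x$tau_n_ms, x$nu1_n_khz, x$offset_n_khz, x$selection))
  cat(sprintf("  dt1 = %d rotor period(s), %d t1 increment(s), %d steps/period\n",
              x$delta_t1_periods, x$t1_increments, x$n_steps))
  invisible(x)
}

.sel_order <- function(selection) if (selection == "DQ") 2L else 1L

# pulse length in whole rotor periods; strict = error, else snap (+ warn)
.tau_periods <- function(tau_n_ms, mas_khz, strict = TRUE) {
  n_exact <- tau_n_ms * mas_khz
  n <- round(n_exact)
  if (abs(n_exact - n) > 1e-6) {
    if (strict) {
      abort(sprintf(
        "tau_N = %g ms is not rotor-synchronised at %g kHz MAS (%.3f periods); nearest: %g ms.",
        tau_n_ms, mas_khz, n_exact, n / mas_khz))
    }
    warn(sprintf("snapping tau_N from %g ms to %g ms (%d rotor periods).",
                 tau_n_ms, n / mas_khz, as.integer(n)))
  }
  as.integer(n)
}

# weighted accumulation of the per-orientation kernel over a powder scheme
.hnc_powder_1d <- function(system, experiment, powder, second_order) {
  ang <- as.matrix(powder[, c("alpha", "beta", "gamma")])
  w <- powder$weight
  n_per <- .tau_periods(experiment$tau_n_ms, system$mas_khz, strict = TRUE)
  sel <- .sel_order(experiment$selection)
  tau_r <- 1 / (system$mas_khz * 1e3)
  w1 <- 2 * pi * experiment$nu1_n_khz * 1e3
  acc <- numeric(6)
  sel_amp <- 0
  for (i in seq_len(nrow(ang))) {
    pre <- .orient_pre(system, ang[i, ])
    offN <- pre$offN + 2 * pi * experiment$offset_n_khz * 1e3
    Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                        pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                        w1, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
    U <- .matpow(Up, n_per)
    k <- cpp_sequence_kernel(U, sel)
    acc <- acc + w[i] * k
    a <- k[2:6]
    sel_amp <- sel_amp + w[i] * sqrt(sum(a[abs(-2:2) == sel]^2))
  }
  list(kernel = acc, selected_amplitude = sel_amp)
}

.hnc_result <- function(efficiency, amps, selected_amplitude, system,
                        experiment, powder, second_order,
                        method = "projection") {
  structure(
    list(
      efficiency = efficiency,
      amplitudes = tibble(order = -2:2, amplitude = amps),
      selected_amplitude = selected_amplitude,
      selection = experiment$selection,
      method = method,
      system = system, experiment = experiment,
      powder_n = nrow(powder), second_order = second_order
    ),
    class = "hnc_result"
  )
}

#' Run the 14N-filtered 1D experiment
#'
#' Starting from unit 13C transverse magnetisation (the idealised
#' post-cross-polarisation state of a single 13C-14N pair), applies the
#' excitation pulse, retains the selected 14N coherence orders by
#' projection, applies an ideal 13C pi pulse, reconverts with an identical
#' 14N pulse, and reports the powder-averaged recovered transverse 13C
#' amplitude relative to the start.
#'
#' @param system A [spin_system()].
#' @param experiment An [hnc_experiment()]; `tau_n_ms` must be a whole
#'   number of rotor periods.
#' @param powder A [zcw_scheme()].
#' @param second_order Include second-order quadrupole self and
#'   quadrupole-dipole cross terms (the transfer mechanism).
#' @return An `hnc_result` with elements `efficiency` (in `[0, 1]`),
#'   `amplitudes` (powder-averaged Frobenius amplitude of each 14N
#'   coherence order after the excitation pulse, relative to the initial
#'   norm) and `selected_amplitude` (combined amplitude of the selected
#'   orders). Use [tidy()]/[glance()] to extract tibbles.
#' @examples
#' \donttest{
#' res <- run_hnc_1d(preset_system("glycine_amine"), hnc_experiment(),
#'                   zcw_scheme(144))
#' glance(res)
#' }
#' @export
run_hnc_1d <- function(system, experiment, powder, second_order = TRUE) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "hnc_experiment"))
  out <- .hnc_powder_1d(system, experiment, powder, second_order)
  .hnc_result(out$kernel[1], out$kernel[2:6], out$selected_amplitude,
              system, experiment, powder, second_order)
}

#' @export
print.hnc_result <- function(x, ...) {
  cat(sprintf("<hnc_result> %s-filtered efficiency %.4f (%s, %d orientations)\n",
              x$selection, x$efficiency, x$method, x$powder_n))
  a <- x$amplitudes
  cat("  coherence amplitudes after excitation: ",
      paste(sprintf("p=%+d: %.3f", a$order, a$amplitude), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-order coherence amplitudes of a density operator
#'
#' Frobenius amplitude of each 14N coherence-order component relative to a
#' reference norm (by default the initial unit 13C transverse state,
#' `||Sx||_F = sqrt(3/2)`). For unitary evolution from that state the
#' squared amplitudes sum to 1.
#'
#' @param rho 6x6 complex density (deviation) operator.
#' @param reference_norm Normalising Frobenius norm.
#' @return A tibble with columns `order` (-2:2) and `amplitude` (>= 0).
#' @export
coherence_amplitudes <- function(rho, reference_norm = sqrt(1.5)) {
  comp <- coherence_decompose(rho)
  tibble(
    order = -2:2,
    amplitude = unname(vapply(comp, function(m) sqrt(sum(Mod(m)^2)),
                              numeric(1))) / reference_norm
  )
}

#' Run the 2D indirect-detection experiment
#'
#' For each `t1 = k * dt1` (`dt1 = delta_t1_periods * tau_r`) the selected
#' 14N coherences evolve freely, split symmetrically around the ideal 13C
#' pi pulse; two interleaved data sets with the excitation phase shifted by
#' `90 / p` degrees provide the States quadrature. The direct dimension is
#' the single complex recovered 13C amplitude per t1 point.
#'
#' @inheritParams run_hnc_1d
#' @return An object of class `hnc_2d`: list with `t1_s`, complex vectors
#'   `cos` and `sin` (one amplitude per t1 point, each normalised to the
#'   initial magnetisation), and acquisition metadata. Feed to
#'   [process_2d_states()].
#' @export
run_hnc_2d <- function(system, experiment, powder, second_order = TRUE) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "hnc_experiment"))
  ang <- as.matrix(powder[, c("alpha", "beta", "gamma")])
  wts <- powder$weight
  n_per <- .tau_periods(experiment$tau_n_ms, system$mas_khz, strict = TRUE)
  sel <- .sel_order(experiment$selection)
  n_t1 <- experiment$t1_increments
  nsync <- experiment$delta_t1_periods
  tau_r <- 1 / (system$mas_khz * 1e3)
  w1 <- 2 * pi * experiment$nu1_n_khz * 1e3
  ops <- .op6()
  selmask <- abs(ops$p) == sel
  # excitation phase shift of 90/p deg advances order p by -90 deg
  quadrature <- exp(-1i * ops$p * (pi / 2) / sel)
  tOp <- t(ops$Sx + 1i * ops$Sy)
  half <- max(1L, experiment$n_steps %/% 2L)
  jmax <- 2L * (n_t1 - 1L) * nsync
  s_cos <- complex(n_t1)
  s_sin <- complex(n_t1)
  for (i in seq_len(nrow(ang))) {
    pre <- .orient_pre(system, ang[i, ])
    offN <- pre$offN + 2 * pi * experiment$offset_n_khz * 1e3
    Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                        pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                        w1, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
    U <- .matpow(Up, n_per)
    rho1 <- U %*% ops$Sx %*% Conj(t(U))
    rho_f <- rho1 * selmask
    rho_fs <- rho_f * quadrature
    # free half-period propagators (no rf): G_j = U(0 -> j tau_r / 2)
    F1 <- cpp_propagate(0, tau_r / 2, half,
                        pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                        0, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
    F2 <- cpp_propagate(tau_r / 2, tau_r / 2, half,
                        pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                        0, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
    G <- vector("list", jmax + 1L)
    G[[1]] <- diag(6) + 0i
    if (jmax > 0) {
      for (j in seq_len(jmax)) {
        G[[j + 1]] <- (if ((j - 1L) %% 2L == 0L) F1 else F2) %*% G[[j]]
      }
    }
    for (k in seq_len(n_t1) - 1L) {
      j <- k * nsync
      Ua <- G[[j + 1L]]
      Ub <- G[[2L * j + 1L]] %*% Conj(t(Ua))
      M <- U %*% Ub %*% ops$Upi %*% Ua
      Mh <- Conj(t(M))
      s_cos[k + 1L] <- s_cos[k + 1L] +
        wts[i] * sum(M %*% rho_f %*% Mh * tOp) / 1.5
      s_sin[k + 1L] <- s_sin[k + 1L] +
        wts[i] * sum(M %*% rho_fs %*% Mh * tOp) / 1.5
    }
  }
  structure(
    list(t1_s = (seq_len(n_t1) - 1) * nsync * tau_r,
         cos = s_cos, sin = s_sin,
         delta_t1_s = nsync * tau_r,
         system = system, experiment = experiment,
         powder_n = nrow(powder), second_order = second_order),
    class = "hnc_2d"
  )
}

#' @export
print.hnc_2d <- function(x, ...) {
  cat(sprintf(
    "<hnc_2d> %d t1 point(s), dt1 = %.1f us (%d rotor periods), %s selection\n",
    length(x$t1_s), x$delta_t1_s * 1e6, x$experiment$delta_t1_periods,
    x$experiment$selection))
  cat(sprintf("  t1 = 0 efficiency: %.4f\n", Re(x$cos[1])))
  invisible(x)
}

#' Coherence selection by explicit phase cycling
#'
#' Repeats the experiment with the excitation-pulse phase stepped through
#' `n_phases` values and sums the transients with receiver weights,
#' reproducing the projection filter of [run_hnc_1d()] when the cycle is
#' adequate (4 steps for SQ, 8 for DQ with cosine receiver weights).
#' Because every non-rf term of the Hamiltonian commutes with the 14N Iz,
#' a pulse phase shift acts exactly as a z-rotation of the phase-0
#' propagator, so the cycle reuses one propagator per crystallite.
#'
#' @inheritParams run_hnc_1d
#' @param n_phases Number of phase steps (default `4 * p` for order-p
#'   selection); must be at least `2 p + 1`.
#' @param receiver Optional explicit receiver weights (length `n_phases`);
#'   default `2 cos(p phi_k) / n_phases`, which retains orders +/-p.
#' @param p_select Coherence order to select; defaults to the experiment's
#'   `selection` (`0` gives the unfiltered echo).
#' @return An `hnc_result` (method `"phase_cycle"`).
#' @export
phase_cycle_run <- function(system, experiment, powder, n_phases = NULL,
                            receiver = NULL, p_select = NULL,
                            second_order = TRUE) {
  stopifnot(inherits(system, "spin_system"),
            inherits(experiment, "hnc_experiment"))
  p_sel <- p_select %||% .sel_order(experiment$selection)
  n_phases <- n_phases %||% max(1L, 4L * p_sel)
  if (n_phases < 2 * p_sel + 1) {
    abort(sprintf("%d phases cannot separate coherence order %d (need >= %d).",
                  n_phases, p_sel, 2 * p_sel + 1))
  }
  phi <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  wrec <- receiver %||% (2 * cos(p_sel * phi) / n_phases)
  if (p_sel == 0 && is.null(receiver)) wrec <- rep(1 / n_phases, n_phases)
  if (length(wrec) != n_phases) abort("`receiver` must have length `n_phases`.")
  ang <- as.matrix(powder[, c("alpha", "beta", "gamma")])
  wts <- powder$weight
  n_per <- .tau_periods(experiment$tau_n_ms, system$mas_khz, strict = TRUE)
  tau_r <- 1 / (system$mas_khz * 1e3)
  w1 <- 2 * pi * experiment$nu1_n_khz * 1e3
  ops <- .op6()
  eff <- 0
  for (i in seq_len(nrow(ang))) {
    pre <- .orient_pre(system, ang[i, ])
    offN <- pre$offN + 2 * pi * experiment$offset_n_khz * 1e3
    Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                        pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                        w1, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
    U <- .matpow(Up, n_per)
    rho1 <- U %*% ops$Sx %*% Conj(t(U))
    rho_acc <- matrix(0i, 6, 6)
    for (k in seq_len(n_phases)) {
      rho_acc <- rho_acc + wrec[k] * rho1 * exp(-1i * ops$p * phi[k])
    }
    rho3 <- U %*% (ops$Upi %*% rho_acc %*% Conj(t(ops$Upi))) %*% Conj(t(U))
    eff <- eff + wts[i] * Re(sum(rho3 * ops$Sx)) / 1.5
  }
  res <- .hnc_result(eff, rep(NA_real_, 5), NA_real_, system, experiment,
                     powder, second_order, method = "phase_cycle")
  res$n_phases <- n_phases
  res
}
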