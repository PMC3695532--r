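# Parameter scans: transfer efficiency vs pulse length, rf amplitude and
# offset, plus the 2D pulse-length x rf-amplitude surface. All scans are
# deterministic; pulse lengths are snapped to whole rotor periods (with a
# warning) because the sequence requires rotor synchronisation. Scanning
# pulse length is cheap: per crystallite the single-period propagator is
# computed once and every tau value is one of its matrix powers.

.scan_result <- function(df, scanned, system, experiment, powder,
                         second_order) {
  mx <- max(df$efficiency)
  df$efficiency_norm <- if (mx > 0) df$efficiency / mx else df$efficiency * 0
  # exact 1.0 at the maximum, per construction
  df$efficiency_norm[which.max(df$efficiency)] <- 1.0
  out <- as_tibble(df)
  class(out) <- c(if (scanned == "grid") "hnc_grid" else "hnc_scan",
                  class(out))
  attr(out, "scanned") <- scanned
  attr(out, "argmax") <- df[which.max(df$efficiency), , drop = FALSE]
  attr(out, "system") <- system
  attr(out, "experiment") <- experiment
  attr(out, "powder_n") <- nrow(powder)
  attr(out, "second_order") <- second_order
  out
}

# shared crystallite loop: f(pre, offN) -> numeric vector of efficiencies
.scan_powder_loop <- function(system, experiment, powder, second_order,
                              n_out, per_orientation) {
  ang <- as.matrix(powder[, c("alpha", "beta", "gamma")])
  wts <- powder$weight
  acc <- numeric(n_out)
  for (i in seq_len(nrow(ang))) {
    pre <- .orient_pre(system, ang[i, ])
    offN <- pre$offN + 2 * pi * experiment$offset_n_khz * 1e3
    acc <- acc + wts[i] * per_orientation(pre, offN)
  }
  acc
}

# efficiencies at several whole-period pulse lengths from one period
# propagator (ascending n): incremental powers
.eff_at_periods <- function(Up, n_periods, sel) {
  ord <- order(n_periods)
  ns <- n_periods[ord]
  out <- numeric(length(ns))
  U <- diag(6) + 0i
  last <- 0L
  for (k in seq_along(ns)) {
    if (ns[k] > last) {
      U <- .matpow(Up, ns[k] - last) %*% U
      last <- ns[k]
    }
    out[k] <- cpp_sequence_kernel(U, sel)[1]
  }
  out[order(ord)] <- out
  out
}

#' Efficiency vs 14N pulse length
#'
#' One [run_hnc_1d()]-equivalent per pulse length, sharing the cached
#' rotor-period propagator across the grid. Pulse lengths are snapped to
#' the nearest whole number of rotor periods.
#'
#' @inheritParams run_hnc_1d
#' @param tau_ms Numeric vector of pulse lengths in ms (non-empty).
#' @return A tibble of class `hnc_scan` with columns `tau_ms` (snapped),
#'   `n_periods`, `efficiency` and `efficiency_norm` (maximum scaled to
#'   exactly 1), with the argmax row in `attr(, "argmax")`.
#' @export
scan_pulse_length <- function(system, experiment, tau_ms, powder,
                              second_order = TRUE) {
  if (length(tau_ms) == 0) abort("empty `tau_ms` grid.")
  n_per <- vapply(tau_ms, .tau_periods, integer(1),
                  mas_khz = system$mas_khz, strict = FALSE)
  sel <- .sel_order(experiment$selection)
  tau_r <- 1 / (system$mas_khz * 1e3)
  w1 <- 2 * pi * experiment$nu1_n_khz * 1e3
  effs <- .scan_powder_loop(
    system, experiment, powder, second_order, length(n_per),
    function(pre, offN) {
      Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                          pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                          w1, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
      .eff_at_periods(Up, n_per, sel)
    })
  .scan_result(
    data.frame(tau_ms = n_per / system$mas_khz, n_periods = n_per,
               efficiency = effs),
    "tau_ms", system, experiment, powder, second_order)
}

#' Efficiency vs 14N rf amplitude
#'
#' @inheritParams scan_pulse_length
#' @param nu1_khz Numeric vector of nutation frequencies in kHz (>= 0).
#' @return A tibble of class `hnc_scan` with columns `nu1_khz`,
#'   `efficiency`, `efficiency_norm`.
#' @export
scan_rf <- function(system, experiment, nu1_khz, powder,
                    second_order = TRUE) {
  if (length(nu1_khz) == 0) abort("empty `nu1_khz` grid.")
  if (any(nu1_khz < 0)) abort("`nu1_khz` must be >= 0.")
  n_per <- .tau_periods(experiment$tau_n_ms, system$mas_khz, strict = FALSE)
  sel <- .sel_order(experiment$selection)
  tau_r <- 1 / (system$mas_khz * 1e3)
  effs <- .scan_powder_loop(
    system, experiment, powder, second_order, length(nu1_khz),
    function(pre, offN) {
      vapply(nu1_khz, function(v1) {
        Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                            pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                            2 * pi * v1 * 1e3, 0, 0, 0,
                            offN, pre$offC, pre$Jw, second_order)
        cpp_sequence_kernel(.matpow(Up, n_per), sel)[1]
      }, numeric(1))
    })
  .scan_result(data.frame(nu1_khz = nu1_khz, efficiency = effs),
               "nu1_khz", system, experiment, powder, second_order)
}

#' Efficiency vs 14N transmitter offset
#'
#' @inheritParams scan_pulse_length
#' @param offset_khz Numeric vector of transmitter offsets in kHz, relative
#'   to the reference carrier.
#' @return A tibble of class `hnc_scan` with columns `offset_khz`,
#'   `efficiency`, `efficiency_norm`; `attr(, "halfmax_band_khz")` gives the
#'   range of scanned offsets with normalised efficiency above 0.5.
#' @export
scan_offset <- function(system, experiment, offset_khz, powder,
                        second_order = TRUE) {
  if (length(offset_khz) == 0) abort("empty `offset_khz` grid.")
  n_per <- .tau_periods(experiment$tau_n_ms, system$mas_khz, strict = FALSE)
  sel <- .sel_order(experiment$selection)
  tau_r <- 1 / (system$mas_khz * 1e3)
  w1 <- 2 * pi * experiment$nu1_n_khz * 1e3
  effs <- .scan_powder_loop(
    system, experiment, powder, second_order, length(offset_khz),
    function(pre, offN_base) {
      vapply(offset_khz, function(off) {
        offN <- pre$offN + 2 * pi * (experiment$offset_n_khz + off) * 1e3
        Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                            pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                            w1, 0, 0, 0, offN, pre$offC, pre$Jw, second_order)
        cpp_sequence_kernel(.matpow(Up, n_per), sel)[1]
      }, numeric(1))
    })
  out <- .scan_result(data.frame(offset_khz = offset_khz, efficiency = effs),
                      "offset_khz", system, experiment, powder, second_order)
  band <- out$offset_khz[out$efficiency_norm > 0.5]
  attr(out, "halfmax_band_khz") <- if (length(band)) range(band) else c(NA, NA)
  out
}

#' 2D efficiency surface: pulse length x rf amplitude
#'
#' @inheritParams scan_pulse_length
#' @param nu1_khz Numeric vector of nutation frequencies in kHz.
#' @return A tibble of class `hnc_grid` with one row per grid cell
#'   (`tau_ms`, `nu1_khz`, `efficiency`, `efficiency_norm`); the argmax cell
#'   is in `attr(, "argmax")`.
#' @export
grid_scan <- function(system, experiment, tau_ms, nu1_khz, powder,
                      second_order = TRUE) {
  if (length(tau_ms) == 0 || length(nu1_khz) == 0) abort("empty grid.")
  n_per <- vapply(tau_ms, .tau_periods, integer(1),
                  mas_khz = system$mas_khz, strict = FALSE)
  sel <- .sel_order(experiment$selection)
  tau_r <- 1 / (system$mas_khz * 1e3)
  effs <- .scan_powder_loop(
    system, experiment, powder, second_order, length(n_per) * length(nu1_khz),
    function(pre, offN) {
      as.vector(vapply(nu1_khz, function(v1) {
        Up <- cpp_propagate(0, tau_r, experiment$n_steps,
                            pre$AQrot, pre$ADrot, pre$d2ra, pre$wr, pre$w0N,
                            2 * pi * v1 * 1e3, 0, 0, 0,
                            offN, pre$offC, pre$Jw, second_order)
        .eff_at_periods(Up, n_per, sel)
      }, numeric(length(n_per))))
    })
  grid <- expand.grid(tau_ms = n_per / system$mas_khz, nu1_khz = nu1_khz,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_periods <- rep(n_per, times = length(nu1_khz))
  grid$efficiency <- effs
  .scan_result(grid, "grid", system, experiment, powder, second_order)
}

#' Optimised 14N transmitter offset
#'
#' Emulates the experimental set-up protocol: the transmitter starts on the
#' reference carrier and is then optimised by a coarse offset scan, within
#' the band around the isotropic shift where the experiment retains most of
#' its efficiency. Needed because the second-order quadrupolar interaction
#' shifts the 14N resonance away from the carrier (about +60 ppm for the
#' amine, +390 ppm for the amide parameter set).
#'
#' @inheritParams scan_pulse_length
#' @param candidates_khz Candidate transmitter offsets (kHz); default a
#'   +/- 10 kHz band in 2 kHz steps.
#' @return The candidate offset (kHz) with maximal efficiency.
#' @export
optimal_offset <- function(system, experiment, powder,
                           candidates_khz = seq(-10, 10, 2),
                           second_order = TRUE) {
  sc <- scan_offset(system, experiment, candidates_khz, powder,
                    second_order = second_order)
  attr(sc, "argmax")$offset_khz + experiment$offset_n_khz
}
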