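# Spectral processing: exponential apodisation, zero filling, Fourier
# transform, hypercomplex States recombination, ppm referencing and slice
# extraction.
#
# Conventions: line broadening multiplies the fid by exp(-pi * lb * t), so a
# long-lived signal acquires a Lorentzian of FWHM = lb Hz. The transform is
# arranged so that a modulation exp(+i 2 pi nu t) appears at +nu on the
# frequency axis. 14N ppm values are referenced to solid ammonium chloride
# (35.9 ppm) assumed at the carrier position.

.ft_shift <- function(x) {
  n <- length(x)
  x[c((n %/% 2 + 1):n, 1:(n %/% 2))]
}

.freq_axis_khz <- function(n, dwell_s) {
  ((seq_len(n) - 1) - n %/% 2) / (n * dwell_s) / 1e3
}

.ft1d <- function(fid, dwell_s, lb_hz, zerofill) {
  n0 <- length(fid)
  t <- (seq_len(n0) - 1) * dwell_s
  x <- fid * exp(-pi * lb_hz * t)
  x[1] <- x[1] / 2            # first-point halving: flat baseline
  x <- c(x, complex(zerofill - n0))
  .ft_shift(fft(x)) * dwell_s * 2
  # forward fft puts a modulation exp(+2pi i nu t) at +nu; the factor
  # dwell*2 makes a unit-amplitude fid integrate to ~1 (continuous-FT units)
}

#' Convert a frequency offset to ppm
#'
#' `ppm = reference_ppm + 1000 * freq_khz / larmor_mhz`. For the 14N
#' channel the reference is crystalline ammonium chloride at 35.9 ppm,
#' assumed to sit at the carrier.
#'
#' @param freq_khz Frequency offset(s) from the carrier, kHz.
#' @param channel `"N14"` or `"C13"`.
#' @param larmor_mhz Larmor frequency of the channel in MHz (defaults:
#'   43.5 for 14N, 150 for 13C).
#' @param reference_ppm Chemical shift of the carrier position (defaults:
#'   35.9 for 14N, 0 for 13C).
#' @return Numeric ppm values.
#' @examples
#' to_ppm(0)                      # 35.9, the ammonium chloride reference
#' to_ppm(0.0435)                 # +1 ppm at 43.5 MHz
#' @export
to_ppm <- function(freq_khz, channel = c("N14", "C13"), larmor_mhz = NULL,
                   reference_ppm = NULL) {
  channel <- match.arg(channel)
  larmor_mhz <- larmor_mhz %||% switch(channel, N14 = 43.5, C13 = 150)
  reference_ppm <- reference_ppm %||% switch(channel, N14 = 35.9, C13 = 0)
  reference_ppm + 1000 * freq_khz / larmor_mhz
}

#' Process a 1D fid
#'
#' Exponential apodisation, zero filling and Fourier transform with the
#' frequency axis centred on the carrier.
#'
#' @param fid Complex vector (non-empty).
#' @param dwell_s Dwell time in seconds.
#' @param lb_hz Lorentzian line broadening in Hz (FWHM of the applied
#'   envelope).
#' @param zerofill Transform length (>= `length(fid)`); default 1024.
#' @param channel,larmor_mhz,reference_ppm Passed to [to_ppm()] for the
#'   ppm axis.
#' @return A tibble of class `nmr_spectrum` with columns `freq_khz`, `ppm`
#'   and `intensity` (real part) plus `intensity_im`; processing metadata in
#'   attributes.
#' @export
process_1d <- function(fid, dwell_s, lb_hz = 0, zerofill = 1024,
                       channel = c("N14", "C13"), larmor_mhz = NULL,
                       reference_ppm = NULL) {
  if (length(fid) == 0) abort("`fid` is empty.")
  if (zerofill < length(fid)) {
    abort("`zerofill` must be at least the fid length.")
  }
  channel <- match.arg(channel)
  spec <- .ft1d(as.complex(fid), dwell_s, lb_hz, zerofill)
  f <- .freq_axis_khz(zerofill, dwell_s)
  out <- tibble(
    freq_khz = f,
    ppm = to_ppm(f, channel, larmor_mhz, reference_ppm),
    intensity = Re(spec),
    intensity_im = Im(spec)
  )
  class(out) <- c("nmr_spectrum", class(out))
  attr(out, "channel") <- channel
  attr(out, "lb_hz") <- lb_hz
  attr(out, "zerofill") <- as.integer(zerofill)
  attr(out, "dwell_s") <- dwell_s
  out
}

#' Hypercomplex (States) processing of a 2D acquisition
#'
#' Recombines cosine- and sine-modulated data sets into a sign-discriminated
#' pure-phase indirect dimension. Accepts either the [run_hnc_2d()] result
#' (whose direct dimension is a single complex point per t1 value) or a pair
#' of complex matrices with one row per t1 point.
#'
#' @param cos_data,sin_data Complex matrices (t1 x t2) or vectors (one
#'   direct point per t1). When `cos_data` is an `hnc_2d` object both data
#'   sets and `dwell1_s` are taken from it.
#' @param dwell1_s Indirect dwell time (s); the indirect spectral width is
#'   `1 / dwell1_s`.
#' @param dwell2_s Direct dwell time (s); required when the tables have
#'   more than one column.
#' @param lb1_hz,lb2_hz Line broadening per dimension, Hz.
#' @param zerofill1,zerofill2 Transform lengths; default 1024 points in
#'   each transformed dimension.
#' @param channel1,larmor1_mhz,reference1_ppm Referencing of the indirect
#'   axis (defaults: 14N at the ammonium chloride carrier).
#' @param carrier1_khz Transmitter displacement from the reference carrier
#'   (kHz); the ppm axis is corrected for it. Taken from the `hnc_2d`
#'   experiment when available.
#' @return A tibble of class `nmr_spectrum2d` with columns `f1_khz`,
#'   `f1_ppm`, `f2_khz` (0 for a single-point direct dimension) and
#'   `intensity`.
#' @export
process_2d_states <- function(cos_data, sin_data = NULL, dwell1_s = NULL,
                              dwell2_s = NULL, lb1_hz = 0, lb2_hz = 0,
                              zerofill1 = 1024, zerofill2 = 1024,
                              channel1 = "N14", larmor1_mhz = NULL,
                              reference1_ppm = NULL, carrier1_khz = 0) {
  if (inherits(cos_data, "hnc_2d")) {
    sin_data <- cos_data$sin
    dwell1_s <- cos_data$delta_t1_s
    larmor1_mhz <- larmor1_mhz %||% cos_data$system$larmor_14n_mhz
    carrier1_khz <- cos_data$experiment$offset_n_khz
    cos_data <- cos_data$cos
  }
  if (is.null(sin_data) || is.null(dwell1_s)) {
    abort("`sin_data` and `dwell1_s` are required.")
  }
  cm <- as.matrix(cos_data)
  sm <- as.matrix(sin_data)
  if (!all(dim(cm) == dim(sm))) abort("cos/sin tables differ in shape.")
  if (ncol(cm) > 1) {
    if (is.null(dwell2_s)) abort("`dwell2_s` required for a sampled direct dimension.")
    ftrow <- function(m) t(apply(m, 1, .ft1d, dwell_s = dwell2_s,
                                 lb_hz = lb2_hz, zerofill = zerofill2))
    ac <- Re(ftrow(cm))   # absorption part after the direct transform
    as <- Re(ftrow(sm))
    f2 <- .freq_axis_khz(zerofill2, dwell2_s)
  } else {
    ac <- matrix(Re(cm), ncol = 1)
    as <- matrix(Re(sm), ncol = 1)
    f2 <- 0
  }
  h <- ac + 1i * as          # States interferogram along t1
  spec <- apply(h, 2, .ft1d, dwell_s = dwell1_s, lb_hz = lb1_hz,
                zerofill = zerofill1)
  spec <- matrix(spec, nrow = zerofill1)
  f1 <- .freq_axis_khz(zerofill1, dwell1_s)
  out <- tibble(
    f1_khz = rep(f1, times = length(f2)),
    f1_ppm = to_ppm(rep(f1, times = length(f2)) + carrier1_khz, channel1,
                    larmor1_mhz, reference1_ppm),
    f2_khz = rep(f2, each = length(f1)),
    intensity = Re(as.vector(spec))
  )
  class(out) <- c("nmr_spectrum2d", class(out))
  attr(out, "sw1_khz") <- 1 / dwell1_s / 1e3
  attr(out, "lb1_hz") <- lb1_hz
  attr(out, "zerofill1") <- as.integer(zerofill1)
  out
}

#' Extract an indirect-dimension slice from a 2D spectrum
#'
#' Nearest-column 1D trace through the direct dimension, normalised to unit
#' maximum.
#'
#' @param spectrum2d An `nmr_spectrum2d` from [process_2d_states()].
#' @param direct_khz Position along the direct axis, kHz.
#' @return A tibble with `f1_khz`, `f1_ppm` and `intensity` (max 1).
#' @export
extract_slice <- function(spectrum2d, direct_khz = 0) {
  f2 <- sort(unique(spectrum2d$f2_khz))
  halfstep <- if (length(f2) > 1) stats::median(diff(f2)) / 2 else Inf
  if (direct_khz < min(f2) - halfstep || direct_khz > max(f2) + halfstep) {
    abort("`direct_khz` is outside the direct axis.")
  }
  pick <- f2[which.min(abs(f2 - direct_khz))]
  sl <- spectrum2d[spectrum2d$f2_khz == pick,
                   c("f1_khz", "f1_ppm", "intensity")]
  mx <- max(abs(sl$intensity))
  if (mx > 0) sl$intensity <- sl$intensity / mx
  as_tibble(sl)
}
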