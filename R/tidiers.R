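# broom-style accessors and ggplot2 autoplot methods for result objects.

#' Tidy an indirect-detection result
#'
#' @param x An `hnc_result` from [run_hnc_1d()] or [phase_cycle_run()].
#' @param ... Unused.
#' @return A tibble with one row per 14N coherence order (`order`,
#'   `amplitude`).
#' @method tidy hnc_result
#' @export
tidy.hnc_result <- function(x, ...) x$amplitudes

#' @rdname tidy.hnc_result
#' @return `glance()`: a one-row tibble summarising the run.
#' @method glance hnc_result
#' @export
glance.hnc_result <- function(x, ...) {
  tibble(
    efficiency = x$efficiency,
    selected_amplitude = x$selected_amplitude,
    selection = x$selection,
    method = x$method,
    tau_n_ms = x$experiment$tau_n_ms,
    nu1_n_khz = x$experiment$nu1_n_khz,
    mas_khz = x$system$mas_khz,
    powder_n = x$powder_n,
    second_order = x$second_order
  )
}

#' Tidy a parameter scan
#'
#' @param x An `hnc_scan` or `hnc_grid`.
#' @param ... Unused.
#' @return The scan as a plain tibble / a one-row summary with the argmax.
#' @method tidy hnc_scan
#' @export
tidy.hnc_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("hnc_scan", "hnc_grid"))
  for (a in c("scanned", "argmax", "system", "experiment", "powder_n",
              "second_order", "halfmax_band_khz")) attr(out, a) <- NULL
  out
}

#' @rdname tidy.hnc_scan
#' @method tidy hnc_grid
#' @export
tidy.hnc_grid <- tidy.hnc_scan

#' @rdname tidy.hnc_scan
#' @method glance hnc_scan
#' @export
glance.hnc_scan <- function(x, ...) {
  am <- attr(x, "argmax")
  out <- as_tibble(am)
  names(out) <- paste0("argmax_", names(out))
  out$n_points <- nrow(x)
  out$powder_n <- attr(x, "powder_n")
  out$scanned <- attr(x, "scanned")
  out
}

#' @rdname tidy.hnc_scan
#' @method glance hnc_grid
#' @export
glance.hnc_grid <- glance.hnc_scan

#' Plot a 1D parameter scan
#'
#' @param object An `hnc_scan`.
#' @param ... Unused.
#' @return A ggplot: normalised efficiency against the scanned parameter.
#' @method autoplot hnc_scan
#' @export
autoplot.hnc_scan <- function(object, ...) {
  xvar <- attr(object, "scanned")
  lab <- c(tau_ms = "14N pulse length / ms",
           nu1_khz = "14N rf amplitude / kHz",
           offset_khz = "14N offset / kHz")[xvar]
  ggplot2::ggplot(tidy.hnc_scan(object),
                  ggplot2::aes(x = .data[[xvar]], y = .data$efficiency_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab, y = "normalised efficiency") +
    ggplot2::theme_minimal()
}

#' Plot a pulse-length x rf-amplitude efficiency surface
#'
#' @param object An `hnc_grid` from [grid_scan()].
#' @param ... Unused.
#' @return A ggplot raster/contour of the normalised efficiency.
#' @method autoplot hnc_grid
#' @export
autoplot.hnc_grid <- function(object, ...) {
  ggplot2::ggplot(tidy.hnc_scan(object),
                  ggplot2::aes(x = .data$tau_ms, y = .data$nu1_khz,
                               fill = .data$efficiency_norm)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$efficiency_norm),
                          colour = "white", bins = 8, linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "efficiency") +
    ggplot2::labs(x = "14N pulse length / ms", y = "14N rf amplitude / kHz") +
    ggplot2::theme_minimal()
}

#' Plot a 1D spectrum
#'
#' @param object An `nmr_spectrum` from [process_1d()].
#' @param ... Unused.
#' @return A ggplot with a reversed ppm axis (NMR convention).
#' @method autoplot nmr_spectrum
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "ppm", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
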