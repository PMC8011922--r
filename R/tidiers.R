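# broom-style tidiers and ggplot2 autoplot methods for every result type

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a generalized-mode set
#'
#' @param x a `vw_modes`.
#' @param ... unused.
#' @return Tibble with one row per mode: `mode`, `eigenvalue` (velocity
#'   variance, amu A^2/fs^2), `frequency_cm1`, `degeneracy_block`.
#' @export
tidy.vw_modes <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 frequency_cm1 = x$frequencies,
                 degeneracy_block = x$degeneracy)
}

#' @rdname tidy.vw_modes
#' @return For `glance`: one-row tibble with `n_modes`, `trace` (sum of
#'   eigenvalues), `n_zero_modes`, `n_assigned`.
#' @export
glance.vw_modes <- function(x, ...) {
  lmax <- max(x$eigenvalues, .Machine$double.xmin)
  tibble::tibble(n_modes = length(x$eigenvalues),
                 trace = sum(x$eigenvalues),
                 n_zero_modes = sum(x$eigenvalues <= 1e-12 * lmax),
                 n_assigned = sum(!is.na(x$frequencies)))
}

#' Tidy a wavelet spectrogram into long form
#'
#' @param x a `vw_spectrogram`.
#' @param ... unused.
#' @return Tibble: `time_fs`, `wavenumber_cm1`, `power`, `in_coi`.
#' @export
tidy.vw_spectrogram <- function(x, ...) {
  mask <- coi_mask(x)
  tibble::tibble(
    time_fs = rep(x$times, each = length(x$wavenumbers)),
    wavenumber_cm1 = rep(x$wavenumbers, times = length(x$times)),
    power = as.vector(x$power),
    in_coi = as.vector(mask))
}

#' @rdname tidy.vw_spectrogram
#' @export
glance.vw_spectrogram <- function(x, ...) {
  idx <- arrayInd(which.max(x$power), dim(x$power))
  tibble::tibble(n_scales = length(x$wavenumbers), n_times = length(x$times),
                 peak_wavenumber_cm1 = x$wavenumbers[idx[1]],
                 peak_time_fs = x$times[idx[2]],
                 total_power = sum(x$power))
}

#' Tidy a power spectrum
#'
#' @param x a `vw_spectrum`.
#' @param ... unused.
#' @return Tibble: `wavenumber_cm1`, `power`.
#' @export
tidy.vw_spectrum <- function(x, ...) {
  tibble::tibble(wavenumber_cm1 = x$wavenumbers, power = x$power)
}

#' @rdname tidy.vw_spectrum
#' @export
glance.vw_spectrum <- function(x, ...) {
  tibble::tibble(n_bins = length(x$power),
                 resolution_cm1 = x$resolution,
                 peak_wavenumber_cm1 = x$wavenumbers[which.max(x$power)])
}

#' Tidy a mode-velocity series into long form
#'
#' @param x a `vw_modevel`.
#' @param ... unused.
#' @return Tibble: `time_fs`, `mode`, `velocity`.
#' @export
tidy.vw_modevel <- function(x, ...) {
  tibble::tibble(time_fs = rep(x$times, times = ncol(x$values)),
                 mode = rep(x$mode_ids, each = nrow(x$values)),
                 velocity = as.vector(x$values))
}

#' Heat-map plot of a wavelet spectrogram
#'
#' Frequency-vs-time power map with the cone of influence drawn as a line;
#' cells below it are edge-contaminated.
#'
#' @param object a `vw_spectrogram`.
#' @param normalize scale power to the map maximum?
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vw_spectrogram <- function(object, normalize = TRUE, ...) {
  if (normalize) object <- normalize_power(object)
  df <- tidy(object)
  coi_df <- data.frame(time_fs = object$times,
                       coi = pmin(object$coi, max(object$wavenumbers)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_fs, y = .data$wavenumber_cm1,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::geom_line(data = coi_df,
                       ggplot2::aes(x = .data$time_fs, y = .data$coi),
                       inherit.aes = FALSE, linetype = "dashed",
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "|W|² (a.u.)") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (fs)", y = "wavenumber (cm⁻¹)")
}

#' Line plot of a power spectrum
#'
#' @param object a `vw_spectrum`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vw_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavenumber_cm1, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "power (a.u.)")
}

#' Stem plot of mode eigenvalues vs assigned frequencies
#'
#' @param object a `vw_modes`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vw_modes <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$frequency_cm1), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_cm1, y = .data$eigenvalue)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency_cm1, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "assigned frequency (cm⁻¹)",
                  y = "mode velocity variance (amu Å²/fs²)")
}

#' @importFrom rlang .data
NULL
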