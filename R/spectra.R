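# velocity autocorrelation functions and their Fourier power spectra

#' Unbiased velocity autocorrelation function
#'
#' \eqn{C(\tau) = \frac{1}{T-\tau} \sum_{t} x(t)\, x(t+\tau)} for
#' \eqn{\tau = 0 \ldots} `max_lag` (unbiased normalization). Computed with an
#' FFT (Wiener-Khinchin) and renormalized per lag, so long series are cheap.
#'
#' @param signal numeric time series.
#' @param max_lag largest lag in frames; must be `< length(signal)`.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorrelation <- function(signal, max_lag) {
  signal <- as.numeric(signal)
  n <- length(signal)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) {
    stop(sprintf("max_lag (%d) must be smaller than the signal length (%d)",
                 max_lag, n))
  }
  if (max_lag < 0L) stop("max_lag must be >= 0")
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(signal, rep(0, npad - n)))
  raw <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / npad
  raw[seq_len(max_lag + 1L)] / (n - 0:max_lag)
}

.supported_tapers <- c("hann", "hamming", "none")

taper_weights <- function(name, n_lags) {
  tau <- 0:(n_lags - 1L)
  switch(name,
    hann    = 0.5 * (1 + cos(pi * tau / (n_lags - 1L))),
    hamming = 0.54 + 0.46 * cos(pi * tau / (n_lags - 1L)),
    none    = rep(1, n_lags),
    stop(sprintf("unknown taper '%s'; supported tapers: %s",
                 name, paste(.supported_tapers, collapse = ", ")))
  )
}

#' Power spectrum of an autocorrelation function
#'
#' Discrete cosine transform of the tapered, zero-padded one-sided
#' autocorrelation: \eqn{S(\nu_k) = w_0 C_0 + 2\sum_{\tau\ge 1} w_\tau C_\tau
#' \cos(2\pi k \tau / N)}. The abscissa is converted to cm^-1 and runs from 0
#' to the Nyquist wavenumber \eqn{1/(2\,dt)}. Small negative excursions from
#' tapering are clamped to zero (power is non-negative by definition).
#'
#' @param C one-sided autocorrelation series (lag 0 first).
#' @param dt timestep in fs.
#' @param window taper name: one of `"hann"` (default), `"hamming"`, `"none"`.
#' @param pad_factor zero-padding factor (default 4) for peak interpolation.
#' @return Object of class `vw_spectrum`: `wavenumbers` (cm^-1, ascending,
#'   uniform), `power` (>= 0, arbitrary units), `resolution` (cm^-1 per bin),
#'   `mode_id`.
#' @export
power_spectrum <- function(C, dt, window = "hann", pad_factor = 4L,
                           mode_id = NA_integer_) {
  C <- as.numeric(C)
  n <- length(C)
  if (n < 8L) stop(sprintf("autocorrelation too short (%d < 8 lags)", n))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  w <- taper_weights(window, n)
  y <- C * w
  npad <- 2^ceiling(log2(n * max(1L, as.integer(pad_factor))))
  yp <- c(y, rep(0, npad - n))
  ft <- stats::fft(yp)
  nyq <- npad %/% 2L
  # one-sided cosine transform: 2*Re(FFT) - C0 term counted once
  S <- 2 * Re(ft[seq_len(nyq + 1L)]) - y[1]
  S[S < 0] <- 0
  nu_fs <- (0:nyq) / (npad * dt)
  structure(list(wavenumbers = fs_to_cm1(nu_fs), power = S,
                 resolution = fs_to_cm1(1 / (npad * dt)), mode_id = mode_id),
            class = "vw_spectrum")
}

#' @export
print.vw_spectrum <- function(x, ...) {
  cat(sprintf("<vw_spectrum> %d bins, 0 - %.0f cm^-1, resolution %.3g cm^-1; peak at %.1f cm^-1\n",
              length(x$power), max(x$wavenumbers), x$resolution,
              x$wavenumbers[which.max(x$power)]))
  invisible(x)
}

#' Equilibrium spectrum of a single time series
#'
#' Convenience wrapper: autocorrelation then [power_spectrum()].
#'
#' @param signal numeric series.
#' @param dt timestep (fs).
#' @param max_lag lag cutoff; default half the length.
#' @inheritParams power_spectrum
#' @return A `vw_spectrum`.
#' @export
equilibrium_spectrum <- function(signal, dt, max_lag = NULL, window = "hann",
                                 pad_factor = 4L, mode_id = NA_integer_) {
  n <- length(signal)
  if (is.null(max_lag)) max_lag <- max(8L, n %/% 2L)
  max_lag <- min(max_lag, n - 1L)
  power_spectrum(autocorrelation(signal, max_lag), dt, window = window,
                 pad_factor = pad_factor, mode_id = mode_id)
}

#' Write a spectrum (or list of spectra) as TSV
#'
#' Columns: `wavenumber_cm-1`, then one `power` column per spectrum
#' (`power_mode<id>` when mode ids are set).
#'
#' @param spectra a `vw_spectrum` or list of them on a common grid.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_spectra_tsv <- function(spectra, path) {
  if (inherits(spectra, "vw_spectrum")) spectra <- list(spectra)
  wn <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (length(s$wavenumbers) != length(wn) ||
        max(abs(s$wavenumbers - wn)) > 1e-9 * max(wn)) {
      stop("spectra are not on a common wavenumber grid")
    }
  }
  cols <- lapply(spectra, `[[`, "power")
  names(cols) <- vapply(seq_along(spectra), function(i) {
    id <- spectra[[i]]$mode_id
    if (is.na(id)) sprintf("power_%d", i) else sprintf("power_mode%d", id)
  }, "")
  df <- cbind(data.frame(`wavenumber_cm-1` = wn, check.names = FALSE),
              as.data.frame(cols))
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
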