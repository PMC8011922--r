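# continuous Morlet wavelet transform: time-frequency power maps of mode
# velocities

#' Morlet mother wavelet
#'
#' \eqn{\psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2}} in rescaled
#' (dimensionless) time, without the small admissibility correction term
#' (negligible, < 1e-7, for `omega0 >= 6`). The default `omega0 = 6` is the
#' standard compromise between time and frequency resolution for spectrogram
#' use.
#'
#' @param t rescaled time (numeric vector).
#' @param omega0 dimensionless center frequency (>= 5 recommended).
#' @return Complex vector.
#' @export
#' @examples
#' morlet_mother(0)          # pi^(-1/4)
morlet_mother <- function(t, omega0 = 6) {
  pi^(-0.25) * exp(1i * omega0 * t) * exp(-t^2 / 2)
}

#' Morlet / scale-grid parameters for the CWT
#'
#' The scale parameter a dilates the mother wavelet and is inversely
#' proportional to the probed frequency through the center-frequency map
#' \eqn{\nu(a) = \omega_0 / (2\pi a)}; the translation parameter b (the time
#' axis of the output) localizes frequencies in time. The default grid uses
#' 150 logarithmic scales over 50-2000 cm^-1: log spacing gives uniform
#' relative frequency resolution, and the lower bound avoids the nu -> 0
#' scale divergence.
#'
#' @param omega0 dimensionless Morlet center frequency; must be >= 5 for the
#'   truncated (admissibility-correction-free) form to be accurate.
#' @param n_scales number of scales (>= 2).
#' @param freq_min,freq_max frequency bounds in cm^-1.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Object of class `vw_morlet_params`.
#' @export
morlet_params <- function(omega0 = 6, n_scales = 150L, freq_min = 50,
                          freq_max = 2000, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (omega0 < 5) stop("omega0 must be >= 5 (admissibility approximation)")
  if (freq_min <= 0) stop("freq_min must be > 0")
  if (freq_max <= freq_min) stop("freq_max must exceed freq_min")
  if (n_scales < 2L) stop("n_scales must be >= 2")
  structure(list(omega0 = omega0, n_scales = as.integer(n_scales),
                 freq_min = freq_min, freq_max = freq_max, spacing = spacing),
            class = "vw_morlet_params")
}

# frequency grid (cm^-1, ascending) and matching scales (fs, descending)
morlet_grid <- function(params) {
  nu <- switch(params$spacing,
    log = exp(seq(log(params$freq_min), log(params$freq_max),
                  length.out = params$n_scales)),
    linear = seq(params$freq_min, params$freq_max, length.out = params$n_scales))
  a <- params$omega0 / (2 * pi * cm1_to_fs(nu))   # fs
  list(wavenumbers = nu, scales = a)
}

#' Continuous wavelet transform of a mode-velocity signal
#'
#' Evaluates \eqn{W(a,b) = a^{-1/2} \sum_t x(t)\,\psi^*((t-b)/a)\,dt} on the
#' scale grid of `params`, with b running over the signal's own time axis.
#' The sum is computed as a circular FFT convolution of the zero-padded
#' signal with the exactly time-sampled Morlet kernel; the padding covers
#' eight Gaussian e-foldings of the largest scale, so the result matches the
#' direct double sum to near machine precision. The returned power is
#' \eqn{|W|^2} (arbitrary units, linear in signal power). The cone of
#' influence marks, per time column, the lowest trustworthy wavenumber: cells
#' whose Gaussian e-folding time \eqn{\sqrt{2}a} reaches past the nearer
#' signal edge are edge-contaminated but retained.
#'
#' @param signal numeric time series (a mode-velocity column), length >= 8.
#' @param params a [morlet_params()] object.
#' @param dt timestep in fs.
#' @param times optional time axis (fs); default `(0:(n-1)) * dt`.
#' @param mode_id provenance label.
#' @return Object of class `vw_spectrogram`: `wavenumbers` (cm^-1 ascending),
#'   `times` (fs), `power` (`n_freq x n_time`, >= 0), `coi` (per-time lowest
#'   trustworthy wavenumber, cm^-1), `scales` (fs), `omega0`, `mode_id`.
#' @export
cwt <- function(signal, params = morlet_params(), dt, times = NULL,
                mode_id = NA_integer_) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 8L) stop(sprintf("signal too short for CWT: %d < 8 frames", n))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  nyq_cm1 <- fs_to_cm1(1 / (2 * dt))
  if (params$freq_max > nyq_cm1) {
    stop(sprintf("freq_max %.1f cm^-1 exceeds the Nyquist wavenumber %.1f cm^-1 at dt = %g fs",
                 params$freq_max, nyq_cm1, dt))
  }
  grid <- morlet_grid(params)
  a <- grid$scales
  # pad so the largest kernel's tail (8 e-foldings) cannot wrap onto the signal
  pad_frames <- ceiling(8 * max(a) / dt)
  P <- 2^ceiling(log2(n + 2 * pad_frames))
  xpad <- c(signal, rep(0, P - n))
  fx <- stats::fft(xpad)
  # signed sample offsets on the circular grid: 0,1,...,P/2-1,-P/2,...,-1
  m <- c(0:(P %/% 2 - 1L), -(P %/% 2):-1L)
  W <- matrix(0i, length(a), n)
  for (s in seq_along(a)) {
    # h(m) = (dt/sqrt(a)) * psi(m*dt/a); W(b_j) = sum_n x_n conj(psi((n-j)dt/a))
    # * dt/sqrt(a) = circular convolution x * h evaluated at j
    h <- (dt / sqrt(a[s])) * morlet_mother(m * dt / a[s], params$omega0)
    conv <- stats::fft(fx * stats::fft(h), inverse = TRUE) / P
    W[s, ] <- conv[seq_len(n)]
  }
  if (is.null(times)) times <- (seq_len(n) - 1L) * dt
  power <- Re(W * Conj(W))
  # cone of influence: scale a trusted at time t iff sqrt(2)*a <= distance to
  # nearer edge; report the lowest trusted wavenumber per column
  tspan <- times - times[1]
  edge <- pmin(tspan, tspan[n] - tspan)
  a_max_ok <- edge / sqrt(2)
  coi <- ifelse(a_max_ok > 0,
                fs_to_cm1(params$omega0 / (2 * pi * a_max_ok)), Inf)
  structure(list(wavenumbers = grid$wavenumbers, times = times, power = power,
                 coi = coi, scales = a, omega0 = params$omega0,
                 mode_id = mode_id, W = W),
            class = "vw_spectrogram")
}

#' @export
print.vw_spectrogram <- function(x, ...) {
  cat(sprintf("<vw_spectrogram> %d scales (%.0f - %.0f cm^-1) x %d times (0 - %.0f fs)\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              length(x$times), max(x$times)))
  invisible(x)
}

#' Cone-of-influence mask
#'
#' @param spec a `vw_spectrogram`.
#' @return Logical `n_freq x n_time` matrix, `TRUE` where the cell is inside
#'   the cone of influence (trustworthy, no edge contamination).
#' @export
coi_mask <- function(spec) {
  outer(spec$wavenumbers, spec$coi, `>=`)
}

#' Ensemble-average wavelet power maps
#'
#' Elementwise mean of `|W|^2` over spectrograms sharing identical frequency
#' and time axes; the combined cone of influence takes the least trustworthy
#' (highest) bound per column.
#'
#' @param spectrograms list of `vw_spectrogram` objects.
#' @return A `vw_spectrogram` with averaged power (complex coefficients are
#'   dropped: the average is incoherent by design).
#' @export
average_power <- function(spectrograms) {
  stopifnot(is.list(spectrograms), length(spectrograms) >= 1L)
  ref <- spectrograms[[1]]
  for (s in spectrograms[-1]) {
    if (length(s$wavenumbers) != length(ref$wavenumbers) ||
        length(s$times) != length(ref$times) ||
        max(abs(s$wavenumbers - ref$wavenumbers)) > 1e-9 * max(ref$wavenumbers) ||
        max(abs(s$times - ref$times)) > 1e-9 * max(ref$times[length(ref$times)], 1)) {
      stop("spectrogram axes mismatch: all members must share frequency and time grids")
    }
  }
  pow <- Reduce(`+`, lapply(spectrograms, `[[`, "power")) / length(spectrograms)
  coi <- Reduce(pmax, lapply(spectrograms, `[[`, "coi"))
  structure(list(wavenumbers = ref$wavenumbers, times = ref$times, power = pow,
                 coi = coi, scales = ref$scales, omega0 = ref$omega0,
                 mode_id = ref$mode_id, W = NULL),
            class = "vw_spectrogram")
}

#' Time series of integrated band power
#'
#' Per time column, trapezoid-integrates the spectrogram power over the
#' wavenumber band `[center - halfwidth, center + halfwidth]`.
#'
#' @param spec a `vw_spectrogram`.
#' @param center band center in cm^-1.
#' @param halfwidth band half-width in cm^-1.
#' @return Tibble with columns `time_fs`, `power`, `in_coi` (whole band inside
#'   the cone of influence?).
#' @export
band_intensity <- function(spec, center, halfwidth) {
  lo <- center - halfwidth; hi <- center + halfwidth
  sel <- which(spec$wavenumbers >= lo & spec$wavenumbers <= hi)
  if (length(sel) == 0L) {
    stop(sprintf("empty band: no grid wavenumbers in [%.1f, %.1f] cm^-1", lo, hi))
  }
  if (length(sel) == 1L) {
    series <- spec$power[sel, ]
  } else {
    dw <- diff(spec$wavenumbers[sel])
    pw <- spec$power[sel, , drop = FALSE]
    series <- colSums((pw[-length(sel), , drop = FALSE] +
                       pw[-1, , drop = FALSE]) * dw) / 2
  }
  band_lo_ok <- spec$coi <= lo
  tibble::tibble(time_fs = spec$times, power = series, in_coi = band_lo_ok)
}

#' Normalize a spectrogram's power to its maximum
#'
#' Reporting convenience: the paperless absolute scale of |W|^2 is arbitrary,
#' so maps are conventionally shown relative to their maximum.
#'
#' @param spec a `vw_spectrogram`.
#' @return The spectrogram with `power` scaled to `max(power) == 1` (zero maps
#'   are returned unchanged).
#' @export
normalize_power <- function(spec) {
  m <- max(spec$power)
  if (m > 0) spec$power <- spec$power / m
  spec
}

#' Write a spectrogram as a TSV matrix
#'
#' Rows are frequencies in cm^-1 (descending), columns times in fs; the first
#' row and first column carry the axes. A final row `coi_cm-1` records the
#' per-time cone-of-influence bound.
#'
#' @param spec a `vw_spectrogram`.
#' @param path output path.
#' @param normalize scale power to the map maximum before writing?
#' @return Invisibly, `path`.
#' @export
write_spectrogram_tsv <- function(spec, path, normalize = TRUE) {
  if (normalize) spec <- normalize_power(spec)
  ord <- order(spec$wavenumbers, decreasing = TRUE)
  header <- paste(c("wavenumber_cm-1", sprintf("%.6g", spec$times)), collapse = "\t")
  rows <- vapply(ord, function(i) {
    paste(c(sprintf("%.8g", spec$wavenumbers[i]),
            sprintf("%.8g", spec$power[i, ])), collapse = "\t")
  }, "")
  coi_row <- paste(c("coi_cm-1", sprintf("%.8g", spec$coi)), collapse = "\t")
  writeLines(c(header, rows, coi_row), path)
  invisible(path)
}
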