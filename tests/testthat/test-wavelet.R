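# Morlet mother wavelet, CWT, ensemble averaging, band kinetics

test_that("Morlet mother wavelet has the standard closed-form properties", {
  expect_equal(Re(morlet_mother(0)), pi^(-0.25))
  expect_equal(Im(morlet_mother(0)), 0)
  t <- c(0.3, 1.7, -2.5, 4)
  expect_equal(abs(morlet_mother(t)), abs(morlet_mother(-t)))  # even envelope
  # unit L2 norm by quadrature: integral |psi|^2 dt = 1
  tt <- seq(-12, 12, by = 1e-3)
  expect_equal(sum(abs(morlet_mother(tt))^2) * 1e-3, 1, tolerance = 1e-8)
})

test_that("morlet parameter validation guards admissibility and Nyquist", {
  expect_error(morlet_params(omega0 = 3), "omega0")
  expect_error(morlet_params(freq_min = -5), "freq_min")
  expect_error(morlet_params(freq_min = 500, freq_max = 100), "freq_max")
  expect_error(morlet_params(n_scales = 1), "n_scales")
  # freq_max above Nyquist: error names the Nyquist wavenumber
  nyq <- fs_to_cm1(1 / (2 * 2.0))
  expect_error(cwt(rnorm(64), morlet_params(freq_max = 2 * nyq), dt = 2.0),
               "Nyquist")
  expect_error(cwt(rnorm(4), morlet_params(), dt = 0.5), "too short")
})

test_that("FFT-based CWT equals the direct double-sum oracle", {
  set.seed(21)
  x <- rnorm(256)
  params <- morlet_params(n_scales = 16, freq_min = 200, freq_max = 2000)
  sg <- cwt(x, params, dt = 0.5)
  W_oracle <- cwt_direct_oracle(x, params, dt = 0.5)
  expect_lt(max(abs(sg$W - W_oracle)) / max(abs(W_oracle)), 1e-8)
  expect_equal(sg$power, Re(W_oracle * Conj(W_oracle)), tolerance = 1e-8)
})

test_that("all-zero signals give all-zero power", {
  sg <- cwt(rep(0, 64), morlet_params(n_scales = 8, freq_min = 300,
                                      freq_max = 2000), dt = 0.5)
  expect_equal(max(sg$power), 0)
})

test_that("a pure tone is localized at its wavenumber inside the cone of influence", {
  dt <- 0.5; n <- 4096
  tone <- sin(2 * pi * cm1_to_fs(1000) * (0:(n - 1)) * dt)
  params <- morlet_params(omega0 = 6, n_scales = 120, freq_min = 100,
                          freq_max = 2000)
  sg <- cwt(tone, params, dt)
  target <- which.min(abs(sg$wavenumbers - 1000))
  cols <- which(sg$coi <= 1000)            # 1000 cm^-1 row inside the cone
  argmax <- apply(sg$power[, cols, drop = FALSE], 2, which.max)
  expect_lte(max(abs(argmax - target)), 1)  # within one scale bin everywhere
})

test_that("CWT is linear and covariant under time shifts", {
  set.seed(8)
  params <- morlet_params(n_scales = 12, freq_min = 300, freq_max = 2000)
  x <- rnorm(128); y <- rnorm(128)
  Wx <- cwt(x, params, 0.5)$W
  Wy <- cwt(y, params, 0.5)$W
  Wxy <- cwt(x + y, params, 0.5)$W
  expect_lt(max(abs(Wxy - (Wx + Wy))) / max(abs(Wxy)), 1e-10)
  # shifting the input shifts the power map; compare columns at least eight
  # Gaussian widths of the largest scale away from either edge and from the
  # content truncated off the end by the shift
  n <- 2048; s <- 16
  params2 <- morlet_params(n_scales = 12, freq_min = 600, freq_max = 2000)
  x2 <- rnorm(n)
  xs <- c(rep(0, s), x2[1:(n - s)])
  Ps <- cwt(xs, params2, 0.5)$power
  P <- cwt(x2, params2, 0.5)$power
  a_max_frames <- ceiling(max(cwt(x2, params2, 0.5)$scales) / 0.5)
  interior <- (s + 8 * a_max_frames):(n - 8 * a_max_frames)
  expect_lt(max(abs(Ps[, interior] - P[, interior - s])) / max(P), 1e-8)
})

test_that("peak power scales as amplitude squared", {
  dt <- 0.5; n <- 1024
  t <- (0:(n - 1)) * dt
  params <- morlet_params(n_scales = 40, freq_min = 400, freq_max = 1800)
  peak <- vapply(c(1, 2, 4), function(A) {
    max(cwt(A * sin(2 * pi * cm1_to_fs(900) * t), params, dt)$power)
  }, 0)
  expect_equal(peak[2] / peak[1], 4, tolerance = 1e-6)
  expect_equal(peak[3] / peak[1], 16, tolerance = 1e-6)
})

test_that("power averaging is elementwise with the least trustworthy cone", {
  set.seed(4)
  params <- morlet_params(n_scales = 10, freq_min = 300, freq_max = 1500)
  a <- cwt(rnorm(64), params, 0.5)
  b <- a; b$power <- 2 * a$power
  avg <- average_power(list(a, b))
  expect_equal(avg$power, 1.5 * a$power)
  expect_equal(average_power(list(a, a))$power, a$power)
  z <- a; z$power[] <- 0
  expect_equal(max(average_power(list(z, z, z))$power), 0)
  short <- cwt(rnorm(32), params, 0.5)
  expect_error(average_power(list(a, short)), "axes mismatch")
})

test_that("band intensity of a stationary tone is flat away from the edges", {
  dt <- 0.5; n <- 4096
  tone <- sin(2 * pi * cm1_to_fs(1000) * (0:(n - 1)) * dt)
  params <- morlet_params(n_scales = 120, freq_min = 100, freq_max = 2000)
  sg <- cwt(tone, params, dt)
  bi <- band_intensity(sg, 1000, 50)
  expect_s3_class(bi, "tbl_df")
  # constancy holds at two e-folding times from the edges; exactly at the
  # one-e-folding cone boundary a pure tone is attenuated by ~12%
  a_band <- max(sg$scales[sg$wavenumbers >= 950 & sg$wavenumbers <= 1050])
  margin <- 2 * sqrt(2) * a_band
  deep <- bi$time_fs >= margin & bi$time_fs <= max(bi$time_fs) - margin
  v <- bi$power[deep]
  expect_lt((max(v) - min(v)) / mean(v), 0.05)
  expect_error(band_intensity(sg, 5000, 10), "empty band")
  # zero map -> zero series
  z <- sg; z$power[] <- 0
  expect_equal(max(band_intensity(z, 1000, 50)$power), 0)
})

test_that("a frequency switch is detected at the true time within the Morlet resolution", {
  spec <- switch_signal_spec(190, 460, switch_time = 500, dt = 0.5,
                             n_frames = 4096)
  sig <- make_switch_signal(spec)
  params <- morlet_params(n_scales = 120, freq_min = 100, freq_max = 2000)
  sg <- cwt(sig$values, params, 0.5)
  bi <- band_intensity(sg, 460, 30)
  plateau <- mean(bi$power[bi$time_fs > 900 & bi$time_fs < 1800])
  t_half <- bi$time_fs[which(bi$power >= plateau / 2 & bi$time_fs >= 100)[1]]
  a460 <- 6 / (2 * pi * cm1_to_fs(460))
  tol <- 2 * sqrt(2) * a460                 # twice the Gaussian e-folding time
  expect_lt(abs(t_half - 500), tol)
})

test_that("spectrogram TSV export is axis-labelled, descending and normalized", {
  set.seed(2)
  sg <- cwt(rnorm(64), morlet_params(n_scales = 8, freq_min = 300,
                                     freq_max = 1500), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrogram_tsv(sg, path)
  lines <- readLines(path)
  expect_match(lines[1], "^wavenumber_cm-1\t0\t")
  wn <- as.numeric(vapply(strsplit(lines[2:9], "\t"), `[[`, "", 1))
  expect_true(all(diff(wn) < 0))            # descending rows
  body <- do.call(rbind, lapply(strsplit(lines[2:9], "\t"),
                                function(x) as.numeric(x[-1])))
  expect_equal(max(body), 1)                # normalized to map maximum
  expect_match(lines[10], "^coi_cm-1\t")
})
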