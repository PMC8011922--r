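# covariance construction, diagonalization, projection, frequency assignment

mw_from_matrix <- function(values, dt = 0.5, atoms = NULL) {
  structure(list(times = (seq_len(nrow(values)) - 1) * dt,
                 values = values, dt = dt, atom_order = atoms),
            class = "vw_mwvel")
}

test_that("covariance is the raw second moment with closed-form values", {
  # zero series -> zero matrix
  z <- mw_from_matrix(matrix(0, 64, 2))
  expect_equal(compute_covariance(z)$K, matrix(0, 2, 2))
  # sin over integer periods: <sin^2> = 1/2
  w <- 2 * pi / 64
  s <- sin(w * (0:1023))
  K1 <- compute_covariance(mw_from_matrix(matrix(s, ncol = 1)))$K
  expect_equal(K1[1, 1], 0.5, tolerance = 1e-9)
  # (sin, cos) over integer periods: diagonal 1/2, off-diagonal 0
  K2 <- compute_covariance(mw_from_matrix(cbind(s, cos(w * (0:1023)))))$K
  expect_equal(diag(K2), c(0.5, 0.5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(abs(K2[1, 2]), 1e-9)
  # no mean subtraction: constant series has K = c^2, not 0
  Kc <- compute_covariance(mw_from_matrix(matrix(3, 16, 1)))$K
  expect_equal(Kc[1, 1], 9)
  expect_error(compute_covariance(mw_from_matrix(matrix(0, 4, 1)), c(2, 2)),
               ">= 2 frames")
})

test_that("diagonalization orders, signs and clamps eigenpairs", {
  K <- structure(list(K = matrix(c(2, 1, 1, 2), 2), n_frames_used = 10,
                      atom_order = NULL), class = "vw_covariance")
  m <- diagonalize(K)
  expect_equal(m$eigenvalues, c(3, 1))
  expect_equal(m$L[, 1], c(1, 1) / sqrt(2))
  expect_equal(m$L[, 2], c(1, -1) / sqrt(2))   # sign rule: largest entry > 0
  # identity: orthonormality and eigenvalues only (degenerate directions free)
  m3 <- diagonalize(diag(3))
  expect_equal(crossprod(m3$L), diag(3), tolerance = 1e-10)
  expect_equal(m3$eigenvalues, rep(1, 3))
  expect_equal(unique(m3$degeneracy), 1L)      # one degenerate block
  expect_error(diagonalize(matrix(c(1, 2, 0, 1), 2)), "not symmetric")
})

test_that("leading covariance mode of a harmonic dimer matches the analytic normal mode", {
  model <- dimer_model(c("C", "O"), k = 0.1, dt = 0.5, n_frames = 2^14, seed = 3)
  tr <- sample_harmonic_trajectory(model)
  mw <- mass_weight(tr)
  modes <- diagonalize(compute_covariance(mw))
  # analytic mass-weighted vibrational mode of a two-mass spring along x
  m <- vibwave:::lookup_masses(c("C", "O"))
  u <- c(sqrt(m[2]), 0, 0, -sqrt(m[1]), 0, 0)
  u <- u / sqrt(sum(u^2))
  expect_gte(abs(sum(modes$L[, 1] * u)), 0.99)
  # assigned frequency matches the reduced-mass closed form
  modes <- assign_frequencies(modes, mw)
  expect_equal(modes$frequencies[1], dimer_analytic_freq_cm1(m[1], m[2], 0.1),
               tolerance = 0.01)
})

test_that("projection is unitary and decorrelates the fitting window", {
  model <- chain5_model(n_frames = 4096)
  mw <- mass_weight(sample_harmonic_trajectory(model))
  K <- compute_covariance(mw)
  modes <- diagonalize(K)
  Q <- project(mw, modes)
  # identity modes: output equals input
  id <- modes; id$L <- diag(ncol(mw$values))
  expect_equal(project(mw, id)$values, mw$values)
  # per-frame kinetic energy conserved
  expect_equal(rowSums(Q$values^2), rowSums(mw$values^2), tolerance = 1e-10)
  # covariance of Q-dot over the same window is diagonal
  KQ <- crossprod(Q$values) / nrow(Q$values)
  off <- max(abs(KQ - diag(diag(KQ))))
  expect_lt(off, 1e-8 * max(modes$eigenvalues))
  # trace bookkeeping: sum of mode variances = trace(K)
  expect_equal(sum(diag(KQ)), sum(diag(K$K)), tolerance = 1e-10)
  expect_error(project(mw_from_matrix(matrix(0, 4, 6)), modes),
               "dimension mismatch.*6.*15|dimension mismatch.*15.*6")
})

test_that("re-diagonalizing projected velocities gives the identity transform", {
  model <- chain5_model(n_frames = 4096)
  mw <- mass_weight(sample_harmonic_trajectory(model))
  modes <- diagonalize(compute_covariance(mw))
  Q <- project(mw, modes)
  QK <- compute_covariance(mw_from_matrix(Q$values))
  L2 <- diagonalize(QK)$L
  # nonzero-eigenvalue block only: zero modes have arbitrary directions
  live <- which(modes$eigenvalues > 1e-8 * max(modes$eigenvalues))
  sub <- abs(L2[live, live])               # modulo sign flips
  expect_lt(max(abs(sub - diag(length(live)))), 1e-6)
})

test_that("frequency assignment localizes tones and flags silent modes", {
  # synthetic 1-D oscillator at 1000 cm^-1, 2^14 frames, dt = 0.5 fs
  dt <- 0.5; n <- 2^14
  tone <- sin(2 * pi * cm1_to_fs(1000) * (0:(n - 1)) * dt)
  mw <- mw_from_matrix(cbind(tone, 0), dt)   # second column silent
  modes <- diagonalize(compute_covariance(mw))
  modes <- assign_frequencies(modes, mw)
  bin <- fs_to_cm1(1 / (n * dt))             # one unpadded spectral bin
  expect_lt(abs(modes$frequencies[1] - 1000), max(bin, 4))
  expect_true(is.na(modes$frequencies[2]))   # zero-variance: undefined
})

test_that("trimer frequencies are recovered within 1% of the analytic oracle", {
  model <- trimer3_model(c(400, 800, 1600), n_frames = 2^14)
  nm <- analytic_normal_modes(model)
  mw <- mass_weight(sample_harmonic_trajectory(model))
  modes <- assign_frequencies(diagonalize(compute_covariance(mw)), mw)
  live <- which(modes$eigenvalues > 1e-6 * max(modes$eigenvalues))
  expect_length(live, 3)
  rec <- sort(modes$frequencies[live])
  expect_equal(rec, sort(nm$frequencies_cm1[nm$frequencies_cm1 > 1]),
               tolerance = 0.01)
})

test_that("mode composition weights are per-atom and sum to one", {
  model <- chain5_model(n_frames = 1024)
  mw <- mass_weight(sample_harmonic_trajectory(model))
  modes <- diagonalize(compute_covariance(mw))
  comp <- mode_composition(modes)
  expect_s3_class(comp, "tbl_df")
  sums <- as.numeric(tapply(comp$weight, comp$mode, sum))
  expect_equal(sums, rep(1, 15), tolerance = 1e-10)
})

test_that("mode sets round-trip through the text archive", {
  model <- chain5_model(n_frames = 1024)
  mw <- mass_weight(sample_harmonic_trajectory(model))
  modes <- suppressWarnings(assign_frequencies(diagonalize(compute_covariance(mw)), mw))
  dir <- withr::local_tempdir()
  write_mode_set(modes, dir)
  back <- read_mode_set(dir, atom_order = modes$atom_order)
  expect_equal(back$L, modes$L, tolerance = 1e-12)
  expect_equal(back$eigenvalues, modes$eigenvalues, tolerance = 1e-12)
  expect_equal(back$frequencies, modes$frequencies, tolerance = 1e-9)
})
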