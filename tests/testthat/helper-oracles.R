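# shared fixtures and independent oracles for the test suite

# Brute-force evaluation of the CWT double sum
#   W(a,b) = (1/sqrt(a)) * sum_t x(t) conj(psi((t-b)/a)) * dt
# at every (scale, translation) pair. Deliberately O(n^2 * n_scales); the
# FFT path in cwt() is checked against this on small instances.
cwt_direct_oracle <- function(x, params, dt) {
  g <- vibwave:::morlet_grid(params)
  n <- length(x)
  t <- (seq_len(n) - 1L) * dt
  W <- matrix(0i, length(g$scales), n)
  for (s in seq_along(g$scales)) {
    a <- g$scales[s]
    for (j in seq_len(n)) {
      W[s, j] <- sum(x * Conj(morlet_mother((t - t[j]) / a, params$omega0))) *
        dt / sqrt(a)
    }
  }
  W
}

# 1-D two-mass spring: analytic vibrational mode of the relative coordinate.
# Masses m1, m2, spring k; vibrational angular frequency sqrt(k/mu) with
# reduced mass mu; mass-weighted mode vector along x is
# (sqrt(m2), -sqrt(m1)) / sqrt(m1 + m2) (up to sign).
dimer_model <- function(m_elems = c("C", "O"), k = 0.1, ...) {
  harmonic_chain(m_elems, k, ...)
}

dimer_analytic_freq_cm1 <- function(m1, m2, k) {
  mu <- m1 * m2 / (m1 + m2)
  vibwave::fs_to_cm1(sqrt(k / mu) / (2 * pi))
}

# 5-atom 1-D chain used across the deeper tests; analytic frequencies span
# roughly 150-1700 cm^-1 (150.1, 295.4, 1557.6, 1652.7)
chain5_model <- function(n_frames = 2^15, dt = 0.5, seed = 11,
                         temperature = 300) {
  harmonic_chain(c("H", "C", "O", "C", "H"),
                 k = c(0.09, 0.02, 0.008, 0.08),
                 temperature = temperature, dt = dt,
                 n_frames = n_frames, seed = seed)
}

# trimer with exactly three nonzero modes in full 3D: force matrix built as
# F = M^(1/2) (sum_j lambda_j u_j u_j') M^(1/2) from an orthonormal triple
trimer3_model <- function(freqs_cm1 = c(400, 800, 1600), n_frames = 8192L,
                          dt = 0.5, seed = 5) {
  elems <- c("O", "H", "H")
  m <- vibwave:::lookup_masses(elems)
  sqm <- sqrt(rep(m, each = 3L))
  set.seed(42)                               # fixed basis, not a sampling seed
  U <- qr.Q(qr(matrix(rnorm(81), 9, 9)))[, 1:3]
  lam <- vibwave::cm1_to_fs(freqs_cm1)^2 * (2 * pi)^2
  D <- U %*% diag(lam) %*% t(U)
  F3 <- D * outer(sqm, sqm)
  F3 <- (F3 + t(F3)) / 2
  harmonic_model(elems, F3, temperature = 300, dt = dt,
                 n_frames = n_frames, seed = seed)
}

# random small trajectory for I/O round-trips
random_trajectory <- function(n_atoms = 5, n_frames = 10, dt = 0.5,
                              velocities = TRUE, seed = 99) {
  set.seed(seed)
  elems <- sample(c("H", "C", "N", "O"), n_atoms, replace = TRUE)
  coords <- array(rnorm(n_frames * n_atoms * 3), c(n_frames, n_atoms, 3))
  vels <- if (velocities) array(rnorm(n_frames * n_atoms * 3),
                                c(n_frames, n_atoms, 3)) else NULL
  trajectory(elems, coords, dt, velocities = vels)
}
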