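# synthetic trajectories and signals with analytic ground truth: harmonic
# mass-spring systems, Morse oscillators, nonstationary switch signals

#' Define a coupled harmonic mass-spring model
#'
#' The model is `m_a d2x/dt2 = -F x` with a symmetric positive-semidefinite
#' force-constant matrix `F` (amu/fs^2) acting on the 3N Cartesian
#' coordinates (index 3(a-1)+k for atom a, component k). Its analytic normal
#' modes are the eigenvectors of the mass-weighted matrix
#' `D = M^{-1/2} F M^{-1/2}`.
#'
#' @param elements chemical symbols (length N); masses come from `masses`.
#' @param force_constants symmetric PSD `3N x 3N` matrix in amu/fs^2.
#' @param temperature temperature in K for thermal sampling.
#' @param dt trajectory timestep in fs; must satisfy
#'   `dt <= 0.1 * shortest analytic period`.
#' @param n_frames number of frames to generate.
#' @param seed RNG seed for reproducible sampling.
#' @param equilibrium optional `N x 3` equilibrium coordinates (Angstrom);
#'   default places atoms 1 Angstrom apart along x.
#' @param masses mass table.
#' @return Object of class `vw_harmonic_model`.
#' @export
harmonic_model <- function(elements, force_constants, temperature = 300,
                           dt = 0.5, n_frames = 2048L, seed = 1L,
                           equilibrium = NULL, masses = mass_table()) {
  m <- lookup_masses(elements, masses)
  n3 <- 3L * length(elements)
  stopifnot(is.matrix(force_constants),
            nrow(force_constants) == n3, ncol(force_constants) == n3)
  if (max(abs(force_constants - t(force_constants))) >
      1e-10 * max(abs(force_constants), 1e-300)) {
    stop("force-constant matrix must be symmetric")
  }
  if (is.null(equilibrium)) {
    equilibrium <- cbind(seq_along(elements) - 1, 0, 0)
  }
  model <- structure(
    list(elements = as.character(elements), masses = m,
         force_constants = force_constants, temperature = temperature,
         dt = dt, n_frames = as.integer(n_frames), seed = as.integer(seed),
         equilibrium = equilibrium),
    class = "vw_harmonic_model")
  nm <- analytic_normal_modes(model)
  pos <- nm$frequencies_cm1[nm$frequencies_cm1 > 1e-9]
  if (length(pos)) {
    t_min <- 1 / cm1_to_fs(max(pos))          # shortest period, fs
    if (dt > 0.1 * t_min) {
      stop(sprintf("dt = %g fs too coarse: shortest analytic period is %.3g fs (need dt <= %.3g)",
                   dt, t_min, 0.1 * t_min))
    }
  }
  model
}

#' Analytic normal modes of a harmonic model
#'
#' Eigen-decomposition of the mass-weighted force-constant matrix; the mode
#' frequency is \eqn{\nu = \sqrt{\lambda}/(2\pi)} converted to cm^-1.
#' Eigenvalues within `-tol * max(|lambda|)` of zero are clamped to zero
#' (translations / rotations of a free system); anything more negative means
#' the model is unstable.
#'
#' @param model a [harmonic_model()].
#' @param tol relative tolerance for the negative-eigenvalue floor.
#' @return List: `frequencies_cm1` (descending), `mode_vectors` (3N x 3N,
#'   columns matching the frequency order, mass-weighted orthonormal),
#'   `omega` (rad/fs).
#' @export
analytic_normal_modes <- function(model, tol = 1e-9) {
  sqm <- sqrt(rep(model$masses, each = 3L))
  D <- model$force_constants / outer(sqm, sqm)
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)
  lam <- e$values
  lmax <- max(abs(lam), .Machine$double.xmin)
  if (any(lam < -tol * lmax)) {
    stop(sprintf("unstable model: negative eigenvalue %.3g in mass-weighted force matrix",
                 min(lam)))
  }
  # relative clamp: eigenvalues below 1e-10 of the stiffest mode are
  #  vibrationally zero (translations/rotations up to roundoff); an absolute
  #  test would let roundoff-scale frequencies through with huge thermal
  #  amplitudes sqrt(2E)/omega
  lam[lam < 1e-10 * lmax] <- 0
  omega <- sqrt(lam)                       # rad/fs, descending
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(frequencies_cm1 = omega_to_cm1(omega), mode_vectors = V, omega = omega)
}

#' Sample an exact thermal trajectory of a harmonic model
#'
#' Each vibrational mode evolves as an exact sinusoid (no integrator error):
#' \eqn{Q_\alpha(t) = A_\alpha \sin(\omega_\alpha (t - t_{0\alpha}) +
#' \phi_\alpha)}. By default mode energies form a deterministic ladder
#' within 8% of `kB T` (mean `kB T`, the classical equipartition value),
#' interleaved so that modes adjacent in frequency receive well-separated
#' energies, with an independent seeded uniform random phase per mode. The
#' spread is deliberate: a single analytic trajectory gives each mode a
#' *fixed* energy, and exactly equal energies make the velocity covariance
#' isotropic on the vibrational subspace, leaving its eigenvectors
#' undefined. The eigenvalue gap that identifies each mode must dominate the
#' residual finite-window cross-correlation between modes, which is largest
#' for spectrally close pairs -- hence the interleaving. Every mode's
#' time-averaged kinetic energy stays inside the equipartition envelope.
#' `energy_sampling = "fixed"` forces exactly `kB T` per mode (useful when
#' only frequencies, not compositions, are probed); `"boltzmann"` draws from
#' the exponential distribution with mean `kB T` (the true classical
#' ensemble, but with per-trajectory energies that can sit far from `kB T`).
#' Zero-frequency modes (translations) are left silent so the system stays
#' bound. Positions and velocities are both emitted analytically.
#'
#' @param model a [harmonic_model()].
#' @param energy_sampling `"spread"` (default; interleaved deterministic
#'   ladder within 8% of kB T), `"fixed"` (exactly kB T) or `"boltzmann"`
#'   (exponential draw, mean kB T).
#' @param mode_energy optional explicit per-mode energies (amu A^2/fs^2),
#'   overriding temperature-based sampling; order matches
#'   [analytic_normal_modes()].
#' @param activation_time optional per-mode onset time in fs: a mode is
#'   silent (zero amplitude) before its onset and oscillates from it onward.
#'   Default 0 (active from the start).
#' @return A `vw_trajectory` with analytic positions and velocities.
#' @export
sample_harmonic_trajectory <- function(model,
                                       energy_sampling = c("spread", "fixed", "boltzmann"),
                                       mode_energy = NULL, activation_time = NULL) {
  energy_sampling <- match.arg(energy_sampling)
  nm <- analytic_normal_modes(model)
  n3 <- length(nm$omega)
  na <- n3 %/% 3L
  kT <- vw_constants()$kB * model$temperature
  with_seed(model$seed, {
    E <- if (!is.null(mode_energy)) {
      stopifnot(length(mode_energy) == n3)
      as.numeric(mode_energy)
    } else if (energy_sampling == "spread") {
      kT * equipartition_ladder(n3, nm$omega > 0)
    } else if (energy_sampling == "fixed") {
      rep(kT, n3)
    } else {
      stats::rexp(n3, rate = 1 / max(kT, .Machine$double.xmin))
    }
    phase <- stats::runif(n3, 0, 2 * pi)
    t0 <- if (is.null(activation_time)) rep(0, n3) else {
      stopifnot(length(activation_time) == n3)
      as.numeric(activation_time)
    }
    live <- nm$omega > 0
    A <- numeric(n3)
    A[live] <- sqrt(2 * E[live]) / nm$omega[live]
    tgrid <- (seq_len(model$n_frames) - 1L) * model$dt
    # mode coordinates and velocities, n_frames x n3
    Qp <- matrix(0, model$n_frames, n3)
    Qv <- matrix(0, model$n_frames, n3)
    for (j in which(live)) {
      tau <- tgrid - t0[j]
      on <- tau >= 0
      Qp[on, j] <- A[j] * sin(nm$omega[j] * tau[on] + phase[j] * (t0[j] == 0))
      Qv[on, j] <- A[j] * nm$omega[j] *
        cos(nm$omega[j] * tau[on] + phase[j] * (t0[j] == 0))
    }
    sqm <- sqrt(rep(model$masses, each = 3L))
    X <- (Qp %*% t(nm$mode_vectors)) / rep(sqm, each = model$n_frames)
    V <- (Qv %*% t(nm$mode_vectors)) / rep(sqm, each = model$n_frames)
    coords <- array(0, c(model$n_frames, na, 3L))
    vels <- array(0, c(model$n_frames, na, 3L))
    for (k in 1:3) {
      cols <- seq.int(k, by = 3L, length.out = na)
      coords[, , k] <- X[, cols] + rep(model$equilibrium[, k], each = model$n_frames)
      vels[, , k] <- V[, cols]
    }
    trajectory(model$elements, coords, model$dt, velocities = vels)
  })
}

# Interleaved energy ladder on [0.92, 1.08] (units of kT) over the live
# (nonzero-frequency) modes, in descending-frequency order. Lower-half and
# upper-half rungs alternate so spectrally adjacent modes -- whose residual
# finite-window velocity cross-correlation is largest -- get the widest
# eigenvalue separation. Deterministic: identifiability must not depend on
# the luck of a random energy draw.
equipartition_ladder <- function(n3, live) {
  out <- numeric(n3)
  nl <- sum(live)
  if (nl == 0L) return(out)
  if (nl == 1L) { out[live] <- 1; return(out) }
  rungs <- seq(0.92, 1.08, length.out = nl)
  h <- ceiling(nl / 2)
  order_idx <- as.vector(rbind(seq_len(h), h + seq_len(h)))[seq_len(nl)]
  out[which(live)] <- rungs[order_idx]
  out
}

#' Specification of a frequency-switch signal
#'
#' A nonstationary test signal whose instantaneous frequency jumps from
#' `freq_before` to `freq_after` at `switch_time`, with phase continuity at
#' the switch and optional additive Gaussian noise. Emulates sequential
#' activation of vibrational bands during a relaxation.
#'
#' @param freq_before,freq_after frequencies in cm^-1 (below Nyquist).
#' @param switch_time switch instant in fs.
#' @param amplitude_before,amplitude_after amplitudes of the two segments.
#' @param dt timestep (fs).
#' @param n_frames series length.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed for the noise.
#' @return Object of class `vw_switch_spec`.
#' @export
switch_signal_spec <- function(freq_before, freq_after, switch_time,
                               amplitude_before = 1, amplitude_after = 1,
                               dt = 0.5, n_frames = 4096L, noise_sd = 0,
                               seed = 1L) {
  nyq <- fs_to_cm1(1 / (2 * dt))
  if (freq_before >= nyq || freq_after >= nyq) {
    stop(sprintf("switch frequencies must be below the Nyquist wavenumber %.1f cm^-1", nyq))
  }
  structure(list(freq_before = freq_before, freq_after = freq_after,
                 switch_time = switch_time, amplitude_before = amplitude_before,
                 amplitude_after = amplitude_after, dt = dt,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "vw_switch_spec")
}

#' Generate a frequency-switch signal
#'
#' `amplitude_before * sin(2 pi nu1 t)` before the switch,
#' `amplitude_after * sin(2 pi nu2 t + phi)` after, with `phi` chosen so the
#' phase is continuous at the switch, plus seeded Gaussian noise.
#'
#' @param spec a [switch_signal_spec()].
#' @return List: `times` (fs), `values`, `spec`.
#' @export
make_switch_signal <- function(spec) {
  stopifnot(inherits(spec, "vw_switch_spec"))
  t <- (seq_len(spec$n_frames) - 1L) * spec$dt
  nu1 <- cm1_to_fs(spec$freq_before)
  nu2 <- cm1_to_fs(spec$freq_after)
  phi <- 2 * pi * (nu1 - nu2) * spec$switch_time    # phase continuity at switch
  before <- t < spec$switch_time
  x <- numeric(spec$n_frames)
  x[before] <- spec$amplitude_before * sin(2 * pi * nu1 * t[before])
  x[!before] <- spec$amplitude_after * sin(2 * pi * nu2 * t[!before] + phi)
  if (spec$noise_sd > 0) {
    x <- x + with_seed(spec$seed, stats::rnorm(spec$n_frames, 0, spec$noise_sd))
  }
  list(times = t, values = x, spec = spec)
}

#' Sample a 1-D Morse oscillator trajectory
#'
#' Integrates `m d2x/dt2 = -dV/dx` for the Morse potential
#' \eqn{V(x) = D (1 - e^{-a x})^2} with velocity Verlet. Generalized modes
#' extracted from such motion are intrinsically anharmonic: the classical
#' oscillation frequency \eqn{\omega(E) = \omega_0 \sqrt{1 - E/D}} red-shifts
#' with energy, approaching the harmonic limit
#' \eqn{\omega_0 = a \sqrt{2 D / m}} as E tends to 0.
#'
#' @param D well depth in amu A^2/fs^2.
#' @param a range parameter in 1/Angstrom.
#' @param m mass in amu (the emitted atom's element is chosen by nearest
#'   standard mass; provide `element` to fix it).
#' @param e0 initial energy as a fraction of `D` (0 < e0 < 1; e0 >= 1 is
#'   unbound).
#' @param dt frame spacing of the emitted trajectory, in fs.
#' @param n_frames number of emitted frames.
#' @param element chemical symbol of the emitted single atom.
#' @param substeps integrator substeps per emitted frame; the velocity-Verlet
#'   step is `dt/substeps`. The default keeps the (bounded, symplectic)
#'   energy oscillation below 1e-6 relative for `dt = 0.25` fs at typical
#'   molecular frequencies.
#' @return A `vw_trajectory` (1 atom, motion along x) with attribute
#'   `energy_drift` (max relative energy deviation over the run).
#' @export
sample_morse_trajectory <- function(D, a, m, e0, dt, n_frames, element = "H",
                                    substeps = 100L) {
  if (e0 >= 1) {
    stop(sprintf("unbound motion: e0 = %.3g >= 1 (energy must stay below the well depth)", e0))
  }
  if (e0 <= 0) stop("e0 must be in (0, 1)")
  E <- e0 * D
  force <- function(x) -2 * D * a * exp(-a * x) * (1 - exp(-a * x))
  pot <- function(x) D * (1 - exp(-a * x))^2
  h <- dt / substeps
  x <- 0; v <- sqrt(2 * E / m)           # start at the minimum, all kinetic
  xs <- numeric(n_frames); vs <- numeric(n_frames)
  f <- force(x)
  for (i in seq_len(n_frames)) {
    xs[i] <- x; vs[i] <- v
    for (s in seq_len(substeps)) {
      x <- x + v * h + 0.5 * (f / m) * h^2
      fn <- force(x)
      v <- v + 0.5 * (f + fn) / m * h
      f <- fn
    }
  }
  etot <- pot(xs) + 0.5 * m * vs^2
  drift <- max(abs(etot - E)) / E
  coords <- array(0, c(n_frames, 1L, 3L)); coords[, 1, 1] <- xs
  vels <- array(0, c(n_frames, 1L, 3L)); vels[, 1, 1] <- vs
  tr <- trajectory(element, coords, dt, velocities = vels,
                   masses = mass_table(stats::setNames(m, element)))
  attr(tr, "energy_drift") <- drift
  tr
}

#' Harmonic-chain helper: nearest-neighbour springs along x
#'
#' Builds the `3N x 3N` force-constant matrix of a free 1-D chain (motion
#' along x only; y and z are force-free) with the given nearest-neighbour
#' spring constants.
#'
#' @param elements chemical symbols, length N.
#' @param k spring constants in amu/fs^2, length N-1.
#' @param ... passed to [harmonic_model()].
#' @return A `vw_harmonic_model`.
#' @export
harmonic_chain <- function(elements, k, ...) {
  n <- length(elements)
  stopifnot(length(k) == n - 1L)
  Fx <- matrix(0, n, n)
  for (b in seq_len(n - 1L)) {
    Fx[b, b] <- Fx[b, b] + k[b]
    Fx[b + 1L, b + 1L] <- Fx[b + 1L, b + 1L] + k[b]
    Fx[b, b + 1L] <- Fx[b, b + 1L] - k[b]
    Fx[b + 1L, b] <- Fx[b + 1L, b] - k[b]
  }
  F3 <- matrix(0, 3L * n, 3L * n)
  ix <- seq.int(1L, by = 3L, length.out = n)
  F3[ix, ix] <- Fx
  harmonic_model(elements, F3, ...)
}
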