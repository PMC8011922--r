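# velocity-covariance matrix, generalized modes, projection, frequency
# assignment

#' Covariance matrix of mass-weighted velocities
#'
#' Computes the raw second-moment matrix
#' \eqn{K_{ij} = \langle \dot q_i \dot q_j \rangle} where the angle brackets
#' average over the frames of the chosen window (no mean subtraction: the
#' quantity averaged is the velocity itself, whose mean vanishes for a bound
#' equilibrium system; with center-of-mass removal it vanishes identically).
#' The result is symmetrized as (K + K')/2 to remove rounding asymmetry.
#'
#' @param series a `vw_mwvel` mass-weighted velocity series.
#' @param frame_range optional integer vector `c(first, last)` (1-based,
#'   inclusive) selecting the averaging window; default all frames.
#' @return Object of class `vw_covariance`: `K` (3N x 3N, amu A^2/fs^2),
#'   `n_frames_used`, `atom_order`.
#' @export
compute_covariance <- function(series, frame_range = NULL) {
  stopifnot(inherits(series, "vw_mwvel"))
  nf <- nrow(series$values)
  if (is.null(frame_range)) frame_range <- c(1L, nf)
  frame_range <- as.integer(frame_range)
  if (length(frame_range) != 2L || frame_range[1] < 1L || frame_range[2] > nf ||
      frame_range[2] < frame_range[1]) {
    stop(sprintf("invalid frame_range: need 1 <= first <= last <= %d", nf))
  }
  win <- frame_range[1]:frame_range[2]
  if (length(win) < 2L) stop("covariance window must contain >= 2 frames")
  X <- series$values[win, , drop = FALSE]
  K <- crossprod(X) / length(win)
  K <- (K + t(K)) / 2
  structure(list(K = K, n_frames_used = length(win),
                 atom_order = series$atom_order),
            class = "vw_covariance")
}

#' @export
print.vw_covariance <- function(x, ...) {
  cat(sprintf("<vw_covariance> %d x %d, trace = %.6g amu A^2/fs^2, %d frames\n",
              nrow(x$K), ncol(x$K), sum(diag(x$K)), x$n_frames_used))
  invisible(x)
}

#' Diagonalize a velocity-covariance matrix into generalized modes
#'
#' Generalized vibrational modes are the eigenvectors of the mass-weighted
#' velocity covariance matrix: collective coordinates with mutually
#' uncorrelated momenta, defined at any temperature without assuming a
#' quadratic potential. Columns of `L` are ordered by descending eigenvalue
#' (mode-velocity variance); each column's sign is fixed so its
#' largest-magnitude entry is positive; small negative eigenvalues within the
#' numerical floor are clamped to zero. Eigenvalues within relative spacing
#' `degeneracy_tol` are grouped into degenerate blocks (eigenvector direction
#' is arbitrary inside such a block).
#'
#' @param K a `vw_covariance` (or a plain symmetric matrix).
#' @param symmetry_tol maximum allowed relative asymmetry of the input.
#' @param degeneracy_tol relative eigenvalue spacing below which neighbouring
#'   modes are reported as one degenerate block.
#' @return Object of class `vw_modes`: `L` (3N x 3N orthonormal, columns =
#'   modes), `eigenvalues` (descending, >= 0), `frequencies` (cm^-1, `NA`
#'   until [assign_frequencies()]), `degeneracy` (integer block labels),
#'   `atom_order`.
#' @export
diagonalize <- function(K, symmetry_tol = 1e-12, degeneracy_tol = 1e-8) {
  atom_order <- NULL
  if (inherits(K, "vw_covariance")) {
    atom_order <- K$atom_order
    K <- K$K
  }
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  scale <- max(abs(K), .Machine$double.xmin)
  asym <- max(abs(K - t(K))) / scale
  if (asym > max(symmetry_tol, 1e-12) * 10) {
    stop(sprintf("matrix not symmetric: relative asymmetry %.3g", asym))
  }
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)        # eigen() returns descending order
  lam <- e$values
  floor_neg <- -1e-10 * sum(diag(K)) / nrow(K)
  lam[lam < 0 & lam >= floor_neg] <- 0
  lam[lam < 0] <- 0                       # clamp anything below as well; PSD by construction
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  # degenerate blocks: split where relative gap exceeds tolerance
  n <- length(lam)
  blocks <- integer(n)
  blk <- 1L
  blocks[1] <- blk
  for (j in seq_len(n - 1L)) {
    ref <- max(abs(lam[j]), abs(lam[j + 1L]), scale * .Machine$double.eps)
    if (abs(lam[j] - lam[j + 1L]) > degeneracy_tol * ref) blk <- blk + 1L
    blocks[j + 1L] <- blk
  }
  structure(list(L = L, eigenvalues = lam,
                 frequencies = rep(NA_real_, n),
                 degeneracy = blocks, atom_order = atom_order),
            class = "vw_modes")
}

#' @export
print.vw_modes <- function(x, ...) {
  n <- length(x$eigenvalues)
  cat(sprintf("<vw_modes> %d modes; eigenvalue range [%.4g, %.4g]\n",
              n, min(x$eigenvalues), max(x$eigenvalues)))
  if (!all(is.na(x$frequencies))) {
    fr <- x$frequencies[!is.na(x$frequencies)]
    cat(sprintf("  assigned frequencies: %d modes, %.1f - %.1f cm^-1\n",
                length(fr), min(fr), max(fr)))
  }
  invisible(x)
}

#' Project mass-weighted velocities onto generalized modes
#'
#' Computes the time-resolved mode velocities \eqn{\dot Q(t) = L' \dot q(t)}
#' per frame. Because `L` is orthonormal, the per-frame kinetic energy
#' \eqn{\sum_\alpha \dot Q_\alpha^2 = \sum_i \dot q_i^2} is conserved by the
#' projection.
#'
#' @param series a `vw_mwvel`.
#' @param modes a `vw_modes`.
#' @param mode_ids optional integer subset of modes to retain.
#' @param trajectory_id provenance label stored with the result.
#' @return Object of class `vw_modevel`: `times` (fs, starting at 0),
#'   `values` (`n_frames x n_modes`), `mode_ids`, `dt`, `trajectory_id`.
#' @export
project <- function(series, modes, mode_ids = NULL, trajectory_id = "traj") {
  stopifnot(inherits(series, "vw_mwvel"), inherits(modes, "vw_modes"))
  d_series <- ncol(series$values)
  d_modes <- nrow(modes$L)
  if (d_series != d_modes) {
    stop(sprintf("dimension mismatch: series has 3N = %d, modes have 3N = %d",
                 d_series, d_modes))
  }
  if (is.null(mode_ids)) mode_ids <- seq_len(ncol(modes$L))
  Q <- series$values %*% modes$L[, mode_ids, drop = FALSE]
  structure(list(times = series$times - series$times[1], values = Q,
                 mode_ids = as.integer(mode_ids), dt = series$dt,
                 trajectory_id = trajectory_id),
            class = "vw_modevel")
}

#' @export
print.vw_modevel <- function(x, ...) {
  cat(sprintf("<vw_modevel> '%s': %d frames x %d modes, dt = %g fs\n",
              x$trajectory_id, nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Assign a vibrational frequency to each generalized mode
#'
#' Per mode, projects the series, Fourier-transforms the velocity
#' autocorrelation function (see [power_spectrum()]) and takes the wavenumber
#' of the global spectral maximum. Modes with (numerically) zero velocity
#' variance get `NA`: no oscillation, no frequency.
#'
#' @param modes a `vw_modes`.
#' @param series the `vw_mwvel` the modes were derived from (or any series
#'   sharing their atom ordering).
#' @param max_lag autocorrelation lag cutoff in frames; default `n/2`.
#' @param taper taper applied to the autocorrelation, see [power_spectrum()].
#' @param pad_factor zero-padding factor for peak interpolation.
#' @param resolution_warn_cm1 emit a warning if the spectral bin width exceeds
#'   this value (assignment is still performed).
#' @return The `vw_modes` with `frequencies` (cm^-1) filled in.
#' @export
assign_frequencies <- function(modes, series, max_lag = NULL, taper = "hann",
                               pad_factor = 4L, resolution_warn_cm1 = 20) {
  stopifnot(inherits(modes, "vw_modes"), inherits(series, "vw_mwvel"))
  Q <- project(series, modes)
  nf <- nrow(Q$values)
  if (is.null(max_lag)) max_lag <- max(8L, nf %/% 2L)
  max_lag <- min(max_lag, nf - 1L)
  res_cm1 <- fs_to_cm1(1 / ((max_lag + 1L) * series$dt))
  if (res_cm1 > resolution_warn_cm1) {
    warning(sprintf(
      "window too short: spectral resolution %.1f cm^-1 exceeds %.1f cm^-1; assigning anyway",
      res_cm1, resolution_warn_cm1))
  }
  vars <- apply(Q$values, 2, function(v) mean(v^2))
  vmax <- max(vars)
  freqs <- rep(NA_real_, ncol(Q$values))
  for (j in seq_len(ncol(Q$values))) {
    if (vars[j] <= 1e-14 * vmax) next    # zero-variance mode: frequency undefined
    ac <- autocorrelation(Q$values[, j], max_lag)
    ps <- power_spectrum(ac, series$dt, window = taper, pad_factor = pad_factor)
    freqs[j] <- ps$wavenumbers[which.max(ps$power)]
  }
  modes$frequencies <- freqs
  modes
}

#' Per-atom composition of each generalized mode
#'
#' The displacement weight of atom a in mode alpha is
#' \eqn{\sum_k L_{3a+k,\alpha}^2}; weights over atoms sum to 1 per mode.
#'
#' @param modes a `vw_modes`.
#' @return Tibble with columns `mode`, `atom`, `element`, `weight`.
#' @export
mode_composition <- function(modes) {
  stopifnot(inherits(modes, "vw_modes"))
  n3 <- nrow(modes$L)
  na <- n3 %/% 3L
  out <- vector("list", ncol(modes$L))
  for (j in seq_len(ncol(modes$L))) {
    w <- colSums(matrix(modes$L[, j]^2, nrow = 3L))   # 3 x N_atoms columns
    out[[j]] <- tibble::tibble(
      mode = j, atom = seq_len(na),
      element = if (is.null(modes$atom_order)) NA_character_ else modes$atom_order,
      weight = w)
  }
  do.call(rbind, out)
}

#' Write a mode set to a directory of text tables
#'
#' Emits `eigen.tsv` (mode index, eigenvalue, frequency_cm-1),
#' `L_matrix.tsv` (dense 3N x 3N eigenvector matrix) and
#' `composition.tsv` (per-atom displacement weights).
#'
#' @param modes a `vw_modes`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_mode_set <- function(modes, dir) {
  stopifnot(inherits(modes, "vw_modes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eig <- data.frame(mode = seq_along(modes$eigenvalues),
                    eigenvalue = modes$eigenvalues,
                    `frequency_cm-1` = modes$frequencies,
                    degeneracy_block = modes$degeneracy,
                    check.names = FALSE)
  utils::write.table(format(eig, digits = 15, trim = TRUE),
                     file.path(dir, "eigen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(as.data.frame(modes$L), digits = 15, trim = TRUE),
                     file.path(dir, "L_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(mode_composition(modes)),
                     file.path(dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a mode set written by [write_mode_set()]
#' @param dir directory containing `eigen.tsv` and `L_matrix.tsv`.
#' @param atom_order optional element vector to attach.
#' @return A `vw_modes`.
#' @export
read_mode_set <- function(dir, atom_order = NULL) {
  eig <- utils::read.table(file.path(dir, "eigen.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  L <- as.matrix(utils::read.table(file.path(dir, "L_matrix.tsv"), sep = "\t"))
  dimnames(L) <- NULL
  structure(list(L = L, eigenvalues = eig$eigenvalue,
                 frequencies = eig[["frequency_cm-1"]] %||% eig[["frequency_cm.1"]],
                 degeneracy = eig$degeneracy_block,
                 atom_order = atom_order),
            class = "vw_modes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
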