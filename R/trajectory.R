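# trajectory container + extended-XYZ I/O

#' Construct a trajectory object
#'
#' A `vw_trajectory` holds an ordered set of MD frames with a uniform
#' timestep: per-atom element symbols, coordinates in Angstrom and (optionally)
#' velocities in Angstrom/fs. Coordinates and velocities are stored as
#' `n_frames x n_atoms x 3` arrays.
#'
#' @param elements character vector of chemical symbols, length `n_atoms`.
#' @param coordinates numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param dt timestep in fs (> 0).
#' @param velocities optional array with the same shape as `coordinates`
#'   (Angstrom/fs).
#' @param comments optional character vector of per-frame comment lines.
#' @param masses mass table used to validate that every symbol is resolvable.
#' @return Object of class `vw_trajectory`.
#' @export
trajectory <- function(elements, coordinates, dt, velocities = NULL,
                       comments = NULL, masses = mass_table()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number (fs)")
  }
  if (length(dim(coordinates)) != 3L || dim(coordinates)[3] != 3L) {
    stop("coordinates must be an n_frames x n_atoms x 3 array")
  }
  n_frames <- dim(coordinates)[1]
  n_atoms <- dim(coordinates)[2]
  if (n_frames < 1L || n_atoms < 1L) stop("trajectory must have >= 1 frame and >= 1 atom")
  if (length(elements) != n_atoms) {
    stop(sprintf("elements length (%d) must equal n_atoms (%d)",
                 length(elements), n_atoms))
  }
  lookup_masses(elements, masses)   # errors on unresolvable symbols
  if (!is.null(velocities) && !identical(dim(velocities), dim(coordinates))) {
    stop("velocities must have the same shape as coordinates")
  }
  if (is.null(comments)) comments <- rep("", n_frames)
  structure(
    list(elements = as.character(elements), coordinates = coordinates,
         velocities = velocities, dt = dt, comments = comments),
    class = "vw_trajectory"
  )
}

#' @export
print.vw_trajectory <- function(x, ...) {
  cat(sprintf("<vw_trajectory> %d atoms x %d frames, dt = %g fs, velocities %s\n",
              n_atoms(x), n_frames(x), x$dt,
              if (is.null(x$velocities)) "absent" else "present"))
  cat("  elements:", paste(utils::head(x$elements, 10), collapse = " "),
      if (n_atoms(x) > 10) "..." else "", "\n")
  invisible(x)
}

#' Trajectory dimensions
#' @param traj a `vw_trajectory`.
#' @return Integer scalar.
#' @export
n_atoms <- function(traj) dim(traj$coordinates)[2]

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$coordinates)[1]

#' Select a subset of atoms from a trajectory
#'
#' @param traj a `vw_trajectory`.
#' @param atoms integer indices (1-based) of atoms to keep.
#' @return A `vw_trajectory` restricted to the selected atoms.
#' @export
subset_atoms <- function(traj, atoms) {
  atoms <- as.integer(atoms)
  if (length(atoms) < 1L || any(atoms < 1L | atoms > n_atoms(traj))) {
    stop(sprintf("atom selection out of range 1..%d", n_atoms(traj)))
  }
  trajectory(
    elements = traj$elements[atoms],
    coordinates = traj$coordinates[, atoms, , drop = FALSE],
    dt = traj$dt,
    velocities = if (is.null(traj$velocities)) NULL else
      traj$velocities[, atoms, , drop = FALSE],
    comments = traj$comments
  )
}

# -- extended XYZ --------------------------------------------------------------
# Dialects accepted:
#   * comment line carrying Properties=species:S:1:pos:R:3[:vel:R:3 | :velo:R:3]
#   * plain columns: symbol x y z [vx vy vz]
# Velocities are per-atom columns 5-7 after x, y, z.

#' Read a multi-frame extended-XYZ trajectory
#'
#' Accepts the extended-XYZ `Properties=species:S:1:pos:R:3:vel:R:3` dialect as
#' well as plain 4- or 7-column frames (symbol, x, y, z, optionally vx, vy,
#' vz). All frames must have the same atom count and ordering.
#'
#' @param path file path.
#' @param dt timestep between frames in fs.
#' @param masses mass table for element validation.
#' @return A [trajectory()] object; velocities are populated when velocity
#'   columns are present in the file.
#' @export
read_xyz_trajectory <- function(path, dt, masses = mass_table()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  pos <- 1L
  frames <- list()
  comments <- character()
  elements0 <- NULL
  frame_idx <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("format error at frame %d: expected atom count, got '%s'",
                   frame_idx, lines[pos]))
    }
    if (pos + 1L + nat > length(lines)) {
      stop(sprintf("format error at frame %d: truncated frame (%d atom lines expected)",
                   frame_idx, nat))
    }
    comment <- lines[pos + 1L]
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol <- lengths(toks)
    if (any(ncol < 4L)) {
      stop(sprintf("format error at frame %d: atom line with < 4 fields", frame_idx))
    }
    has_vel <- all(ncol >= 7L)
    sym <- vapply(toks, `[[`, "", 1L)
    if (is.null(elements0)) {
      elements0 <- sym
    } else if (length(sym) != length(elements0) || !all(sym == elements0)) {
      stop(sprintf("format error at frame %d: atom count/order differs from frame 0",
                   frame_idx))
    }
    num <- matrix(suppressWarnings(as.numeric(unlist(lapply(toks, function(tk)
      tk[2:(if (has_vel) 7L else 4L)])))),
      nrow = nat, byrow = TRUE)
    if (anyNA(num)) {
      stop(sprintf("format error at frame %d: non-numeric coordinate/velocity field",
                   frame_idx))
    }
    frames[[frame_idx + 1L]] <- num
    comments[frame_idx + 1L] <- comment
    pos <- pos + 2L + nat
    frame_idx <- frame_idx + 1L
  }
  if (frame_idx == 0L) stop(sprintf("no frames found in %s", path))
  ncols <- vapply(frames, ncol, 0L)
  has_vel <- all(ncols == 6L)
  nf <- frame_idx
  nat <- length(elements0)
  coords <- array(NA_real_, c(nf, nat, 3L))
  vels <- if (has_vel) array(NA_real_, c(nf, nat, 3L)) else NULL
  for (f in seq_len(nf)) {
    coords[f, , ] <- frames[[f]][, 1:3, drop = FALSE]
    if (has_vel) vels[f, , ] <- frames[[f]][, 4:6, drop = FALSE]
  }
  trajectory(elements0, coords, dt, velocities = vels, comments = comments,
             masses = masses)
}

#' Write a trajectory as multi-frame extended XYZ
#'
#' Numeric fields are written with 15 significant digits so a read/write
#' round-trip preserves values to at least 12 significant digits. When the
#' trajectory carries velocities the comment line advertises
#' `Properties=species:S:1:pos:R:3:vel:R:3`.
#'
#' @param traj a `vw_trajectory`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "vw_trajectory"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "Properties=species:S:1:pos:R:3:vel:R:3"
           else "Properties=species:S:1:pos:R:3"
  for (f in seq_len(n_frames(traj))) {
    cmt <- traj$comments[f]
    if (!grepl("Properties=", cmt, fixed = TRUE)) {
      cmt <- trimws(paste(props, cmt))
    }
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(cmt, con)
    for (a in seq_len(n_atoms(traj))) {
      fields <- sprintf("%.15g", traj$coordinates[f, a, ])
      if (has_vel) fields <- c(fields, sprintf("%.15g", traj$velocities[f, a, ]))
      writeLines(paste(c(traj$elements[a], fields), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Estimate velocities from coordinates by central differences
#'
#' For position-only trajectories, v(t_k) = (x(t_{k+1}) - x(t_{k-1})) / (2 dt)
#' at interior frames; the first and last frames are dropped so that every
#' retained frame has a second-order-accurate velocity.
#'
#' @param traj a `vw_trajectory` without velocities and with >= 3 frames.
#' @return A `vw_trajectory` with `n_frames - 2` frames and velocities set.
#' @export
estimate_velocities <- function(traj) {
  stopifnot(inherits(traj, "vw_trajectory"))
  if (!is.null(traj$velocities)) stop("trajectory already has velocities")
  nf <- n_frames(traj)
  if (nf < 3L) stop(sprintf("insufficient data: need >= 3 frames, have %d", nf))
  interior <- 2:(nf - 1L)
  vel <- (traj$coordinates[interior + 1L, , , drop = FALSE] -
          traj$coordinates[interior - 1L, , , drop = FALSE]) / (2 * traj$dt)
  trajectory(traj$elements,
             traj$coordinates[interior, , , drop = FALSE],
             traj$dt, velocities = vel,
             comments = traj$comments[interior])
}

#' Mass-weight the velocities of a trajectory
#'
#' Builds the mass-weighted velocity series q-dot with components
#' \eqn{\dot q_{3a+k}(t) = \sqrt{m_a}\, v_{a,k}(t)} (atom-major,
#' component-minor flattening; units \eqn{\sqrt{amu}} Angstrom/fs). With
#' `remove_com_translation = TRUE`, the center-of-mass velocity is subtracted
#' from every atom per frame before weighting, which zeroes the total
#' mass-weighted momentum.
#'
#' @param traj a `vw_trajectory` with velocities present.
#' @param masses mass table.
#' @param remove_com_translation subtract the per-frame center-of-mass
#'   velocity before weighting?
#' @return Object of class `vw_mwvel`: list with `times` (fs), `values`
#'   (`n_frames x 3N` matrix), `dt`, `atom_order`.
#' @export
mass_weight <- function(traj, masses = mass_table(), remove_com_translation = FALSE) {
  stopifnot(inherits(traj, "vw_trajectory"))
  if (is.null(traj$velocities)) {
    stop("trajectory has no velocities: supply them or call estimate_velocities()")
  }
  m <- lookup_masses(traj$elements, masses)
  nf <- n_frames(traj); na <- n_atoms(traj)
  vel <- traj$velocities
  if (isTRUE(remove_com_translation)) {
    mtot <- sum(m)
    for (k in 1:3) {
      vcom <- (vel[, , k, drop = FALSE][, , 1] %*% m) / mtot   # nf x 1
      vel[, , k] <- vel[, , k] - as.vector(vcom)
    }
  }
  # flatten to nf x 3N with column index 3*(a-1)+k
  values <- matrix(NA_real_, nf, 3L * na)
  sq <- sqrt(m)
  for (k in 1:3) values[, seq.int(k, by = 3L, length.out = na)] <- vel[, , k] *
      rep(sq, each = nf)
  structure(
    list(times = (seq_len(nf) - 1L) * traj$dt, values = values, dt = traj$dt,
         atom_order = traj$elements),
    class = "vw_mwvel"
  )
}

#' @export
print.vw_mwvel <- function(x, ...) {
  cat(sprintf("<vw_mwvel> %d frames x %d coordinates (3N), dt = %g fs\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}
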