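# Internal unit system: Angstrom, femtosecond, amu.
# Energy unit is then amu * A^2 / fs^2; frequencies are fs^-1 internally and
# reported in cm^-1. All conversion factors live here (9-digit CODATA values)
# so that no other file contains a raw physical constant.

#' Physical constants and unit conversions
#'
#' The package works internally in Angstrom / femtosecond / amu units.
#' `vw_constants()` returns the conversion factors used throughout:
#' \describe{
#'   \item{cm1_per_inv_fs}{wavenumber (cm^-1) per fs^-1 of linear frequency,
#'     \eqn{10^{15} / c} with \eqn{c = 2.99792458 \times 10^{10}} cm/s,
#'     i.e. 33356.4095 cm^-1.}
#'   \item{kB}{Boltzmann constant in amu A^2 fs^-2 K^-1.}
#' }
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' vw_constants()$cm1_per_inv_fs
vw_constants <- function() {
  list(
    cm1_per_inv_fs = 1e15 / 2.99792458e10,       # 33356.4095 cm^-1 per fs^-1
    kB = 1.38064900e-23 / 1.66053907e-17          # J/K over J per amu*A^2/fs^2
  )
}

# frequency conversions -------------------------------------------------------

#' Convert between fs^-1 and cm^-1
#'
#' Linear frequency nu in fs^-1 maps to wavenumber nu/c in cm^-1.
#'
#' @param nu_fs frequency in fs^-1.
#' @param nu_cm wavenumber in cm^-1.
#' @return Numeric vector in the target unit.
#' @export
fs_to_cm1 <- function(nu_fs) nu_fs * vw_constants()$cm1_per_inv_fs

#' @rdname fs_to_cm1
#' @export
cm1_to_fs <- function(nu_cm) nu_cm / vw_constants()$cm1_per_inv_fs

# angular frequency (rad/fs) <-> wavenumber
omega_to_cm1 <- function(omega) fs_to_cm1(omega / (2 * pi))
cm1_to_omega <- function(nu_cm) 2 * pi * cm1_to_fs(nu_cm)

# mass table -------------------------------------------------------------------

# Standard atomic weights (amu), conventional values, common elements.
.standard_masses <- c(
  H = 1.008, D = 2.014, He = 4.002602,
  Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, Ne = 20.1797,
  Na = 22.989769, Mg = 24.305, Al = 26.981539, Si = 28.085, P = 30.973762,
  S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.0983, Ca = 40.078, Sc = 44.955908, Ti = 47.867, V = 50.9415,
  Cr = 51.9961, Mn = 54.938044, Fe = 55.845, Co = 58.933194, Ni = 58.6934,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.63, As = 74.921595,
  Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.4678, Sr = 87.62, I = 126.90447, Xe = 131.293, Cs = 132.905452,
  Ba = 137.327, Pt = 195.084, Au = 196.966569, Hg = 200.592, Pb = 207.2
)

#' Atomic mass table
#'
#' Returns the mapping from chemical symbol to atomic mass in amu. Built-in
#' standard atomic weights can be overridden or extended either with a named
#' numeric vector or with a two-column whitespace-separated text file
#' (symbol, mass).
#'
#' @param overrides named numeric vector of masses (amu), or `NULL`.
#' @param file path to a two-column text file (symbol mass), or `NULL`.
#' @return Named numeric vector, class `vw_mass_table`.
#' @export
#' @examples
#' mt <- mass_table(c(X = 10))
#' mt[["X"]]
mass_table <- function(overrides = NULL, file = NULL) {
  m <- .standard_masses
  if (!is.null(file)) {
    tab <- utils::read.table(file, header = FALSE, col.names = c("symbol", "mass"),
                             stringsAsFactors = FALSE)
    ov <- stats::setNames(as.numeric(tab$mass), as.character(tab$symbol))
    m[names(ov)] <- ov
  }
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    m[names(overrides)] <- overrides
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("mass table invalid: all masses must be finite and > 0")
  }
  structure(m, class = c("vw_mass_table", "numeric"))
}

# Resolve a vector of element symbols to masses, with a clear error on misses.
lookup_masses <- function(elements, masses = mass_table()) {
  idx <- match(elements, names(masses))
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop(sprintf("unknown element symbol(s): %s (no mass available)",
                 paste(bad, collapse = ", ")))
  }
  as.numeric(masses[idx])
}

# Run expr with a temporarily seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
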