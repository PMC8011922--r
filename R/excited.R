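# projection of excited-state (second-ensemble) trajectories onto
# ground-state generalized modes

#' Define an ensemble of second-state trajectories
#'
#' Members share atom ordering and timestep with the ground-state reference;
#' typically a handful of excited-state runs started from configurations and
#' momenta sampled along the equilibrium ground-state trajectory.
#'
#' @param members list of `vw_trajectory` objects, or a character vector of
#'   extended-XYZ paths.
#' @param dt timestep in fs (required when `members` are paths).
#' @param masses mass table used when reading paths.
#' @return Object of class `vw_ensemble` (list of trajectories + `dt`).
#' @export
ensemble_spec <- function(members, dt = NULL, masses = mass_table()) {
  if (is.character(members)) {
    if (is.null(dt)) stop("dt is required when members are file paths")
    members <- lapply(members, read_xyz_trajectory, dt = dt, masses = masses)
  }
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, TRUE, "vw_trajectory")))
  na <- vapply(members, n_atoms, 0L)
  dts <- vapply(members, `[[`, 0, "dt")
  if (length(unique(na)) != 1L) {
    stop(sprintf("ensemble members disagree on atom count: %s",
                 paste(unique(na), collapse = ", ")))
  }
  if (max(dts) - min(dts) > 1e-12 * max(dts)) {
    stop("ensemble members disagree on timestep dt")
  }
  el0 <- members[[1]]$elements
  for (i in seq_along(members)[-1]) {
    if (!identical(members[[i]]$elements, el0)) {
      bad <- which(members[[i]]$elements != el0)[1]
      stop(sprintf("ensemble member %d atom order differs from member 1 at atom %d (%s vs %s)",
                   i, bad, members[[i]]$elements[bad], el0[bad]))
    }
  }
  structure(list(members = members, dt = dts[1]), class = "vw_ensemble")
}

#' Project an ensemble onto ground-state generalized modes
#'
#' For each member, computes mass-weighted velocities and applies the
#' ground-state mode composition: \eqn{\dot Q_{ES}(t) = L' \dot q_{ES}(t)}.
#' The working assumption is that the ground-state mode composition still
#' holds near the Franck-Condon region, i.e. early in the relaxation. Each
#' member's time axis is zeroed at its first frame (the excitation instant).
#'
#' @param ensemble a [ensemble_spec()] (or list of `vw_trajectory`).
#' @param modes ground-state `vw_modes`.
#' @param masses mass table.
#' @param remove_com_translation passed to [mass_weight()].
#' @return List of `vw_modevel`, one per member, `trajectory_id` = `"es_<i>"`.
#' @export
project_ensemble <- function(ensemble, modes, masses = mass_table(),
                             remove_com_translation = FALSE) {
  if (!inherits(ensemble, "vw_ensemble")) ensemble <- ensemble_spec(ensemble)
  stopifnot(inherits(modes, "vw_modes"))
  if (!is.null(modes$atom_order)) {
    el <- ensemble$members[[1]]$elements
    if (length(el) != length(modes$atom_order) ||
        !identical(el, as.character(modes$atom_order))) {
      bad <- which(el != as.character(modes$atom_order))[1]
      if (is.na(bad)) bad <- min(length(el), length(modes$atom_order)) + 1L
      stop(sprintf("atom-order mismatch at index %d", bad))
    }
  }
  lapply(seq_along(ensemble$members), function(i) {
    tr <- ensemble$members[[i]]
    if (is.null(tr$velocities)) tr <- estimate_velocities(tr)
    mw <- mass_weight(tr, masses, remove_com_translation = remove_com_translation)
    project(mw, modes, trajectory_id = sprintf("es_%d", i))
  })
}

#' Truncate mode-velocity series to their common time window
#'
#' Ensemble members may differ in length; analyses that average across the
#' ensemble need a shared axis, so every series is cut to the shortest
#' member.
#'
#' @param series_list non-empty list of `vw_modevel`.
#' @return List with every member truncated to the minimum frame count.
#' @export
truncate_common_window <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  nmin <- min(vapply(series_list, function(s) nrow(s$values), 0L))
  lapply(series_list, function(s) {
    s$values <- s$values[seq_len(nmin), , drop = FALSE]
    s$times <- s$times[seq_len(nmin)]
    s
  })
}

#' Ensemble-averaged wavelet power map of one mode
#'
#' Computes the CWT of the selected mode's velocity in every ensemble member
#' and averages the power maps (incoherent average). Averaging |W|^2 rather
#' than the velocities preserves transient band intensity: raw velocities of
#' independent members carry uncorrelated phases and would cancel
#' destructively. The coherent alternative (average velocities first, one
#' CWT) is available via `average = "velocity"`.
#'
#' @param series_list list of `vw_modevel` sharing mode ordering.
#' @param mode index into the mode columns.
#' @param params [morlet_params()].
#' @param average `"power"` (default, incoherent) or `"velocity"` (coherent).
#' @return A `vw_spectrogram`.
#' @export
ensemble_spectrogram <- function(series_list, mode, params = morlet_params(),
                                 average = c("power", "velocity")) {
  average <- match.arg(average)
  series_list <- truncate_common_window(series_list)
  dt <- series_list[[1]]$dt
  if (average == "velocity") {
    v <- Reduce(`+`, lapply(series_list, function(s) s$values[, mode])) /
      length(series_list)
    return(cwt(v, params, dt, mode_id = mode))
  }
  maps <- lapply(series_list, function(s) cwt(s$values[, mode], params, dt,
                                              mode_id = mode))
  average_power(maps)
}

#' Write mode-velocity series as TSV
#'
#' Columns: `time_fs`, then one column per selected mode (`mode<i>`).
#'
#' @param series a `vw_modevel`.
#' @param path output path.
#' @param modes optional subset of mode columns.
#' @return Invisibly, `path`.
#' @export
write_mode_velocity_tsv <- function(series, path, modes = NULL) {
  if (is.null(modes)) modes <- seq_len(ncol(series$values))
  df <- data.frame(time_fs = series$times,
                   series$values[, modes, drop = FALSE])
  names(df)[-1] <- sprintf("mode%d", series$mode_ids[modes])
  utils::write.table(format(df, digits = 12, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
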