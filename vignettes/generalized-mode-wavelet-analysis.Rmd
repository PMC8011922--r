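---
title: "Generalized-mode wavelet analysis of MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized-mode wavelet analysis of MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibwave)
```

## The model

`vibwave` analyzes vibrational dynamics from MD velocities in three stages.

**Generalized modes.** For a trajectory with uniform timestep, the
mass-weighted velocity vector q̇(t) (components √m·v, units √amu·Å/fs) is
accumulated into the second-moment matrix K with elements
⟨q̇ᵢ q̇ⱼ⟩ averaged over frames. K is a *raw* second moment, not a
mean-centered covariance: the averaged quantity is a velocity, whose mean
vanishes for bound equilibrium motion (and identically once center-of-mass
translation is removed), and the raw form is what the projection algebra
assumes. Diagonalizing K gives orthonormal mode vectors (columns of L) with
mutually uncorrelated mode velocities Q̇ = Lᵀq̇. Because L is orthonormal,
per-frame kinetic energy is conserved by the projection and
Σ var(Q̇) = tr K exactly — the package tests both identities to 1e-10.
No quadratic potential is assumed anywhere, which is the point: the mode
frequencies are the anharmonic ones the trajectory actually explores.

**Frequency assignment.** Each mode's frequency is the global maximum of the
power spectrum of its velocity autocorrelation function (unbiased
normalization, Hann taper, 4x zero-padding for peak interpolation). Modes
with numerically zero velocity variance get `NA`: no motion, no frequency.
The spectral bin width is 1/(max_lag·dt); `assign_frequencies()` warns when
it exceeds 20 cm⁻¹ but still assigns.

**Time–frequency localization.** A second ensemble (e.g. excited-state
trajectories started from equilibrium snapshots; t = 0 is each member's
first frame) is projected with the *ground-state* L — the standard
Franck–Condon-region approximation, valid while the force pattern has not
rearranged. Each mode-velocity series is then transformed with the
continuous Morlet wavelet ψ(t) = π^(−1/4)·e^(iω₀t)·e^(−t²/2), without the
admissibility correction term, which is below 1e-7 for the default ω₀ = 6
(the usual time/frequency compromise). Scales map to wavenumbers by the
center-frequency convention ν = ω₀/(2πa).

## Numerical choices

- **CWT discretization.** The transform W(a,b) = a^(−1/2) Σ x(t)ψ*((t−b)/a)dt
  is evaluated as a circular FFT convolution of the zero-padded signal with
  the *time-sampled* Morlet kernel. The padding covers eight Gaussian
  e-foldings of the largest scale, so periodization leakage is below 1e-12
  and the FFT route reproduces the direct double sum to machine precision —
  the suite's core anti-bug property, checked against a brute-force oracle.
  Sampling the kernel in time (rather than using the continuous-frequency
  Gaussian) is what makes the two routes identical rather than merely close.
- **Cone of influence.** A cell is edge-contaminated when the Gaussian
  e-folding time √2·a reaches past the nearer signal edge; the spectrogram
  stores, per time column, the lowest trustworthy wavenumber, and keeps the
  contaminated cells rather than trimming them. Note a hard boundary is a
  convention, not a cliff: a pure tone's band power is attenuated by roughly
  12% *at* the one-e-folding boundary and becomes flat (to 5% and far
  better) by two e-foldings; kinetics read near the map edges should be
  treated accordingly.
- **Frequency grid.** Default 150 logarithmic scales over 50–2000 cm⁻¹:
  log spacing gives uniform relative resolution, and the lower bound avoids
  the ν → 0 scale divergence. `freq_max` must stay below the Nyquist
  wavenumber 1/(2dt); the error message names it.
- **Ensemble averaging.** Power maps (|W|²) are averaged, not velocities:
  members of an ensemble carry uncorrelated phases, and a coherent velocity
  average cancels exactly the transient oscillations of interest. The
  coherent variant remains available (`average = "velocity"`) for
  phase-locked inputs. The combined cone of influence takes the least
  trustworthy bound per column.
- **Reporting scale.** |W|² is in arbitrary units; the CLI and exports
  normalize each map to its maximum by default (flag to disable), while the
  library functions return raw linear power so that amplitude-squared
  scaling and averaging identities hold.
- **Degeneracy and signs.** Eigenvalues within relative spacing 1e-8 are
  reported as one degenerate block — eigenvector direction inside a block is
  arbitrary, and tests on degenerate systems should compare subspaces, not
  vectors. Each mode's sign is fixed by making its largest-magnitude
  component positive.
- **Units.** Å, fs, amu internally; wavenumbers via
  1 fs⁻¹ = 10¹⁵/c ≈ 33356.41 cm⁻¹; Boltzmann constant in amu·Å²/fs²/K.
  All constants live in `vw_constants()`.
- **Global rotation** is not removed (only optional center-of-mass
  translation removal is offered): rotational contamination sits below
  ~100 cm⁻¹ and is readily distinguished in the spectra, while removing it
  would entangle the mode algebra with an Eckart-frame choice.
- **Position-only inputs.** When velocity columns are absent,
  `estimate_velocities()` uses central differences and drops both endpoint
  frames, keeping a uniform second-order accuracy (relative error bounded by
  (ω·dt)²/6 for a mode at ω) rather than mixing in first-order one-sided
  estimates.
- **Atom scope.** Whether solvent atoms belong in K is system-dependent; the
  tools default to all atoms in the file and expose an atom-subset selection
  (`subset_atoms()`, CLI `--select "atoms 1-3"`) for solute-only analyses.
- **Averaging window.** The covariance window is exposed as `frame_range`;
  shorter windows trade frequency resolution for stationarity, and the
  resolution consequence surfaces through the `assign_frequencies()`
  warning.

## The synthetic generators: what they emulate, and what they do not

Every stage is testable without electronic structure via three generators,
all exactly reproducible under a seed.

**Coupled harmonic systems** (`harmonic_model()`, `harmonic_chain()`,
`sample_harmonic_trajectory()`): arbitrary symmetric PSD force-constant
matrices with analytic normal modes as oracle. Trajectories are generated
*analytically per mode* — exact sinusoids, no integrator error — so
recovery tests compare against the oracle up to rounding plus finite-window
statistics only. Mode energies default to a deterministic interleaved
ladder within 8% of kT. This is a deliberate departure from literal thermal
sampling: a single analytic trajectory fixes each mode's energy forever, and
exactly equal energies make K isotropic on the vibrational subspace, where
eigenvectors are undefined; a Boltzmann draw, conversely, can hand two
spectrally adjacent modes nearly equal energies, leaving their eigenvectors
mixed by the residual finite-window cross-correlation (which decays only as
1/(Δω·T)). The ladder keeps every mode's time-averaged kinetic energy
within the equipartition envelope (kT/2 ± 8%) while guaranteeing the
eigenvalue gaps that make the composition identifiable, independent of
seed. `"fixed"` and `"boltzmann"` sampling remain available, and explicit
`mode_energy` / `activation_time` vectors support mode-selective and
delayed-onset experiments (the onset is a velocity step: silent before,
full amplitude after).

**Morse oscillators** (`sample_morse_trajectory()`): 1-D anharmonic motion
integrated with velocity Verlet at `dt/substeps` (default 100 substeps,
keeping relative energy oscillation below 1e-6). The exact classical
frequency ω(E) = ω₀√(1 − E/D) is the oracle for the red-shift tests; the
initial energy is given as a fraction of the well depth, and values ≥ 1 are
rejected as unbound.

**Nonstationary switch signals** (`make_switch_signal()`): a sinusoid whose
frequency jumps at a known time, phase-continuous at the switch, with
optional seeded Gaussian noise — ground truth for time-localization tests
(the measured half-rise of the new band must land within the Morlet time
resolution 2√2·a of the switch).

What these generators do *not* emulate: mode–mode anharmonic coupling,
energy flow between modes, spectral diffusion, finite-temperature frequency
shifts, or solvent friction. Passing tests therefore demonstrate that the
*analysis* is correct and well-conditioned — not that real ES trajectories
satisfy the ground-state-composition assumption, which remains a physics
judgement about the system under study.

## Problem sizes used in tests and the acceptance script

Mode recovery uses the 5-atom chain (springs 0.09/0.02/0.008/0.08 amu/fs²
on H–C–O–C–H; analytic frequencies 150.1–1652.7 cm⁻¹) with 2¹⁵ frames at
dt = 0.5 fs — about 74 periods of the slowest mode, enough for sub-percent
frequency recovery with the finite-window cross-terms decayed to the 1e-3
level. The CWT oracle comparison runs 256 frames × 16 scales (the direct
double sum is O(n²·n_scales)); localization tests use 4096 frames × 120
scales; Morse runs use 8192–16384 frames at dt = 0.25 fs. The whole suite
completes in well under a minute on one CPU.

## Known limitations

- Extended-XYZ only (velocities in columns 5–7, `Properties` dialect or
  plain 7-column); no PDB/DCD/TRR, no periodic-boundary unwrapping.
- The equilibrium second moment assumes a stationary, bound trajectory;
  drifting inputs should have center-of-mass translation removed.
- Ground-state L applied to excited-state velocities is an early-time
  approximation; the package offers no test of when it breaks down.
- No Raman/IR intensity weighting: maps are kinetic-energy power, so band
  intensities are comparable across time within a mode, not across modes to
  experiment.
- Frequency assignment picks the global spectral maximum; for strongly
  mixed or overtone-dominated modes inspect the full spectrum
  (`equilibrium_spectrum()`, `autoplot()`) rather than trusting the single
  number.
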