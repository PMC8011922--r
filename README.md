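# vibwave

Time-resolved vibrational analysis of molecular-dynamics trajectories:
generalized normal modes from the velocity covariance matrix, excited-state
mode projection, and Morlet-wavelet time–frequency maps.

## The problem

Transient vibrational spectroscopies (e.g. femtosecond stimulated Raman)
watch individual vibrational bands rise and decay during ultrafast
relaxation. To interpret such kinetics from simulation one needs, for each
molecular vibration, *when* it is active and *at what frequency* — not just
the time-averaged spectrum. `vibwave` implements that analysis for anyone
with MD trajectories in hand (ab initio or classical), with no electronic
structure or Hessian required.

## The method

Let q̇(t) be the 3N-vector of mass-weighted atomic velocities,
q̇\_{3a+k} = √m\_a · v\_{a,k}. Its second-moment matrix over an equilibrium
trajectory,

    K_ij = ⟨ q̇_i(t) q̇_j(t) ⟩_t ,

is symmetric positive-semidefinite. Its eigenvectors, collected in the
orthonormal matrix **L**, define *generalized modes*: collective coordinates
with mutually uncorrelated momenta. Unlike harmonic normal modes they are
defined at any temperature and assume no quadratic potential, so they carry
intrinsically anharmonic frequencies. Projection gives time-resolved mode
velocities Q̇(t) = **L**ᵀ q̇(t); each mode's frequency is the peak of the
Fourier transform of its velocity autocorrelation function.

For a second ensemble — typically excited-state trajectories launched from
snapshots of the equilibrium run — the same ground-state composition is
applied, Q̇\_ES(t) = **L**ᵀ q̇\_ES(t), valid near the Franck–Condon region.
Each mode velocity is then localized in time *and* frequency with the
continuous wavelet transform

    W(a, b) = a^(-1/2) ∫ Q̇(t) ψ*((t − b)/a) dt ,
    ψ(t) = π^(-1/4) exp(iω₀t) exp(−t²/2)        (Morlet, ω₀ = 6),

where the scale a ∝ 1/frequency (ν = ω₀/2πa) and the translation b is the
time axis. The power |W(ν, t)|² is the intensity of the instantaneous
frequency contribution; ensemble members are averaged on power (incoherent),
and band kinetics are read off as frequency-integrated power vs time.

## Worked example

Ground-state modes of a 5-atom harmonic chain (analytic frequencies 150.1,
295.4, 1557.6, 1652.7 cm⁻¹), then an "excited-state" ensemble in which the
1557.6 cm⁻¹ mode switches on 400 fs after excitation:

```r
library(vibwave)

model <- harmonic_chain(c("H", "C", "O", "C", "H"),
                        k = c(0.09, 0.02, 0.008, 0.08),   # amu/fs^2
                        temperature = 300, dt = 0.5,
                        n_frames = 32768, seed = 1)
traj  <- sample_harmonic_trajectory(model)
qdot  <- mass_weight(traj)
modes <- assign_frequencies(diagonalize(compute_covariance(qdot)), qdot)
tidy(modes)
#> # A tibble: 15 × 4
#>    mode eigenvalue frequency_cm1 degeneracy_block
#>   <int>      <dbl>         <dbl>            <int>
#> 1     1   2.70e- 4          150.                1
#> 2     2   2.56e- 4         1557.                2
#> 3     3   2.43e- 4          295.                3
#> 4     4   2.29e- 4         1653.                4
#> 5     5   3.68e-19           NA                 5
#> # i 10 more rows
```

The four vibrations are recovered within 0.1% of the analytic values
(eigenvalues are mode-velocity variances in amu Å²/fs²; the 11 silent modes
are the unexcited y/z directions and the translation). Now the transient:

```r
activation <- rep(0, 15); activation[2] <- 400      # switch mode 2 on at 400 fs
es <- lapply(1:5, function(i) {
  m <- harmonic_chain(c("H", "C", "O", "C", "H"), k = c(0.09, 0.02, 0.008, 0.08),
                      temperature = 300, dt = 0.5, n_frames = 4096, seed = 100 + i)
  sample_harmonic_trajectory(m, activation_time = activation)
})
series <- project_ensemble(ensemble_spec(es), modes)
params <- morlet_params(n_scales = 120, freq_min = 100, freq_max = 2000)
pmode  <- which.min(abs(modes$frequencies - 1557.6))
map    <- ensemble_spectrogram(series, pmode, params)   # 5-member power average
kin    <- band_intensity(map, 1557.6, 40)               # band kinetics

plateau <- mean(kin$power[kin$time_fs > 900 & kin$time_fs < 1800])
kin$time_fs[which(kin$power >= plateau / 2 & kin$time_fs >= 50)[1]]
#> [1] 410.5
```

The 1557 cm⁻¹ band's half-rise is found at 410.5 fs — 10.5 fs from the true
activation, well inside the Morlet time resolution at that frequency
(2√2·a ≈ 58 fs). `autoplot(map)` draws the frequency-vs-time heat map with
the cone of influence; `autoplot(modes)` and `tidy()`/`glance()` methods
cover the other result types.

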