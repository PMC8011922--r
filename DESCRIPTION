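Package: vibwave
Title: Time-Resolved Vibrational Analysis of MD Trajectories via
    Generalized Modes and Morlet Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives generalized vibrational modes from the covariance matrix of
    mass-weighted atomic velocities of an equilibrium molecular-dynamics
    trajectory, projects velocities from excited-state (or any second-ensemble)
    trajectories onto those modes, and localizes each mode's vibrational signal
    in both time and frequency with a continuous Morlet wavelet transform.
    Includes an extended-XYZ trajectory reader/writer, equilibrium
    velocity-autocorrelation spectra, synthetic harmonic, Morse and
    nonstationary signal generators with analytic ground truth, broom-style
    tidiers, ggplot2 autoplot methods, and a command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    generics,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
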