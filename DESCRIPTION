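Package: nuqspec
Title: Nuclear-Ensemble Absorption Spectra with Quantum-Corrected Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing electronic absorption spectra from
    ensembles of vertical excitations (the nuclear ensemble method).
    Includes generalized smoothed trajectory analysis (GSTA), a
    Fourier-domain convolution filter that imprints quantum
    harmonic-oscillator amplitudes onto classical molecular-dynamics
    trajectories; harmonic Wigner and classical thermal configurational
    samplers with potential-energy diagnostics; statistically optimal
    Gaussian broadening of stick spectra selected by leave-one-out
    cross-validation; Marcus-theory solvent broadening; axis conversion
    and window normalization; and desk-scale toy chromophore models
    (Langevin dynamics on harmonic and Morse surfaces, a displaced
    harmonic oscillator with a closed-form Franck-Condon oracle) for
    end-to-end validation of the spectral pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
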