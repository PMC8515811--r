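---
title: "Nuclear-ensemble absorption spectra with quantum-corrected trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-ensemble absorption spectra with quantum-corrected trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuqspec)
```

## The method

The nuclear ensemble estimate of an absorption spectrum replaces the full
vibronic calculation by an average over ground-state nuclear
configurations: for each sampled geometry one computes the vertical
excitation energies $X_i$ and oscillator strengths $Y_i$, and the
spectrum is the per-snapshot average of Gaussian-broadened sticks,

$$\hat s(x) \;=\; \frac{1}{N_{\text{snap}}}\sum_i Y_i\, K_\Delta(x - X_i),$$

with $K_\Delta$ the unit-area Gaussian density of standard deviation
$\Delta$ (eV). This captures inhomogeneous broadening — the spread of
excitation energies across the sampled conformations and environments —
but not vibronic fine structure or lifetime broadening, which are outside
this package's scope.

Two design problems dominate in practice, and they are the two things
`nuqspec` automates.

### Quantum-corrected sampling (GSTA)

A classical thermostated trajectory samples each harmonic mode with
variance $k_BT/m\omega^2$; the true quantum variance is larger by

$$w(\nu) \;=\; \frac{\beta h\nu}{2}\coth\frac{\beta h\nu}{2} \;\ge\; 1,$$

the ratio of quantum to classical harmonic-oscillator energies. At
300 K, $w \approx 7.2$ for a 3000 cm$^{-1}$ X–H stretch: classical
ensembles are far too narrow in exactly the coordinates that matter for
spectral broadening. A cheap lower estimate of the amplitude mismatch is
$\sqrt{E_{\text{ZPV}}/E_{\text{th}}} = \sqrt{(h\nu/2)/k_BT}$, between 2
and 3 for X–H stretches at room temperature
(`amplitude_ratio_lower_estimate()`).

Generalized smoothed trajectory analysis repairs this *after the fact*:
the trajectory is convolved with a finite moving-window kernel whose
amplitude response at frequency $\nu$ is $\sqrt{w(\nu)}$. The square
root is deliberate: $w$ is an *energy* ratio and energy is quadratic in
amplitude, so a $\sqrt{w}$ gain in coordinates produces a $w$-fold gain
in variance — verified in the test suite by filtering a long classical
Langevin trajectory of a harmonic oscillator and recovering the quantum
coordinate variance $(\hbar/2m\omega)\coth(\beta\hbar\omega/2)$ to
within 5%. Because $w(0)=1$, slow conformational motion, which the
harmonic Wigner picture handles poorly, passes through unchanged; this
is the practical advantage of MD + filtering over Wigner sampling for
floppy molecules.

Construction details (`build_gsta_kernel()`):

* The taps are the inverse DFT of $\sqrt{w(\nu_k)}$ over the window's
  own discrete frequency grid, folded symmetrically about Nyquist. No
  taper is applied; the discretization error at resolvable frequencies
  is bounded in the tests at 2%.
* The window must be odd so the filter is centered; the default is 241
  frames at a 0.5 fs timestep, i.e. a 120 fs window, long enough to
  resolve frequencies down to a few hundred cm$^{-1}$ at spectroscopic
  accuracy.
* The half-window at each trajectory end is discarded, not padded:
  padding would invent data and bias variance-based checks. Filtering
  therefore costs $(\text{window}-1)$ frames.
* $x\coth x$ is evaluated with a series branch below $10^{-4}$, an
  `expm1`-based form in the body, and the asymptote $x$ above 350, so
  short windows whose Nyquist bin sits deep in the zero-point regime
  cannot overflow.
* DC gain is exactly 1, so time averages of constant or periodic
  signals are preserved exactly; for a generic finite signal the
  discard-ends policy changes the mean at the partial-period level,
  which is why the mean-preservation test uses a constant and a
  sinusoid rather than noise.

### Choosing the broadening width by cross-validation

$\Delta$ is a smoothing parameter, not a physical width: it should
vanish as the number of sticks grows, and it should never be fitted to
the experimental spectrum one is trying to predict. `nuqspec` selects it
in two steps. For a candidate $\Delta$, the best global amplitude
mapping the kernel sum back onto the stick strengths minimizes the mean
squared error and has the closed form
$a(\Delta) = \sum_i Y_i\hat s(X_i)\big/\sum_i \hat s(X_i)^2$
(`fit_amplitude()`). With $a(\Delta)$ fixed, the leave-one-out score

$$L_{cv}(\Delta) \;=\; \sum_i \bigl(Y_i - a(\Delta)\,\hat s_{-i}(X_i)\bigr)^2$$

is minimized over a log-spaced grid with golden-section refinement of
the best interior bracket (relative tolerance $10^{-3}$), ties broken
toward smaller $\Delta$ (`optimize_bandwidth()`). The deleted-point sum
$\hat s_{-i}$ is obtained by subtracting the self-term $Y_iK_\Delta(0)$,
which is algebraically identical to the brute-force per-point refit — an
equivalence the tests assert to $10^{-10}$. The kernel convention
(unit-area vs unit-height) rescales $a$ by $\Delta\sqrt{2\pi}$ but
leaves $L_{cv}$, and hence the selected width, unchanged.

Degenerate inputs are flagged rather than hidden: if the loss is
minimal at a boundary of the scanned range — which includes the exactly
flat loss of a coincident pair of sticks, and also the case of strictly
constant strengths discussed below — the scan carries a
`boundary_warning`.

Plotted spectra use the plain per-snapshot-averaged kernel sum, with
$a(\Delta)$ confined to the CV objective. Area-normalized shapes make
the two presentations identical, and the plain sum keeps the exact
conservation law: the curve integral equals the per-snapshot mean total
oscillator strength at any $\Delta$. Single-geometry spectra
(`single_point_spectrum()`) take a caller-supplied width, defaulting to
the 0.14 eV that single-point calculations empirically need to mimic
ensemble broadening; that default is a documented constant, not a
computed optimum. An optional absolute-units mode is deliberately
absent: all comparisons in the package are made on normalized shapes,
so the cross-section prefactor would be an unused constant.

### Samplers and diagnostics

`sample_wigner()` draws each mass-weighted normal coordinate from the
thermal harmonic Wigner marginal, a zero-mean Gaussian of variance
$(\hbar/2\omega)\coth(\beta\hbar\omega/2)$ (coordinates only — momenta
are irrelevant for vertical excitations); `sample_classical()` uses the
Boltzmann marginal $k_BT/\omega^2$. Their per-mode variance ratio is
$w(\nu)$, tying the samplers to the GSTA filter through one formula.
`potential_energy_distribution()` evaluates the harmonic energy of each
sample and moment-matches a gamma law: classical sampling of $M$ modes
must give shape $M/2$ and scale $k_BT$ (the $\chi^2$ identity), while
Wigner sampling at 0 K must average half the zero-point energy per mode.
Moment matching is used instead of maximum likelihood because it is
deterministic and closed-form — adequate for a diagnostic. The
distribution "width" reported is a standard deviation; FWHM conventions
differ and are not used.

## The toy models and what they do (and do not) emulate

The synthetic layer replaces expensive electronic-structure stages with
analytically solvable stand-ins:

* **Langevin dynamics** (`simulate_langevin()`, BAOAB splitting) on the
  harmonic ground state of a DHO chromophore, a Morse well, or a
  normal-mode surface. BAOAB is used because its configurational
  sampling accuracy is excellent and it needs a single friction
  parameter; the choice of thermostat is irrelevant to the
  post-processing being validated. Defaults: 300 K, dt = 0.5 fs
  (1/23 of the default DHO vibrational period), $2\times10^5$ steps
  (100 ps), friction 0.05 fs$^{-1}$ — weak enough to leave the
  vibrational line narrow, strong enough to decorrelate the ~2000
  snapshots taken at the every-100th-frame cadence. Integration is
  refused above period/5 and warned above period/10.
* **DHO vertical excitations** (`dho_vertical_excitation()`): the gap
  between two identical displaced harmonic surfaces is linear in the
  coordinate, $E(x) = E_{00} + S\hbar\omega - m\omega^2 d\,x$ with
  $d = \sqrt{2S\hbar/m\omega}$, and the oscillator strength is constant
  (Condon). Default toy parameters ħω = 0.18 eV, S = 1, E₀₀ = 3.0 eV —
  a mid-UV organic chromophore with a single dominant
  vibronically-active mode.
* **The Franck–Condon oracle** (`fc_dho_oracle()`): the exact Poisson
  progression at 0 K (truncated at cumulative intensity
  $1-10^{-10}$) and exact closed-form band moments at any temperature,
  $\langle E\rangle = E_{00}+S\hbar\omega$ and
  $\mathrm{Var} = S(\hbar\omega)^2\coth(\beta\hbar\omega/2)$ (moments
  are never computed from the truncated sticks). The central validation
  of the package is *pipeline closure*: Langevin sampling + GSTA +
  linear-gap excitations reproduces these moments, the classical branch
  is narrower by exactly $\sqrt{w(\omega)}$, and Wigner sampling of the
  same mode gives the same Gaussian moments — three routes, one answer.
* **Morse overextension** (`morse_overextension_fraction()`): harmonic
  samplers applied to a dissociative well produce a tail of unphysically
  stretched geometries; the Wigner tail always dominates the classical
  one. This is a qualitative analogue of harmonic-Wigner failure on
  real anharmonic molecules, checked against Gaussian tail integrals —
  no claim is made about any specific molecule's fragmentation
  statistics.

What the toys deliberately do **not** emulate: anharmonic mode
coupling, solute–solvent electronic coupling, non-Condon strength
variation, multiple electronic states, and the conformational
heterogeneity of real solutes. Passing the closure tests shows the
*post-processing machinery* is exact for the model class it assumes
(harmonic modes, linear gaps); it does not certify any electronic
structure method.

One consequence of the Condon choice is worth stating plainly: with
strictly constant strengths, $Y$ versus $X$ is a flat envelope, so
$L_{cv}$ keeps improving as the kernel flattens the sampled density and
the scan terminates at the upper boundary of the range (with its
warning) for the classical and quantized ensembles alike. The
kernel-width robustness check in the acceptance suite therefore holds
trivially at the selected widths, and is complemented by a
non-degenerate probe: doubling the kernel width across the
0.02–0.09 eV scale that realistic ensembles select changes the
quantized band's second moment by under 5% — the ensemble, not the
kernel, carries the broadening.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| window | `build_gsta_kernel` | 241 frames | 120 fs at dt = 0.5 fs; resolves modes ≥ ~300 cm⁻¹ |
| dt | trajectory/config | 0.5 fs | ~1/20 of an X–H stretch period |
| temperature | kernel, samplers, MD | 300 K | ambient |
| friction | `toy_md_config` | 0.05 fs⁻¹ | snapshot decorrelation vs spectral narrowness |
| every | `dho_excite_trajectory` | 100 frames | 50 fs between snapshots |
| delta range | `optimize_bandwidth` | 0.005–0.5 eV | brackets widths real ensembles select |
| delta | `single_point_spectrum` | 0.14 eV | empirical single-point default |
| window | `normalize_window` | 300–700 nm | the visible/near-UV comparison window |

Units are fixed package-wide: Å, fs, eV, cm⁻¹, amu, K; every conversion
goes through the exported `nuq_constants` (CODATA-derived), and the
internal dynamics energy unit is 1 amu Å²/fs² = 103.64 eV.

## Numerical choices and edge cases

* Orthonormality of mass-weighted mode displacements is validated to
  $10^{-6}$ on construction and on file read; imaginary frequencies are
  rejected.
* XYZ parsing enforces identical atom sets and ordering across frames
  and reports the offending frame/line; readers never reorder records.
* Kernel taps are symmetrized after the inverse DFT to remove
  rounding-level asymmetry; tap sums are exactly 1 by construction
  ($w(0)=1$).
* `optimize_bandwidth` stores the refined point inside its scan, so the
  reported optimum is always the argmin of the stored losses.
* The convergence diagnostic (`convergence_profile()`) compares
  unit-area curves from the first $k$ snapshots (and optionally random
  subsets under a seed) against the full ensemble, under max-abs or L1
  distance.
* All stochastic operations take explicit seeds and restore the
  caller's RNG state.

## Problem sizes used in validation

The shipped tests run the full pipeline at $2\times10^5$ Langevin steps
(~2000 snapshots), bandwidth scans on up to 2000 sticks over 20 seeds,
and sampler diagnostics at $2\times10^4$ samples for up to 100 modes —
sizes chosen so the whole suite completes in about two minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* GSTA is exact only for harmonic modes; for strongly anharmonic or
  diffusive coordinates the $\sqrt{w}$ gain is an approximation, and
  the package makes no attempt to correct mode-coupled anharmonicity.
* The filter acts on coordinates only; filtered velocities/forces for
  thermodynamic applications are out of scope.
* Bandwidth selection needs strength variation across the sticks;
  strictly flat envelopes are detected (`boundary_warning`) but the
  returned boundary width is then a range artifact, not an optimum.
* The DHO stand-in has a single mode and two states; vibronic structure
  beyond its Poisson progression, lifetime broadening and non-Condon
  effects are not modeled.
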