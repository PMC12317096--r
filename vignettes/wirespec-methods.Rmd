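---
title: "Models and numerical methods in wirespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in wirespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wirespec analyses molecular-dynamics trajectories of quasi-one-dimensional
water chains ("water wires") in cylindrical confinement, the arrangement
water adopts inside sub-nanometre carbon nanotubes.  The package covers the
full observable chain from raw positions and velocities to third-order
nonlinear spectroscopy: axial diffusion, dipole reorientation, vibrational
density of states, instantaneous OH-stretch frequencies by continuous
wavelet transform, their distributions and correlations, 2D-IR correlation
spectra, and photon-echo observables, together with hydrogen-bond
statistics.  Because ab initio trajectories of such systems are expensive
and rarely deposited, the package ships a synthetic-data module: a minimal
flexible-water force field that reproduces the *statistical structure* of a
confined wire, plus exact stochastic processes with closed-form statistics
that serve as analytic oracles for every spectroscopy stage.  This vignette
records the models, the tunable parameters, and the numerical decisions.

## Units

Internally: Angstrom, femtosecond, amu, kcal/mol.  Frequencies are reported
in wavenumbers via $\tilde\nu\,[\mathrm{cm^{-1}}] = \nu\,[\mathrm{fs^{-1}}]/c$
with $c = 2.99792458\times10^{-5}$ cm/fs; phase integrals use angular
frequencies in rad/fs ($\omega = 2\pi c\tilde\nu$).  Diffusion coefficients
are reported in $10^{-10}\,\mathrm{m^2\,s^{-1}}$ ($1\,\mathrm{\AA^2/ps} =
100\times10^{-10}\,\mathrm{m^2\,s^{-1}}$).

## Trajectories

Extended-XYZ is the only trajectory format (`read_xyz_trajectory()`,
`write_xyz_trajectory()`); frames must share atom count and order and a
uniform timestep.  The O-H topology is inferred once, from frame 1 (each H
to its nearest O within 1.2 A), and never updated: transient proton
excursions must not relabel an OH mode mid-run, since every downstream
observable is a property of a *fixed* local OH oscillator.  Coordinates are
stored wrapped into $[0, L)$ on periodic axes; displacement-based analyses
operate on unwrapped copies (`unwrap_axis()` folds inter-frame jumps larger
than half the box).  A `stride` parameter is exposed where subsampling is
sensible (wavelet analysis defaults to every 2nd frame; at a 1 fs sampling
the ~9.5 fs OH-stretch period is still oversampled more than 4-fold).

## The toy water wire

`generate_water_wire()` integrates a deliberately minimal flexible 3-site
water model: a Morse O-H stretch, harmonic H-O-H bend, SPC/Fw-style site
charges and O-O Lennard-Jones between molecules, and a flat-bottom harmonic
radial wall standing in for the pore; there are no explicit wall atoms, no
Ewald summation (minimum image on the periodic axis only, with
*shifted-force* truncation so force and potential vanish continuously at
the cutoff -- without this the minimum-image switch would destroy NVE energy
conservation), no polarizability and no nuclear quantum effects.  The goal
is statistical structure -- a continuous hydrogen-bonded single file in
which each water donates about one hydrogen bond and keeps one dangling OH
-- not fidelity to any particular electronic-structure method.

The Morse stretch is the one deliberately *physical* ingredient: its
anharmonicity makes the stretch frequency fall as the bond elongates, and
hydrogen-bond donation elongates the bond, so the donating-OH red shift and
the donor/free asymmetry *emerge* from the dynamics instead of being put
in.  Defaults ($D_e = 120$ kcal/mol, $a = 2.17$ A$^{-1}$, $r_0 = 1.012$ A)
put the isolated-molecule stretch near 3700 cm$^{-1}$, the bend constant
(75.9 kcal/mol/rad$^2$) puts the bend near 1500 cm$^{-1}$, so the free/bonded
split lands in the experimentally familiar 3400-3800 cm$^{-1}$ window.

The default run — the reference system used in examples, tests and the
acceptance script — is 12 waters on a 33 A periodic axis (2.75 A spacing),
wall of free radius 1 A and 20 kcal/mol/A$^2$ stiffness, 300 K, 0.5 fs
timestep, 10 ps equilibration with a stochastic velocity-rescaling (CSVR)
thermostat (exact kinetic-energy propagation, time constant 100 fs),
followed by 20 ps of strictly microcanonical production.  Problem sizes
throughout the tests (ensembles of 100-600 stochastic oscillators, 20-120 ps
series, response grids of a few hundred femtoseconds) were chosen as the
smallest at which the corresponding closed-form statistics converge inside
their stated tolerances.  Energy conservation is
assessed as *secular* drift — the linear-fit slope of total energy times the
run length over the mean — because velocity Verlet at 0.5 fs carries a
bounded sinusoidal energy oscillation of order 1% of a stretch quantum that
does not accumulate; the measured secular drift of the default wire is
below $10^{-4}$ relative.  Wire continuity is asserted after production:
every oxygen must keep a neighbouring oxygen within 4 A in every frame.

`bulk_reference_config()` turns the same molecules into an unconfined
reference (wall off, fully periodic cube at roughly liquid density), used
for the directional check that confinement *reduces* axial diffusion.

## Stochastic oracles

Three generators have closed-form statistics and anchor the test suite:

* **Ornstein-Uhlenbeck frequencies** (`generate_ou_frequencies()`): exact
  discrete updates (no Euler error at any timestep) of a stationary
  Gaussian process with mean $\bar\omega$, standard deviation $\Delta$ and
  memory $\tau_c$ — the Kubo model.  Its frequency correlation is
  $\Delta^2 e^{-t/\tau_c}$ and its absorption lineshape follows
  $g(t) = \Delta^2\tau_c^2(e^{-t/\tau_c} - 1 + t/\tau_c)$ analytically,
  which checks the entire response-function machinery in both the
  motional-narrowing ($\Delta\tau_c \ll 1$, Lorentzian) and inhomogeneous
  ($\Delta\tau_c \gg 1$, Gaussian) limits.
* **Axial Brownian motion** (`generate_brownian_z()`): Gaussian increments
  of variance $2D\,dt$; MSD slope recovers $D$.
* **Rotational diffusion** (`generate_rotational_diffusion()`): each unit
  vector rotates per step about a random perpendicular axis by a Gaussian
  angle of variance $4 D_r\,dt$.  The factor 4 matters: the tangential
  displacement spreads over the two perpendicular directions on the sphere,
  giving $2 D_r\,dt$ per direction, which is exactly isotropic rotational
  diffusion with constant $D_r$ and $C_2(t) = e^{-6 D_r t}$.  A per-step
  variance of $2 D_r\,dt$ would instead realize an effective constant
  $D_r/2$ and decay $e^{-3 D_r t}$.

All generators consume a single integer seed and are bit-reproducible.

## Structural and transport observables

* **MSD / diffusion**: $\mathrm{MSD}(t)$ along the pore axis over all time
  origins (FFT algorithm), lags to half the run; by default over water
  oxygens (molecular translation proxy — hydrogen MSD is contaminated by
  libration), with an `"all"` option for the literal sum over wire atoms.
  $D_z = \mathrm{slope}/2$ (1-D), ordinary least squares on the diffusive
  window, default 1-6 ps; $r^2 < 0.99$ warns of non-diffusive curvature.
* **Orientational correlation**: $C_2(t) = \langle P_2(\hat e(t)\cdot\hat
  e(0))\rangle$ with $\hat e$ the geometric HOH-bisector unit vector (no
  charge weighting), normalized at zero lag, computed from the six unique
  tensor-product autocorrelations by FFT.
* **Pair distributions**: distance histograms with minimum image on
  periodic axes, normalized by the full-box ideal density.  For the
  quasi-1D geometry this normalization only scales the curve — peak
  *positions*, the physically interpreted feature, are unaffected — and is
  kept for its ideal-gas flatness property, which the tests exploit.
* **Hydrogen bonds**: distance-only definition — two waters are bonded when
  their O···O distance is at or below 3.3 A (boundary inclusive); no
  angular criterion.  The mean HB count per water is $2 N_{bonds}/N_{water}$.
  The **continuous lifetime** correlation $S_{HB}(t)$ counts a bonded pair
  at lag $t$ only if it stayed bonded at every intermediate frame; both the
  numerator and denominator count only origins whose $t$-window fits inside
  the run, so an always-bonded pair gives $S_{HB} \equiv 1$ rather than a
  finite-window artifact.  The lifetime is the trapezoidal integral of
  $S_{HB}$ to its first drop below 0.01, flagged *censored* if it never
  drops.

## Instantaneous OH frequencies

Per OH bond the complex signal $f(t) = \delta r_{OH}(t) + i\,\delta
p_{OH}(t)/(\mu\,\omega_{ref})$ combines the bond-length fluctuation and the
reduced-mass-weighted relative velocity projected on the bond, each about
its own time mean.  The momentum scaling ($\omega_{ref} = 3500$ cm$^{-1}$,
configurable) gives both parts length units so that harmonic motion traces
a circle in the complex plane — the representation in which a
time-frequency ridge is sharpest.

The continuous wavelet transform uses a Morlet mother wavelet of
dimensionless width 6 (exposed in the API), evaluated by FFT on a
log-spaced grid of 128 scales spanning 2800-4300 cm$^{-1}$ by default.  Two
conventions matter:

* scales map to frequencies by $\omega = \omega_0/s$ with a *flat* (not
  $\sqrt{s}$-weighted) scale normalization, which makes the modulus maximum
  of a monochromatic signal fall exactly on its own frequency — with the
  common $\sqrt{s}$ energy normalization the ridge would be biased by
  $\approx 1/(2\omega_0^2)\sim 1.4\%$, i.e. tens of cm$^{-1}$ here;
* both rotation senses are analysed ($f$ and $\bar f$) and the larger
  modulus kept, so the bound-motion sign convention never matters.

The ridge is the argmax of the modulus over scales at each time, with no
continuity penalty.  Edges are trimmed by one wavelet support (4 Gaussian
widths of the largest scale) per side; only the `valid_range` feeds
downstream statistics.  Histograms (`frequency_distribution()`) use 10
cm$^{-1}$ bins and weight frames equally.

**Donor/free labelling** (`classify_oh_modes()`): the O···O rule alone
cannot say *which* H donates, so a donor layer is added: for each bonded
O···O pair, the H of either oxygen nearest to the partner oxygen donates if
its H···O distance is at or below 2.45 A.  Within each molecule the bond
with the larger donation fraction over the run is OH1 (donating), the
sibling OH2; molecules that never donate have both bonds OH2.  The
asymmetry $\gamma = \bar\omega_{OH1} - \bar\omega_{OH2}$ is reported
signed (negative when the donating OH is red-shifted, as physics dictates);
magnitudes are what is usually quoted.

## Frequency correlations and joint distributions

The FTCF $C_{\omega\omega}(t) = \langle\delta\omega(0)\,\delta\omega(t)\rangle$
takes $\delta\omega$ about **each bond's own time mean**, so static
inter-bond inhomogeneity (a permanently red OH1 vs blue OH2) does not
masquerade as a frozen correlation component; this choice sets the long-lag
plateau to zero and is the one a spectral-diffusion timescale needs.
Timescales come from the two-exponential fit
$a_0 e^{-t/\tau_0} + (1-a_0)e^{-t/\tau_1}$ under a fixed multi-start grid
($\tau_0 \in \{0.02,0.05,0.1,0.3\}$ ps, $\tau_1 \in \{0.5,1,2,5\}$ ps,
$a_0 \in \{0.2,0.5,0.8\}$) with bounded least squares; best residual wins,
ties go to the smallest $\tau_1$, and constants are returned ordered.  The
grid makes the fit deterministic and testable.  An optional constant
offset extends the model to
$c + (1-c)(a_0 e^{-t/\tau_0} + (1-a_0)e^{-t/\tau_1})$ for correlations
that relax to a persistent-order plateau rather than zero — the toy wire's
$C_2$ is the motivating case: its dipoles librate and spin about the pore
axis within ~100 fs but the chain's axial polarization survives the whole
run, leaving $C_2$ at a plateau near 0.2.  `spectral_diffusion_time()`
reports $\tau_1$; when the slow component carries under 5% of the amplitude
the decay is effectively single-exponential and $\tau_1$ is collapsed onto
the dominant constant (otherwise it would chase tail noise).

Joint distributions $P(\omega_3, t_2, \omega_1)$ are plain 2-D histograms
of $(\omega(s), \omega(s+t_2))$ pairs on the same 10 cm$^{-1}$ bins as the
marginals — by construction their marginals reproduce
`frequency_distribution()` exactly on shared breaks.  $t_2$ must be a grid
multiple; there is no interpolation.  Outputs are raw probabilities; any
colour scaling is a plotting concern.

## Third-order response and 2D-IR

OH oscillators are treated as two-level systems in the Condon
approximation with unit transition dipole; anharmonicity and excited-state
absorption are omitted, so spectra are single-peaked by construction, and
no lifetime ($T_1$) damping is applied.  For fluctuation $\delta\omega_{10}$
about the ensemble-mean frequency (here the ensemble mean, not the per-bond
mean: static inter-oscillator inhomogeneity must contribute to rephasing),
the rephasing/non-rephasing phase factors over delays $(t_1, t_2, t_3)$ are
accumulated by trapezoidal cumulative integration of $\delta\omega_{10}$
per oscillator and time origin, averaged (origins strided, default 50 fs,
capped), and multiplied by the mean-frequency carriers.  The 2D spectrum
$S = \mathrm{Re}[S_{rp} + S_{nr}]$ uses opposite $t_1$ Fourier signs for
the two pathways so both map onto positive $\omega_1$ and the dispersive
parts cancel.  The double transform is evaluated as a trapezoid-weighted
discrete transform directly onto a wavenumber grid centred on the carrier;
the `zero_pad` factor refines that grid exactly as zero padding would.
Grid defaults (1 ps extents, 2 fs spacing, pad 4) resolve 10 cm$^{-1}$
structure; the test suite uses shorter grids matched to the linewidths of
its oracle processes.

The **center-line slope** quantifies peak tilt: for every $\omega_1$ column
whose maximum lies within the FWHM of the peak, the $\omega_3$ of maximum
is located with sub-grid parabolic refinement, and a line is fitted through
the maxima weighted by column height.  CLS tracks the normalized FTCF in
the inhomogeneous regime ($\Delta\tau_c \gg 1$); for intermediate
modulation ($\Delta\tau_c \sim 1$) frequencies wander during the coherence
periods themselves and CLS systematically underestimates the FTCF — a
physical limitation of the observable, not an implementation artifact,
which is why the correspondence test runs at $\Delta\tau_c \approx 40$.

The **integrated echo** $I(t_1, t_2) = \int dt_3 |R_{rp}|^2$ (trapezoid)
and its short-time slope **S3PE** $= \partial I/\partial t_1|_{t_1=0}$
(two-point forward difference over one grid step) are normalized to the
smallest waiting time; a static oscillator has identically zero slope and
is returned raw with a degenerate flag.

## VDOS

The vibrational density of states is the cosine transform of the per-atom
velocity autocorrelation (averaged over atoms and origins, FFT) over
$\pm\tau$ with **no apodization window** and **no mass weighting**; output
on a wavenumber grid to the Nyquist limit with one point per resolution
element $1/(2\tau)$.  The modulus is taken, so mild truncation undershoot
never produces negative densities.

## Pipeline

`run_pipeline()` executes requested stages in dependency order from a YAML
config (or list), writes every output as delimited text with unit headers,
and emits a manifest (config snapshot, seed, package version, per-stage
wall-clock, MD5 digest per output).  Stage outputs are pure functions of
(inputs, config, seed); re-running a config reproduces every digest, which
the test suite asserts.  A thin `inst/exec/wirespec` script exposes
`run` / `generate` / `analyze` from a shell.

## What the synthetic data does and does not show

The toy wire reproduces the qualitative structure the analyses are built
for: a continuous single file with ~1.9 hydrogen bonds per water, roughly
half the OH hydrogens donating at any instant, a donating-OH red shift of
a few tens of cm$^{-1}$, OH-stretch frequencies in the 3400-3800 cm$^{-1}$
window, and axial diffusion well below the unconfined reference.  It does
*not* emulate electronic polarization, charge transfer, proton transfer,
nuclear quantum effects, or the wall corrugation of a real nanotube, and
its frequency fluctuations are faster and smaller than those of
first-principles water.  Passing tests therefore demonstrate that the
*observable pipeline* is correct (against closed forms) and that the
generator emulates the right statistical regime — not that the toy model
predicts real nanotube water quantitatively.

## Known limitations

* RDF normalization assumes a homogeneous ideal gas in the full box; only
  peak positions should be interpreted for quasi-1D systems.
* The wavelet ridge has no continuity penalty, so in spectrally crowded
  signals it can hop between nearby components within one support.
* The response accumulator holds the full $(t_1, t_3)$ phase grid per call;
  very fine grids with many origins are memory- and time-hungry — stride
  and cap parameters exist for exactly that reason.
* The bi-exponential fit window and multi-start grid suit picosecond-scale
  water dynamics; radically different timescales need a custom window.
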