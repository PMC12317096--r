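# wirespec

Vibrational dynamics and nonlinear spectroscopy of nanoconfined water wires.

Water confined in sub-nanometre cylindrical pores (narrow carbon nanotubes)
arranges into a single-file hydrogen-bonded chain — a *water wire* — in
which each molecule typically donates one hydrogen bond along the chain and
keeps one dangling OH.  The structure and dynamics of that chain are
encoded in OH-stretch spectroscopy: the donating OH is red-shifted, the
free OH blue-shifted, and the speed of hydrogen-bond rearrangement sets the
rate at which an OH mode forgets its frequency (*spectral diffusion*),
observable in 2D-IR lineshapes and photon-echo experiments.

wirespec is an R package for computing that entire observable chain from
molecular-dynamics trajectories (extended-XYZ with velocities):

* **transport / structure** — axial mean-square displacement and diffusion
  coefficient `D_z = lim (1/2t) MSD_z(t)`; pair distribution functions;
  hydrogen-bond counts (O···O ≤ 3.3 Å) and continuous HB lifetime
  correlation; orientational correlation
  `C2(t) = <P2(e(t)·e(0))>` of the water dipole;
* **vibrations** — velocity-autocorrelation density of states (no window,
  no mass weighting); instantaneous OH frequencies from a Morlet continuous
  wavelet transform of `f(t) = δr_OH + i δp_OH/(μ ω_ref)`; frequency
  distributions `P(ω)` (10 cm⁻¹ bins) and the intramolecular asymmetry
  `γ = ω̄_OH1 − ω̄_OH2` between donating (OH1) and free (OH2) bonds;
* **time-resolved spectroscopy** — joint distributions `P(ω3, t2, ω1)`;
  frequency–frequency correlation `C(t) = <δω(0) δω(t)>` with
  two-exponential timescale fits `a0 e^(−t/τ0) + (1−a0) e^(−t/τ1)`;
  two-level-system third-order response functions
  `R_rp/nr = μ⁴ e^(∓iω̄t3 ± iω̄t1) <exp[±i∫δω − i∫δω]>`, 2D-IR correlation
  spectra `S(ω1, t2, ω3) = Re[S_rp + S_nr]` with center-line-slope
  analysis, and the integrated photon echo `I(t1,t2) = ∫dt3 |R_rp|²` with
  its short-time slope (S3PE);
* **synthetic data** — a minimal flexible-water force field (Morse OH,
  harmonic bend, SPC/Fw-like nonbonded terms, implicit radial wall, CSVR
  equilibration + NVE production) generating confined wires, and exact
  Ornstein–Uhlenbeck / Brownian / rotational-diffusion processes whose
  closed-form statistics anchor the test suite.

It is written for molecular-simulation practitioners who need a tested,
scriptable reference implementation of these estimators — particularly the
wavelet-frequency and response-function stages, which are easy to get
subtly wrong — independent of any particular MD engine.

## Worked example

Generate the default toy wire (12 waters, 300 K, 0.5 fs timestep, 10 ps
CSVR equilibration + 20 ps NVE production) and push it through the
spectroscopy stages:

```r
library(wirespec)

traj <- generate_water_wire(wire_config(seed = 1))
traj
#> wire_trajectory: 36 atoms, 40001 frames, dt = 0.5 fs (20 ps), with
#> velocities, box 20.00 x 20.00 x 33.00 A, periodic: z

hb <- detect_hbonds(traj, cutoff_OO = 3.3)
hb
#> hb_stats: cutoff 3.30 A, 1.946 HBs per water (40001 frames, 66 candidate pairs)

freqs <- wire_frequencies(traj, frame_stride = 2)   # Morlet wavelet ridges
frequency_distribution(freqs)
#> frequency_distribution (all): mean 3663.9 cm^-1, sd 142.7, 151 bins of 10 cm^-1

asymmetry(freqs, classify_oh_modes(traj, hb))
#> asymmetry: OH1 3640.8, OH2 3687.0, gamma = -46.2 cm^-1 (|gamma| = 46.2)

spectral_diffusion_time(ftcf(freqs))$tau1          # spectral-diffusion time, ps
#> [1] 0.362
```

The HB count (~1.9 per water: a continuous chain with thermal breaks), the
mean OH frequency in the 3600–3700 cm⁻¹ window, the negative γ (donating
OH red of the free OH by ~46 cm⁻¹) and a sub-picosecond spectral-diffusion
time are the signatures of a tightly hydrogen-bonded single-file chain
with fast frequency modulation; the methods vignette
(`vignettes/wirespec-methods.Rmd`) discusses what the toy model does and
does not emulate.

2D-IR spectra and echoes come from the same frequency set:

```r
resp <- compute_response(freqs, t2 = 100, t_max = 400, dt_r = 4)
spec <- spectrum_2d(resp, zero_pad = 4)
center_line_slope(spec)                 # peak tilt, decays with t2
echo <- echo_intensity(freqs, t2_values = seq(0, 1600, 200))
```

A YAML-driven pipeline (`run_pipeline()`) chains all stages, writes
delimited-text outputs and a digest manifest; `inst/exec/wirespec` exposes
it from a shell.

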