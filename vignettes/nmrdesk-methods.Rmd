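---
title: "Processing and deconvoluting 2D and pseudo-3D NMR spectra with nmrdesk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and deconvoluting 2D and pseudo-3D NMR spectra with nmrdesk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdesk)
```

# Scope and model

nmrdesk is a headless toolchain for two-dimensional and pseudo-3D solution
NMR data. It covers the path from a Bruker time-domain directory to a phased
frequency-domain spectrum, from that spectrum to a deconvoluted peak list
with Voigt lineshapes, and from a stack of planes (relaxation or CEST
series) to per-peak exponential rates or saturation profiles, plus contour
and 3D renderings of the results.

The signal model throughout is the standard one for liquid-state 2D
experiments: each cross-peak `j` contributes a separable damped complex
exponential

    s_j(t2, t1) = A_j exp(i 2π f_xj t2 − R2xj t2) · q(f_yj, t1) exp(−R2yj t1)

where `q` encodes the indirect quadrature scheme (States, States-TPPI, or
echo/antiecho pairs) and optional Gaussian terms `exp(−a t²)` model static
inhomogeneity. After Fourier transformation the corresponding lineshape is a
product of 1D Voigt profiles, which is what the fitter assumes.

# Conventions that everything else depends on

* **Point ordering.** Index 0 of every frequency axis is the downfield
  (highest ppm) edge; all indices are 0-based; ranges are half-open. The
  FFT output is reordered so the carrier sits at the centre index `n/2`.
* **Axis calibration.** An axis is `(n_points, sw_hz, obs_mhz, origin_hz)`
  with `origin_hz` the frequency of the *last* point, the convention of the
  ft2 header ecosystem. ppm↔point maps are affine and exactly invertible.
* **First-order phase.** `p1` is the total sweep across the displayed
  spectrum with the pivot at point 0. Adding 360° to `p0` never changes a
  phased real spectrum.
* **Half-first-point scaling.** The first time-domain point of each
  dimension is halved immediately before that dimension's transform. This
  suppresses the baseline offset that otherwise appears as a constant ridge;
  it is fixed behaviour, documented here, not configurable. The elementary
  `transform_direct()` is a pure FFT (Parseval holds exactly); the halving is
  applied by the pipeline stage so both facts can be tested independently.

# Processing pipeline

`process_2d()` runs, per plane: (direct dimension, per row) solvent filter →
apodization → half-first-point → zero-filling → FFT with group-delay
compensation → phasing → extraction; then (indirect dimension, per column)
quadrature recombination → apodization → half-first-point → zero-filling →
FFT → phasing. All four hypercomplex quadrants are kept so phases can be
readjusted later.

**Window defaults** are a sine-bell `off = 0.5, end = 0.95, pow = 2` on both
dimensions with one fold of zero-filling — ordinary HSQC practice. The
sine-bell weight at point `i` of `n` is `sin(π·off + π(end−off)·i/(n−1))^pow`;
the exponential window is `exp(−π·lb·t)` with `lb` in Hz.

**Solvent suppression** subtracts a centred boxcar moving average
(half-width 16 complex points, shrinking at the edges) from each direct
FID — a low-pass whose stop band contains every off-carrier resonance of
interest. On a pure DC signal the filter is exact to machine precision; an
off-resonance tone at a quarter of the sweep width loses less than 5% of its
height. The half-width trades DC rejection against attenuation of
near-carrier signals; 16 points at sw = 8 kHz puts the −3 dB edge at roughly
±120 Hz.

**Group delay.** Bruker digital filters delay the FID by a non-integer
number of points (`GRPDLY`, e.g. 67.98). The default compensation is a
first-order phase ramp totalling `360·GRPDLY` degrees across the spectrum;
a circular-shift variant (integer part as a time shift, remainder as a
ramp) is available because ecosystem dialects differ. Either way the
correction is exact for the analytic signal; what remains on real data is a
truncation-level ripple, so the contract tested is positional: peaks move by
less than 0.01 points relative to a delay-free acquisition.

**Automatic phasing.** The source tool does not disclose its autophasing
algorithm, so correctness here is defined by parameter recovery, not output
identity. The objective is ACME-like: with the real part normalised by the
spectrum maximum,

    f(p0, p1) = entropy(|d Re/dk|) + 50 · Σ max(0, −Re)²

minimised over a coarse 10°×30° grid on `[−180,180)×[−360,360]` followed by
Nelder–Mead. The entropy term prefers the narrow derivative distribution of
absorption lines; the negativity penalty resolves the 180° ambiguity and
anchors the baseline. The λ = 50 weight makes a typical dispersion
contamination (negative lobes of ~0.1 of the peak height) dominate the
entropy differences of order 0.01–0.1; with the penalty normalised per point
instead, the entropy term biases phases by several degrees on unapodized
Lorentzian rows (we measured ~7°), which is why the max-normalised form is
used. On 5-peak synthetic spectra with SNR ≥ 50, recovery is within ±2°
(p0) and ±10° (p1) over seeded trials. Note that `p0` and `p1` are only
*jointly* identifiable when resonances span the spectral window; peaks
clustered in a narrow band constrain `p0 + p1·x` at one `x` only, and any
autophasing method will trade the two off. Indirect-dimension autophasing is
refused for NUS data: those phases must come from the pulse sequence.

# Non-uniform sampling

NUS reconstruction is iterative soft thresholding (IST) and explicitly does
**not** claim parity with SMILE; it satisfies the same contract (phased data
in, uniform time domain out). Per indirect column: zero-fill the unsampled
increments, FFT, shrink every magnitude by the threshold τ (soft
thresholding), inverse FFT, restore the measured increments; τ starts at the
initial spectrum maximum and decays geometrically (`0.98` per iteration, 200
iterations). Two implementation points matter:

* The working grid is internally zero-filled (one fold by default,
  `internal_zf`). On the bare grid, a weakly decaying off-grid resonance is
  truncation-dominated — its spectrum is not compressible — and the
  soft-threshold bias reaches 7–15% of peak height at 25% sampling. The
  extended grid lets the unmeasured tail continue the decay and restores
  heights to well within the tested bounds. The measured increments are
  restored on the original grid positions and only the first `full_size`
  points are returned.
* The data-consistency residual at the sampled increments is recorded per
  iteration and is non-increasing on the test fixtures; the zeroth-order
  indirect phase is applied in the time domain before reconstruction (exact),
  the first-order term after the final FFT.

Schedules use seeded Poisson-gap-like sampling (gaps grow sinusoidally
towards late t1, increment 0 always sampled). A complete schedule reduces
the whole NUS path to uniform processing exactly, which is tested at 1e-6.

# Peak picking and deconvolution

Noise is `1.4826 × MAD` per 32×32 block, median over blocks — robust to a
few percent of signal-bearing pixels. The picker returns strict 8-neighbour
local maxima above `threshold_sigma × noise` (default 5.5), refined per axis
by parabolic interpolation. It is a classical stand-in with the same
interface a learned picker could occupy; on noiseless synthetic spectra the
truncation ripple of strong peaks is itself above any threshold proportional
to a near-zero noise level, so thresholds are meaningful only at realistic
SNR.

Fitting minimises the squared residual of a sum of separable Voigt products
over connected above-threshold regions (8-connectivity at `5.5σ`, padded by
3 points; the 5.5 default is low enough to join overlapped shoulders and
high enough to keep regions small). Peak heights enter the model linearly,
so they are solved by linear least squares inside every objective
evaluation (variable projection); the nonlinear search over positions and
widths uses bounded quasi-Newton (`nlminb`) with central-difference
gradients, positions bounded to the patch and widths to `[0.3, patch]`
points. Fitted peaks below `3σ` are culled and the region refit once. When
a spectrum has several regions, a second pass refits each region on the
data minus the other regions' models: without it, cross-region Lorentzian
tails bias parameters at the ~5×10⁻⁴ level, which is visible against the
noiseless reconstruction-fidelity bound (residual rms < 1e-6 of the
maximum). The Voigt profile itself is evaluated through the Faddeeva
function (Weideman's 64-pole rational expansion, ~1e-13 accurate in the
upper half-plane), with closed-form Gaussian/Lorentzian branches when one
width underflows.

Pseudo-3D fits share all six shape parameters (x, y, σx, γx, σy, γy) per
peak across planes and free only the per-plane heights — reported as
`Z_A0, Z_A1, …` relative to plane 0 by default (absolute behind a flag).
Because heights are linear, the joint fit costs little more than a single
plane.

# Downstream analysis

`fit_exponential()` fits `A·exp(−R t)` by least squares, initialised from
the log-linear regression of the positive heights, with the standard error
of `R` from the Jacobian at the optimum. It is scale-invariant, so relative
Z_A heights need no renormalisation. Only mono-exponential decays are
modelled. CEST profiles are intensities normalised by a reference
(off-resonance) plane, ordered by offset.

# Visualization

Contours come from marching squares with exact linear interpolation on cell
edges; saddle cells are disambiguated by the cell-centre average so outputs
are reproducible. Default levels are geometric: lowest `5.5σ`, factor 1.4,
at most 20 levels capped below the matrix maximum. Overlays draw items in
ascending z-order with per-item reference shifts applied as pure ppm axis
offsets, both axes reversed per NMR convention. Peak labels are placed by a
greedy displacement search that only guarantees the no-overlap outcome, not
optimality. SVG output is produced by a built-in writer with fixed number
formatting, so identical inputs give byte-identical files — interactive
zooming is replaced by re-rendering with ppm-window arguments, which keeps
the tool headless and CI-friendly. The 3D surface and terrace views use an
orthographic back-to-front painter over the (optionally downsampled) mesh;
the terrace mode quantizes heights to the contour levels.

# What the synthetic generator does and does not emulate

`generate_fid()` produces analytic FIDs from declared peak tables: Lorentzian
(and optionally Gaussian) decays, quadrature encoding for all three indirect
modes, per-peak dephasing (applied as the constant phase each resonance
accumulates at its own spectral position — exact at peak centres,
approximate across a linewidth), axial contamination that ignores the t1
phase cycling, seeded complex Gaussian noise, group delay as a shift of the
direct time axis, per-plane scaling from explicit factors or exponential
decays, and genuine Bruker `ser`/`acqus`/`acqu2s` output (float64 or padded
int32, either byte order). For int32 fixtures the ground truth is rounded at
generation so file round trips are exact.

It does **not** simulate J-coupling multiplets, relaxation during pulses,
solvent dynamics, baseline distortions, or temperature/field drift. A green
test therefore establishes correctness of the transforms, conventions and
estimators on well-modelled data — not robustness to every artifact of real
spectra. Default magnitudes (sw 8000×2000 Hz, obs 600.13×60.81 MHz,
carriers 4.7/118 ppm) exercise realistic ppm arithmetic but nothing depends
on them.

# Numerical and format notes

* ft2 and ucsf store data and calibration as float32. A float64 in-memory
  spectrum is preserved to float32 relative precision on the first
  write/read and exactly thereafter (the round trip is a fixed point). For
  the same reason the ft2↔ucsf ppm-map agreement is ~1e-7 relative: 1e-6
  ppm absolute on a proton axis, ~|ppm|·2⁻²³ on a 100–130 ppm nitrogen axis.
* The accepted TopSpin text dialect requires `F1LEFT/F1RIGHT`,
  `F2LEFT/F2RIGHT`, `NROWS`, `NCOLS` headers; other dialects are rejected
  loudly rather than guessed. totxt files carry no spectrometer frequency,
  so those axes use a nominal 1 MHz observe frequency (exact in ppm).
* Degenerate inputs: empty schedules and peak lists raise errors; a flat or
  signal-free row makes `autophase()` return (0, 0) with a warning; a level
  above the matrix maximum yields an empty contour set, not an error.
* Exit codes of the `nmrdesk` CLI: 0 success, 1 validation error, 2 I/O
  error; outputs contain no timestamps, so identical argv + seed give
  hash-identical files.

# Known limitations

IST is not SMILE: at 25% sampling its height accuracy (median within 10% on
separated resonances) is far from SMILE's parametric accuracy, and NUS in
more than one dimension is out of scope. The picker is classical, not the
neural picker of the original toolchain. Linear prediction, baseline
correction beyond the solvent filter, Bloch–McConnell CEST fitting and
multi-exponential relaxation models are deliberately absent.
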