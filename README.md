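# nmrdesk

A headless R toolchain for processing, deconvoluting and visualizing 2D and
pseudo-3D solution NMR spectra. It is aimed at spectroscopists and pipeline
builders who need a scriptable, fully reproducible path from raw Bruker
time-domain data to phased spectra, Voigt-fitted peak lists, per-plane peak
heights and relaxation/CEST parameters — without a GUI.

## What it does

* **Formats** — read Bruker time-domain directories (`ser`/`fid` +
  `acqus`/`acqu2s`, int32 or float64, either byte order, group delay
  recorded); read/write NMRPipe `ft2` (512-float header, hypercomplex
  quadrants, pseudo-3D stacks) and UCSF Sparky `ucsf` (tiled); read TopSpin
  `totxt` text exports; read/write peak lists in NMRPipe tab (with
  `Z_A0, Z_A1, …` plane-height columns) and Sparky list dialects; read
  `nuslist` sampling schedules.
* **Processing** — solvent (zero-frequency) suppression, NMRPipe-style
  window functions, zero-filling by folds, FFT with States / States-TPPI /
  echo-antiecho quadrature handling and group-delay compensation, automatic
  (entropy + negativity objective) or manual phase correction, ppm region
  extraction, identical processing of all planes of a pseudo-3D series.
* **NUS** — iterative soft-thresholding reconstruction of the indirect
  dimension (an IST substitute for SMILE, with measured-point consistency
  and documented non-parity).
* **Peaks** — robust noise estimation, classical peak picking with
  sub-point interpolation, region-clustered deconvolution with separable
  Voigt/Gaussian/Lorentzian lineshapes, and pseudo-3D fits that share peak
  positions and lineshapes across planes while letting only heights vary.
* **Analysis** — mono-exponential relaxation rates (R1/R2-type) from
  `Z_A` heights; CEST profiles.
* **Viz** — marching-squares contours, deterministic SVG (and PNG)
  overlays of any number of spectra with independent chemical-shift
  references and de-overlapped peak labels, 1D cross-sections/projections,
  3D surface and terrace renderings.
* **Synthetic data** — a ground-truth generator that writes genuine Bruker
  fixtures from declared peak parameters, so the entire pipeline is testable
  offline.

The fitted lineshape is a product of 1D Voigt profiles
`V(x; σ, γ) = Re[w((x + iγ)/(σ√2))]/(σ√(2π))` evaluated via the Faddeeva
function; a pseudo-3D peak is `h_p · V(x−x0) · V(y−y0)` with shared
`(x0, y0, σx, γx, σy, γy)` and per-plane heights `h_p`. Relaxation series
are fit as `h(t) = A·exp(−R t)`.

## Worked example

Simulate a 4-plane relaxation series with three cross-peaks decaying at
1.2, 2.0 and 3.5 s⁻¹, write it as a Bruker directory, process, pick, fit
jointly and extract the rates:

```r
library(nmrdesk)

truth <- new_ground_truth(
  peaks = data.frame(x_ppm = c(8.2, 7.0, 6.1), y_ppm = c(124, 112, 118),
                     amplitude = c(10, 7, 6), r2_x_hz = 18, r2_y_hz = 8),
  noise_sigma = 4,
  plane_decay = list(delays_s = c(0.01, 0.2, 0.5, 0.9),
                     rate_per_s = c(1.2, 2.0, 3.5)),
  seed = 42)
td <- generate_fid(truth)
write_bruker_fixture(td, td$meta, "fixture/")

raw  <- read_bruker("fixture/")
spec <- process_pseudo3d(raw$td, scheme = new_scheme(
  direct_phase = new_phase(0, 0), indirect_phase = new_phase(0, 0)))
spec$noise_sigma <- estimate_noise(spec)

picked <- pick_peaks(spec, threshold_sigma = 8)
fit    <- fit_pseudo3d(spec, picked, new_fit_options("voigt"))
as.data.frame(fit$peaks)[, c("x_ppm","y_ppm","height","Z_A0","Z_A1","Z_A2","Z_A3")]
#>   x_ppm y_ppm height Z_A0   Z_A1   Z_A2    Z_A3
#> 1   8.2   124  40676    1 0.7957 0.5573 0.35477
#> 2   7.0   112  28191    1 0.6768 0.3726 0.15596
#> 3   6.1   118  22982    1 0.5121 0.1698 0.03827

rates_from_peaklist(fit$peaks, delays_s = c(0.01, 0.2, 0.5, 0.9))
#>   label rate_per_s amplitude rate_stderr r_squared
#> 1    P1       1.18      1.01      0.0129         1
#> 2    P2       2.05      1.02      0.0259         1
#> 3    P3       3.58      1.04      0.0403         1

render_overlay(list(overlay_item(spec, color = "black")),
               labels = fit$peaks, out_path = "overlay.svg")
```

The three fitted positions match the declared shifts to the digital
resolution; the `Z_A` columns are the per-plane heights relative to plane 0
(e.g. peak 3 decays fastest), and the recovered rates 1.18, 2.05 and
3.58 s⁻¹ agree with the injected 1.2, 2.0 and 3.5 s⁻¹ within the noise.

The same pipeline is scriptable from the shell via the bundled CLI wrapper:

```sh
nmrdesk=$(Rscript -e 'cat(system.file("cli/nmrdesk", package="nmrdesk"))')
Rscript "$nmrdesk" process --in fixture/ --config scheme.cfg --out planes.ft2
Rscript "$nmrdesk" pick    --in planes.ft2 --threshold 8 --out peaks.tab
Rscript "$nmrdesk" fit3d   --in planes.ft2 --peaks peaks.tab --out fitted.tab
Rscript "$nmrdesk" rates   --peaks fitted.tab --delays 0.01,0.2,0.5,0.9 --out rates.tsv
Rscript "$nmrdesk" plot    --in planes.ft2 --peaks peaks.tab --out fig.svg
```

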