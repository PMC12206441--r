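---
title: "kirquant: generator models, numerical methods and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kirquant: generator models, numerical methods and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirquant)
```

kirquant quantifies three assays used to characterise a loss-of-function
mutation in an inward-rectifier potassium (Kir) channel, and ships a
seedable synthetic generator for each, with exact ground truth. This
vignette documents the generator models and their assumptions, the default
parameters and why they were chosen, the numerical methods, and what the
generators deliberately do *not* emulate.

## 1. Electrophysiology

### Generator model

Each simulated cell is a voltage-clamped membrane carrying a Kir
conductance, an ohmic leak, and additive Gaussian current noise:

$$I(V) = \left[\, g_{kir}\, r(V)\, (V - E_{rev}) + g_{leak}\, V \,\right]
          C_m + \varepsilon,\qquad
  r(V) = \frac{1}{1 + e^{(V - V_{1/2})/k}}.$$

Conductance densities are in nS/pF, capacitance in pF, voltages in mV, so
currents come out in pA. The Boltzmann factor $r(V)$ produces inward
rectification: near-unity open fraction at strongly negative potentials,
small at positive ones. Setting `rect_slope = NA` (or `Inf`) disables
rectification and yields an ohmic conductor — the closed-form oracle used
throughout the tests. (A literal slope → 0 limit of the Boltzmann is a step
function, not "no rectification", hence the explicit switch.)

The command waveform is a 400 ms linear ramp from +150 to −150 mV sampled
at 10 kHz, flanked by 20 ms holds at 0 mV. In the Ba²⁺ condition $g_{kir}$
is scaled by `1 − ba_block_frac` (default 0.95, i.e. 95 % block by 200 µM
Ba²⁺) while the leak is untouched; control-minus-Ba²⁺ subtraction therefore
cancels the leak exactly and isolates the Kir component.

Defaults: `e_rev = −5` mV is the K⁺ Nernst potential for 140 mM internal /
115 mM external K⁺ at 22 °C (`nernst_k()`); `rect_vhalf = −20`,
`rect_slope = 20` mV give strong but smooth rectification over the ramp
span; `g_leak = 0.05` nS/pF and `noise_sd_pa = 20` pA produce realistic
but clearly sub-dominant nuisance components; `capacitance_pf = 15 ± 2` pF
is a typical transfected HEK-sized cell.

### Preset calibration

`ephys_preset()` returns groups whose *true* Ba²⁺-sensitive current
densities at −150 mV have sample mean and SD exactly equal to the stated
group values (WT −147.7 ± 23.1 pA/pF, N = 5; MT −8.4 ± 2.3, N = 7; WT+MT
−19.1 ± 3.2, N = 5): the per-cell target densities are drawn as a normal
sample standardised to those exact moments, and each cell's $g_{kir}$ is
back-computed as
$cd / (f_{block}\, r(-150)\, (-150 - E_{rev}))$. This makes parameter
recovery sharp — the only error left is the pipeline's own.

### Analysis methods

* **Ramp location** (`ramp_segment`): longest strictly decreasing run of
  the command voltage, so holding-segment layout does not matter.
* **Current density** (`current_density`): local linear fit of the
  difference current over ±1 mV around the readout voltage, evaluated at
  the readout voltage, divided by capacitance. A windowed median would be
  biased by half a window at the ramp end, where −150 mV sits; the local
  fit keeps the noise averaging without the edge bias.
* **Reversal potential** (`reversal_potential`): running-mean smoothing
  (21 samples), linear interpolation of the zero crossing; with multiple
  crossings the one nearest the Nernst prior is taken.
* **Chord conductance** (`chord_conductance`): $G = I/(V - V_{rev})$ on a
  2 mV grid over −140…−20 mV, excluding ±5 mV around $V_{rev}$ where the
  ratio is 0/0-amplified.

## 2. Blot densitometry

### Generator model

A lane is a 400 px (migration axis) × 40 px patch. Migration position is
tied to molecular weight by a monotone piecewise-linear map between
log₁₀(MW) and pixels, anchored at ladder bands (70 kDa at 40 px, 25 kDa at
360 px). The lane-mean profile is

$$y(p) = b_0 + b_1 p + \sum_{\text{bands}} A\,\phi(p; c, \sigma) + \text{noise},$$

i.e. a tilted baseline plus Gaussian bands whose *areas* equal the designed
amounts $A$ (mature target ≈ 45 kDa, immature ≈ 43 kDa, loading control
≈ 50 kDa; $\sigma$ = 4 px). The generator refuses designs where band
centres fall closer than 3σ (unresolvable by construction).

Presets: untreated lanes carry 70 % of the target in the mature band
(ratio 7/3 ≈ 2.33); the mutant preset has 0.40× the wild-type abundance;
the deglycosylation preset collapses the signal to the lower band
(`upper_frac = 0.05`); the non-transfected preset carries only the loading
control.

### Analysis methods

* **Background** (`subtract_background`): morphological opening (rolling
  minimum then rolling maximum; half-window 4σ per side), which removes
  constant and tilted baselines exactly away from bands. Because an opening
  can bulge under clusters of overlapping bands wider than its window, the
  baseline is re-interpolated linearly between anchor points where the
  profile sits on the opening, excluding the expected band regions (centres
  ± 5σ) and extrapolating linearly at the lane edges (where the opening is
  biased over the outermost half-window). The pixel-noise level is
  estimated from successive differences *before* zero-clipping and carried
  forward as the detection floor.
* **Detection** (`detect_and_integrate_bands`): local maximum inside the
  calibrated window (expected MW ± 2 kDa) with sub-pixel parabolic
  refinement; a peak below 3× the noise floor is reported absent with zero
  intensity. Two labels landing on (nearly) the same peak keep only the one
  closer to its expected position; the other is flagged
  `collapsed_into_neighbor`.
* **Integration**: the 43 and 45 kDa glycoforms sit ~3.5σ apart, so plain
  ±3σ windows double-count tails. The default is a per-cluster linear
  least-squares unmixing with unit-area Gaussians at the detected centres
  (fixed width) plus a local intercept; band intensity is the fitted
  amplitude (= area). A `method = "sum"` alternative integrates ±3σ
  truncated at midpoints between neighbours.
* **Normalisation**: total target / loading control per lane; fold change
  relative to the mean of untreated wild-type lanes (non-transfected lanes
  can never serve as reference).

A consequence of peak-based detection worth knowing: at
`upper_frac = 0.05` the residual mature band is a *shoulder* (no local
maximum) on the 19×-larger immature band and is reported absent, so the
measured post-deglycosylation ratio is 0 rather than 0.05. This is
conservative for any "ratio below a bound" readout.

## 3. Imaging

### Generator model

Cells are non-overlapping discs (radius 26 ± 3 px) placed by rejection
sampling in a 384×384 px field; each has an elliptical nucleus (axis ratio
0.85, strictly interior) with dark nucleoli, a membrane ring (width 3 px)
in the marker channel, and a target channel in which `membrane_fraction`
of the cell's total expression is spread uniformly over the ring and the
rest over the cytoplasm. All three channels share one arbitrary-unit
intensity scale (nuclear stain 100, marker 80, target set by
`total_expression`), so a single `noise_sd` behaves like camera noise;
optional Poisson resampling models photon counting. The summed target
channel equals the summed per-cell expression exactly (noiseless), and
per-cell masks (nucleus / cell / ring) are returned as ground truth.

### Analysis methods

* **Nuclei** (`segment_nuclei`): Gaussian blur (σ = 2), Otsu threshold,
  hole filling (removes nucleoli), watershed on the distance transform
  (splits touching nuclei), size filter (≥ 50 px²).
* **Cells** (`segment_cells`): Voronoi propagation from nucleus seeds over
  a cell-foreground mask. The foreground threshold is background median +
  3 MAD (+ small floor) on the smoothed marker+target sum — *not* Otsu,
  whose bimodal split lands between the dim cytoplasm and the bright
  membrane ring and discards the cytoplasm. Expansion is capped at 1.5×
  the median equivalent-disc radius; only the component connected to the
  seed is kept. Near-empty foreground degrades to dilated nuclei with a
  `low_foreground` flag.
* **Membrane** (`segment_membrane`): the band just inside each cell
  boundary (ring width + 3 px slack absorbing the outward bias of
  intensity-thresholded boundaries) intersected with marker-positive
  (Otsu) pixels. Border-touching cells are flagged `partial_ring`.
* **Metrics** (`quantify_membrane`): after subtracting the median non-cell
  background, per cell: ring signal per ring area, and ring signal as a
  fraction of whole-cell target signal. `aggregate_cells` applies a
  positivity filter before group comparisons.

On the noiseless presets the chain recovers cell counts exactly for 1–20
cells, mask IoU ≥ 0.8, and the membrane fraction to three decimals across
the 0.1–0.9 grid; it tolerates `noise_sd = 2` (2 % of the nuclear
intensity) without losing cells.

## 4. Statistics and reporting

`t_unpaired` (pooled-variance Student by default, Welch by flag),
`anova_oneway` (between/within mean squares computed directly so degenerate
data follow an explicit contract: all-identical data give F = 0, p = 1;
zero within-group variance with distinct means gives F = ∞, p = 0; the
t test follows the same contract), `star_annotation` (strict thresholds at
0.05 / 0.01 / 0.001 / 0.0001), and `compare_conductance` (per-voltage
multiple t tests, uncorrected by design, or a two-factor ANOVA). No
multiple-testing correction is applied anywhere. `build_report` writes one
CSV per analysis arm plus a combined comparison table; reruns with the same
inputs are byte-identical.

## 5. Problem sizes and runtime

A ramp pair is 4 400 samples per sweep; a 7-cell group simulates and
analyses in well under a second. A 6-lane blot is a 400 × 290 px image;
rendering plus full densitometry takes ~0.1 s. A 384×384 px field with 10
cells segments in a few seconds (the watershed and propagation dominate).
The full test suite runs in under a minute.

## 6. Limitations

* Electrophysiology: no series-resistance or capacitance-transient
  artefacts, no rundown, no Ba²⁺ voltage-dependent block kinetics; the
  rectification is a static Boltzmann, not a spermine/Mg²⁺ block model.
  Recordings are exchanged as CSV (plus a metadata sidecar); vendor binary
  formats are out of scope.
* Densitometry: bands are ideal Gaussians on a linear baseline; no smile,
  lane warping, saturation or spot artefacts. Quantification assumes the
  calibrated band width.
* Imaging: 2-D discs only — no irregular morphology, overlap, out-of-focus
  light or 3-D stacks; segmentation is classical (no learned models), and
  colocalization analysis beyond the ring metrics is out of scope.
* Statistics: cells are treated as independent units; no mixed-effects
  modelling of cell-within-field nesting, no Bayesian analysis.
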