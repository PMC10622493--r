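---
title: "Multifractal analysis of FTIR spectrum trace images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal analysis of FTIR spectrum trace images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfir)
```

## The problem

ATR-FTIR spectroscopy of intact cell suspensions produces mid-infrared
absorbance curves (4000–650 cm⁻¹) whose fine structure reflects membrane
composition and hydration. Cells of higher metastatic potential have more
hydrated, more fluid membranes, and their spectra differ from those of
less aggressive cells of the same lineage in ways that are hard to reduce
to a single band ratio. `mfir` implements a pipeline that treats the
*plotted spectrum itself* as a geometric object: the curve is rendered as
an axis-free binary image, the image is box-counted across scales, and
the resulting multifractal spectrum is reduced to one scalar — the
**multifractal number** — intended to rank samples by phenotype and to
track the fraction of abnormal cells in a mixture.

The pipeline is deliberately simple to state:

1. **Normalize** the absorbance to `[0, 1]` (min–max). Any positive
   rescaling of the input — e.g. from a different cell concentration on
   the ATR crystal — then produces a *byte-identical* image, which is
   the mechanism behind the concentration-independence property.
2. **Render** the curve on a `width × height` canvas (default
   1024 × 128 px) as a connected 1-px polyline: wavenumber maps linearly
   to column (4000 cm⁻¹ at the left), absorbance to row, no axes, grids
   or margins. The 128-px amplitude axis mirrors the 7-bit quantization
   of the original imaging protocol.
3. **Binarize** (threshold 128; the dark trace is foreground) and
   box-count with a FracLac-style grid scan: up to 100 box sizes,
   geometrically spaced from 10 px to 60 % of the smaller image
   dimension, moment orders Q from −10 to 10 in steps of 0.25.
4. **Estimate** the mass exponents τ(Q), generalized dimensions D(Q),
   and the singularity spectrum f(α) (below), and reduce to the
   multifractal number.

## Estimation

For each box size ε the foreground mass in box *i* is normalized to a
probability `P_i(ε)` over occupied boxes. Three families of per-scale
sums are formed, all in log space so that Q = ±10 cannot overflow even
when `P_i` is as small as one pixel's share:

* the partition function `Z(Q, ε) = Σ P_i^Q`,
* the Chhabra–Jensen numerator `Σ μ_i log P_i` with
  `μ_i = P_i^Q / Z(Q, ε)`,
* its entropy companion `Σ μ_i log μ_i`.

τ(Q) is the scaling exponent of `log Z` against `log ε`;
`D(Q) = τ(Q)/(Q−1)` for Q ≠ 1, with the information dimension D(1)
obtained from the entropy limit (`Σ P_i log P_i` against `log ε`) rather
than by division. α(Q) and f(Q) come from the direct (Chhabra–Jensen)
sums, which avoid numerically differentiating a noisy τ; the Legendre
transform `α = ∂τ/∂Q`, `f = Qα − τ` is also computed, as a cross-check
channel. A per-Q R² accompanies every fit, and summary scalars
(`alpha_min`, `alpha_max`, `delta_alpha`, `f_max`) are taken only over Q
values whose fits pass `fit_min_r2` (default 0.90) — on real trace
images the strongly negative Q moments are dominated by near-empty
partial boxes and rarely scale cleanly, and would otherwise inflate the
spectrum width.

### The anchored scaling fit

The scaling fits default to least squares **constrained through the
whole-image anchor** `(log L, 0)`, `L = max(dims)`: at ε = L a single
box holds all mass, so `log Z`, the Chhabra–Jensen numerator and the
entropy sum are all exactly zero. This is the ratio form
`τ(Q) = log Z(Q, ε) / log(ε/L)` of the scaling definition, averaged over
scales with least-squares weights.

The choice matters. On ideal scale-invariant measures (the cascades
below) the anchored and free fits coincide to machine precision, because
the exact `log Z` line passes through the anchor anyway. On finite,
weakly multifractal images they differ, and the anchored form has a
structural advantage: the fitted D(Q) becomes a positively weighted
mixture of per-scale Rényi entropies, so

* D(Q) is non-increasing in Q — in particular D(0) ≥ D(1) ≥ D(2),
* f(α) has a single hump with its maximum exactly at Q = 0, equal to
  D(0),
* the tangency f(α(1)) = α(1) holds exactly,

on *every* input, not just asymptotically. With the free fit we observed
systematic D(1) > D(0) inversions of order 0.01–0.03 on smooth spectrum
traces, an artifact of box-mass heterogeneity that grows toward coarse
scales over the narrow 10–76 px window the protocol allows. The free fit
remains available (`mfa_config(regression = "free")`) for sensitivity
analysis.

### Interpreting the paper-protocol parameters

The grid-scan defaults follow the published FracLac settings, read as:
"box/grid sizes 100" → 100 distinct box edges; "minimum pixel size 10" →
smallest edge 10 px; "maximum image percentage 60" → largest edge
`floor(0.60 × min(width, height))` (76 px on the default canvas). Each
is an overridable `mfa_config` field. Multiple grid origins (FracLac's
grid scans) are supported (`n_grid_origins`, seeded); the default is the
single origin (0, 0) for reproducibility. Partial boxes at the image
edge are included by default (their mass counts); discarding them is a
flag, and affects mainly negative-Q moments.

One printed relation of the source protocol, τ(Q) = Q·H(Q) − 128, cannot
be reconciled dimensionally with D(Q) = τ(Q)/(Q−1); the constant is
almost certainly an artifact of the 128-px image convention. The package
implements the standard partition-function τ(Q) and exposes
`H(Q) = (τ(Q) + D(0))/Q` as a derived column so the quantity remains
inspectable.

### The multifractal number

The literature this pipeline derives from never pins down which scalar
of the f(α)–α plot is "the" multifractal number. The default here is the
spectrum width `Δα = alpha_max − alpha_min` over quality-gated Q — the
width is what the α_min/α_max markers of a singularity spectrum
emphasize, and it is zero exactly in the monofractal collapse
f = α = D. Alternatives are selectable to hedge the ambiguity:
`alpha0`, `d1`, `f_at_q(q*)`, and an `aperture` reading
`|f(Q=1) − f(Q=−1)|` (labelled experimental; the source text's aperture
sentence admits several readings).

## Verification oracles

Because no spectra are publicly deposited, correctness rests on
multiplicative cascades with closed-form spectra. A binomial cascade
with weights `(p, 1−p)` and scale ratio ½ has

```
tau(q)  = −log2(p^q + (1−p)^q)
D(1)    = −p log2 p − (1−p) log2 (1−p)
alpha_min = −log2 max(p, 1−p),  alpha_max = −log2 min(p, 1−p)
```

and the 2-D quadrant cascade generalizes with four weights. With exact
dyadic box sizes the estimator recovers these to near machine precision
(the acceptance suite uses depth 12 in 1-D, depth 8–9 in 2-D; tolerances
0.03 on dimensions, 0.15 on Δα at |Q| ≤ 10). The uniform pair and
quadruple collapse to D ≡ 1 and D ≡ 2 with Δα at rounding level, the
degenerate f = α = D case.

## The synthetic spectrum generator

`synth_ftir_spectrum()` emulates what the pipeline needs from a cell
spectrum, not its biochemistry:

* five Gaussian bands at OH/NH (3300/200/0.6), CH (2925/60/0.3), amide I
  (1650/40/0.9), amide II (1545/40/0.6) and a phosphate-like band
  (1080/60/0.4) (center cm⁻¹ / σ cm⁻¹ / amplitude AU) — fixture
  conventions, not measured values;
* a fine-structure texture: `roughness_amp` × the centered **log** of a
  shuffled binomial cascade measure (depth 11 at the default 2048
  points);
* a white detector-noise floor (`noise_amp`, default 0.008 AU, in the
  spirit of the ~42 dB ceiling the 7-bit protocol itself concedes).

The log-cascade texture is the load-bearing choice. The log of a cascade
mass is a sum of independent per-level log-multipliers accumulated along
the dyadic tree, so it fluctuates on every scale of the wavenumber axis,
and its standard deviation is fixed by the cascade parameter itself:
per level `sd{log(2p), log(2(1−p))}` ≈ 0.69 at p = 0.2 against 0.10 at
p = 0.45. A smaller `roughness_p` therefore yields an intrinsically
rougher, more intermittent texture with **no per-realization
rescaling** — the knob's direction is cascade mathematics, not a gain
dial. Raw cascade masses (an additive spike field) do not work at this
canvas size: after amplitude normalization a skewed cascade's bulk
texture is invisible at 128-px quantization and the knob inverts.

`mix_spectra()` forms the pointwise convex combination
`(1−φ)·healthy + φ·cancer` on a shared grid, recording φ, which is the
fixture for the disease-progression experiment: healthy-like
(p = 0.45) vs cancer-like (p = 0.20) endpoints mixed at
φ ∈ {0.2, 0.4, 0.6, 0.8, 1.0} give a monotone increase of the
multifractal number (median Spearman ρ ≈ 1 over seeds).

What the generator does **not** emulate: ATR penetration-depth optics,
Mie scatter, water-vapor lines, baseline drift, or any claim about which
real spectral features carry phenotype information. Passing tests on
these fixtures demonstrate that the pipeline measures multi-scale
roughness correctly and monotonically — not that real cancer spectra
possess that roughness; the biological claim is outside what synthetic
data can establish.

## Statistical summaries

`compare_groups()` reports per-group mean/SD/n and a Welch t-test (two
groups) or one-way ANOVA (more), chosen because the source protocol
names no test and replicate counts are small. At the protocol's n = 3
replicates Welch's t is conservative (true level ≈ 0.03 at α = 0.05);
the package's calibration check therefore simulates n = 5 per group,
where the level is ≈ 0.045. Zero-variance groups (identical replicates)
are handled deterministically rather than erroring. `dose_response()`
reports Spearman's ρ between mixing fraction and multifractal number,
with ties reported as undefined rather than silently dropped.

## Numerical choices and problem sizes

* Q grid −10…10 step 0.25; Q = 1 always via the entropy path; Q = 0
  never divides.
* All moment sums in log space (`log-sum-exp`); occupied boxes only
  (P = 0 boxes are excluded — negative Q would diverge).
* Row rounding in the renderer: absorbance a → row
  `floor((1−a)(height−1) + 0.5)`, ties toward the top; no
  anti-aliasing, since grey edge pixels would corrupt the binary mass.
* Default test/acceptance problem sizes: depth-12 (4096-cell) 1-D
  cascades, depth 8–9 2-D cascades (256²–512²), 1024 × 128 trace
  images, 20-spectrum property sweeps, 5-seed × 5-φ mixing experiments,
  2000–4000-replicate calibration simulations. On one CPU the full test
  suite runs in ~30 s and the acceptance script in ~15 s.

## Known limitations

* A 1024 × 128 canvas with boxes of 10–76 px spans less than one decade
  of scales; estimates on real traces are finite-range descriptors, not
  asymptotic dimensions, and negative-Q moments usually fail the R²
  gate. This is inherent to the published protocol, which its authors
  themselves flag as quantization-limited.
* JCAMP-DX support is the AFFN single-block subset ((X++(Y..Y)) and
  (XY..XY)); compressed encodings (DIFDUP etc.) are not read.
* No baseline, scatter or atmospheric correction is applied — by design,
  since the emulated protocol applies none.
* The aperture variant of the multifractal number implements one
  defensible reading of an ambiguous definition and is labelled
  experimental.
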