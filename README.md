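# mfir — multifractal analysis of mid-infrared absorbance spectra

`mfir` turns an ATR-FTIR absorbance spectrum of a cell suspension into a
single scalar — a **multifractal number** — by rendering the spectrum as
an axis-free binary trace image, box-counting that image across scales,
and measuring the width of its singularity spectrum. The motivating
application is label-free cancer diagnostics: cells of higher metastatic
potential have more hydrated, more fluid membranes, their mid-IR spectra
carry different fine structure, and the multifractal number ranks cell
lines by phenotype, is invariant to the cell concentration assayed, and
rises with the fraction of cancerous cells in a mixed population. The
package is aimed at spectroscopists and image-analysis researchers who
want that pipeline as a reproducible, testable tool rather than a chain
of GUI steps.

## The method

For a binary image, box counting at edge size ε yields occupied-box
probabilities `P_i(ε)`. The pipeline estimates, over Q ∈ [−10, 10]:

- mass exponents **τ(Q)**, the scaling of the partition function
  `Σᵢ P_i(ε)^Q ∼ ε^{τ(Q)}`;
- generalized (Rényi) dimensions **D(Q) = τ(Q)/(Q−1)**, with the
  information dimension D(1) from the entropy limit
  `Σᵢ P_i log P_i ∼ D(1)·log ε`;
- the singularity spectrum **f(α)** by the direct (Chhabra–Jensen)
  estimator, `μ_i = P_i^Q/Σ P_j^Q`, α(Q) and f(Q) from the scaling of
  `Σ μᵢ log Pᵢ` and `Σ μᵢ log μᵢ`, with the Legendre transform
  `α = ∂τ/∂Q, f = Qα − τ` as a cross-check;
- the **multifractal number**, by default the spectrum width
  `Δα = α_max − α_min` over fit-quality-gated Q (alternatives: α₀,
  D(1), f(α(q*)), aperture).

Scaling fits are least squares anchored at the whole-image scale
(`log Z = 0` at ε = L), which makes D(Q) a positive mixture of Rényi
entropies — so D(0) ≥ D(1) ≥ D(2), the single f(α) hump at Q = 0 and
the f(α(1)) = α(1) tangency hold exactly on every input, and ideal
cascade measures are recovered to machine precision. Estimator
correctness is verified against multiplicative binomial/multinomial
cascades with closed-form spectra (`theory_tau`, `theory_dimension`,
`theory_alpha_f`); since the underlying study's raw spectra are not
deposited, a seeded synthetic generator (`synth_ftir_spectrum`)
emulates cell spectra with Gaussian bands plus a cascade-driven
roughness texture, and `mix_spectra` builds cancer/healthy mixtures.
See the methods vignette (`vignettes/multifractal-ftir.Rmd`) for design
rationale and limitations.

## Worked example

```r
library(mfir)

s <- synth_ftir_spectrum(roughness_p = 0.2, seed = 42,
                         meta = list(sample_id = "cancer-like"))
img <- spectrum_to_binary(s)       # normalize -> render 1024x128 -> threshold
ms  <- analyze(img, mfa_config())
ms
#> Multifractal spectrum (box counting)
#>   Q in [-10, 10] step 0.25; 61 box sizes in [10, 76]
#>   D(0)=1.1972  D(1)=1.1229  D(2)=1.0878
#>   alpha in [0.9538, 1.2387]  delta_alpha=0.2849  f_max=1.1880
#>   41/81 Q values failed the R^2 >= 0.90 fit gate

multifractal_number(ms)
#> multifractal number (delta_alpha): 0.28495
```

The D(Q) ordering and the sub-unity-to-plane range (1 ≤ D(0) ≤ 2) say
the trace is a mildly multifractal curve; Δα ≈ 0.28 is its width. A
healthy-like fixture (`roughness_p = 0.45`, same seed) gives
`delta_alpha: 0.20045` — smoother fine structure, narrower spectrum.
Triplicates of each phenotype separate in the group summary:

```r
grp <- compare_groups(list(
  healthy = sapply(1:3, function(k)
    spectrum_mf_number(synth_ftir_spectrum(roughness_p = 0.45, seed = k))$value),
  cancer  = sapply(1:3, function(k)
    spectrum_mf_number(synth_ftir_spectrum(roughness_p = 0.20, seed = k))$value)))
grp
#> Group comparison of multifractal numbers
#>    group n      mean          sd
#>  healthy 3 0.2442658 0.008195195
#>   cancer 3 0.3654111 0.045578332
#> welch_t: statistic = -4.531, p = 0.04036
```

Scaling the *same* spectrum by ×2, ×4, ×10 (the concentration analogue)
leaves the binary image byte-identical, so `invariance_report()` returns
a spread of exactly 0.

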