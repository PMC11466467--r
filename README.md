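# ctiq — quantitative CT image quality and protocol harmonization

`ctiq` is an R toolkit for medical physicists who need to compare CT
scanners quantitatively and translate a clinical scan protocol from one
scanner to another. It implements the task-based image-quality (IQ) metric
chain used for modern CT performance assessment — noise power spectrum
(NPS), insert contrast and CNR, the task transfer function (TTF) from a
circular edge, and the non-prewhitening-with-eye-filter (NPWE) model
observer — plus a five-step cross-scanner harmonization procedure:

1. classify protocols (body / brain);
2. match the noise level between scanners by rescaling CTDI_vol so the
   area under the radial NPS curve (AUC_NPS) agrees;
3. acquire a CTDI_vol x reconstruction factorial;
4. quantify each iterative-reconstruction (IR) level as the change ratio
   (IQ_IR − IQ_FBP)/IQ_FBP per metric, averaged over dose;
5. match the reference IR level to the candidate scanner's levels by
   Spearman correlation of pooled IQ vectors.

The core quantities:

- NPS (per uniform ROI, 2nd-order polynomial detrended):
  `NPS2D(fx,fy) = (ΔxΔy)/(NxNy) · mean_i |FFT2D(I_i − P_i)|²`,
  summarized as noise SD, NPS peak (NPS_p), peak frequency (FREQ_p),
  weighted mean frequency (FREQ_m) and AUC_NPS;
- TTF from the circular-edge ESF → LSF → normalized |FT|, with a
  sigmoid-plus-two-Gaussians parametric edge model for low-CNR edges
  (CNR < 15);
- NPWE detectability for a disk task `W(ρ) = ΔHU·(πd²/4)·2J₁(πdρ)/(πdρ)`:
  `d′² = [∬TTF²W²E²]² / ∬NPS·TTF²W²E⁴`, converted to an ROC area by
  `AUC = ½[1 + erf(d′/2)] = Φ(d′/√2)`.

A built-in phantom simulator generates image series with a planted radial
noise spectrum, `1/√CTDI_vol` noise scaling, a parametric IR operator
(noise suppression + low-frequency texture shift), and anti-aliased
sensitometry / low-contrast / edge inserts — so every estimator in the
chain can be validated against known ground truth, and the whole
harmonization procedure can be exercised end to end without scanner data.
DICOM CT series (uncompressed, Explicit VR little endian) and a portable
raw+JSON fixture format are supported for I/O.

## Worked example

```r
library(ctiq)

cfg <- default_config(seed = 1, ctdi_list = c(5, 10, 20, 40),
                      hybrid_levels = 1:3, modelbased_levels = 1:2,
                      shape = c(128, 128), n_slices = 8, n_grid = 256)
out <- run_pipeline(cfg, outdir = "run1", reference_label = "hybrid-2")

out$scale
#> <ctiq_scale> CTDI_B/CTDI_A = 1.138 (from 3 dose points)

out$harmonization$match
#> <ctiq_match> candidate rhos:
#>      hybrid-1      hybrid-2      hybrid-3 model-based-1 model-based-2
#>        0.9909        0.9950        0.9897        0.8919        0.8890
#> best: hybrid-2 (tie set: hybrid-1, hybrid-2)

round(out$harmonization$change_ratio$CT_A, 2)
#>               noise_sd nps_p freq_p freq_m cnr_LDPE cnr_Derlin dprime_12mm_25HU dprime_7mm_10HU
#> FBP               0.00  0.00   0.00   0.00     0.00       0.00             0.00            0.00
#> hybrid-1         -0.08 -0.11  -0.12  -0.03     0.05       0.12             0.11            0.26
#> hybrid-2         -0.16 -0.20  -0.21  -0.06     0.20       0.19             0.12            0.22
#> hybrid-3         -0.24 -0.28  -0.30  -0.11     0.29       0.32             0.00           -0.02
#> model-based-1    -0.76 -0.85  -0.72  -0.34     2.92       3.00             0.56            0.68
#> model-based-2    -0.84 -0.86  -0.87  -0.52     4.82       4.84             0.61            0.77
```

Reading the output: scanner B (planted dose efficiency 1/1.15) needs
~14–15% more dose than scanner A for the same noise, which step 2 recovers
as the scale factor. The change-ratio matrix shows hybrid IR reducing noise
moderately (|ratio| < 0.3) with little texture change, while the
model-based emulation suppresses noise strongly (|ratio| > 0.6) and shifts
the NPS toward low frequencies (FREQ_m down 34–52%) — the signature that
makes strong IR images look "blotchy". The matching step then identifies
which of scanner B's levels behaves most like the reference reconstruction
(here, the same hybrid level 2, with level 1 inside the 0.005 tie band).

Per-metric pieces are available individually: `noise_metrics()`,
`contrast_cnr()`, `extract_esf()`/`fit_esf_ott()`/`compute_ttf()`,
`task_spec()`/`d_prime_npwe()`/`auc_from_dprime()`,
`estimate_ctdi_scale()`, `iq_change_ratio()`, `match_ir_level()`; the
simulator via `scanner_profile()`, `ir_emulation()`, `synth_cell()` and
`synth_study()`. See the vignette in `vignettes/` for the model details,
defaults and validation design.

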