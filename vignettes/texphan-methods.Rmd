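---
title: "Simulating an MR radiomics robustness study with texphan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an MR radiomics robustness study with texphan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texphan)
```

## The problem

Radiomics promises to turn routine MR images into quantitative tissue
descriptors, but MR intensities are not quantitative: shimming, coil
choice, field strength, voxel size and the discretization pipeline all
move texture feature values around. Before a feature can be trusted in a
clinical model, its repeatability (same setup, repeated scans) and
reliability (different setups) must be measured. Physical test objects are
the classical tool — fruit and vegetables for realistic texture, and
3D-printed objects with exactly known geometry for reproducible texture.
A printed QR-code cube is particularly attractive: the imaged texture
carries machine-verifiable information, so "how much texture survived the
scanner" becomes a decoding success rate rather than a subjective rating.

`texphan` reproduces this entire study design digitally. Every stage of
the physical experiment has a simulated counterpart, so the analysis
machinery — feature definitions, normalization, discretization,
repeatability statistics, readability scoring — can be exercised,
validated, and reused on real NIfTI volumes.

## Pipeline overview

1. **`phantom_forge`** — ground-truth voxel phantoms on a fine grid
   (default pitch 0.25 mm): `make_qr_phantom()`, `make_hilbert_phantom()`,
   `make_bio_phantom()` and `rotate_phantom()`.
2. **`virtual_mr`** — `enumerate_setups()` builds the 24-setup factorial
   design; `repeat_scan()` produces repeated magnitude volumes through
   `assign_contrast()` and `acquire()`.
3. **`voiprep`** — `cubic_voi()` / `grow_voi()`, `normalize_mu3sigma()`,
   `discretize_fbs()` / `discretize_fbn()`.
4. **`texturex`** — `extract_all()` returns the 45 features
   (18 GLCM + 11 GLRLM + 11 GLSZM + 5 histogram).
5. **`repstats`** — `cv()`, `rpd()`, `icc()`, `exclude_unstable()`,
   `summarize_cv()`, and the orchestrator `run_study()`.
6. **`qrread`** — coronal slice export, Lanczos interpolation,
   `decode_slice()` with pluggable binarization backends,
   `reading_ratio()` and `middle_slice_grid()`.

## Phantom geometry

The QR phantom is a hollow plastic container (2 mm walls) filled with a
bright NiCl~2~-like solution; the code modules are plastic columns
extruded through 30 mm (large) or 20 mm (small) of the container depth.
The payload `"UNIDEB MRI Texture Analysis Phantom"` is 35 bytes, which in
byte mode at error-correction level M lands on a version-3 symbol:
29 × 29 modules. The code plus a one-module quiet ring spans the 46 mm
interior, giving **1.48 mm modules** in the large phantom and **1.16 mm**
in the small one. That single geometric fact drives the headline
readability result: at 1 mm isotropic sampling the large code sits just
above the Nyquist limit and decodes; at 2 mm both codes are under-sampled
and nothing decodes. We chose the one-module quiet ring (rather than the
four modules typical of printed media) because the physical interior
cannot hold a 29-module code at ≈1.5 mm modules *and* a four-module ring;
the surrounding bright solution and the decoder's tolerance make the
narrow ring sufficient.

The Hilbert phantom voxelizes a square-section plastic pipe (default
6 mm) along the level-2 3D Hilbert curve — 64 cells in a 4 × 4 × 4
lattice, one self-avoiding chain of 63 unit steps, computed with
Skilling's transpose-to-axes algorithm — plus an alternating
plastic/air checker pattern (5 mm squares) carved into the outer half of
the walls. The checker dimensions are a configuration default: only the
qualitative "chessboard-like" appearance is specified by the physical
design.

Biological phantoms are procedural stand-ins with the right *kind* of
structure: kiwi (bright core, radial striations, a ring of dark seed
points), tomato (pericarp wall, locule wedges, seed clusters), onion
(concentric alternating shells). Shell counts, seed densities and class
fractions are documented config entries (`bio_default_params()`), not
measurements; a smooth multiplicative modulation field (±8–10%) gives
continuous within-class texture so that co-occurrence statistics are not
degenerate.

## The virtual scanner

Sequence physics is deliberately not simulated. The acquisition chain
models exactly the factors the repeatability analysis is sensitive to:

| stage | model | default |
|---|---|---|
| contrast | per-material mean intensity by weighting | solution 1500/1300 (T1/T2), plastic 60, air 0, tissues 250–1050 |
| resolution | Gaussian PSF, FWHM = acquired voxel; box-average downsampling | 1 or 2 mm isotropic |
| repositioning | random sub-voxel shift per repetition | uniform(±0.3) voxel |
| bias field | smooth multiplicative low-frequency field | ±5% at 1.5 T, ±7.5% at 3 T |
| gain drift | global multiplicative factor per repetition | sd 3% |
| noise | Rician: magnitude of (signal + g₁, g₂) | SNR at 1 mm in fill: 18 (1.5 T/6ch), 25 (3 T/8ch), 35 (3 T/32ch); × voxel volume; × 0.6 for T2 |

Intensity units are arbitrary but fixed so that the raw intensity range
spans roughly 40 bins of width 50, keeping the raw-FBS and normalized-FBS
bin counts comparable. The SNR presets and the larger 3 T bias amplitude
are declared assumptions, chosen once to reproduce the qualitative
ordering seen on real hardware (better repeatability at 1.5 T, better
read-out at higher SNR, T1 readable where T2 is not); all are overridable
through `default_contrast_model(overrides)`. Box averaging (not
decimation) is used for downsampling because partial-volume mixing is
what degrades the QR modules; decimation would alias them. In the
signal-free background the magnitude image is Rayleigh distributed, which
the tests exploit: mean/sd = 1.91, and `estimate_background_noise()`
recovers the preset sigma from the background mean.

## Normalization and discretization

`normalize_mu3sigma()` maps VOI intensities to z-scores clipped to ±3
(sample n−1 standard deviation throughout the package). Clipping, rather
than excluding, keeps the mask geometry intact for run/zone statistics;
the exclusion variant is available via `clip = FALSE`. Whether the
original study clipped or excluded is not stated; clip is the default.

FBS discretization is `ceiling((I − I_min)/B)` with the VOI minimum
assigned level 1, `B = 0.15` on normalized and `B = 50` on raw
intensities — both spans give ≈40 bins, which anchors this reading of the
(typographically damaged) printed formula. An IBSI-style
`floor(...) + 1` variant sits behind a flag. FBN is
`ceiling(D (I − I_min)/(I_max − I_min))` with the minimum pinned to 1 and
`D = 64`; a constant VOI yields all-1 levels with a warning rather than
an error, because uniform phantoms are legitimate inputs.

## Texture features

GLCM and GLRLM use 3D Chebyshev distance 1 over the 13 unique directions,
symmetric accumulation, features computed per direction and averaged
(the most common IBSI aggregation); GLSZM uses 26-connected zones and a
single matrix. Entropies are base-2. Gray levels index 1..G with
G = observed maximum (FBS) or D (FBN), which fixes the normalization of
GLN/ZSN. Degenerate single-level VOIs return analytic limits
(JointEntropy 0, Energy 1, Contrast 0, Correlation defined as 1) instead
of NaN. Histogram statistics (min, max, mean, median, voxel count) are
taken on the raw pre-normalization intensities; on z-scored values the
mean is ≈0 by construction and its CV would be undefined.

The matrices obey exact conservation laws — per-direction GLCM
probabilities sum to 1, run-length- and zone-size-weighted counts equal
the masked voxel count — and the test suite checks them, plus bit-exact
agreement with naive brute-force enumerators on over a hundred random
VOIs.

## Repeatability statistics

* `cv()`: sample-sd/mean × 100 across the 3 repetitions; zero-mean cases
  are flagged undefined, dropped from averages and counted.
* `rpd()`: (mean₁ − mean₂)/mean₁ × 100, signed, setup 1 fixed as the
  denominator; summaries use magnitudes.
* `comparison_pairs()`: the 14 standard setup pairs (7 per weighting:
  resolution within coil, field at matched resolution, coil count at 3 T).
* `icc()`: two-way ANOVA mean squares and
  ICC = (MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE)), the
  absolute-agreement single-measurement form, applied to per-object means
  over repetitions; categories excellent/good/moderate/poor at
  0.9/0.75/0.5. Negative values are reported, not clamped.
* `exclude_unstable()`: a feature is dropped when its aggregated CV
  exceeds 10%. The aggregation (mean over objects and setups, versus
  "any setup exceeds") is not pinned down by the study description; the
  mean is the default and `aggregate = "any"` is available.

`run_study()` chains everything deterministically from one master seed
and writes CSV tables, an exclusion JSON and per-object CV heatmaps.

## QR readability

Coronal (fixed-y) slices are min–max windowed to 8-bit, optionally
Lanczos-3 interpolated to 1024 × 1024 (square-padded first), and passed
to `decode_slice()`. Reader diversity — the study's five phones — is
emulated by three binarization backends feeding one standards
implementation: global Otsu, global mean, and an adaptive local-mean
blend. Detection scans rows and columns for 1:1:3:1:1 finder runs,
selects the finder triple by constellation geometry, maps module
coordinates through an affine fit, and registers the sampling grid
against the known function-module template before sampling. Decoding
reads the format information (BCH, ≤3 bit errors per copy), unmasks,
deinterleaves, and applies Berlekamp–Massey/Chien/Forney correction
(13 codewords at version 3-M); success requires an exact payload match.
The middle slice is `floor(N/2)` in 0-based indexing. `reading_ratio()`
reports the percentage of decodable coronal slices.

## What the simulation does and does not show

The generator emulates contrast, resolution, repositioning, bias, gain
drift and Rician noise. It does **not** simulate k-space acquisition,
coil sensitivity maps, Gibbs ringing, motion during readout, NiCl₂
relaxometry, or 3D-printing artifacts — so passing tests demonstrate that
the *analysis machinery* is correct and that resolution/noise-driven
effects reproduce, not that any specific real-scanner CV value will be
matched. The real study's headline tables derive from undeposited scans
and are out of reach by construction; the package reproduces the
analysis, the enumerative structure, and the readability behaviour.

Two planted-effect checks deserve a note. The feature-exclusion test
plants nine high-variance features and requires the CV > 10% rule to flag
exactly that set — it validates the rule, not the claim that those nine
are unstable on any particular scanner. The resolution-direction check
runs the study with the voxel-SNR exponent overridden to −1 so that 2 mm
acquisitions are noisier; the default model keeps the physical 8×
voxel-volume SNR gain, under which coarser voxels are *less* noisy and
the CV direction is governed by repositioning instead.

## Numerical choices and problem sizes

Ground-truth pitch is 0.25 mm (≥4 voxels per acquired 1 mm voxel) for
readability analyses; the test-suite studies use 0.5 mm phantoms and
2-setup/4-setup configurations, which keeps the full suite around two
minutes while preserving every code path. Seeds for repetitions derive
deterministically from the master seed (`derive_seed()`, kept below
2³¹). Boundary handling: convolution kernels are renormalized at the
edges; Lanczos weights are normalized per output pixel and clamped to
0..255. Ties in Otsu's criterion resolve to the lowest threshold;
region-growing erosion uses the full 26-neighbourhood, and the most
apical/basal occupied axial slices are removed, so a grown VOI can never
touch the volume's extreme slices.

## Limitations

* The QR decoder is tuned for axis-aligned symbols as produced by the
  slice exporter; arbitrary in-plane rotation is not supported (the
  physical study displayed upright images too).
* Only error-correction level M (versions 1–9) is generated and decoded.
* Biological phantoms are texture stand-ins; their parameters are
  plausible, not fitted to produce specific real-fruit feature values.
* `grow_voi()` implements threshold-plus-connectivity growing; it is not
  an interactive multi-label editor.
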