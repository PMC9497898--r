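# texphan

Digital texture phantoms and repeatability analysis for MR radiomics.

MR texture features ("radiomics indices") are sensitive to everything
around them: field strength, coil, voxel size, intensity normalization,
gray-level discretization. Assessing which features are repeatable across
repeated scans — and reliable across acquisition setups — is usually done
with physical phantoms: fruit and vegetables for realistic texture, and
3D-printed objects for exactly reproducible texture. A printed,
solution-filled **QR-code cube** goes one step further: the imaged texture
encodes machine-verifiable information, so texture fidelity becomes a
decoding success rate.

`texphan` implements that whole study digitally, for methodologists who
want to exercise and validate a radiomics repeatability pipeline without a
scanner, and then reuse the identical machinery on real NIfTI volumes:

* **Phantoms** — a QR-code cube (ISO/IEC 18004 encoder built in), a
  level-2 3D Hilbert-curve cube, and procedural kiwi/tomato/onion
  look-alikes, all as labeled voxel grids at 0.25 mm pitch.
* **Virtual scanner** — the 24-setup factorial design
  (1.5 T/6ch, 3 T/8ch, 3 T/32ch × T1/T2 × 1/2 mm × FBS/FBN), with
  partial-volume blur, repositioning shifts, bias fields, gain drift and
  Rician noise.
* **Feature extraction** — µ±3σ normalization, fixed-bin-size
  (B = 0.15 normalized / 50 raw) and fixed-bin-number (D = 64)
  discretization, and 45 IBSI-style features: 18 GLCM + 11 GLRLM +
  11 GLSZM + 5 histogram statistics.
* **Statistics** — coefficient of variation `CV = sd/mean·100` over
  3 repetitions, relative percentage difference
  `RPD = (m₁−m₂)/m₁·100` over 14 canonical setup pairs, and the two-way
  ANOVA intraclass correlation
  `ICC = (MSR−MSE)/(MSR+(k−1)MSE+(k/n)(MSC−MSE))` with
  excellent/good/moderate/poor categories at 0.9/0.75/0.5, plus the
  CV > 10% feature-exclusion rule.
* **Readability** — coronal slice export, Lanczos interpolation to
  1024², and QR decoding through three binarization backends (global
  Otsu, global mean, adaptive) emulating reader diversity, with
  per-slice reading ratios and middle-slice success grids.

## Worked example

```r
library(texphan)

ph     <- make_qr_phantom("UNIDEB MRI Texture Analysis Phantom")  # 50x50x40 mm
setups <- enumerate_setups()                                      # 24 rows
vols   <- repeat_scan(ph, setups[1, ], n_rep = 3, base_seed = 7)  # 1.5T_T1_6ch_1mm_FBS

fv <- extract_all(vols[[1]], cubic_voi(vols[[1]], edge_mm = 35), setups[1, ])
round(fv[c("JointEntropy", "Contrast", "SRE", "SAE", "mean", "voxel_count")], 3)
#> JointEntropy     Contrast          SRE          SAE         mean  voxel_count
#>        8.620       41.753        0.937        0.607      877.971    42875.000

vals <- sapply(vols, function(v)
  extract_all(v, cubic_voi(v, edge_mm = 35), setups[1, ])["Contrast"])
cv(vals)
#> [1] 2.74   # percent, across the three repetitions

middle_slice_grid(list("1.5T_T1_6ch_1mm_FBS" = vols), ph$payload)
#>   setup               decoder  successes n_rep
#> 1 1.5T_T1_6ch_1mm_FBS otsu             3     3
#> 2 1.5T_T1_6ch_1mm_FBS mean             3     3
#> 3 1.5T_T1_6ch_1mm_FBS adaptive         3     3
```

The feature vector is the 45-element repeatability unit: `JointEntropy`
is in bits, `mean` is in the scanner's arbitrary intensity units,
`voxel_count` is the VOI volume (35³ here). The CV of 2.74% says GLCM
contrast moved by under 3% across repeated scans of this setup. The
middle-slice grid mirrors a smartphone read-out table: at 1 mm the
encoded payload is recovered in all three repetitions by every backend —
at 2 mm resolution (setup rows 3–4) nothing decodes, because the
1.48 mm QR modules fall below the sampling limit.

`run_study()` chains phantom → scans → VOIs → features → CV/RPD/ICC →
exclusion for a whole configuration and writes `features.csv`, `cv.csv`,
`rpd.csv`, `icc.csv`, `excluded_features.json` and CV heatmaps.

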