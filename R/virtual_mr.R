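# Virtual MR scanner: maps a ground-truth phantom to repeated magnitude
# volumes for each acquisition setup of the study's factorial design
# (1.5 T / 3 T, T1 / T2 weighting, 6 / 8 / 32 channel coils, 1 / 2 mm
# isotropic voxels, FBS / FBN discretization; 24 setups in all).
#
# Sequence physics (TR/TE/NSA) is deliberately not simulated: weighting and
# hardware collapse into a ContrastModel of per-material mean intensities and
# SNR presets. The acquisition chain models what the repeatability analysis is
# actually sensitive to: partial-volume blur, gridding, a smooth multiplicative
# bias field, sub-voxel repositioning between repetitions, per-repetition
# global gain drift (MR intensities are not quantitative), and Rician noise.

#' Enumerate the 24 acquisition setups
#'
#' The full factorial of field strength/coil (1.5 T with 6 channels, 3 T with
#' 8 or 32 channels), weighting (T1, T2), acquired voxel size (1, 2 mm) and
#' gray-level discretization (FBS, FBN), in canonical table order.
#'
#' @return A tibble with 24 rows: `label`, `field_T`, `weighting`, `channels`,
#'   `voxel_mm`, `discretization`.
#' @export
enumerate_setups <- function() {
  rows <- list()
  for (weighting in c("T1", "T2")) {
    for (hw in list(c(1.5, 6), c(3, 8), c(3, 32))) {
      for (voxel in c(1, 2)) {
        for (disc in c("FBS", "FBN")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            field_T = hw[1], weighting = weighting, channels = as.integer(hw[2]),
            voxel_mm = voxel, discretization = disc
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$label <- format_setup_label(out)
  out$setup_id <- seq_len(nrow(out))
  out[, c("setup_id", "label", "field_T", "weighting", "channels", "voxel_mm",
          "discretization")]
}

format_setup_label <- function(s) {
  paste0(ifelse(s$field_T == 1.5, "1.5T", "3T"), "_", s$weighting, "_",
         s$channels, "ch_", s$voxel_mm, "mm_", s$discretization)
}

#' Parse a setup label back into its fields
#'
#' @param label Character vector of labels such as `"1.5T_T1_6ch_1mm_FBS"`.
#' @return A tibble with one row per label.
#' @export
parse_setup_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("malformed setup label: ", label[bad][1])
  out <- tibble::tibble(
    field_T = vapply(parts, function(p) as.numeric(sub("T$", "", p[1])), numeric(1)),
    weighting = vapply(parts, `[`, character(1), 2L),
    channels = vapply(parts, function(p) as.integer(sub("ch$", "", p[3])), integer(1)),
    voxel_mm = vapply(parts, function(p) as.numeric(sub("mm$", "", p[4])), numeric(1)),
    discretization = vapply(parts, `[`, character(1), 5L)
  )
  ok <- (out$field_T == 1.5 & out$channels == 6) |
    (out$field_T == 3 & out$channels %in% c(8L, 32L))
  if (!all(ok)) stop("invalid field/coil combination in label: ", label[!ok][1])
  out$label <- format_setup_label(out)
  if (!all(out$label == label)) stop("label does not round-trip: ", label[out$label != label][1])
  out
}

#' Default contrast and noise model of the virtual scanner
#'
#' Mean intensities per material and weighting (arbitrary units chosen so the
#' raw intensity range spans roughly 40 bins of width 50), SNR presets per
#' field/coil at 1 mm in the fill solution, and bias-field amplitudes.
#' T2 acquisitions carry a lower SNR multiplier, giving T1 the higher
#' contrast-to-noise; plastic and air are near signal-void on both weightings.
#'
#' @param overrides Named list to override entries (`intensity`, `snr`,
#'   `bias_amp`, `weighting_snr`, `gain_sd`, `shift_frac`).
#' @return A `ContrastModel` list.
#' @export
default_contrast_model <- function(overrides = list()) {
  model <- list(
    # rows: label id 0..5; cols: T1, T2
    intensity = matrix(
      c(0, 0,      # air
        60, 60,    # plastic
        1500, 1300,  # NiCl2 fill solution
        700, 900,  # tissue_a (flesh / pericarp / shell a)
        1050, 650, # tissue_b (core / locules / shell b)
        250, 300), # tissue_c (seeds / core)
      nrow = 6, byrow = TRUE, dimnames = list(names(PHANTOM_LABELS), c("T1", "T2"))
    ),
    snr = c("1.5T_6ch" = 18, "3T_8ch" = 25, "3T_32ch" = 35),  # at 1 mm, fill mean
    weighting_snr = c(T1 = 1, T2 = 0.6),
    bias_amp = c("1.5T" = 0.05, "3T" = 0.075),
    gain_sd = 0.03,      # per-repetition global multiplicative gain drift
    shift_frac = 0.3,    # repositioning shift, uniform(+-0.3) acquired voxels
    voxel_snr_exp = 3    # SNR gain with voxel volume (2 mm => 8x at exp 3)
  )
  utils::modifyList(model, overrides)
}

# Map phantom labels (plus optional within-class modulation) to a continuous
# ground-truth intensity volume at the phantom pitch.
#' Assign material contrast to a phantom
#'
#' @param phantom A `VoxelPhantom`.
#' @param model A `ContrastModel` from [default_contrast_model()].
#' @param weighting `"T1"` or `"T2"`.
#' @return Numeric 3D array of mean intensities at the ground-truth pitch.
#' @export
assign_contrast <- function(phantom, model = default_contrast_model(),
                            weighting = c("T1", "T2")) {
  weighting <- match.arg(weighting)
  labs <- phantom$labels
  present <- sort(unique(as.vector(labs)))
  if (any(present + 1L > nrow(model$intensity))) {
    stop("contrast model has no entry for label ", max(present))
  }
  lut <- model$intensity[, weighting]
  vol <- array(lut[labs + 1L], dim = dim(labs))
  if (!is.null(phantom$modulation)) vol <- vol * phantom$modulation
  vol
}

#' Simulate one MR acquisition
#'
#' Pipeline: Gaussian point-spread blur with FWHM equal to the acquired voxel
#' size, sub-voxel repositioning shift, box-average downsampling to the
#' acquired grid, smooth multiplicative bias field, global gain drift, and
#' Rician noise (magnitude of a complex Gaussian). The SNR preset refers to
#' the fill-solution mean at 1 mm and scales with acquired voxel volume.
#'
#' @param truth Continuous ground-truth volume (from [assign_contrast()]).
#' @param pitch_mm Pitch of `truth` in mm.
#' @param setup One row of [enumerate_setups()] (or a one-row tibble/list with
#'   the same fields).
#' @param noise_seed Integer seed for this repetition.
#' @param model `ContrastModel` (for SNR/bias/gain presets).
#' @param noiseless If `TRUE`, skip shift, bias, gain and noise (PSF +
#'   gridding only).
#' @return An `MRVolume` list.
#' @export
acquire <- function(truth, pitch_mm, setup, noise_seed = 1L,
                    model = default_contrast_model(), noiseless = FALSE) {
  voxel <- setup$voxel_mm
  f <- voxel / pitch_mm
  if (abs(f - round(f)) > 1e-8 || f < 2) {
    stop("ground-truth pitch ", pitch_mm, " mm incompatible with ", voxel,
         " mm acquisition (need an integer factor >= 2)")
  }
  f <- as.integer(round(f))
  sigma_vox <- voxel / 2.355 / pitch_mm  # FWHM = acquired voxel size
  vol <- gaussian_blur3d(truth, sigma_vox)

  key <- paste0(ifelse(setup$field_T == 1.5, "1.5T", "3T"), "_", setup$channels, "ch")
  snr <- model$snr[[key]] * model$weighting_snr[[setup$weighting]] *
    voxel^(model$voxel_snr_exp %||% 3)
  fill_mean <- model$intensity["solution", setup$weighting]
  sigma_noise <- fill_mean / snr

  if (!noiseless) {
    shift <- with_seed(derive_seed(noise_seed, 1L), {
      round(stats::runif(3, -model$shift_frac, model$shift_frac) * f)
    })
    vol <- array_shift3d(vol, shift, fill = 0)
  }
  vol <- box_downsample3d(vol, f, pad_value = 0)

  if (!noiseless) {
    amp <- model$bias_amp[[ifelse(setup$field_T == 1.5, "1.5T", "3T")]]
    bias <- with_seed(derive_seed(noise_seed, 2L), smooth_random_field3d(dim(vol), amp))
    gain <- with_seed(derive_seed(noise_seed, 3L), stats::rnorm(1, 1, model$gain_sd))
    vol <- vol * bias * gain
    vol <- with_seed(derive_seed(noise_seed, 4L), {
      n <- length(vol)
      g1 <- stats::rnorm(n, 0, sigma_noise)
      g2 <- stats::rnorm(n, 0, sigma_noise)
      array(sqrt((as.vector(vol) + g1)^2 + g2^2), dim = dim(vol))
    })
  }

  structure(list(
    intensities = vol,
    voxel_mm = voxel,
    setup = setup,
    repetition = NA_integer_,
    noise_seed = as.integer(noise_seed),
    sigma_noise = sigma_noise,
    provenance = attr(truth, "phantom_name") %||% "unnamed"
  ), class = "MRVolume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MRVolume <- function(x, ...) {
  cat("MRVolume:", x$provenance, "|", x$setup$label %||% "<no setup>",
      "| rep", x$repetition, "\n")
  cat("  grid:", paste(dim(x$intensities), collapse = " x "), "at",
      x$voxel_mm, "mm\n")
  invisible(x)
}

#' Repeated acquisitions of one phantom
#'
#' Repetitions share the phantom and setup and differ only in repositioning
#' shift, bias field, gain and noise realization; all seeds derive
#' deterministically from `base_seed`.
#'
#' @param phantom A `VoxelPhantom`.
#' @param setup One row of [enumerate_setups()].
#' @param n_rep Number of repetitions (>= 2; the study default is 3).
#' @param base_seed Master seed.
#' @param model `ContrastModel`.
#' @return List of `MRVolume`s of length `n_rep`.
#' @export
repeat_scan <- function(phantom, setup, n_rep = 3L, base_seed = 1L,
                        model = default_contrast_model()) {
  stopifnot(n_rep >= 2L)
  truth <- assign_contrast(phantom, model, setup$weighting)
  attr(truth, "phantom_name") <- phantom$name
  lapply(seq_len(n_rep), function(r) {
    v <- acquire(truth, phantom$pitch_mm, setup,
                 noise_seed = derive_seed(base_seed, match(setup$weighting, c("T1", "T2")),
                                          setup$channels, round(setup$voxel_mm * 10), r),
                 model = model)
    v$repetition <- as.integer(r)
    v
  })
}

#' Estimate the Rician noise level from a signal-free background
#'
#' In magnitude MR images the signal-free background is Rayleigh distributed
#' with mean `sigma * sqrt(pi / 2)`; the underlying Gaussian noise sigma is
#' recovered from the background mean.
#'
#' @param volume An `MRVolume` (or numeric array of background intensities).
#' @param background Logical array marking background voxels; by default the
#'   whole volume is treated as background.
#' @return Estimated noise standard deviation.
#' @export
estimate_background_noise <- function(volume, background = NULL) {
  v <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  x <- if (is.null(background)) as.vector(v) else v[background]
  mean(x) / sqrt(pi / 2)
}
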