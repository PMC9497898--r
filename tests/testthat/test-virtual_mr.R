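# The virtual scanner: setup enumeration, contrast assignment, the
# acquisition chain and its noise statistics.

test_that("setup enumeration reproduces the 24-row factorial design", {
  s <- enumerate_setups()
  expect_identical(nrow(s), 24L)
  expect_identical(s$label[1], "1.5T_T1_6ch_1mm_FBS")
  expect_identical(s$label[24], "3T_T2_32ch_2mm_FBN")
  expect_identical(sum(s$field_T == 1.5), 8L)
  expect_false(anyDuplicated(s$label) > 0)
  # imaging-only deduplication: 12 distinct scan protocols
  expect_identical(nrow(unique(s[, c("field_T", "weighting", "channels",
                                     "voxel_mm")])), 12L)
  expect_identical(enumerate_setups(), s)  # idempotent
})

test_that("setup labels round-trip and invalid coil/field pairs are rejected", {
  s <- enumerate_setups()
  back <- parse_setup_label(s$label)
  expect_identical(back$label, s$label)
  expect_error(parse_setup_label("1.5T_T1_32ch_1mm_FBS"), "invalid field/coil")
  expect_error(parse_setup_label("junk"), "malformed")
})

test_that("contrast assignment maps materials as expected", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  model <- default_contrast_model()
  for (w in c("T1", "T2")) {
    vol <- assign_contrast(ph, model, w)
    plastic_mean <- mean(vol[ph$labels == 1L])
    solution_mean <- mean(vol[ph$labels == 2L])
    expect_lt(plastic_mean, solution_mean)  # code dark on bright fill
  }
  # uniform fill-only phantom maps to a constant volume
  fill <- new_voxel_phantom("fill", array(2L, dim = c(8, 8, 8)), 1)
  vol <- assign_contrast(fill, model, "T1")
  expect_true(all(vol == model$intensity["solution", "T1"]))
  # missing label entry errors
  weird <- new_voxel_phantom("weird", array(9L, dim = c(4, 4, 4)), 1)
  expect_error(assign_contrast(weird, model, "T1"), "no entry")
})

test_that("the noiseless limit equals blur plus box downsampling exactly", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  truth <- assign_contrast(ph, weighting = "T1")
  setup <- enumerate_setups()[1, ]
  nl <- acquire(truth, 0.5, setup, noiseless = TRUE)
  ref <- box_downsample3d(gaussian_blur3d(truth, 1 / 2.355 / 0.5), 2L)
  expect_equal(nl$intensities, ref)
  expect_error(acquire(truth, 0.7, setup), "incompatible")
})

test_that("blur and downsampling conserve the mean of a uniform region", {
  truth <- array(100, dim = c(48, 48, 48))
  setup <- enumerate_setups()[1, ]
  nl <- acquire(truth, 0.5, setup, noiseless = TRUE)
  core <- nl$intensities[5:20, 5:20, 5:20]
  expect_lt(abs(mean(core) - 100) / 100, 0.005)
})

test_that("acquisition is deterministic in the noise seed", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  truth <- assign_contrast(ph, weighting = "T1")
  setup <- enumerate_setups()[3, ]
  a <- acquire(truth, 0.5, setup, noise_seed = 9L)
  b <- acquire(truth, 0.5, setup, noise_seed = 9L)
  expect_identical(a$intensities, b$intensities)
  c2 <- acquire(truth, 0.5, setup, noise_seed = 10L)
  expect_false(identical(a$intensities, c2$intensities))
})

test_that("signal-free background is Rayleigh with mean/sd ratio 1.91", {
  truth <- array(0, dim = c(48, 48, 48))  # pure air
  setup <- enumerate_setups()[1, ]
  v <- acquire(truth, 0.5, setup, noise_seed = 5L)
  bg <- as.vector(v$intensities)
  expect_gte(length(bg), 1e4)
  ratio <- mean(bg) / stats::sd(bg)
  expect_equal(ratio, sqrt(pi / 2) / sqrt(2 - pi / 2), tolerance = 0.05)
})

test_that("doubling the SNR halves the background noise", {
  truth <- array(0, dim = c(40, 40, 40))
  setup <- enumerate_setups()[1, ]
  m1 <- default_contrast_model(list(snr = c("1.5T_6ch" = 18, "3T_8ch" = 25, "3T_32ch" = 35)))
  m2 <- default_contrast_model(list(snr = c("1.5T_6ch" = 36, "3T_8ch" = 25, "3T_32ch" = 35)))
  s1 <- stats::sd(acquire(truth, 0.5, setup, 5L, model = m1)$intensities)
  s2 <- stats::sd(acquire(truth, 0.5, setup, 5L, model = m2)$intensities)
  expect_equal(s1 / s2, 2, tolerance = 0.05)
})

test_that("repeated scans differ only in their noise realization and are reproducible", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  setup <- enumerate_setups()[1, ]
  vols <- repeat_scan(ph, setup, 3, base_seed = 21L)
  expect_length(vols, 3L)
  expect_false(identical(vols[[1]]$intensities, vols[[2]]$intensities))
  expect_false(identical(vols[[2]]$intensities, vols[[3]]$intensities))
  again <- repeat_scan(ph, setup, 3, base_seed = 21L)
  for (r in 1:3) expect_identical(vols[[r]]$intensities, again[[r]]$intensities)
  expect_error(repeat_scan(ph, setup, 1), "n_rep")
})

test_that("fill-region repetition noise matches the preset sigma", {
  # isolate the stochastic noise: no bias, gain drift or repositioning
  model <- default_contrast_model(list(gain_sd = 0, shift_frac = 0,
                                       bias_amp = c("1.5T" = 0, "3T" = 0)))
  fill <- new_voxel_phantom("fill", array(2L, dim = c(24, 24, 24)), 0.5)
  setup <- enumerate_setups()[1, ]
  vols <- repeat_scan(fill, setup, 50, base_seed = 3L, model = model)
  stack <- vapply(vols, function(v) as.vector(v$intensities[4:9, 4:9, 4:9]),
                  numeric(216))
  per_voxel_sd <- apply(stack, 1, stats::sd)
  expect_equal(median(per_voxel_sd), vols[[1]]$sigma_noise, tolerance = 0.1)
})

test_that("background noise level is recovered from the Rayleigh mean", {
  truth <- array(0, dim = c(40, 40, 40))
  setup <- enumerate_setups()[5, ]
  v <- acquire(truth, 0.5, setup, noise_seed = 8L)
  est <- estimate_background_noise(v)
  expect_equal(est, v$sigma_noise, tolerance = 0.1)
})

test_that("volumes survive a NIfTI round trip with setup metadata", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  setup <- enumerate_setups()[1, ]
  v <- repeat_scan(ph, setup, 2, 1L)[[1]]
  prefix <- file.path(withr::local_tempdir(), "vol")
  write_mrvolume(v, prefix)
  back <- read_mrvolume(prefix)
  expect_equal(back$intensities, v$intensities, tolerance = 1e-6)
  expect_identical(back$setup$label, setup$label)
  expect_equal(back$voxel_mm, 1)
})
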