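# Ground-truth phantom generation: QR voxelization, Hilbert geometry,
# biological textures, rotations.

test_that("QR phantom voxelization preserves the module matrix bit-for-bit", {
  for (spec in list(list(dims = c(50, 50, 40), h = 30),
                    list(dims = c(40, 40, 30), h = 20))) {
    ph <- make_qr_phantom(study_payload, spec$dims, spec$h, pitch_mm = 0.5)
    expect_s3_class(ph, "VoxelPhantom")
    expect_true(all(qr_phantom_modules(ph) == ph$qr_modules))
    expect_identical(ph$payload, study_payload)
    # dims invariant: grid extents x pitch match the requested size
    expect_equal(sort(ph$dims_mm), sort(spec$dims), tolerance = 0.5)
    expect_true(all(ph$labels %in% PHANTOM_LABELS))
  }
})

test_that("QR phantom rejects oversized payloads and too-coarse pitches", {
  expect_error(make_qr_phantom(strrep("q", 400), pitch_mm = 0.5), "capacity")
  expect_error(make_qr_phantom(study_payload, pitch_mm = 1), "pitch too coarse")
  expect_error(make_qr_phantom(study_payload, code_height_mm = 45), "smaller")
})

test_that("QR phantom generation is deterministic", {
  a <- make_qr_phantom(study_payload, pitch_mm = 0.5)
  b <- make_qr_phantom(study_payload, pitch_mm = 0.5)
  expect_identical(a$labels, b$labels)
})

test_that("3D Hilbert curves are self-avoiding unit-step chains", {
  h1 <- hilbert_curve3d(1)
  expect_identical(dim(h1), c(8L, 3L))
  expect_true(all(rowSums(abs(diff(h1))) == 1))
  h2 <- hilbert_curve3d(2)
  expect_identical(dim(h2), c(64L, 3L))
  expect_identical(nrow(unique(h2)), 64L)       # visits every cell once
  expect_true(all(h2 >= 0 & h2 <= 3))           # 4 x 4 x 4 lattice
  expect_true(all(rowSums(abs(diff(h2))) == 1)) # 63 unit steps
})

test_that("the Hilbert pipe is a single 26-connected component", {
  ph <- make_hilbert_phantom(pitch_mm = 0.5)
  lab <- ph$labels
  iw <- round((ph$wall_mm + 0.5) / 0.5)
  d <- dim(lab)
  inner <- lab[(iw + 1):(d[1] - iw), (iw + 1):(d[2] - iw), (iw + 1):(d[3] - iw)]
  pipe <- array(as.integer(inner == PHANTOM_LABELS[["plastic"]]), dim = dim(inner))
  comp <- label_equal_components3d(pipe)
  expect_identical(max(comp), 1L)
  # outer faces carry both plastic and carved air
  face <- lab[1, , ]
  expect_true(any(face == PHANTOM_LABELS[["air"]]) &&
                any(face == PHANTOM_LABELS[["plastic"]]))
})

test_that("too-wide pipes raise a geometry error", {
  expect_error(make_hilbert_phantom(pipe_width_mm = 20, pitch_mm = 0.5),
               "exceeds the Hilbert cell size")
})

test_that("biological phantoms are deterministic and have at least 3 tissue classes", {
  for (kind in c("kiwi", "tomato", "onion")) {
    a <- make_bio_phantom(kind, c(40, 40, 40), rng_seed = 1, pitch_mm = 1)
    b <- make_bio_phantom(kind, c(40, 40, 40), rng_seed = 1, pitch_mm = 1)
    expect_identical(a$labels, b$labels)
    expect_identical(a$modulation, b$modulation)
    classes <- setdiff(unique(as.vector(a$labels)), 0L)
    expect_gte(length(classes), 3L)
    c2 <- make_bio_phantom(kind, c(40, 40, 40), rng_seed = 2, pitch_mm = 1)
    expect_false(identical(a$labels, c2$labels) && identical(a$modulation, c2$modulation))
  }
  expect_error(make_bio_phantom("banana", c(40, 40, 40), 1))
  expect_error(make_bio_phantom("kiwi", c(60, 45, 40), 1), "50 mm")
})

test_that("onion shell volume fractions match the ellipsoidal-shell geometry", {
  ph <- make_bio_phantom("onion", c(40, 40, 40), rng_seed = 7, pitch_mm = 0.5)
  p <- ph$params
  # analytic fractions: shells live between fractional radii k*t..(k+1)*t and
  # an ellipsoidal shell's volume fraction is u_hi^3 - u_lo^3; the core
  # (u <= core_frac) overrides whichever shells it intersects
  t <- p$shell_frac
  fr <- c(a = 0, b = 0)
  k <- 0
  while (k * t < 1) {
    lo <- max(k * t, p$core_frac)
    hi <- min(1, (k + 1) * t)
    if (hi > lo) {
      cls <- if (k %% 2 == 0) "a" else "b"
      fr[cls] <- fr[cls] + hi^3 - lo^3
    }
    k <- k + 1
  }
  core <- p$core_frac^3
  body <- sum(ph$labels > 0)
  got <- c(a = sum(ph$labels == 3L) / body, b = sum(ph$labels == 4L) / body,
           core = sum(ph$labels == 5L) / body)
  expect_equal(unname(got["a"]), unname(fr["a"]), tolerance = 0.02)
  expect_equal(unname(got["b"]), unname(fr["b"]), tolerance = 0.02)
  expect_equal(unname(got["core"]), core, tolerance = 0.02)
  # shell count along the mid-line is within the configured range
  d <- dim(ph$labels)
  profile <- ph$labels[(d[1] %/% 2):d[1], d[2] %/% 2, d[3] %/% 2]
  profile <- profile[profile > 0]
  n_shells <- length(rle(as.vector(profile))$lengths)
  expect_gte(n_shells, 5L)
  expect_lte(n_shells, ceiling(1 / t) + 1L)
})

test_that("90-degree rotations are exact grid permutations", {
  ph <- make_bio_phantom("kiwi", c(40, 40, 40), rng_seed = 3, pitch_mm = 1)
  r1 <- rotate_phantom(ph, "z", 90)
  # same label multiset, exact permutation
  expect_identical(sort(table(r1$labels)), sort(table(ph$labels)))
  # rotating four times returns the original grid
  r4 <- ph
  for (i in 1:4) r4 <- rotate_phantom(r4, "z", 90)
  expect_identical(r4$labels, ph$labels)
  # direct index-permutation check for one slice
  d <- dim(ph$labels)
  expect_identical(r1$labels[, , d[3] %/% 2],
                   t(ph$labels[, , d[3] %/% 2])[d[2]:1, , drop = FALSE])
})

test_that("arbitrary-angle rotation resamples labels without inventing classes", {
  ph <- make_bio_phantom("onion", c(40, 40, 40), rng_seed = 5, pitch_mm = 1)
  r <- rotate_phantom(ph, "z", 45)
  expect_true(all(unique(as.vector(r$labels)) %in% unique(as.vector(ph$labels))))
  expect_identical(dim(r$labels), dim(ph$labels))
})

test_that("phantom kinds are texture-distinguishable beyond within-kind spread", {
  # GLCM contrast of the noiseless contrast-assigned volume, FBN-discretized:
  # kiwi and onion must differ by more than the spread across seeds
  contrast_of <- function(kind, seed) {
    ph <- make_bio_phantom(kind, c(40, 40, 40), rng_seed = seed, pitch_mm = 1)
    vol <- assign_contrast(ph, weighting = "T1")
    mask <- ph$labels > 0
    dv <- discretize_fbn(vol, mask, D = 16)
    unname(glcm_features(compute_glcm(dv))["Contrast"])
  }
  kiwi <- vapply(1:3, function(s) contrast_of("kiwi", s), numeric(1))
  onion <- vapply(1:3, function(s) contrast_of("onion", s), numeric(1))
  gap <- abs(mean(kiwi) - mean(onion))
  spread <- max(diff(range(kiwi)), diff(range(onion)))
  expect_gt(gap, spread)
})

test_that("phantoms survive a NIfTI round trip", {
  prefix <- file.path(withr::local_tempdir(), "phantom")
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  write_phantom(ph, prefix)
  back <- read_phantom(prefix)
  expect_identical(back$labels, ph$labels)
  expect_identical(back$payload, ph$payload)
  expect_equal(back$pitch_mm, ph$pitch_mm)
})
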