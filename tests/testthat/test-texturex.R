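# Texture matrices and features against hand arithmetic and brute-force
# enumeration oracles.

toy22 <- function() {
  # 2x2 plane: levels [[1,1],[1,2]] with rows as the first array axis
  mk_dvoi(array(c(1L, 1L, 1L, 2L), dim = c(2, 2, 1)))
}

test_that("GLCM on the 2x2 toy grid matches hand enumeration", {
  g <- compute_glcm(toy22())
  dirs <- unique_directions3d()
  kx <- which(vapply(dirs, function(d) all(d == c(1, 0, 0)), logical(1)))
  # two vertical pairs (along the first axis): (1,1) and (1,2), symmetrized
  expect_equal(g$prob[, , kx], matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  f <- glcm_features_one(matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(unname(f["Energy"]), 0.375)
  expect_equal(unname(f["JointEntropy"]), 1.5)  # bits
})

test_that("GLCM/GLRLM/GLSZM equal brute-force enumeration on random VOIs", {
  dirs <- all_directions13()
  withr::with_seed(10, {
    for (trial in 1:12) {
      n <- sample(4:6, 3, replace = TRUE)
      g <- sample(2:5, 1)
      arr <- array(sample(seq_len(g), prod(n), replace = TRUE), dim = n)
      dv <- mk_dvoi(arr)
      dv$G <- g
      lv <- arr
      gm <- compute_glcm(dv)
      rm <- compute_glrlm(dv)
      zm <- compute_glszm(dv)
      for (k in seq_along(dirs)) {
        expect_true(all(gm$counts[, , k] == brute_glcm(lv, dirs[[k]], g)))
        bg <- brute_glrlm(lv, dirs[[k]], g)
        got <- gm_r <- rm$counts[, , k]
        expect_true(all(got[, seq_len(ncol(bg)), drop = FALSE] == bg))
        if (ncol(got) > ncol(bg)) expect_true(all(got[, (ncol(bg) + 1):ncol(got)] == 0))
      }
      bz <- brute_glszm(lv, g)
      expect_true(all(zm$counts[, seq_len(ncol(bz)), drop = FALSE] == bz))
    }
  })
})

test_that("matrix conservation laws hold exactly", {
  withr::with_seed(20, {
    arr <- array(sample(1:4, 7^3, replace = TRUE), dim = c(7, 7, 7))
  })
  dv <- mk_dvoi(arr)
  g <- compute_glcm(dv)
  for (k in seq_len(g$n_directions)) {
    expect_equal(sum(g$prob[, , k]), 1)
  }
  r <- compute_glrlm(dv)
  lens <- seq_len(dim(r$counts)[2])
  for (k in seq_len(r$n_directions)) {
    expect_equal(sum(r$counts[, , k] %*% lens), 343)
  }
  z <- compute_glszm(dv)
  expect_equal(sum(z$counts %*% seq_len(ncol(z$counts))), 343)
})

test_that("GLRLM short-run emphasis matches the 1D hand example", {
  dv <- mk_dvoi(array(c(1L, 1L, 2L), dim = c(3, 1, 1)))
  r <- compute_glrlm(dv)
  dirs <- unique_directions3d()
  kx <- which(vapply(dirs, function(d) all(d == c(1, 0, 0)), logical(1)))
  f <- rl_features_one(matrix(r$counts[, , kx], r$G, dim(r$counts)[2]), 3, "run")
  expect_equal(unname(f["SRE"]), 0.625)  # (1/4 + 1) / 2
})

test_that("constant VOIs give single runs whose LRE grows with row length squared", {
  dirs <- unique_directions3d()
  kx <- which(vapply(dirs, function(d) all(d == c(1, 0, 0)), logical(1)))
  lre <- vapply(c(4L, 8L), function(L) {
    dv <- mk_dvoi(array(1L, dim = c(L, 2, 2)))
    r <- compute_glrlm(dv)
    unname(rl_features_one(matrix(r$counts[, , kx], 1), r$n_voxels, "run")["LRE"])
  }, numeric(1))
  expect_equal(lre[2] / lre[1], 4)  # L^2 scaling
})

test_that("GLSZM hand examples: toy zones and constant-VOI zone percentage", {
  z <- compute_glszm(toy22())
  f <- glszm_features(z)
  expect_equal(unname(f["SAE"]), (1 / 9 + 1) / 2)
  zc <- compute_glszm(mk_dvoi(array(1L, dim = c(3, 3, 3))))
  expect_equal(unname(glszm_features(zc)["ZP"]), 1 / 27)
})

test_that("checkerboard contrast is 1 along axis directions", {
  d <- c(6, 6, 6)
  idx <- arrayInd(seq_len(prod(d)), d)
  chk <- array(1L + (idx[, 1] + idx[, 2] + idx[, 3]) %% 2L, dim = d)
  g <- compute_glcm(mk_dvoi(chk))
  dirs <- unique_directions3d()
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    k <- which(vapply(dirs, function(dd) all(dd == ax), logical(1)))
    f <- glcm_features_one(matrix(g$prob[, , k], 2, 2))
    expect_equal(unname(f["Contrast"]), 1)
  }
})

test_that("degenerate single-level VOIs return the analytic limits", {
  dv <- mk_dvoi(array(1L, dim = c(4, 4, 4)))
  f <- glcm_features(compute_glcm(dv))
  expect_equal(unname(f["JointEntropy"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Jmax"]), 1)
  expect_true(all(is.finite(glrlm_features(compute_glrlm(dv)))))
  expect_true(all(is.finite(glszm_features(compute_glszm(dv)))))
})

test_that("direction-averaged features are invariant under 90-degree rotations", {
  withr::with_seed(30, {
    arr <- array(sample(1:4, 6^3, replace = TRUE), dim = c(6, 6, 6))
  })
  rot_z <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  a2 <- rot_z(arr)
  f1 <- glcm_features(compute_glcm(mk_dvoi(arr)))
  f2 <- glcm_features(compute_glcm(mk_dvoi(a2)))
  expect_equal(f1, f2, tolerance = 1e-12)
  r1 <- glrlm_features(compute_glrlm(mk_dvoi(arr)))
  r2 <- glrlm_features(compute_glrlm(mk_dvoi(a2)))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("histogram statistics match direct computation", {
  arr <- array(c(1, 2, 3, 4), dim = c(4, 1, 1))
  m <- array(TRUE, dim = dim(arr))
  h <- histogram_stats(arr, m)
  expect_equal(unname(h), c(1, 4, 2.5, 2.5, 4))
  single <- histogram_stats(array(7, c(1, 1, 1)), array(TRUE, c(1, 1, 1)))
  expect_equal(unname(single), c(7, 7, 7, 7, 1))
  withr::with_seed(40, {
    x <- stats::rnorm(1e4, 10, 2)
  })
  h2 <- histogram_stats(array(x, c(100, 100, 1)), array(TRUE, c(100, 100, 1)))
  expect_lt(abs(h2["mean"] - 10), 3 * 2 / sqrt(1e4))
})

test_that("the feature catalogue has 45 names in four families", {
  fam <- feature_families()
  expect_identical(nrow(fam), 45L)
  expect_identical(as.integer(table(fam$family)[c("GLCM", "GLRLM", "GLSZM", "Histogram")]),
                   c(18L, 11L, 11L, 5L))
  # the features later excluded for poor repeatability must all be members
  excluded9 <- c("Jmax", "Energy", "ClusterShade", "HGRE", "SRHGE", "LRHGE",
                 "LZE", "LZLGE", "LZHGE")
  expect_true(all(excluded9 %in% fam$feature))
})

test_that("extract_all returns 45 finite features and honours discretization", {
  ph <- make_qr_phantom(study_payload, c(40, 40, 30), 20, pitch_mm = 0.5)
  setups <- enumerate_setups()
  vol <- repeat_scan(ph, setups[1, ], 2, 11L)[[1]]
  voi <- cubic_voi(vol, edge_mm = 30)
  for (si in c(1, 2)) {  # FBS and FBN
    fv <- extract_all(vol, voi, setups[si, ])
    expect_length(fv, 45L)
    expect_true(all(is.finite(fv)))
    expect_identical(names(fv), feature_families()$feature)
  }
  # FBN features are invariant when the volume is rescaled by 10
  vol10 <- vol
  vol10$intensities <- vol$intensities * 10
  fa <- extract_all(vol, voi, setups[2, ])
  fb <- extract_all(vol10, voi, setups[2, ])
  tex <- setdiff(names(fa), c("min", "max", "mean", "median"))
  expect_equal(fa[tex], fb[tex], tolerance = 1e-10)
})
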