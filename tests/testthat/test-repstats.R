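# CV / RPD / ICC statistics, feature exclusion, CV summaries and the study
# orchestrator.

test_that("CV matches hand arithmetic and flags undefined cases", {
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)  # sample sd 1, mean 2
  z <- cv(c(0, 0, 0))
  expect_true(is.na(z))
  expect_identical(attr(z, "undefined"), "zero mean")
})

test_that("CV is scale invariant", {
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- stats::rnorm(5, 50, 4)
      c0 <- stats::runif(1, 0.1, 10)
      expect_equal(cv(c0 * x), cv(x), tolerance = 1e-10)
    }
  })
})

test_that("RPD is signed, anchored at setup 1 and flags zero denominators", {
  expect_equal(rpd(2, 1), 50)
  expect_equal(rpd(5, 5), 0)
  expect_equal(rpd(1, 2), -100)  # not symmetric
  expect_true(is.na(rpd(0, 1)))
})

test_that("the 14 comparison pairs reference valid setups", {
  p <- comparison_pairs()
  expect_identical(nrow(p), 14L)
  expect_identical(p$comparison[1], "1.5T_T1_6ch_1mm-2mm")
  expect_identical(c(p$setup1[1], p$setup2[1]), c(1L, 3L))
  s <- enumerate_setups()
  expect_true(all(c(p$setup1, p$setup2) %in% s$setup_id))
  expect_identical(sum(grepl("T1", p$comparison)), 7L)
  expect_identical(sum(grepl("T2", p$comparison)), 7L)
})

test_that("ICC matches the hand-worked two-way ANOVA example", {
  r <- icc(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))
  expect_equal(r$MSR, 8)
  expect_equal(r$MSC, 1.5)
  expect_equal(r$MSE, 0)
  expect_equal(r$icc, 8 / 9)
  expect_identical(r$category, "good")
})

test_that("ICC of identical columns is exactly 1; constant offsets lower it", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  expect_equal(icc(m)$icc, 1)
  expect_identical(icc(m)$category, "excellent")
  m2 <- m
  m2[, 2] <- m2[, 2] + 1
  expect_lt(icc(m2)$icc, 1)
  # degenerate all-constant matrix is flagged undefined
  expect_true(is.na(icc(matrix(5, 3, 2))$icc))
})

test_that("ICC categories follow the 0.9/0.75/0.5 thresholds", {
  expect_identical(icc_category(0.92), "excellent")
  expect_identical(icc_category(0.8), "good")
  expect_identical(icc_category(0.6), "moderate")
  expect_identical(icc_category(0.3), "poor")
})

test_that("ICC equals an lm()-based ANOVA oracle on random matrices", {
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- sample(3:8, 1)
      k <- sample(2:5, 1)
      m <- matrix(stats::rnorm(n * k, 10, 3), n, k)
      expect_equal(icc(m)$icc, icc_oracle(m), tolerance = 1e-10)
    }
  })
})

fake_repeat_table <- function(features, objects = "obj1",
                              labels = "1.5T_T1_6ch_1mm_FBS", n_rep = 3,
                              noise_sd = 0.001, base = 100, seed = 5) {
  withr::with_seed(seed, {
    rows <- expand.grid(object = objects, label = labels,
                        repetition = seq_len(n_rep), feature = features,
                        stringsAsFactors = FALSE)
    rows$value <- base + stats::rnorm(nrow(rows), 0, noise_sd * base)
    tibble::as_tibble(rows)
  })
}

test_that("exclusion flags exactly the planted high-variance features", {
  stable <- setdiff(feature_families()$feature,
                    c("Jmax", "Energy", "ClusterShade", "HGRE", "SRHGE",
                      "LRHGE", "LZE", "LZLGE", "LZHGE"))
  planted <- c("Jmax", "Energy", "ClusterShade", "HGRE", "SRHGE", "LRHGE",
               "LZE", "LZLGE", "LZHGE")
  labels <- c("1.5T_T1_6ch_1mm_FBS", "3T_T1_8ch_1mm_FBS")
  tab <- dplyr::bind_rows(
    fake_repeat_table(stable, objects = c("a", "b"), labels = labels,
                      noise_sd = 0.005),
    fake_repeat_table(planted, objects = c("a", "b"), labels = labels,
                      noise_sd = 0.25, seed = 6)
  )
  cvs <- cv_table(tab)
  res <- exclude_unstable(cvs, threshold = 10)
  expect_setequal(res$excluded, planted)
  expect_setequal(res$retained, stable)
  # a feature with all-zero CVs is retained
  const_tab <- fake_repeat_table("const_feature", noise_sd = 0)
  expect_identical(exclude_unstable(cv_table(const_tab))$excluded, character(0))
})

test_that("CV summaries average within groups and conserve the global mean", {
  tab <- fake_repeat_table(c("f1", "f2"), objects = c("a", "b"),
                           labels = c("1.5T_T1_6ch_1mm_FBS", "1.5T_T1_6ch_2mm_FBS"),
                           noise_sd = 0.02)
  cvs <- cv_table(tab)
  by_obj <- summarize_cv(cvs, "object")
  # weighted recombination of group means equals the global mean
  glob <- mean(abs(cvs$cv))
  recomb <- sum(by_obj$cv_average * by_obj$n_defined) / sum(by_obj$n_defined)
  expect_equal(recomb, glob, tolerance = 1e-12)
  expect_identical(nrow(summarize_cv(cvs, "voxel_mm")), 2L)
  # trivial group mean
  one <- tibble::tibble(object = "o", label = "1.5T_T1_6ch_1mm_FBS",
                        feature = c("f1", "f2"), cv = c(1, 3), n_rep = 3L)
  expect_equal(summarize_cv(one, "object")$cv_average, 2)
})

test_that("rpd and icc tables cover the comparisons present in the data", {
  labels <- enumerate_setups()$label[c(1, 3)]
  tab <- fake_repeat_table(c("f1", "f2"), objects = c("a", "b", "c"),
                           labels = labels, noise_sd = 0.01)
  rp <- rpd_table(tab)
  expect_setequal(unique(rp$comparison), "1.5T_T1_6ch_1mm-2mm")
  expect_identical(nrow(rp), 6L)  # 3 objects x 2 features
  ic <- icc_table(tab)
  expect_identical(nrow(ic), 2L)  # 2 features, one comparison
  expect_true(all(ic$icc <= 1))
})

test_that("a small end-to-end study has the expected cardinality and is deterministic", {
  cfg <- study_config(
    phantoms = c("smallQR", "onion"),
    setups = enumerate_setups()$label[c(1, 2, 3, 4)],
    n_rep = 2, seed = 3, phantom_pitch_mm = 0.5
  )
  res <- run_study(cfg)
  expect_identical(nrow(res$features), 2L * 4L * 2L * 45L)
  expect_identical(sort(unique(res$features$object)), c("onion", "smallQR"))
  out1 <- withr::local_tempdir()
  write_study(res, out1)
  expect_true(file.exists(file.path(out1, "features.csv")))
  expect_true(file.exists(file.path(out1, "cv_onion.png")))
  # heatmap integrity: every plotted CV is a value from cv.csv
  csv <- utils::read.csv(file.path(out1, "cv.csv"))
  expect_equal(nrow(csv), nrow(res$cv))
  expect_equal(sort(csv$cv), sort(res$cv$cv), tolerance = 1e-8)
  # byte-identical reruns under the same master seed
  res2 <- run_study(cfg)
  out2 <- withr::local_tempdir()
  write_study(res2, out2)
  expect_identical(unname(tools::md5sum(file.path(out1, "features.csv"))),
                   unname(tools::md5sum(file.path(out2, "features.csv"))))
})
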