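# Repeatability and reliability statistics: coefficient of variation across
# repeated scans, relative percentage differences between acquisition setups,
# two-way ANOVA intraclass correlation, CV-based feature exclusion, and the
# study orchestrator that chains phantom -> scan -> VOI -> features -> stats.

#' Coefficient of variation of repeated measurements
#'
#' `CV = sd(x) / mean(x) * 100` with the sample (n-1) standard deviation.
#' A zero mean makes the CV undefined; it is returned as `NA` with an
#' attribute flag so aggregation layers can log and drop it.
#'
#' @param values Numeric vector of at least 2 repetition values.
#' @return CV in percent, or `NA` (flagged) for a zero mean.
#' @export
cv <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) {
    return(structure(NA_real_, undefined = "zero mean"))
  }
  stats::sd(values) / m * 100
}

#' Relative percentage difference between two setup means
#'
#' `RPD = (mean1 - mean2) / mean1 * 100`; signed, with the first setup fixed
#' as the denominator (so the measure is not symmetric). Summaries use the
#' absolute value.
#'
#' @param mean1,mean2 Mean feature values of the two setups.
#' @return Signed RPD in percent, or flagged `NA` if `mean1` is zero.
#' @export
rpd <- function(mean1, mean2) {
  if (mean1 == 0) {
    return(structure(NA_real_, undefined = "zero denominator"))
  }
  (mean1 - mean2) / mean1 * 100
}

#' The 14 between-setup comparisons
#'
#' Seven comparisons per weighting, referencing FBS-row setup ids of
#' [enumerate_setups()]: resolution (1 vs 2 mm) within each coil, field
#' strength at matched resolution, and coil count at 3 T.
#'
#' @return A tibble with `comparison`, `setup1`, `setup2`.
#' @export
comparison_pairs <- function() {
  t1 <- tibble::tribble(
    ~comparison, ~setup1, ~setup2,
    "1.5T_T1_6ch_1mm-2mm", 1L, 3L,
    "1.5T_T1_6ch-3T_T1_8ch_1mm", 1L, 5L,
    "1.5T_T1_6ch-3T_T1_8ch_2mm", 3L, 7L,
    "3T_T1_8ch_1mm-2mm", 5L, 7L,
    "3T_T1_8ch-32ch_1mm", 5L, 9L,
    "3T_T1_8ch-32ch_2mm", 7L, 11L,
    "3T_T1_32ch_1mm-2mm", 9L, 11L
  )
  t2 <- t1
  t2$comparison <- gsub("T1", "T2", t2$comparison, fixed = TRUE)
  t2$setup1 <- t2$setup1 + 12L
  t2$setup2 <- t2$setup2 + 12L
  dplyr::bind_rows(t1, t2)
}

#' Intraclass correlation coefficient (two-way ANOVA, absolute agreement)
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the
#' two-way ANOVA mean squares of an n-subjects x k-measurements matrix
#' (single rater/measurement, absolute agreement). Values can be negative;
#' categories use the 0.9 / 0.75 / 0.5 thresholds.
#'
#' @param mat Numeric matrix, rows = subjects (objects), columns = setups
#'   (per-object means over repetitions).
#' @return An `ICCResult` list: `icc`, `MSR`, `MSC`, `MSE`, `n`, `k`,
#'   `category`.
#' @export
icc <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < .Machine$double.eps * max(1, abs(msr))) {
    return(structure(list(icc = NA_real_, MSR = msr, MSC = msc, MSE = mse,
                          n = n, k = k, category = NA_character_,
                          undefined = "zero variance"), class = "ICCResult"))
  }
  val <- (msr - mse) / denom
  structure(list(icc = val, MSR = msr, MSC = msc, MSE = mse, n = n, k = k,
                 category = icc_category(val)), class = "ICCResult")
}

#' ICC repeatability category
#'
#' @param x ICC value(s).
#' @return `"excellent"` (> 0.9), `"good"` (0.75-0.9], `"moderate"`
#'   (0.5-0.75], or `"poor"` (<= 0.5).
#' @export
icc_category <- function(x) {
  ifelse(x > 0.9, "excellent",
         ifelse(x > 0.75, "good",
                ifelse(x > 0.5, "moderate", "poor")))
}

#' @export
print.ICCResult <- function(x, ...) {
  cat("ICC =", format(x$icc, digits = 4), "(", x$category, ") n =", x$n,
      "k =", x$k, "\n")
  invisible(x)
}

# ---- RepeatTable helpers ----------------------------------------------------

# A RepeatTable is a long tibble with columns object, setup_label (or label),
# repetition, feature, value.

#' Per-feature CVs of a repeat table
#'
#' @param table Long tibble with columns `object`, `label`, `repetition`,
#'   `feature`, `value`.
#' @return Tibble with one row per (object, label, feature) and its `cv`;
#'   undefined CVs (zero mean) are `NA`.
#' @export
cv_table <- function(table) {
  table |>
    dplyr::group_by(.data$object, .data$label, .data$feature) |>
    dplyr::summarise(
      cv = as.numeric(cv(.data$value)),
      n_rep = dplyr::n(),
      .groups = "drop"
    )
}

#' Exclude features with poor repeatability
#'
#' A feature is excluded when its aggregated CV exceeds `threshold` percent.
#' The default aggregation is the mean of the defined (non-`NA`) CVs over all
#' objects and setups; `"any"` instead excludes a feature whose CV exceeds
#' the threshold for any object/setup.
#'
#' @param cvs Output of [cv_table()] (uses absolute CV values).
#' @param threshold CV threshold in percent (study rule: 10).
#' @param aggregate `"mean"` or `"any"`.
#' @return List with `retained`, `excluded` (feature names) and the
#'   aggregated `cv_by_feature` tibble.
#' @export
exclude_unstable <- function(cvs, threshold = 10, aggregate = c("mean", "any")) {
  aggregate <- match.arg(aggregate)
  agg <- cvs |>
    dplyr::filter(!is.na(.data$cv)) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      cv_agg = if (aggregate == "mean") mean(abs(.data$cv)) else max(abs(.data$cv)),
      .groups = "drop"
    )
  excluded <- agg$feature[agg$cv_agg > threshold]
  list(
    retained = setdiff(unique(cvs$feature), excluded),
    excluded = excluded,
    cv_by_feature = agg
  )
}

#' Average CVs by a grouping property
#'
#' Arithmetic mean of the defined CVs within groups of a setup property
#' (`"field_T"`, `"voxel_mm"`, `"weighting"`, `"discretization"`), the
#' feature family, or the object. Undefined (`NA`) CVs are dropped and
#' counted.
#'
#' @param cvs Output of [cv_table()].
#' @param group_by Character vector of grouping columns; setup properties are
#'   derived from the label.
#' @return Tibble of group means (`cv_average`) with `n_defined`, `n_undefined`.
#' @export
summarize_cv <- function(cvs, group_by = "object") {
  props <- parse_setup_label(cvs$label)
  fam <- feature_families()
  full <- dplyr::bind_cols(cvs, props[, c("field_T", "weighting", "voxel_mm",
                                          "discretization")])
  full <- dplyr::left_join(full, fam, by = "feature")
  full |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      cv_average = mean(abs(.data$cv[!is.na(.data$cv)])),
      n_defined = sum(!is.na(.data$cv)),
      n_undefined = sum(is.na(.data$cv)),
      .groups = "drop"
    )
}

#' RPDs for the 14 standard comparisons
#'
#' @param table Repeat table (long) restricted to one normalization state.
#' @param pairs Comparison definitions from [comparison_pairs()].
#' @param setups Setup table from [enumerate_setups()].
#' @return Tibble with signed `rpd` per (object, comparison, feature).
#' @export
rpd_table <- function(table, pairs = comparison_pairs(), setups = enumerate_setups()) {
  means <- table |>
    dplyr::group_by(.data$object, .data$label, .data$feature) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    l1 <- setups$label[pairs$setup1[i]]
    l2 <- setups$label[pairs$setup2[i]]
    m1 <- means[means$label == l1, c("object", "feature", "m")]
    m2 <- means[means$label == l2, c("object", "feature", "m")]
    j <- dplyr::inner_join(m1, m2, by = c("object", "feature"),
                           suffix = c("1", "2"))
    if (!nrow(j)) next
    j$rpd <- ifelse(j$m1 == 0, NA_real_, (j$m1 - j$m2) / j$m1 * 100)
    j$comparison <- pairs$comparison[i]
    out[[length(out) + 1L]] <- j[, c("object", "comparison", "feature", "rpd")]
  }
  dplyr::bind_rows(out)
}

#' ICCs for the 14 standard comparisons
#'
#' For each comparison and feature, the subjects are the objects and the two
#' columns are the per-object means (over repetitions) under the two setups.
#'
#' @inheritParams rpd_table
#' @return Tibble with `icc` and `category` per (comparison, feature).
#' @export
icc_table <- function(table, pairs = comparison_pairs(), setups = enumerate_setups()) {
  means <- table |>
    dplyr::group_by(.data$object, .data$label, .data$feature) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    l1 <- setups$label[pairs$setup1[i]]
    l2 <- setups$label[pairs$setup2[i]]
    feats <- unique(means$feature)
    for (f in feats) {
      m1 <- means[means$label == l1 & means$feature == f, c("object", "m")]
      m2 <- means[means$label == l2 & means$feature == f, c("object", "m")]
      j <- dplyr::inner_join(m1, m2, by = "object", suffix = c("1", "2"))
      if (nrow(j) < 2) next
      r <- icc(as.matrix(j[, c("m1", "m2")]))
      out[[length(out) + 1L]] <- tibble::tibble(
        comparison = pairs$comparison[i], feature = f,
        icc = r$icc, category = r$category %||% NA_character_
      )
    }
  }
  dplyr::bind_rows(out)
}

# ---- Study orchestration ----------------------------------------------------

#' Default study configuration
#'
#' Desk-scale defaults: the three printed phantoms and three biological
#' phantoms, all 24 setups, 3 repetitions. `phantom_pitch_mm` defaults to
#' 0.5 mm to keep the full factorial tractable; the ground-truth default of
#' 0.25 mm in [make_qr_phantom()] is used for readability analyses.
#'
#' @param ... Overrides of the config fields.
#' @return Named list.
#' @export
study_config <- function(...) {
  cfg <- list(
    phantoms = c("largeQR", "smallQR", "hilbert", "kiwi", "tomato", "onion"),
    setups = NULL,           # NULL = all 24
    n_rep = 3L,
    seed = 1L,
    normalize = TRUE,
    phantom_pitch_mm = 0.5,
    contrast_overrides = list(),
    voi_edge_mm = c(largeQR = 55, smallQR = 45, hilbert = 50),
    exclusion_threshold = 10,
    payload = "UNIDEB MRI Texture Analysis Phantom"
  )
  utils::modifyList(cfg, list(...))
}

study_phantom <- function(name, cfg) {
  p <- cfg$phantom_pitch_mm
  switch(name,
    largeQR = make_qr_phantom(cfg$payload, c(50, 50, 40), 30, pitch_mm = p),
    smallQR = make_qr_phantom(cfg$payload, c(40, 40, 30), 20, pitch_mm = p),
    hilbert = make_hilbert_phantom(pitch_mm = p),
    kiwi = make_bio_phantom("kiwi", c(45, 45, 40), derive_seed(cfg$seed, 31L), pitch_mm = p),
    tomato = make_bio_phantom("tomato", c(45, 45, 40), derive_seed(cfg$seed, 32L), pitch_mm = p),
    onion = make_bio_phantom("onion", c(40, 40, 40), derive_seed(cfg$seed, 33L), pitch_mm = p),
    stop("unknown phantom name: ", name)
  )
}

#' Run the full simulated repeatability study
#'
#' Forges the configured phantoms, scans each under every configured setup
#' with `n_rep` repetitions, places VOIs (cubic for the printed phantoms,
#' region-grown for the biological ones), extracts the 45 features, and
#' computes CV, RPD, ICC and the CV-based exclusion. Deterministic for a
#' fixed `cfg$seed`.
#'
#' @param cfg Configuration from [study_config()].
#' @param out_dir Optional directory: writes `features.csv`, `cv.csv`,
#'   `rpd.csv`, `icc.csv`, `excluded_features.json` and CV heatmaps.
#' @return List: `features` (repeat table), `cv`, `rpd`, `icc`, `exclusion`,
#'   `setups`, `config`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL) {
  setups <- enumerate_setups()
  if (!is.null(cfg$setups)) {
    setups <- setups[setups$label %in% cfg$setups, ]
    if (!nrow(setups)) stop("study stage 'setups': no configured setup matches")
  }
  model <- default_contrast_model(cfg$contrast_overrides)

  rows <- list()
  for (ph_name in cfg$phantoms) {
    phantom <- tryCatch(study_phantom(ph_name, cfg),
                        error = function(e) stop("study stage 'forge' (", ph_name, "): ",
                                                 conditionMessage(e)))
    # imaging-only protocols: scan once per unique protocol, reuse for FBS/FBN
    proto <- unique(setups[, c("field_T", "weighting", "channels", "voxel_mm")])
    for (pi in seq_len(nrow(proto))) {
      prot <- proto[pi, ]
      sub <- setups[setups$field_T == prot$field_T &
                      setups$weighting == prot$weighting &
                      setups$channels == prot$channels &
                      setups$voxel_mm == prot$voxel_mm, ]
      scan_setup <- sub[1, ]
      vols <- tryCatch(
        repeat_scan(phantom, scan_setup, cfg$n_rep,
                    base_seed = derive_seed(cfg$seed, match(ph_name, cfg$phantoms)),
                    model = model),
        error = function(e) stop("study stage 'scan' (", ph_name, ", ",
                                 scan_setup$label, "): ", conditionMessage(e)))
      for (r in seq_along(vols)) {
        vol <- vols[[r]]
        mask <- tryCatch({
          if (ph_name %in% names(cfg$voi_edge_mm)) {
            edge <- min(cfg$voi_edge_mm[[ph_name]],
                        (dim(vol$intensities) - 1) * vol$voxel_mm)
            cubic_voi(vol, edge_mm = edge)
          } else {
            grow_voi(vol)
          }
        }, error = function(e) stop("study stage 'voi' (", ph_name, "): ",
                                    conditionMessage(e)))
        for (si in seq_len(nrow(sub))) {
          fv <- tryCatch(
            extract_all(vol, mask, sub[si, ], normalize = cfg$normalize),
            error = function(e) stop("study stage 'extract' (", ph_name, ", ",
                                     sub$label[si], "): ", conditionMessage(e)))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            object = ph_name, label = sub$label[si], repetition = r,
            feature = names(fv), value = as.numeric(fv)
          )
        }
      }
    }
  }
  features <- dplyr::bind_rows(rows)
  cvs <- cv_table(features)
  excl <- exclude_unstable(cvs, cfg$exclusion_threshold)
  rpds <- rpd_table(features, setups = enumerate_setups())
  iccs <- if (length(unique(features$object)) >= 2) {
    icc_table(features, setups = enumerate_setups())
  } else {
    tibble::tibble(comparison = character(), feature = character(),
                   icc = numeric(), category = character())
  }
  res <- list(features = features, cv = cvs, rpd = rpds, icc = iccs,
              exclusion = excl, setups = setups, config = cfg)
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(res$cv, file.path(out_dir, "cv.csv"), row.names = FALSE)
  utils::write.csv(res$rpd, file.path(out_dir, "rpd.csv"), row.names = FALSE)
  utils::write.csv(res$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  jsonlite::write_json(res$exclusion[c("retained", "excluded")],
                       file.path(out_dir, "excluded_features.json"))
  for (obj in unique(res$cv$object)) {
    p <- cv_heatmap(res$cv, obj)
    ggplot2::ggsave(file.path(out_dir, paste0("cv_", obj, ".png")), p,
                    width = 9, height = 6, dpi = 120)
  }
  invisible(out_dir)
}

#' CV heatmap for one object (setups x features)
#'
#' @param cvs Output of [cv_table()].
#' @param object Object name to plot.
#' @return A ggplot object.
#' @export
cv_heatmap <- function(cvs, object) {
  d <- cvs[cvs$object == object, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$label,
                                  fill = abs(.data$cv))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "CV (%)", na.value = "black") +
    ggplot2::labs(title = paste("CV,", object), x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
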