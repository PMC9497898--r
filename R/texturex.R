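# Texture matrices (GLCM, GLRLM, GLSZM) and the study's 45 features:
# 18 co-occurrence, 11 run-length, 11 size-zone and 5 histogram statistics,
# following the IBSI definitions. GLCM and GLRLM use 3D distance-1 offsets
# over the 13 unique directions with symmetric accumulation and features
# averaged over directions; GLSZM uses 26-connected zones and a single
# matrix. Logarithms are base 2 (entropies in bits).

glcm_feature_names <- function() {
  c("Jmax", "JointAverage", "JointVariance", "JointEntropy",
    "DifferenceAverage", "DifferenceVariance", "DifferenceEntropy",
    "SumAverage", "SumVariance", "SumEntropy", "Energy", "Contrast",
    "Dissimilarity", "InverseDifference", "InverseDifferenceMoment",
    "Correlation", "ClusterShade", "ClusterProminence")
}

glrlm_feature_names <- function() {
  c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE", "SRHGE",
    "LRLGE", "LRHGE")
}

glszm_feature_names <- function() {
  c("SAE", "LZE", "GLN_z", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE", "SZHGE",
    "LZLGE", "LZHGE")
}

histogram_feature_names <- function() {
  c("min", "max", "mean", "median", "voxel_count")
}

#' Names and families of the 45 features
#'
#' @return A tibble with columns `feature` and `family`.
#' @export
feature_families <- function() {
  tibble::tibble(
    feature = c(glcm_feature_names(), glrlm_feature_names(),
                glszm_feature_names(), histogram_feature_names()),
    family = rep(c("GLCM", "GLRLM", "GLSZM", "Histogram"),
                 times = c(18L, 11L, 11L, 5L))
  )
}

levels_of <- function(dvoi) {
  lv <- dvoi$levels
  lv[is.na(lv)] <- 0L
  lv
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence counts of in-mask voxel pairs at Chebyshev
#' distance `distance` along the 13 unique 3D directions, plus per-direction
#' probability normalization.
#'
#' @param dvoi A `DiscreteVOI`.
#' @param distance Offset length in voxels.
#' @return A `TextureMatrix` with `counts` and `prob` arrays of dim
#'   `c(G, G, 13)`.
#' @export
compute_glcm <- function(dvoi, distance = 1L) {
  lv <- levels_of(dvoi)
  g <- dvoi$G
  if (sum(lv > 0L) == 0L) stop("empty mask")
  dirs <- unique_directions3d()
  counts <- array(0, dim = c(g, g, length(dirs)))
  for (k in seq_along(dirs)) {
    b <- array_shift3d(lv, -dirs[[k]] * distance, fill = 0L)
    ok <- lv > 0L & b > 0L
    if (any(ok)) {
      tab <- tabulate((lv[ok] - 1L) * g + b[ok], nbins = g * g)
      m <- matrix(tab, g, g, byrow = TRUE)
      counts[, , k] <- m + t(m)  # symmetric accumulation
    }
  }
  prob <- counts
  for (k in seq_along(dirs)) {
    s <- sum(counts[, , k])
    if (s > 0) prob[, , k] <- counts[, , k] / s
  }
  structure(list(kind = "GLCM", counts = counts, prob = prob, G = g,
                 distance = distance, n_directions = length(dirs),
                 n_voxels = sum(lv > 0L)), class = "TextureMatrix")
}

glcm_features_one <- function(p) {
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)
  j <- t(i)
  nz <- p > 0
  mu <- sum(i * p)
  jvar <- sum((i - mu)^2 * p)
  adiff <- abs(i - j)
  pd <- vapply(0:(g - 1L), function(k) sum(p[adiff == k]), numeric(1))
  kd <- 0:(g - 1L)
  da <- sum(kd * pd)
  ps <- vapply(2:(2 * g), function(s) sum(p[(i + j) == s]), numeric(1))
  ks <- 2:(2 * g)
  sa <- sum(ks * ps)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  corr <- if (jvar > 0) (sum(i * j * p) - mu^2) / jvar else 1
  c(
    Jmax = max(p),
    JointAverage = mu,
    JointVariance = jvar,
    JointEntropy = ent(p),
    DifferenceAverage = da,
    DifferenceVariance = sum((kd - da)^2 * pd),
    DifferenceEntropy = ent(pd),
    SumAverage = sa,
    SumVariance = sum((ks - sa)^2 * ps),
    SumEntropy = ent(ps),
    Energy = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Dissimilarity = sum(adiff * p),
    InverseDifference = sum(p / (1 + adiff)),
    InverseDifferenceMoment = sum(p / (1 + (i - j)^2)),
    Correlation = corr,
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p)
  )
}

#' GLCM features (18, averaged over directions)
#'
#' @param m A `TextureMatrix` from [compute_glcm()].
#' @return Named numeric vector of length 18.
#' @export
glcm_features <- function(m) {
  stopifnot(m$kind == "GLCM")
  per_dir <- vapply(seq_len(m$n_directions), function(k) {
    glcm_features_one(matrix(m$prob[, , k], m$G, m$G))
  }, numeric(18L))
  rowMeans(per_dir)
}

#' Gray-level run-length matrix
#'
#' Maximal runs of equal gray level along each of the 13 unique directions.
#'
#' @param dvoi A `DiscreteVOI`.
#' @return A `TextureMatrix` with `counts` of dim `c(G, max_run, 13)`.
#' @export
compute_glrlm <- function(dvoi) {
  lv <- levels_of(dvoi)
  g <- dvoi$G
  nvox <- sum(lv > 0L)
  if (nvox == 0L) stop("empty mask")
  dirs <- unique_directions3d()
  pos <- arrayInd(which(lv > 0L), dim(lv))
  val <- lv[lv > 0L]
  runs <- vector("list", length(dirs))
  max_len <- 1L
  for (k in seq_along(dirs)) {
    d <- dirs[[k]]
    ax1 <- which(d != 0)[1]
    t <- pos[, ax1] * d[ax1]  # monotone step counter along the direction
    key1 <- pos[, 1] - t * d[1]
    key2 <- pos[, 2] - t * d[2]
    key3 <- pos[, 3] - t * d[3]
    o <- order(key1, key2, key3, t)
    kk1 <- key1[o]; kk2 <- key2[o]; kk3 <- key3[o]
    tt <- t[o]; vv <- val[o]
    brk <- c(TRUE, diff(kk1) != 0 | diff(kk2) != 0 | diff(kk3) != 0 |
               diff(tt) != 1 | diff(vv) != 0)
    rid <- cumsum(brk)
    rlen <- tabulate(rid)
    rlev <- vv[brk]
    max_len <- max(max_len, max(rlen))
    runs[[k]] <- list(lev = rlev, len = rlen)
  }
  counts <- array(0, dim = c(g, max_len, length(dirs)))
  for (k in seq_along(dirs)) {
    tab <- tabulate((runs[[k]]$lev - 1L) * max_len + runs[[k]]$len,
                    nbins = g * max_len)
    counts[, , k] <- matrix(tab, g, max_len, byrow = TRUE)
  }
  structure(list(kind = "GLRLM", counts = counts, G = g,
                 n_directions = length(dirs), n_voxels = nvox),
            class = "TextureMatrix")
}

rl_features_one <- function(r, nvox, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  if (!is.matrix(r)) r <- matrix(r, nrow = 1)
  gi <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  ji <- t(matrix(seq_len(ncol(r)), ncol(r), nrow(r)))
  n <- sum(r)
  ri <- rowSums(r)
  rj <- colSums(r)
  vals <- c(
    sum(r / ji^2) / n,            # short runs / small zones emphasis
    sum(r * ji^2) / n,            # long runs / large zones
    sum(ri^2) / n,                # gray-level non-uniformity
    sum(rj^2) / n,                # length / size non-uniformity
    n / nvox,                     # run / zone percentage
    sum(r / gi^2) / n,            # low gray-level emphasis
    sum(r * gi^2) / n,            # high gray-level emphasis
    sum(r / (gi^2 * ji^2)) / n,
    sum(r * gi^2 / ji^2) / n,
    sum(r * ji^2 / gi^2) / n,
    sum(r * gi^2 * ji^2) / n
  )
  names(vals) <- if (prefix == "run") glrlm_feature_names() else glszm_feature_names()
  vals
}

#' GLRLM features (11, averaged over directions)
#'
#' @param m A `TextureMatrix` from [compute_glrlm()].
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(m) {
  stopifnot(m$kind == "GLRLM")
  per_dir <- vapply(seq_len(m$n_directions), function(k) {
    rl_features_one(matrix(m$counts[, , k], m$G, dim(m$counts)[2]), m$n_voxels, "run")
  }, numeric(11L))
  rowMeans(per_dir)
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal 26-connected components of equal gray level; a single
#' matrix without directionality.
#'
#' @param dvoi A `DiscreteVOI`.
#' @return A `TextureMatrix` with `counts` of dim `c(G, max_zone_size)`.
#' @export
compute_glszm <- function(dvoi) {
  lv <- levels_of(dvoi)
  g <- dvoi$G
  nvox <- sum(lv > 0L)
  if (nvox == 0L) stop("empty mask")
  comp <- label_equal_components3d(lv)
  memb <- comp[comp > 0L]
  sizes <- tabulate(memb)
  first_of <- match(seq_along(sizes), memb)
  zlev <- lv[comp > 0L][first_of]
  counts <- matrix(0, g, max(sizes))
  tab <- tabulate((zlev - 1L) * max(sizes) + sizes, nbins = g * max(sizes))
  counts <- matrix(tab, g, max(sizes), byrow = TRUE)
  structure(list(kind = "GLSZM", counts = counts, G = g, n_voxels = nvox),
            class = "TextureMatrix")
}

#' GLSZM features (11)
#'
#' @param m A `TextureMatrix` from [compute_glszm()].
#' @return Named numeric vector of length 11.
#' @export
glszm_features <- function(m) {
  stopifnot(m$kind == "GLSZM")
  rl_features_one(m$counts, m$n_voxels, "zone")
}

#' Histogram statistics over the masked raw intensities
#'
#' Minimum, maximum, mean, median and voxel count of the pre-discretization
#' intensities inside the mask.
#'
#' @param volume An `MRVolume` or numeric array.
#' @param mask A `VOIMask` or logical array.
#' @return Named numeric vector of length 5.
#' @export
histogram_stats <- function(volume, mask) {
  v <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  x <- v[m]
  if (!length(x)) stop("empty mask")
  c(min = min(x), max = max(x), mean = mean(x), median = stats::median(x),
    voxel_count = length(x))
}

#' Extract the full 45-feature vector for one VOI
#'
#' Optionally applies mu +/- 3 sigma normalization, discretizes according to
#' the setup (FBS with B = 0.15 normalized / 50 raw, or FBN with D = 64) and
#' computes all four feature families. Histogram statistics are taken on the
#' raw (pre-normalization) intensities.
#'
#' @param volume An `MRVolume`.
#' @param mask A `VOIMask` or logical array.
#' @param setup One row of [enumerate_setups()] (uses `discretization`).
#' @param normalize Apply normalization before discretization (study default).
#' @return Named numeric vector of length 45.
#' @export
extract_all <- function(volume, mask, setup, normalize = TRUE) {
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  raw <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  if (normalize) {
    nrm <- normalize_mu3sigma(raw, m)
    vals <- nrm$values
    m <- nrm$mask
  } else {
    vals <- raw
  }
  dv <- discretize_for_setup(vals, m, setup, normalized = normalize)
  out <- c(
    glcm_features(compute_glcm(dv)),
    glrlm_features(compute_glrlm(dv)),
    glszm_features(compute_glszm(dv)),
    histogram_stats(raw, m)
  )
  stopifnot(length(out) == 45L)
  out
}
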