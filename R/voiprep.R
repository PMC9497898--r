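# VOI definition, mu +/- 3 sigma intensity normalization and gray-level
# discretization (fixed bin size / fixed bin number).

#' Axis-aligned cubic volume of interest
#'
#' @param volume An `MRVolume`.
#' @param center_mm Cube center in mm (defaults to the volume center).
#' @param edge_mm Cube edge length in mm (the study uses 55, 50 and 45 mm for
#'   the large QR, Hilbert and small QR phantoms).
#' @return A `VOIMask` list with a logical `mask` and `voxel_count`.
#' @export
cubic_voi <- function(volume, center_mm = NULL, edge_mm) {
  d <- dim(volume$intensities)
  vx <- volume$voxel_mm
  if (is.null(center_mm)) center_mm <- d * vx / 2
  half <- edge_mm / 2
  idx <- lapply(1:3, function(k) {
    mm_range_idx(center_mm[k] - half, center_mm[k] + half, vx, d[k])
  })
  n_expect <- round(edge_mm / vx)
  if (any(lengths(idx) < n_expect)) {
    stop("cubic VOI of edge ", edge_mm, " mm exceeds the volume bounds")
  }
  idx <- lapply(idx, function(i) i[seq_len(n_expect)])
  mask <- array(FALSE, dim = d)
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  structure(list(mask = mask, method = "cubic", edge_mm = edge_mm,
                 voxel_count = sum(mask)), class = "VOIMask")
}

#' Region-grown volume of interest for biological phantoms
#'
#' Otsu foreground threshold, restriction to the 26-connected component(s)
#' containing the seeds, one-voxel morphological erosion (border-zone
#' exclusion) and removal of the most apical and basal occupied axial (z)
#' slices.
#'
#' @param volume An `MRVolume`.
#' @param seeds Matrix of voxel indices (rows = seeds, 3 columns), or `NULL`
#'   to seed at the brightest voxel.
#' @return A `VOIMask`.
#' @export
grow_voi <- function(volume, seeds = NULL) {
  v <- volume$intensities
  thr <- otsu_threshold(as.vector(v))
  fg <- v > thr
  if (!any(fg)) stop("empty VOI: no foreground above the Otsu threshold")
  if (is.null(seeds)) {
    seeds <- matrix(arrayInd(which.max(v), dim(v)), nrow = 1)
  }
  seeds <- matrix(as.integer(seeds), ncol = 3)
  comp <- label_equal_components3d(array(as.integer(fg), dim = dim(v)))
  seed_comp <- unique(comp[seeds])
  seed_comp <- setdiff(seed_comp, 0L)
  if (!length(seed_comp)) stop("empty VOI: no seed lies in the foreground")
  mask <- array(comp %in% seed_comp, dim = dim(v))
  mask <- erode26(mask)
  zocc <- which(apply(mask, 3, any))
  if (length(zocc) > 2) {
    mask[, , c(zocc[1], zocc[length(zocc)])] <- FALSE
  } else {
    mask[] <- FALSE
  }
  if (!any(mask)) stop("empty VOI after border and apical/basal slice exclusion")
  structure(list(mask = mask, method = "grown", edge_mm = NA_real_,
                 voxel_count = sum(mask)), class = "VOIMask")
}

#' Normalize VOI intensities to mu +/- 3 sigma z-scores
#'
#' Within the mask, intensities map to `z = (I - mu) / sigma` with `mu`, and
#' the sample (n-1) standard deviation `sigma`, computed over the mask;
#' values beyond three standard deviations are clipped to +-3 by default
#' (alternatively excluded from the mask).
#'
#' @param volume An `MRVolume` or numeric 3D array.
#' @param mask A `VOIMask` or logical array.
#' @param clip If `TRUE` (default) clip `|z| > 3`; otherwise drop those voxels
#'   from the returned mask.
#' @return List with `values` (normalized array, `NA` outside the mask),
#'   `mask`, and the `NormalizationSpec` fields `mu`, `sigma`, `clip_k`.
#' @export
normalize_mu3sigma <- function(volume, mask, clip = TRUE) {
  v <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  x <- v[m]
  if (length(x) < 2) stop("normalization needs at least 2 voxels in the mask")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("degenerate VOI: zero standard deviation")
  z <- (v - mu) / sigma
  out_mask <- m
  if (clip) {
    z[m & z > 3] <- 3
    z[m & z < -3] <- -3
  } else {
    out_mask <- m & abs(z) <= 3
  }
  z[!out_mask] <- NA_real_
  list(values = z, mask = out_mask, mu = mu, sigma = sigma, clip_k = 3)
}

#' Fixed-bin-size gray-level discretization
#'
#' Levels are `ceiling((I - I_min) / B)` with the VOI minimum mapped to
#' level 1, so bins have width `B` anchored at the VOI minimum. The study
#' uses `B = 0.15` for normalized and `B = 50` for raw intensities, chosen to
#' give a similar bin count (a normalized range of 6 spans 40 bins). An
#' IBSI-style variant `floor((I - I_min) / B) + 1` is available.
#'
#' @param volume Numeric 3D array (or `MRVolume`).
#' @param mask Logical array or `VOIMask`.
#' @param B Bin width (> 0).
#' @param variant `"ceil"` (default) or `"ibsi_floor"`.
#' @return A `DiscreteVOI`: integer `levels` array (`NA` outside mask),
#'   `mask`, `G` (maximum occupied level), `method`, `B`.
#' @export
discretize_fbs <- function(volume, mask, B = 0.15, variant = c("ceil", "ibsi_floor")) {
  variant <- match.arg(variant)
  stopifnot(B > 0)
  v <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  if (!any(m)) stop("empty mask")
  x <- v[m]
  imin <- min(x)
  lev <- if (variant == "ceil") {
    l <- ceiling((x - imin) / B)
    l[l < 1] <- 1L
    l
  } else {
    floor((x - imin) / B) + 1
  }
  levels <- array(NA_integer_, dim = dim(v))
  levels[m] <- as.integer(lev)
  structure(list(levels = levels, mask = m, G = max(lev), method = "FBS",
                 B = B, D = NA_integer_), class = "DiscreteVOI")
}

#' Fixed-bin-number gray-level discretization
#'
#' Levels are 1 at the VOI minimum and `ceiling(D * (I - I_min) /
#' (I_max - I_min))` otherwise, always in `[1, D]`; the study uses `D = 64`.
#' A constant VOI yields all levels 1 with a warning.
#'
#' @inheritParams discretize_fbs
#' @param D Number of bins (>= 2).
#' @return A `DiscreteVOI` with `G = D`.
#' @export
discretize_fbn <- function(volume, mask, D = 64L) {
  stopifnot(D >= 2)
  v <- if (inherits(volume, "MRVolume")) volume$intensities else volume
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  if (!any(m)) stop("empty mask")
  x <- v[m]
  imin <- min(x)
  imax <- max(x)
  if (imax == imin) {
    warning("constant VOI: all gray levels set to 1")
    lev <- rep(1L, length(x))
  } else {
    lev <- ceiling(D * (x - imin) / (imax - imin))
    lev[x == imin] <- 1L
    lev[lev > D] <- as.integer(D)
  }
  levels <- array(NA_integer_, dim = dim(v))
  levels[m] <- as.integer(lev)
  structure(list(levels = levels, mask = m, G = as.integer(D), method = "FBN",
                 B = NA_real_, D = as.integer(D)), class = "DiscreteVOI")
}

# Discretize according to an acquisition setup: FBS uses B = 0.15 on
# normalized and B = 50 on raw intensities; FBN uses D = 64.
discretize_for_setup <- function(values, mask, setup, normalized) {
  if (setup$discretization == "FBS") {
    discretize_fbs(values, mask, B = if (normalized) 0.15 else 50)
  } else {
    discretize_fbn(values, mask, D = 64L)
  }
}
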