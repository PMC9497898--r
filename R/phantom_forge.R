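# Ground-truth voxel phantoms: an extruded QR-code cube, a 3D Hilbert-curve
# cube, and procedural biological look-alikes (kiwi / tomato / onion).
#
# Phantoms are stored on a fine isotropic grid (default 0.25 mm pitch, at
# least 4 ground-truth voxels per 1 mm acquired voxel) so that the virtual
# scanner can model partial-volume averaging faithfully. Label conventions:
# 0 = air, 1 = plastic (signal void), 2 = fill solution (bright),
# 3+ = tissue classes of the biological phantoms.

PHANTOM_LABELS <- c(air = 0L, plastic = 1L, solution = 2L,
                    tissue_a = 3L, tissue_b = 4L, tissue_c = 5L)

new_voxel_phantom <- function(name, labels, pitch_mm, payload = NULL,
                              rng_seed = NA_integer_, modulation = NULL,
                              extra = list()) {
  structure(
    c(list(
      name = name,
      labels = labels,
      pitch_mm = pitch_mm,
      dims_mm = dim(labels) * pitch_mm,
      payload = payload,
      rng_seed = rng_seed,
      modulation = modulation
    ), extra),
    class = "VoxelPhantom"
  )
}

#' @export
print.VoxelPhantom <- function(x, ...) {
  cat("VoxelPhantom:", x$name, "\n")
  cat("  grid:", paste(dim(x$labels), collapse = " x "),
      "at", x$pitch_mm, "mm pitch ->",
      paste(round(x$dims_mm, 1), collapse = " x "), "mm\n")
  tab <- table(x$labels)
  cat("  labels:", paste(names(tab), collapse = "/"),
      "counts:", paste(tab, collapse = "/"), "\n")
  if (!is.null(x$payload)) cat("  payload:", x$payload, "\n")
  invisible(x)
}

# Voxel index range whose centers fall inside [lo, hi) mm along an axis.
mm_range_idx <- function(lo, hi, pitch, n) {
  i0 <- max(1L, floor(lo / pitch + 0.5) + 1L)
  i1 <- min(n, floor(hi / pitch + 0.5))
  if (i1 < i0) integer(0) else i0:i1
}

#' Build a fillable QR-code phantom
#'
#' A hollow plastic container whose interior fill solution embeds the QR code
#' of `text` as plastic columns extruded along the container's height axis.
#' The code face lies in the x-z plane so that coronal (fixed-y) slices of the
#' simulated scans show the full code; module rows run top (high z) to bottom.
#'
#' @param text Payload string encoded into the QR pattern.
#' @param outer_dims_mm Outer dimensions as (face width, face height,
#'   extrusion depth) in mm; the code face must be square.
#' @param code_height_mm Extrusion depth of the code columns along y (mm).
#' @param pitch_mm Ground-truth voxel pitch (mm).
#' @param wall_mm Plastic wall thickness (mm).
#' @param quiet_modules Solution-filled quiet-zone width in modules around the
#'   code.
#' @return A `VoxelPhantom` with the module matrix in `$qr_modules`.
#' @export
make_qr_phantom <- function(text, outer_dims_mm = c(50, 50, 40),
                            code_height_mm = 30, pitch_mm = 0.25,
                            wall_mm = 2, quiet_modules = 1) {
  stopifnot(is.character(text), nzchar(text))
  if (code_height_mm >= outer_dims_mm[3]) {
    stop("code_height_mm must be smaller than the container depth")
  }
  modules <- qr_encode_matrix(text)  # errors out when the payload is too long
  nmod <- nrow(modules)

  X <- outer_dims_mm[1]
  Z <- outer_dims_mm[2]
  Y <- outer_dims_mm[3]
  nx <- round(X / pitch_mm)
  ny <- round(Y / pitch_mm)
  nz <- round(Z / pitch_mm)

  interior <- min(X, Z) - 2 * wall_mm
  module_mm <- interior / (nmod + 2 * quiet_modules)
  if (module_mm < 2 * pitch_mm) {
    stop("pitch too coarse: one QR module spans ", round(module_mm / pitch_mm, 2),
         " ground-truth voxels (need >= 2); use a finer pitch")
  }

  labels <- array(PHANTOM_LABELS[["plastic"]], dim = c(nx, ny, nz))
  ix <- mm_range_idx(wall_mm, X - wall_mm, pitch_mm, nx)
  iy <- mm_range_idx(wall_mm, Y - wall_mm, pitch_mm, ny)
  iz <- mm_range_idx(wall_mm, Z - wall_mm, pitch_mm, nz)
  labels[ix, iy, iz] <- PHANTOM_LABELS[["solution"]]

  side <- (nmod + 2 * quiet_modules) * module_mm
  x0 <- (X - side) / 2
  z1 <- (Z - side) / 2 + side  # top edge of the quiet zone
  y_lo <- (Y - code_height_mm) / 2
  y_hi <- y_lo + code_height_mm
  iy_code <- mm_range_idx(y_lo, y_hi, pitch_mm, ny)

  for (r in seq_len(nmod)) {
    zi <- mm_range_idx(z1 - (quiet_modules + r) * module_mm,
                       z1 - (quiet_modules + r - 1) * module_mm, pitch_mm, nz)
    for (c in seq_len(nmod)) {
      if (!modules[r, c]) next
      xi <- mm_range_idx(x0 + (quiet_modules + c - 1) * module_mm,
                         x0 + (quiet_modules + c) * module_mm, pitch_mm, nx)
      labels[xi, iy_code, zi] <- PHANTOM_LABELS[["plastic"]]
    }
  }

  new_voxel_phantom(
    name = paste0("qr_", nmod, "mod"),
    labels = labels, pitch_mm = pitch_mm, payload = text,
    extra = list(qr_modules = modules, module_mm = module_mm,
                 wall_mm = wall_mm, quiet_modules = quiet_modules,
                 code_height_mm = code_height_mm,
                 code_y_range_mm = c(y_lo, y_hi))
  )
}

# ---- 3D Hilbert curve (Skilling transform) ----------------------------------

# Cell coordinates (0-based, 2^level per axis) visited by the 3D Hilbert curve.
hilbert_curve3d <- function(level) {
  stopifnot(level >= 1)
  n <- 3L
  b <- as.integer(level)
  npts <- 2L^(n * b)
  coords <- matrix(0L, nrow = npts, ncol = 3)
  for (h in 0:(npts - 1L)) {
    hb <- int_to_bits(h, n * b)           # MSB first
    x <- integer(n)
    for (i in seq_len(n)) {
      xb <- hb[seq(i, n * b, by = n)]
      x[i] <- bits_to_int(xb)
    }
    # Skilling: transpose -> axes
    N <- bitwShiftL(2L, b - 1L)
    t <- bitwShiftR(x[n], 1L)
    if (n > 1) for (i in n:2) x[i] <- bitwXor(x[i], x[i - 1L])
    x[1] <- bitwXor(x[1], t)
    q <- 2L
    while (q != N) {
      p <- q - 1L
      for (i in n:1) {
        if (bitwAnd(x[i], q) != 0L) {
          x[1] <- bitwXor(x[1], p)
        } else {
          t <- bitwAnd(bitwXor(x[1], x[i]), p)
          x[1] <- bitwXor(x[1], t)
          x[i] <- bitwXor(x[i], t)
        }
      }
      q <- bitwShiftL(q, 1L)
    }
    coords[h + 1L, ] <- x
  }
  coords
}

#' Build the Hilbert-cube phantom
#'
#' A plastic square-section pipe following the 3D Hilbert curve of the given
#' recursion level, embedded in fill solution inside a cubic container whose
#' outer wall faces carry an alternating plastic/air checker pattern.
#'
#' @param outer_dims_mm Outer cube dimensions (mm).
#' @param recursion_level Hilbert curve recursion level (>= 1).
#' @param pipe_width_mm Square pipe edge length (mm).
#' @param pitch_mm Ground-truth voxel pitch (mm).
#' @param wall_mm Wall thickness (mm).
#' @param checker_mm Checker square edge of the face pattern (mm); carved into
#'   the outer half of the wall. `0` disables the pattern.
#' @return A `VoxelPhantom`; the visited cell centers are in `$curve_cells`.
#' @export
make_hilbert_phantom <- function(outer_dims_mm = c(50, 50, 50),
                                 recursion_level = 2, pipe_width_mm = 6,
                                 pitch_mm = 0.25, wall_mm = 2, checker_mm = 5) {
  stopifnot(recursion_level >= 1, pipe_width_mm >= 2 * pitch_mm)
  d <- outer_dims_mm
  nxyz <- round(d / pitch_mm)
  ncell <- 2^recursion_level
  interior <- d - 2 * wall_mm
  cell_mm <- min(interior) / ncell
  if (pipe_width_mm > cell_mm) {
    stop("pipe width ", pipe_width_mm, " mm exceeds the Hilbert cell size of ",
         round(cell_mm, 2), " mm at recursion level ", recursion_level)
  }

  labels <- array(PHANTOM_LABELS[["plastic"]], dim = nxyz)
  inr <- lapply(1:3, function(k) mm_range_idx(wall_mm, d[k] - wall_mm, pitch_mm, nxyz[k]))
  labels[inr[[1]], inr[[2]], inr[[3]]] <- PHANTOM_LABELS[["solution"]]

  cells <- hilbert_curve3d(recursion_level)
  centers <- wall_mm + (cells + 0.5) * cell_mm
  w2 <- pipe_width_mm / 2
  fill_box <- function(lo, hi) {
    xi <- mm_range_idx(lo[1], hi[1], pitch_mm, nxyz[1])
    yi <- mm_range_idx(lo[2], hi[2], pitch_mm, nxyz[2])
    zi <- mm_range_idx(lo[3], hi[3], pitch_mm, nxyz[3])
    labels[xi, yi, zi] <<- PHANTOM_LABELS[["plastic"]]
  }
  for (s in seq_len(nrow(centers) - 1L)) {
    a <- centers[s, ]
    bpt <- centers[s + 1L, ]
    fill_box(pmin(a, bpt) - w2, pmax(a, bpt) + w2)
  }

  if (checker_mm > 0) {
    depth <- wall_mm / 2  # carve only the outer half so the container seals
    ax_pairs <- list(c(2, 3), c(1, 3), c(1, 2))
    centers_ax <- lapply(1:3, function(k) ((seq_len(nxyz[k])) - 0.5) * pitch_mm)
    for (k in 1:3) {
      ij <- ax_pairs[[k]]
      chk <- outer(floor(centers_ax[[ij[1]]] / checker_mm),
                   floor(centers_ax[[ij[2]]] / checker_mm), "+") %% 2 == 1
      for (side in 1:2) {
        if (side == 1) {
          face <- mm_range_idx(0, depth, pitch_mm, nxyz[k])
        } else {
          face <- mm_range_idx(d[k] - depth, d[k], pitch_mm, nxyz[k])
        }
        idx <- vector("list", 3)
        idx[[k]] <- face
        idx[[ij[1]]] <- seq_len(nxyz[ij[1]])
        idx[[ij[2]]] <- seq_len(nxyz[ij[2]])
        sub <- labels[idx[[1]], idx[[2]], idx[[3]]]
        subd <- array(sub, dim = c(length(idx[[1]]), length(idx[[2]]), length(idx[[3]])))
        carve <- aperm(array(chk, dim = c(nxyz[ij[1]], nxyz[ij[2]], length(face))),
                       order(c(ij, k)))
        subd[carve] <- PHANTOM_LABELS[["air"]]
        labels[idx[[1]], idx[[2]], idx[[3]]] <- subd
      }
    }
  }

  new_voxel_phantom(
    name = paste0("hilbert_l", recursion_level),
    labels = labels, pitch_mm = pitch_mm,
    extra = list(curve_cells = cells, cell_mm = cell_mm,
                 pipe_width_mm = pipe_width_mm, wall_mm = wall_mm)
  )
}

# ---- Biological phantoms ----------------------------------------------------

bio_default_params <- function(kind) {
  switch(kind,
    kiwi = list(core_frac = 0.18, seed_n = 250, seed_radius_mm = 0.9,
                seed_annulus = c(0.30, 0.55), striations = 24,
                striation_amp = 0.12, mod_amp = 0.10),
    tomato = list(wall_frac = 0.18, locules = 4, locule_gap_deg = 18,
                  locule_radial = c(0.25, 0.85), seed_n = 120,
                  seed_radius_mm = 1.1, mod_amp = 0.10),
    onion = list(shell_frac = 0.11, core_frac = 0.15, mod_amp = 0.08),
    stop("unknown biological phantom kind: ", kind)
  )
}

#' Build a procedural biological phantom
#'
#' Ellipsoidal bodies with at least three tissue classes and kind-specific
#' internal structure: `kiwi` has a bright central core, radial striations and
#' a ring of dark seed points; `tomato` has a pericarp wall, locule wedges and
#' seed clusters; `onion` has concentric alternating shells. A smooth random
#' within-class modulation field provides continuous texture.
#'
#' @param kind One of `"kiwi"`, `"tomato"`, `"onion"`.
#' @param dims_mm Bounding dimensions (mm), each at most 50 mm.
#' @param rng_seed Integer seed; identical seeds give identical phantoms.
#' @param pitch_mm Ground-truth voxel pitch (mm).
#' @param params Named list overriding the kind defaults from
#'   `bio_default_params()`.
#' @return A `VoxelPhantom`.
#' @export
make_bio_phantom <- function(kind, dims_mm = c(45, 45, 40), rng_seed = 1L,
                             pitch_mm = 0.25, params = list()) {
  kind <- match.arg(kind, c("kiwi", "tomato", "onion"))
  if (any(dims_mm > 50)) stop("biological phantoms must fit below 50 mm per edge")
  p <- utils::modifyList(bio_default_params(kind), params)
  nxyz <- round(dims_mm / pitch_mm)
  semi <- dims_mm / 2 - 1  # 1 mm air margin

  cx <- (seq_len(nxyz[1]) - 0.5) * pitch_mm - dims_mm[1] / 2
  cy <- (seq_len(nxyz[2]) - 0.5) * pitch_mm - dims_mm[2] / 2
  cz <- (seq_len(nxyz[3]) - 0.5) * pitch_mm - dims_mm[3] / 2
  xg <- array(cx, dim = nxyz)
  yg <- aperm(array(cy, dim = nxyz[c(2, 1, 3)]), c(2, 1, 3))
  zg <- aperm(array(cz, dim = nxyz[c(3, 2, 1)]), c(3, 2, 1))
  u <- sqrt((xg / semi[1])^2 + (yg / semi[2])^2 + (zg / semi[3])^2)
  body <- u <= 1

  labels <- array(PHANTOM_LABELS[["air"]], dim = nxyz)

  with_seed(derive_seed(rng_seed, match(kind, c("kiwi", "tomato", "onion"))), {
    if (kind == "kiwi") {
      labels[body] <- PHANTOM_LABELS[["tissue_a"]]
      ur <- sqrt((xg / semi[1])^2 + (yg / semi[2])^2)  # radial, primary axis z
      core <- body & ur <= p$core_frac & abs(zg) <= 0.85 * semi[3]
      labels[core] <- PHANTOM_LABELS[["tissue_b"]]
      n_seed <- stats::rpois(1, p$seed_n)
      theta <- stats::runif(n_seed, 0, 2 * pi)
      rad <- stats::runif(n_seed, p$seed_annulus[1], p$seed_annulus[2])
      zfr <- stats::runif(n_seed, -0.7, 0.7)
      sx <- rad * cos(theta) * semi[1]
      sy <- rad * sin(theta) * semi[2]
      sz <- zfr * semi[3]
      rs <- p$seed_radius_mm
      for (s in seq_len(n_seed)) {
        xi <- mm_range_idx(sx[s] - rs + dims_mm[1] / 2, sx[s] + rs + dims_mm[1] / 2, pitch_mm, nxyz[1])
        yi <- mm_range_idx(sy[s] - rs + dims_mm[2] / 2, sy[s] + rs + dims_mm[2] / 2, pitch_mm, nxyz[2])
        zi <- mm_range_idx(sz[s] - rs + dims_mm[3] / 2, sz[s] + rs + dims_mm[3] / 2, pitch_mm, nxyz[3])
        if (!length(xi) || !length(yi) || !length(zi)) next
        sub <- array(labels[xi, yi, zi], dim = c(length(xi), length(yi), length(zi)))
        sphere <- outer(outer((cx[xi] - sx[s])^2, (cy[yi] - sy[s])^2, "+"),
                        (cz[zi] - sz[s])^2, "+") <= rs^2
        sub[sphere & sub != PHANTOM_LABELS[["air"]]] <- PHANTOM_LABELS[["tissue_c"]]
        labels[xi, yi, zi] <- sub
      }
    } else if (kind == "tomato") {
      labels[body] <- PHANTOM_LABELS[["tissue_a"]]
      theta <- atan2(yg, xg)
      ur <- sqrt((xg / semi[1])^2 + (yg / semi[2])^2)
      inner <- body & u <= (1 - p$wall_frac)
      wedge_w <- 2 * pi / p$locules
      gap <- p$locule_gap_deg * pi / 180
      ang <- (theta + pi) %% wedge_w
      in_wedge <- ang > gap / 2 & ang < wedge_w - gap / 2
      loc <- inner & in_wedge & ur >= p$locule_radial[1] & ur <= p$locule_radial[2]
      labels[loc] <- PHANTOM_LABELS[["tissue_b"]]
      n_seed <- stats::rpois(1, p$seed_n)
      idx_loc <- which(loc)
      if (length(idx_loc) && n_seed > 0) {
        pick <- sample(idx_loc, min(n_seed, length(idx_loc)))
        rs <- p$seed_radius_mm
        pk <- arrayInd(pick, nxyz)
        for (s in seq_len(nrow(pk))) {
          ctr <- c(cx[pk[s, 1]], cy[pk[s, 2]], cz[pk[s, 3]])
          xi <- mm_range_idx(ctr[1] - rs + dims_mm[1] / 2, ctr[1] + rs + dims_mm[1] / 2, pitch_mm, nxyz[1])
          yi <- mm_range_idx(ctr[2] - rs + dims_mm[2] / 2, ctr[2] + rs + dims_mm[2] / 2, pitch_mm, nxyz[2])
          zi <- mm_range_idx(ctr[3] - rs + dims_mm[3] / 2, ctr[3] + rs + dims_mm[3] / 2, pitch_mm, nxyz[3])
          if (!length(xi) || !length(yi) || !length(zi)) next
          sub <- array(labels[xi, yi, zi], dim = c(length(xi), length(yi), length(zi)))
          sphere <- outer(outer((cx[xi] - ctr[1])^2, (cy[yi] - ctr[2])^2, "+"),
                          (cz[zi] - ctr[3])^2, "+") <= rs^2
          sub[sphere & sub == PHANTOM_LABELS[["tissue_b"]]] <- PHANTOM_LABELS[["tissue_c"]]
          labels[xi, yi, zi] <- sub
        }
      }
    } else {  # onion
      ring <- floor(u / p$shell_frac)
      lab <- ifelse(ring %% 2 == 0, PHANTOM_LABELS[["tissue_a"]], PHANTOM_LABELS[["tissue_b"]])
      labels[body] <- lab[body]
      labels[body & u <= p$core_frac] <- PHANTOM_LABELS[["tissue_c"]]
    }

    modulation <- smooth_random_field3d(nxyz, p$mod_amp)
    if (kind == "kiwi") {
      theta <- atan2(yg, xg)
      modulation <- modulation * (1 + p$striation_amp * sin(p$striations * theta))
    }
  })

  new_voxel_phantom(
    name = paste0(kind, "_s", rng_seed),
    labels = labels, pitch_mm = pitch_mm, rng_seed = as.integer(rng_seed),
    modulation = modulation,
    extra = list(kind = kind, params = p)
  )
}

#' Rotate a phantom about a coordinate axis
#'
#' Multiples of 90 degrees are exact grid permutations; other angles use
#' nearest-neighbour label resampling about the grid center (the grid extents
#' are kept, so corners may clip for strongly anisotropic phantoms).
#'
#' @param phantom A `VoxelPhantom`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg Rotation angle in degrees.
#' @return The rotated `VoxelPhantom`.
#' @export
rotate_phantom <- function(phantom, axis = c("z", "x", "y"), angle_deg = 90) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  rot1 <- function(arr, fill) {
    # +90 degrees about axis k: for k = z, (x, y) -> (-y, x)
    ij <- setdiff(1:3, k)
    perm <- 1:3
    perm[ij] <- ij[2:1]
    out <- aperm(arr, perm)
    idx <- vector("list", 3)
    for (m in 1:3) idx[[m]] <- seq_len(dim(out)[m])
    idx[[ij[1]]] <- rev(idx[[ij[1]]])
    do.call(`[`, c(list(out), idx, list(drop = FALSE)))
  }
  ang <- angle_deg %% 360
  lab <- phantom$labels
  modu <- phantom$modulation
  if (ang %% 90 == 0) {
    for (i in seq_len(ang %/% 90)) {
      lab <- rot1(lab, PHANTOM_LABELS[["air"]])
      if (!is.null(modu)) modu <- rot1(modu, 1)
    }
  } else {
    rot_nn <- function(arr, fill) {
      d <- dim(arr)
      ij <- setdiff(1:3, k)
      a2 <- aperm(arr, c(ij, k))  # planes perpendicular to the axis come last
      dp <- dim(a2)
      ctr <- (dp[1:2] + 1) / 2
      th <- ang * pi / 180
      A <- matrix(seq_len(dp[1]), dp[1], dp[2]) - ctr[1]
      B <- matrix(seq_len(dp[2]), dp[1], dp[2], byrow = TRUE) - ctr[2]
      sa <- round(cos(th) * A + sin(th) * B + ctr[1])
      sb <- round(-sin(th) * A + cos(th) * B + ctr[2])
      ok <- sa >= 1 & sa <= dp[1] & sb >= 1 & sb <= dp[2]
      out <- array(fill, dim = dp)
      src <- cbind(sa[ok], sb[ok])
      for (s in seq_len(dp[3])) {
        pl <- a2[, , s]
        np <- matrix(fill, dp[1], dp[2])
        np[ok] <- pl[src]
        out[, , s] <- np
      }
      aperm(out, order(c(ij, k)))
    }
    lab <- rot_nn(lab, PHANTOM_LABELS[["air"]])
    if (!is.null(modu)) modu <- rot_nn(modu, 1)
  }
  out <- phantom
  out$labels <- lab
  out$modulation <- modu
  out$dims_mm <- dim(lab) * phantom$pitch_mm
  out$name <- paste0(phantom$name, "_rot", axis, angle_deg)
  out
}

#' Collapse the QR code region of a phantom back to a module matrix
#'
#' Averages the plastic fraction over the extrusion axis within each module
#' cell and thresholds at 0.5; used to verify that the voxelization preserves
#' the code bit-for-bit.
#'
#' @param phantom A QR `VoxelPhantom` from [make_qr_phantom()].
#' @return Logical module matrix.
#' @export
qr_phantom_modules <- function(phantom) {
  stopifnot(!is.null(phantom$qr_modules))
  modules <- phantom$qr_modules
  nmod <- nrow(modules)
  pitch <- phantom$pitch_mm
  d <- dim(phantom$labels)
  X <- d[1] * pitch
  Z <- d[3] * pitch
  side <- (nmod + 2 * phantom$quiet_modules) * phantom$module_mm
  x0 <- (X - side) / 2
  z1 <- (Z - side) / 2 + side
  iy <- mm_range_idx(phantom$code_y_range_mm[1] + 1, phantom$code_y_range_mm[2] - 1,
                     pitch, d[2])
  out <- matrix(FALSE, nmod, nmod)
  q <- phantom$quiet_modules
  m <- phantom$module_mm
  for (r in seq_len(nmod)) {
    zi <- mm_range_idx(z1 - (q + r) * m, z1 - (q + r - 1) * m, pitch, d[3])
    for (c in seq_len(nmod)) {
      xi <- mm_range_idx(x0 + (q + c - 1) * m, x0 + (q + c) * m, pitch, d[1])
      frac <- mean(phantom$labels[xi, iy, zi] == PHANTOM_LABELS[["plastic"]])
      out[r, c] <- frac > 0.5
    }
  }
  out
}
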