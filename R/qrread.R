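# QR-code readability of simulated scans: coronal slice export, Lanczos
# interpolation to 1024 x 1024, finder-pattern detection, module grid
# sampling and payload decoding with pluggable binarization backends.
#
# The "decoders" emulate reader diversity (the study's phones and software
# readers) through distinct binarization strategies feeding one standards
# implementation: global Otsu, global mean, and adaptive local-mean
# thresholds behave differently on low-contrast, shaded or noisy slices.

#' Registered QR decoder backends
#'
#' @return Character vector of decoder identifiers.
#' @export
qr_decoders <- function() {
  c("otsu", "mean", "adaptive")
}

binarize_image <- function(img, decoder = "otsu") {
  if (!decoder %in% qr_decoders()) {
    stop("unknown decoder backend: ", decoder)
  }
  # light denoising so isolated noise pixels do not split finder runs
  if (min(dim(img)) >= 64) img <- box_mean2d(img, 3L)
  if (decoder == "otsu") {
    thr <- otsu_threshold(as.vector(img))
    img < thr
  } else if (decoder == "mean") {
    img < mean(img)
    } else {
    # adaptive: blend of local mean and global Otsu so flat regions fall back
    # to the global threshold while shaded regions follow the local one
    n <- dim(img)
    w <- max(15L, 2L * (round(min(n) / 16) %/% 2L) + 1L)
    local <- box_mean2d(img, w)
    thr <- 0.5 * local + 0.5 * otsu_threshold(as.vector(img))
    img < thr
  }
}

# Box mean filter via cumulative sums (window w odd).
box_mean2d <- function(img, w) {
  r <- (w - 1L) %/% 2L
  n <- nrow(img)
  m <- ncol(img)
  cs <- apply(rbind(0, img), 2, cumsum)
  lo <- pmax(1L, seq_len(n) - r)
  hi <- pmin(n, seq_len(n) + r)
  colsum <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cnt_r <- hi - lo + 1L
  cs2 <- t(apply(cbind(0, colsum), 1, cumsum))
  lo2 <- pmax(1L, seq_len(m) - r)
  hi2 <- pmin(m, seq_len(m) + r)
  total <- cs2[, hi2 + 1L, drop = FALSE] - cs2[, lo2, drop = FALSE]
  cnt_c <- hi2 - lo2 + 1L
  total / outer(cnt_r, cnt_c)
}

# ---- Slice handling ---------------------------------------------------------

#' Export every coronal slice of a volume as an 8-bit image
#'
#' Coronal planes are fixed-y; rows run from the top of the phantom (high z)
#' downwards, columns along x. Each slice is min-max windowed to 0..255;
#' constant slices map to mid-gray.
#'
#' @param volume An `MRVolume`.
#' @return List of `SliceImage` lists (`pixels`, `slice_index`, `variant`).
#' @export
export_coronal_slices <- function(volume) {
  v <- volume$intensities
  ny <- dim(v)[2]
  nz <- dim(v)[3]
  lapply(seq_len(ny), function(j) {
    sl <- t(v[, j, ])[nz:1, , drop = FALSE]  # rows = z top-down, cols = x
    rng <- range(sl)
    px <- if (diff(rng) == 0) {
      matrix(128, nrow(sl), ncol(sl))
    } else {
      round((sl - rng[1]) / diff(rng) * 255)
    }
    list(pixels = px, slice_index = j, variant = "original",
         source = volume$provenance)
  })
}

#' Write a slice image as PNG
#'
#' @param slice A `SliceImage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(slice, path) {
  png::writePNG(slice$pixels / 255, path)
  invisible(path)
}

#' Read a PNG back as a slice image
#'
#' @param path PNG path.
#' @return A `SliceImage` with 0..255 pixels.
#' @export
read_slice_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  list(pixels = round(px * 255), slice_index = NA_integer_,
       variant = "original", source = path)
}

#' Lanczos interpolation of a slice to 1024 x 1024
#'
#' The slice is padded to a square with its minimum (dark background) before
#' separable Lanczos-3 resampling, then clamped to 0..255.
#'
#' @param slice A `SliceImage`.
#' @param size Output edge length in pixels.
#' @return The interpolated `SliceImage`.
#' @export
interpolate_slice <- function(slice, size = 1024L) {
  px <- slice$pixels
  n <- dim(px)
  if (n[1] != n[2]) {
    s <- max(n)
    sq <- matrix(min(px), s, s)
    r0 <- (s - n[1]) %/% 2L
    c0 <- (s - n[2]) %/% 2L
    sq[r0 + seq_len(n[1]), c0 + seq_len(n[2])] <- px
    px <- sq
  }
  out <- lanczos_resize(px, c(size, size))
  out <- pmin(pmax(out, 0), 255)
  list(pixels = out, slice_index = slice$slice_index, variant = "interpolated",
       source = slice$source)
}

# ---- Finder-pattern detection and grid sampling -----------------------------

# Check a 5-run subsequence for the 1:1:3:1:1 finder signature.
finder_ratio_ok <- function(lens) {
  m <- sum(lens) / 7
  if (m < 1) return(FALSE)
  all(lens[c(1, 2, 4, 5)] >= 0.4 * m) && all(lens[c(1, 2, 4, 5)] <= 1.9 * m) &&
    lens[3] >= 2 * m && lens[3] <= 4.6 * m
}

# Candidate finder centers from horizontal and vertical scans, each with a
# cross-direction verification.
locate_finder_patterns <- function(dark) {
  cand <- rbind(scan_finder_candidates(dark),
                swap_rowcol(scan_finder_candidates(t(dark))))
  cluster_finder_candidates(cand)
}

swap_rowcol <- function(cand) {
  if (is.null(cand)) return(NULL)
  cand[, c("row", "col")] <- cand[, c("col", "row")]
  cand
}

scan_finder_candidates <- function(dark) {
  n <- nrow(dark)
  m <- ncol(dark)
  stride <- max(1L, n %/% 256L)
  cand <- list()
  for (r in seq(1L, n, by = stride)) {
    runs <- rle(dark[r, ])
    if (length(runs$lengths) < 5L) next
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (s in seq_len(length(runs$lengths) - 4L)) {
      if (!runs$values[s]) next  # must start dark
      lens <- runs$lengths[s:(s + 4L)]
      if (!finder_ratio_ok(lens)) next
      cx <- (starts[s] + ends[s + 4L]) / 2
      w <- sum(lens)
      # vertical verification at the candidate column
      col <- dark[, round(cx)]
      vr <- rle(col)
      vends <- cumsum(vr$lengths)
      vstarts <- vends - vr$lengths + 1L
      vi <- findInterval(r, vstarts)
      if (vi < 3L || vi > length(vr$lengths) - 2L) next
      if (!vr$values[vi]) next
      vlens <- vr$lengths[(vi - 2L):(vi + 2L)]
      if (!finder_ratio_ok(vlens)) next
      vw <- sum(vlens)
      if (vw < 0.5 * w || vw > 2 * w) next
      cy <- (vstarts[vi - 2L] + vends[vi + 2L]) / 2
      cand[[length(cand) + 1L]] <- c(row = cy, col = cx, w = (w + vw) / 2)
    }
  }
  if (!length(cand)) return(NULL)
  do.call(rbind, cand)
}

cluster_finder_candidates <- function(cand) {
  if (is.null(cand) || !nrow(cand)) return(NULL)
  # cluster by proximity
  clusters <- list()
  for (i in seq_len(nrow(cand))) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      ctr <- clusters[[k]]
      if (abs(cand[i, "row"] - mean(ctr[, "row"])) < cand[i, "w"] / 2 &&
          abs(cand[i, "col"] - mean(ctr[, "col"])) < cand[i, "w"] / 2) {
        clusters[[k]] <- rbind(ctr, cand[i, , drop = FALSE])
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- cand[i, , drop = FALSE]
  }
  votes <- vapply(clusters, nrow, integer(1))
  keep <- order(votes, decreasing = TRUE)[seq_len(min(12L, length(clusters)))]
  centers <- t(vapply(clusters[keep], function(cl) {
    c(row = mean(cl[, "row"]), col = mean(cl[, "col"]), w = mean(cl[, "w"]))
  }, numeric(3)))
  cbind(centers, votes = votes[keep])
}

# Choose the three centers most consistent with a QR finder constellation:
# similar widths, two roughly equal edges at a right angle, and a plausible
# implied module count.
best_finder_triple <- function(centers) {
  k <- nrow(centers)
  if (k < 3L) return(NULL)
  best <- NULL
  best_score <- -Inf
  for (tri in utils::combn(k, 3L, simplify = FALSE)) {
    p <- centers[tri, , drop = FALSE]
    ws <- p[, "w"]
    if (max(ws) / min(ws) > 1.35) next
    for (ci in 1:3) {
      o <- setdiff(1:3, ci)
      v1 <- p[o[1], 1:2] - p[ci, 1:2]
      v2 <- p[o[2], 1:2] - p[ci, 1:2]
      l1 <- sqrt(sum(v1^2))
      l2 <- sqrt(sum(v2^2))
      if (l1 == 0 || l2 == 0) next
      cosang <- abs(sum(v1 * v2)) / (l1 * l2)
      if (cosang > 0.25) next
      if (max(l1, l2) / min(l1, l2) > 1.25) next
      n_est <- (l1 + l2) / 2 / (mean(ws) / 7) + 7
      if (n_est < 17 || n_est > 55) next
      score <- sum(p[, "votes"]) * (1 - cosang)
      if (score > best_score) {
        best_score <- score
        best <- p
      }
    }
  }
  best
}

# Sample the module grid given three finder centers; returns a logical matrix
# or NULL. `n_mod` forces the grid size; otherwise it is estimated from the
# finder geometry.
sample_qr_grid <- function(dark, centers, n_mod = NULL) {
  if (is.null(centers) || nrow(centers) < 3L) return(NULL)
  pts <- best_finder_triple(centers)
  if (is.null(pts)) return(NULL)
  # corner (top-left analogue) = point where the two edge vectors are most
  # orthogonal
  best_i <- 1L
  best_dot <- Inf
  for (i in 1:3) {
    o <- setdiff(1:3, i)
    v1 <- pts[o[1], 1:2] - pts[i, 1:2]
    v2 <- pts[o[2], 1:2] - pts[i, 1:2]
    dt <- abs(sum(v1 * v2)) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    if (dt < best_dot) {
      best_dot <- dt
      best_i <- i
    }
  }
  tl <- pts[best_i, ]
  others <- pts[setdiff(1:3, best_i), , drop = FALSE]
  # TR: predominantly horizontal displacement from the corner
  d1 <- others[1, 1:2] - tl[1:2]
  if (abs(d1[2]) >= abs(d1[1])) {
    tr <- others[1, ]
    bl <- others[2, ]
  } else {
    tr <- others[2, ]
    bl <- others[1, ]
  }
  ms <- mean(pts[, "w"]) / 7
  dist_tr <- sqrt(sum((tr[1:2] - tl[1:2])^2))
  dist_bl <- sqrt(sum((bl[1:2] - tl[1:2])^2))
  if (is.null(n_mod)) {
    n_est <- (dist_tr + dist_bl) / 2 / ms + 7
    n_mod <- 21L + 4L * max(0L, round((n_est - 21) / 4))
  }
  if (n_mod > 53L || n_mod < 21L) return(NULL)

  # affine map (u, v) module units -> (col, row) pixels from the three centers
  src <- rbind(c(3.5, 3.5), c(n_mod - 3.5, 3.5), c(3.5, n_mod - 3.5))
  dst <- rbind(c(tl["col"], tl["row"]), c(tr["col"], tr["row"]),
               c(bl["col"], bl["row"]))
  a <- cbind(src, 1)
  coef <- tryCatch(solve(a, dst), error = function(e) NULL)
  if (is.null(coef)) return(NULL)

  u <- matrix(rep(seq_len(n_mod) - 0.5, each = n_mod), n_mod, n_mod)  # col units
  v <- matrix(rep(seq_len(n_mod) - 0.5, times = n_mod), n_mod, n_mod) # row units
  ms_px <- dist_tr / (n_mod - 7)
  rad <- if (ms_px >= 8) round(ms_px / 7) else 0L
  nr <- nrow(dark)
  nc <- ncol(dark)

  sample_at <- function(du, dv) {
    px_col <- coef[1, 1] * (u + du) + coef[2, 1] * (v + dv) + coef[3, 1]
    px_row <- coef[1, 2] * (u + du) + coef[2, 2] * (v + dv) + coef[3, 2]
    acc <- matrix(0, n_mod, n_mod)
    cnt <- matrix(0, n_mod, n_mod)
    for (dr in (-rad):rad) for (dc in (-rad):rad) {
      rr <- round(px_row) + dr
      cc <- round(px_col) + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      acc[ok] <- acc[ok] + dark[cbind(rr[ok], cc[ok])]
      cnt[ok] <- cnt[ok] + 1
    }
    if (any(cnt == 0)) return(NULL)
    acc / cnt > 0.5
  }

  # known function modules (finders, timing, alignment, dark module) act as a
  # registration template; pick the sub-module grid offset that matches best
  version <- (n_mod - 17L) %/% 4L
  if (version >= 1L && version <= 9L) {
    tmpl <- qr_template(version)
    known <- tmpl$fmask
    for (p in c(qr_format_coords(n_mod)$a, qr_format_coords(n_mod)$b)) {
      known[p[1L], p[2L]] <- FALSE
    }
    best <- NULL
    best_score <- -1
    for (du in c(-0.3, -0.15, 0, 0.15, 0.3)) {
      for (dv in c(-0.3, -0.15, 0, 0.15, 0.3)) {
        g <- sample_at(du, dv)
        if (is.null(g)) next
        score <- mean(g[known] == tmpl$mat[known])
        if (score > best_score) {
          best_score <- score
          best <- g
        }
      }
    }
    if (!is.null(best) && best_score >= 0.8) return(best)
    return(best)
  }
  sample_at(0, 0)
}

#' Attempt to decode the QR payload of a slice image
#'
#' Binarizes with the chosen backend, locates finder patterns, samples the
#' module grid and decodes; the four grid orientations are tried.
#'
#' @param slice A `SliceImage` (or bare numeric matrix of 0..255 pixels).
#' @param decoder One of [qr_decoders()].
#' @return The decoded payload string, or `NULL` on failure.
#' @export
decode_slice <- function(slice, decoder = "otsu") {
  img <- if (is.list(slice)) slice$pixels else slice
  dark <- binarize_image(img, decoder)
  centers <- locate_finder_patterns(dark)
  if (is.null(centers)) return(NULL)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  # provisional grid sizes: geometry estimate first, then its neighbours
  # (binarization can bias the apparent module size)
  grid0 <- sample_qr_grid(dark, centers)
  n0 <- if (!is.null(grid0)) nrow(grid0) else 29L
  sizes <- unique(pmax(21L, pmin(53L, c(n0, n0 - 4L, n0 + 4L, n0 - 8L, n0 + 8L))))
  for (nm in sizes) {
    grid <- if (!is.null(grid0) && nm == nrow(grid0)) grid0 else
      sample_qr_grid(dark, centers, n_mod = nm)
    if (is.null(grid)) next
    g <- grid
    for (rot in 1:4) {
      out <- qr_decode_matrix(g)
      if (!is.null(out)) return(out)
      g <- rot90(g)
    }
  }
  NULL
}

#' Fraction of coronal slices whose QR payload decodes
#'
#' @param volume An `MRVolume` of a QR phantom.
#' @param payload Expected payload; success requires an exact match.
#' @param variant `"interpolated"` (1024 x 1024 Lanczos, default) or
#'   `"original"`.
#' @param decoder One of [qr_decoders()].
#' @return Reading ratio in percent (0..100).
#' @export
reading_ratio <- function(volume, payload, variant = c("interpolated", "original"),
                          decoder = "otsu") {
  variant <- match.arg(variant)
  slices <- export_coronal_slices(volume)
  hits <- vapply(slices, function(sl) {
    if (variant == "interpolated") sl <- interpolate_slice(sl)
    identical(decode_slice(sl, decoder), payload)
  }, logical(1))
  100 * sum(hits) / length(hits)
}

#' Middle-slice decode grid over setups, repetitions and decoders
#'
#' For each setup, the middle coronal slice (index `floor(N/2)`, 0-based) of
#' each repetition is decoded by every backend; successes out of the
#' repetition count are tabulated as in smartphone read-out reports.
#'
#' @param volumes_by_setup Named list (setup label -> list of `MRVolume`
#'   repetitions).
#' @param payload Expected payload string.
#' @param decoders Backends to use.
#' @param variant Slice variant, as in [reading_ratio()].
#' @return Tibble with `setup`, `decoder`, `successes`, `n_rep`.
#' @export
middle_slice_grid <- function(volumes_by_setup, payload,
                              decoders = qr_decoders(),
                              variant = c("interpolated", "original")) {
  variant <- match.arg(variant)
  rows <- list()
  for (lbl in names(volumes_by_setup)) {
    vols <- volumes_by_setup[[lbl]]
    mids <- lapply(vols, function(v) {
      slices <- export_coronal_slices(v)
      sl <- slices[[floor(length(slices) / 2) + 1L]]
      if (variant == "interpolated") sl <- interpolate_slice(sl)
      sl
    })
    for (dec in decoders) {
      succ <- sum(vapply(mids, function(sl) {
        identical(decode_slice(sl, dec), payload)
      }, logical(1)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        setup = lbl, decoder = dec, successes = succ, n_rep = length(vols)
      )
    }
  }
  dplyr::bind_rows(rows)
}
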