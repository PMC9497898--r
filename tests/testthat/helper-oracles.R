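# Independent brute-force oracles for the texture matrices and the ICC.
# These deliberately use naive enumeration (per-voxel loops, BFS flood fill,
# lm()-based ANOVA) so that they share no code path with the package
# implementations they validate.

mk_dvoi <- function(arr) {
  lv <- array(as.integer(arr), dim = dim(arr))
  structure(list(levels = lv, mask = !is.na(lv), G = max(lv, na.rm = TRUE)),
            class = "DiscreteVOI")
}

all_directions13 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    nz <- d[d != 0]
    if (nz[1] < 0) next
    out[[length(out) + 1L]] <- d
  }
  out
}

# Symmetric co-occurrence counts by explicit pair enumeration.
brute_glcm <- function(lv, d, g) {
  cnt <- matrix(0, g, g)
  dd <- dim(lv)
  for (x in seq_len(dd[1])) for (y in seq_len(dd[2])) for (z in seq_len(dd[3])) {
    q <- c(x, y, z) + d
    if (all(q >= 1) && all(q <= dd)) {
      i <- lv[x, y, z]
      j <- lv[q[1], q[2], q[3]]
      if (i > 0 && j > 0) {
        cnt[i, j] <- cnt[i, j] + 1
        cnt[j, i] <- cnt[j, i] + 1
      }
    }
  }
  cnt
}

# Run-length counts by walking each maximal run from its start voxel.
brute_glrlm <- function(lv, d, g) {
  dd <- dim(lv)
  runs <- list()
  for (x in seq_len(dd[1])) for (y in seq_len(dd[2])) for (z in seq_len(dd[3])) {
    v <- lv[x, y, z]
    if (v == 0) next
    p <- c(x, y, z) - d
    prev_same <- all(p >= 1) && all(p <= dd) && lv[p[1], p[2], p[3]] == v
    if (prev_same) next  # not a run start
    len <- 1L
    q <- c(x, y, z) + d
    while (all(q >= 1) && all(q <= dd) && lv[q[1], q[2], q[3]] == v) {
      len <- len + 1L
      q <- q + d
    }
    runs[[length(runs) + 1L]] <- c(v, len)
  }
  m <- do.call(rbind, runs)
  maxlen <- max(m[, 2])
  cnt <- matrix(0, g, maxlen)
  for (r in seq_len(nrow(m))) cnt[m[r, 1], m[r, 2]] <- cnt[m[r, 1], m[r, 2]] + 1
  cnt
}

# Size-zone counts by BFS flood fill over the 26-neighbourhood.
brute_glszm <- function(lv, g) {
  dd <- dim(lv)
  seen <- array(FALSE, dim = dd)
  zones <- list()
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  for (start in which(lv > 0 & !seen)) {
    if (seen[start]) next
    v <- lv[start]
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      p <- arrayInd(cur, dd)
      for (k in seq_len(nrow(nbr))) {
        q <- p + nbr[k, ]
        if (any(q < 1) || any(q > dd)) next
        qi <- q[1] + (q[2] - 1L) * dd[1] + (q[3] - 1L) * dd[1] * dd[2]
        if (!seen[qi] && lv[qi] == v) {
          seen[qi] <- TRUE
          queue <- c(queue, qi)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(v, size)
  }
  m <- do.call(rbind, zones)
  cnt <- matrix(0, g, max(m[, 2]))
  for (r in seq_len(nrow(m))) cnt[m[r, 1], m[r, 2]] <- cnt[m[r, 1], m[r, 2]] + 1
  cnt
}

# ICC(2,1)-style absolute agreement via lm()-based two-way ANOVA.
icc_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), times = k)),
    meas = factor(rep(seq_len(k), each = n))
  )
  a <- stats::anova(stats::lm(y ~ subj + meas, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["meas", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Clean QR rendering at a given pixel-per-module scale.
render_qr_image <- function(modules, px = 10, quiet = 4) {
  n <- nrow(modules)
  size <- (n + 2 * quiet) * px
  img <- matrix(255, size, size)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (modules[r, c]) {
      rr <- ((quiet + r - 1) * px + 1):((quiet + r) * px)
      cc <- ((quiet + c - 1) * px + 1):((quiet + c) * px)
      img[rr, cc] <- 0
    }
  }
  img
}

study_payload <- "UNIDEB MRI Texture Analysis Phantom"
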