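# Shared numerical helpers: deterministic RNG scoping, separable image-domain
# filters and 3D morphology used by the phantom generator, the virtual scanner
# and the texture extractor.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic combination of a base seed and stream indices, kept well below
# .Machine$integer.max.
derive_seed <- function(base, ...) {
  ids <- c(as.integer(base), as.integer(c(...)))
  s <- 0
  for (x in ids) s <- (s * 7919 + (x %% 104729) + 13) %% 2147483629
  as.integer(s)
}

# 1D Gaussian kernel, unit sum.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Apply a 1D convolution along one axis of a 3D array via a sparse band
# matrix; boundaries are renormalized (kernel mass outside is dropped).
conv_axis3d <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  i <- rep(seq_len(n), each = length(kernel))
  j <- i + rep(-r:r, times = n)
  v <- rep(kernel, times = n)
  keep <- j >= 1L & j <= n
  w <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = v[keep], dims = c(n, n))
  w <- w / Matrix::rowSums(w)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  m <- as.matrix(w %*% m)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

gaussian_blur3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  k <- gaussian_kernel(sigma_vox)
  for (axis in 1:3) arr <- conv_axis3d(arr, k, axis)
  arr
}

# Block-average (box) downsampling by integer factor f, padding with
# `pad_value` up to a multiple of f; models partial-volume averaging.
box_downsample3d <- function(arr, f, pad_value = 0) {
  f <- as.integer(f)
  d <- dim(arr)
  dn <- ceiling(d / f) * f
  if (any(dn != d)) {
    out <- array(pad_value, dim = dn)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- out
  }
  d <- dim(arr)
  g <- d %/% f
  a <- array(arr, dim = c(f, g[1], f, g[2], f, g[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  m <- matrix(a, nrow = f^3)
  array(colMeans(m), dim = g)
}

# Integer circular-free shift of a 3D array; vacated cells take `fill`.
array_shift3d <- function(arr, s, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    sk <- s[k]
    if (abs(sk) >= d[k]) return(out)
    if (sk >= 0) {
      dst[[k]] <- (1 + sk):d[k]
      src[[k]] <- 1:(d[k] - sk)
    } else {
      dst[[k]] <- 1:(d[k] + sk)
      src[[k]] <- (1 - sk):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Otsu's threshold on a numeric vector.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / nbins * diff(rng)
}

# Offsets of the 13 unique 3D directions (half of the 26-neighbourhood).
unique_directions3d <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    nz <- d[d != 0]
    if (nz[1] < 0) next  # canonical sign: first non-zero component positive
    out[[length(out) + 1L]] <- d
  }
  out
}

# Label connected components of equal-valued cells in a 3D integer array.
# `values` has 0/NA outside the region of interest. Returns an integer array of
# component labels (0 outside). 26-connectivity.
label_equal_components3d <- function(values) {
  d <- dim(values)
  vals <- values
  vals[is.na(vals)] <- 0L
  inmask <- vals != 0L
  nvox <- sum(inmask)
  if (nvox == 0L) return(array(0L, dim = d))
  idx <- array(0L, dim = d)
  idx[inmask] <- seq_len(nvox)
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (off in unique_directions3d()) {
    a <- array_shift3d(vals, off, fill = 0L)
    ia <- array_shift3d(idx, off, fill = 0L)
    hit <- inmask & a == vals & a != 0L
    if (any(hit)) {
      edges_from <- c(edges_from, idx[hit])
      edges_to <- c(edges_to, ia[hit])
    }
  }
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(g)$membership
  out <- array(0L, dim = d)
  out[inmask] <- as.integer(comp)
  out
}

# Erosion of a logical 3D mask by the full 3x3x3 structuring element.
erode26 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & array_shift3d(mask, c(dx, dy, dz), fill = FALSE)
  }
  out
}

# Separable Lanczos-a resampling weights mapping `n_in` samples to `n_out`.
lanczos_weights <- function(n_in, n_out, a = 3) {
  scale <- n_in / n_out
  centers <- (seq_len(n_out) - 0.5) * scale + 0.5  # input coordinate of output center
  support <- a * max(1, scale)
  rows <- integer(0)
  cols <- integer(0)
  vals <- numeric(0)
  for (o in seq_len(n_out)) {
    c0 <- centers[o]
    lo <- max(1L, floor(c0 - support))
    hi <- min(n_in, ceiling(c0 + support))
    x <- (lo:hi - c0) / max(1, scale)
    w <- ifelse(abs(x) < 1e-12, 1,
                ifelse(abs(x) < a,
                       a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2), 0))
    if (sum(w) == 0) {
      w <- rep(1, length(x))
    }
    w <- w / sum(w)
    rows <- c(rows, rep(o, length(w)))
    cols <- c(cols, lo:hi)
    vals <- c(vals, w)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n_out, n_in))
}

# Lanczos resize of a numeric matrix to out_dim = c(nrow, ncol).
lanczos_resize <- function(img, out_dim, a = 3) {
  wr <- lanczos_weights(nrow(img), out_dim[1], a)
  wc <- lanczos_weights(ncol(img), out_dim[2], a)
  as.matrix(wr %*% img %*% Matrix::t(wc))
}

# Low-frequency random field in [1 - amp, 1 + amp], product of cosine modes
# with random phase; used for bias fields and within-class texture modulation.
smooth_random_field3d <- function(dims, amp, n_modes = 4L) {
  d <- dims
  ax <- lapply(d, function(n) seq(0, 1, length.out = n))
  field <- array(0, dim = d)
  for (m in seq_len(n_modes)) {
    freq <- stats::runif(3, 0.5, 2.5)
    phase <- stats::runif(3, 0, 2 * pi)
    w <- stats::rnorm(1)
    gx <- cos(2 * pi * freq[1] * ax[[1]] + phase[1])
    gy <- cos(2 * pi * freq[2] * ax[[2]] + phase[2])
    gz <- cos(2 * pi * freq[3] * ax[[3]] + phase[3])
    field <- field + w * (outer(outer(gx, gy), gz))
  }
  mx <- max(abs(field))
  if (mx > 0) field <- field / mx
  1 + amp * field
}
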