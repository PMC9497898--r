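# ISO/IEC 18004 (QR code) encoder and matrix-level decoder.
#
# The package embeds QR codes as 3D phantom textures and later re-reads them
# from simulated MR slices, so both directions are implemented natively:
# byte-mode encoding with Reed-Solomon error correction over GF(256), mask
# selection by the standard penalty rules, and a decoder that corrects symbol
# errors with Berlekamp-Massey / Chien / Forney. Versions 1-9 at error
# correction level M are supported, which is ample for short payloads.

.qr_env <- new.env(parent = emptyenv())

# ---- GF(256) arithmetic (primitive polynomial 0x11D) ------------------------

qr_gf_tables <- function() {
  if (!is.null(.qr_env$exp)) return(invisible(NULL))
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exp_t[256:510] <- exp_t[1:255]
  .qr_env$exp <- exp_t
  .qr_env$log <- log_t
  invisible(NULL)
}

gf_mul <- function(a, b) {
  qr_gf_tables()
  out <- integer(length(a) * 0 + max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- .qr_env$exp[.qr_env$log[a[nz] + 1L] + .qr_env$log[b[nz] + 1L] + 1L]
  out
}

gf_div <- function(a, b) {
  qr_gf_tables()
  stopifnot(all(b != 0L))
  if (a == 0L) return(0L)
  .qr_env$exp[(.qr_env$log[a + 1L] - .qr_env$log[b + 1L] + 255L) %% 255L + 1L]
}

gf_pow <- function(e) {
  qr_gf_tables()
  .qr_env$exp[(as.integer(e) %% 255L) + 1L]
}

# Polynomials as integer vectors of coefficients, highest degree first.
gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    r[i:(i + length(q) - 1L)] <- bitwXor(r[i:(i + length(q) - 1L)], gf_mul(p[i], q))
  }
  r
}

gf_poly_eval <- function(p, x) {
  y <- p[1L]
  for (i in seq_along(p)[-1L]) y <- bitwXor(gf_mul(y, x)[1L], p[i])
  y
}

rs_generator_poly <- function(nsym) {
  g <- 1L
  for (i in 0:(nsym - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow(i)))
  g
}

rs_encode_block <- function(data, nsym) {
  gen <- rs_generator_poly(nsym)
  buf <- c(as.integer(data), integer(nsym))
  for (i in seq_along(data)) {
    coef <- buf[i]
    if (coef != 0L) {
      idx <- i:(i + nsym)
      buf[idx] <- bitwXor(buf[idx], gf_mul(coef, gen))
    }
  }
  buf[(length(data) + 1L):(length(data) + nsym)]
}

# ---- Reed-Solomon decoding --------------------------------------------------

rs_syndromes <- function(msg, nsym) {
  vapply(0:(nsym - 1L), function(j) gf_poly_eval(msg, gf_pow(j)), integer(1))
}

# Berlekamp-Massey; synd ascending (S_0 first); returns locator coefficients
# ascending (Lambda_0 = 1 first).
rs_error_locator <- function(synd) {
  lambda <- 1L
  prev <- 1L
  l <- 0L
  m <- 1L
  b <- 1L
  for (n in seq_along(synd)) {
    delta <- synd[n]
    if (l >= 1L) {
      for (i in seq_len(min(l, length(lambda) - 1L))) {
        if (n - i >= 1L) delta <- bitwXor(delta, gf_mul(lambda[i + 1L], synd[n - i])[1L])
      }
    }
    if (delta == 0L) {
      m <- m + 1L
    } else {
      shifted <- c(integer(m), gf_mul(prev, gf_div(delta, b)))
      if (2L * l <= n - 1L) {
        t <- lambda
        lambda <- xor_pad(lambda, shifted)
        l <- n - l
        prev <- t
        b <- delta
        m <- 1L
      } else {
        lambda <- xor_pad(lambda, shifted)
        m <- m + 1L
      }
    }
  }
  lambda
}

xor_pad <- function(a, b) {
  n <- max(length(a), length(b))
  length(a) <- n
  length(b) <- n
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  bitwXor(a, b)
}

# Correct up to floor(nsym/2) symbol errors in place; NULL when uncorrectable.
rs_correct_block <- function(msg, nsym) {
  msg <- as.integer(msg)
  synd <- rs_syndromes(msg, nsym)
  if (all(synd == 0L)) return(msg)
  lambda <- rs_error_locator(synd)
  nerr <- length(lambda) - 1L
  if (nerr == 0L || nerr > nsym %/% 2L) return(NULL)
  n <- length(msg)
  # Chien search over valid codeword positions (powers 0..n-1)
  err_pow <- integer(0)
  lam_desc <- rev(lambda)
  for (e in 0:(n - 1L)) {
    xinv <- gf_pow(255L - e)
    if (gf_poly_eval(lam_desc, xinv) == 0L) err_pow <- c(err_pow, e)
  }
  if (length(err_pow) != nerr) return(NULL)
  # Forney: Omega = S * Lambda mod x^nsym (ascending)
  omega_full <- rev(gf_poly_mul(rev(lambda), rev(synd)))
  omega <- omega_full[seq_len(min(nsym, length(omega_full)))]
  # formal derivative of Lambda (ascending): odd-degree terms shift down
  dlam <- lambda[seq(2L, length(lambda), by = 2L)]
  for (e in err_pow) {
    xi <- gf_pow(e)
    xinv <- gf_pow(255L - e)
    om <- 0L
    xp <- 1L
    for (k in seq_along(omega)) {
      om <- bitwXor(om, gf_mul(omega[k], xp)[1L])
      xp <- gf_mul(xp, xinv)[1L]
    }
    dv <- 0L
    xp <- 1L
    xinv2 <- gf_mul(xinv, xinv)[1L]
    for (k in seq_along(dlam)) {
      dv <- bitwXor(dv, gf_mul(dlam[k], xp)[1L])
      xp <- gf_mul(xp, xinv2)[1L]
    }
    if (dv == 0L) return(NULL)
    mag <- gf_mul(xi, gf_div(om, dv))[1L]
    pos <- n - e
    msg[pos] <- bitwXor(msg[pos], mag)
  }
  if (any(rs_syndromes(msg, nsym) != 0L)) return(NULL)
  msg
}

# ---- Version structure (error correction level M) ---------------------------

qr_version_table <- function() {
  # total codewords, EC codewords per block, block counts / data lengths
  data.frame(
    version = 1:9,
    total   = c(26L, 44L, 70L, 100L, 134L, 172L, 196L, 242L, 292L),
    ec      = c(10L, 16L, 26L, 18L, 24L, 16L, 18L, 22L, 22L),
    blk1    = c(1L, 1L, 1L, 2L, 2L, 4L, 4L, 2L, 3L),
    data1   = c(16L, 28L, 44L, 32L, 43L, 27L, 31L, 38L, 36L),
    blk2    = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L, 2L),
    data2   = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 39L, 37L)
  )
}

qr_alignment_centers <- function(version) {
  switch(version,
    integer(0), c(6L, 18L), c(6L, 22L), c(6L, 26L), c(6L, 30L),
    c(6L, 34L), c(6L, 22L, 38L), c(6L, 24L, 42L), c(6L, 26L, 46L))
}

qr_byte_capacity <- function(version) {
  tab <- qr_version_table()
  row <- tab[tab$version == version, ]
  dc <- row$blk1 * row$data1 + row$blk2 * row$data2
  dc - 2L  # 4-bit mode + 8-bit count indicator
}

# ---- Matrix construction ----------------------------------------------------

# Function-module mask and fixed pattern for a version. Returns list(mat, fmask)
# where mat holds the finder/timing/alignment/dark modules (TRUE = dark) and
# fmask marks every reserved (non-data) module including format areas.
qr_template <- function(version) {
  n <- 4L * version + 17L
  mat <- matrix(FALSE, n, n)
  fmask <- matrix(FALSE, n, n)

  put_finder <- function(r0, c0) {
    for (dr in 0:6) for (dc in 0:6) {
      dark <- dr %in% c(0L, 6L) || dc %in% c(0L, 6L) ||
        (dr >= 2L && dr <= 4L && dc >= 2L && dc <= 4L)
      mat[r0 + dr, c0 + dc] <<- dark
    }
    rs <- max(1L, r0 - 1L):min(n, r0 + 7L)
    cs <- max(1L, c0 - 1L):min(n, c0 + 7L)
    fmask[rs, cs] <<- TRUE  # finder + separator
  }
  put_finder(1L, 1L)
  put_finder(1L, n - 6L)
  put_finder(n - 6L, 1L)

  # timing patterns (row/col 7 in 1-based indexing)
  for (k in 9:(n - 8L)) {
    dark <- (k %% 2L) == 1L
    if (!fmask[7L, k]) mat[7L, k] <- dark
    if (!fmask[k, 7L]) mat[k, 7L] <- dark
    fmask[7L, k] <- TRUE
    fmask[k, 7L] <- TRUE
  }

  # alignment patterns
  ctr <- qr_alignment_centers(version)
  if (length(ctr)) {
    lo <- min(ctr)
    hi <- max(ctr)
    for (cr in ctr) for (cc in ctr) {
      if ((cr == lo && cc == lo) || (cr == lo && cc == hi) || (cr == hi && cc == lo)) next
      for (dr in -2:2) for (dc in -2:2) {
        dark <- max(abs(dr), abs(dc)) != 1L
        mat[cr + 1L + dr, cc + 1L + dc] <- dark
        fmask[cr + 1L + dr, cc + 1L + dc] <- TRUE
      }
    }
  }

  # dark module + reserved format areas
  mat[n - 7L, 9L] <- TRUE
  fmask[n - 7L, 9L] <- TRUE
  for (p in qr_format_coords(n)$a) fmask[p[1L], p[2L]] <- TRUE
  for (p in qr_format_coords(n)$b) fmask[p[1L], p[2L]] <- TRUE
  list(mat = mat, fmask = fmask, n = n)
}

# Format information bit positions, 1-based (row, col); element i carries
# format bit i with bit 1 the most significant of the 15-bit sequence.
qr_format_coords <- function(n) {
  a <- list(
    c(9L, 1L), c(9L, 2L), c(9L, 3L), c(9L, 4L), c(9L, 5L), c(9L, 6L),
    c(9L, 8L), c(9L, 9L), c(8L, 9L), c(6L, 9L), c(5L, 9L), c(4L, 9L),
    c(3L, 9L), c(2L, 9L), c(1L, 9L))
  b <- c(
    lapply(0:6, function(i) c(n - i, 9L)),
    lapply(7:14, function(i) c(9L, n - 14L + i)))
  list(a = a, b = b)
}

qr_format_bits <- function(ec, mask) {
  ecb <- switch(ec, L = c(0L, 1L), M = c(0L, 0L), Q = c(1L, 1L), H = c(1L, 0L))
  mb <- as.integer(intToBits(mask))[3:1]
  data5 <- c(ecb, mb)
  # BCH(15,5) remainder, generator 0x537
  reg <- c(data5, integer(10L))
  gen <- c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L)
  for (i in 1:5) {
    if (reg[i] == 1L) reg[i:(i + 10L)] <- bitwXor(reg[i:(i + 10L)], gen)
  }
  fmt <- c(data5, reg[6:15])
  bitwXor(fmt, c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L))
}

qr_all_formats <- function() {
  if (!is.null(.qr_env$formats)) return(.qr_env$formats)
  out <- list()
  for (ec in c("L", "M", "Q", "H")) for (m in 0:7) {
    out[[paste0(ec, m)]] <- list(ec = ec, mask = m, bits = qr_format_bits(ec, m))
  }
  .qr_env$formats <- out
  out
}

# Data-module coordinates in placement order (list of c(row, col), 1-based).
qr_data_coords <- function(fmask) {
  n <- nrow(fmask)
  coords <- vector("list", n * n)
  k <- 0L
  upward <- TRUE
  cs <- n
  while (cs >= 1L) {
    if (cs == 7L) cs <- 6L  # skip the vertical timing column
    rows <- if (upward) n:1 else 1:n
    for (r in rows) {
      for (c in c(cs, cs - 1L)) {
        if (c >= 1L && !fmask[r, c]) {
          k <- k + 1L
          coords[[k]] <- c(r, c)
        }
      }
    }
    upward <- !upward
    cs <- cs - 2L
  }
  coords[seq_len(k)]
}

qr_mask_matrix <- function(n, mask) {
  i <- matrix(0:(n - 1L), n, n)        # row index, 0-based
  j <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  switch(as.character(mask),
    "0" = (i + j) %% 2L == 0L,
    "1" = i %% 2L == 0L,
    "2" = j %% 3L == 0L,
    "3" = (i + j) %% 3L == 0L,
    "4" = (i %/% 2L + j %/% 3L) %% 2L == 0L,
    "5" = (i * j) %% 2L + (i * j) %% 3L == 0L,
    "6" = ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    "7" = ((i + j) %% 2L + (i * j) %% 3L) %% 2L == 0L)
}

qr_penalty <- function(mat) {
  n <- nrow(mat)
  score <- 0L
  run_pen <- function(v) {
    len <- rle(v)$lengths
    sum(len[len >= 5L] - 2L)  # 3 + (L - 5) per qualifying run
  }
  for (r in 1:n) score <- score + run_pen(mat[r, ])
  for (c in 1:n) score <- score + run_pen(mat[, c])
  blk <- mat[-n, -n] & mat[-1, -n] & mat[-n, -1] & mat[-1, -1]
  blk2 <- !mat[-n, -n] & !mat[-1, -n] & !mat[-n, -1] & !mat[-1, -1]
  score <- score + 3L * (sum(blk) + sum(blk2))
  pat1 <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pat2 <- rev(pat1)
  count_pat <- function(v) {
    if (length(v) < 11L) return(0L)
    hits <- 0L
    for (s in 1:(length(v) - 10L)) {
      w <- v[s:(s + 10L)]
      if (all(w == pat1) || all(w == pat2)) hits <- hits + 1L
    }
    hits
  }
  for (r in 1:n) score <- score + 40L * count_pat(mat[r, ])
  for (c in 1:n) score <- score + 40L * count_pat(mat[, c])
  pct <- sum(mat) / (n * n) * 100
  score + 10L * (abs(pct - 50) %/% 5)
}

# ---- Encoding ---------------------------------------------------------------

#' Encode text as a QR code module matrix
#'
#' Byte-mode ISO/IEC 18004 encoding at error-correction level M with automatic
#' version selection (versions 1-9) and standard penalty-based mask choice.
#'
#' @param text Character scalar; the payload.
#' @param version Optional integer to force a version; default auto-select.
#' @return Logical matrix, `TRUE` = dark module, without quiet zone.
#' @examples
#' m <- qr_encode_matrix("hello")
#' dim(m)
#' @export
qr_encode_matrix <- function(text, version = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  nb <- length(bytes)
  tab <- qr_version_table()
  if (is.null(version)) {
    ok <- which(vapply(tab$version, qr_byte_capacity, integer(1)) >= nb)
    if (!length(ok)) {
      stop("payload of ", nb, " bytes exceeds the byte-mode capacity (",
           qr_byte_capacity(9L), " bytes at version 9, level M)")
    }
    version <- tab$version[ok[1L]]
  }
  if (qr_byte_capacity(version) < nb) {
    stop("payload of ", nb, " bytes exceeds version ", version,
         " level-M capacity of ", qr_byte_capacity(version), " bytes")
  }
  row <- tab[tab$version == version, ]
  dc_total <- row$blk1 * row$data1 + row$blk2 * row$data2

  bits <- c(c(0L, 1L, 0L, 0L), int_to_bits(nb, 8L))
  for (b in bytes) bits <- c(bits, int_to_bits(b, 8L))
  bits <- c(bits, integer(min(4L, dc_total * 8L - length(bits))))
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  cw <- bits_to_bytes(bits)
  pad <- c(236L, 17L)
  i <- 0L
  while (length(cw) < dc_total) {
    i <- i + 1L
    cw <- c(cw, pad[(i - 1L) %% 2L + 1L])
  }

  # split into blocks, compute EC, interleave
  sizes <- c(rep(row$data1, row$blk1), rep(row$data2, row$blk2))
  blocks <- vector("list", length(sizes))
  off <- 0L
  for (b in seq_along(sizes)) {
    blocks[[b]] <- cw[(off + 1L):(off + sizes[b])]
    off <- off + sizes[b]
  }
  ecs <- lapply(blocks, rs_encode_block, nsym = row$ec)
  inter <- integer(0)
  for (k in seq_len(max(sizes))) {
    for (b in seq_along(blocks)) if (k <= sizes[b]) inter <- c(inter, blocks[[b]][k])
  }
  for (k in seq_len(row$ec)) {
    for (b in seq_along(ecs)) inter <- c(inter, ecs[[b]][k])
  }

  tmpl <- qr_template(version)
  coords <- qr_data_coords(tmpl$fmask)
  dbits <- unlist(lapply(inter, int_to_bits, n = 8L))
  dbits <- c(dbits, integer(length(coords) - length(dbits)))

  best <- NULL
  best_pen <- Inf
  for (m in 0:7) {
    mk <- qr_mask_matrix(tmpl$n, m)
    mat <- tmpl$mat
    for (k in seq_along(coords)) {
      p <- coords[[k]]
      mat[p[1L], p[2L]] <- xor(dbits[k] == 1L, mk[p[1L], p[2L]])
    }
    fmt <- qr_format_bits("M", m)
    fc <- qr_format_coords(tmpl$n)
    for (k in 1:15) {
      mat[fc$a[[k]][1L], fc$a[[k]][2L]] <- fmt[k] == 1L
      mat[fc$b[[k]][1L], fc$b[[k]][2L]] <- fmt[k] == 1L
    }
    pen <- qr_penalty(mat)
    if (pen < best_pen) {
      best <- mat
      best_pen <- pen
    }
  }
  attr(best, "version") <- version
  best
}

int_to_bits <- function(x, n) {
  as.integer(rev(as.integer(intToBits(x))[seq_len(n)]))
}

bits_to_bytes <- function(bits) {
  m <- matrix(bits, nrow = 8L)
  as.integer(2L^(7:0) %*% m)
}

bits_to_int <- function(bits) {
  sum(bits * 2L^(rev(seq_along(bits)) - 1L))
}

# ---- Decoding (module matrix -> payload) ------------------------------------

#' Decode a QR module matrix
#'
#' Reads format information (correcting up to 3 bit errors per copy), unmasks,
#' deinterleaves codewords and applies Reed-Solomon error correction.
#'
#' @param mat Logical matrix of modules, `TRUE` = dark.
#' @return Decoded payload string, or `NULL` when decoding fails.
#' @export
qr_decode_matrix <- function(mat) {
  n <- nrow(mat)
  if (n != ncol(mat) || n < 21L || (n - 17L) %% 4L != 0L) return(NULL)
  version <- (n - 17L) %/% 4L
  if (version > 9L) return(NULL)

  fc <- qr_format_coords(n)
  read_fmt <- function(coords) {
    vapply(coords, function(p) as.integer(mat[p[1L], p[2L]]), integer(1))
  }
  cand <- qr_all_formats()
  best <- NULL
  best_d <- Inf
  for (bits in list(read_fmt(fc$a), read_fmt(fc$b))) {
    for (f in cand) {
      d <- sum(bits != f$bits)
      if (d < best_d) {
        best_d <- d
        best <- f
      }
    }
  }
  if (best_d > 3L || best$ec != "M") return(NULL)

  tmpl <- qr_template(version)
  mk <- qr_mask_matrix(n, best$mask)
  coords <- qr_data_coords(tmpl$fmask)
  bits <- vapply(coords, function(p) {
    as.integer(xor(mat[p[1L], p[2L]], mk[p[1L], p[2L]]))
  }, integer(1))

  row <- qr_version_table()[version, ]
  ncw <- row$total
  cw <- bits_to_bytes(bits[seq_len(ncw * 8L)])

  # deinterleave
  sizes <- c(rep(row$data1, row$blk1), rep(row$data2, row$blk2))
  nblk <- length(sizes)
  data_blocks <- lapply(sizes, integer)
  idx <- 1L
  for (k in seq_len(max(sizes))) {
    for (b in seq_len(nblk)) {
      if (k <= sizes[b]) {
        data_blocks[[b]][k] <- cw[idx]
        idx <- idx + 1L
      }
    }
  }
  ec_blocks <- lapply(seq_len(nblk), function(b) integer(row$ec))
  for (k in seq_len(row$ec)) {
    for (b in seq_len(nblk)) {
      ec_blocks[[b]][k] <- cw[idx]
      idx <- idx + 1L
    }
  }

  data <- integer(0)
  for (b in seq_len(nblk)) {
    fixed <- rs_correct_block(c(data_blocks[[b]], ec_blocks[[b]]), row$ec)
    if (is.null(fixed)) return(NULL)
    data <- c(data, fixed[seq_len(sizes[b])])
  }

  stream <- unlist(lapply(data, int_to_bits, n = 8L))
  if (length(stream) < 12L) return(NULL)
  mode <- bits_to_int(stream[1:4])
  if (mode != 4L) return(NULL)  # byte mode only
  count <- bits_to_int(stream[5:12])
  if (12L + 8L * count > length(stream)) return(NULL)
  bytes <- bits_to_bytes(stream[13:(12L + 8L * count)])
  out <- tryCatch(rawToChar(as.raw(bytes)), error = function(e) NULL)
  if (!is.null(out)) Encoding(out) <- "UTF-8"
  out
}
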