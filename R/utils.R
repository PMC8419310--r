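#' @importFrom stats fft rnorm runif median sd
NULL

# Internal: validate a scalar
.chk_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Gaussian kernel (discrete, truncated at 3 sigma, normalized)
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded Toeplitz smoothing matrix of size n for a symmetric kernel.
# Rows are renormalized so constants are preserved at the edges.
.smooth_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n)
    tgt <- idx + j
    ok <- tgt >= 1L & tgt <= n
    K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + kernel[j + r + 1L]
  }
  K / rowSums(K)
}

#' Weighted, NA-aware separable Gaussian smoothing of a 2D image
#'
#' Smooths `x` with an isotropic Gaussian of standard deviation `sigma`
#' (pixels).  Pixels where `w == 0` or `x` is `NA` do not contribute;
#' the result is renormalized by the smoothed weight so that constant
#' images are preserved.  Pixels with zero total weight return `NA`.
#'
#' @param x numeric or complex matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` is the identity.
#' @param w optional non-negative weight matrix (defaults to all ones).
#' @return matrix of the same shape as `x`.
#' @keywords internal
gauss_smooth2d <- function(x, sigma, w = NULL) {
  if (sigma <= 0 && is.null(w)) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (is.null(w)) w <- matrix(1, nr, nc)
  bad <- !is.finite(Re(x)) | (is.complex(x) & !is.finite(Im(x)))
  w[bad] <- 0
  x[bad] <- 0
  if (sigma <= 0) { x[w == 0] <- NA; return(x) }
  k <- .gauss_kernel(sigma)
  Kr <- .smooth_matrix(nr, k)
  Kc <- .smooth_matrix(nc, k)
  num <- Kr %*% (w * x) %*% t(Kc)
  den <- Kr %*% w %*% t(Kc)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA
  out
}

# Apply gauss_smooth2d slice-wise to a (slices, rows, cols) array
.smooth_slices <- function(a, sigma, w = NULL) {
  for (s in seq_len(dim(a)[1])) {
    ws <- if (is.null(w)) NULL else matrix(w[s, , ], dim(a)[2], dim(a)[3])
    a[s, , ] <- gauss_smooth2d(matrix(a[s, , ], dim(a)[2], dim(a)[3]), sigma, ws)
  }
  a
}

# Deterministic sub-seed scheme: a global seed fans out to per-stage /
# per-animal / per-timepoint streams via a fixed counter so that changing
# the cohort size does not reshuffle earlier animals.  Kept below 2^31.
.subseed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ks) s <- (s * 69069 + as.double(k) * 1299709 + 1013904223) %% 2147483629
  # the LCG combination alone leaves detectable correlation between
  # nearby streams; scramble once more through the generator itself
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(s))
  out <- sample.int(2147483646L, 1L)
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  out
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Cheap content digest for provenance (no external digest dependency):
# fold the serialized object through a 32-bit FNV-style hash.
.hash <- function(x) {
  b <- as.integer(serialize(x, NULL, ascii = FALSE)[-(1:14)])  # skip header
  h <- 2166136261
  for (i in seq(1L, length(b), by = max(1L, length(b) %/% 4096L)))
    h <- ((h * 16777619) %% 4294967296) + b[i] %% 256
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Rasterize an ellipse on a rows x cols grid (row0, col0 centre in pixels)
.ellipse_mask <- function(rows, cols, row0, col0, semi_row, semi_col) {
  r <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - row0) / semi_row)^2 + ((cc - col0) / semi_col)^2 <= 1
}

# Rasterize a disc (Euclidean) of radius rad pixels
.disc_mask <- function(rows, cols, row0, col0, rad) {
  .ellipse_mask(rows, cols, row0, col0, rad, rad)
}

# Erode a logical slice stack by `px` pixels (4-connected, in-plane)
.erode_slices <- function(mask, px) {
  if (px <= 0) return(mask)
  b <- EBImage::makeBrush(3L, "diamond")
  for (s in seq_len(dim(mask)[1])) {
    m <- matrix(as.numeric(mask[s, , ]), dim(mask)[2], dim(mask)[3])
    for (i in seq_len(px)) m <- EBImage::erode(m, b)
    mask[s, , ] <- m > 0.5
  }
  mask
}
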