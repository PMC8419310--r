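#' Complex shear wavenumber from speed and loss angle
#'
#' The package's convention: a wave travelling along `+x` is
#' `u(x) = exp(i k x)` with `k = (omega/c) * (1 + i tan(phi/2))`, so the
#' real part of `k` is `omega/c` (the phase-speed ground truth) and the
#' imaginary part encodes attenuation with `phi` the loss angle of the
#' complex shear modulus `G* = rho c^2 cos^2(phi/2) exp(-i phi)` (the sign
#' of `arg G*` follows from the package's time convention; the loss angle
#' reported everywhere is its magnitude).
#'
#' @param c_ms shear wave speed in m/s.
#' @param phi loss angle in rad, in `[0, pi/2)`.
#' @param freq_hz vibration frequency in Hz.
#' @return complex wavenumber in rad/m.
#' @export
shear_wavenumber <- function(c_ms, phi, freq_hz) {
  (2 * pi * freq_hz / c_ms) * complex(real = 1, imaginary = tan(phi / 2))
}

#' Analytic damped plane wave on a slice grid
#'
#' Closed-form oracle for the forward physics: `u(x) = exp(i k (x . d))`
#' with the complex wavenumber of [shear_wavenumber()].  Amplitude decays
#' along `direction` when `phi > 0` and is constant in the elastic limit.
#'
#' @param c_ms,phi,freq_hz material and drive parameters.
#' @param direction length-2 in-plane direction `(drow, dcol)`; normalized
#'   internally.
#' @param rows,cols grid size in pixels.
#' @param spacing_mm in-plane pixel spacing `(dy, dx)` in mm.
#' @return complex `rows x cols` matrix.
#' @export
simulate_plane_wave <- function(c_ms, phi, freq_hz, direction = c(0, 1),
                                rows = 60L, cols = 90L,
                                spacing_mm = c(0.18, 0.18)) {
  .chk_num(c_ms, "c_ms", positive = TRUE)
  .chk_num(freq_hz, "freq_hz", positive = TRUE)
  if (!is.finite(phi) || phi < 0 || phi >= pi / 2)
    stop("phi must lie in [0, pi/2)", call. = FALSE)
  d <- direction / sqrt(sum(direction^2))
  k <- shear_wavenumber(c_ms, phi, freq_hz)
  y <- (seq_len(rows) - 1) * spacing_mm[1] * 1e-3
  x <- (seq_len(cols) - 1) * spacing_mm[2] * 1e-3
  proj <- outer(y * d[1], x * d[2], "+")
  exp(1i * k * proj)
}

# ---- FDFD Helmholtz solver -------------------------------------------------

# Solve div(G grad u) + rho omega^2 (1 + i alpha) u = 0 on one slice,
# with a Dirichlet source on one edge.  `bc` gives the treatment of the
# other three edges: "absorb" (graded damping layer + zero Dirichlet) or
# "neumann" (zero normal derivative; exact lateral wall for a plane wave).
.helmholtz_slice <- function(G, rho, omega, hy, hx, source_edge,
                             source_amp = 1 + 0i, bc = "absorb",
                             absorb_px = 10L, absorb_max = 1.2) {
  R <- nrow(G); C <- ncol(G)
  N <- R * C
  idx <- function(i, j) i + (j - 1L) * R

  edges <- c(top = "absorb", bottom = "absorb", left = "absorb", right = "absorb")
  edges[] <- bc
  edges[source_edge] <- "source"

  # graded damping (cubic ramp) from each absorbing edge
  alpha <- matrix(0, R, C)
  ii <- matrix(seq_len(R), R, C); jj <- matrix(seq_len(C), R, C, byrow = TRUE)
  ramp <- function(depth) absorb_max * pmax(0, (depth / absorb_px))^3
  if (edges[["top"]] == "absorb")    alpha <- pmax(alpha, ramp(absorb_px - ii + 1))
  if (edges[["bottom"]] == "absorb") alpha <- pmax(alpha, ramp(ii - (R - absorb_px)))
  if (edges[["left"]] == "absorb")   alpha <- pmax(alpha, ramp(absorb_px - jj + 1))
  if (edges[["right"]] == "absorb")  alpha <- pmax(alpha, ramp(jj - (C - absorb_px)))

  ti <- integer(0); tj <- integer(0); tx <- complex(0)
  add <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, v)
  }

  src <- matrix(FALSE, R, C)
  src[switch(source_edge,
             top = cbind(1L, seq_len(C)), bottom = cbind(R, seq_len(C)),
             left = cbind(seq_len(R), 1L), right = cbind(seq_len(R), C))] <- TRUE

  diag_acc <- as.vector(rho * omega^2 * (1 + 1i * alpha))

  # neighbor coupling in +row direction (and symmetric partner)
  couple <- function(di, dj, h) {
    i1 <- which(ii + di >= 1 & ii + di <= R & jj + dj >= 1 & jj + dj <= C)
    p <- i1
    q <- idx(ii[i1] + di, jj[i1] + dj)
    Ge <- (as.vector(G)[p] + as.vector(G)[q]) / 2 / h^2
    keep <- !as.vector(src)[p]
    add(p[keep], q[keep], Ge[keep])
    diag_acc[p[keep]] <<- diag_acc[p[keep]] - Ge[keep]
  }
  couple(1L, 0L, hy); couple(-1L, 0L, hy)
  couple(0L, 1L, hx); couple(0L, -1L, hx)

  # Dirichlet-0 closure on absorbing outer edges (neumann edges get the
  # natural zero-flux closure by simply omitting the outside term)
  dir0 <- function(sel, h) {
    p <- which(sel & !src)
    if (length(p)) diag_acc[p] <<- diag_acc[p] - as.vector(G)[p] / h^2
  }
  if (edges[["top"]] == "absorb")    dir0(as.vector(ii == 1L), hy)
  if (edges[["bottom"]] == "absorb") dir0(as.vector(ii == R), hy)
  if (edges[["left"]] == "absorb")   dir0(as.vector(jj == 1L), hx)
  if (edges[["right"]] == "absorb")  dir0(as.vector(jj == C), hx)

  psrc <- which(as.vector(src))
  diag_acc[psrc] <- 1
  add(seq_len(N), seq_len(N), diag_acc)
  b <- complex(N); b[psrc] <- source_amp

  # complex sparse solve via the equivalent real 2N block system
  Ar <- Re(tx); Ai <- Im(tx)
  Bi <- c(ti, ti + N, ti, ti + N)
  Bj <- c(tj, tj + N, tj + N, tj)
  Bx <- c(Ar, Ar, -Ai, Ai)
  B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx, dims = c(2L * N, 2L * N))
  rhs <- c(Re(b), Im(b))
  sol <- as.vector(Matrix::solve(B, rhs))
  # backward-error residual, scaled by the matrix and solution magnitude
  scale <- max(abs(Bx)) * sqrt(sum(sol^2)) + sqrt(sum(rhs^2))
  resid <- sqrt(sum((as.vector(B %*% sol) - rhs)^2)) / max(scale, 1e-300)
  if (!is.finite(resid) || resid > 1e-10)
    stop(sprintf("Helmholtz solve did not converge (relative residual %.3e)", resid),
         call. = FALSE)
  matrix(complex(real = sol[seq_len(N)], imaginary = sol[N + seq_len(N)]), R, C)
}

# Phase-integration ("ray") forward model: damped plane waves entering from
# the four cardinal edges, with phase and attenuation accumulated from the
# local complex wavenumber.  By construction the local wavenumber of each
# component equals omega/c(x) and the local decay tan(phi/2) * omega/c —
# the exact quantity the inversions estimate.
.ray_slice <- function(cmap, phimap, omega, hy, hx, phases, amps = rep(1, 4)) {
  kr <- omega / cmap
  ki <- kr * tan(phimap / 2)
  rev_c <- rev(seq_len(ncol(kr))); rev_r <- rev(seq_len(nrow(kr)))
  # midpoint cumulative phase/attenuation integrals along each cardinal
  ps_x <- t(apply(kr, 1, function(v) (cumsum(v) - v / 2) * hx))
  as_x <- t(apply(ki, 1, function(v) (cumsum(v) - v / 2) * hx))
  ps_xr <- t(apply(kr[, rev_c], 1, function(v) (cumsum(v) - v / 2) * hx))[, rev_c]
  as_xr <- t(apply(ki[, rev_c], 1, function(v) (cumsum(v) - v / 2) * hx))[, rev_c]
  ps_y <- apply(kr, 2, function(v) (cumsum(v) - v / 2) * hy)
  as_y <- apply(ki, 2, function(v) (cumsum(v) - v / 2) * hy)
  ps_yr <- apply(kr[rev_r, ], 2, function(v) (cumsum(v) - v / 2) * hy)[rev_r, ]
  as_yr <- apply(ki[rev_r, ], 2, function(v) (cumsum(v) - v / 2) * hy)[rev_r, ]
  amps[1] * exp(1i * (ps_x + phases[1])) * exp(-as_x) +
    amps[2] * exp(1i * (ps_xr + phases[2])) * exp(-as_xr) +
    amps[3] * exp(1i * (ps_y + phases[3])) * exp(-as_y) +
    amps[4] * exp(1i * (ps_yr + phases[4])) * exp(-as_yr)
}

#' Simulate a multifrequency shear-wave field through a phantom
#'
#' For each vibration frequency, generates the steady-state complex
#' displacement field on every slice.  Two forward models are available:
#'
#' * `"helmholtz"` (default): per-slice scalar finite-difference
#'   frequency-domain solve of `div(G* grad u) + rho omega^2 u = 0`, with
#'   full-edge Dirichlet excitation from each of the four edges in turn
#'   (superposed with per-source phases) and a 10-pixel graded damping
#'   layer on the remaining edges.
#' * `"rays"`: fast phase-integration model superposing four damped waves
#'   whose local wavenumber is exactly `omega/c(x)`; suitable for large
#'   cohort simulations where the quantity of interest is the local phase
#'   speed rather than diffraction detail.
#'
#' Complex Gaussian noise of standard deviation `noise_sigma` (per real
#' and imaginary part, in source-amplitude units) is added everywhere.
#' The physical field extends beyond the brain (the surrounding tissue
#' vibrates too) and is kept by default, which avoids truncation
#' artifacts in the Fourier-domain inversion; `mask_outside = TRUE`
#' blanks non-brain voxels to `NA` instead.  Deterministic for fixed
#' `(phantom, arguments, seed)`.
#'
#' @param phantom an [make_phantom()] object.
#' @param frequencies_hz vibration frequencies in Hz (default: the
#'   acquisition set 1000..1400 Hz in 100 Hz steps).
#' @param noise_sigma complex-noise standard deviation (a.u.).
#' @param seed integer seed.
#' @param method `"helmholtz"` or `"rays"`.
#' @param lateral_bc for the Helmholtz model, treatment of the edges that
#'   are neither source nor opposite absorber: `"absorb"` or `"neumann"`.
#' @param sources which edges act as vibration sources.
#' @param supersample integer in-plane refinement factor for the
#'   Helmholtz solve (material upsampled by nearest neighbour, solution
#'   decimated back; reduces numerical dispersion).
#' @param mask_outside blank voxels outside the brain to `NA`.
#' @param phase_seed seed of the per-source drive phases; defaults to
#'   `seed`.  Paired scans of one animal share the actuator set-up, so
#'   cohort simulation passes the same `phase_seed` for both timepoints
#'   while the measurement-noise seed differs.
#' @param secondary_amp relative amplitude of the non-dominant sources.
#'   At each drive frequency the cranial geometry favors one propagation
#'   direction; the dominant source cycles across frequencies so the
#'   multifrequency set covers all four cardinals.
#' @return an object of class `mre_wavefield`.
#' @export
simulate_wavefield <- function(phantom,
                               frequencies_hz = seq(1000, 1400, by = 100),
                               noise_sigma = 0, seed = 1L,
                               method = c("helmholtz", "rays"),
                               lateral_bc = "absorb",
                               sources = c("left", "right", "top", "bottom"),
                               supersample = 1L, mask_outside = FALSE,
                               phase_seed = seed, secondary_amp = 0.08) {
  stopifnot(inherits(phantom, "mre_phantom"))
  method <- match.arg(method)
  if (!length(frequencies_hz)) stop("frequencies_hz must be nonempty", call. = FALSE)
  if (any(!is.finite(frequencies_hz) | frequencies_hz <= 0))
    stop("frequencies must be positive", call. = FALSE)
  dims <- dim(phantom$c_true); S <- dims[1]; R <- dims[2]; C <- dims[3]
  hy <- phantom$pixel_spacing_mm[2] * 1e-3
  hx <- phantom$pixel_spacing_mm[3] * 1e-3
  rho <- phantom$density_rho
  m <- as.integer(supersample)

  u_all <- vector("list", length(frequencies_hz))
  for (f in seq_along(frequencies_hz)) {
    omega <- 2 * pi * frequencies_hz[f]
    uf <- array(NA_complex_, dims)
    # the cranial geometry favors one propagation direction per drive
    # frequency; cycling the dominant source across frequencies gives the
    # multifrequency average full directional coverage
    dom <- (f - 1L) %% length(sources) + 1L
    amps <- rep(secondary_amp, length(sources)); amps[dom] <- 1
    for (s in seq_len(S)) {
      cmap <- matrix(phantom$c_true[s, , ], R, C)
      pmap <- matrix(phantom$phi_true[s, , ], R, C)
      phases <- .with_seed(.subseed(phase_seed, 11L, f, s),
                           runif(length(sources), 0, 2 * pi))
      if (method == "rays") {
        us <- .ray_slice(cmap, pmap, omega, hy, hx, phases, amps)
      } else {
        G <- rho * cmap^2 * cos(pmap / 2)^2 * exp(-1i * pmap)
        if (m > 1L) {
          G2 <- G[rep(seq_len(R), each = m), rep(seq_len(C), each = m)]
          us2 <- matrix(0i, R * m, C * m)
          for (d in seq_along(sources))
            us2 <- us2 + .helmholtz_slice(G2, rho, omega, hy / m, hx / m,
                                          sources[d],
                                          amps[d] * exp(1i * phases[d]),
                                          bc = lateral_bc,
                                          absorb_px = 10L * m)
          off <- (m + 1L) %/% 2L
          us <- us2[seq(off, by = m, length.out = R),
                    seq(off, by = m, length.out = C)]
        } else {
          us <- matrix(0i, R, C)
          for (d in seq_along(sources))
            us <- us + .helmholtz_slice(G, rho, omega, hy, hx, sources[d],
                                        amps[d] * exp(1i * phases[d]),
                                        bc = lateral_bc)
        }
      }
      if (noise_sigma > 0) {
        ns <- .with_seed(.subseed(seed, 13L, f, s),
                         complex(real = rnorm(R * C, 0, noise_sigma),
                                 imaginary = rnorm(R * C, 0, noise_sigma)))
        us <- us + matrix(ns, R, C)
      }
      if (mask_outside) us[!phantom$brain[s, , ]] <- NA_complex_
      uf[s, , ] <- us
    }
    u_all[[f]] <- uf
  }
  structure(list(frequencies_hz = frequencies_hz, u = u_all,
                 pixel_spacing_mm = phantom$pixel_spacing_mm,
                 brain = phantom$brain, density_rho = rho,
                 method = method, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "mre_wavefield")
}

#' @export
print.mre_wavefield <- function(x, ...) {
  d <- dim(x$u[[1]])
  cat("Multifrequency MRE wave field\n")
  cat(sprintf("  %d frequencies: %s Hz\n", length(x$frequencies_hz),
              paste(x$frequencies_hz, collapse = ", ")))
  cat(sprintf("  grid %d x %d x %d, forward model: %s, noise sd %.3g a.u.\n",
              d[1], d[2], d[3], x$method, x$noise_sigma))
  invisible(x)
}

# ---- Contrast-agent image pairs -------------------------------------------

# Rician-corrupted magnitude image
.rician <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n1 <- rnorm(length(img), 0, sigma); n2 <- rnorm(length(img), 0, sigma)
  array(sqrt((as.vector(img) + n1)^2 + n2^2), dim(img))
}

#' Simulate a pre/post contrast-agent image pair
#'
#' The pre image is a smooth tissue baseline (signal intensity 100 a.u. in
#' brain tissue, darker ventricles and background).  The post image
#' differs from it only inside the corresponding lesion *contrast* region:
#' raised SI for gadolinium (`t1_gbca`, hyperintense enhancement) or
#' lowered SI for iron-oxide foci (`t2star_vsop`, hypointense).  Rician
#' noise models the MR magnitude statistics; it guarantees nonnegative SI
#' and a positive bias relative to the noiseless image.
#'
#' @param phantom an [make_phantom()] object.
#' @param modality `"t1_gbca"` or `"t2star_vsop"`.
#' @param enhancement_pct percent SI change magnitude inside the lesion
#'   class (default 30 for gd enhancement, 40 for the vsop signal drop).
#' @param noise_sigma Rician noise sd (a.u.; baseline tissue SI is 100).
#' @param seed integer seed.
#' @return a `contrast_pair` with `pre`, `post` arrays and metadata.
#' @export
simulate_contrast_pair <- function(phantom, modality = c("t1_gbca", "t2star_vsop"),
                                   enhancement_pct = if (match.arg(modality) == "t1_gbca") 30 else 40,
                                   noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(phantom, "mre_phantom"))
  modality <- match.arg(modality)
  if (enhancement_pct <= 0)
    stop("enhancement_pct must be > 0 (magnitude of the SI change)", call. = FALSE)
  dims <- dim(phantom$brain)
  pre <- array(20, dims)
  pre[phantom$brain] <- 100
  pre[phantom$ventricles] <- if (modality == "t1_gbca") 60 else 120
  post <- pre
  if (modality == "t1_gbca") {
    post[phantom$gd_contrast] <- pre[phantom$gd_contrast] * (1 + enhancement_pct / 100)
  } else {
    post[phantom$vsop_contrast] <- pre[phantom$vsop_contrast] * (1 - enhancement_pct / 100)
  }
  if (noise_sigma > 0) {
    pre <- .with_seed(.subseed(seed, 21L, 1L), .rician(pre, noise_sigma))
    post <- .with_seed(.subseed(seed, 21L, 2L), .rician(post, noise_sigma))
  }
  structure(list(pre = pre, post = post, modality = modality,
                 enhancement_pct = enhancement_pct,
                 pixel_spacing_mm = phantom$pixel_spacing_mm,
                 brain = phantom$brain, noise_sigma = noise_sigma),
            class = "contrast_pair")
}

#' @export
print.contrast_pair <- function(x, ...) {
  cat(sprintf("Contrast image pair (%s), grid %s, noise sd %.3g\n",
              x$modality, paste(dim(x$pre), collapse = " x "), x$noise_sigma))
  invisible(x)
}
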