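#' Configuration of the multifrequency inversions
#'
#' @param n_directions number of angular sectors of the directional fan
#'   filter (width `2*pi/n_directions` each).  The default of 4 matches
#'   the four-point excitation geometry; wider sectors also pass the full
#'   spatial bandwidth of focal lesions, which narrower fans clip
#'   transversely to the propagation direction.
#' @param bandpass_k_min,bandpass_k_max radial spatial-frequency band in
#'   rad/m applied by the fan filter.  `NULL` selects the default band
#'   bracketing physiological wavelengths for an expected speed range of
#'   1-6 m/s at the supplied frequencies:
#'   `[omega_max / (3 * 6), 3 * omega_min / 1]`.
#' @param amplitude_weight_power exponent `p` of the amplitude weights
#'   `w = |u|^p` used when averaging speeds.
#' @param smoothing_sigma_px Gaussian smoothing (pixels) applied to the
#'   phase-gradient components and, for the loss-angle inversion, to the
#'   complex fields before differentiation.
#' @param density_rho tissue density, kg/m^3.
#' @param edge_margin_px pixels adjacent to the brain-mask boundary marked
#'   invalid (differentiation stencils straddle the mask there).
#' @param weight_floor_rel pixels whose summed amplitude weight falls
#'   below this fraction of the image maximum are marked invalid.
#' @param amp_floor_rel pixels whose raw (pre-normalization) displacement
#'   amplitude, summed over frequencies, falls below this fraction of its
#'   maximum are marked invalid.
#' @param c_phys_range physically admissible speed range (m/s); local
#'   wavenumbers outside the corresponding band get zero weight.
#' @return an `inversion_config` list.
#' @export
inversion_config <- function(n_directions = 4L,
                             bandpass_k_min = NULL, bandpass_k_max = NULL,
                             amplitude_weight_power = 2,
                             smoothing_sigma_px = 1.0,
                             density_rho = 1000,
                             edge_margin_px = 2L,
                             weight_floor_rel = 1e-6,
                             amp_floor_rel = 1e-4,
                             c_phys_range = c(0.5, 20)) {
  if (n_directions < 1L) stop("n_directions must be >= 1", call. = FALSE)
  if (!is.null(bandpass_k_min) && !is.null(bandpass_k_max) &&
      bandpass_k_min >= bandpass_k_max)
    stop("bandpass_k_min must be < bandpass_k_max", call. = FALSE)
  if (edge_margin_px < 0L) stop("edge_margin_px must be >= 0", call. = FALSE)
  structure(list(n_directions = as.integer(n_directions),
                 bandpass_k_min = bandpass_k_min,
                 bandpass_k_max = bandpass_k_max,
                 amplitude_weight_power = amplitude_weight_power,
                 smoothing_sigma_px = smoothing_sigma_px,
                 density_rho = density_rho,
                 edge_margin_px = as.integer(edge_margin_px),
                 weight_floor_rel = weight_floor_rel,
                 amp_floor_rel = amp_floor_rel,
                 c_phys_range = c_phys_range),
            class = "inversion_config")
}

.default_band <- function(frequencies_hz, c_range = c(1, 6)) {
  c(k_min = 2 * pi * max(frequencies_hz) / (3 * c_range[2]),
    k_max = 3 * 2 * pi * min(frequencies_hz) / c_range[1])
}

#' Directional fan filtering of a complex wave image
#'
#' Decomposes a 2D complex displacement image into `n_directions` images
#' whose spatial-frequency content is restricted to half-overlapping
#' raised-cosine angular sectors of width `2*pi/n_directions` (a partition
#' of unity: summing the sector images without radial band limits
#' reconstructs the input exactly) and, optionally, to a radial band
#' `[k_min, k_max]` in rad/m with raised-cosine rolloffs.
#'
#' @param img complex matrix (`NA`s are treated as zeros).
#' @param n_directions number of sectors.
#' @param spacing_mm in-plane pixel spacing `(dy, dx)` in mm.
#' @param k_min,k_max radial band in rad/m (`0`/`Inf` disable).
#' @return list of `n_directions` complex matrices.
#' @export
directional_filter <- function(img, n_directions = 8L,
                               spacing_mm = c(0.18, 0.18),
                               k_min = 0, k_max = Inf) {
  stopifnot(is.matrix(img))
  R <- nrow(img); C <- ncol(img)
  img[!is.finite(Re(img)) | !is.finite(Im(img))] <- 0
  U <- stats::fft(img)
  fy <- c(seq(0, floor(R / 2)), seq(-ceiling(R / 2) + 1, -1)) / (R * spacing_mm[1] * 1e-3)
  fx <- c(seq(0, floor(C / 2)), seq(-ceiling(C / 2) + 1, -1)) / (C * spacing_mm[2] * 1e-3)
  ky <- 2 * pi * matrix(fy, R, C)
  kx <- 2 * pi * matrix(fx, R, C, byrow = TRUE)
  kmag <- sqrt(kx^2 + ky^2)
  theta <- atan2(ky, kx)

  wrad <- matrix(1, R, C)
  if (k_min > 0) {
    lo <- 0.8 * k_min
    wrad <- wrad * ifelse(kmag >= k_min, 1,
                          ifelse(kmag <= lo, 0,
                                 0.5 - 0.5 * cos(pi * (kmag - lo) / (k_min - lo))))
  }
  if (is.finite(k_max)) {
    hi <- 1.2 * k_max
    wrad <- wrad * ifelse(kmag <= k_max, 1,
                          ifelse(kmag >= hi, 0,
                                 0.5 + 0.5 * cos(pi * (kmag - k_max) / (hi - k_max))))
  }

  out <- vector("list", n_directions)
  if (n_directions == 1L) {
    out[[1]] <- stats::fft(U * wrad, inverse = TRUE) / (R * C)
    return(out)
  }
  delta <- 2 * pi / n_directions
  for (d in seq_len(n_directions)) {
    th0 <- (d - 1) * delta
    dth <- atan2(sin(theta - th0), cos(theta - th0))  # wrapped difference
    wang <- ifelse(abs(dth) < delta, cos(pi * dth / (2 * delta))^2, 0)
    out[[d]] <- stats::fft(U * wang * wrad, inverse = TRUE) / (R * C)
  }
  out
}

#' Local wavenumber and amplitude of a (filtered) wave image
#'
#' The phase gradient is computed unwrap-free as the centred difference of
#' the phase itself, `Arg(u[+1] * Conj(u[-1])) / (2h)` — the discrete form
#' of `Im(grad u / u)`, exact for locally linear phase — and its
#' components are Gaussian-smoothed with amplitude-squared weights before
#' taking the magnitude `k = |grad(phase)|`.  Pixels whose amplitude is
#' below machine tolerance are flagged invalid (`NA`) rather than
#' propagating indeterminate phases.
#'
#' @param img complex matrix.
#' @param spacing_mm `(dy, dx)` pixel spacing in mm.
#' @param smoothing_sigma_px Gaussian sigma in pixels.
#' @return list with `k` (rad/m, `NA` where invalid) and `amplitude`.
#' @export
estimate_wavenumber <- function(img, spacing_mm = c(0.18, 0.18),
                                smoothing_sigma_px = 1.0) {
  stopifnot(is.matrix(img))
  hy <- spacing_mm[1] * 1e-3; hx <- spacing_mm[2] * 1e-3
  amp <- Mod(img)
  ok <- is.finite(amp) & amp > sqrt(.Machine$double.eps) * max(amp, na.rm = TRUE)
  u <- img; u[!ok] <- NA_complex_
  R <- nrow(u); C <- ncol(u)

  gr <- function(um, uf, h2) {
    g <- Arg(uf * Conj(um)) / h2
    g[!is.finite(g)] <- NA
    g
  }
  kx <- matrix(NA_real_, R, C); ky <- matrix(NA_real_, R, C)
  if (C >= 3) kx[, 2:(C - 1)] <- gr(u[, 1:(C - 2)], u[, 3:C], 2 * hx)
  if (C >= 2) {
    kx[, 1] <- Arg(u[, 2] * Conj(u[, 1])) / hx
    kx[, C] <- Arg(u[, C] * Conj(u[, C - 1])) / hx
  }
  if (R >= 3) ky[2:(R - 1), ] <- gr(u[1:(R - 2), ], u[3:R, ], 2 * hy)
  if (R >= 2) {
    ky[1, ] <- Arg(u[2, ] * Conj(u[1, ])) / hy
    ky[R, ] <- Arg(u[R, ] * Conj(u[R - 1, ])) / hy
  }
  w <- amp^2; w[!ok] <- 0
  kxs <- gauss_smooth2d(kx, smoothing_sigma_px, w)
  kys <- gauss_smooth2d(ky, smoothing_sigma_px, w)
  k <- sqrt(kxs^2 + kys^2)
  k[!ok] <- NA
  list(k = k, amplitude = amp)
}

# shared checks for the inversion entry points
.check_wavefield <- function(wavefield) {
  stopifnot(inherits(wavefield, "mre_wavefield"))
  if (!length(wavefield$frequencies_hz)) stop("empty frequency list", call. = FALSE)
  if (all(vapply(wavefield$u, function(a) all(!is.finite(Re(a))), logical(1))))
    stop("wave field contains no finite values", call. = FALSE)
  invisible(TRUE)
}

#' Multifrequency wavenumber inversion for shear wave speed
#'
#' Each field is first amplitude-normalized to its phase-only form
#' `u/|u|` (shear waves at kilohertz frequencies are strongly damped in
#' brain tissue, and the raw field's spectrum is otherwise too broad for
#' clean fan filtering).  For every frequency and fan-filter direction the local
#' wavenumber `k` of the filtered normalized field is estimated, and the
#' phase speeds `omega/k` are averaged across all component fields with
#' amplitude weights: `c = sum(w_i * omega_i / k_i) / sum(w_i)`,
#' `w_i = amplitude_i^p`, where `amplitude_i` is the sector amplitude of
#' the normalized field (the local directional content).
#' Pixels with summed weight below threshold, with wavenumbers outside
#' the physically admissible band, or within `edge_margin_px` of the
#' brain-mask boundary are marked invalid.
#'
#' @param wavefield an [simulate_wavefield()] object (or any
#'   `mre_wavefield`).
#' @param config an [inversion_config()].
#' @return list with `c_map` (m/s; `NA` where invalid), `valid` (logical)
#'   and `weight` arrays.
#' @export
invert_stiffness <- function(wavefield, config = inversion_config()) {
  .check_wavefield(wavefield)
  dims <- dim(wavefield$u[[1]]); S <- dims[1]
  sp <- wavefield$pixel_spacing_mm[2:3]
  band <- c(config$bandpass_k_min, config$bandpass_k_max)
  if (is.null(config$bandpass_k_min) || is.null(config$bandpass_k_max)) {
    db <- .default_band(wavefield$frequencies_hz)
    band <- c(if (is.null(config$bandpass_k_min)) db[1] else config$bandpass_k_min,
              if (is.null(config$bandpass_k_max)) db[2] else config$bandpass_k_max)
  }
  p <- config$amplitude_weight_power

  num <- array(0, dims); den <- array(0, dims)
  araw <- array(0, dims)
  for (f in seq_along(wavefield$frequencies_hz)) {
    omega <- 2 * pi * wavefield$frequencies_hz[f]
    klo <- omega / config$c_phys_range[2]; khi <- omega / config$c_phys_range[1]
    for (s in seq_len(S)) {
      img <- matrix(wavefield$u[[f]][s, , ], dims[2], dims[3])
      amp0 <- Mod(img)
      araw[s, , ] <- araw[s, , ] + ifelse(is.finite(amp0), amp0, 0)
      # amplitude normalization (phase-only field): shear waves at these
      # frequencies decay over a few pixels, which broadens the raw
      # spectrum far beyond what fan filtering tolerates; the normalized
      # field has unit amplitude and a clean directional spectrum
      un <- img / amp0
      un[!is.finite(Re(un)) | !is.finite(Im(un))] <- 0
      # raw local amplitude carries the per-frequency reliability: regions
      # shadowed by strong attenuators at this frequency get negligible
      # weight and are filled in by the other frequencies
      wraw <- ifelse(is.finite(amp0), amp0, 0)^2
      wraw <- wraw / max(wraw, 1e-300)
      comps <- directional_filter(un, config$n_directions, sp,
                                  k_min = band[1], k_max = band[2])
      for (cmp in comps) {
        est <- estimate_wavenumber(cmp, sp, config$smoothing_sigma_px)
        w <- est$amplitude^p * wraw
        good <- is.finite(est$k) & est$k >= klo & est$k <= khi
        w[!good] <- 0
        num[s, , ] <- num[s, , ] + ifelse(good, w * (omega / est$k), 0)
        den[s, , ] <- den[s, , ] + w
      }
    }
  }
  valid <- den > config$weight_floor_rel * max(den) &
    araw > config$amp_floor_rel * max(araw)
  valid <- valid & .erode_slices(wavefield$brain, config$edge_margin_px)
  c_map <- num / den
  c_map[!valid] <- NA_real_
  if (!any(valid)) stop("stiffness inversion: no valid pixels (all weights below threshold)",
                        call. = FALSE)
  list(c_map = c_map, valid = valid, weight = den)
}

#' Laplacian-based direct multifrequency inversion for the loss angle
#'
#' Per pixel, `phi = arccos( -sum_j Re(Lap u_j * Conj(u_j)) /
#' sum_j |Lap u_j| * |u_j| )`, the sum running over all frequency fields,
#' with the spacing-scaled 5-point in-plane Laplacian applied to
#' Gaussian-smoothed fields (slices are treated independently: the slice
#' gap is far coarser than the in-plane spacing).  For a damped plane wave
#' this recovers the loss angle of the complex shear modulus exactly up to
#' stencil discretization.  Output is clipped to `[0, pi]`; pixels whose
#' denominator is below tolerance are invalid.
#'
#' @inheritParams invert_stiffness
#' @return list with `phi_map` (rad), `valid`.
#' @export
invert_loss_angle <- function(wavefield, config = inversion_config()) {
  .check_wavefield(wavefield)
  dims <- dim(wavefield$u[[1]]); S <- dims[1]
  hy <- wavefield$pixel_spacing_mm[2] * 1e-3
  hx <- wavefield$pixel_spacing_mm[3] * 1e-3

  num <- array(0, dims); den <- array(0, dims)
  pw <- array(0, dims)  # field power, for the local wavenumber estimate
  for (f in seq_along(wavefield$frequencies_hz)) {
    for (s in seq_len(S)) {
      img <- matrix(wavefield$u[[f]][s, , ], dims[2], dims[3])
      us <- gauss_smooth2d(img, config$smoothing_sigma_px)
      R <- nrow(us); C <- ncol(us)
      lap <- matrix(NA_complex_, R, C)
      if (R >= 3 && C >= 3) {
        ctr <- us[2:(R - 1), 2:(C - 1)]
        lap[2:(R - 1), 2:(C - 1)] <-
          (us[1:(R - 2), 2:(C - 1)] + us[3:R, 2:(C - 1)] - 2 * ctr) / hy^2 +
          (us[2:(R - 1), 1:(C - 2)] + us[2:(R - 1), 3:C] - 2 * ctr) / hx^2
      }
      ok <- is.finite(Re(lap)) & is.finite(Re(us))
      contrib_n <- ifelse(ok, -Re(lap * Conj(us)), 0)
      contrib_d <- ifelse(ok, Mod(lap) * Mod(us), 0)
      num[s, , ] <- num[s, , ] + contrib_n
      den[s, , ] <- den[s, , ] + contrib_d
      pw[s, , ] <- pw[s, , ] + ifelse(ok, Mod(us)^2, 0)
    }
  }
  tol <- .Machine$double.eps * max(den)
  valid <- den > tol & .erode_slices(wavefield$brain, config$edge_margin_px)
  phi_map <- array(acos(pmin(1, pmax(-1, as.vector(num / den)))), dims)
  # leading-order debias of the 5-point stencil: the discrete Laplacian of
  # a damped wave carries arg(sin^2) curvature, shifting the recovered
  # angle by -(kh)^2 tan(phi/2)/6; the local |k|^2 is den/power
  h2 <- (hy + hx)^2 / 4
  k2 <- den / pw
  corr <- k2 * h2 * sin(phi_map) / 12
  corr[!is.finite(corr)] <- 0
  phi_map <- pmin(pi, phi_map + corr)
  phi_map <- array(phi_map, dims)
  phi_map[!valid] <- NA_real_
  list(phi_map = phi_map, valid = valid)
}

#' Joint inversion to stiffness and fluidity parameter maps
#'
#' Runs [invert_stiffness()] and [invert_loss_angle()] and combines them
#' under a single validity mask (the intersection).  Provenance records
#' the configuration and a content hash of the input field.
#'
#' @inheritParams invert_stiffness
#' @return an object of class `mre_maps` with `c_map` (m/s), `phi_map`
#'   (rad), `valid`, `pixel_spacing_mm`, `provenance`.
#' @export
invert <- function(wavefield, config = inversion_config()) {
  st <- invert_stiffness(wavefield, config)
  la <- invert_loss_angle(wavefield, config)
  valid <- st$valid & la$valid
  c_map <- st$c_map; c_map[!valid] <- NA_real_
  phi_map <- la$phi_map; phi_map[!valid] <- NA_real_
  structure(list(c_map = c_map, phi_map = phi_map, valid = valid,
                 pixel_spacing_mm = wavefield$pixel_spacing_mm,
                 provenance = list(config = unclass(config),
                                   n_frequencies = length(wavefield$frequencies_hz),
                                   input_hash = .hash(lapply(wavefield$u, function(a) {
                                     v <- a[is.finite(Re(a))]
                                     c(length(v), Re(sum(v)), Im(sum(v)))
                                   })))),
            class = "mre_maps")
}

#' @export
print.mre_maps <- function(x, ...) {
  cat("MRE parameter maps\n")
  cat(sprintf("  grid %s; %d valid px\n",
              paste(dim(x$c_map), collapse = " x "), sum(x$valid)))
  cat(sprintf("  c:   median %.3f m/s (IQR %.3f-%.3f)\n",
              median(x$c_map[x$valid]), stats::quantile(x$c_map[x$valid], .25),
              stats::quantile(x$c_map[x$valid], .75)))
  cat(sprintf("  phi: median %.3f rad (IQR %.3f-%.3f)\n",
              median(x$phi_map[x$valid]), stats::quantile(x$phi_map[x$valid], .25),
              stats::quantile(x$phi_map[x$valid], .75)))
  invisible(x)
}

#' @export
plot.mre_maps <- function(x, slice = ceiling(dim(x$c_map)[1] / 2), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  for (nm in c("c_map", "phi_map")) {
    m <- matrix(x[[nm]][slice, , ], dim(x$c_map)[2], dim(x$c_map)[3])
    graphics::image(t(m)[, rev(seq_len(nrow(m)))], asp = nrow(m) / ncol(m),
                    col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                    main = sprintf("%s, slice %d", nm, slice))
  }
  invisible(x)
}
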