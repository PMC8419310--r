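# Shared fixtures built in code: analytic plane-wave wave fields and small
# random masks with brute-force set-operation oracles.

acq_freqs <- seq(1000, 1400, by = 100)

# wrap analytic plane waves (one per frequency) into an mre_wavefield
plane_wavefield <- function(c_ms, phi, direction = c(0, 1),
                            frequencies = acq_freqs,
                            rows = 60L, cols = 90L) {
  u <- lapply(frequencies, function(f) {
    a <- array(NA_complex_, c(1L, rows, cols))
    a[1, , ] <- simulate_plane_wave(c_ms, phi, f, direction, rows, cols)
    a
  })
  structure(list(frequencies_hz = frequencies, u = u,
                 pixel_spacing_mm = c(0.8, 0.18, 0.18),
                 brain = array(TRUE, c(1L, rows, cols)),
                 density_rho = 1000, method = "analytic",
                 noise_sigma = 0, seed = NA_integer_),
            class = "mre_wavefield")
}

# interior of a single-slice map, >= margin pixels from every grid edge
interior <- function(map3d, margin = 7L) {
  d <- dim(map3d)
  map3d[1, (margin + 1):(d[2] - margin), (margin + 1):(d[3] - margin)]
}

# random lesion-mask-set fixture on a small grid
random_mask <- function(dims, p = 0.2) array(runif(prod(dims)) < p, dims)

# brute-force set operations on voxel index sets
idx_set <- function(mask) which(as.vector(mask))
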