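#' Percent signal-intensity change map of a contrast pair
#'
#' `100 * (post - pre) / pre`, restricted to the brain (hyperintense
#' enhancement is positive, hypointense accumulation negative).  Outside
#' the brain, and wherever the pre-contrast SI is not positive, the map is
#' `NA`.
#'
#' @param pair a [simulate_contrast_pair()] object (or any list with
#'   `pre`, `post`, `brain` arrays).
#' @return numeric array, percent.
#' @export
percent_change_si <- function(pair) {
  stopifnot(!is.null(pair$pre), !is.null(pair$post))
  if (!identical(dim(pair$pre), dim(pair$post)))
    stop("pre and post images must share a grid", call. = FALSE)
  out <- 100 * (pair$post - pair$pre) / pair$pre
  out[pair$pre <= 0] <- NA_real_
  if (!is.null(pair$brain)) out[!pair$brain] <- NA_real_
  out
}

# remove in-plane connected components smaller than min_size_px
.filter_small <- function(mask, min_size_px) {
  if (min_size_px <= 1L) return(mask)
  for (s in seq_len(dim(mask)[1])) {
    m <- matrix(as.numeric(mask[s, , ]), dim(mask)[2], dim(mask)[3])
    lab <- EBImage::bwlabel(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < min_size_px)
      m[lab %in% drop] <- 0
    }
    mask[s, , ] <- m > 0.5
  }
  mask
}

#' Gadolinium-enhancement mask from a percent-change map
#'
#' Thresholds the percent-change SI map at `threshold` (automated stand-in
#' for manual lesion drawing) and removes in-plane connected components
#' smaller than `min_size_px`.
#'
#' @param change_map percent-change array from [percent_change_si()].
#' @param threshold percent-change threshold (> 0).
#' @param min_size_px minimum component size in pixels.
#' @return logical array.
#' @export
gd_mask_from_change <- function(change_map, threshold = 15, min_size_px = 5L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  m <- !is.na(change_map) & change_map >= threshold
  .filter_small(m, min_size_px)
}

#' Iron-oxide (VSOP) mask from post/pre hypointensity
#'
#' Marks pixels whose post/pre SI ratio falls to or below
#' `ratio_threshold` within the brain, then removes small components.
#'
#' @param pair contrast pair (`t2star_vsop` modality).
#' @param ratio_threshold post/pre ratio in (0, 1); `0` yields an empty
#'   mask (the bound is unattainable for positive images).
#' @param min_size_px minimum component size in pixels.
#' @return logical array.
#' @export
vsop_mask_from_hypointensity <- function(pair, ratio_threshold = 0.8,
                                         min_size_px = 5L) {
  if (ratio_threshold < 0 || ratio_threshold >= 1)
    stop("ratio_threshold must lie in [0, 1)", call. = FALSE)
  ratio <- pair$post / pair$pre
  m <- is.finite(ratio) & ratio <= ratio_threshold & pair$pre > 0
  if (!is.null(pair$brain)) m <- m & pair$brain
  .filter_small(m, min_size_px)
}

#' Morphological dilation of a mask, in-plane
#'
#' Applies `pixels` iterations of dilation with a 4-connected cross
#' (in-plane only; voxels are strongly anisotropic).  Two iterations grow
#' a single pixel into the 13-pixel L1 ball of radius 2.  If `brain` is
#' supplied the result is clipped to it.
#'
#' @param mask logical array `(slices, rows, cols)` or matrix.
#' @param pixels number of dilation iterations (>= 0).
#' @param brain optional clip mask.
#' @return logical array of the same shape.
#' @export
dilate_mask <- function(mask, pixels = 2L, brain = NULL) {
  if (pixels < 0) stop("pixels must be >= 0", call. = FALSE)
  was_mat <- is.matrix(mask)
  if (was_mat) mask <- array(mask, c(1L, nrow(mask), ncol(mask)))
  if (pixels > 0) {
    b <- EBImage::makeBrush(3L, "diamond")
    for (s in seq_len(dim(mask)[1])) {
      m <- matrix(as.numeric(mask[s, , ]), dim(mask)[2], dim(mask)[3])
      for (i in seq_len(pixels)) m <- EBImage::dilate(m, b)
      mask[s, , ] <- m > 0.5
    }
  }
  if (!is.null(brain)) {
    bb <- if (is.matrix(brain)) array(brain, dim(mask)) else brain
    mask <- mask & bb
  }
  if (was_mat) matrix(mask[1, , ], dim(mask)[2], dim(mask)[3]) else mask
}

#' Bundle lesion masks with their processing state
#'
#' @param gd,vsop,ventricles,brain logical arrays on one grid.
#' @param state processing state: `"raw"` (fresh thresholds), `"dilated"`
#'   (VSOP dilation applied), `"exclusive"`, or `"final"`.
#' @param provenance character vector of applied operations.
#' @return a `lesion_masks` object.
#' @export
lesion_mask_set <- function(gd, vsop, ventricles, brain, state = "raw",
                            provenance = character()) {
  dims <- dim(brain)
  for (m in list(gd, vsop, ventricles))
    if (!identical(dim(m), dims)) stop("masks must share a grid", call. = FALSE)
  state <- match.arg(state, c("raw", "dilated", "exclusive", "final"))
  if (state %in% c("exclusive", "final") && any(gd & vsop))
    stop("state '", state, "' requires gd and vsop to be disjoint", call. = FALSE)
  if (state == "final" && any((gd | vsop) & ventricles))
    stop("state 'final' requires ventricle-free lesion masks", call. = FALSE)
  structure(list(gd = gd, vsop = vsop, ventricles = ventricles, brain = brain,
                 state = state, provenance = provenance),
            class = "lesion_masks")
}

#' @export
print.lesion_masks <- function(x, ...) {
  cat(sprintf("Lesion mask set [state: %s]\n", x$state))
  cat(sprintf("  gd %d px, vsop %d px, ventricles %d px, brain %d px\n",
              sum(x$gd), sum(x$vsop), sum(x$ventricles), sum(x$brain)))
  if (length(x$provenance)) cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Enforce mutual exclusivity and remove ventricles
#'
#' Pixels marked by both contrast agents are disregarded (removed from
#' both masks), then ventricle pixels are removed from both, and both are
#' clipped to the brain.  Expects the VSOP mask to be already dilated
#' (state `"dilated"`); advances the state to `"final"`.
#'
#' @param set a [lesion_mask_set()] in state `"dilated"`.
#' @return the finalized `lesion_masks` object.
#' @export
make_exclusive <- function(set) {
  stopifnot(inherits(set, "lesion_masks"))
  if (set$state != "dilated")
    stop("make_exclusive expects state 'dilated' (dilate the VSOP mask first)",
         call. = FALSE)
  overlap <- set$gd & set$vsop
  gd <- set$gd & !overlap & !set$ventricles & set$brain
  vsop <- set$vsop & !overlap & !set$ventricles & set$brain
  lesion_mask_set(gd, vsop, set$ventricles, set$brain, state = "final",
                  provenance = c(set$provenance, "mutual_exclusion",
                                 "ventricle_removal"))
}

#' Derive the final lesion mask set for one session
#'
#' Runs the frozen mask pipeline: threshold the Gd percent-change map and
#' the VSOP hypointensity ratio, dilate the VSOP mask by `vsop_dilate_px`
#' pixels (small focal accumulations at this resolution are otherwise
#' dominated by single-pixel effects), then apply mutual exclusion and
#' ventricle removal.
#'
#' @param gd_pair,vsop_pair contrast pairs of the session.
#' @param ventricles,brain logical arrays.
#' @param gd_threshold percent-change threshold for Gd enhancement.
#' @param vsop_ratio_threshold post/pre ratio threshold for VSOP foci.
#' @param vsop_dilate_px VSOP dilation iterations.
#' @param min_size_px minimum component size.
#' @return a finalized `lesion_masks` object.
#' @export
derive_lesion_masks <- function(gd_pair, vsop_pair, ventricles, brain,
                                gd_threshold = 15, vsop_ratio_threshold = 0.8,
                                vsop_dilate_px = 2L, min_size_px = 5L) {
  gd <- gd_mask_from_change(percent_change_si(gd_pair), gd_threshold, min_size_px)
  vs <- vsop_mask_from_hypointensity(vsop_pair, vsop_ratio_threshold, min_size_px)
  vs <- dilate_mask(vs, vsop_dilate_px, brain = brain)
  set <- lesion_mask_set(gd & brain, vs, ventricles, brain, state = "dilated",
                         provenance = c(sprintf("gd_threshold_%g", gd_threshold),
                                        sprintf("vsop_ratio_%g", vsop_ratio_threshold),
                                        sprintf("vsop_dilate_%d", vsop_dilate_px)))
  make_exclusive(set)
}

#' Resample an image stack along the slice axis
#'
#' Maps `n_source` slices of spacing `src_spacing_mm` onto a target grid
#' of `n_target` slices spanning `target_span_mm`, both centred on the
#' same physical position (emulating interpolation of an acquisition slab
#' into a reference-atlas space).  Target slices whose centres fall
#' outside the source slab carry no data (`NA`).  Masks must use
#' `"nearest"`.
#'
#' @param image array `(slices, rows, cols)` (logical or numeric).
#' @param n_target number of target slices.
#' @param method `"nearest"` or `"linear"`.
#' @param src_spacing_mm source slice spacing.
#' @param target_span_mm physical extent of the target grid (defaults to
#'   the package's 215-slice toy atlas spanning 20.8 mm).
#' @return array `(n_target, rows, cols)`; logical input stays logical
#'   (`NA`-free: unpopulated slices are `FALSE`).
#' @export
resample_slices <- function(image, n_target = 215L,
                            method = c("nearest", "linear"),
                            src_spacing_mm = 0.8,
                            target_span_mm = 20.8) {
  method <- match.arg(method)
  if (src_spacing_mm <= 0 || target_span_mm <= 0)
    stop("spacings must be positive", call. = FALSE)
  dims <- dim(image); S <- dims[1]
  was_logical <- is.logical(image)
  if (was_logical && method == "linear")
    stop("masks must be resampled with method = 'nearest'", call. = FALSE)
  t_spacing <- target_span_mm / n_target
  # physical slice-centre coordinates, both grids centred on 0
  z_src <- (seq_len(S) - (S + 1) / 2) * src_spacing_mm
  z_tgt <- (seq_len(n_target) - (n_target + 1) / 2) * t_spacing
  lo <- min(z_src) - src_spacing_mm / 2
  hi <- max(z_src) + src_spacing_mm / 2

  out <- array(if (was_logical) FALSE else NA_real_, c(n_target, dims[2], dims[3]))
  for (t in seq_len(n_target)) {
    z <- z_tgt[t]
    if (z < lo || z > hi) next
    if (method == "nearest") {
      i <- which.min(abs(z_src - z))
      out[t, , ] <- image[i, , ]
    } else {
      if (z <= z_src[1]) out[t, , ] <- image[1, , ]
      else if (z >= z_src[S]) out[t, , ] <- image[S, , ]
      else {
        i <- findInterval(z, z_src)
        w <- (z - z_src[i]) / (z_src[i + 1] - z_src[i])
        out[t, , ] <- (1 - w) * image[i, , ] + w * image[i + 1, , ]
      }
    }
  }
  out
}

#' Voxelwise incidence map over a cohort of masks
#'
#' The percentage of animals whose mask covers each voxel; values lie on
#' the discrete grid `{0, 100/n, ..., 100}`.
#'
#' @param masks list of logical arrays on one grid (one per animal).
#' @param modality `"gd"` or `"vsop"` (metadata).
#' @return an `incidence_map` object with `percent`, `n_animals`,
#'   `modality`.
#' @export
incidence_map <- function(masks, modality = c("gd", "vsop")) {
  modality <- match.arg(modality)
  if (!length(masks)) stop("need at least one mask", call. = FALSE)
  dims <- dim(masks[[1]])
  counts <- array(0, dims)
  for (m in masks) {
    if (!identical(dim(m), dims)) stop("masks must share a grid", call. = FALSE)
    counts <- counts + (m & !is.na(m))
  }
  structure(list(percent = 100 * counts / length(masks),
                 n_animals = length(masks), modality = modality),
            class = "incidence_map")
}

#' @export
print.incidence_map <- function(x, ...) {
  cat(sprintf("Incidence map (%s, n = %d): max %.1f%% of animals\n",
              x$modality, x$n_animals, max(x$percent)))
  invisible(x)
}

#' Region-wise lesion incidence table
#'
#' For every atlas label, the percentage of animals whose mask intersects
#' the region (the tabulation used for anatomical incidence reporting).
#'
#' @param masks list of logical arrays (one per animal).
#' @param atlas integer label array on the same grid.
#' @param key named integer vector mapping region names to labels
#'   (defaults to all nonzero labels present).
#' @return data.frame with `region`, `incidence_pct` (one decimal place is
#'   conventional for reporting; values returned at full precision),
#'   `n_animals`.
#' @export
regional_incidence <- function(masks, atlas, key = NULL) {
  if (!length(masks)) stop("need at least one mask", call. = FALSE)
  if (!identical(dim(masks[[1]]), dim(atlas)))
    stop("atlas grid does not match masks", call. = FALSE)
  if (is.null(key)) {
    labs <- sort(unique(as.vector(atlas[atlas > 0])))
    key <- stats::setNames(labs, paste0("region_", labs))
  }
  if (any(!key %in% atlas)) stop("unknown label in key", call. = FALSE)
  n <- length(masks)
  pct <- vapply(key, function(lab) {
    hit <- vapply(masks, function(m) any(m[atlas == lab], na.rm = TRUE), logical(1))
    100 * sum(hit) / n
  }, numeric(1))
  data.frame(region = names(key), incidence_pct = unname(pct),
             n_animals = n, row.names = NULL)
}
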