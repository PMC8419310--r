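#' Write a parameter map or image volume as NIfTI-1
#'
#' Data are written as float32/float64 with the voxel spacing recorded in
#' the header; validity is carried by `NA` voxels.  Logical masks should
#' use [write_mask_nifti()].
#'
#' @param volume numeric array `(slices, rows, cols)`.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param pixel_spacing_mm `(dz, dy, dx)` in mm.
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(volume, path, pixel_spacing_mm = c(0.8, 0.18, 0.18)) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array", call. = FALSE)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- pixel_spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume with its spacing
#'
#' @param path file path.
#' @return list with `data` (array) and `pixel_spacing_mm`.
#' @export
read_nifti_map <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt NIfTI header: ", path, call. = FALSE))
  list(data = array(as.vector(img), dim(img)),
       pixel_spacing_mm = RNifti::pixdim(img))
}

#' Write a binary mask as uint8 NIfTI
#' @inheritParams write_nifti_map
#' @param mask logical array.
#' @export
write_mask_nifti <- function(mask, path, pixel_spacing_mm = c(0.8, 0.18, 0.18)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- pixel_spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a uint8 mask back as a logical array
#' @param path file path.
#' @export
read_mask_nifti <- function(path) {
  m <- read_nifti_map(path)
  array(m$data > 0.5, dim(m$data))
}

#' Write a multifrequency wave field as paired real/imaginary NIfTI files
#'
#' One `<stem>_f<freq>_real.nii.gz` / `_imag.nii.gz` pair per frequency,
#' plus a small CSV manifest listing frequencies and paths.
#'
#' @param wavefield an `mre_wavefield`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return manifest path, invisibly.
#' @export
write_wavefield_nifti <- function(wavefield, dir, stem = "wave") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in seq_along(wavefield$frequencies_hz)) {
    fr <- wavefield$frequencies_hz[f]
    pr <- file.path(dir, sprintf("%s_f%04d_real.nii.gz", stem, round(fr)))
    pi_ <- file.path(dir, sprintf("%s_f%04d_imag.nii.gz", stem, round(fr)))
    write_nifti_map(Re(wavefield$u[[f]]), pr, wavefield$pixel_spacing_mm)
    write_nifti_map(Im(wavefield$u[[f]]), pi_, wavefield$pixel_spacing_mm)
    rows[[f]] <- data.frame(frequency_hz = fr, real = basename(pr),
                            imag = basename(pi_))
  }
  man <- file.path(dir, paste0(stem, "_manifest.csv"))
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE)
  invisible(man)
}

#' Read a wave field written by [write_wavefield_nifti()]
#'
#' @param manifest path to the `_manifest.csv`.
#' @param brain optional logical brain mask to attach.
#' @return an `mre_wavefield`.
#' @export
read_wavefield_nifti <- function(manifest, brain = NULL) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  u <- vector("list", nrow(man))
  sp <- NULL
  for (i in seq_len(nrow(man))) {
    re <- read_nifti_map(file.path(dir, man$real[i]))
    im <- read_nifti_map(file.path(dir, man$imag[i]))
    u[[i]] <- array(complex(real = re$data, imaginary = im$data), dim(re$data))
    sp <- re$pixel_spacing_mm
  }
  if (is.null(brain)) brain <- array(is.finite(Re(u[[1]])), dim(u[[1]]))
  structure(list(frequencies_hz = man$frequency_hz, u = u,
                 pixel_spacing_mm = sp, brain = brain, density_rho = 1000,
                 method = "file", noise_sigma = NA_real_, seed = NA_integer_),
            class = "mre_wavefield")
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' Round-trips losslessly: classed specs are stored with a `.class` tag
#' and re-tagged on read.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored config (read).
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      cl <- class(x)
      out <- lapply(unclass(x), strip)
      if (!identical(cl, "list")) out[[".class"]] <- cl
      out
    } else x
  }
  yaml::write_yaml(lapply(unclass(config), strip), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  restore <- function(x) {
    if (is.list(x)) {
      cl <- x[[".class"]]
      x[[".class"]] <- NULL
      out <- lapply(x, restore)
      if (!is.null(cl)) class(out) <- unlist(cl)
      out
    } else x
  }
  raw <- yaml::read_yaml(path)
  cfg <- lapply(raw, function(x) {
    y <- restore(x)
    # yaml flattens length-1 vectors; specs tolerate that
    y
  })
  class(cfg) <- "pipeline_config"
  # integer restoration for grid shapes
  if (!is.null(cfg$cohort$grid_shape))
    cfg$cohort$grid_shape <- as.integer(unlist(cfg$cohort$grid_shape))
  cfg
}

#' Write the cohort manifest CSV
#'
#' One row per (animal, timepoint) with the wave-field manifest, mask and
#' map paths and the seed, mirroring how acquired data would be indexed.
#'
#' @param rows data.frame assembled by [run_pipeline()].
#' @param path CSV path.
#' @export
write_cohort_manifest <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
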