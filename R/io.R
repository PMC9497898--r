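# NIfTI + JSON-sidecar I/O for phantoms, simulated volumes and VOI masks.
# The same readers accept user-supplied real volumes and label maps.

#' Write a phantom as a NIfTI label volume with JSON sidecar
#'
#' @param phantom A `VoxelPhantom`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  img <- RNifti::asNifti(array(as.integer(phantom$labels), dim = dim(phantom$labels)),
                         pixdim = rep(phantom$pitch_mm, 3), datatype = "int16")
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  meta <- list(
    name = phantom$name,
    pitch_mm = phantom$pitch_mm,
    dims_mm = phantom$dims_mm,
    payload = phantom$payload,
    rng_seed = phantom$rng_seed,
    labels = as.list(PHANTOM_LABELS)
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `VoxelPhantom` (without the generator-specific extras).
#' @export
read_phantom <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_voxel_phantom(
    name = meta$name,
    labels = array(as.integer(img), dim = dim(img)),
    pitch_mm = meta$pitch_mm,
    payload = meta$payload,
    rng_seed = meta$rng_seed %||% NA_integer_
  )
}

#' Write a simulated volume as NIfTI with JSON sidecar
#'
#' @param volume An `MRVolume`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_mrvolume <- function(volume, prefix) {
  img <- RNifti::asNifti(volume$intensities, pixdim = rep(volume$voxel_mm, 3))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  meta <- list(
    voxel_mm = volume$voxel_mm,
    setup_label = volume$setup$label,
    repetition = volume$repetition,
    noise_seed = volume$noise_seed,
    provenance = volume$provenance
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a volume written by [write_mrvolume()] (or any NIfTI scalar volume)
#'
#' @param prefix Path prefix; `<prefix>.json` is optional for foreign data.
#' @return An `MRVolume`.
#' @export
read_mrvolume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  pix <- RNifti::pixdim(img)
  meta <- if (file.exists(paste0(prefix, ".json"))) {
    jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  } else {
    list()
  }
  setup <- if (!is.null(meta$setup_label)) {
    parse_setup_label(meta$setup_label)
  } else {
    list(label = NULL)
  }
  structure(list(
    intensities = array(as.numeric(img), dim = dim(img)),
    voxel_mm = meta$voxel_mm %||% pix[1],
    setup = setup,
    repetition = meta$repetition %||% NA_integer_,
    noise_seed = meta$noise_seed %||% NA_integer_,
    provenance = meta$provenance %||% prefix
  ), class = "MRVolume")
}

#' Write a VOI mask as a NIfTI label map
#'
#' @param mask A `VOIMask`.
#' @param path Output `.nii.gz` path.
#' @param voxel_mm Voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_voi_mask <- function(mask, path, voxel_mm = 1) {
  m <- if (inherits(mask, "VOIMask")) mask$mask else mask
  img <- RNifti::asNifti(array(as.integer(m), dim = dim(m)),
                         pixdim = rep(voxel_mm, 3), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a VOI label map
#'
#' @param path NIfTI path; non-zero voxels become the mask.
#' @return A `VOIMask`.
#' @export
read_voi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.integer(img) != 0L, dim = dim(img))
  structure(list(mask = m, method = "file", edge_mm = NA_real_,
                 voxel_count = sum(m)), class = "VOIMask")
}
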