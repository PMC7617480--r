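# NIfTI and config file I/O.

#' Write an array as NIfTI
#'
#' @param arr Numeric array (2-D to 4-D). NA values are stored as-is.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixel_mm In-plane voxel size (mm).
#' @param slice_mm Slice thickness (mm).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(arr, path, pixel_mm = 2.3, slice_mm = 8) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixel_mm, pixel_mm, slice_mm,
                           1)[seq_len(min(4, max(2, nd)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a plain array
#'
#' @param path File path.
#' @return Numeric array with attribute `pixdim`.
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Write a complex image stack as a real/imaginary NIfTI pair
#'
#' @param arr Complex array.
#' @param prefix Path prefix; writes `<prefix>_real.nii.gz` and
#'   `<prefix>_imag.nii.gz`.
#' @param pixel_mm,slice_mm Voxel dimensions (mm).
#' @return The two paths, invisibly.
#' @export
write_complex_nifti <- function(arr, prefix, pixel_mm = 2.3, slice_mm = 8) {
  p1 <- paste0(prefix, "_real.nii.gz")
  p2 <- paste0(prefix, "_imag.nii.gz")
  write_nifti_map(Re(arr), p1, pixel_mm, slice_mm)
  write_nifti_map(Im(arr), p2, pixel_mm, slice_mm)
  invisible(c(p1, p2))
}

#' Read a real/imaginary NIfTI pair as a complex array
#'
#' @param prefix Path prefix used by [write_complex_nifti()].
#' @return Complex array.
#' @export
read_complex_nifti <- function(prefix) {
  re <- read_nifti_map(paste0(prefix, "_real.nii.gz"))
  im <- read_nifti_map(paste0(prefix, "_imag.nii.gz"))
  array(complex(real = re, imaginary = im), dim(re))
}

#' Read a pipeline configuration file (YAML)
#'
#' @param path YAML file.
#' @return Config list, merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Write a pipeline configuration (YAML)
#'
#' @param config Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
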