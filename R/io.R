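## Volume and report I/O: NIfTI for voxel grids, JSON for reports.

#' Write a voxel array as NIfTI
#'
#' @param arr 3-D numeric array
#' @param path output path (.nii or .nii.gz)
#' @param spacing voxel spacing, mm
#' @return the path, invisibly
#' @export
writeVolume <- function(arr, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file
#' @return list with \code{data} (array) and \code{spacing} (mm)
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img))
}

#' Write a report list as JSON
#'
#' @param x a (nested) list of scalars/vectors
#' @param path output path
#' @return the path, invisibly
#' @export
writeReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
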