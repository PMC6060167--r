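#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti carrying the phantom's isotropic voxel size.
#' `write_nifti_volume` writes 3D/4D numeric arrays (masks as uint8),
#' `read_nifti_volume` returns a plain array with a `voxel_size` attribute.
#'
#' @param arr numeric or logical array (3D or 4D).
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size isotropic voxel edge, mm.
#' @return `write_nifti_volume` invisibly returns `path`.
#' @export
write_nifti_volume <- function(arr, path, voxel_size) {
  is_mask <- is.logical(arr)
  if (is_mask) {
    d <- dim(arr)
    arr <- array(as.integer(arr), dim = d)
  }
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  attr(img, "pixdim") <- c(rep(voxel_size, 3), rep(1, nd - 3))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
  out
}

#' Write a simulated study to a BIDS-like directory
#'
#' Writes one 4D NIfTI per repetition plus the shared bvals/bvecs pair,
#' the phantom region labels, and the ground-truth tensor field (6
#' components, Dxx Dxy Dxz Dyy Dyz Dzz).
#'
#' @param study a [simulate_acquisition()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dwi_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- study$phantom$voxel_size
  files <- character(0)
  for (r in seq_along(study$repetitions)) {
    p <- file.path(dir, sprintf("dwi_rep%02d.nii.gz", r))
    write_nifti_volume(study$repetitions[[r]], p, h)
    files <- c(files, p)
  }
  write_bvals_bvecs(study$protocol$gradients,
                    file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  lab <- study$phantom$labels
  write_nifti_volume(array(as.integer(lab), dim = dim(lab)) > 1L,
                     file.path(dir, "brain_mask.nii.gz"), h)
  write_nifti_volume(study$phantom$tensors,
                     file.path(dir, "truth_tensors.nii.gz"), h)
  invisible(c(files, file.path(dir, c("dwi.bval", "dwi.bvec",
                                      "brain_mask.nii.gz",
                                      "truth_tensors.nii.gz"))))
}
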