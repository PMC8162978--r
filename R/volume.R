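#' Segmented tumor volumes
#'
#' Container for a 3D intensity grid, a binary segmentation mask of the same
#' extent, and the voxel spacing in mm. All radiomic feature extraction in
#' this package operates on this type.
#'
#' @param intensities 3D numeric array.
#' @param mask 3D logical (or 0/1) array of the same extent; must contain at
#'   least one voxel.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm, strictly positive.
#' @return A list of class `tumor_volume` with elements `img`, `mask`,
#'   `spacing`.
#' @export
tumor_volume <- function(intensities, mask, spacing = c(1, 1, 1)) {
  intensities <- as.array(intensities)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(intensities)) != 3 || length(dim(mask)) != 3) {
    stop("'intensities' and 'mask' must be 3D arrays")
  }
  if (!identical(dim(intensities), dim(mask))) {
    stop("intensity and mask extents differ")
  }
  if (!any(mask)) stop("mask is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values")
  }
  structure(list(img = intensities, mask = mask, spacing = spacing),
            class = "tumor_volume")
}

#' @export
print.tumor_volume <- function(x, ...) {
  cat(sprintf("tumor_volume: %s grid, %d mask voxels, spacing %s mm\n",
              paste(dim(x$img), collapse = "x"), sum(x$mask),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read / write tumor volumes as NIfTI pairs
#'
#' Volumes are stored as two NIfTI files sharing a stem: `<stem>_img.nii.gz`
#' with the intensities and `<stem>_mask.nii.gz` with the binary mask, both
#' carrying the voxel spacing.
#'
#' @param stem path stem (without the `_img`/`_mask` suffix).
#' @return `read_tumor_volume` returns a [tumor_volume()];
#'   `write_tumor_volume` returns `stem` invisibly.
#' @export
read_tumor_volume <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, "_img.nii.gz"))
  msk <- RNifti::readNifti(paste0(stem, "_mask.nii.gz"))
  spacing <- RNifti::pixdim(img)[1:3]
  tumor_volume(as.array(img), as.array(msk) > 0.5, spacing = spacing)
}

#' @rdname read_tumor_volume
#' @param volume a [tumor_volume()].
#' @export
write_tumor_volume <- function(volume, stem) {
  img <- RNifti::asNifti(volume$img)
  RNifti::pixdim(img) <- volume$spacing
  msk <- RNifti::asNifti(array(as.numeric(volume$mask), dim(volume$mask)))
  RNifti::pixdim(msk) <- volume$spacing
  RNifti::writeNifti(img, paste0(stem, "_img.nii.gz"))
  RNifti::writeNifti(msk, paste0(stem, "_mask.nii.gz"))
  invisible(stem)
}
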