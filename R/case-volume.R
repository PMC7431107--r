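# CaseVolume: an image volume with an aligned binary ROI mask.

#' Construct a case volume
#'
#' Bundles a 3-D scalar image, an aligned binary region-of-interest mask,
#' and the voxel spacing. The mask must have the image's shape and contain
#' at least one foreground voxel; spacing must be strictly positive.
#'
#' @param case_id Case identifier.
#' @param image 3-D numeric array (arbitrary intensity units).
#' @param mask 3-D array of 0/1 (or logical), same shape as `image`.
#' @param spacing Numeric 3-vector of voxel edge lengths in mm.
#' @return An object of class `case_volume`.
#' @export
case_volume <- function(case_id, image, mask, spacing = c(1, 1, 1)) {
  image <- as.array(image)
  mask <- as.array(mask)
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!identical(dim(image), dim(mask)))
    stop_input("image and mask shapes differ")
  if (length(dim(image)) != 3L)
    stop_input("image must be a 3-D array")
  mask <- array(as.integer(mask != 0), dim(mask))
  if (sum(mask) == 0L) stop_input("empty ROI")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("spacing must be three positive numbers")
  structure(list(case_id = as.character(case_id), image = image,
                 mask = mask, spacing = spacing),
            class = "case_volume")
}

#' @method print case_volume
#' @export
print.case_volume <- function(x, ...) {
  cat(sprintf("<case_volume> %s: %s voxels, ROI %d voxels, spacing %s mm\n",
              x$case_id, paste(dim(x$image), collapse = "x"),
              sum(x$mask), paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Read a case volume from NIfTI image and ROI files
#'
#' @param case_id Case identifier.
#' @param image_path Path to the NIfTI image (.nii or .nii.gz).
#' @param roi_path Path to the NIfTI binary mask.
#' @return A [case_volume()]. Spacing is taken from the image header.
#' @export
read_case_volume <- function(case_id, image_path, roi_path) {
  if (!file.exists(image_path)) stop_input("missing image file: ", image_path)
  if (!file.exists(roi_path)) stop_input("missing ROI file: ", roi_path)
  img <- RNifti::readNifti(image_path)
  roi <- RNifti::readNifti(roi_path)
  sp <- RNifti::pixdim(img)
  sp <- c(sp, rep(1, 3))[1:3]
  # strip the NIfTI header attributes down to plain arrays
  img_arr <- array(as.numeric(img), dim(img))
  roi_arr <- array(as.numeric(roi), dim(roi))
  case_volume(case_id, img_arr, roi_arr, sp)
}

#' Write a case volume's image or mask as NIfTI
#'
#' @param volume A [case_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @param what `"image"` or `"mask"`.
#' @return Invisibly, `path`.
#' @export
write_case_volume <- function(volume, path, what = c("image", "mask")) {
  what <- match.arg(what)
  arr <- if (what == "image") volume$image else volume$mask
  nif <- RNifti::asNifti(arr)
  RNifti::pixdim(nif) <- volume$spacing
  RNifti::writeNifti(nif, path)
  invisible(path)
}

# In-ROI intensities, in column-major voxel order.
roi_values <- function(volume) volume$image[volume$mask == 1L]
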