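#' Construct an SUV image
#'
#' An `suv_image` is a 3D array of standardised uptake values (SUV,
#' dimensionless, non-negative) together with the voxel spacing in mm and the
#' index of the grid axis whose midplane is taken as the anatomical
#' mid-sagittal (anterior-posterior midline) plane. Inputs are assumed to be
#' brain-extracted and rigidly aligned so that the midline coincides with a
#' grid-axis midplane; `midline_axis` selects that axis.
#'
#' @param voxels 3D numeric array of finite, non-negative SUV values.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm,
#'   all positive.
#' @param midline_axis Integer in 1..3: the array axis perpendicular to the
#'   mid-sagittal plane (default 1, the first array axis).
#' @return An object of class `suv_image`: the array with `spacing` and
#'   `midline_axis` attributes.
#' @seealso [read_suv_image()], [voxel_mask()], [make_tbr_map()]
#' @export
suv_image <- function(voxels, spacing, midline_axis = 1L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimension(s)")
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("SUV values must all be finite")
  if (any(voxels < 0))
    stop("SUV values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm")
  midline_axis <- as.integer(midline_axis)
  if (length(midline_axis) != 1L || is.na(midline_axis) ||
      midline_axis < 1L || midline_axis > 3L)
    stop("`midline_axis` must be 1, 2 or 3")
  structure(voxels,
            spacing = spacing,
            midline_axis = midline_axis,
            class = "suv_image")
}

#' Construct a binary voxel mask
#'
#' A `voxel_mask` is a logical 3D array on the same grid as its parent image;
#' it represents any volume of interest: brain mask, BTV, contralateral
#' reference (CTRL) VOI, or crescent VOI.
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @param spacing Numeric length-3 voxel spacing in mm, usually inherited
#'   from the parent image.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (is.numeric(voxels)) {
    if (anyNA(voxels) || !all(voxels %in% c(0, 1)))
      stop("numeric mask values must be 0 or 1")
    dims <- dim(voxels)
    voxels <- array(voxels != 0, dim = dims)
  }
  if (!is.logical(voxels) || anyNA(voxels))
    stop("mask voxels must be logical without NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm")
  structure(voxels, spacing = spacing, class = "voxel_mask")
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<suv_image> %d x %d x %d voxels, spacing %s mm, midline axis %d\n",
              d[1], d[2], d[3],
              paste(signif(img_spacing(x), 4), collapse = " x "),
              midline_axis(x)))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, %d on (%.3f cm^3)\n",
              d[1], d[2], d[3], sum(x), voi_volume_cm3(x)))
  invisible(x)
}

#' Voxel spacing of an image or mask
#' @param x An `suv_image`, `tbr_map` or `voxel_mask`.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
img_spacing <- function(x) attr(x, "spacing")

#' Midline axis of an image
#' @param x An `suv_image` or `tbr_map`.
#' @return Integer axis index (1..3) perpendicular to the mid-sagittal plane.
#' @export
midline_axis <- function(x) attr(x, "midline_axis")

check_same_grid <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match image shape (", paste(dim(image), collapse = "x"), ")")
  invisible(TRUE)
}

#' Volume of a mask in cubic centimetres
#'
#' @param mask A [voxel_mask()].
#' @return Volume in cm^3: true-voxel count times the voxel volume (product
#'   of the spacing components, mm^3) divided by 1000. An empty mask has
#'   volume 0.
#' @export
voi_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask) * prod(img_spacing(mask)) / 1000
}

#' Mean image value over a mask
#'
#' The mean SUV (or TBR) of the voxels selected by `mask`; this is the
#' `SUV_mean` statistic of a reference VOI. An empty mask is an error, the
#' failure signal for a degenerate (fully excluded) reference region.
#'
#' @param image An `suv_image` or `tbr_map`.
#' @param mask A nonempty [voxel_mask()] on the same grid.
#' @return The arithmetic mean of the masked voxels.
#' @export
voi_mean <- function(image, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  check_same_grid(image, mask)
  n <- sum(mask)
  if (n == 0L) stop("reference region is empty")
  sum(unclass(image)[which(mask)]) / n
}

#' Read a 3D SUV image from a NIfTI-1 file
#'
#' Voxel spacing is taken from the NIfTI header; the volume must be 3D.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param midline_axis Axis index (1..3) whose midplane is the mid-sagittal
#'   plane; override when the image orientation differs from the default
#'   first-axis convention.
#' @return An [suv_image()].
#' @export
read_suv_image <- function(path, midline_axis = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  # tolerate trailing singleton dimensions (some writers emit 3D-as-4D)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    arr <- array(arr, dim = d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("expected 3D volume in ", path, ", got ", length(d), "D")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header of ", path)
  suv_image(arr, sp, midline_axis)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing 0/1 voxels.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  img <- read_suv_image(path)
  voxel_mask(unclass(img) != 0, img_spacing(img))
}

#' Write an image or mask to NIfTI-1
#'
#' Images are written as 32-bit float; masks as unsigned 8-bit 0/1, the
#' de-facto dialect for segmentation interchange. Spacing goes into the
#' header `pixdim`.
#'
#' @param x An `suv_image`, `tbr_map` or `voxel_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  sp <- img_spacing(x)
  is_mask <- inherits(x, "voxel_mask")
  arr <- array(if (is_mask) as.integer(unclass(x)) else as.double(unclass(x)),
               dim = dim(x))
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = if (is_mask) "uint8" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
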