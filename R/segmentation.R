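#' Seeded threshold-connected region growing
#'
#' Grows, from each seed, the maximal connected component of
#' `{voxel : value >= threshold and voxel in brain}` containing that seed,
#' and returns the union over seeds. This is the segmentation primitive of
#' both pipelines: on an SUV image with threshold 2.2 it produces the
#' initial tumour segmentation, on a TBR map with threshold 1.9 the
#' biological tumour volume. The threshold comparison is inclusive (>=).
#'
#' @param map An `suv_image` or `tbr_map` to grow on.
#' @param seeds A [seed_set()]; every seed must be inside `brain` and at or
#'   above `threshold` on `map`.
#' @param threshold Positive inclusion threshold, in the units of `map`.
#' @param brain Brain [voxel_mask()] confining the growth.
#' @param connectivity 26 (faces + edges + corners, default) or 6 (faces
#'   only).
#' @return A [voxel_mask()] containing all seeds.
#' @export
region_grow <- function(map, seeds, threshold, brain, connectivity = 26L) {
  stopifnot(inherits(seeds, "seed_set"), inherits(brain, "voxel_mask"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("`connectivity` must be 6 or 26")
  check_same_grid(map, brain)
  validate_seeds(seeds, map, brain)
  vox <- unclass(map)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (vox[s[1], s[2], s[3]] < threshold)
      stop("seed below threshold: seed ", i, " (", paste(s, collapse = ","),
           ") has value ", signif(vox[s[1], s[2], s[3]], 6),
           " < ", threshold)
  }
  grown <- .flood_fill3d(as.double(vox), dim(vox), unclass(seeds),
                         threshold, as.logical(brain), connectivity)
  voxel_mask(array(grown, dim = dim(vox)), img_spacing(brain))
}

#' Reflect a mask across the mid-sagittal midplane
#'
#' A true voxel at index i along `axis` maps to index N + 1 - i (N the axis
#' length); the other axes are unchanged. For an even-sized axis the
#' reflection is about the inter-voxel midplane; for an odd-sized axis the
#' central slab is fixed. Voxel count (hence volume) is preserved and the
#' operation is an involution. This generates the contralateral mirror-image
#' VOI from a tumour segmentation.
#'
#' @param mask A nonempty [voxel_mask()].
#' @param axis Axis index (1..3) perpendicular to the midline, typically
#'   [midline_axis()] of the parent image.
#' @return The reflected [voxel_mask()].
#' @export
mirror_mask <- function(mask, axis) {
  stopifnot(inherits(mask, "voxel_mask"))
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3")
  if (!any(mask)) stop("cannot mirror an empty mask")
  n <- dim(mask)[axis]
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[axis]] <- n:1
  flipped <- do.call(`[`, c(list(unclass(mask)), idx, list(drop = FALSE)))
  voxel_mask(array(flipped, dim = dim(mask)), img_spacing(mask))
}

#' Remove tumour overlap and out-of-brain voxels from a reference VOI
#'
#' Returns `ctrl AND NOT btv AND brain`: any part of the candidate reference
#' region overlapping the tumour segmentation is removed (so infiltrating
#' tumour cannot contaminate the background estimate), and voxels falling
#' outside the brain are clipped so the reference is plausible tissue. A
#' fully excluded reference region is an error: it signals a degenerate
#' case, e.g. a midline tumour whose mirror lands on itself.
#'
#' @param ctrl Candidate reference [voxel_mask()].
#' @param btv Tumour segmentation [voxel_mask()].
#' @param brain Brain [voxel_mask()].
#' @return A [voxel_mask()] disjoint from `btv` and contained in `brain`.
#' @export
exclude_overlap <- function(ctrl, btv, brain) {
  stopifnot(inherits(ctrl, "voxel_mask"), inherits(btv, "voxel_mask"),
            inherits(brain, "voxel_mask"))
  check_same_grid(ctrl, btv)
  check_same_grid(ctrl, brain)
  out <- unclass(ctrl) & !unclass(btv) & unclass(brain)
  if (!any(out))
    stop("reference region fully excluded: the mirrored VOI has no voxels ",
         "outside the tumour and inside the brain (midline or ",
         "symmetry-destroying lesion?)")
  voxel_mask(out, img_spacing(ctrl))
}
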