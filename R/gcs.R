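#' Run the guided crescent-shape (gCS) pipeline
#'
#' The manual comparator: the background SUV_mean is taken from a
#' reader-drawn crescent-shape VOI in the contralateral hemisphere, the
#' image is normalised once into a TBR map, and the BTV is grown once from
#' the seed(s) at the TBR threshold. No iteration, no overlap handling: the
#' normalisation is determined solely by the drawn VOI, so this method does
#' not adapt to multifocal uptake.
#'
#' The crescent must be nonempty and lie entirely inside the brain mask; a
#' VOI leaking outside the brain indicates broken inputs and is rejected
#' rather than clipped.
#'
#' @param image Brain-extracted [suv_image()] in SUV units.
#' @param brain Brain [voxel_mask()].
#' @param seeds A [seed_set()]; each seed's TBR after normalisation must
#'   reach the TBR threshold.
#' @param crescent Reader-drawn crescent [voxel_mask()] (CTRL_CS VOI).
#' @param config An [mi_config()]; only `tbr_threshold` and `connectivity`
#'   are used.
#' @return An object of class `gcs_result`: `btv`, `ctrl` (the crescent as
#'   supplied), `tbr`, `ctrl_suv_mean`, `btv_volume_cm3`.
#' @seealso [run_mi()]
#' @export
run_gcs <- function(image, brain, seeds, crescent, config = mi_config()) {
  stopifnot(inherits(image, "suv_image"), inherits(brain, "voxel_mask"),
            inherits(crescent, "voxel_mask"), inherits(config, "mi_config"))
  check_same_grid(image, crescent)
  check_same_grid(image, brain)
  if (!any(crescent)) stop("crescent VOI is empty")
  if (any(unclass(crescent) & !unclass(brain)))
    stop("crescent VOI extends outside the brain mask")
  validate_seeds(seeds, image, brain)

  s <- voi_mean(image, crescent)
  tbr <- make_tbr_map(image, s)
  btv <- region_grow(tbr, seeds, config$tbr_threshold, brain,
                     config$connectivity)

  structure(list(btv = btv, ctrl = crescent, tbr = tbr,
                 ctrl_suv_mean = s,
                 btv_volume_cm3 = voi_volume_cm3(btv),
                 config = config),
            class = "gcs_result")
}

#' @export
print.gcs_result <- function(x, ...) {
  cat("<gcs_result> guided crescent-shape background / BTV definition\n")
  cat(sprintf("  CTRL SUV_mean: %.4f\n", x$ctrl_suv_mean))
  cat(sprintf("  BTV: %.3f cm^3   crescent VOI: %.3f cm^3\n",
              x$btv_volume_cm3, voi_volume_cm3(x$ctrl)))
  invisible(x)
}

#' One-row summary of a crescent-shape run
#'
#' @param x A `gcs_result`.
#' @param ... Unused.
#' @return A one-row tibble: `ctrl_suv_mean`, `btv_volume_cm3`,
#'   `ctrl_volume_cm3`.
#' @method glance gcs_result
#' @export
glance.gcs_result <- function(x, ...) {
  tibble::tibble(ctrl_suv_mean = x$ctrl_suv_mean,
                 btv_volume_cm3 = x$btv_volume_cm3,
                 ctrl_volume_cm3 = voi_volume_cm3(x$ctrl))
}
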