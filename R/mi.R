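#' Configuration for the mirror-image pipeline
#'
#' Defaults follow the published protocol: an SUV threshold of 2.2 for the
#' initial tumour growth, a TBR threshold of 1.9 for growth on the
#' normalised map, and a convergence tolerance of 0.2 cm^3 on the volume
#' match between the new BTV and the previous reference VOI.
#'
#' @param suv_threshold SUV cut-off for the initial segmentation (BTV_0).
#' @param tbr_threshold TBR cut-off for BTV growth on the normalised map.
#' @param volume_tolerance_cm3 Convergence tolerance in cm^3.
#' @param max_iterations Iteration cap; runs hitting it are returned with
#'   `converged = FALSE`, never as a silent answer.
#' @param connectivity Region-growing neighbourhood, 26 or 6.
#' @param exclude_suprabackground If `TRUE`, voxels whose final TBR is at or
#'   above `tbr_threshold` are also removed from the final reference VOI
#'   (beyond the tumour-overlap removal), so that any supra-background
#'   uptake disconnected from the seeds cannot enter the background
#'   estimate. Off by default.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(suv_threshold = 2.2, tbr_threshold = 1.9,
                      volume_tolerance_cm3 = 0.2, max_iterations = 50L,
                      connectivity = 26L, exclude_suprabackground = FALSE) {
  stopifnot(suv_threshold > 0, tbr_threshold > 0,
            volume_tolerance_cm3 >= 0, max_iterations >= 1)
  structure(list(suv_threshold = suv_threshold,
                 tbr_threshold = tbr_threshold,
                 volume_tolerance_cm3 = volume_tolerance_cm3,
                 max_iterations = as.integer(max_iterations),
                 connectivity = as.integer(connectivity),
                 exclude_suprabackground = isTRUE(exclude_suprabackground)),
            class = "mi_config")
}

#' Normalise an SUV image into a tumour-to-brain-ratio map
#'
#' Divides every voxel by the background reference SUV_mean; the mean TBR
#' over the reference VOI that produced the normaliser is 1 by construction.
#'
#' @param image An [suv_image()].
#' @param ctrl_suv_mean Positive background SUV_mean.
#' @return A `tbr_map` (subclass of `suv_image`) with a `normaliser`
#'   attribute.
#' @export
make_tbr_map <- function(image, ctrl_suv_mean) {
  stopifnot(inherits(image, "suv_image"))
  if (!is.numeric(ctrl_suv_mean) || length(ctrl_suv_mean) != 1L ||
      !is.finite(ctrl_suv_mean) || ctrl_suv_mean <= 0)
    stop("`ctrl_suv_mean` must be a single positive number")
  out <- suv_image(unclass(image) / ctrl_suv_mean, img_spacing(image),
                   midline_axis(image))
  attr(out, "normaliser") <- ctrl_suv_mean
  class(out) <- c("tbr_map", "suv_image")
  out
}

#' Run the mirror-image (MI) pipeline
#'
#' Iterative semiautomated background and BTV definition. An initial tumour
#' segmentation BTV_0 is grown from the seed(s) on the SUV image at the SUV
#' threshold. Each iteration then (1) reflects the current BTV across the
#' mid-sagittal midplane into the contralateral hemisphere, removing any
#' overlap with the BTV and clipping to the brain, to obtain the reference
#' (CTRL) VOI; (2) normalises the image by the CTRL SUV_mean into a TBR map;
#' (3) regrows the BTV from the same seeds on the TBR map at the TBR
#' threshold. The loop stops when the new BTV volume matches the previous
#' CTRL volume within the tolerance. After convergence the CTRL VOI is
#' recomputed against the final BTV and the reported background SUV_mean is
#' taken from that post-exclusion VOI; no further regrowth is performed.
#'
#' Multiple seeds (multifocal disease) grow a union BTV whose mirror forms a
#' multi-component reference region.
#'
#' Because the converged result depends on the seeds only through the
#' components they select, any seed placed anywhere inside the same lesion
#' yields the identical result — the mechanism behind the method's zero
#' intra-reader variability.
#'
#' @param image Brain-extracted [suv_image()] in SUV units.
#' @param brain Brain [voxel_mask()].
#' @param seeds A [seed_set()]; each seed's SUV must be at or above the SUV
#'   threshold.
#' @param config An [mi_config()].
#' @return An object of class `mi_result` with elements `btv`, `ctrl`
#'   (final masks), `tbr` (final TBR map), `ctrl_suv_mean`,
#'   `btv_volume_cm3`, `ctrl_volume_cm3`, `converged`, `iterations`, and
#'   `trace` (a tibble with one row per iteration: BTV volume, CTRL volume,
#'   CTRL SUV_mean).
#' @seealso [run_gcs()] for the single-pass comparator; [tidy.mi_result()],
#'   [glance.mi_result()], [autoplot.mi_result()].
#' @export
run_mi <- function(image, brain, seeds, config = mi_config()) {
  stopifnot(inherits(image, "suv_image"), inherits(brain, "voxel_mask"),
            inherits(config, "mi_config"))
  axis <- midline_axis(image)
  validate_seeds(seeds, image, brain)

  btv <- region_grow(image, seeds, config$suv_threshold, brain,
                     config$connectivity)
  trace <- list()
  converged <- FALSE
  btv_vols <- numeric()
  s <- NA_real_

  for (k in seq_len(config$max_iterations)) {
    ctrl <- tryCatch(
      exclude_overlap(mirror_mask(btv, axis), btv, brain),
      error = function(e) stop("iteration ", k - 1L, ": ", conditionMessage(e)))
    s <- voi_mean(image, ctrl)
    v_btv <- voi_volume_cm3(btv)
    v_ctrl <- voi_volume_cm3(ctrl)
    trace[[k]] <- c(iteration = k - 1, btv_volume_cm3 = v_btv,
                    ctrl_volume_cm3 = v_ctrl, ctrl_suv_mean = s)
    tbr <- make_tbr_map(image, s)
    btv_new <- region_grow(tbr, seeds, config$tbr_threshold, brain,
                           config$connectivity)
    v_new <- voi_volume_cm3(btv_new)
    btv_vols <- c(btv_vols, v_new)
    n <- length(btv_vols)
    if (n >= 3 && isTRUE(all.equal(btv_vols[n], btv_vols[n - 2])) &&
        btv_vols[n] != btv_vols[n - 1])
      warning("BTV volume is oscillating between ",
              signif(btv_vols[n - 1], 6), " and ", signif(btv_vols[n], 6),
              " cm^3 (two-cycle); run will stop at max_iterations")
    btv <- btv_new
    if (abs(v_new - v_ctrl) <= config$volume_tolerance_cm3) {
      converged <- TRUE
      break
    }
  }

  # final reference VOI against the converged BTV, then extract statistics
  ctrl <- exclude_overlap(mirror_mask(btv, axis), btv, brain)
  tbr <- make_tbr_map(image, voi_mean(image, ctrl))
  if (config$exclude_suprabackground) {
    keep <- unclass(ctrl) & unclass(tbr) < config$tbr_threshold
    if (!any(keep))
      stop("reference region fully excluded after supra-background removal")
    ctrl <- voxel_mask(keep, img_spacing(ctrl))
    tbr <- make_tbr_map(image, voi_mean(image, ctrl))
  }
  s_final <- attr(tbr, "normaliser")
  trace[[length(trace) + 1L]] <- c(iteration = length(trace),
                                   btv_volume_cm3 = voi_volume_cm3(btv),
                                   ctrl_volume_cm3 = voi_volume_cm3(ctrl),
                                   ctrl_suv_mean = s_final)
  trace <- tibble::as_tibble(do.call(rbind, trace))

  if (!converged)
    warning("MI pipeline did not converge within ", config$max_iterations,
            " iterations; result flagged converged = FALSE")

  structure(list(btv = btv, ctrl = ctrl, tbr = tbr,
                 ctrl_suv_mean = s_final,
                 btv_volume_cm3 = voi_volume_cm3(btv),
                 ctrl_volume_cm3 = voi_volume_cm3(ctrl),
                 converged = converged,
                 iterations = nrow(trace) - 1L,
                 trace = trace,
                 config = config),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("<mi_result> mirror-image background / BTV definition\n")
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              if (x$converged) "yes" else "NO", x$iterations))
  cat(sprintf("  CTRL SUV_mean: %.4f\n", x$ctrl_suv_mean))
  cat(sprintf("  BTV: %.3f cm^3   CTRL VOI: %.3f cm^3\n",
              x$btv_volume_cm3, x$ctrl_volume_cm3))
  invisible(x)
}

#' Per-iteration trace of a mirror-image run
#'
#' @param x An `mi_result`.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `btv_volume_cm3`,
#'   `ctrl_volume_cm3`, `ctrl_suv_mean`; the last row is the converged
#'   state after the final overlap removal.
#' @method tidy mi_result
#' @export
tidy.mi_result <- function(x, ...) x$trace

#' One-row summary of a mirror-image run
#'
#' @param x An `mi_result`.
#' @param ... Unused.
#' @return A one-row tibble: `ctrl_suv_mean`, `btv_volume_cm3`,
#'   `ctrl_volume_cm3`, `converged`, `iterations`.
#' @method glance mi_result
#' @export
glance.mi_result <- function(x, ...) {
  tibble::tibble(ctrl_suv_mean = x$ctrl_suv_mean,
                 btv_volume_cm3 = x$btv_volume_cm3,
                 ctrl_volume_cm3 = x$ctrl_volume_cm3,
                 converged = x$converged,
                 iterations = x$iterations)
}

#' Convergence plot for a mirror-image run
#'
#' BTV and CTRL VOI volumes against iteration; convergence shows as the two
#' curves meeting within the tolerance band.
#'
#' @param object An `mi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mi_result
#' @export
autoplot.mi_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace,
                            cols = c("btv_volume_cm3", "ctrl_volume_cm3"),
                            names_to = "region", values_to = "volume_cm3")
  df$region <- ifelse(df$region == "btv_volume_cm3", "BTV", "CTRL VOI")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$volume_cm3,
                                   colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "volume (cm³)", colour = NULL,
                  title = "Mirror-image pipeline convergence") +
    ggplot2::theme_minimal()
}

#' Write pipeline outputs to a directory
#'
#' Writes `btv.nii.gz`, `ctrl.nii.gz`, `tbr.nii.gz` and `result.json`
#' (scalars plus, for MI runs, the iteration trace) under `dir`. JSON
#' output is deterministic: fixed key order, fixed precision.
#'
#' @param result An `mi_result` or `gcs_result`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, c("mi_result", "gcs_result")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(result$btv, file.path(dir, "btv.nii.gz"))
  write_image(result$ctrl, file.path(dir, "ctrl.nii.gz"))
  if (!is.null(result$tbr))
    write_image(result$tbr, file.path(dir, "tbr.nii.gz"))
  scalars <- list(
    method = if (inherits(result, "mi_result")) "MI" else "gCS",
    ctrl_suv_mean = round(result$ctrl_suv_mean, 6),
    btv_volume_cm3 = round(result$btv_volume_cm3, 6))
  if (inherits(result, "mi_result")) {
    scalars$converged <- result$converged
    scalars$iterations <- result$iterations
    scalars$trace <- lapply(seq_len(nrow(result$trace)), function(i)
      lapply(as.list(result$trace[i, ]), function(v)
        if (is.numeric(v)) round(v, 6) else v))
  }
  jsonlite::write_json(scalars, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
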