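# run code with a private RNG state so generators are deterministic
# without clobbering the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic lesion
#'
#' @param centre Length-3 voxel coordinate (1-based) of the lesion centre.
#' @param radius_mm Sphere radius in mm (for ellipsoids, length-3 semi-axes).
#' @param suv Lesion uptake; must exceed the phantom background.
#' @param rim_width_mm Width of an optional surrounding rim of intermediate
#'   uptake (0 = no rim). A rim with SUV between the TBR and SUV growth
#'   thresholds exercises the difference between the SUV-grown initial
#'   segmentation and the TBR-grown BTV.
#' @param rim_suv Rim uptake (required when `rim_width_mm > 0`).
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(centre, radius_mm, suv = 3.0, rim_width_mm = 0,
                        rim_suv = NULL, shape = c("sphere", "ellipsoid")) {
  shape <- match.arg(shape)
  radius_mm <- as.numeric(radius_mm)
  if (shape == "sphere" && length(radius_mm) == 1L)
    radius_mm <- rep(radius_mm, 3L)
  stopifnot(length(centre) == 3L, length(radius_mm) == 3L,
            all(radius_mm > 0), suv > 0)
  if (rim_width_mm > 0 && is.null(rim_suv))
    stop("`rim_suv` must be given when `rim_width_mm` > 0")
  structure(list(centre = as.numeric(centre), radius_mm = radius_mm,
                 suv = suv, rim_width_mm = rim_width_mm, rim_suv = rim_suv,
                 shape = shape),
            class = "lesion_spec")
}

#' Specify a synthetic brain phantom
#'
#' The phantom emulates a brain-extracted FET PET scan: an ellipsoidal
#' brain, mirror-symmetric about the mid-sagittal midplane, with
#' near-uniform background uptake (SUV about 1, optional additive Gaussian
#' noise clipped at 0) and one or more high-uptake lesions placed off- (or,
#' for degenerate-case fixtures, on-) midline. Defaults put the lesion SUV
#' at 3.0 on background 1.0, so both growth thresholds (SUV 2.2, TBR 1.9)
#' stay active.
#'
#' @param shape Grid dimensions (voxels).
#' @param spacing Voxel spacing in mm.
#' @param brain_semi_axes_mm Ellipsoid semi-axes of the brain, mm.
#' @param background_suv Background uptake inside the brain.
#' @param noise_sd SD of additive Gaussian noise on the background (SUV).
#' @param lesions List of [lesion_spec()]s; default one 10 mm sphere at
#'   SUV 3.0 offset 25 mm from the midline.
#' @param midline_axis Axis perpendicular to the mid-sagittal plane.
#' @param seed RNG seed; identical seeds give bitwise-identical phantoms.
#' @param allow_outside_brain Permit lesions extending beyond the brain
#'   (midline-edge-case fixtures only).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 80L, 56L), spacing = c(2, 2, 2),
                         brain_semi_axes_mm = c(55, 70, 45),
                         background_suv = 1.0, noise_sd = 0,
                         lesions = list(lesion_spec(centre = c(45, 40, 28),
                                                    radius_mm = 10,
                                                    suv = 3.0)),
                         midline_axis = 1L, seed = 42L,
                         allow_outside_brain = FALSE) {
  stopifnot(length(shape) == 3L, all(shape >= 4), length(spacing) == 3L,
            all(spacing > 0), all(brain_semi_axes_mm > 0),
            background_suv > 0, noise_sd >= 0, length(lesions) >= 0)
  for (l in lesions) {
    stopifnot(inherits(l, "lesion_spec"))
    if (l$suv <= background_suv)
      stop("lesion SUV (", l$suv, ") must exceed background (",
           background_suv, ")")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 brain_semi_axes_mm = as.numeric(brain_semi_axes_mm),
                 background_suv = background_suv, noise_sd = noise_sd,
                 lesions = lesions, midline_axis = as.integer(midline_axis),
                 seed = as.integer(seed),
                 allow_outside_brain = isTRUE(allow_outside_brain)),
            class = "phantom_spec")
}

# voxel-centre coordinates (mm) relative to the grid centre, per axis
axis_coords_mm <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
}

ellipsoid_mask <- function(shape, spacing, centre_vox, semi_axes_mm) {
  cx <- (seq_len(shape[1]) - centre_vox[1]) * spacing[1] / semi_axes_mm[1]
  cy <- (seq_len(shape[2]) - centre_vox[2]) * spacing[2] / semi_axes_mm[2]
  cz <- (seq_len(shape[3]) - centre_vox[3]) * spacing[3] / semi_axes_mm[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(d2 <= 1, dim = shape)
}

#' Generate a synthetic brain phantom
#'
#' Builds the SUV image, brain mask and ground-truth lesion masks from a
#' [phantom_spec()]. Background voxels get `background_suv` plus optional
#' Gaussian noise (clipped at 0); lesion (and rim) voxels are overwritten
#' with their nominal uptake; everything outside the brain is 0. The brain
#' mask is mirror-symmetric about the midline axis by construction, so the
#' mirrored reference region of the MI pipeline always lands in valid
#' tissue.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `image` ([suv_image()]), `brain`
#'   ([voxel_mask()]), `lesions` (list of ground-truth [voxel_mask()]s,
#'   cores only), `rim` (mask of all rim voxels, or `NULL`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  ctr <- (shape + 1) / 2
  brain <- ellipsoid_mask(shape, spec$spacing, ctr, spec$brain_semi_axes_mm)

  vox <- array(0, dim = shape)
  if (spec$noise_sd > 0) {
    nb <- sum(brain)
    noise <- with_local_seed(spec$seed, rnorm(nb, 0, spec$noise_sd))
    vox[brain] <- pmax(spec$background_suv + noise, 0)
  } else {
    vox[brain] <- spec$background_suv
  }

  lesion_masks <- list()
  rim_all <- array(FALSE, dim = shape)
  for (l in spec$lesions) {
    core <- ellipsoid_mask(shape, spec$spacing, l$centre, l$radius_mm)
    if (!spec$allow_outside_brain && any(core & !brain))
      stop("lesion at (", paste(l$centre, collapse = ","),
           ") extends outside the brain ellipsoid")
    if (l$rim_width_mm > 0) {
      rim <- ellipsoid_mask(shape, spec$spacing, l$centre,
                            l$radius_mm + l$rim_width_mm) & !core
      rim <- rim & brain
      vox[rim] <- l$rim_suv
      rim_all <- rim_all | rim
    }
    vox[core & brain] <- l$suv
    if (spec$allow_outside_brain) core <- core & brain
    lesion_masks <- c(lesion_masks,
                      list(voxel_mask(core, spec$spacing)))
  }

  structure(list(image = suv_image(vox, spec$spacing, spec$midline_axis),
                 brain = voxel_mask(brain, spec$spacing),
                 lesions = lesion_masks,
                 rim = if (any(rim_all)) voxel_mask(rim_all, spec$spacing)
                       else NULL,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s grid, %d lesion(s), background %.2f SUV, noise sd %.3f\n",
              paste(x$spec$shape, collapse = "x"), length(x$lesions),
              x$spec$background_suv, x$spec$noise_sd))
  invisible(x)
}

mask_which_coords <- function(mask) {
  which(unclass(mask), arr.ind = TRUE)
}

# deterministic sub-seed per (reader, repeat), below 2^31
derive_subseed <- function(seed, reader, rep) {
  (as.double(seed) * 7919 + reader * 104729 + rep * 101) %% 2147483629
}

#' Simulate reader inputs for a phantom
#'
#' Emulates the manual inputs of a reader study: for each of `n_readers`
#' readers and `n_repeats` repeats, a seed set (one seed sampled uniformly
#' from each true lesion's supra-threshold voxels) and a crescent-shape
#' background VOI. Crescents are contiguous shell segments placed in the
#' contralateral hemisphere around the mirrored lesion position, with
#' jittered position and extent, restricted to a slab of axial slices the
#' way a reader draws on consecutive slices. With
#' `contamination_fraction > 0` (requires a phantom with a rim), a
#' binomially-sampled fraction of each crescent's voxels is swapped for
#' elevated-uptake rim voxels, emulating imperfect placement near
#' higher-uptake tissue.
#'
#' All randomness derives deterministically from `seed` via per-
#' (reader, repeat) sub-seeds, so partial reruns match full runs.
#'
#' @param phantom A [generate_phantom()] result with at least one lesion.
#' @param n_readers,n_repeats Study design; defaults 7 readers, 6 repeats.
#' @param suv_threshold Seeds are sampled among lesion voxels at or above
#'   this SUV (default 2.2, the growth threshold).
#' @param crescent_radii_mm Inner/outer radius of the crescent shell (mm).
#' @param crescent_jitter_mm Maximum positional jitter of the crescent
#'   centre along each axis (mm).
#' @param slab_halfwidth_vox Half-thickness, in slices, of the axial slab
#'   the crescent is drawn on.
#' @param contamination_fraction Expected fraction of crescent voxels
#'   replaced by rim voxels (0 = pure background crescents).
#' @param seed Top-level RNG seed.
#' @return A tibble with columns `reader`, `repeat`, `seeds` (list of
#'   [seed_set()]), `crescent` (list of [voxel_mask()]).
#' @export
simulate_reader_inputs <- function(phantom, n_readers = 7L, n_repeats = 6L,
                                   suv_threshold = 2.2,
                                   crescent_radii_mm = c(10, 18),
                                   crescent_jitter_mm = 4,
                                   slab_halfwidth_vox = 2L,
                                   contamination_fraction = 0,
                                   seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), n_readers >= 1, n_repeats >= 1,
            contamination_fraction >= 0, contamination_fraction < 1)
  if (length(phantom$lesions) == 0L)
    stop("phantom has no lesions to seed")
  if (contamination_fraction > 0 && is.null(phantom$rim))
    stop("contamination requested but the phantom has no rim voxels")

  spec <- phantom$spec
  img <- unclass(phantom$image)
  axis <- spec$midline_axis
  shape <- spec$shape

  lesion_coords <- lapply(phantom$lesions, function(m) {
    co <- mask_which_coords(m)
    keep <- img[co] >= suv_threshold
    if (!any(keep))
      stop("lesion has no voxels at or above the SUV threshold")
    co[keep, , drop = FALSE]
  })
  for (co in lesion_coords)
    if (nrow(co) < n_repeats)
      warning("lesion too small to sample distinct seeds; sampling with replacement")

  # exclusion zone for crescents: lesions, rims, and their mirrors
  excl <- Reduce(`|`, lapply(phantom$lesions, unclass),
                 array(FALSE, dim = shape))
  if (!is.null(phantom$rim)) excl <- excl | unclass(phantom$rim)
  excl <- excl | unclass(mirror_mask(voxel_mask(excl, spec$spacing), axis))
  bg_ok <- unclass(phantom$brain) & !excl

  # crescent anchor: mirrored centroid of the first lesion
  cent <- colMeans(mask_which_coords(phantom$lesions[[1]]))
  cent[axis] <- shape[axis] + 1 - cent[axis]
  rim_coords <- if (!is.null(phantom$rim)) mask_which_coords(phantom$rim)

  coords_mm <- axis_coords_mm(shape, spec$spacing)

  make_crescent <- function() {
    for (attempt in 1:20) {
      jit <- runif(3, -crescent_jitter_mm, crescent_jitter_mm) / spec$spacing
      c0 <- cent + jit
      r_in <- crescent_radii_mm[1] * runif(1, 0.85, 1.15)
      r_out <- crescent_radii_mm[2] * runif(1, 0.85, 1.15)
      dx <- (seq_len(shape[1]) - c0[1]) * spec$spacing[1]
      dy <- (seq_len(shape[2]) - c0[2]) * spec$spacing[2]
      dz <- (seq_len(shape[3]) - c0[3]) * spec$spacing[3]
      d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
      shell <- d2 >= r_in^2 & d2 <= r_out^2
      z0 <- round(c0[3])
      slab <- abs(slice.index(shell, 3) - z0) <= slab_halfwidth_vox
      cres <- shell & slab & bg_ok
      if (sum(cres) >= 20) {
        if (contamination_fraction > 0) {
          n_c <- sum(cres)
          k <- stats::rbinom(1, n_c, contamination_fraction)
          if (k > 0) {
            on_idx <- which(cres)
            drop_idx <- sample(on_idx, k)
            cres[drop_idx] <- FALSE
            add <- rim_coords[sample(nrow(rim_coords), min(k, nrow(rim_coords))), ,
                              drop = FALSE]
            cres[add] <- TRUE
          }
        }
        return(voxel_mask(array(cres, dim = shape), spec$spacing))
      }
    }
    stop("could not place a crescent VOI inside the background")
  }

  rows <- list()
  for (r in seq_len(n_readers)) {
    for (t in seq_len(n_repeats)) {
      sub <- derive_subseed(seed, r, t)
      pair <- with_local_seed(sub, {
        sds <- do.call(rbind, lapply(lesion_coords, function(co)
          co[sample(nrow(co), 1L), , drop = FALSE]))
        list(seeds = seed_set(sds), crescent = make_crescent())
      })
      rows[[length(rows) + 1L]] <-
        tibble::tibble(reader = r, `repeat` = t,
                       seeds = list(pair$seeds),
                       crescent = list(pair$crescent))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a phantom bundle to disk
#'
#' Writes `suv.nii.gz`, `brain.nii.gz`, `lesion_<i>.nii.gz`, optional
#' simulated reader inputs under `readers/`, and a JSON echo of the spec.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory.
#' @param reader_inputs Optional tibble from [simulate_reader_inputs()].
#' @return `dir`, invisibly.
#' @export
write_phantom_bundle <- function(phantom, dir, reader_inputs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(phantom$image, file.path(dir, "suv.nii.gz"))
  write_image(phantom$brain, file.path(dir, "brain.nii.gz"))
  for (i in seq_along(phantom$lesions))
    write_image(phantom$lesions[[i]],
                file.path(dir, sprintf("lesion_%d.nii.gz", i)))
  spec <- phantom$spec
  spec$lesions <- lapply(spec$lesions, unclass)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(reader_inputs)) {
    rdir <- file.path(dir, "readers")
    dir.create(rdir, showWarnings = FALSE)
    for (i in seq_len(nrow(reader_inputs))) {
      tag <- sprintf("reader%02d_repeat%02d",
                     reader_inputs$reader[i], reader_inputs$`repeat`[i])
      write_seeds(reader_inputs$seeds[[i]],
                  file.path(rdir, paste0(tag, "_seeds.json")))
      write_image(reader_inputs$crescent[[i]],
                  file.path(rdir, paste0(tag, "_crescent.nii.gz")))
    }
  }
  invisible(dir)
}
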