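test_that("TBR normalisation divides voxelwise and records the normaliser", {
  img <- uniform_image(2.0)
  tbr <- make_tbr_map(img, 2.0)
  expect_true(all(unclass(tbr) == 1))
  expect_equal(attr(tbr, "normaliser"), 2.0)

  tbr1 <- make_tbr_map(img, 1.0)
  expect_equal(unclass(tbr1), unclass(img), ignore_attr = TRUE)

  vox <- array(1, c(4, 4, 4)); vox[2, 2, 2] <- 3.8
  tbr2 <- make_tbr_map(suv_image(vox, c(1, 1, 1)), 2.0)
  expect_equal(tbr2[2, 2, 2], 1.9)

  expect_error(make_tbr_map(img, 0), "positive")
  expect_error(make_tbr_map(img, -1), "positive")

  # mean TBR over the VOI that produced the normaliser is 1
  ph <- small_phantom(noise_sd = 0.1, seed = 2)
  bg <- unclass(ph$brain) & !unclass(ph$lesions[[1]])
  m <- voxel_mask(bg, img_spacing(ph$brain))
  tbr3 <- make_tbr_map(ph$image, voi_mean(ph$image, m))
  expect_equal(voi_mean(tbr3, m), 1.0, tolerance = 1e-12)
})

test_that("MI converges on the noiseless phantom and recovers the truth", {
  ph <- small_phantom()
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  res <- run_mi(ph$image, ph$brain, seed_set(lesion_vox[1, ]))

  expect_true(res$converged)
  expect_equal(res$ctrl_suv_mean, 1.0)
  expect_identical(unclass(res$btv), unclass(ph$lesions[[1]]))
  tr <- tidy(res)
  expect_s3_class(tr, "tbl_df")
  # convergence contract against the previous iteration's CTRL volume
  n <- nrow(tr)
  expect_lte(abs(tr$btv_volume_cm3[n] - tr$ctrl_volume_cm3[n - 1]), 0.2)
  # CTRL disjoint from BTV and inside brain
  expect_false(any(unclass(res$ctrl) & unclass(res$btv)))
  expect_true(all(unclass(ph$brain)[unclass(res$ctrl)]))
  # trace CTRL volumes never exceed matching BTV volumes
  expect_true(all(tr$ctrl_volume_cm3 <= tr$btv_volume_cm3 + 1e-12))

  g <- glance(res)
  expect_equal(g$btv_volume_cm3, voi_volume_cm3(ph$lesions[[1]]))
})

test_that("the MI result is identical for any seed inside the lesion", {
  ph <- small_phantom()
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  set.seed(17)
  picks <- lesion_vox[sample(nrow(lesion_vox), 6), , drop = FALSE]
  results <- lapply(seq_len(6), function(i)
    run_mi(ph$image, ph$brain, seed_set(picks[i, ])))
  for (i in 2:6) {
    expect_identical(unclass(results[[i]]$btv), unclass(results[[1]]$btv))
    expect_identical(results[[i]]$ctrl_suv_mean, results[[1]]$ctrl_suv_mean)
    expect_identical(results[[i]]$trace, results[[1]]$trace)
  }
})

test_that("MI is scale-equivariant in the SUV calibration", {
  ph <- small_phantom()
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  s <- seed_set(lesion_vox[1, ])
  base <- run_mi(ph$image, ph$brain, s)

  c0 <- 2.7
  scaled_img <- suv_image(unclass(ph$image) * c0, img_spacing(ph$image),
                          midline_axis(ph$image))
  scaled <- run_mi(scaled_img, ph$brain, s,
                   mi_config(suv_threshold = 2.2 * c0))
  expect_identical(unclass(scaled$btv), unclass(base$btv))
  expect_equal(scaled$ctrl_suv_mean, c0 * base$ctrl_suv_mean)
})

test_that("multiple seeds segment multifocal disease as a union", {
  ph <- generate_phantom(phantom_spec(
    shape = c(32L, 24L, 18L), spacing = c(2, 2, 2),
    brain_semi_axes_mm = c(28, 20, 14),
    lesions = list(lesion_spec(c(23, 8, 9), 4, suv = 3),
                   lesion_spec(c(24, 17, 9), 4, suv = 3))))
  s1 <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)[1, ]
  s2 <- which(unclass(ph$lesions[[2]]), arr.ind = TRUE)[1, ]
  res <- run_mi(ph$image, ph$brain, seed_set(rbind(s1, s2)))
  expect_true(res$converged)
  truth <- unclass(ph$lesions[[1]]) | unclass(ph$lesions[[2]])
  expect_equal(unclass(res$btv), truth, ignore_attr = TRUE)
  expect_equal(res$ctrl_suv_mean, 1.0)
})

test_that("MI fails loudly on degenerate and sub-threshold inputs", {
  ph <- small_phantom()
  bg <- which(unclass(ph$brain) & unclass(ph$image) < 2, arr.ind = TRUE)
  expect_error(run_mi(ph$image, ph$brain, seed_set(bg[1, ])),
               "seed below threshold")

  # midline lesion: its mirror is itself, so the reference region vanishes
  mid <- generate_phantom(phantom_spec(
    shape = c(25L, 20L, 16L), spacing = c(2, 2, 2),
    brain_semi_axes_mm = c(22, 17, 13),
    lesions = list(lesion_spec(c(13, 10, 8), 5, suv = 3))))
  s <- which(unclass(mid$lesions[[1]]), arr.ind = TRUE)[1, ]
  expect_error(run_mi(mid$image, mid$brain, seed_set(s)),
               "fully excluded")
})

test_that("runs hitting the iteration cap are flagged, not silently returned", {
  ph <- small_phantom(rim = TRUE)
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  s <- seed_set(lesion_vox[1, ])
  # with the rim, the TBR-grown BTV exceeds the initial SUV-grown BTV by the
  # rim volume, so a single iteration at zero tolerance cannot converge
  expect_warning(
    res <- run_mi(ph$image, ph$brain, s,
                  mi_config(volume_tolerance_cm3 = 0, max_iterations = 1L)),
    "did not converge")
  expect_false(res$converged)
  expect_s3_class(res$trace, "tbl_df")

  # with the default tolerance the same phantom converges and the BTV
  # includes the supra-TBR rim
  res2 <- run_mi(ph$image, ph$brain, s)
  expect_true(res2$converged)
  expect_true(all(unclass(res2$btv)[unclass(ph$rim)]))
})

test_that("pipeline outputs round-trip through the output directory", {
  ph <- small_phantom()
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  res <- run_mi(ph$image, ph$brain, seed_set(lesion_vox[1, ]))
  dir <- withr::local_tempdir()
  write_pipeline_outputs(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("btv.nii.gz", "ctrl.nii.gz", "tbr.nii.gz", "result.json")))))
  js <- jsonlite::fromJSON(file.path(dir, "result.json"))
  expect_equal(js$ctrl_suv_mean, res$ctrl_suv_mean, tolerance = 1e-6)
  expect_true(js$converged)
  btv_back <- read_mask(file.path(dir, "btv.nii.gz"))
  expect_identical(unclass(btv_back) > 0, unclass(res$btv) > 0)
})
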