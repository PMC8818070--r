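test_that("region growing matches a brute-force flood-fill oracle", {
  set.seed(101)
  d <- c(7L, 7L, 7L)
  brain <- array(TRUE, d)
  # two disjoint supra-threshold blobs
  vox <- array(1, d)
  vox[1:3, 1:3, 1:3] <- 3.0
  vox[5:7, 5:7, 5:7] <- 2.5
  img <- suv_image(vox, c(1, 1, 1))
  bm <- voxel_mask(brain, c(1, 1, 1))

  for (conn in c(6L, 26L)) {
    got_a <- region_grow(img, seed_set(c(2, 2, 2)), 1.9, bm, conn)
    exp_a <- flood_oracle(vox, rbind(c(2, 2, 2)), 1.9, brain, conn)
    expect_identical(unclass(got_a) > 0, exp_a, info = paste("conn", conn))
    expect_false(any(unclass(got_a)[5:7, 5:7, 5:7]))

    both <- seed_set(rbind(c(2, 2, 2), c(6, 6, 6)))
    got_ab <- region_grow(img, both, 1.9, bm, conn)
    exp_ab <- flood_oracle(vox, rbind(c(2, 2, 2), c(6, 6, 6)), 1.9, brain, conn)
    expect_identical(unclass(got_ab) > 0, exp_ab)
    expect_true(all(unclass(got_a)[unclass(got_ab) == FALSE] == FALSE))
  }

  # random maps, property-style comparison against the oracle
  for (i in 1:5) {
    vox <- array(runif(prod(d), 0, 3), d)
    seeds_ok <- which(vox >= 2, arr.ind = TRUE)
    s <- seed_set(seeds_ok[sample(nrow(seeds_ok), 1L), ])
    got <- region_grow(suv_image(vox, c(1, 1, 1)), s, 2, bm)
    expect_identical(unclass(got) > 0, flood_oracle(vox, unclass(s), 2, brain))
  }
})

test_that("saturated and isolated growth behave per contract", {
  ph <- small_phantom()
  # uniform supra-threshold field fills the whole brain
  img3 <- suv_image(array(3, dim(ph$brain)) * unclass(ph$brain),
                    img_spacing(ph$brain))
  centre <- round(colMeans(which(unclass(ph$brain), arr.ind = TRUE)))
  grown <- region_grow(img3, seed_set(centre), 1.9, ph$brain)
  expect_identical(unclass(grown), unclass(ph$brain))

  # exactly one supra-threshold voxel at the seed
  vox <- array(1, c(5, 5, 5)); vox[3, 3, 3] <- 5
  got <- region_grow(suv_image(vox, c(1, 1, 1)), seed_set(c(3, 3, 3)), 2,
                     full_mask(c(5L, 5L, 5L), c(1, 1, 1)))
  expect_equal(sum(got), 1L)
  expect_true(got[3, 3, 3])
})

test_that("region growing rejects bad seeds and reports which", {
  ph <- small_phantom()
  bg <- which(unclass(ph$brain) & unclass(ph$image) < 2, arr.ind = TRUE)
  expect_error(region_grow(ph$image, seed_set(bg[1, ]), 2.2, ph$brain),
               "seed below threshold")
  expect_error(region_grow(ph$image, seed_set(c(1, 1, 1)), 2.2, ph$brain),
               "outside brain")
})

test_that("growth is seed-invariant and monotone in the threshold", {
  ph <- small_phantom()
  lesion_vox <- which(unclass(ph$lesions[[1]]), arr.ind = TRUE)
  ref <- region_grow(ph$image, seed_set(lesion_vox[1, ]), 2.2, ph$brain)
  # every voxel of the grown region regenerates the identical region
  set.seed(5)
  for (i in sample(nrow(lesion_vox), 5)) {
    again <- region_grow(ph$image, seed_set(lesion_vox[i, ]), 2.2, ph$brain)
    expect_identical(unclass(again), unclass(ref))
  }
  # t1 <= t2 => grow(t2) subset of grow(t1)
  noisy <- small_phantom(noise_sd = 0.4, seed = 8)
  s <- seed_set(lesion_vox[1, ])
  g_low <- region_grow(noisy$image, s, 1.5, noisy$brain)
  g_high <- region_grow(noisy$image, s, 2.5, noisy$brain)
  expect_true(all(unclass(g_low)[unclass(g_high)]))
  expect_gt(sum(g_low), sum(g_high))
})

test_that("mirroring is an index reflection, volume-preserving and involutive", {
  d <- c(10L, 6L, 6L)
  m <- array(FALSE, d); m[2, 3, 4] <- TRUE
  mm <- mirror_mask(voxel_mask(m, c(1, 1, 1)), 1)
  expect_true(mm[9, 3, 4])  # i -> N + 1 - i with N = 10
  expect_equal(sum(mm), 1L)

  set.seed(21)
  for (axis in 1:3) {
    r <- array(runif(prod(d)) > 0.7, d)
    if (!any(r)) r[1, 1, 1] <- TRUE
    vm <- voxel_mask(r, c(2, 2, 2))
    flipped <- mirror_mask(vm, axis)
    expect_equal(voi_volume_cm3(flipped), voi_volume_cm3(vm))
    expect_identical(unclass(mirror_mask(flipped, axis)), unclass(vm))
  }

  # a midplane-symmetric mask is a fixed point
  sym <- array(FALSE, d); sym[c(3, 8), 2, 2] <- TRUE
  vs <- voxel_mask(sym, c(1, 1, 1))
  expect_identical(unclass(mirror_mask(vs, 1)), unclass(vs))

  expect_error(mirror_mask(voxel_mask(array(FALSE, d), c(1, 1, 1)), 1),
               "empty")
})

test_that("overlap exclusion removes tumour and out-of-brain voxels", {
  d <- c(8L, 8L, 8L)
  sp <- c(1, 1, 1)
  brain <- voxel_mask(array(TRUE, d), sp)

  ctrl <- array(FALSE, d); ctrl[1:4, 1:5, 1:5] <- TRUE   # 100 voxels
  btv <- array(FALSE, d);  btv[1:3, 1:5, 1:2] <- TRUE    # 30-voxel overlap
  out <- exclude_overlap(voxel_mask(ctrl, sp), voxel_mask(btv, sp), brain)
  expect_equal(sum(out), 70L)
  expect_false(any(unclass(out) & btv))

  # disjoint ctrl passes through (intersected with brain)
  far <- array(FALSE, d); far[6:8, 6:8, 6:8] <- TRUE
  out2 <- exclude_overlap(voxel_mask(ctrl, sp), voxel_mask(far, sp), brain)
  expect_equal(unclass(out2), ctrl, ignore_attr = TRUE)

  # total exclusion is an error
  expect_error(
    exclude_overlap(voxel_mask(btv, sp), voxel_mask(ctrl, sp), brain),
    "fully excluded")
})
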