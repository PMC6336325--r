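test_that("frame schedules validate and derive timing", {
  s <- frame_schedule(c(0, 10, 20), c(10, 20, 50))
  expect_equal(frame_duration_s(s), c(10, 10, 30))
  expect_equal(frame_mid_s(s), c(5, 15, 35))
  expect_error(frame_schedule(c(0, 5), c(10, 20)), "overlap")
  expect_error(frame_schedule(c(10, 0), c(20, 10)), "sorted")
  expect_error(frame_schedule(0, 0), "end_s > start_s")

  d <- pib_frame_schedule()
  expect_equal(n_frames(d), 23L)
  expect_equal(max(d$end_s), 3580)
  expect_equal(frame_duration_s(d)[1:8], c(rep(10, 7), 30))
})

test_that("extract_tac averages a region frame by frame", {
  img <- uniform_dynamic(rep(5, 4))
  mask <- array(TRUE, c(3, 3, 3))
  expect_equal(extract_tac(img, mask)$value, rep(5, 4))

  arr <- array(0, c(2, 1, 1, 3))
  arr[1, 1, 1, ] <- 1; arr[2, 1, 1, ] <- 3
  img2 <- dynamic_image(arr, 2, frame_schedule(c(0, 10, 20), c(10, 20, 30)))
  expect_equal(extract_tac(img2, array(TRUE, c(2, 1, 1)))$value, rep(2, 3))

  set.seed(11)
  arr <- array(rnorm(4 * 4 * 4 * 5), c(4, 4, 4, 5))
  sched <- frame_schedule(seq(0, 40, 10), seq(10, 50, 10))
  img3 <- dynamic_image(arr, 2, sched)
  mask3 <- array(FALSE, c(4, 4, 4))
  mask3[sample(64, 7)] <- TRUE
  got <- extract_tac(img3, mask3)$value
  # loop-based oracle
  oracle <- numeric(5)
  for (f in 1:5) {
    acc <- 0; cnt <- 0
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      if (mask3[i, j, k]) { acc <- acc + arr[i, j, k, f]; cnt <- cnt + 1 }
    oracle[f] <- acc / cnt
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(extract_tac(img3, array(FALSE, c(4, 4, 4))), "empty region")
  expect_error(extract_tac(img3, array(TRUE, c(3, 4, 4))), "shape")
})

test_that("extract_tac is linear in the image", {
  set.seed(3)
  sched <- frame_schedule(c(0, 10), c(10, 20))
  a1 <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  a2 <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  mask <- array(c(TRUE, FALSE), c(2, 2, 2))
  lhs <- extract_tac(dynamic_image(3 * a1 - 2 * a2, 2, sched), mask)$value
  rhs <- 3 * extract_tac(dynamic_image(a1, 2, sched), mask)$value -
    2 * extract_tac(dynamic_image(a2, 2, sched), mask)$value
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("Gaussian smoothing reproduces the analytic kernel", {
  vox <- 2; fwhm <- 6
  sig <- fwhm / (2 * sqrt(2 * log(2))) / vox
  a <- array(0, c(33, 33, 33)); a[17, 17, 17] <- 1
  img <- static_image(a, vox)

  expect_identical(smooth_gaussian(img, 0)$voxels, a)

  sm <- smooth_gaussian(img, fwhm)
  expect_equal(sum(sm$voxels), 1, tolerance = 1e-6)

  k <- seq(-16, 16)
  taps <- pnorm((k + 0.5) / sig) - pnorm((k - 0.5) / sig)
  oracle <- array(outer(outer(taps, taps), taps), c(33, 33, 33))
  expect_lt(max(abs(sm$voxels - oracle)), 1e-6)

  expect_error(smooth_gaussian(img, -1), "nonnegative")
})

test_that("smoothing commutes with translation for interior deltas", {
  a <- array(0, c(24, 24, 24)); a[10, 12, 11] <- 1
  b <- array(0, c(24, 24, 24)); b[13, 12, 11] <- 1
  sa <- smooth_gaussian(static_image(a, 2), 5)$voxels
  sb <- smooth_gaussian(static_image(b, 2), 5)$voxels
  # shift sa by +3 along x and compare on the overlap
  expect_equal(sb[4:24, , ], sa[1:21, , ], tolerance = 1e-12)
})

test_that("brain masking zeroes outside and validates", {
  img <- uniform_dynamic(c(1, 2, 3))
  all_true <- array(TRUE, c(3, 3, 3))
  expect_equal(apply_brain_mask(img, all_true)$voxels, img$voxels)
  expect_error(apply_brain_mask(img, array(FALSE, c(3, 3, 3))),
               "empty brain mask")
  half <- array(FALSE, c(3, 3, 3)); half[1:2, , ] <- TRUE
  out <- apply_brain_mask(img, half)
  expect_true(all(out$voxels[3, , , ] == 0))
  expect_equal(out$voxels[1:2, , , ], img$voxels[1:2, , , ])

  st <- static_image(array(1, c(3, 3, 3)), 2)
  expect_error(apply_brain_mask(st, array(TRUE, c(2, 3, 3))), "shape")
})

test_that("NIfTI and sidecar round trips are exact", {
  dir <- withr::local_tempdir()
  set.seed(21)
  sched <- frame_schedule(c(0, 10, 20), c(10, 20, 40))
  dyn <- dynamic_image(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)), 2.5, sched)
  p <- file.path(dir, "dyn.nii.gz")
  write_dynamic_image(dyn, p)
  back <- read_dynamic_image(p)
  expect_equal(back$voxels, dyn$voxels, tolerance = 0)
  expect_equal(back$schedule$start_s, sched$start_s)
  expect_equal(back$schedule$end_s, sched$end_s)
  expect_equal(back$voxel_size_mm, 2.5)

  st <- static_image(array(runif(27), c(3, 3, 3)), 4)
  ps <- file.path(dir, "st.nii.gz")
  write_static_image(st, ps)
  expect_equal(read_static_image(ps)$voxels, st$voxels, tolerance = 0)

  atl <- slab_atlas()
  write_atlas(atl, file.path(dir, "atl.nii.gz"), file.path(dir, "atl.tsv"))
  back_atl <- read_atlas(file.path(dir, "atl.nii.gz"),
                         file.path(dir, "atl.tsv"))
  expect_identical(back_atl$labels, atl$labels)
  expect_equal(back_atl$table$name, atl$table$name)
  expect_equal(back_atl$reference_label, atl$reference_label)
})
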