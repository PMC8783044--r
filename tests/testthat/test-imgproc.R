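point_source_grid <- function(d = c(9, 21, 21), vs = c(0.25, 0.1, 0.1)) {
  a <- array(0, d)
  a[5, 11, 11] <- 100
  voxel_grid(a, vs)
}

test_that("Richardson-Lucy with a near-delta PSF is an identity fixed point", {
  g <- point_source_grid()
  g$values <- g$values + 1  # strictly positive background
  out <- richardson_lucy(g, psf_model(0.01, 0.025), n_iter = 5)
  expect_equal(out$values, g$values, tolerance = 1e-6)
})

test_that("Richardson-Lucy sharpens a blurred point source and conserves intensity", {
  psf <- psf_model(0.15, 0.4)
  g <- point_source_grid()
  blurred <- voxel_grid(acquant:::blur_psf(g$values, psf, g$voxel_size),
                        g$voxel_size)
  peaks <- vapply(c(1, 5, 20), function(it)
    max(richardson_lucy(blurred, psf, it)$values), numeric(1))
  expect_true(all(diff(peaks) > 0))
  out <- richardson_lucy(blurred, psf, 20)
  expect_true(all(out$values >= 0))
  # object far from borders: total intensity conserved within 1%
  expect_equal(sum(out$values), sum(blurred$values), tolerance = 0.01)
})

test_that("Richardson-Lucy rejects negative input and warns on all-zero input", {
  bad <- voxel_grid(array(1, c(2, 2, 2)), c(1, 1, 1))
  bad$values[1] <- -1
  expect_error(richardson_lucy(bad, psf_model(0.1, 0.1)), "non-negative")
  zero <- voxel_grid(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_warning(out <- richardson_lucy(zero, psf_model(0.1, 0.1)), "all-zero")
  expect_equal(out$values, zero$values)
})

blob_frame <- function(cy, cx, d = c(40, 50)) {
  m <- matrix(0, d[1], d[2])
  ys <- pmax(1, cy - 2):pmin(d[1], cy + 2)
  xs <- pmax(1, cx - 2):pmin(d[2], cx + 2)
  m[ys, xs] <- outer(ys - cy, xs - cx, function(a, b) exp(-(a^2 + b^2) / 4))
  m
}

test_that("translation registration recovers applied integer shifts exactly", {
  f0 <- blob_frame(20, 25)
  still <- register_translation(list(f0, f0, f0))
  expect_true(all(still$shifts == 0))

  shifted <- acquant:::shift_image(f0, 3, -2)
  reg <- register_translation(list(f0, shifted))
  expect_equal(reg$shifts[2, ], c(dy = 3, dx = -2))
  expect_equal(reg$registered[[2]], f0)

  # inverse consistency in integer mode
  fwd <- register_translation(list(f0, shifted))$shifts[2, ]
  bwd <- register_translation(list(shifted, f0))$shifts[2, ]
  expect_equal(fwd, -bwd)
})

test_that("registration guards: half-frame shifts rejected, constant frames warned", {
  f0 <- blob_frame(20, 25)
  far <- f0[c(21:40, 1:20), ]  # circular shift by exactly half the frame
  expect_error(register_translation(list(f0, far)), "ambiguous")
  expect_warning(register_translation(list(matrix(1, 4, 4), matrix(1, 4, 4))),
                 "constant frame")
})

test_that("projections collapse correctly, conserve sums and are idempotent on 2D", {
  a <- array(runif(3 * 4 * 5), c(3, 4, 5))
  expect_equal(sum(sum_project(a, "z")), sum(a))
  expect_equal(dim(max_project(a, "z")), c(4, 5))
  single <- array(runif(1 * 4 * 5), c(1, 4, 5))
  expect_equal(max_project(single, "z"), single[1, , ])
  # disjoint spots in different slices both survive the MIP
  two <- array(0, c(2, 6, 6)); two[1, 2, 2] <- 5; two[2, 5, 5] <- 7
  mp <- max_project(two, "z")
  expect_equal(mp[2, 2], 5); expect_equal(mp[5, 5], 7)
  m <- matrix(runif(12), 3)
  expect_identical(max_project(m), m)
})

test_that("peak-centred cropping pads, centres and breaks ties row-major", {
  img <- matrix(0, 10, 10); img[1, 1] <- 3
  cr <- center_crop_on_peak(img, 9, 9)
  expect_equal(dim(cr), c(9, 9))
  expect_equal(cr[5, 5], 3)           # centre pixel (floor(9/2)+1 = 5)
  expect_equal(sum(cr), 3)            # everything else zero-padded
  tie <- matrix(0, 6, 6); tie[4, 2] <- 1; tie[2, 5] <- 1
  tie[2, 6] <- 0.5  # marker pixel right of the row-major-first maximum
  cr2 <- center_crop_on_peak(tie, 5, 5)
  expect_equal(cr2[3, 3], 1)
  expect_equal(cr2[3, 4], 0.5)  # (2,5) was centred, not (4,2)
  # the default crop is the field-standard 90 x 144 window
  expect_equal(dim(center_crop_on_peak(blob_frame(20, 25))), c(90, 144))
})

test_that("binarize thresholds relative to the maximum and guards degenerate input", {
  img <- matrix(runif(100, 0, 1000), 10); img[1] <- 1000
  mask <- binarize(img, level = 0.05)
  expect_identical(mask, img >= 50)
  expect_warning(empty <- binarize(matrix(0, 4, 4)), "all-zero")
  expect_false(any(empty))
  expect_error(binarize(matrix(1, 4, 4), mode = "otsu-per-frame"),
               "no bimodality")
  # otsu on a bimodal frame separates the modes
  bi <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  expect_identical(binarize(bi, mode = "otsu-per-frame"), bi > 100)
})
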