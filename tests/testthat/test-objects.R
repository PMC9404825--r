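test_that("gaussian smoothing preserves constants, mass, and the delta limit", {
  const <- matrix(0.42, 9, 9)
  expect_equal(smooth_gaussian(const, 2), const, tolerance = 1e-12)

  img <- matrix(0, 9, 9); img[5, 5] <- 1
  sm <- smooth_gaussian(img, 0.5)
  expect_equal(sum(sm), 1, tolerance = 1e-6)   # kernel support stays interior
  expect_equal(sm, oracle_gaussian(img, 0.5), tolerance = 1e-9)

  set.seed(91)
  r <- matrix(runif(81), 9, 9)
  expect_equal(smooth_gaussian(r, 1e-3), r, tolerance = 1e-6)
  expect_error(smooth_gaussian(r, 0), class = "fq_parameter_error")
})

test_that("smoothing is mask-aware: invalid pixels contribute nothing", {
  set.seed(101)
  a <- matrix(runif(100), 10, 10)
  b <- a
  v <- matrix(runif(100) > 0.3, 10, 10)
  b[!v] <- runif(sum(!v))           # perturb only invalid pixels
  sa <- smooth_gaussian(a, 1.2, v)
  sb <- smooth_gaussian(b, 1.2, v)
  expect_equal(sa[v], sb[v], tolerance = 1e-12)
  expect_true(all(sa[!v] == 0))
})

test_that("otsu threshold separates a two-level image and matches the exhaustive oracle", {
  vals <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  spec <- threshold_spec("otsu")
  t <- compute_threshold(vals, spec)
  expect_gt(t, 0.1); expect_lt(t, 0.9)
  expect_identical(t, oracle_otsu(as.vector(vals)))
})

test_that("otsu equals exhaustive intra-class-variance minimization on random images", {
  set.seed(111)
  spec <- threshold_spec("otsu")
  for (rep in 1:40) {
    img <- matrix(runif(64), 8, 8)
    if (rep %% 3 == 0) img <- matrix(sample(c(0.2, 0.5, 0.8), 64, TRUE) + runif(64, 0, 0.05), 8, 8)
    expect_identical(compute_threshold(img, spec), oracle_otsu(as.vector(img)))
  }
})

test_that("threshold spec applies correction factor then clamps", {
  img <- matrix(runif(16), 4, 4)
  expect_equal(compute_threshold(img, threshold_spec("fixed", fixed_value = 0.4)), 0.4)
  expect_equal(compute_threshold(img, threshold_spec("fixed", correction_factor = 2,
                                                     upper_bound = 0.5, fixed_value = 0.30)), 0.5)
  expect_equal(compute_threshold(img, threshold_spec("fixed", correction_factor = 0.1,
                                                     lower_bound = 0.25, fixed_value = 0.30)), 0.25)
  expect_error(threshold_spec("otsu", correction_factor = 0), class = "fq_parameter_error")
})

test_that("degenerate and empty threshold inputs follow the contract", {
  const <- matrix(0.37, 5, 5)
  expect_equal(compute_threshold(const, threshold_spec("otsu")), 0.37)
  none <- matrix(FALSE, 5, 5)
  expect_error(compute_threshold(const, threshold_spec("otsu"), none),
               class = "fq_empty_input_error")
})

test_that("invalid pixels never influence the computed threshold", {
  set.seed(121)
  img <- matrix(runif(100), 10, 10)
  v <- matrix(runif(100) > 0.4, 10, 10)
  img2 <- img
  img2[!v] <- runif(sum(!v))
  spec <- threshold_spec("otsu")
  expect_identical(compute_threshold(img, spec, v), compute_threshold(img2, spec, v))
})

test_that("apply_threshold is the strict pixelwise comparison on valid pixels", {
  set.seed(131)
  img <- matrix(runif(48), 6, 8)
  expect_false(any(apply_threshold(img, 1)))
  expect_true(all(apply_threshold(pmax(img, 0.01), 0)))
  v <- matrix(runif(48) > 0.3, 6, 8)
  got <- apply_threshold(img, 0.5, v)
  expect_identical(got, (img > 0.5) & v)
})

test_that("connectivity 4 vs 8 distinguishes diagonal touching", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(n_objects(label_components(m, 4)), 2)
  expect_equal(n_objects(label_components(m, 8)), 1)
  expect_equal(n_objects(label_components(matrix(FALSE, 4, 4), 8)), 0)
})

test_that("labeling matches brute-force flood fill on random masks", {
  set.seed(141)
  for (rep in 1:25) {
    m <- matrix(runif(256) > runif(1, 0.3, 0.7), 16, 16)
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      want <- oracle_flood_fill(m, conn)
      expect_identical(unclass(got)[, ], want[, ])
      expect_equal(n_objects(got), attr(want, "n_objects"))
    }
  }
})

test_that("object measurements report area, centroid and equivalent diameter", {
  lab <- matrix(0L, 6, 6); lab[2:4, 2:4] <- 1L
  m <- measure_objects(lab)
  expect_equal(m$area, 9)
  expect_equal(m$equiv_diameter, 2 * sqrt(9 / pi))
  expect_equal(m$centroid_x, 2.5)  # cols 2:4, 0-based centers 1.5, 2.5, 3.5
  expect_equal(m$centroid_y, 2.5)
  expect_equal(nrow(measure_objects(matrix(0L, 3, 3))), 0)
  set.seed(151)
  lab2 <- label_components(matrix(runif(144) > 0.5, 12, 12), 8)
  m2 <- measure_objects(lab2)
  for (i in seq_len(nrow(m2))) {
    expect_equal(m2$area[i], sum(lab2 == m2$label[i]))
  }
  expect_equal(sum(m2$area), sum(lab2 > 0))
})

test_that("identify_primary_objects finds disks inside the diameter filter", {
  img <- matrix(0, 48, 64)
  centers <- list(c(12, 12), c(12, 40), c(36, 24))
  for (cc in centers) img[disk_mask(48, 64, cc[2], cc[1], 12)] <- 0.9
  filt <- object_filter(8, 20, 8)
  spec <- threshold_spec("otsu")
  lab <- identify_primary_objects(img, filt, spec)
  expect_equal(n_objects(lab), 3)

  blank <- matrix(0, 16, 16)
  expect_equal(n_objects(identify_primary_objects(blank, filt, spec)), 0)

  small <- matrix(0, 20, 20); small[disk_mask(20, 20, 10, 10, 4)] <- 0.9
  expect_equal(n_objects(identify_primary_objects(small, object_filter(8, 20), spec)), 0)
})

test_that("diameter filtering is monotone and the border policy is honoured", {
  set.seed(161)
  img <- matrix(0, 32, 32)
  img[disk_mask(32, 32, 8, 8, 9)] <- 0.8
  img[disk_mask(32, 32, 20, 20, 13)] <- 0.8
  img[1:3, 15:18] <- 0.8                        # border-touching block
  spec <- threshold_spec("fixed", fixed_value = 0.5)
  narrow <- n_objects(identify_primary_objects(img, object_filter(6, 12), spec))
  wide <- n_objects(identify_primary_objects(img, object_filter(2, 40), spec))
  expect_lte(narrow, wide)
  with_border <- identify_primary_objects(img, object_filter(2, 40, keep_border = TRUE), spec)
  no_border <- identify_primary_objects(img, object_filter(2, 40, keep_border = FALSE), spec)
  expect_equal(n_objects(with_border), 3)
  expect_equal(n_objects(no_border), 2)
})

test_that("identify_primary_objects is idempotent on its own binary rendering", {
  set.seed(171)
  img <- matrix(runif(40 * 40, 0, 0.3), 40, 40)
  img[disk_mask(40, 40, 12, 12, 10)] <- 0.9
  img[disk_mask(40, 40, 30, 25, 14)] <- 0.95
  filt <- object_filter(6, 30, 8)
  spec <- threshold_spec("otsu")
  lab1 <- identify_primary_objects(img, filt, spec)
  rendering <- objects_to_mask(lab1) * 1
  lab2 <- identify_primary_objects(rendering, filt, threshold_spec("fixed", fixed_value = 0.5))
  expect_equal(n_objects(lab2), n_objects(lab1))
})

test_that("objects_to_mask feeds mask_image to zero exactly the labeled pixels", {
  lab <- matrix(0L, 5, 5); lab[2, 2:4] <- 1L; lab[4, 1:2] <- 2L
  msk <- objects_to_mask(lab)
  expect_equal(sum(msk), 5)
  set.seed(181)
  g <- matrix(runif(25), 5, 5)
  m <- mask_image(g, msk, invert_mask = TRUE)
  expect_true(all(m$image[lab > 0] == 0))
  expect_equal(m$image[lab == 0], g[lab == 0])
})
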