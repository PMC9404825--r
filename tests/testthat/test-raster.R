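test_that("write/read round trip on lossless PNG preserves pixels to 8-bit quantization", {
  set.seed(11)
  for (rep in 1:5) {
    img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
    p <- withr::local_tempfile(fileext = ".png")
    write_image(img, p)
    back <- read_image(p)
    expect_equal(dim(back), c(8, 8, 3))
    expect_lt(max(abs(back - img)), 1 / 255)
  }
})

test_that("bit depths normalize to [0,1] and gray/alpha inputs become 3-channel", {
  p <- withr::local_tempfile(fileext = ".png")
  write_image(array(1, dim = c(1, 1, 3)), p)
  expect_equal(as.numeric(read_image(p)), c(1, 1, 1))

  p16 <- withr::local_tempfile(fileext = ".tif")
  e <- EBImage::Image(array(c(1, 0, 0), dim = c(1, 1, 3)), colormode = "Color")
  EBImage::writeImage(e, p16, bits.per.sample = 16L)
  expect_equal(as.numeric(read_image(p16)), c(1, 0, 0), tolerance = 1e-4)

  pg <- withr::local_tempfile(fileext = ".png")
  g <- matrix(seq(0, 1, length.out = 12), 3, 4)
  write_image(g, pg)
  back <- read_image(pg)
  expect_equal(back[, , 1], back[, , 2])
  expect_equal(back[, , 1], back[, , 3])
  expect_lt(max(abs(back[, , 1] - g)), 1 / 255)
})

test_that("unreadable paths raise I/O errors naming the path", {
  expect_error(read_image("no/such/file.png"), "no/such/file.png", class = "fq_io_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(read_image(bad), class = "fq_io_error")
})

test_that("color_to_gray is the weighted channel sum", {
  img <- array(0.5, dim = c(4, 4, 3))
  expect_equal(color_to_gray(img, c(0.2, 0.3, 0.5)), matrix(0.5, 4, 4))
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(color_to_gray(red, c(1, 0, 0)), matrix(1, 2, 2))
  set.seed(21)
  img <- array(runif(2 * 3 * 3), dim = c(2, 3, 3))
  w <- c(0.2, 0.7, 0.1)
  manual <- matrix(0, 2, 3)
  for (i in 1:2) for (j in 1:3) manual[i, j] <- sum(img[i, j, ] * w)
  expect_equal(color_to_gray(img, w), manual, tolerance = 1e-12)
  expect_error(color_to_gray(img, c(-0.1, 0.6, 0.5)), class = "fq_parameter_error")
})

test_that("image_math implements invert/arithmetic with clamping", {
  set.seed(31)
  a <- matrix(runif(20), 4, 5)
  expect_equal(image_math("invert", image_math("invert", a)), a)
  expect_equal(image_math("invert", matrix(0.3, 2, 2)), matrix(0.7, 2, 2))
  expect_equal(image_math("add", matrix(0.8, 2, 2), 0.5), matrix(1, 2, 2))
  expect_equal(image_math("add", matrix(0.8, 2, 2), 0.5, clamp = FALSE), matrix(1.3, 2, 2))
  # add/subtract invert each other where no clamping occurs
  b <- matrix(runif(20, 0, 0.4), 4, 5)
  a2 <- matrix(runif(20, 0, 0.5), 4, 5)
  expect_equal(image_math("subtract", image_math("add", a2, b), b), a2, tolerance = 1e-12)
  z <- image_math("divide", a, matrix(0, 4, 5))
  expect_true(all(z == 0))
  expect_error(image_math("add", a, matrix(0, 2, 2)), class = "fq_shape_error")
})

test_that("mask_image zeroes deselected pixels and composes validities", {
  set.seed(41)
  img <- array(runif(6 * 5 * 3), dim = c(6, 5, 3))
  all_true <- matrix(TRUE, 6, 5)
  m <- mask_image(img, all_true)
  expect_equal(m$image, img)
  expect_true(all(m$validity))

  m0 <- mask_image(img, !all_true)
  expect_true(all(m0$image == 0))
  expect_false(any(m0$validity))

  mask <- matrix(runif(30) > 0.5, 6, 5)
  m1 <- mask_image(img, mask, invert_mask = TRUE)
  for (i in 1:6) for (j in 1:5) {
    if (mask[i, j]) expect_equal(as.numeric(m1$image[i, j, ]), c(0, 0, 0))
    else            expect_equal(m1$image[i, j, ], img[i, j, ])
  }
  expect_equal(m1$validity, !mask)

  # composing two maskings equals masking with the AND of the masks
  g <- matrix(runif(30), 6, 5)
  m_a <- matrix(runif(30) > 0.4, 6, 5)
  m_b <- matrix(runif(30) > 0.4, 6, 5)
  step <- mask_image(g, m_a)
  step <- mask_image(step$image, m_b, validity = step$validity)
  once <- mask_image(g, m_a & m_b)
  expect_equal(step$image, once$image)
  expect_equal(step$validity, once$validity)
  expect_error(mask_image(g, matrix(TRUE, 2, 2)), class = "fq_shape_error")
})

test_that("rasterize_rois selects pixels whose centers fall inside polygons", {
  expect_equal(rasterize_rois(roi_set(), 4, 4), matrix(FALSE, 4, 4))
  rect <- roi_set(list(cbind(c(0.5, 4.5, 4.5, 0.5), c(0.5, 0.5, 2.5, 2.5))))
  m <- rasterize_rois(rect, 10, 10)
  expect_equal(sum(m), 8)
  expect_true(all(m[1:2, 1:4]))
  full <- roi_set(list(cbind(c(-1, 20, 20, -1), c(-1, -1, 20, 20))))
  expect_true(all(rasterize_rois(full, 10, 10)))
  expect_error(roi_set(list(cbind(c(0, 1), c(0, 1)))), class = "fq_format_error")
})

test_that("rasterization agrees with the per-pixel-center point-in-polygon oracle", {
  set.seed(51)
  for (rep in 1:8) {
    H <- sample(4:32, 1); W <- sample(4:32, 1)
    nv <- sample(3:7, 1)
    poly <- cbind(runif(nv, -2, W + 2), runif(nv, -2, H + 2))
    got <- rasterize_rois(roi_set(list(poly)), H, W)
    want <- matrix(FALSE, H, W)
    for (r in 1:H) for (cc in 1:W) {
      want[r, cc] <- oracle_point_in_polygon(cc - 0.5, r - 0.5, poly)
    }
    expect_identical(got, want)
  }
})

test_that("ROI YAML files round-trip into roi_set objects", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "rois:",
    "  - name: glom_1",
    "    vertices: [[1.0, 2.0], [5.0, 2.0], [3.0, 6.0]]",
    "  - name: vessel",
    "    vertices: [[0, 0], [4, 0], [4, 4], [0, 4]]"
  ), p)
  rs <- read_roi_file(p)
  expect_length(rs$polygons, 2)
  expect_equal(names(rs$polygons), c("glom_1", "vessel"))
  expect_equal(rs$polygons[[1]][, "x"], c(1, 5, 3))
  expect_equal(rs$polygons[[2]][3, ], c(x = 4, y = 4))
})
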