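test_that("lesion cropping masks and validates", {
  img <- en_face_image(matrix(runif(64 * 64, 0, 255), 64, 64))
  full <- matrix(TRUE, 64, 64)
  cr <- crop_lesion(img, full)
  expect_identical(octaquant:::pixels_of(cr), octaquant:::pixels_of(img))
  expect_error(crop_lesion(img, matrix(TRUE, 64, 32)), "shape")
  expect_error(crop_lesion(img, matrix(FALSE, 64, 64)), "empty")
  expect_error(crop_lesion(img, full & (row(full) == 1 & col(full) <= 10)), "floor")
  disc <- (row(full) - 32)^2 + (col(full) - 32)^2 <= 25
  crd <- crop_lesion(img, disc, min_area = 10)
  expect_true(all(is.na(unclass(crd)[!disc])))
  expect_false(anyNA(unclass(crd)[disc]))
})

test_that("the ROI pixel count drives the vessel-density denominator", {
  mask <- matrix(FALSE, 32, 32)
  mask[sample.int(1024, 50)] <- TRUE
  binary <- mask & (row(mask) %% 2 == 0)
  expect_equal(vessel_density(binary, mask), 100 * sum(binary) / 50)
})

test_that("global Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(11)
  for (i in 1:40) {
    x <- c(
      round(rnorm(400, runif(1, 40, 100), runif(1, 4, 30))),
      round(rnorm(400, runif(1, 120, 220), runif(1, 4, 40)))
    )
    counts <- tabulate(pmin(pmax(x, 0), 255) + 1, 256)
    expect_identical(octaquant:::otsu_from_counts(counts), otsu_oracle(counts))
  }
})

test_that("a perfectly separable two-valued image is recovered exactly", {
  px <- matrix(10, 50, 50)
  px[20:30, 20:30] <- 50
  img <- en_face_image(px)
  for (mode in c("global", "local")) {
    b <- binarize_otsu(img, mode = mode)
    expect_true(all((b > 0) == (px == 50)))
  }
})

test_that("VD and VLD are invariant under monotone grey remapping", {
  px <- matrix(20, 48, 48)
  px[10:20, 10:40] <- 90
  remap <- function(v) 255 * (v / 255)^0.4 # monotone gamma curve
  b1 <- binarize_otsu(en_face_image(px), mode = "global")
  b2 <- binarize_otsu(en_face_image(remap(px)), mode = "global")
  roi <- matrix(TRUE, 48, 48)
  expect_equal(vessel_density(b1, roi), vessel_density(b2, roi))
  expect_equal(
    vessel_length_density(skeletonize_vessels(b1), roi),
    vessel_length_density(skeletonize_vessels(b2), roi)
  )
})

test_that("a constant ROI binarises to an all-zero map with a warning", {
  img <- en_face_image(matrix(99, 40, 40))
  for (mode in c("global", "local")) {
    expect_warning(b <- binarize_otsu(img, mode = mode), "constant")
    expect_false(any(b))
  }
})

test_that("window parameter is validated", {
  img <- en_face_image(matrix(runif(100, 0, 255), 10, 10))
  expect_error(binarize_otsu(img, mode = "local", window = 4), "odd")
  expect_error(binarize_otsu(img, mode = "local", window = 1), "odd")
})

test_that("local and global Otsu agree on a uniformly illuminated phantom", {
  p <- small_scene(seed = 9, speckle_shape = Inf, additive_sigma = 0, jitter_sigma = 0)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  cr <- crop_lesion(f, tr$lesion_mask)
  bg <- binarize_otsu(cr, roi = tr$lesion_mask, mode = "global")
  bl <- binarize_otsu(cr, roi = tr$lesion_mask, mode = "local")
  agree <- mean((bg == bl)[tr$lesion_mask])
  expect_gte(agree, 0.95)
})

test_that("thinning preserves already-thin structures and empty maps", {
  line <- matrix(FALSE, 10, 60)
  line[5, 10:50] <- TRUE
  expect_identical(octaquant:::thin_mask(line), line)
  empty <- matrix(FALSE, 8, 8)
  expect_identical(octaquant:::thin_mask(empty), empty)
  dot <- matrix(FALSE, 8, 8)
  dot[4, 4] <- TRUE
  expect_identical(octaquant:::thin_mask(dot), dot)
})

test_that("a filled rectangle thins to a 1-px curve no longer than its length", {
  rect <- matrix(FALSE, 30, 40)
  rect[10:14, 10:30] <- TRUE
  sk <- skeletonize_vessels(rect)
  expect_true(all(!sk | rect))
  expect_lte(sum(sk), 21)
  expect_gte(sum(sk), 15)
})

test_that("thinning is complete: no removable simple pixel remains", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(48 * 48) < 0.4, 48, 48)
    sk <- octaquant:::thin_mask(m)
    expect_identical(octaquant:::thin_mask(sk), sk)
  }
})

test_that("skeletonisation preserves the subset chain and component count", {
  for (s in 1:5) {
    p <- small_scene(seed = 30 + s)
    tr <- generate_truth(p)
    f <- render_frame(tr, p, 0)
    cr <- crop_lesion(f, tr$lesion_mask)
    b <- binarize_otsu(cr, roi = tr$lesion_mask, mode = "local")
    sk <- skeletonize_vessels(b)
    expect_false(any(sk & !b)) # skeleton within binary
    expect_false(any(b & !tr$lesion_mask)) # binary within ROI
    expect_identical(
      octaquant:::count_components8(sk),
      octaquant:::count_components8(b)
    )
  }
})
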