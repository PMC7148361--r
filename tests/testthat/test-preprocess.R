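test_that("identical frames register with zero shift", {
  p <- small_scene(seed = 1)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  reg <- register_frames(list(f, f, f))
  expect_true(all(abs(attr(reg, "shifts")) < 1e-6))
  expect_identical(unclass(reg[[2]]), unclass(f))
})

test_that("a known integer shift is recovered exactly", {
  p <- small_scene(seed = 2)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  shifted <- en_face_image(roll_matrix(unclass(f), 3, -2))
  d <- octaquant:::estimate_shift(f, shifted)
  expect_equal(d, c(-3, 2), tolerance = 0.05)
  # and registration undoes it (away from wrap-around borders)
  reg <- register_frames(list(f, shifted))
  inner <- 10:86
  expect_lt(
    mean(abs(unclass(reg[[2]])[inner, inner] - unclass(f)[inner, inner])),
    1.0
  )
})

test_that("fractional shifts are recovered to sub-pixel precision", {
  p <- small_scene(seed = 3, jitter_sigma = 0)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  shifted <- en_face_image(octaquant:::shift_image(unclass(f), 1.4, -0.7))
  d <- octaquant:::estimate_shift(f, shifted)
  expect_lt(max(abs(d - c(-1.4, 0.7))), 0.5)
})

test_that("implausibly large shifts are rejected with a warning", {
  p <- small_scene(seed = 4)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  far <- en_face_image(roll_matrix(unclass(f), 30, 0))
  expect_warning(d <- octaquant:::estimate_shift(f, far, max_shift = 10), "max_shift")
  expect_identical(d, c(0, 0))
})

test_that("registration refuses mismatched dimensions and tiny stacks", {
  f1 <- en_face_image(matrix(0, 32, 32))
  f2 <- en_face_image(matrix(0, 32, 48))
  expect_error(register_frames(list(f1, f2)), "identical dimensions")
  expect_error(register_frames(list(f1)), "at least 2")
})

test_that("registering already-registered frames is idempotent", {
  p <- scene_params(rng_seed = 3)
  tr <- generate_truth(p)
  fr <- render_sequence(tr, p)
  reg <- register_frames(fr)
  reg2 <- register_frames(reg)
  expect_lt(max(abs(attr(reg2, "shifts"))), 0.25)
})

test_that("frame averaging has the stated algebra", {
  p <- small_scene(seed = 5)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  one <- average_frames(list(f))
  expect_equal(unclass(one), unclass(f), ignore_attr = TRUE)
  inv <- en_face_image(255 - unclass(f))
  sym <- average_frames(list(f, inv))
  expect_true(all(unclass(sym) == 127.5))
  expect_match(attr(sym, "provenance"), "averaged\\(2\\)")
  expect_error(average_frames(list()), "empty")
})

test_that("flat-region variance of an n-frame average scales like 1/n", {
  # 20 flat scenes here; the full 100-scene calibration runs with the
  # acceptance suite
  ratios <- vapply(1:20, function(s) {
    p <- scene_params(
      image_size = 64, lesion_radius = 12, rim_width = 4,
      n_seed_vessels = 0, jitter_sigma = 0, background_level = 60,
      rng_seed = 100 + s
    )
    tr <- generate_truth(p)
    fr <- render_sequence(tr, p)
    flat <- tr$intensity_truth == 60 & !tr$lesion_mask
    pf <- mean(vapply(fr, function(f) stats::var(unclass(f)[flat]), numeric(1)))
    av <- average_frames(fr)
    stats::var(unclass(av)[flat]) / pf
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / 10), 0.15 / 10)
})

test_that("expected flat-region variance is non-increasing in frame count", {
  vars <- matrix(NA_real_, 30, 4)
  for (s in 1:30) {
    p <- scene_params(
      image_size = 64, lesion_radius = 12, rim_width = 4,
      n_seed_vessels = 0, jitter_sigma = 0, background_level = 60,
      rng_seed = 200 + s
    )
    tr <- generate_truth(p)
    fr <- render_sequence(tr, p)
    flat <- tr$intensity_truth == 60 & !tr$lesion_mask
    for (j in seq_along(c(1, 2, 5, 10))) {
      n <- c(1, 2, 5, 10)[j]
      av <- average_frames(fr[seq_len(n)])
      vars[s, j] <- stats::var(unclass(av)[flat])
    }
  }
  expect_true(all(diff(colMeans(vars)) < 0))
})

test_that("denoisers leave degenerate inputs alone", {
  flat <- en_face_image(matrix(37, 48, 48))
  expect_true(all(unclass(denoise_frame(flat, "median")) == 37))
  p <- small_scene(seed = 6)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  g0 <- denoise_frame(f, "gaussian", strength = list(sigma = 0))
  expect_identical(octaquant:::pixels_of(g0), octaquant:::pixels_of(f))
})

test_that("denoisers reduce flat-region variance and keep dimensions", {
  p <- small_scene(seed = 7)
  tr <- generate_truth(p)
  f <- render_frame(tr, p, 0)
  flat <- tr$background_mask
  v0 <- stats::var(unclass(f)[flat])
  for (m in c("median", "gaussian", "nonlocal_means")) {
    d <- denoise_frame(f, m)
    expect_identical(dim(d), dim(f))
    expect_identical(attr(d, "provenance"), "denoised")
    expect_lt(stats::var(unclass(d)[flat]), v0)
  }
})

test_that("unknown denoise methods fail with the list of valid ones", {
  f <- en_face_image(matrix(0, 32, 32))
  expect_error(denoise_frame(f, "wavelet"), "median, gaussian, nonlocal_means")
})
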