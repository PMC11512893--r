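test_that("padding adds a fill ring and leaves the interior untouched", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(pad_image(img, 0), img)
  p <- pad_image(img, 4, fill = 1)
  expect_equal(dim(p), c(16, 16))
  expect_equal(p[5:12, 5:12], img)
  ring <- p; ring[5:12, 5:12] <- NA
  expect_true(all(ring[!is.na(ring)] == 1))
  expect_error(pad_image(img, -1), class = "spinalzfnet_argument_error")
})

test_that("right-angle rotations are exact permutations", {
  set.seed(3)
  img <- matrix(runif(64^2), 64, 64)
  expect_equal(rotate_image(rotate_image(img, 180), 180), img)
  expect_equal(sum(rotate_image(img, 90)), sum(img))
  r <- img
  for (k in 1:4) r <- rotate_image(r, 90)
  expect_equal(r, img)
})

test_that("rotating a centred disk changes it only by interpolation error", {
  # radially symmetric with a smooth rim, so the exact rotation is the
  # identity and any residual is bilinear interpolation error
  # background 0 so out-of-frame fill matches the profile's tail
  rad <- outer(1:65, 1:65, function(i, j) sqrt((i - 33)^2 + (j - 33)^2))
  disk <- 0.8 / (1 + exp((rad - 18) / 3))
  for (ang in c(30, 117, 245)) {
    r <- rotate_image(disk, ang, fill = 0)
    expect_lt(max(abs(r - disk)), 0.05)
  }
  expect_error(rotate_image(disk, 0), class = "spinalzfnet_argument_error")
  expect_error(rotate_image(disk, 360), class = "spinalzfnet_argument_error")
})

test_that("translation shifts content, fills vacated strips, and inverts", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(translate_image(img, c(0, 0)), img)
  t1 <- translate_image(img, c(3, 0), fill = 1)
  expect_true(all(t1[, 1:3] == 1))
  expect_equal(t1[, 4:10], img[, 1:7])
  # an image whose 3-px right margin is fill shifts right then back intact
  img2 <- img; img2[, 8:10] <- 1
  back <- translate_image(translate_image(img2, c(3, 0), fill = 1),
                          c(-3, 0), fill = 1)
  expect_equal(back, img2)
  expect_error(translate_image(img, c(10, 0)),
               class = "spinalzfnet_argument_error")
})

test_that("dataset augmentation multiplies counts, keeps labels, is seeded", {
  samples <- noisy_phantoms()[1:4]
  expect_identical(augment_dataset(samples, 1), samples)
  aug <- augment_dataset(samples, 3, seed = 9)
  expect_length(aug, 12)
  labs <- vapply(aug, `[[`, "", "label")
  expect_identical(labs[5:12],
                   rep(vapply(samples, `[[`, "", "label"), each = 2))
  expect_identical(augment_dataset(samples, 3, seed = 9), aug)
  expect_false(identical(augment_dataset(samples, 3, seed = 10), aug))
  # transformed copies stay aligned with their transformed masks
  for (s in aug[5:12]) {
    expect_true(all(s$image[s$kidney_mask == 0 & s$image > 0] <= 1))
    angle <- s$provenance$angle
    expect_true(angle >= 1 && angle <= 359)
  }
})
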