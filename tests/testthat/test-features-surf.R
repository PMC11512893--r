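test_that("a constant image has no interest points", {
  expect_equal(nrow(detect_surf(matrix(0.5, 64, 64))), 0)
})

test_that("a Gaussian blob is detected near the smoothed-Hessian maximum", {
  img <- blob_image(64, cx = 30, cy = 34)
  pts <- detect_surf(img)
  expect_gt(nrow(pts), 0)
  # independent oracle: dense determinant of the Gaussian-smoothed Hessian
  k <- dnorm(-8:8, sd = 2); k <- k / sum(k)
  smooth <- function(m) {
    sm <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
    t(apply(t(sm), 2, function(col) stats::filter(col, k, circular = TRUE)))
  }
  s <- smooth(img)
  dxx <- s[, c(2:64, 64)] + s[, c(1, 1:63)] - 2 * s
  dyy <- s[c(2:64, 64), ] + s[c(1, 1:63), ] - 2 * s
  dxy <- (s[c(2:64, 64), c(2:64, 64)] + s[c(1, 1:63), c(1, 1:63)] -
            s[c(2:64, 64), c(1, 1:63)] - s[c(1, 1:63), c(2:64, 64)]) / 4
  det <- dxx * dyy - dxy^2
  peak <- which(det == max(det), arr.ind = TRUE)[1, ]
  d <- sqrt((pts$y[1] - peak[1])^2 + (pts$x[1] - peak[2])^2)
  expect_lt(d, 3)
})

test_that("the keypoint cap and minimum image size are enforced", {
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  pts <- detect_surf(img, hessian_threshold = 1e-6, max_points = 5)
  expect_lte(nrow(pts), 5)
  expect_error(detect_surf(matrix(0.5, 16, 16)),
               class = "spinalzfnet_argument_error")
})

test_that("descriptors are 64-long unit vectors, 320 values for five points", {
  set.seed(9)
  img <- pmin(pmax(blob_image(64, 30, 34) + blob_image(64, 44, 20, s2 = 4, amp = 0.4) +
                     matrix(runif(64 * 64, 0, 0.1), 64, 64) - 0.1, 0), 1)
  pts <- detect_surf(img, hessian_threshold = 1e-6, max_points = 5)
  d <- suppressWarnings(describe_surf(img, pts))
  expect_equal(ncol(d$descriptors), 64)
  norms <- sqrt(rowSums(d$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  # five keypoints at 64 values each fill the 320-slot block
  expect_length(surf_features(img), 320)
})

test_that("descriptors are invariant to a contrast scaling of the image", {
  set.seed(9)
  img <- pmin(pmax(blob_image(64, 30, 34) +
                     matrix(runif(64 * 64, 0, 0.08), 64, 64) - 0.08, 0), 1)
  pts <- detect_surf(img, max_points = 5)
  d1 <- suppressWarnings(describe_surf(img, pts))
  d2 <- suppressWarnings(describe_surf(img * 0.5, pts))
  expect_equal(d1$descriptors, d2$descriptors, tolerance = 1e-6)
})

test_that("points whose window leaves the image are skipped with a warning", {
  img <- blob_image(64, 30, 34)
  pts <- data.frame(x = 2, y = 2, scale = 2, response = 1)
  expect_warning(d <- describe_surf(img, pts), "skipped")
  expect_equal(nrow(d$descriptors), 0)
})
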