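test_that("the shape block has five descriptors with sane disk values", {
  disk <- disk_mask(64, r = 20)
  h <- shape_features(disk)
  expect_length(h, 5)
  expect_named(h, c("area", "perimeter", "major_axis", "minor_axis", "solidity"))
  expect_equal(unname(h["area"]), sum(disk))
  expect_equal(unname(h["solidity"]), 1, tolerance = 0.02)   # disks are convex
  expect_equal(unname(h["perimeter"]), 2 * pi * 20, tolerance = 0.1 * 2 * pi * 20)
  expect_equal(unname(h["major_axis"]), 40, tolerance = 2)
  expect_error(shape_features(matrix(0, 8, 8)),
               class = "spinalzfnet_argument_error")
})

test_that("axis lengths match a covariance-eigenvalue oracle on an ellipse", {
  m <- ellipse_mask_fx(64, a = 20, b = 10)
  h <- shape_features(m)
  idx <- which(m == 1, arr.ind = TRUE)
  ev <- eigen(cov(idx) * (nrow(idx) - 1) / nrow(idx), only.values = TRUE)$values
  expect_equal(unname(h["major_axis"]), 4 * sqrt(ev[1] + 1 / 12), tolerance = 1e-6)
  expect_equal(unname(h["minor_axis"]), 4 * sqrt(ev[2] + 1 / 12), tolerance = 1e-6)
  # minor/major ratio of a 20x10 ellipse is 0.5 up to discretization
  expect_equal(shape_eccentricity(m), 0.5, tolerance = 0.05)
})

test_that("the statistical block has four descriptors with exact trivial cases", {
  s <- statistical_features(matrix(0.5, 16, 16))
  expect_length(s, 4)
  expect_named(s, c("mean", "entropy", "correlation", "contrast"))
  expect_equal(unname(s["contrast"]), 0)
  expect_equal(unname(s["entropy"]), 0)    # one occupied GLCM cell
  two <- matrix(c(0.2, 0.4), 16, 16)
  expect_equal(unname(statistical_features(two)["mean"]), 0.3)
  expect_error(statistical_features(matrix(0.5, 4, 4), matrix(0, 4, 4)),
               class = "spinalzfnet_argument_error")
})

test_that("GLCM statistics match a double-loop brute-force oracle", {
  set.seed(13)
  for (rep in 1:5) {
    img <- matrix(sample(0:7, 256, replace = TRUE) / 8 + 1 / 16, 16, 16)
    g <- glcm_matrix(img, levels = 8)
    q <- pmin(floor(img * 8), 7) + 1
    ref <- matrix(0, 8, 8)
    for (i in 1:16) for (j in 1:15) {
      ref[q[i, j], q[i, j + 1]] <- ref[q[i, j], q[i, j + 1]] + 1
      ref[q[i, j + 1], q[i, j]] <- ref[q[i, j + 1], q[i, j]] + 1
    }
    ref <- ref / sum(ref)
    expect_equal(g, ref, tolerance = 1e-12, ignore_attr = TRUE)
    st <- statistical_features(img)
    ent <- 0; corr_num <- 0; contr <- 0
    mi <- 0; mj <- 0
    for (a in 1:8) for (b in 1:8) { mi <- mi + a * ref[a, b]; mj <- mj + b * ref[a, b] }
    si <- 0; sj <- 0
    for (a in 1:8) for (b in 1:8) {
      si <- si + (a - mi)^2 * ref[a, b]; sj <- sj + (b - mj)^2 * ref[a, b]
    }
    for (a in 1:8) for (b in 1:8) {
      p <- ref[a, b]
      if (p > 0) ent <- ent - p * log2(p)
      corr_num <- corr_num + (a - mi) * (b - mj) * p
      contr <- contr + abs(a - b)^2 * p
    }
    expect_equal(unname(st["entropy"]), ent, tolerance = 1e-9)
    expect_equal(unname(st["correlation"]), corr_num / sqrt(si * sj),
                 tolerance = 1e-9)
    expect_equal(unname(st["contrast"]), contr, tolerance = 1e-9)
  }
})

test_that("feature records assemble 1652 values with gap-free offsets", {
  s <- noisy_phantoms()[[1]]
  rec <- extract_record(s$image * (s$kidney_mask > 0), s$kidney_mask, s$label)
  expect_length(rec, 1652)
  expect_equal(length(rec$surf), 320)
  expect_equal(length(rec$texture), 1323)
  expect_equal(length(rec$shape), 5)
  expect_equal(length(rec$stat), 4)
  offs <- unlist(rec$offsets, use.names = FALSE)
  expect_identical(offs, 1:1652)            # partition, no gaps
  expect_length(as.numeric(rec), 1652)
})

test_that("stat blocks separate a stone phantom from a normal one", {
  samples <- clean_phantoms()
  lab <- vapply(samples, `[[`, "", "label")
  st <- function(s) statistical_features(s$image * (s$kidney_mask > 0),
                                         s$kidney_mask)
  a <- st(samples[[which(lab == "normal")[1]]])
  b <- st(samples[[which(lab == "stone")[1]]])
  expect_gt(max(abs(a - b)), 1e-3)
})
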