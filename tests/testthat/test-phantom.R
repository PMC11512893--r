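test_that("generator yields one sample per class with consistent masks", {
  samples <- generate_phantoms(phantom_spec(image_size = 64, n_per_class = 1,
                                            seed = 7))
  expect_length(samples, 4)
  expect_setequal(vapply(samples, `[[`, "", "label"),
                  c("normal", "cyst", "tumor", "stone"))
  for (s in samples) {
    expect_equal(dim(s$image), dim(s$kidney_mask))
    expect_equal(dim(s$image), dim(s$lesion_mask))
    expect_true(all(s$lesion_mask <= s$kidney_mask))  # lesion inside kidney
    expect_true(min(s$image) >= 0 && max(s$image) <= 1)
    if (s$label == "normal") expect_equal(sum(s$lesion_mask), 0)
    else expect_gt(sum(s$lesion_mask), 0)
  }
})

test_that("generation is bit-identical under a fixed spec and seed-sensitive", {
  spec <- phantom_spec(image_size = 64, n_per_class = 2, seed = 7)
  a <- generate_phantoms(spec)
  b <- generate_phantoms(spec)
  expect_identical(a, b)
  c <- generate_phantoms(phantom_spec(image_size = 64, n_per_class = 2, seed = 8))
  expect_gt(max(abs(a[[1]]$image - c[[1]]$image)), 0)
})

test_that("noise-free lesion intensities order stone > parenchyma > tumor > cyst", {
  samples <- clean_phantoms()
  lab <- vapply(samples, `[[`, "", "label")
  lesion_mean <- function(s) mean(s$image[s$lesion_mask > 0])
  parenchyma <- mean(vapply(samples[lab == "normal"], function(s)
    mean(s$image[s$kidney_mask > 0]), 0))
  stone <- mean(vapply(samples[lab == "stone"], lesion_mean, 0))
  tumor <- mean(vapply(samples[lab == "tumor"], lesion_mean, 0))
  cyst <- mean(vapply(samples[lab == "cyst"], lesion_mean, 0))
  expect_gt(stone, parenchyma)
  expect_gt(parenchyma, tumor)
  expect_gt(tumor, cyst)
})

test_that("invalid specs raise configuration errors naming the field", {
  expect_error(phantom_spec(image_size = 32), "image_size",
               class = "spinalzfnet_config_error")
  expect_error(phantom_spec(n_per_class = 0), "n_per_class")
  expect_error(phantom_spec(impulse_frac = 0.5), "impulse_frac")
  expect_error(phantom_spec(classes = c("normal", "bone")), "classes")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("datasets round-trip through disk with an intact manifest", {
  dir <- withr::local_tempdir()
  samples <- generate_phantoms(phantom_spec(image_size = 64, n_per_class = 1,
                                            seed = 3))
  manifest <- write_phantom_dataset(samples, dir)
  tab <- read.csv(manifest)
  expect_equal(nrow(tab), 4)
  expect_identical(names(tab), c("filename", "label", "mask"))
  expect_true(all(tab$label %in% c("normal", "cyst", "tumor", "stone")))
  back <- read_phantom_dataset(dir)
  for (i in seq_along(samples)) {
    # written pixels are 8-bit quantized; the reader recovers them exactly
    expect_equal(back[[i]]$image, round(samples[[i]]$image * 255) / 255,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$kidney_mask, samples[[i]]$kidney_mask + 0)
    expect_identical(back[[i]]$label, samples[[i]]$label)
  }
  expect_error(write_phantom_dataset(samples, "/proc/nope/dir"),
               class = "spinalzfnet_io_error")
})
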