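small_enet_config <- function() {
  enet_config(initial_channels = 4L, stage_channels = c(8L, 8L, 8L))
}

test_that("forward output matches input resolution with C class maps", {
  net <- build_enet(small_enet_config(), seed = 1)
  for (hw in list(c(16, 16), c(24, 32))) {
    x <- array(runif(prod(hw)), c(hw, 1, 1))
    out <- enet_forward(net, x)
    expect_equal(dim(out$val), c(hw, 2, 1))
  }
  expect_error(enet_forward(net, array(0, c(20, 20, 1, 1))),
               class = "spinalzfnet_argument_error")
})

test_that("no projection in any bottleneck carries a bias term", {
  net <- build_enet(small_enet_config(), seed = 1)
  conv_names_ok <- function(b) {
    for (nm in c("proj", "main", "main_a", "main_b", "expand", "skip"))
      if (!is.null(b[[nm]]))
        expect_named(b[[nm]], "w")   # weight only, never a bias
  }
  for (st in c("stage1", "stage2", "stage3", "stage4", "stage5"))
    lapply(net[[st]], conv_names_ok)
  expect_named(net$initial$conv, "w")
})

test_that("bottlenecks use fewer parameters than an equal-depth plain conv net", {
  cfg <- enet_config(initial_channels = 8L, stage_channels = c(16L, 32L, 32L))
  net <- build_enet(cfg, seed = 1)
  # baseline: one full 3x3 convolution (with batch norm) per bottleneck,
  # same in/out widths at every position
  plain <- 0
  for (st in c("stage1", "stage2", "stage3", "stage4", "stage5"))
    for (b in net[[st]])
      plain <- plain + 9 * b$ic * b$oc + 2 * b$oc
  enet_encoder <- sum(vapply(
    c("stage1", "stage2", "stage3", "stage4", "stage5"),
    function(st) sum(vapply(net[[st]], n_parameters, 0)), 0))
  expect_lt(enet_encoder, plain)
})

test_that("unpooling scatters values back to the argmax positions", {
  set.seed(2)
  x <- spinalzfnet:::ag_const(array(runif(16 * 16 * 2 * 1), c(16, 16, 2, 1)))
  p <- spinalzfnet:::ag_maxpool(x, 2)
  u <- spinalzfnet:::ag_maxunpool(p, p$pool_idx, p$pool_in_hw)
  # every pooled value reappears exactly at its source index
  nz <- u$val != 0
  expect_equal(sum(nz), length(p$val))
  expect_true(all(u$val[nz] == x$val[nz]))
})

test_that("brief training reduces the loss deterministically", {
  samples <- noisy_phantoms()[c(1, 4, 7, 10)]
  net <- build_enet(small_enet_config(), seed = 3)
  net <- train_segmenter(net, samples, epochs = 3, seed = 5, lr = 5e-3,
                         batch_size = 2, resolution = 32)
  expect_length(net$loss_trace, 3)
  expect_lt(net$loss_trace[3], net$loss_trace[1])
  net2 <- build_enet(small_enet_config(), seed = 3)
  net2 <- train_segmenter(net2, samples, epochs = 3, seed = 5, lr = 5e-3,
                          batch_size = 2, resolution = 32)
  expect_identical(net$loss_trace, net2$loss_trace)
  expect_error(train_segmenter(net, list()), class = "spinalzfnet_argument_error")

  seg <- segment_image(net, samples[[1]]$image)
  expect_true(all(seg$mask %in% c(0L, 1L)))
  expect_true(all(seg$masked_image[seg$mask == 0] == 0))
  iou <- mask_iou(seg$mask, samples[[1]]$kidney_mask)
  expect_gte(iou, 0); expect_lte(iou, 1)
})
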