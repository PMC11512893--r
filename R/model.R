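## The hybrid classifier: a SpinalNet branch over the flattened masked
## image, a gated fusion layer combining the handcrafted feature record
## with the SpinalNet output, and a ZFNet convolutional head over the
## fused vector lifted onto a small grid.

#' SpinalNet configuration
#'
#' @param input_dim flattened input length (default `64 * 64`).
#' @param input_split number of segments the input is cut into.
#' @param hidden_width neurons per intermediate sub-layer.  The canonical
#'   description uses two; the default widens to 32, which is wide enough
#'   to learn the phantoms (the two-neuron variant remains configurable).
#' @param out_dim dimension of the branch output C1.
#' @export
spinal_config <- function(input_dim = 4096L, input_split = 8L,
                          hidden_width = 32L, out_dim = 64L) {
  if (input_split < 2) stop_config("input_split", "must be >= 2")
  if (hidden_width < 1) stop_config("hidden_width", "must be >= 1")
  if (input_dim < input_split) stop_config("input_dim", "must be >= input_split")
  structure(list(input_dim = as.integer(input_dim),
                 input_split = as.integer(input_split),
                 hidden_width = as.integer(hidden_width),
                 out_dim = as.integer(out_dim)),
            class = "spinal_config")
}

spinal_new <- function(config) {
  seg <- ceiling(config$input_dim / config$input_split)
  hw <- config$hidden_width
  layers <- list()
  for (k in seq_len(config$input_split)) {
    nin <- if (k == 1) seg else seg + hw
    layers[[k]] <- list(w = ag_param(init_mat(nin, hw), decay = TRUE),
                        b = ag_param(numeric(hw)),
                        out = ag_param(init_mat(hw, config$out_dim), decay = TRUE))
  }
  list(config = config, seg_len = seg, layers = layers,
       out_bias = ag_param(numeric(config$out_dim)))
}

#' SpinalNet branch forward pass
#'
#' The flattened input is cut into `input_split` segments; sub-layer k
#' receives its segment concatenated with the previous sub-layer's hidden
#' output and applies an affine map plus ReLU.  Each sub-layer's hidden
#' state is projected to the output dimension and the projections are
#' summed into C1.
#'
#' @param x numeric matrix (N x input_dim) or `ag_node`; shorter rows are
#'   zero-padded to a whole number of segments.
#' @param model a structure from the internal constructor (created inside
#'   [spinalzfnet_new()]); exposed for direct use in experiments.
#' @return `ag_node` with the (N x out_dim) branch output C1.
#' @export
spinalnet_forward <- function(x, model) {
  xv <- if (inherits(x, "ag_node")) x$val else x
  cfg <- model$config
  need <- model$seg_len * cfg$input_split
  if (ncol(xv) < need)
    xv <- cbind(xv, matrix(0, nrow(xv), need - ncol(xv)))
  h <- NULL
  outs <- list()
  for (k in seq_len(cfg$input_split)) {
    segment <- ag_const(xv[, (k - 1) * model$seg_len + seq_len(model$seg_len),
                           drop = FALSE])
    inp <- if (k == 1) segment else ag_cbind(segment, h)
    h <- ag_relu(ag_linear(inp, model$layers[[k]]$w, model$layers[[k]]$b))
    outs[[k]] <- ag_matmul(h, model$layers[[k]]$out)
  }
  ag_bias_rows(ag_sum_nodes(outs), model$out_bias)
}

fusion_new <- function(record_dim, stat_dim = 4L, shape_dim = 5L,
                       fusion_dim = 64L) {
  # the full-record map is weight-decayed (it sees the high-dimensional,
  # mostly uninformative block); the 4- and 5-input maps and the gate are
  # left unregularized
  list(fusion_dim = as.integer(fusion_dim),
       Wp = ag_param(init_mat(record_dim, fusion_dim) / sqrt(record_dim / 64),
                     decay = TRUE),
       Wp1 = ag_param(init_mat(stat_dim, fusion_dim)),
       Wp2 = ag_param(init_mat(shape_dim, fusion_dim)),
       gate_w = ag_param(init_mat(3L * fusion_dim, 1L) * 0.1),
       gate_b = ag_param(0))
}

#' Gated fusion of the feature record with the SpinalNet output
#'
#' Realizes the weighted sums p (full record), p1 (statistical block) and
#' p2 (shape block) as bias-free learnable linear maps to a common fusion
#' width, gates them with `U = sigmoid(w^T [p; p1; p2] + b)` in (0, 1), and
#' combines
#' `C2 = U p + 1/2 U p1 + 1/6 (1-U) p2 + 1/24 (1-U)(2-U) C1`.
#'
#' @param H list with `full` (N x record_dim), `stat` (N x 4), `shape`
#'   (N x 5) matrices -- the feature record split into its blocks.
#' @param C1 SpinalNet output (`ag_node` or matrix, N x fusion_dim).
#' @param model fusion parameter structure (from [spinalzfnet_new()]).
#' @param force_U optionally clamp the gate to a constant in `[0, 1]`
#'   (used to exercise the coefficient algebra).
#' @return list with `C2` (`ag_node`) and `state` (numeric `p`, `p1`,
#'   `p2`, `U`, `C1`, `C2` -- the fusion intermediates).
#' @export
fusion_forward <- function(H, C1, model, force_U = NULL) {
  for (blk in c("full", "stat", "shape"))
    if (is.null(H[[blk]])) stop_arg("feature block '%s' missing", blk)
  if (!inherits(C1, "ag_node")) C1 <- ag_const(C1)
  p <- ag_matmul(ag_const(H$full), model$Wp)
  p1 <- ag_matmul(ag_const(H$stat), model$Wp1)
  p2 <- ag_matmul(ag_const(H$shape), model$Wp2)
  U <- if (is.null(force_U)) {
    z <- ag_matmul(ag_cbind(ag_cbind(p, p1), p2), model$gate_w)
    ag_sigmoid(ag_bias_rows(z, model$gate_b))
  } else {
    ag_const(matrix(force_U, nrow(H$full), 1))
  }
  one_minus <- ag_affine(U, -1, 1)          # 1 - U
  two_minus <- ag_affine(U, -1, 2)          # 2 - U
  C2 <- ag_sum_nodes(list(
    ag_rowscale(p, U),
    ag_affine(ag_rowscale(p1, U), 1 / 2),
    ag_affine(ag_rowscale(p2, one_minus), 1 / 6),
    ag_affine(ag_rowscale(C1, ag_mul(one_minus, two_minus)), 1 / 24)))
  list(C2 = C2,
       state = list(p = p$val, p1 = p1$val, p2 = p2$val,
                    U = as.numeric(U$val), C1 = C1$val, C2 = C2$val))
}

#' ZFNet head configuration
#'
#' Five 3x3 convolutions with local response normalization after the
#' first and second, 2x2 stride-2 max pooling after the first, second and
#' fifth, then fully connected layers down to the four class logits.  The
#' canonical large-image sizes are scaled to the 8x8 fused-feature grid.
#'
#' @param input_dim fused vector length fed to the learned grid lift.
#' @param grid side length of the lifted square grid.
#' @param channels five convolution widths.
#' @param fc_widths hidden fully-connected widths.
#' @param pool_stride pooling stride J (>= 2).
#' @param n_classes number of classes (4).
#' @export
zfnet_config <- function(input_dim = 64L, grid = 8L,
                         channels = c(16L, 32L, 48L, 48L, 32L),
                         fc_widths = c(128L, 64L), pool_stride = 2L,
                         n_classes = 4L) {
  if (n_classes != 4) stop_config("n_classes", "must be 4")
  if (pool_stride < 2) stop_config("pool_stride", "must be >= 2")
  if (length(channels) != 5) stop_config("channels", "must give 5 widths")
  if (grid %% pool_stride^3 != 0)
    stop_config("grid", "must be divisible by pool_stride^3 (three pools)")
  structure(list(input_dim = as.integer(input_dim), grid = as.integer(grid),
                 channels = as.integer(channels),
                 fc_widths = as.integer(fc_widths),
                 pool_stride = as.integer(pool_stride),
                 n_classes = as.integer(n_classes)),
            class = "zfnet_config")
}

zfnet_new <- function(config) {
  ch <- config$channels
  ic <- c(1L, ch[1:4])
  convs <- lapply(seq_len(5), function(k)
    list(w = ag_param(init_conv_w(3L, 3L, ic[k], ch[k]), decay = k > 1),
         b = ag_param(numeric(ch[k]))))
  g2 <- config$grid %/% config$pool_stride^3   # after the three pools
  flat <- g2 * g2 * ch[5]
  widths <- c(flat, config$fc_widths, config$n_classes)
  nfc <- length(widths) - 1
  fcs <- lapply(seq_len(nfc), function(k)
    list(w = ag_param(init_mat(widths[k], widths[k + 1]), decay = k < nfc),
         b = ag_param(numeric(widths[k + 1]))))
  list(config = config,
       lift = list(w = ag_param(init_mat(config$input_dim, config$grid^2),
                                decay = TRUE),
                   b = ag_param(numeric(config$grid^2))),
       convs = convs, fcs = fcs)
}

#' ZFNet head forward pass
#'
#' @param C2 fused feature node or matrix (N x input_dim).
#' @param model ZFNet parameter structure.
#' @param training enables nothing stochastic here but is kept for
#'   interface symmetry.
#' @return `ag_node` of class logits (N x 4); apply [softmax_rows()] of
#'   the value for probabilities.
#' @export
zfnet_forward <- function(C2, model, training = FALSE) {
  if (!inherits(C2, "ag_node")) C2 <- ag_const(C2)
  cfg <- model$config
  if (ncol(C2$val) != cfg$input_dim)
    stop_arg("fused input width %d does not match configured %d",
             ncol(C2$val), cfg$input_dim)
  h <- ag_linear(C2, model$lift$w, model$lift$b)
  h <- ag_to_grid(h, c(cfg$grid, cfg$grid, 1L))
  s <- cfg$pool_stride
  for (k in seq_len(5)) {
    h <- ag_conv2d(h, model$convs[[k]]$w, pad = 1L)
    h <- ag_bias_chan(h, model$convs[[k]]$b)
    h <- ag_relu(h)
    if (k <= 2) h <- ag_lrn(h)
    if (k %in% c(1L, 2L, 5L)) h <- ag_maxpool(h, s)
  }
  h <- ag_flatten(h)
  nfc <- length(model$fcs)
  for (k in seq_len(nfc)) {
    h <- ag_linear(h, model$fcs[[k]]$w, model$fcs[[k]]$b)
    if (k < nfc) h <- ag_relu(h)
  }
  h
}
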