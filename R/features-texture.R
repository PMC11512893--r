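## Texture feature branch: one-level orthonormal Haar wavelet analysis,
## Weber local descriptor maps on each retained subband, and a histogram
## of oriented gradients on the differential-excitation map, concatenated
## into the J2 texture block.

#' One-level 2-D Haar wavelet decomposition
#'
#' Orthonormal analysis (a constant image `c` yields an LL subband
#' identically `2c`).  The three subbands retained downstream are LL
#' (approximation), LH and HH; the HL detail subband is computed (so the
#' transform is energy-preserving and invertible) but not used by the
#' texture extractor.
#'
#' @param image numeric matrix; odd dimensions are extended by edge
#'   replication to the next even size.
#' @return list with `ll`, `lh`, `hh`, `hl` (each of dimension
#'   `ceiling(dim/2)`) and `mean_coeff`, the arithmetic mean of all
#'   transform coefficients.
#' @export
dwt_decompose <- function(image) {
  if (!is.matrix(image) || min(dim(image)) < 2)
    stop_arg("image must be a matrix with both dimensions >= 2")
  H <- nrow(image); W <- ncol(image)
  if (H %% 2 == 1) image <- rbind(image, image[H, , drop = FALSE])
  if (W %% 2 == 1) image <- cbind(image, image[, ncol(image), drop = FALSE])
  a <- image[seq(1, nrow(image), 2), , drop = FALSE]
  b <- image[seq(2, nrow(image), 2), , drop = FALSE]
  lo_r <- (a + b) / sqrt(2)   # low-pass along rows
  hi_r <- (a - b) / sqrt(2)
  split_c <- function(m) {
    p <- m[, seq(1, ncol(m), 2), drop = FALSE]
    q <- m[, seq(2, ncol(m), 2), drop = FALSE]
    list(lo = (p + q) / sqrt(2), hi = (p - q) / sqrt(2))
  }
  lo <- split_c(lo_r); hi <- split_c(hi_r)
  subs <- list(ll = lo$lo, lh = lo$hi, hl = hi$lo, hh = hi$hi)
  subs$mean_coeff <- mean(c(subs$ll, subs$lh, subs$hl, subs$hh))
  subs
}

## 8-neighbour shifts with edge replication
shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) + dr, 1), H), pmin(pmax(seq_len(W) + dc, 1), W)]
}

#' Weber local descriptor maps of a subband
#'
#' Differential excitation `arctan(sum_i (f_i - f_h) / f_h)` over the
#' 8-neighbourhood, the gradient-orientation component from horizontal /
#' vertical `(-1, 0, 1)` kernels, and the gradient magnitude and ratio.
#' The subband is affinely rescaled to `[eps, 1 + eps]` first so the Weber
#' ratio never divides by zero.
#'
#' @param subband numeric matrix (any real range).
#' @param eps positivity shift (default `1e-3`).
#' @return list with matrices `excitation` (values in `(-pi/2, pi/2)`),
#'   `orientation`, `magnitude`, `ratio`.
#' @export
wld_maps <- function(subband, eps = 1e-3) {
  if (!is.matrix(subband)) stop_arg("subband must be a matrix")
  rng <- range(subband)
  f <- if (rng[2] > rng[1]) eps + (subband - rng[1]) / (rng[2] - rng[1])
       else matrix(eps, nrow(subband), ncol(subband))
  if (min(f) <= 0) stop_classed("spinalzfnet_internal_error",
                                "non-positive pixels after shift")
  acc <- matrix(0, nrow(f), ncol(f))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + (shift_replicate(f, dr, dc) - f) / f
  }
  ax <- shift_replicate(f, 0, 1) - shift_replicate(f, 0, -1)   # horizontal
  ay <- shift_replicate(f, 1, 0) - shift_replicate(f, -1, 0)   # vertical
  ratio <- ay / ax
  ratio[ax == 0 & ay == 0] <- 0
  orient <- atan(ratio)
  orient[ax == 0 & ay != 0] <- pi / 2 * sign(ay[ax == 0 & ay != 0])
  list(excitation = atan(acc),
       orientation = orient,
       magnitude = sqrt(ax^2 + ay^2),
       ratio = ratio)
}

#' Histogram of oriented gradients on a 64x64 window
#'
#' Central-difference gradients, unsigned orientation (0-180 degrees) in 9
#' bins with linear interpolation between adjacent bins, magnitude-weighted
#' histograms over 16x16-pixel cells placed at stride 8 (a 7x7 grid), and
#' L2 normalization of the concatenated vector.
#'
#' @param channel numeric matrix, exactly 64x64.
#' @return numeric vector of length `7 * 7 * 9 = 441`, non-negative before
#'   normalization and identically zero for a constant input.
#' @export
hog_extract <- function(channel) {
  if (!is.matrix(channel) || nrow(channel) != 64 || ncol(channel) != 64)
    stop_arg("channel must be a 64x64 matrix, got %dx%d",
             nrow(channel), ncol(channel))
  gx <- (shift_replicate(channel, 0, 1) - shift_replicate(channel, 0, -1)) / 2
  gy <- (shift_replicate(channel, 1, 0) - shift_replicate(channel, -1, 0)) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi        # (-180, 180]
  ang <- ang %% 180                      # unsigned orientation
  nb <- 9L; bw <- 180 / nb
  pos <- ang / bw                        # bin centres at 0, 20, ..., 160 deg
  b0 <- floor(pos)
  w1 <- pos - b0
  bin0 <- (b0 %% nb) + 1L
  bin1 <- ((b0 + 1) %% nb) + 1L
  cells <- seq(1, 49, by = 8)            # 7 cell origins per axis
  out <- numeric(7 * 7 * 9)
  k <- 0L
  for (cj in cells) for (ci in cells) {
    rs <- ci:(ci + 15); cs <- cj:(cj + 15)
    h <- numeric(nb)
    m <- mag[rs, cs]; i0 <- bin0[rs, cs]; i1 <- bin1[rs, cs]; w <- w1[rs, cs]
    for (b in seq_len(nb)) {
      h[b] <- sum(m[i0 == b] * (1 - w[i0 == b])) + sum(m[i1 == b] * w[i1 == b])
    }
    out[k + seq_len(nb)] <- h
    k <- k + nb
  }
  nrm <- sqrt(sum(out^2))
  if (nrm > 0) out <- out / nrm
  out
}

#' Texture feature block J2
#'
#' Haar-decomposes the image, computes the Weber differential-excitation
#' map of each retained subband (LL, LH, HH), resamples each map to the
#' 64x64 HOG window, and concatenates the three 441-long HOG vectors.
#'
#' @param image numeric matrix (a segmented / augmented CT image).
#' @return numeric vector of length `3 * 441 = 1323`.
#' @export
texture_features <- function(image) {
  subs <- dwt_decompose(image)
  unlist(lapply(subs[c("ll", "lh", "hh")], function(s) {
    exc <- wld_maps(s)$excitation
    hog_extract(resize_bilinear(exc, 64, 64))
  }), use.names = FALSE)
}
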