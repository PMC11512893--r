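## Geometric augmentation of segmented images: padding, rotation about the
## image centre, and integer translation.  Rotation/translation preserve
## the raster size; vacated regions are filled with a black (0) or white
## (1) background.

check_fill <- function(fill) {
  if (!is.numeric(fill) || length(fill) != 1 || !(fill %in% c(0, 1)))
    stop_arg("fill must be 0 (black) or 1 (white)")
  fill
}

#' Pad an image on all four sides
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param pad_px non-negative number of pixels added per side.
#' @param fill background value, 0 or 1.
#' @export
pad_image <- function(image, pad_px, fill = 0) {
  check_gray_image(image)
  check_fill(fill)
  if (!is.numeric(pad_px) || length(pad_px) != 1 || pad_px < 0 ||
      pad_px != round(pad_px))
    stop_arg("pad_px must be a non-negative integer")
  p <- as.integer(pad_px)
  if (p == 0L) return(image)
  out <- matrix(fill, nrow(image) + 2L * p, ncol(image) + 2L * p)
  out[p + seq_len(nrow(image)), p + seq_len(ncol(image))] <- image
  out
}

#' Rotate an image about its centre
#'
#' Arbitrary angles use inverse-mapped bilinear interpolation with the
#' requested background fill; multiples of 90 degrees on square images are
#' exact pixel permutations (so 180-degree rotation is an exact involution
#' and 90-degree rotation conserves total intensity).
#'
#' @param image numeric matrix.
#' @param angle_deg rotation angle in degrees, in `[1, 359]`,
#'   counter-clockwise.
#' @param fill background value, 0 or 1.
#' @param interp "bilinear" for intensity images, "nearest" for label masks.
#' @export
rotate_image <- function(image, angle_deg, fill = 0, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  check_fill(fill)
  if (!is.numeric(angle_deg) || length(angle_deg) != 1 ||
      angle_deg < 1 || angle_deg > 359)
    stop_arg("angle_deg must lie in [1, 359], got %s", format(angle_deg))
  H <- nrow(image); W <- ncol(image)
  if (H == W && angle_deg %% 90 == 0) {
    n <- H
    # exact pixel permutations: out[r, c] = in[n+1-c, r] (90 deg CCW), etc.
    return(switch(as.character(angle_deg %% 360),
                  "90" = t(image)[, n:1],
                  "180" = image[n:1, n:1],
                  "270" = t(image)[n:1, ]))
  }
  th <- angle_deg * pi / 180
  c_r <- (H + 1) / 2; c_c <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W) - c_r
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - c_c
  # inverse rotation of output coordinates back onto the source grid
  src_c <- cos(th) * cc + sin(th) * rr + c_c
  src_r <- -sin(th) * cc + cos(th) * rr + c_r
  sample_grid(image, src_r, src_c, fill, interp)
}

## sample image at (possibly fractional) source coordinates
sample_grid <- function(image, src_r, src_c, fill, interp) {
  H <- nrow(image); W <- ncol(image)
  if (interp == "nearest") {
    r <- round(src_r); cth <- round(src_c)
    ok <- r >= 1 & r <= H & cth >= 1 & cth <= W
    out <- matrix(fill, nrow(src_r), ncol(src_r))
    out[ok] <- image[cbind(r[ok], cth[ok])]
    return(out)
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(fill, nrow(ri), ncol(ri))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

#' Translate an image by an integer pixel shift
#'
#' @param image numeric matrix.
#' @param shift integer `c(dx, dy)`: dx moves content right (columns), dy
#'   moves it down (rows); both must be smaller than the image size.
#' @param fill value for the vacated strip, 0 or 1.
#' @export
translate_image <- function(image, shift, fill = 0) {
  check_fill(fill)
  if (length(shift) != 2 || any(shift != round(shift)))
    stop_arg("shift must be two integers c(dx, dy)")
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  H <- nrow(image); W <- ncol(image)
  if (abs(dx) >= W || abs(dy) >= H)
    stop_arg("shift (%d, %d) out of bounds for a %dx%d image", dx, dy, H, W)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

#' Expand a dataset with randomized rotations and translations
#'
#' Each sample yields `multiplier - 1` transformed copies with a uniform
#' rotation angle in `[1, 359]`, integer shifts up to 10 percent of the
#' image size, and a Bernoulli(0.5) black-or-white background fill, all
#' drawn under the given seed.  Labels are preserved; masks (when present)
#' receive the same geometric transform with nearest-neighbour sampling and
#' background fill 0, so augmented images stay aligned with their masks.
#' Padding is exposed via [pad_image()] but not drawn here because it
#' changes the raster size.
#'
#' @param samples list of samples (fields `image`, optionally
#'   `kidney_mask`, `lesion_mask`, `label`).
#' @param multiplier total copies per input sample (`>= 1`).
#' @param seed integer seed for the parameter draws.
#' @return expanded list: the originals followed by the transformed copies.
#' @export
augment_dataset <- function(samples, multiplier, seed = 1L) {
  if (!is.numeric(multiplier) || multiplier < 1 || multiplier != round(multiplier))
    stop_arg("multiplier must be an integer >= 1")
  multiplier <- as.integer(multiplier)
  if (multiplier == 1L) return(samples)
  with_seed(seed, {
    out <- samples
    for (s in samples) {
      H <- nrow(s$image); W <- ncol(s$image)
      smax <- max(1L, round(0.1 * min(H, W)))
      for (k in seq_len(multiplier - 1L)) {
        angle <- stats::runif(1, 1, 359)
        dx <- sample(seq(-smax, smax), 1)
        dy <- sample(seq(-smax, smax), 1)
        fill <- stats::rbinom(1, 1, 0.5)
        tf <- function(m, interp, f)
          translate_image(rotate_image(m, angle, f, interp), c(dx, dy), f)
        cp <- s
        cp$image <- clamp01(tf(s$image, "bilinear", fill))
        if (!is.null(cp$kidney_mask))
          cp$kidney_mask <- tf(s$kidney_mask, "nearest", 0)
        if (!is.null(cp$lesion_mask))
          cp$lesion_mask <- tf(s$lesion_mask, "nearest", 0)
        cp$provenance <- list(augmented_from = s$label, angle = angle,
                              shift = c(dx, dy), fill = fill)
        out[[length(out) + 1L]] <- cp
      }
    }
    out
  })
}
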