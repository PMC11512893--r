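## SURF interest points: integral-image box-filter approximation of the
## Hessian determinant, 3x3x3 scale-space non-maximum suppression with
## quadratic interpolation, Haar-response orientation assignment, and the
## 64-dimensional 4x4-subregion descriptor.

integral_image <- function(img) {
  ii <- apply(img, 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  cbind(0, rbind(0, ii))  # (H+1) x (W+1), ii[a+1, b+1] = sum over 1..a, 1..b
}

## Sum over the box rows (i+dr1)..(i+dr2), cols (j+dc1)..(j+dc2) for every
## pixel (i, j), exploiting separable clamped indexing on the padded table.
boxmap <- function(ii, H, W, dr1, dc1, dr2, dc2) {
  rA <- pmin(pmax(seq_len(H) + dr2, 0), H) + 1L
  rB <- pmin(pmax(seq_len(H) + dr1 - 1L, 0), H) + 1L
  cA <- pmin(pmax(seq_len(W) + dc2, 0), W) + 1L
  cB <- pmin(pmax(seq_len(W) + dc1 - 1L, 0), W) + 1L
  ii[rA, cA] - ii[rB, cA] - ii[rA, cB] + ii[rB, cB]
}

## Hessian-determinant response map for one box-filter size L (odd multiple
## of 3).  The mixed term carries the canonical 0.81 relative weight.
hessian_det_map <- function(ii, H, W, L) {
  l <- L %/% 3L
  b <- (L - 1L) %/% 2L
  h <- (l - 1L) %/% 2L
  inv <- 1 / (L * L)
  dxx <- boxmap(ii, H, W, -l + 1L, -b, l - 1L, b) -
    3 * boxmap(ii, H, W, -l + 1L, -h, l - 1L, -h + l - 1L)
  dyy <- boxmap(ii, H, W, -b, -l + 1L, b, l - 1L) -
    3 * boxmap(ii, H, W, -h, -l + 1L, -h + l - 1L, l - 1L)
  dxy <- boxmap(ii, H, W, -l, 1L, -1L, l) + boxmap(ii, H, W, 1L, -l, l, -1L) -
    boxmap(ii, H, W, -l, -l, -1L, -1L) - boxmap(ii, H, W, 1L, 1L, l, l)
  dxx <- dxx * inv; dyy <- dyy * inv; dxy <- dxy * inv
  dxx * dyy - 0.81 * dxy * dxy
}

## 3x3 neighbourhood maximum (including the centre), -Inf beyond borders
local_max3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(-Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    sub <- matrix(-Inf, H, W)
    sub[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out <- pmax(out, sub)
  }
  out
}

surf_filter_sizes <- list(c(9L, 15L, 21L, 27L), c(15L, 27L, 39L, 51L))

#' Detect SURF interest points
#'
#' Local maxima of the box-filter Hessian determinant over a 3x3x3
#' image/scale neighbourhood across two filter octaves, refined by
#' quadratic interpolation, sorted by response and capped.
#'
#' @param image numeric matrix, at least 32x32.
#' @param hessian_threshold minimum determinant response (default `1e-4`,
#'   tuned for images on the `[0, 1]` intensity scale).
#' @param max_points cap on the number of returned points.
#' @return data frame with columns `x` (column), `y` (row), `scale`,
#'   `response` (0 rows for e.g. a constant image, whose Hessian vanishes).
#' @export
detect_surf <- function(image, hessian_threshold = 1e-4, max_points = 5L) {
  check_gray_image(image)
  H <- nrow(image); W <- ncol(image)
  if (H < 32 || W < 32)
    stop_arg("image too small for SURF box filters (need >= 32x32, got %dx%d)", H, W)
  ii <- integral_image(image)
  pts <- list()
  for (sizes in surf_filter_sizes) {
    maps <- lapply(sizes, function(L) hessian_det_map(ii, H, W, L))
    for (s in 2:3) {
      d <- maps[[s]]
      cand <- d > hessian_threshold &
        d >= local_max3(d) &
        d > local_max3(maps[[s - 1]]) &
        d > local_max3(maps[[s + 1]])
      # ignore the border band where the largest filter of the triplet is
      # clipped by the image edge (clamped box sums are not valid responses)
      m <- (sizes[s + 1] - 1L) %/% 2L + 1L
      if (2 * m >= min(H, W)) next
      cand[c(seq_len(m), H - seq_len(m) + 1L), ] <- FALSE
      cand[, c(seq_len(m), W - seq_len(m) + 1L)] <- FALSE
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; c0 <- idx[k, 2]
        ref <- surf_refine(maps, s, r, c0, sizes)
        pts[[length(pts) + 1L]] <- data.frame(
          x = ref$x, y = ref$y, scale = ref$scale, response = d[r, c0])
      }
    }
  }
  if (!length(pts))
    return(data.frame(x = numeric(0), y = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  out <- do.call(rbind, pts)
  out <- out[out$x >= 1 & out$x <= W & out$y >= 1 & out$y <= H, , drop = FALSE]
  out <- out[order(-out$response), , drop = FALSE]
  out <- out[seq_len(min(nrow(out), max_points)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## quadratic sub-pixel / sub-scale refinement of a scale-space maximum
surf_refine <- function(maps, s, r, c0, sizes) {
  H <- nrow(maps[[s]]); W <- ncol(maps[[s]])
  sigma_of <- function(Lf) 1.2 * Lf / 9
  base <- list(x = c0, y = r, scale = sigma_of(sizes[s]))
  if (r <= 1 || r >= H || c0 <= 1 || c0 >= W) return(base)
  v <- function(ds, dr, dc) maps[[s + ds]][r + dr, c0 + dc]
  g <- c((v(0, 0, 1) - v(0, 0, -1)) / 2,
         (v(0, 1, 0) - v(0, -1, 0)) / 2,
         (v(1, 0, 0) - v(-1, 0, 0)) / 2)
  hxx <- v(0, 0, 1) + v(0, 0, -1) - 2 * v(0, 0, 0)
  hyy <- v(0, 1, 0) + v(0, -1, 0) - 2 * v(0, 0, 0)
  hss <- v(1, 0, 0) + v(-1, 0, 0) - 2 * v(0, 0, 0)
  hxy <- (v(0, 1, 1) - v(0, 1, -1) - v(0, -1, 1) + v(0, -1, -1)) / 4
  hxs <- (v(1, 0, 1) - v(1, 0, -1) - v(-1, 0, 1) + v(-1, 0, -1)) / 4
  hys <- (v(1, 1, 0) - v(1, -1, 0) - v(-1, 1, 0) + v(-1, -1, 0)) / 4
  Hm <- matrix(c(hxx, hxy, hxs, hxy, hyy, hys, hxs, hys, hss), 3, 3)
  off <- tryCatch(solve(Hm, -g), error = function(e) NULL)
  if (is.null(off) || any(!is.finite(off)) || any(abs(off) > 1)) return(base)
  step <- (sizes[s + 1] - sizes[s - 1]) / 2
  list(x = c0 + off[1], y = r + off[2],
       scale = sigma_of(sizes[s] + off[3] * step))
}

## Haar responses at integer centres; s is the full wavelet side length
haar_xy <- function(ii, H, W, r, c0, s) {
  half <- max(1L, round(s / 2))
  box <- function(r1, c1, r2, c2) {
    rA <- min(max(r2, 0), H) + 1L; rB <- min(max(r1 - 1L, 0), H) + 1L
    cA <- min(max(c2, 0), W) + 1L; cB <- min(max(c1 - 1L, 0), W) + 1L
    ii[rA, cA] - ii[rB, cA] - ii[rA, cB] + ii[rB, cB]
  }
  gx <- box(r - half + 1L, c0 + 1L, r + half, c0 + half) -
    box(r - half + 1L, c0 - half + 1L, r + half, c0)
  gy <- box(r + 1L, c0 - half + 1L, r + half, c0 + half) -
    box(r - half + 1L, c0 - half + 1L, r, c0 + half)
  c(gx, gy)
}

#' Compute 64-dimensional SURF descriptors
#'
#' Assigns each point a dominant orientation (largest summed Haar-response
#' vector over a sliding 60-degree window within a 6-sigma disc), then sums
#' oriented Haar responses over a 4x4 grid of subregions spanning a
#' 20-sigma square: per subregion `(sum dx, sum dy, sum |dx|, sum |dy|)`.
#' The final vector is L2-normalized, which removes illumination/contrast
#' scaling.  Points whose descriptor window leaves the image are skipped
#' with a warning.
#'
#' @param image numeric matrix the points were detected on.
#' @param points data frame from [detect_surf()].
#' @return list with `descriptors` (k x 64 matrix, unit rows) and `points`
#'   (the surviving points with an added `orientation` column, radians).
#' @export
describe_surf <- function(image, points) {
  check_gray_image(image)
  H <- nrow(image); W <- ncol(image)
  ii <- integral_image(image)
  desc <- list(); kept <- list()
  for (k in seq_len(nrow(points))) {
    r <- round(points$y[k]); c0 <- round(points$x[k])
    sg <- points$scale[k]
    # 10 sigma window radius + Haar support; oriented samples that poke
    # past this at 45 degrees use clamped (partial) box sums, which stay
    # linear in intensity so descriptor invariances are unaffected
    margin <- ceiling(10.5 * sg) + 1L
    if (r - margin < 1 || r + margin > H || c0 - margin < 1 || c0 + margin > W) {
      warning(sprintf("SURF point at (%d, %d) too close to border; skipped",
                      r, c0))
      next
    }
    th <- surf_orientation(ii, H, W, r, c0, sg)
    d <- surf_descriptor(ii, H, W, r, c0, sg, th)
    desc[[length(desc) + 1L]] <- d
    p <- points[k, , drop = FALSE]
    p$orientation <- th
    kept[[length(kept) + 1L]] <- p
  }
  if (!length(desc))
    return(list(descriptors = matrix(0, 0, 64), points = cbind(points[0, ], orientation = numeric(0))))
  list(descriptors = do.call(rbind, desc), points = do.call(rbind, kept))
}

surf_orientation <- function(ii, H, W, r, c0, sg) {
  step <- max(1L, round(sg))
  rad <- 6 * sg
  offs <- seq(-6L, 6L)
  gx <- c(); gy <- c(); ang <- c()
  for (di in offs) for (dj in offs) {
    if (di * di + dj * dj > 36) next
    g <- haar_xy(ii, H, W, r + di * step, c0 + dj * step, round(4 * sg))
    wgt <- exp(-(di * di + dj * dj) / (2 * 2.5^2))
    gx <- c(gx, g[1] * wgt); gy <- c(gy, g[2] * wgt)
    ang <- c(ang, atan2(g[2] * wgt, g[1] * wgt))
  }
  best <- 0; best_norm <- -1
  for (a0 in seq(0, 2 * pi, by = 0.15)) {
    d <- (ang - a0) %% (2 * pi)
    inwin <- d < pi / 3
    sx <- sum(gx[inwin]); sy <- sum(gy[inwin])
    nr <- sx * sx + sy * sy
    if (nr > best_norm) { best_norm <- nr; best <- atan2(sy, sx) }
  }
  best
}

surf_descriptor <- function(ii, H, W, r, c0, sg, th) {
  ct <- cos(th); st <- sin(th)
  out <- numeric(64)
  for (sj in 0:3) for (si in 0:3) {
    sums <- c(0, 0, 0, 0)
    for (l in 0:4) for (m in 0:4) {
      u <- (sj * 5 + l - 9.5) * sg   # along-orientation axis
      v <- (si * 5 + m - 9.5) * sg
      px <- round(c0 + u * ct - v * st)
      py <- round(r + u * st + v * ct)
      g <- haar_xy(ii, H, W, py, px, round(2 * sg))
      wgt <- exp(-(u * u + v * v) / (2 * (3.3 * sg)^2))
      rx <- wgt * (ct * g[1] + st * g[2])
      ry <- wgt * (-st * g[1] + ct * g[2])
      sums <- sums + c(rx, ry, abs(rx), abs(ry))
    }
    out[(si + 4 * sj) * 4 + 1:4] <- sums
  }
  nrm <- sqrt(sum(out^2))
  if (nrm > 0) out <- out / nrm
  out
}

#' SURF feature block J1 with a fixed keypoint budget
#'
#' Detects and describes up to `max_points` interest points and packs the
#' descriptors into a fixed `64 * max_points` slot vector, zero-padded when
#' fewer points are found (extra detections are dropped by response rank).
#'
#' @inheritParams detect_surf
#' @return numeric vector of length `64 * max_points` (320 by default).
#' @export
surf_features <- function(image, hessian_threshold = 1e-4, max_points = 5L) {
  pts <- detect_surf(image, hessian_threshold, max_points)
  out <- numeric(64L * max_points)
  if (nrow(pts) == 0) return(out)
  d <- suppressWarnings(describe_surf(image, pts))
  k <- min(nrow(d$descriptors), max_points)
  if (k > 0) out[seq_len(64L * k)] <- as.vector(t(d$descriptors[seq_len(k), , drop = FALSE]))
  out
}
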