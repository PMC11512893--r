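## Region shape descriptors and GLCM-based statistical descriptors.

## vectorized crossing-number point-in-polygon (polygon closed implicitly)
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Shape feature block
#'
#' Five descriptors of a binary region: pixel area, perimeter (chained
#' Euclidean distance along the traced boundary contour), major and minor
#' axis lengths (from second-order central moments, the ellipse with
#' matching moments), and solidity (area over convex-hull area, where the
#' hull area is counted in rasterized pixels so a convex region scores 1
#' up to discretization).
#'
#' @param mask binary matrix (0/1 or logical) with at least one foreground
#'   pixel; with multiple components the largest is measured.
#' @return named numeric vector
#'   `c(area, perimeter, major_axis, minor_axis, solidity)`.
#' @seealso [shape_eccentricity()] for the derived minor/major axis ratio.
#' @export
shape_features <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || sum(mask > 0) < 1)
    stop_arg("mask must be a matrix with at least one foreground pixel")
  lab <- EBImage::bwlabel(mask > 0)
  tab <- tabulate(lab[lab > 0])
  biggest <- which.max(tab)
  reg <- (lab == biggest) * 1
  area <- sum(reg)

  # perimeter: chained segment lengths along the traced boundary
  oc <- EBImage::ocontour(reg)[[1]]          # 0-based (x, y) vertices
  per <- if (nrow(oc) > 1) {
    d <- sqrt(diff(c(oc[, 1], oc[1, 1]))^2 + diff(c(oc[, 2], oc[1, 2]))^2)
    sum(d)
  } else 0

  # axis lengths from central moments (ellipse of equal second moments)
  idx <- which(reg == 1, arr.ind = TRUE)
  ybar <- mean(idx[, 1]); xbar <- mean(idx[, 2])
  # + 1/12: each pixel is a unit square, not a point mass
  mu20 <- mean((idx[, 2] - xbar)^2) + 1 / 12
  mu02 <- mean((idx[, 1] - ybar)^2) + 1 / 12
  mu11 <- mean((idx[, 2] - xbar) * (idx[, 1] - ybar))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  major <- 2 * sqrt(2) * sqrt(mu20 + mu02 + common)
  minor <- 2 * sqrt(2) * sqrt(max(mu20 + mu02 - common, 0))

  # solidity: rasterized convex-hull area
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  vx <- idx[hull, 2]; vy <- idx[hull, 1]
  box_r <- range(idx[, 1]); box_c <- range(idx[, 2])
  grid <- expand.grid(r = box_r[1]:box_r[2], c = box_c[1]:box_c[2])
  inhull <- points_in_polygon(grid$c, grid$r, vx, vy)
  # hull vertices themselves count as inside
  hull_area <- sum(inhull | (reg[cbind(grid$r, grid$c)] == 1))
  solidity <- area / hull_area

  c(area = area, perimeter = per, major_axis = major,
    minor_axis = minor, solidity = solidity)
}

#' Eccentricity as the minor/major axis ratio
#'
#' Defined here as minor over major axis length (the reciprocal of the
#' focal-distance convention), derived from [shape_features()].
#' @param mask binary region mask.
#' @export
shape_eccentricity <- function(mask) {
  h <- shape_features(mask)
  unname(h["minor_axis"] / h["major_axis"])
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes `[0, 1]` intensities into `levels` equal-width bins and counts
#' horizontally adjacent (offset distance 1, angle 0) in-mask pixel pairs,
#' symmetrized and normalized to probabilities.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask binary matrix; both pixels of a pair must be foreground.
#' @param levels number of gray levels (default 8).
#' @return `levels` x `levels` matrix of pair probabilities.
#' @export
glcm_matrix <- function(image, mask = NULL, levels = 8L) {
  check_gray_image(image)
  if (is.null(mask)) mask <- matrix(1, nrow(image), ncol(image))
  q <- pmin(floor(image * levels), levels - 1L) + 1L  # 1..levels
  W <- ncol(image)
  a <- q[, -W, drop = FALSE]; b <- q[, -1, drop = FALSE]
  ok <- (mask[, -W, drop = FALSE] > 0) & (mask[, -1, drop = FALSE] > 0)
  g <- matrix(0, levels, levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    g <- unclass(tab) + t(unclass(tab))
    g <- g / sum(g)
  }
  g
}

#' Statistical feature block
#'
#' Four descriptors of the masked region: mean intensity, Shannon entropy
#' of the GLCM cell probabilities (reported as `-sum p log2 p`, so it is
#' non-negative and zero exactly when one cell is occupied), GLCM
#' correlation, and GLCM contrast `sum |c-d|^2 p(c,d)`.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector `c(mean, entropy, correlation, contrast)`.
#' @export
statistical_features <- function(image, mask = NULL, levels = 8L) {
  check_gray_image(image)
  if (is.null(mask)) mask <- matrix(1, nrow(image), ncol(image))
  if (sum(mask > 0) < 1) stop_arg("mask must contain foreground pixels")
  mu <- mean(image[mask > 0])
  g <- glcm_matrix(image, mask, levels)
  p <- g[g > 0]
  ent <- if (length(p)) -sum(p * log2(p)) else 0
  i <- row(g); j <- col(g)
  mi <- sum(i * g); mj <- sum(j * g)
  si <- sqrt(sum((i - mi)^2 * g)); sj <- sqrt(sum((j - mj)^2 * g))
  corr <- if (si > 0 && sj > 0) sum((i - mi) * (j - mj) * g) / (si * sj) else 0
  contr <- sum(abs(i - j)^2 * g)
  c(mean = mu, entropy = ent, correlation = corr, contrast = contr)
}
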