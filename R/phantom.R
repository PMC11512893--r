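## Synthetic kidney-CT phantom generator.
##
## Every image carries a bright kidney-shaped ellipse on a dark background;
## the four disease classes differ by the lesion drawn inside the kidney:
##   normal - no lesion
##   cyst   - dark circular low-intensity inclusion
##   tumor  - irregular mid-intensity mass (radially perturbed blob)
##   stone  - tiny near-maximum-intensity speck (<= 5 px)
## Intensities live in [0, 1]; Gaussian noise is applied first, then
## salt-and-pepper impulse noise (which the median filter is there to kill).

PHANTOM_CLASSES <- c("normal", "cyst", "tumor", "stone")

## noise-free tissue intensities; ordered so that on clean phantoms
## stone > parenchyma > tumor > cyst (class separability contract)
.phantom_levels <- list(background = 0.1, kidney = 0.6,
                        cyst = 0.25, tumor = 0.45, stone = 0.95)

#' Specification for a synthetic phantom dataset
#'
#' @param image_size pixels per side (square images), at least 64.
#' @param n_per_class images generated per class.
#' @param classes ordered subset of `c("normal","cyst","tumor","stone")`.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   intensity units on the `[0, 1]` scale.
#' @param impulse_frac fraction of pixels replaced by salt-and-pepper
#'   impulses, in `[0, 0.2]`.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L, n_per_class = 10L,
                         classes = PHANTOM_CLASSES,
                         noise_sd = 0.02, impulse_frac = 0.02, seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size < 64)
    stop_config("image_size", "must be a single number >= 64")
  if (!is.numeric(n_per_class) || length(n_per_class) != 1 || n_per_class < 1)
    stop_config("n_per_class", "must be a single number >= 1")
  if (length(classes) < 1 || !all(classes %in% PHANTOM_CLASSES))
    stop_config("classes", "must be a non-empty subset of %s",
                paste(PHANTOM_CLASSES, collapse = "/"))
  if (anyDuplicated(classes))
    stop_config("classes", "must not contain duplicates")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop_config("noise_sd", "must be a single non-negative number")
  if (!is.numeric(impulse_frac) || length(impulse_frac) != 1 ||
      impulse_frac < 0 || impulse_frac > 0.2)
    stop_config("impulse_frac", "must lie in [0, 0.2]")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 classes = as.character(classes),
                 noise_sd = noise_sd, impulse_frac = impulse_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## rotated-ellipse membership test on a pixel-center grid
ellipse_mask <- function(size, cx, cy, a, b, theta) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  y <- matrix(seq_len(size), size, size) - cy
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

## irregular blob: ellipse radius modulated by low-order angular harmonics
blob_mask <- function(size, cx, cy, r0, wobble) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  y <- matrix(seq_len(size), size, size) - cy
  phi <- atan2(y, x)
  rad <- r0 * (1 + wobble[1] * cos(2 * phi + wobble[4]) +
                 wobble[2] * cos(3 * phi + wobble[5]) +
                 wobble[3] * cos(4 * phi + wobble[6]))
  sqrt(x^2 + y^2) <= pmax(rad, 1)
}

draw_one_phantom <- function(size, label, noise_sd, impulse_frac) {
  lv <- .phantom_levels
  cx <- size / 2 + stats::runif(1, -0.05, 0.05) * size
  cy <- size / 2 + stats::runif(1, -0.05, 0.05) * size
  a <- stats::runif(1, 0.24, 0.30) * size
  b <- stats::runif(1, 0.15, 0.20) * size
  theta <- stats::runif(1, 0, pi)
  kidney <- ellipse_mask(size, cx, cy, a, b, theta)
  img <- matrix(lv$background, size, size)
  img[kidney] <- lv$kidney
  lesion <- matrix(FALSE, size, size)
  prov <- list(center = c(cx, cy), axes = c(a, b), angle = theta)
  if (label != "normal") {
    # lesion center placed well inside the ellipse
    u <- stats::runif(1, 0, 0.35)
    phi <- stats::runif(1, 0, 2 * pi)
    lx <- cx + cos(theta) * a * u * cos(phi) - sin(theta) * b * u * sin(phi)
    ly <- cy + sin(theta) * a * u * cos(phi) + cos(theta) * b * u * sin(phi)
    if (label == "cyst") {
      r <- stats::runif(1, 0.05, 0.08) * size
      lesion <- ellipse_mask(size, lx, ly, r, r, 0)
      intensity <- lv$cyst
      prov$lesion <- list(center = c(lx, ly), radius = r)
    } else if (label == "stone") {
      # speck of at most 5 pixels: centre pixel plus 4-neighbourhood
      lesion <- ellipse_mask(size, round(lx), round(ly), 1.2, 1.2, 0)
      intensity <- lv$stone
      prov$lesion <- list(center = c(round(lx), round(ly)))
    } else {
      r0 <- stats::runif(1, 0.055, 0.09) * size
      wob <- c(stats::runif(3, 0.08, 0.25), stats::runif(3, 0, 2 * pi))
      lesion <- blob_mask(size, lx, ly, r0, wob)
      intensity <- lv$tumor
      prov$lesion <- list(center = c(lx, ly), radius = r0, wobble = wob)
    }
    lesion <- lesion & kidney
    img[lesion] <- intensity
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
  if (impulse_frac > 0) {
    n_imp <- round(impulse_frac * size * size)
    if (n_imp > 0) {
      pos <- sample.int(size * size, n_imp)
      img[pos] <- stats::rbinom(n_imp, 1L, 0.5)
    }
  }
  list(image = clamp01(img),
       kidney_mask = kidney * 1L,
       lesion_mask = lesion * 1L,
       label = label,
       provenance = prov)
}

#' Generate a synthetic phantom dataset
#'
#' Produces `n_per_class * length(classes)` samples; the RNG state is local
#' to the call, so the same spec always yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list of `phantom_sample` objects, each with fields `image`
#'   (matrix in `[0, 1]`), `kidney_mask`, `lesion_mask` (0/1 matrices),
#'   `label` and `provenance`.
#' @export
#' @examples
#' samples <- generate_phantoms(phantom_spec(n_per_class = 1, seed = 7))
#' vapply(samples, `[[`, "", "label")
generate_phantoms <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    spec <- do.call(phantom_spec, as.list(spec))
  with_seed(spec$seed, {
    out <- list()
    for (cl in spec$classes) {
      for (i in seq_len(spec$n_per_class)) {
        s <- draw_one_phantom(spec$image_size, cl,
                              spec$noise_sd, spec$impulse_frac)
        class(s) <- "phantom_sample"
        out[[length(out) + 1L]] <- s
      }
    }
    out
  })
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale PNG images and kidney masks plus a CSV manifest
#' with header `filename,label,mask`; the written pixels round-trip
#' losslessly through [read_image()] at 8-bit precision.
#'
#' @param samples list of phantom samples (or any list with `image`,
#'   `kidney_mask`, `label`).
#' @param directory output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_phantom_dataset <- function(samples, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L)
    stop_io("cannot write to directory '%s'", directory)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fn <- sprintf("img_%04d.png", i)
    mn <- file.path("masks", sprintf("mask_%04d.png", i))
    write_image(s$image, file.path(directory, fn))
    write_image(s$kidney_mask, file.path(directory, mn))
    data.frame(filename = fn, label = s$label, mask = mn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_phantom_dataset()]
#'
#' @param manifest path to a manifest CSV (or a directory containing
#'   `manifest.csv`).
#' @return list of samples with `image`, `kidney_mask`, `label`.
#' @export
read_phantom_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop_io("manifest not found: '%s'", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    s <- list(image = read_image(file.path(base, tab$filename[i])),
              kidney_mask = round(read_image(file.path(base, tab$mask[i]))),
              lesion_mask = NULL,
              label = tab$label[i])
    class(s) <- "phantom_sample"
    s
  })
}
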