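#' Assemble the full per-image feature record
#'
#' Concatenates the four feature branches into one fixed-length vector:
#' J1, the SURF block (`64 * max_points` slots, zero-padded); J2, the
#' texture block (WLD excitation of the LL/LH/HH Haar subbands through a
#' 441-long HOG each, 1323 values); the 5-value shape block; and the
#' 4-value statistical block.  Block offsets partition the vector with no
#' gaps, so a default record has `320 + 1323 + 5 + 4 = 1652` entries.
#'
#' @param image numeric matrix in `[0, 1]` (a segmented, possibly
#'   augmented image).
#' @param mask binary region mask aligned with `image` (used by the shape
#'   and statistical branches).
#' @param label optional class label carried along.
#' @param max_points SURF keypoint budget (default 5).
#' @param hessian_threshold SURF detector threshold.
#' @return object of class `feature_record`: list with `surf`, `texture`,
#'   `shape`, `stat`, `label`, and `offsets` (named list of index ranges).
#' @export
extract_record <- function(image, mask, label = NA_character_,
                           max_points = 5L, hessian_threshold = 1e-4) {
  check_gray_image(image)
  if (!all(dim(image) == dim(mask)))
    stop_arg("image and mask dimensions differ")
  surf <- surf_features(image, hessian_threshold, max_points)
  tex <- texture_features(image)
  shp <- shape_features(mask)
  st <- statistical_features(image, mask)
  lens <- c(surf = length(surf), texture = length(tex),
            shape = length(shp), stat = length(st))
  ends <- cumsum(lens)
  offsets <- Map(function(e, l) (e - l + 1L):e, ends, lens)
  structure(list(surf = surf, texture = tex, shape = unname(shp),
                 stat = unname(st), label = label, offsets = offsets),
            class = "feature_record")
}

#' Flatten a feature record into its numeric vector
#' @param x a `feature_record`.
#' @keywords internal
record_vector <- function(x) c(x$surf, x$texture, x$shape, x$stat)

#' @param x a `feature_record`.
#' @param ... unused.
#' @rdname extract_record
#' @export
as.double.feature_record <- function(x, ...) record_vector(x)

#' @export
length.feature_record <- function(x) {
  length(x$surf) + length(x$texture) + length(x$shape) + length(x$stat)
}

#' @export
print.feature_record <- function(x, ...) {
  cat("<feature_record> label:", x$label, "\n")
  cat(sprintf("  surf: %d  texture: %d  shape: %d  stat: %d  (total %d)\n",
              length(x$surf), length(x$texture), length(x$shape),
              length(x$stat), length(x)))
  invisible(x)
}

#' Extract feature records for a list of samples
#'
#' @param samples list with `image` and masks; when a sample carries no
#'   mask a full-frame mask is used (the no-segmentation fallback).
#' @param ... passed to [extract_record()].
#' @return list of `feature_record`s.
#' @export
extract_records <- function(samples, ...) {
  lapply(samples, function(s) {
    m <- s$kidney_mask
    if (is.null(m)) m <- matrix(1, nrow(s$image), ncol(s$image))
    if (sum(m) == 0) m <- matrix(1, nrow(s$image), ncol(s$image))
    extract_record(s$image, m, label = s$label, ...)
  })
}

#' Tabulate feature records as a data frame
#'
#' One row per image with the CSV schema
#' `filename,label,surf_0..,tex_0..,shape_0..,stat_0..`.
#' @param records list of `feature_record`s.
#' @param filenames optional character vector of source files.
#' @export
records_to_table <- function(records, filenames = NULL) {
  mat <- do.call(rbind, lapply(records, record_vector))
  r1 <- records[[1]]
  colnames(mat) <- c(sprintf("surf_%d", seq_along(r1$surf) - 1L),
                     sprintf("tex_%d", seq_along(r1$texture) - 1L),
                     sprintf("shape_%d", seq_along(r1$shape) - 1L),
                     sprintf("stat_%d", seq_along(r1$stat) - 1L))
  if (is.null(filenames)) filenames <- sprintf("img_%04d.png", seq_along(records))
  cbind(data.frame(filename = filenames,
                   label = vapply(records, function(r) as.character(r$label), ""),
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}
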