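## Shared validation, error classes, and seeding helpers.

stop_classed <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Configuration error naming the offending field
#' @keywords internal
stop_config <- function(field, msg, ...) {
  stop_classed("spinalzfnet_config_error",
               paste0("invalid configuration field '", field, "': ", msg), ...)
}

#' @keywords internal
stop_arg <- function(msg, ...) stop_classed("spinalzfnet_argument_error", msg, ...)

#' @keywords internal
stop_io <- function(msg, ...) stop_classed("spinalzfnet_io_error", msg, ...)

check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_arg("%s must be a numeric matrix", arg)
  if (anyNA(image) || any(!is.finite(image)))
    stop_arg("%s contains non-finite values", arg)
  if (min(image) < 0 || max(image) > 1)
    stop_arg("%s must lie in [0, 1] (range %.3f..%.3f)", arg,
             min(image), max(image))
  invisible(image)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a per-stage seed from the global seed
#'
#' Hashes the stage name onto the global seed so each pipeline stage can be
#' rerun in isolation with reproducible randomness.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bilinear resampling of a matrix to a new size
#' @keywords internal
resize_bilinear <- function(image, out_h, out_w) {
  H <- nrow(image); W <- ncol(image)
  if (H == out_h && W == out_w) return(image)
  # map output pixel centers onto input pixel-center coordinates
  ri <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  ci <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  r0 <- pmin(pmax(floor(ri), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(ci), 1), W); c1 <- pmin(c0 + 1, W)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- image[r0, c0, drop = FALSE]; b <- image[r1, c0, drop = FALSE]
  cc <- image[r0, c1, drop = FALSE]; d <- image[r1, c1, drop = FALSE]
  top <- a * (1 - fr) + b * fr
  bot <- cc * (1 - fr) + d * fr
  sweep(top, 2, 1 - fc, "*") + sweep(bot, 2, fc, "*")
}

#' Nearest-neighbour resize (for label masks)
#' @keywords internal
resize_nearest <- function(mask, out_h, out_w) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * H / out_h), 1), H)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * W / out_w), 1), W)
  mask[ri, ci, drop = FALSE]
}
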