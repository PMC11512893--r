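## Image and configuration I/O.

#' Read a grayscale image
#'
#' PNG or TIFF, 8- or 16-bit; RGB inputs are converted by Rec. 709
#' luminance.  Values are returned on the `[0, 1]` scale (the underlying
#' readers already divide 8-bit data by 255 and 16-bit data by 65535).
#'
#' @param path file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io("cannot read image: '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           stop_io("unsupported image format '.%s' for '%s'", ext, path)),
    error = function(e) stop_io("failed to read '%s': %s", path, conditionMessage(e)))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img <- img[, , 1]
  }
  clamp01(img)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are quantized to 8 bits; [read_image()] recovers them within
#' 1/255.
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path ending in `.png`.
#' @export
write_image <- function(image, path) {
  if (is.integer(image)) storage.mode(image) <- "double"
  check_gray_image(image)
  ok <- tryCatch({ png::writePNG(image, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io("cannot write image to '%s'", path)
  invisible(path)
}

## -- run configuration ------------------------------------------------------

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "spinalzfnet_run",
    phantom = list(image_size = 64L, n_per_class = 40L,
                   noise_sd = 0.02, impulse_frac = 0.02),
    preprocess = list(enabled = TRUE, window = 3L),
    segment = list(enabled = TRUE, initial_channels = 8L,
                   stage_channels = c(16L, 32L, 32L),
                   epochs = 25L, lr = 8e-3, batch_size = 8L,
                   resolution = 64L),
    augment = list(multiplier = 1L),
    features = list(max_points = 5L, hessian_threshold = 1e-4),
    model = list(fusion_dim = 64L),
    train = list(optimizer = "adam", batch_size = 4L, lr = 1e-3,
                 max_epochs = 30L, plateau_patience = 5L,
                 min_delta = 1e-4, lr_factor = 0.5,
                 early_stop_patience = 50L, weight_decay = 2e-3),
    evaluate = list(mode = "split", train_pct = 80, k = 10)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop_config(here, "unknown configuration key")
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Build a pipeline run configuration
#'
#' Starts from package defaults and overlays user values; unknown keys are
#' rejected so typos surface immediately.  The configuration round-trips
#' unchanged through YAML.
#'
#' @param ... named overrides (possibly nested lists, e.g.
#'   `phantom = list(n_per_class = 10)`).
#' @param file optional YAML file whose contents are applied first.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) stop_io("config file '%s' not found", file)
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  user <- list(...)
  if (length(user)) cfg <- merge_config(cfg, user)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
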