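## Assembly and training of the full hybrid classifier.

CLASS_LEVELS <- c("normal", "cyst", "tumor", "stone")

#' Create an untrained hybrid classifier
#'
#' @param record_dim length of the flattened feature record.
#' @param image_dim side length the masked image is resampled to before
#'   flattening into the SpinalNet branch (default 64).
#' @param fusion_dim common width of the fusion intermediates p, p1, p2,
#'   C1, C2.
#' @param spinal a [spinal_config()] (its `input_dim`/`out_dim` are forced
#'   to match `image_dim` and `fusion_dim`).
#' @param zfnet a [zfnet_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `spinalzfnet_model`.
#' @export
spinalzfnet_new <- function(record_dim = 1652L, image_dim = 64L,
                            fusion_dim = 64L,
                            spinal = spinal_config(),
                            zfnet = zfnet_config(),
                            seed = 1L) {
  spinal$input_dim <- as.integer(image_dim^2)
  spinal$out_dim <- as.integer(fusion_dim)
  zfnet$input_dim <- as.integer(fusion_dim)
  with_seed(seed, {
    m <- list(record_dim = as.integer(record_dim),
              image_dim = as.integer(image_dim),
              fusion_dim = as.integer(fusion_dim),
              spinal = spinal_new(spinal),
              fusion = fusion_new(record_dim, 4L, 5L, fusion_dim),
              zfnet = zfnet_new(zfnet),
              scaler = NULL,
              classes = CLASS_LEVELS)
    class(m) <- "spinalzfnet_model"
    m
  })
}

## feature schema fingerprint: block lengths must match between fit and use
schema_of <- function(record) {
  paste(length(record$surf), length(record$texture),
        length(record$shape), length(record$stat), sep = "/")
}

## build the numeric design blocks for a list of (sample, record) pairs
classifier_design <- function(samples, records, image_dim) {
  n <- length(samples)
  full <- do.call(rbind, lapply(records, record_vector))
  stat <- do.call(rbind, lapply(records, `[[`, "stat"))
  shape <- do.call(rbind, lapply(records, `[[`, "shape"))
  img <- matrix(0, n, image_dim^2)
  for (i in seq_len(n)) {
    m <- samples[[i]]$kidney_mask
    masked <- if (is.null(m)) samples[[i]]$image else samples[[i]]$image * (m > 0)
    img[i, ] <- as.vector(resize_bilinear(masked, image_dim, image_dim))
  }
  list(full = full, stat = stat, shape = shape, img = img)
}

scale_fit <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}
## standardize, then divide by sqrt(block width) so every feature block
## carries comparable total energy regardless of its dimensionality (the
## 1652-entry record would otherwise drown the 4-entry statistical block)
scale_apply <- function(m, s) {
  sweep(sweep(m, 2, s$mu), 2, s$sd, "/") / sqrt(ncol(m))
}

classifier_forward <- function(model, design, training = FALSE) {
  C1 <- spinalnet_forward(design$img, model$spinal)
  fz <- fusion_forward(list(full = design$full, stat = design$stat,
                            shape = design$shape), C1, model$fusion)
  zfnet_forward(fz$C2, model$zfnet, training)
}

#' Train the hybrid classifier on feature records
#'
#' Standardizes each feature block on the training set, then optimizes the
#' SpinalNet branch, fusion gate and ZFNet head jointly with softmax
#' cross-entropy under the training-control schedule in `config`
#' (plateau learning-rate halving, early stopping, best-checkpoint
#' restore on validation accuracy).
#'
#' @param model a [spinalzfnet_new()] model.
#' @param samples training samples (`image`, `kidney_mask`, `label`).
#' @param records matching list of `feature_record`s.
#' @param config a [train_config()].
#' @param val_frac fraction held out (stratified) for validation.
#' @return the trained model with `$history` attached.
#' @export
train_spinalzfnet <- function(model, samples, records,
                              config = train_config(), val_frac = 0.25) {
  labels <- vapply(records, function(r) as.character(r$label), "")
  if (!all(labels %in% model$classes))
    stop_arg("unknown labels: %s",
             paste(setdiff(labels, model$classes), collapse = ", "))
  y <- match(labels, model$classes)
  model$schema <- schema_of(records[[1]])
  design <- classifier_design(samples, records, model$image_dim)
  with_seed(config$seed, {
    idx_val <- stratified_holdout(y, val_frac)
    tr <- setdiff(seq_along(y), idx_val)
    if (!length(idx_val)) idx_val <- tr   # degenerate tiny datasets
    sc <- list(full = scale_fit(design$full[tr, , drop = FALSE]),
               stat = scale_fit(design$stat[tr, , drop = FALSE]),
               shape = scale_fit(design$shape[tr, , drop = FALSE]))
    model$scaler <- sc
    dz <- list(full = scale_apply(design$full, sc$full),
               stat = scale_apply(design$stat, sc$stat),
               shape = scale_apply(design$shape, sc$shape),
               img = design$img)
    sub_design <- function(i) lapply(dz, function(m) m[i, , drop = FALSE])
    params <- collect_params(model[c("spinal", "fusion", "zfnet")])
    opt <- optimizer(params, config$optimizer, lr = config$lr,
                     weight_decay = config$weight_decay)
    step_fn <- function(epoch, lr) {
      opt$lr <- lr
      ord <- sample(tr)
      losses <- c()
      for (st in seq(1, length(ord), by = config$batch_size)) {
        sel <- ord[st:min(st + config$batch_size - 1, length(ord))]
        ag_zero_grad(params)
        logits <- classifier_forward(model, sub_design(sel), training = TRUE)
        loss <- ag_softmax_ce(logits, y[sel])
        ag_backward(loss)
        opt$step()
        losses <- c(losses, loss$val)
      }
      mean(losses)
    }
    val_fn <- function(epoch) {
      logits <- classifier_forward(model, sub_design(idx_val), training = FALSE)
      mean(max.col(logits$val) == y[idx_val])
    }
    fit <- train_loop(config, step_fn, val_fn,
                      get_state = function() params_get_state(params),
                      set_state = function(s) params_set_state(params, s))
    model$history <- fit
  })
  model
}

## indices of a stratified holdout of roughly `frac` per class; every class
## keeps at least one training sample (singleton classes are never held out)
stratified_holdout <- function(y, frac) {
  unlist(lapply(unique(y), function(cl) {
    i <- which(y == cl)
    k <- min(max(1L, round(frac * length(i))), length(i) - 1L)
    if (k < 1L) return(integer(0))
    sample(i, k)
  }), use.names = FALSE)
}

#' Predict class probabilities for new samples
#'
#' @param model a trained `spinalzfnet_model`.
#' @param samples list of samples with `image` and `kidney_mask`.
#' @param records optional precomputed `feature_record`s (extracted on the
#'   fly otherwise).
#' @return list with `label` (character), `probabilities` (N x 4 matrix,
#'   rows summing to 1).
#' @export
predict_spinalzfnet <- function(model, samples, records = NULL) {
  if (is.null(model$scaler)) stop_arg("model has not been trained")
  if (is.null(records)) records <- extract_records(samples)
  if (schema_of(records[[1]]) != model$schema)
    stop_config("feature schema",
                "records have block layout %s but the model was trained on %s",
                schema_of(records[[1]]), model$schema)
  design <- classifier_design(samples, records, model$image_dim)
  dz <- list(full = scale_apply(design$full, model$scaler$full),
             stat = scale_apply(design$stat, model$scaler$stat),
             shape = scale_apply(design$shape, model$scaler$shape),
             img = design$img)
  logits <- classifier_forward(model, dz, training = FALSE)
  probs <- softmax_rows(logits$val)
  colnames(probs) <- model$classes
  list(label = model$classes[max.col(probs)], probabilities = probs)
}

#' Classify a single image given its mask
#'
#' Convenience wrapper around feature extraction and
#' [predict_spinalzfnet()]; deterministic at inference.
#' @param image numeric matrix in `[0, 1]` (segmented image).
#' @param mask binary kidney mask.
#' @param model trained model.
#' @export
spinalzfnet_predict <- function(image, mask, model) {
  s <- list(image = image, kidney_mask = mask, label = NA)
  r <- predict_spinalzfnet(model, list(s))
  list(label = r$label[1], probabilities = r$probabilities[1, ])
}
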