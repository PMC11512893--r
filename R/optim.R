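## Stochastic optimizers over lists of ag_param nodes.

#' Create an optimizer
#'
#' @param params list of parameter nodes.
#' @param method one of "adam", "sgd", "rmsprop".
#' @param lr learning rate (mutable via `opt$lr <- ...` for schedules).
#' @return environment with a `step()` function that consumes the
#'   accumulated gradients and updates parameter values in place.
#' @keywords internal
optimizer <- function(params, method = c("adam", "sgd", "rmsprop"),
                      lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, momentum = 0.9, weight_decay = 0) {
  method <- match.arg(method)
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim(as.array(p$val))))
  opt$v <- lapply(params, function(p) array(0, dim(as.array(p$val))))
  opt$step <- function() {
    opt$t <- opt$t + 1L
    for (k in seq_along(params)) {
      p <- params[[k]]
      if (is.null(p$grad)) next
      g <- p$grad
      if (method == "adam") {
        opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
        opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
        mhat <- opt$m[[k]] / (1 - beta1^opt$t)
        vhat <- opt$v[[k]] / (1 - beta2^opt$t)
        p$val <- p$val - opt$lr * mhat / (sqrt(vhat) + eps)
      } else if (method == "sgd") {
        opt$m[[k]] <- momentum * opt$m[[k]] + g
        p$val <- p$val - opt$lr * opt$m[[k]]
      } else {
        opt$v[[k]] <- 0.9 * opt$v[[k]] + 0.1 * g * g
        p$val <- p$val - opt$lr * g / (sqrt(opt$v[[k]]) + eps)
      }
    }
    if (weight_decay > 0)
      for (p in params)
        if (isTRUE(p$decay)) p$val <- p$val * (1 - weight_decay)
    invisible(NULL)
  }
  opt
}

#' Snapshot / restore parameter values (model checkpointing)
#' @keywords internal
params_get_state <- function(params) lapply(params, function(p) p$val)

#' @keywords internal
params_set_state <- function(params, state) {
  stopifnot(length(params) == length(state))
  for (k in seq_along(params)) params[[k]]$val <- state[[k]]
  invisible(NULL)
}

## He-style initialization helpers (deterministic under the caller's seed).
init_conv_w <- function(kh, kw, ic, oc) {
  array(stats::rnorm(kh * kw * ic * oc, 0, sqrt(2 / (kh * kw * ic))),
        c(kh, kw, ic, oc))
}
init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}
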