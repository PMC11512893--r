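## Training-control loop: plateau learning-rate halving, early stopping,
## and best-checkpoint restore, all driven by validation accuracy.

#' Training configuration
#'
#' @param optimizer one of "adam", "sgd", "rmsprop".
#' @param batch_size minibatch size (default 32).
#' @param max_epochs epoch budget (default 100).
#' @param lr initial learning rate (default 0.001).
#' @param plateau_patience epochs without improvement of the monitored
#'   validation accuracy before the learning rate is halved (default 5).
#' @param min_delta minimum increase counted as improvement (default 1e-4).
#' @param lr_factor multiplicative factor applied at a plateau (default 0.5).
#' @param early_stop_patience epochs without improvement before training
#'   stops (default 50).
#' @param weight_decay decoupled weight decay applied to the
#'   high-capacity weight matrices after each optimizer step.
#' @param seed RNG seed controlling shuffling and weight draws.
#' @export
train_config <- function(optimizer = "adam", batch_size = 32L,
                         max_epochs = 100L, lr = 1e-3,
                         plateau_patience = 5L, min_delta = 1e-4,
                         lr_factor = 0.5, early_stop_patience = 50L,
                         weight_decay = 2e-3, seed = 1L) {
  if (!optimizer %in% c("adam", "sgd", "rmsprop"))
    stop_config("optimizer", "must be adam, sgd or rmsprop")
  if (lr <= 0) stop_config("lr", "must be positive")
  if (batch_size < 1) stop_config("batch_size", "must be >= 1")
  if (plateau_patience < 1) stop_config("plateau_patience", "must be >= 1")
  if (early_stop_patience < 1) stop_config("early_stop_patience", "must be >= 1")
  structure(list(optimizer = optimizer, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 plateau_patience = as.integer(plateau_patience),
                 min_delta = min_delta, lr_factor = lr_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Generic epoch loop with plateau schedule, early stop and checkpointing
#'
#' Model-agnostic: the caller supplies a training step, a validation
#' metric, and state snapshot/restore callbacks, so the schedule contracts
#' can be exercised with scripted stub models as well as real networks.
#'
#' An epoch counts as an improvement when validation accuracy exceeds the
#' best seen by more than `min_delta`.  After `plateau_patience`
#' consecutive non-improving epochs the learning rate is multiplied by
#' `lr_factor` and the plateau counter resets.  Training stops once
#' `early_stop_patience` epochs have passed since the best epoch, and the
#' best-epoch state is restored before returning.
#'
#' @param config a [train_config()].
#' @param step_fn function(epoch, lr) running one training epoch and
#'   returning its mean loss.
#' @param val_fn function(epoch) returning validation accuracy in `[0, 1]`.
#' @param get_state,set_state checkpoint callbacks.
#' @return list with `history` (data frame: epoch, lr, train_loss,
#'   val_accuracy, improved), `lr_halvings` (epochs at which the rate
#'   dropped), `best_epoch`, `best_accuracy`, `stopped_epoch`.
#' @export
train_loop <- function(config, step_fn, val_fn, get_state, set_state) {
  lr <- config$lr
  best <- -Inf; best_epoch <- 0L; best_state <- NULL
  plateau <- 0L
  halvings <- integer(0)
  hist <- list()
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    loss <- step_fn(epoch, lr)
    acc <- val_fn(epoch)
    improved <- acc > best + config$min_delta
    # the checkpoint keeps the most recent epoch attaining the best
    # validation accuracy (ties refresh it); scheduling uses the strict
    # min_delta improvement criterion
    if (acc >= best) {
      best_state <- get_state()
      best_epoch <- epoch
    }
    if (improved) {
      best <- acc
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= config$plateau_patience) {
        lr <- lr * config$lr_factor
        halvings <- c(halvings, epoch)
        plateau <- 0L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, train_loss = loss,
                                val_accuracy = acc, improved = improved)
    if (epoch - best_epoch >= config$early_stop_patience) {
      stopped <- epoch
      break
    }
  }
  if (!is.null(best_state)) set_state(best_state)
  list(history = do.call(rbind, hist), lr_halvings = halvings,
       best_epoch = best_epoch, best_accuracy = best,
       stopped_epoch = stopped)
}
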