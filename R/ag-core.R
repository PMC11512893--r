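## Minimal reverse-mode automatic differentiation on a dynamic tape.
## Nodes are environments; each op records its parents and a closure that
## maps the incoming gradient to per-parent gradients.  The tape is implicit
## in the node creation order (monotone ids), so backward() is a reverse
## topological sweep.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_next_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

#' Create an autodiff node
#'
#' @param val numeric array/matrix/vector value of the node.
#' @param parents list of parent nodes this value was computed from.
#' @param backfn function(grad) returning a list of gradients, one per
#'   parent (NULL entries allowed for parents that need no gradient).
#' @param req does any parameter lie in this node's ancestry?
#' @keywords internal
ag_node <- function(val, parents = list(), backfn = NULL, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$req <- req
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

#' Constant (gradient-free) leaf
#' @keywords internal
ag_const <- function(val) ag_node(val)

#' Trainable parameter leaf
#' @param decay is this parameter subject to weight decay?  Convention:
#'   high-capacity weight matrices opt in; biases, gains and the
#'   low-dimensional fusion projections stay decay-free.
#' @keywords internal
ag_param <- function(val, decay = FALSE) {
  n <- ag_node(val, req = TRUE)
  n$is_param <- TRUE
  n$decay <- decay
  n
}

ag_subtree_req <- function(parents) {
  for (p in parents) if (isTRUE(p$req)) return(TRUE)
  FALSE
}

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the loss gradient with 1 and sweeps the tape in reverse creation
#' order, accumulating gradients into every reachable node with `req = TRUE`.
#' @param loss an `ag_node` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"), length(loss$val) == 1L)
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !isTRUE(n$req)) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) if (isTRUE(p$req)) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- 1
  for (n in nodes[ord]) {
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (isTRUE(p$req) && !is.null(gs[[k]])) ag_accum(p, gs[[k]])
    }
    if (!isTRUE(n$is_param)) n$grad <- NULL  # free intermediate gradients
  }
  invisible(loss)
}

#' Reset accumulated gradients on a list of parameters
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$val else x
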