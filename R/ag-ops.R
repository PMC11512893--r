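## Dense / elementwise differentiable operations.

#' @keywords internal
ag_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b),
          function(g) list(g, g),
          ag_subtree_req(list(a, b)))
}

#' @keywords internal
ag_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  ag_node(av * bv, list(a, b),
          function(g) list(g * bv, g * av),
          ag_subtree_req(list(a, b)))
}

#' Affine map of a node by scalar constants: y = alpha * x + beta
#' @keywords internal
ag_affine <- function(x, alpha, beta = 0) {
  ag_node(alpha * x$val + beta, list(x),
          function(g) list(alpha * g), x$req)
}

#' @keywords internal
ag_matmul <- function(a, b) {
  av <- a$val; bv <- b$val
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)),
          ag_subtree_req(list(a, b)))
}

#' Row-broadcast bias add: x is (N, M), b length M
#' @keywords internal
ag_bias_rows <- function(x, b) {
  n <- nrow(x$val)
  ag_node(x$val + matrix(b$val, n, length(b$val), byrow = TRUE),
          list(x, b),
          function(g) list(g, colSums(g)),
          ag_subtree_req(list(x, b)))
}

#' Fully connected layer on row-major batches
#' @keywords internal
ag_linear <- function(x, w, b = NULL) {
  y <- ag_matmul(x, w)
  if (!is.null(b)) y <- ag_bias_rows(y, b) else y
}

#' @keywords internal
ag_relu <- function(x) {
  m <- x$val > 0
  ag_node(x$val * m, list(x), function(g) list(g * m), x$req)
}

#' PReLU with a single learnable slope per layer
#' @keywords internal
ag_prelu <- function(x, a) {
  xv <- x$val
  av <- as.numeric(a$val)
  pos <- pmax(xv, 0); neg <- pmin(xv, 0)
  ag_node(pos + av * neg, list(x, a),
          function(g) list(g * ifelse(xv > 0, 1, av), sum(g * neg)),
          ag_subtree_req(list(x, a)))
}

#' @keywords internal
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)), x$req)
}

#' Scale each row of an (N, M) node by the matching scalar of u (N, 1)
#' @keywords internal
ag_rowscale <- function(x, u) {
  xv <- x$val; uv <- as.numeric(u$val)
  ag_node(xv * uv, list(x, u),
          function(g) list(g * uv, matrix(rowSums(g * xv), ncol = 1)),
          ag_subtree_req(list(x, u)))
}

#' Column-wise concatenation of two row-major batches
#' @keywords internal
ag_cbind <- function(a, b) {
  na <- ncol(a$val)
  ag_node(cbind(a$val, b$val), list(a, b),
          function(g) list(g[, seq_len(na), drop = FALSE],
                           g[, -seq_len(na), drop = FALSE]),
          ag_subtree_req(list(a, b)))
}

#' Sum a list of same-shaped nodes
#' @keywords internal
ag_sum_nodes <- function(nodes) {
  v <- nodes[[1]]$val
  for (k in seq_along(nodes)[-1]) v <- v + nodes[[k]]$val
  ag_node(v, nodes,
          function(g) rep(list(g), length(nodes)),
          ag_subtree_req(nodes))
}

#' Fused softmax + cross-entropy over rows of a logit matrix
#'
#' @param logits (N, K) node; @param labels integer class ids in 1..K.
#' @return node whose value is the mean cross-entropy; the fitted class
#'   probabilities are attached as attribute `probs` on the node.
#' @keywords internal
ag_softmax_ce <- function(logits, labels) {
  lv <- logits$val
  n <- nrow(lv)
  m <- lv - apply(lv, 1, max)
  e <- exp(m)
  probs <- e / rowSums(e)
  ll <- -log(pmax(probs[cbind(seq_len(n), labels)], 1e-12))
  node <- ag_node(mean(ll), list(logits),
                  function(g) {
                    d <- probs
                    d[cbind(seq_len(n), labels)] <-
                      d[cbind(seq_len(n), labels)] - 1
                    list(g * d / n)
                  }, logits$req)
  node$probs <- probs
  node
}

#' Softmax probabilities (inference helper, not differentiated)
#' @keywords internal
softmax_rows <- function(logits) {
  m <- logits - apply(logits, 1, max)
  e <- exp(m)
  e / rowSums(e)
}
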