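# Minimal reverse-mode tape used by the segmentation networks. Values are
# dense arrays in (H, W, C, N) layout; the heavy kernels (convolution,
# max-pooling, nearest-neighbour upsampling) live in src/kernels.cpp. Each node
# stores its value, the ids of its parents and a backward closure mapping the
# incoming gradient to one gradient per parent. Gradients are checked against
# numerical differentiation in the test suite.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

ag_node <- function(g, value, parents = integer(0), bwd = NULL) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(value = value, parents = parents, bwd = bwd)
  id
}

ag_value <- function(g, id) {
  force(id) # a lazily evaluated id expression may itself append nodes
  g$nodes[[id]]$value
}

ag_input <- function(g, x) ag_node(g, x)

ag_conv <- function(g, x, w, b) {
  xv <- ag_value(g, x); wv <- ag_value(g, w); bv <- ag_value(g, b)
  out <- cpp_conv_fwd(xv, wv, bv)
  ag_node(g, out, c(x, w, b), function(grad) {
    d <- cpp_conv_bwd(xv, wv, grad)
    list(d$dx, d$dw, d$db)
  })
}

ag_relu <- function(g, x) {
  xv <- ag_value(g, x)
  pos <- xv > 0
  ag_node(g, xv * pos, x, function(grad) list(grad * pos))
}

ag_maxpool <- function(g, x, f) {
  xv <- ag_value(g, x)
  r <- cpp_maxpool_fwd(xv, as.integer(f))
  xd <- dim(xv)
  ag_node(g, r$out, x, function(grad) list(cpp_maxpool_bwd(r$argmax, grad, xd)))
}

ag_upsample <- function(g, x, f) {
  xv <- ag_value(g, x)
  ag_node(g, cpp_upsample_fwd(xv, as.integer(f)), x,
          function(grad) list(cpp_upsample_bwd(grad, as.integer(f))))
}

# Concatenate along the channel dimension (dim 3).
ag_concat <- function(g, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) ag_value(g, i))
  dims <- lapply(vals, dim)
  nch <- vapply(dims, `[`, 0L, 3L)
  d0 <- dims[[1]]
  out <- array(0, c(d0[1], d0[2], sum(nch), d0[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    out[, , at + seq_len(nch[i]), ] <- vals[[i]]
    at <- at + nch[i]
  }
  ag_node(g, out, ids, function(grad) {
    at <- 0L
    lapply(seq_along(ids), function(i) {
      sl <- grad[, , at + seq_len(nch[i]), , drop = FALSE]
      at <<- at + nch[i]
      array(sl, dims[[i]])
    })
  })
}

# Instance normalisation with affine parameters: each (channel, sample) map
# is standardised over its spatial extent, then scaled and shifted per
# channel. No running state, so training and inference are identical.
ag_instnorm <- function(g, x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(g, x)
  gv <- ag_value(g, gamma)
  bv <- ag_value(g, beta)
  d <- dim(xv)
  HW <- d[1] * d[2]
  xm <- matrix(xv, HW, d[3] * d[4])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = HW)
  s <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc / rep(s, each = HW)
  gcn <- rep(rep(gv, times = d[4]), each = HW)
  y <- xhat * gcn + rep(rep(bv, times = d[4]), each = HW)
  ag_node(g, array(y, d), c(x, gamma, beta), function(grad) {
    gm <- matrix(grad, HW, d[3] * d[4])
    dxhat <- gm * gcn
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = HW) - xhat * rep(m2, each = HW)) /
      rep(s, each = HW)
    list(array(dx, d),
         rowSums(matrix(colSums(gm * xhat), d[3], d[4])),
         rowSums(matrix(colSums(gm), d[3], d[4])))
  })
}

# Mean binary cross-entropy from logits (numerically stable form):
# mean over all elements of max(z,0) - z*t + log(1 + exp(-|z|)).
ag_bce_logits <- function(g, x, target) {
  z <- ag_value(g, x)
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  ag_node(g, loss, x, function(grad) {
    list(grad * (stats::plogis(z) - target) / n)
  })
}

# Mean of scalar nodes (used to weight deep-supervision heads equally).
ag_mean_scalars <- function(g, ids) {
  ids <- as.integer(unlist(ids))
  vals <- vapply(ids, function(i) ag_value(g, i), 0)
  k <- length(ids)
  ag_node(g, mean(vals), ids, function(grad) rep(list(grad / k), k))
}

ag_backward <- function(g, id) {
  n <- length(g$nodes)
  grads <- vector("list", n)
  grads[[id]] <- 1
  for (i in seq.int(n, 1L)) {
    node <- g$nodes[[i]]
    gr <- grads[[i]]
    if (is.null(gr) || is.null(node$bwd)) next
    pg <- node$bwd(gr)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[i] <- list(NULL) # free as we go
  }
  grads
}
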