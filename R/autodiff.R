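# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records every operation as a node holding its value, its parent
# nodes and a backward closure mapping the incoming gradient to parent
# gradients.  Values are plain numeric matrices (scalars are 1x1).  The
# engine implements exactly the primitives the network needs: affine maps,
# elementwise nonlinearities, gather/scatter over row indices (for graph
# message passing), grouped and masked softmax (for edge attention and
# cross-attention), layer normalization, and the two loss kernels (Huber,
# binary cross-entropy from the logit).  Gradient correctness is checked
# against central finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$param_ids <- integer(0)
  class(tp) <- "ad_tape"
  tp
}

# Nodes are immutable once created, so plain lists (cheap) rather than
# environments; only the tape itself is mutable.
ad_node <- function(tape, value, parents = integer(0), backfn = NULL, name = NULL) {
  n <- tape$n + 1L
  tape$n <- n
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd <- list(value = value, parents = parents, backfn = backfn, name = name, id = n)
  class(nd) <- "ad_node"
  tape$nodes[[n]] <- nd
  nd
}

is_ad_node <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad_node(x)) x$value else x

# Leaf holding a trainable parameter; `name` keys the gradient on collection.
ad_param <- function(tape, value, name) {
  nd <- ad_node(tape, value, name = name)
  tape$param_ids <- c(tape$param_ids, nd$id)
  nd
}

ad_const <- function(x) x  # constants stay raw; ops treat non-nodes as constant

# Reverse sweep from a scalar node; returns gradients indexed by node id.
ad_backward <- function(tape, loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      pid <- ps[[k]]
      grads[[pid]] <- if (is.null(grads[[pid]])) gk else grads[[pid]] + gk
    }
  }
  grads
}

# Collect gradients for named parameter leaves; absent => exact zero.
ad_param_grads <- function(tape, grads) {
  out <- list()
  for (i in tape$param_ids) {
    nd <- tape$nodes[[i]]
    g <- grads[[nd$id]]
    if (is.null(g)) {
      g <- if (is.null(dim(nd$value))) numeric(length(nd$value))
           else array(0, dim(nd$value))
    }
    out[[nd$name]] <- g
  }
  out
}

## ---- primitives ------------------------------------------------------------

# Matrix product.  Either argument may be a constant matrix.
op_mm <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- av %*% bv
  parents <- integer(0); slot_a <- 0L; slot_b <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g %*% t(bv)
    if (slot_b > 0L) pg[[slot_b]] <- t(av) %*% g
    pg
  })
}

# Elementwise sum; b may also be a length-ncol(a) bias vector broadcast
# across rows (gradient is the column sum).
op_add <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  bias <- !is.matrix(bv) && length(bv) == ncol(av)
  v <- if (bias) t(t(av) + bv) else av + bv
  parents <- integer(0); slot_a <- 0L; slot_b <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g
    if (slot_b > 0L) pg[[slot_b]] <- if (bias) colSums(g) else g
    pg
  })
}

op_sub <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  parents <- integer(0); slot_a <- 0L; slot_b <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, av - bv, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g
    if (slot_b > 0L) pg[[slot_b]] <- -g
    pg
  })
}

# Hadamard product with a constant or node of identical shape.
op_mul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  parents <- integer(0); slot_a <- 0L; slot_b <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, av * bv, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g * bv
    if (slot_b > 0L) pg[[slot_b]] <- g * av
    pg
  })
}

# Multiply by a scalar (node or numeric).
op_scale <- function(tape, a, s) {
  av <- ad_value(a); sv <- as.numeric(ad_value(s))
  parents <- integer(0); slot_a <- 0L; slot_s <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(s)) { parents <- c(parents, s$id); slot_s <- length(parents) }
  ad_node(tape, av * sv, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g * sv
    if (slot_s > 0L) pg[[slot_s]] <- matrix(sum(g * av), 1L, 1L)
    pg
  })
}

# Scale row i of x by v[i].
op_rowscale <- function(tape, x, v) {
  xv <- ad_value(x); vv <- as.numeric(ad_value(v))
  parents <- integer(0); slot_x <- 0L; slot_v <- 0L
  if (is_ad_node(x)) { parents <- c(parents, x$id); slot_x <- length(parents) }
  if (is_ad_node(v)) { parents <- c(parents, v$id); slot_v <- length(parents) }
  ad_node(tape, xv * vv, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_x > 0L) pg[[slot_x]] <- g * vv
    if (slot_v > 0L) pg[[slot_v]] <- matrix(rowSums(g * xv), ncol = 1L)
    pg
  })
}

op_leaky_relu <- function(tape, x, slope = 0.05) {
  xv <- ad_value(x)
  neg <- xv <= 0
  v <- xv
  v[neg] <- slope * xv[neg]
  if (!is_ad_node(x)) return(ad_node(tape, v))
  dmask <- array(1, dim(as.matrix(xv)))
  dmask[neg] <- slope
  ad_node(tape, v, x$id, function(g) list(g * dmask))
}

op_sigmoid <- function(tape, x) {
  xv <- ad_value(x)
  v <- 1 / (1 + exp(-xv))
  if (!is_ad_node(x)) return(ad_node(tape, v))
  ad_node(tape, v, x$id, function(g) list(g * v * (1 - v)))
}

op_tanh <- function(tape, x) {
  xv <- ad_value(x)
  v <- tanh(xv)
  if (!is_ad_node(x)) return(ad_node(tape, v))
  ad_node(tape, v, x$id, function(g) list(g * (1 - v^2)))
}

op_exp <- function(tape, x) {
  v <- exp(ad_value(x))
  if (!is_ad_node(x)) return(ad_node(tape, v))
  ad_node(tape, v, x$id, function(g) list(g * v))
}

# Clamp with zero gradient outside [lo, hi] (subgradient convention).
op_clamp <- function(tape, x, lo, hi) {
  xv <- ad_value(x)
  v <- pmin(pmax(xv, lo), hi)
  if (!is_ad_node(x)) return(ad_node(tape, v))
  pass <- (xv > lo & xv < hi) * 1
  ad_node(tape, v, x$id, function(g) list(g * pass))
}

# Row gather: value x[idx, ]; backward scatter-adds into the source rows.
op_gather <- function(tape, x, idx) {
  xv <- ad_value(x)
  idx <- as.integer(idx)
  v <- xv[idx, , drop = FALSE]
  if (!is_ad_node(x)) return(ad_node(tape, v))
  nr <- nrow(xv); nc <- ncol(xv)
  ad_node(tape, v, x$id, function(g) {
    out <- matrix(0, nr, nc)
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# Scatter-sum rows of x into n_out bins given by idx; backward is a gather.
op_scatter_sum <- function(tape, x, idx, n_out) {
  xv <- ad_value(x)
  idx <- as.integer(idx)
  out <- matrix(0, n_out, ncol(xv))
  rs <- rowsum(xv, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  if (!is_ad_node(x)) return(ad_node(tape, out))
  ad_node(tape, out, x$id, function(g) list(g[idx, , drop = FALSE]))
}

# Softmax of a column-vector of logits within groups (edge attention over
# the in-edges of each node).  Groups must cover 1..max(groups) (guaranteed
# here by self-loops).
op_group_softmax <- function(tape, x, groups) {
  xv <- as.numeric(ad_value(x))
  groups <- as.integer(groups)
  # shift-free when logits are safely inside exp()'s range: keeps each
  # group's softmax numerically independent of the others (bitwise locality
  # across graph components); per-group max shift only for extreme logits
  if (max(abs(xv)) < 50) {
    e <- exp(xv)
  } else {
    mx <- as.numeric(tapply(xv, groups, max))
    e <- exp(xv - mx[groups])
  }
  s <- rowsum(e, groups)           # rows ordered by group id 1..n
  p <- e / s[groups]
  vmat <- matrix(p, ncol = 1L)
  if (!is_ad_node(x)) return(ad_node(tape, vmat))
  ad_node(tape, vmat, x$id, function(g) {
    gv <- as.numeric(g)
    inner <- rowsum(p * gv, groups)[groups]
    list(matrix(p * (gv - inner), ncol = 1L))
  })
}

# Row-wise softmax of a score matrix with a key mask (TRUE = attendable).
# Masked keys get exactly zero probability (-Inf pre-softmax).
op_masked_softmax <- function(tape, scores, mask = NULL) {
  sv <- ad_value(scores)
  if (is.null(mask)) mask <- rep(TRUE, ncol(sv))
  mask <- as.logical(mask)
  if (!any(mask)) stop("masked softmax: all keys are masked out")
  s2 <- sv
  s2[, !mask] <- -Inf
  mx <- s2[cbind(seq_len(nrow(s2)), max.col(s2, ties.method = "first"))]
  e <- exp(s2 - mx)
  e[, !mask] <- 0
  p <- e / rowSums(e)
  if (!is_ad_node(scores)) return(ad_node(tape, p))
  ad_node(tape, p, scores$id, function(g) {
    inner <- rowSums(p * g)
    list(p * (g - inner))
  })
}

# Row-wise layer normalization with learnable gain/bias vectors.
op_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ad_value(x); gv <- as.numeric(ad_value(gamma)); bv <- as.numeric(ad_value(beta))
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- t(t(xhat) * gv + bv)
  parents <- integer(0); slot_x <- 0L; slot_g <- 0L; slot_b <- 0L
  if (is_ad_node(x)) { parents <- c(parents, x$id); slot_x <- length(parents) }
  if (is_ad_node(gamma)) { parents <- c(parents, gamma$id); slot_g <- length(parents) }
  if (is_ad_node(beta)) { parents <- c(parents, beta$id); slot_b <- length(parents) }
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    gxhat <- t(t(g) * gv)
    if (slot_x > 0L) {
      m1 <- rowMeans(gxhat)
      m2 <- rowMeans(gxhat * xhat)
      pg[[slot_x]] <- inv * (gxhat - m1 - xhat * m2)
    }
    if (slot_g > 0L) pg[[slot_g]] <- colSums(g * xhat)
    if (slot_b > 0L) pg[[slot_b]] <- colSums(g)
    pg
  })
}

# Column slice (used to split multi-head projections).
op_cols <- function(tape, x, cols) {
  xv <- ad_value(x)
  cols <- as.integer(cols)
  v <- xv[, cols, drop = FALSE]
  if (!is_ad_node(x)) return(ad_node(tape, v))
  nr <- nrow(xv); nc <- ncol(xv)
  ad_node(tape, v, x$id, function(g) {
    out <- matrix(0, nr, nc)
    out[, cols] <- g
    list(out)
  })
}

# Column-bind a list of nodes/constants.
op_cbind <- function(tape, xs) {
  vals <- lapply(xs, ad_value)
  v <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, 0L)
  parents <- integer(0); slots <- integer(length(xs))
  for (k in seq_along(xs)) {
    if (is_ad_node(xs[[k]])) { parents <- c(parents, xs[[k]]$id); slots[k] <- length(parents) }
  }
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    for (k in seq_along(xs)) {
      if (slots[k] > 0L) pg[[slots[k]]] <- g[, starts[k]:ends[k], drop = FALSE]
    }
    pg
  })
}

op_rbind <- function(tape, xs) {
  vals <- lapply(xs, ad_value)
  v <- do.call(rbind, vals)
  heights <- vapply(vals, nrow, 0L)
  parents <- integer(0); slots <- integer(length(xs))
  for (k in seq_along(xs)) {
    if (is_ad_node(xs[[k]])) { parents <- c(parents, xs[[k]]$id); slots[k] <- length(parents) }
  }
  ends <- cumsum(heights); starts <- ends - heights + 1L
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    for (k in seq_along(xs)) {
      if (slots[k] > 0L) pg[[slots[k]]] <- g[starts[k]:ends[k], , drop = FALSE]
    }
    pg
  })
}

op_sum <- function(tape, x) {
  xv <- ad_value(x)
  v <- matrix(sum(xv), 1L, 1L)
  if (!is_ad_node(x)) return(ad_node(tape, v))
  ad_node(tape, v, x$id, function(g) {
    list(array(as.numeric(g), dim(xv)))
  })
}

op_mean_rows <- function(tape, x) {
  xv <- ad_value(x)
  n <- nrow(xv)
  v <- matrix(colMeans(xv), 1L)
  if (!is_ad_node(x)) return(ad_node(tape, v))
  ad_node(tape, v, x$id, function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

# Huber loss of a scalar prediction against a constant label.
op_huber <- function(tape, pred, label, delta) {
  pv <- as.numeric(ad_value(pred))
  e <- pv - label
  v <- if (abs(e) <= delta) 0.5 * e^2 else delta * (abs(e) - 0.5 * delta)
  v <- matrix(v, 1L, 1L)
  if (!is_ad_node(pred)) return(ad_node(tape, v))
  de <- if (abs(e) <= delta) e else delta * sign(e)
  ad_node(tape, v, pred$id, function(g) list(matrix(as.numeric(g) * de, 1L, 1L)))
}

# Numerically stable binary cross-entropy taking the (pre-sigmoid) logit.
op_bce_logit <- function(tape, logit, target) {
  z <- as.numeric(ad_value(logit))
  v <- matrix(max(z, 0) - z * target + log1p(exp(-abs(z))), 1L, 1L)
  if (!is_ad_node(logit)) return(ad_node(tape, v))
  dz <- 1 / (1 + exp(-z)) - target
  ad_node(tape, v, logit$id, function(g) list(matrix(as.numeric(g) * dz, 1L, 1L)))
}


# Fused affine map x %*% W + bias (one node instead of two).
op_linear <- function(tape, x, W, b) {
  xv <- ad_value(x); Wv <- ad_value(W); bv <- as.numeric(ad_value(b))
  v <- t(t(xv %*% Wv) + bv)
  parents <- integer(0); slot_x <- 0L; slot_w <- 0L; slot_b <- 0L
  if (is_ad_node(x)) { parents <- c(parents, x$id); slot_x <- length(parents) }
  if (is_ad_node(W)) { parents <- c(parents, W$id); slot_w <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_x > 0L) pg[[slot_x]] <- g %*% t(Wv)
    if (slot_w > 0L) pg[[slot_w]] <- t(xv) %*% g
    if (slot_b > 0L) pg[[slot_b]] <- colSums(g)
    pg
  })
}
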