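# The screening network: attention-based graph convolutions interleaved with
# cross-attention graph blocks over frozen per-residue protein latents,
# commutative pooling, and five prediction heads (four affinities + a
# temperature-scaled, clipped binder-vs-decoy logit).

BIND_CHECKPOINT_VERSION <- 1L

#' Model configuration
#'
#' @param d_hidden Hidden width of node states (default 64).
#' @param n_attention_heads Number of cross-attention heads; must divide
#'   `d_hidden`.
#' @param encoder_layer_indices Encoder depths of the protein embedder whose
#'   latents are cross-attended to, consumed in ascending order, one per
#'   block.  The paper-faithful preset for a 33-layer ESM-2-class embedder is
#'   `c(1, 11, 21, 31)`; the desk-scale default targets the built-in toy
#'   embedder's depths `c(0, 1, 2, 3)`.
#' @param n_blocks Number of conv + cross-attention + feed-forward blocks;
#'   must equal `length(encoder_layer_indices)`.
#' @param dropout Dropout fraction applied to the cross-attention weights
#'   during training (default 0.1).
#' @param leaky_slope Negative slope of the leaky ReLU activations
#'   (default 0.05).
#' @param tau_init Initial value of the trainable temperature scaling the
#'   classifier logit (default 0.07; the logit is multiplied by `exp(tau)`).
#' @param logit_clip Symmetric clipping bound on the scaled logit
#'   (default 100).
#' @param pooling Node-to-graph pooling: `"lcm"` (learnable commutative
#'   monoid reduced over a balanced binary tree), `"sum"`, or `"mean"`.
#' @param pre_norm Use pre-norm residual blocks instead of the default
#'   post-norm (transformer-decoder style) placement.
#' @param seed Integer seed for parameter initialization.
#' @return A `bind_config` list.
#' @export
bind_config <- function(d_hidden = 64L, n_attention_heads = 4L,
                        encoder_layer_indices = c(0L, 1L, 2L, 3L),
                        n_blocks = length(encoder_layer_indices),
                        dropout = 0.1, leaky_slope = 0.05,
                        tau_init = 0.07, logit_clip = 100,
                        pooling = c("lcm", "sum", "mean"),
                        pre_norm = FALSE, seed = 1L) {
  pooling <- match.arg(pooling)
  encoder_layer_indices <- as.integer(encoder_layer_indices)
  if (n_blocks != length(encoder_layer_indices)) {
    stop("n_blocks must equal length(encoder_layer_indices)")
  }
  if (is.unsorted(encoder_layer_indices, strictly = TRUE)) {
    stop("encoder_layer_indices must be strictly increasing")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (logit_clip <= 0) stop("logit_clip must be positive")
  if (d_hidden %% n_attention_heads != 0L) {
    stop("n_attention_heads must divide d_hidden")
  }
  structure(list(
    d_hidden = as.integer(d_hidden),
    n_attention_heads = as.integer(n_attention_heads),
    encoder_layer_indices = encoder_layer_indices,
    n_blocks = as.integer(n_blocks),
    dropout = dropout, leaky_slope = leaky_slope,
    tau_init = tau_init, logit_clip = logit_clip,
    pooling = pooling, pre_norm = pre_norm,
    d_node = length(node_feature_names()),
    d_edge = length(edge_feature_names()),
    seed = as.integer(seed)
  ), class = "bind_config")
}

# Run code under a temporary RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a model
#'
#' Builds the full trainable parameter set (Xavier-uniform weights, zero
#' biases, unit layer-norm gains, and the temperature `tau` at its
#' configured initial value).  The protein embedder is not part of the
#' parameter set: it is frozen by construction.
#'
#' @param config A [bind_config()].
#' @param d_latent Width of the protein embedder latents that will be
#'   cross-attended to.
#' @return A `bind_model`: list with `config`, `params` (named list of
#'   matrices), and `d_latent`.
#' @export
bind_model <- function(config, d_latent) {
  stopifnot(inherits(config, "bind_config"))
  d <- config$d_hidden
  P <- list()
  with_seed(config$seed, {
    P[["embed.W"]] <- .xavier(config$d_node, d)
    P[["embed.b"]] <- numeric(d)
    for (b in seq_len(config$n_blocks)) {
      pre <- sprintf("conv%d.", b)
      P[[paste0(pre, "W_src")]] <- .xavier(d, d)
      P[[paste0(pre, "W_tgt")]] <- .xavier(d, d)
      P[[paste0(pre, "W_edge")]] <- .xavier(config$d_edge, d)
      P[[paste0(pre, "a")]] <- .xavier(d, 1L)
      P[[paste0(pre, "b_out")]] <- numeric(d)
      P[[paste0(pre, "ln_g")]] <- rep(1, d)
      P[[paste0(pre, "ln_b")]] <- numeric(d)
      pre <- sprintf("xatt%d.", b)
      P[[paste0(pre, "adapt.W")]] <- .xavier(d_latent, d)
      P[[paste0(pre, "adapt.b")]] <- numeric(d)
      P[[paste0(pre, "adapt_ln.g")]] <- rep(1, d)
      P[[paste0(pre, "adapt_ln.b")]] <- numeric(d)
      P[[paste0(pre, "Wq")]] <- .xavier(d, d)
      P[[paste0(pre, "Wk")]] <- .xavier(d, d)
      P[[paste0(pre, "Wv")]] <- .xavier(d, d)
      P[[paste0(pre, "Wo")]] <- .xavier(d, d)
      P[[paste0(pre, "bo")]] <- numeric(d)
      P[[paste0(pre, "ln_g")]] <- rep(1, d)
      P[[paste0(pre, "ln_b")]] <- numeric(d)
      pre <- sprintf("ffn%d.", b)
      P[[paste0(pre, "W1")]] <- .xavier(d, d)
      P[[paste0(pre, "b1")]] <- numeric(d)
      P[[paste0(pre, "W2")]] <- .xavier(d, d)
      P[[paste0(pre, "b2")]] <- numeric(d)
      P[[paste0(pre, "ln_g")]] <- rep(1, d)
      P[[paste0(pre, "ln_b")]] <- numeric(d)
    }
    if (config$pooling == "lcm") {
      P[["lcm.W1"]] <- .xavier(2L * d, d)
      P[["lcm.b1"]] <- numeric(d)
      P[["lcm.W2"]] <- .xavier(d, d)
      P[["lcm.b2"]] <- numeric(d)
    }
    P[["pool_ln.g"]] <- rep(1, d)
    P[["pool_ln.b"]] <- numeric(d)
    # heads see the pooled hidden state plus the molecule's mean raw node
    # features (input skip: composition is linearly visible to every head)
    for (h in c("pKi", "pKd", "pIC50", "pEC50", "logit")) {
      pre <- sprintf("head_%s.", h)
      P[[paste0(pre, "W1")]] <- .xavier(d + config$d_node, d)
      P[[paste0(pre, "b1")]] <- numeric(d)
      P[[paste0(pre, "W2")]] <- .xavier(d, 1L)
      P[[paste0(pre, "b2")]] <- numeric(1L)
    }
    P[["tau"]] <- matrix(config$tau_init, 1L, 1L)
  })
  structure(list(config = config, params = P, d_latent = as.integer(d_latent)),
            class = "bind_model")
}

#' Count trainable parameters
#' @param model A `bind_model`.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

## ---- tape builders (shared by training and the exposed operations) ---------

# Multi-head scaled dot-product cross-attention of node states over residue
# latents.  `mask` marks attendable residues; masked keys receive exactly
# zero weight.  Returns the attended output (pre-residual) and, on request,
# the per-head attention matrices.
.attend <- function(tape, H, E, mask, p, n_heads, drop_mask = NULL,
                    want_attention = FALSE) {
  d <- ncol(ad_value(H))
  dk <- d %/% n_heads
  Q <- op_linear(tape, H, p$Wq, if (is.null(p$bq)) numeric(d) else p$bq)
  K <- op_mm(tape, E, p$Wk)
  V <- op_mm(tape, E, p$Wv)
  outs <- vector("list", n_heads)
  att <- if (want_attention) vector("list", n_heads) else NULL
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- op_cols(tape, Q, cols)
    Kh <- op_cols(tape, K, cols)
    Vh <- op_cols(tape, V, cols)
    scores <- op_scale(tape, op_mm_nt(tape, Qh, Kh), 1 / sqrt(dk))
    A <- op_masked_softmax(tape, scores, mask)
    if (!is.null(drop_mask)) A <- op_mul(tape, A, drop_mask[[h]])
    if (want_attention) att[[h]] <- ad_value(A)
    outs[[h]] <- op_mm(tape, A, Vh)
  }
  O <- op_cbind(tape, outs)
  out <- op_linear(tape, O, p$Wo, p$bo)
  list(out = out, attention = att)
}

# a %*% t(b) as one primitive (keeps the tape free of explicit transposes).
op_mm_nt <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- av %*% t(bv)
  parents <- integer(0); slot_a <- 0L; slot_b <- 0L
  if (is_ad_node(a)) { parents <- c(parents, a$id); slot_a <- length(parents) }
  if (is_ad_node(b)) { parents <- c(parents, b$id); slot_b <- length(parents) }
  ad_node(tape, v, parents, function(g) {
    pg <- vector("list", length(parents))
    if (slot_a > 0L) pg[[slot_a]] <- g %*% bv
    if (slot_b > 0L) pg[[slot_b]] <- t(g) %*% av
    pg
  })
}

# GATv2-style dynamic-attention convolution over directed edges with edge
# features in the attention logit; self-loops (zero edge features) included.
.gatv2 <- function(tape, H, edge_index, edge_features, p, n_nodes, leaky_slope) {
  src <- c(edge_index[, 1L], seq_len(n_nodes))
  tgt <- c(edge_index[, 2L], seq_len(n_nodes))
  ef <- rbind(edge_features,
              matrix(0, n_nodes, ncol(edge_features)))
  S <- op_mm(tape, H, p$W_src)
  Tt <- op_mm(tape, H, p$W_tgt)
  Ef <- op_mm(tape, ef, p$W_edge)
  Z <- op_add(tape, op_add(tape, op_gather(tape, S, src), op_gather(tape, Tt, tgt)), Ef)
  U <- op_leaky_relu(tape, Z, leaky_slope)
  logits <- op_mm(tape, U, p$a)
  alpha <- op_group_softmax(tape, logits, tgt)
  msg <- op_rowscale(tape, op_gather(tape, S, src), alpha)
  out <- op_scatter_sum(tape, msg, tgt, n_nodes)
  op_add(tape, out, p$b_out)
}

# Learnable-commutative-monoid reduction of one graph's node rows over a
# balanced binary tree.  The binary operator acts on the symmetric pair
# encoding [a + b, a * b], so it is commutative by construction; the tree
# shape (not the pair order) is the only residual order sensitivity.
.lcm_reduce <- function(tape, rows, p, leaky_slope) {
  n <- length(rows)
  if (n == 1L) return(rows[[1L]])
  half <- n %/% 2L
  a <- .lcm_reduce(tape, rows[seq_len(half)], p, leaky_slope)
  b <- .lcm_reduce(tape, rows[(half + 1L):n], p, leaky_slope)
  s <- op_add(tape, a, b)
  m <- op_mul(tape, a, b)
  x <- op_cbind(tape, list(s, m))
  h <- op_leaky_relu(tape, op_linear(tape, x, p$W1, p$b1), leaky_slope)
  op_linear(tape, h, p$W2, p$b2)
}

.pool <- function(tape, H, membership, n_graphs, mode, p, leaky_slope) {
  counts <- tabulate(membership, nbins = n_graphs)
  if (any(counts == 0L)) stop("pooling: a graph has zero nodes")
  if (mode == "sum") {
    op_scatter_sum(tape, H, membership, n_graphs)
  } else if (mode == "mean") {
    s <- op_scatter_sum(tape, H, membership, n_graphs)
    op_rowscale(tape, s, 1 / counts)
  } else {
    pooled <- lapply(seq_len(n_graphs), function(k) {
      idx <- which(membership == k)
      rows <- lapply(idx, function(i) op_gather(tape, H, i))
      .lcm_reduce(tape, rows, p, leaky_slope)
    })
    op_rbind(tape, pooled)
  }
}

.head <- function(tape, pooled, p, leaky_slope) {
  h <- op_leaky_relu(tape, op_add(tape, op_mm(tape, pooled, p$W1), p$b1), leaky_slope)
  op_add(tape, op_mm(tape, h, p$W2), p$b2)
}

.sub_params <- function(P, prefix) {
  keys <- names(P)[startsWith(names(P), prefix)]
  out <- P[keys]
  names(out) <- substring(keys, nchar(prefix) + 1L)
  out
}

# Full forward pass on a tape.  `P` holds parameter nodes (training) or raw
# matrices (inference); `stack_layers` is the list of residue-latent matrices
# matching the configured encoder layers, in order.
.bind_forward <- function(tape, P, config, batch, stack_layers, training = FALSE) {
  n <- nrow(batch$node_features)
  H <- op_linear(tape, batch$node_features, P[["embed.W"]], P[["embed.b"]])
  slope <- config$leaky_slope
  for (b in seq_len(config$n_blocks)) {
    cp <- .sub_params(P, sprintf("conv%d.", b))
    xp <- .sub_params(P, sprintf("xatt%d.", b))
    fp <- .sub_params(P, sprintf("ffn%d.", b))
    E <- stack_layers[[b]]
    # The adapter ends in a layer norm so keys/values enter the attention at
    # unit scale regardless of the embedder's native latent scale.
    Ead <- op_layernorm(tape,
                        op_linear(tape, E, xp[["adapt.W"]], xp[["adapt.b"]]),
                        xp[["adapt_ln.g"]], xp[["adapt_ln.b"]])
    drop_mask <- NULL
    if (training && config$dropout > 0) {
      L <- nrow(E)
      drop_mask <- lapply(seq_len(config$n_attention_heads), function(h) {
        keep <- matrix(stats::runif(n * L) >= config$dropout, n, L)
        keep / (1 - config$dropout)
      })
    }
    if (config$pre_norm) {
      Hn <- op_layernorm(tape, H, cp$ln_g, cp$ln_b)
      conv <- .gatv2(tape, Hn, batch$edge_index, batch$edge_features, cp, n, slope)
      H <- op_add(tape, H, conv)
      Hn <- op_layernorm(tape, H, xp$ln_g, xp$ln_b)
      at <- .attend(tape, Hn, Ead, NULL, xp, config$n_attention_heads, drop_mask)
      H <- op_add(tape, H, at$out)
      Hn <- op_layernorm(tape, H, fp$ln_g, fp$ln_b)
      f <- op_linear(tape, op_leaky_relu(tape,
             op_linear(tape, Hn, fp$W1, fp$b1), slope), fp$W2, fp$b2)
      H <- op_add(tape, H, f)
    } else {
      conv <- .gatv2(tape, H, batch$edge_index, batch$edge_features, cp, n, slope)
      H <- op_layernorm(tape, op_add(tape, H, conv), cp$ln_g, cp$ln_b)
      at <- .attend(tape, H, Ead, NULL, xp, config$n_attention_heads, drop_mask)
      H <- op_layernorm(tape, op_add(tape, H, at$out), xp$ln_g, xp$ln_b)
      f <- op_linear(tape, op_leaky_relu(tape,
             op_linear(tape, H, fp$W1, fp$b1), slope), fp$W2, fp$b2)
      H <- op_layernorm(tape, op_add(tape, H, f), fp$ln_g, fp$ln_b)
    }
  }
  pooled <- .pool(tape, H, batch$membership, batch$n_graphs, config$pooling,
                  .sub_params(P, "lcm."), slope)
  # The pooled representation is layer-normalized before the heads so the
  # head input scale is independent of molecule size and pooling mode.
  pooled <- op_layernorm(tape, pooled, P[["pool_ln.g"]], P[["pool_ln.b"]])
  # input skip: mean raw node features per graph (constant w.r.t. params)
  counts <- tabulate(batch$membership, nbins = batch$n_graphs)
  raw_mean <- rowsum(batch$node_features, batch$membership) / counts
  pooled <- op_cbind(tape, list(pooled, raw_mean))
  heads <- list()
  for (h in c("pKi", "pKd", "pIC50", "pEC50", "logit")) {
    heads[[h]] <- .head(tape, pooled, .sub_params(P, sprintf("head_%s.", h)), slope)
  }
  raw <- heads[["logit"]]
  scaled <- op_clamp(tape, op_scale(tape, raw, op_exp(tape, P[["tau"]])),
                     -config$logit_clip, config$logit_clip)
  list(pKi = heads$pKi, pKd = heads$pKd, pIC50 = heads$pIC50,
       pEC50 = heads$pEC50, logit_raw = raw, logit = scaled, pooled = pooled)
}

# Pull the residue-latent matrices matching the configured encoder layers.
.stack_for_config <- function(stack, config) {
  if (!identical(as.integer(stack$layer_indices),
                 as.integer(config$encoder_layer_indices))) {
    stop(sprintf(
      "embedding stack carries layers [%s] but the model expects [%s]",
      paste(stack$layer_indices, collapse = ","),
      paste(config$encoder_layer_indices, collapse = ",")))
  }
  stack$layers
}

#' Predict affinities and the binder-vs-decoy logit
#'
#' Runs the network in evaluation mode (no dropout; deterministic for fixed
#' parameters).
#'
#' @param model A `bind_model`.
#' @param graphs A `molgraph`, a list of them, or a `batched_molgraph`.
#' @param stack A `residue_embedding_stack` for the protein, carrying exactly
#'   the encoder layers the model was configured with.
#' @return Data frame with one row per graph: `pKi`, `pKd`, `pIC50`, `pEC50`
#'   (in -log10 molar units), the scaled and clipped `logit`, and
#'   `probability = sigmoid(logit)`.
#' @export
bind_predict <- function(model, graphs, stack) {
  stopifnot(inherits(model, "bind_model"))
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  if (inherits(graphs, "batched_molgraph")) graphs <- unbatch_graphs(graphs)
  layers <- .stack_for_config(stack, model$config)
  if (.kernel_supported(model$config)) {
    recs <- lapply(graphs, function(g) {
      .kernel_record(.kernel_graph(g), layers, rep(NA_real_, 4L), FALSE)
    })
    pm <- .kernel_predict(model$params, recs, model$config)
    out <- as.data.frame(pm)
    out$probability <- 1 / (1 + exp(-out$logit))
    return(out)
  }
  batch <- batch_graphs(graphs)
  tape <- ad_tape()
  out <- .bind_forward(tape, model$params, model$config, batch, layers,
                       training = FALSE)
  logit <- as.numeric(ad_value(out$logit))
  data.frame(
    pKi = as.numeric(ad_value(out$pKi)),
    pKd = as.numeric(ad_value(out$pKd)),
    pIC50 = as.numeric(ad_value(out$pIC50)),
    pEC50 = as.numeric(ad_value(out$pEC50)),
    logit = logit,
    probability = 1 / (1 + exp(-logit))
  )
}

## ---- exposed building-block operations (numeric interfaces) ----------------

#' Cross-attention graph block
#'
#' Each graph node acts as a query token over the protein's residue
#' keys/values via multi-head scaled dot-product attention; masked residues
#' receive exactly zero attention weight; the attended output is
#' residual-added to the input and layer-normalized (both togglable for
#' inspection).  Node count, width, and graph connectivity are unchanged.
#'
#' @param node_states Numeric matrix `n_nodes x d`.
#' @param residue_latents Numeric matrix `seq_len x d` (already width-adapted).
#' @param residue_mask Logical vector of length `seq_len`; `TRUE` =
#'   attendable.  `NULL` attends everywhere.
#' @param params Named list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`), `bo`
#'   (length `d`), and, when `norm = TRUE`, `ln_g`, `ln_b`.
#' @param n_heads Number of attention heads (must divide `d`).
#' @param residual,norm Apply the residual connection / layer norm.
#' @param return_attention Also return the per-head attention matrices.
#' @return The updated `n_nodes x d` matrix, or a list with `output` and
#'   `attention` when `return_attention = TRUE`.
#' @export
cross_attention_graph_block <- function(node_states, residue_latents,
                                        residue_mask = NULL, params,
                                        n_heads = 1L, residual = TRUE,
                                        norm = TRUE, return_attention = FALSE) {
  node_states <- as.matrix(node_states)
  residue_latents <- as.matrix(residue_latents)
  d <- ncol(node_states)
  if (ncol(residue_latents) != d) {
    stop("width mismatch: residue latents must already be adapted to d_hidden")
  }
  if (d %% n_heads != 0L) stop("n_heads must divide the hidden width")
  if (!is.null(residue_mask)) {
    residue_mask <- as.logical(residue_mask)
    if (length(residue_mask) != nrow(residue_latents)) {
      stop("residue_mask length must equal the number of residues")
    }
    if (!any(residue_mask)) stop("all residues are masked: no valid keys")
  }
  tape <- ad_tape()
  at <- .attend(tape, node_states, residue_latents, residue_mask, params,
                n_heads, want_attention = return_attention)
  out <- at$out
  if (residual) out <- op_add(tape, out, node_states)
  if (norm) out <- op_layernorm(tape, out, params$ln_g, params$ln_b)
  res <- ad_value(out)
  if (return_attention) list(output = res, attention = at$attention) else res
}

#' Dynamic-attention (GATv2-style) graph convolution
#'
#' Message passing over directed edges with edge features entering the
#' attention logit; self-loops with zero edge features are always included.
#'
#' @param node_states Numeric matrix `n_nodes x d`.
#' @param edge_index 2-column integer matrix of directed edges (source,
#'   target), 1-based.
#' @param edge_features Numeric matrix with one row per directed edge.
#' @param params Named list with `W_src`, `W_tgt` (`d x d`), `W_edge`
#'   (`d_edge x d`), `a` (`d x 1`), `b_out` (length `d`).
#' @param leaky_slope Negative slope used inside the attention logit.
#' @return Updated `n_nodes x d` matrix.
#' @export
gatv2_conv <- function(node_states, edge_index, edge_features, params,
                       leaky_slope = 0.05) {
  node_states <- as.matrix(node_states)
  n <- nrow(node_states)
  edge_index <- matrix(as.integer(edge_index), ncol = 2L)
  if (nrow(edge_index) > 0L &&
      (max(edge_index) > n || min(edge_index) < 1L)) {
    stop("edge_index refers to a node outside the graph")
  }
  tape <- ad_tape()
  ad_value(.gatv2(tape, node_states, edge_index, as.matrix(edge_features),
                  params, n, leaky_slope))
}

#' Pool node states into per-graph vectors
#'
#' @param node_states Numeric matrix of node rows.
#' @param membership Integer vector mapping each node to its graph (1-based).
#' @param mode `"sum"`, `"mean"`, or `"lcm"` (learned binary operator over a
#'   balanced binary tree; needs `params`).
#' @param params For `mode = "lcm"`: named list `W1` (`2d x d`), `b1`, `W2`
#'   (`d x d`), `b2`.
#' @param leaky_slope Activation slope inside the learned operator.
#' @return Matrix `n_graphs x d`.
#' @export
pool_nodes <- function(node_states, membership, mode = c("sum", "mean", "lcm"),
                       params = NULL, leaky_slope = 0.05) {
  mode <- match.arg(mode)
  node_states <- as.matrix(node_states)
  membership <- as.integer(membership)
  n_graphs <- max(membership)
  tape <- ad_tape()
  ad_value(.pool(tape, node_states, membership, n_graphs, mode, params,
                 leaky_slope))
}

#' Temperature-scale and clip a classifier logit
#'
#' Returns `clamp(raw_logit * exp(tau), -clip, clip)`.
#'
#' @param raw_logit Raw classifier head output (finite numeric).
#' @param tau Temperature parameter (the exponential is applied here).
#' @param clip Symmetric clipping bound (default 100).
#' @return Scaled, clipped logit (same shape as `raw_logit`).
#' @export
scale_logit <- function(raw_logit, tau, clip = 100) {
  raw_logit <- as.numeric(raw_logit)
  tau <- as.numeric(tau)
  if (!all(is.finite(raw_logit)) || !all(is.finite(tau))) {
    stop("scale_logit: inputs must be finite")
  }
  pmin(pmax(raw_logit * exp(tau), -clip), clip)
}

## ---- checkpointing ----------------------------------------------------------

#' Save / load a versioned model checkpoint
#'
#' The checkpoint stores a format version, the configuration, all trainable
#' parameters (including the temperature `tau`), and the latent width.
#' Loading refuses checkpoints written under a different format version.
#'
#' @param model A `bind_model`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `bind_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "bind_model"))
  obj <- list(format_version = BIND_CHECKPOINT_VERSION,
              config = model$config, params = model$params,
              d_latent = model$d_latent)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format_version, BIND_CHECKPOINT_VERSION)) {
    stop(sprintf("checkpoint format version %s does not match supported version %s",
                 obj$format_version, BIND_CHECKPOINT_VERSION))
  }
  structure(list(config = obj$config, params = obj$params,
                 d_latent = obj$d_latent), class = "bind_model")
}
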