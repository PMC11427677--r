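# Compiled fast path.  The default (post-norm) network has a hand-derived
# C++ forward/backward (src/bind_kernel.cpp) that the test suite verifies
# against the R tape engine, value and gradient, at tight tolerance.  The
# tape remains the reference implementation and serves the pre-norm variant
# and the exposed building-block operations.

#' @useDynLib bindscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.kernel_supported <- function(config) {
  !isTRUE(config$pre_norm) && config$pooling %in% c("lcm", "sum", "mean")
}

# Precompute the kernel-ready view of a molecular graph: 0-based directed
# edges with self loops appended, and edge features padded with zero rows
# for the self loops.
.kernel_graph <- function(graph) {
  n <- nrow(graph$node_features)
  ei <- graph$edge_index
  edges <- rbind(ei, cbind(seq_len(n), seq_len(n))) - 1L
  storage.mode(edges) <- "integer"
  ef <- rbind(graph$edge_features, matrix(0, n, ncol(graph$edge_features)))
  list(node_features = graph$node_features, edges = edges, edge_features = ef)
}

.kernel_record <- function(kg, stack_layers, labels, is_decoy) {
  list(node_features = kg$node_features, edges = kg$edges,
       edge_features = kg$edge_features, E = stack_layers,
       labels = as.numeric(labels), is_decoy = isTRUE(is_decoy))
}

# Summed gradients + loss over a batch of kernel records.
.kernel_grad_batch <- function(params, records, config, delta, training) {
  .bind_grad_batch_cpp(params, records, unclass(config), delta, training)
}

# Evaluation-mode prediction matrix (pKi, pKd, pIC50, pEC50, scaled logit).
.kernel_predict <- function(params, records, config) {
  .bind_forward_batch_cpp(params, records, unclass(config))
}
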