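# Frozen per-residue protein latents behind a uniform interface.
#
# A deterministic toy embedder supports desk-scale work: each residue is
# encoded as its own one-hot plus the one-hots of its two sequence
# neighbours (local trigram context) plus a sinusoidal position encoding,
# passed through a fixed, seeded random projection and L frozen random
# affine + tanh layers.  The latents are therefore position-, composition-
# and local-context-sensitive, so a planted sequence motif is linearly
# detectable from them.  A real pre-trained protein language model can be
# plugged in by implementing the `plm_embed` generic for its handle;
# latents are passed through unchanged (no pooling or re-normalization).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Fixed internal seed: the toy embedder's weights are a package constant so
# identical sequences embed identically across sessions and processes.
.TOY_EMBEDDER_SEED <- 20240927L

#' Construct the deterministic toy protein embedder
#'
#' All weights are generated from a fixed internal seed and are frozen: the
#' embedder exposes no trainable parameters, and `n_calls` counts embedding
#' computations (used to verify per-protein caching).
#'
#' @param d_embed Latent width (default 64).
#' @param n_layers Number of frozen affine + tanh layers; valid layer
#'   indices are `0:n_layers` where 0 is the projection output (default 3,
#'   giving depths 0-3).
#' @param d_pos Width of the sinusoidal position encoding (default 16).
#' @param pos_scale Amplitude of the position encoding relative to the
#'   residue one-hots (default 0.25).  Kept well below 1 so the latents are
#'   dominated by composition, not position: with unit amplitude the 16
#'   sinusoid dimensions would out-weigh the 3 one-hot dimensions and
#'   same-length proteins would embed almost identically.
#' @return A `toy_embedder` handle (an environment, so call counting works).
#' @export
toy_embedder <- function(d_embed = 64L, n_layers = 3L, d_pos = 16L,
                         pos_scale = 0.25) {
  d_in <- 3L * length(AA_ALPHABET) + d_pos
  be <- new.env(parent = emptyenv())
  be$d_embed <- as.integer(d_embed)
  be$n_layers <- as.integer(n_layers)
  be$d_pos <- as.integer(d_pos)
  be$pos_scale <- pos_scale
  be$n_calls <- 0L
  with_seed(.TOY_EMBEDDER_SEED, {
    be$proj <- matrix(stats::rnorm(d_in * d_embed, sd = 1 / sqrt(d_in)), d_in, d_embed)
    be$layers <- lapply(seq_len(n_layers), function(l) {
      list(A = matrix(stats::rnorm(d_embed * d_embed, sd = 1 / sqrt(d_embed)),
                      d_embed, d_embed),
           b = stats::rnorm(d_embed, sd = 0.1))
    })
  })
  class(be) <- "toy_embedder"
  be
}

# Checksum over all frozen weights; used to assert the backend is untouched
# by training.
embedder_checksum <- function(backend) {
  sum(backend$proj) + sum(vapply(backend$layers, function(l) sum(l$A) + sum(l$b), 0))
}

.position_encoding <- function(n, d_pos) {
  pos <- seq_len(n)
  out <- matrix(0, n, d_pos)
  for (k in seq_len(d_pos %/% 2L)) {
    w <- 1 / 10000^(2 * (k - 1) / d_pos)
    out[, 2L * k - 1L] <- sin(pos * w)
    out[, 2L * k] <- cos(pos * w)
  }
  out
}

#' Embed a protein sequence (generic over embedder backends)
#'
#' @param backend An embedder handle, e.g. [toy_embedder()].
#' @param sequence Amino-acid string over the 20 standard residues plus X.
#' @param layer_indices Encoder depths to return, strictly increasing.
#' @return A `residue_embedding_stack`.
#' @export
plm_embed <- function(backend, sequence, layer_indices) {
  UseMethod("plm_embed")
}

#' @export
plm_embed.toy_embedder <- function(backend, sequence, layer_indices) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  idx <- match(chars, AA_ALPHABET)
  nv <- length(AA_ALPHABET)
  onehot <- matrix(0, n, nv)
  onehot[cbind(seq_len(n), idx)] <- 1
  # local trigram context: previous and next residue one-hots (zero rows at
  # the chain termini)
  prev <- rbind(matrix(0, 1L, nv), onehot[-n, , drop = FALSE])
  nxt <- rbind(onehot[-1L, , drop = FALSE], matrix(0, 1L, nv))
  X <- cbind(prev, onehot, nxt,
             backend$pos_scale * .position_encoding(n, backend$d_pos))
  H <- tanh(X %*% backend$proj)
  depths <- list(`0` = H)
  for (l in seq_len(backend$n_layers)) {
    H <- tanh(H %*% backend$layers[[l]]$A +
                matrix(backend$layers[[l]]$b, n, backend$d_embed, byrow = TRUE))
    depths[[as.character(l)]] <- H
  }
  backend$n_calls <- backend$n_calls + 1L
  layers <- lapply(layer_indices, function(li) depths[[as.character(li)]])
  structure(list(layers = layers, layer_indices = as.integer(layer_indices),
                 sequence = sequence),
            class = "residue_embedding_stack")
}

#' Frozen per-residue latents for a protein sequence
#'
#' Validates the sequence and layer indices, then delegates to the backend.
#' Identical inputs give identical outputs for a fixed backend, and no
#' gradients ever flow into the backend (its weights are not part of any
#' trainable parameter set).
#'
#' @param sequence Non-empty amino-acid string (20 standard residues plus X).
#' @param layer_indices Strictly increasing encoder depths valid for the
#'   backend.
#' @param backend Embedder handle (default: a fresh [toy_embedder()]).
#' @return A `residue_embedding_stack`: list of `seq_len x d_embed` matrices
#'   (one per requested layer), the `layer_indices`, and the source
#'   `sequence`.
#' @export
embed_sequence <- function(sequence, layer_indices, backend = toy_embedder()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf("character '%s' at position %d is outside the amino-acid alphabet",
                 chars[bad[1L]], bad[1L]))
  }
  layer_indices <- as.integer(layer_indices)
  if (length(layer_indices) == 0L || is.unsorted(layer_indices, strictly = TRUE)) {
    stop("layer_indices must be non-empty and strictly increasing")
  }
  if (inherits(backend, "toy_embedder") &&
      (min(layer_indices) < 0L || max(layer_indices) > backend$n_layers)) {
    stop(sprintf("layer index out of range 0..%d for this backend", backend$n_layers))
  }
  plm_embed(backend, sequence, layer_indices)
}

#' Concatenate protein chains for multi-chain targets
#'
#' Multi-chain evaluation targets are handled by plain concatenation of the
#' chain sequences in the given order, with no separator token.
#'
#' @param chain_sequences Non-empty list/vector of non-empty chain strings.
#' @return The concatenated sequence.
#' @export
concat_chains <- function(chain_sequences) {
  chain_sequences <- unlist(chain_sequences, use.names = FALSE)
  if (length(chain_sequences) == 0L) stop("no chains given")
  if (any(!nzchar(chain_sequences))) stop("empty chain in input")
  paste0(chain_sequences, collapse = "")
}

## ---- embedding cache --------------------------------------------------------

#' Create an embedding store
#'
#' In-memory store, optionally backed by a directory so embeddings persist
#' across sessions (entries are keyed by protein id or sequence hash).
#'
#' @param dir Optional directory for on-disk persistence.
#' @return An `embedding_store` environment.
#' @export
embedding_store <- function(dir = NULL) {
  st <- new.env(parent = emptyenv())
  st$mem <- new.env(parent = emptyenv())
  st$dir <- dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  class(st) <- "embedding_store"
  st
}

#' Hash a protein sequence for cache keying
#' @param sequence Amino-acid string.
#' @return MD5 hex digest of the sequence.
#' @export
sequence_hash <- function(sequence) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sequence, tf)
  unname(tools::md5sum(tf))
}

#' Cache / fetch / evict a residue embedding stack
#'
#' @param protein_id Key (an id or [sequence_hash()]).
#' @param stack A `residue_embedding_stack`.
#' @param store An [embedding_store()].
#' @return `cache_embedding` and `evict_embedding` return the store
#'   invisibly; `fetch_embedding` returns the stack (error if absent).
#' @export
cache_embedding <- function(protein_id, stack, store) {
  assign(protein_id, stack, envir = store$mem)
  if (!is.null(store$dir)) {
    saveRDS(stack, file.path(store$dir, paste0(protein_id, ".rds")))
  }
  invisible(store)
}

#' @rdname cache_embedding
#' @export
fetch_embedding <- function(protein_id, store) {
  if (exists(protein_id, envir = store$mem, inherits = FALSE)) {
    return(get(protein_id, envir = store$mem, inherits = FALSE))
  }
  if (!is.null(store$dir)) {
    f <- file.path(store$dir, paste0(protein_id, ".rds"))
    if (file.exists(f)) {
      stack <- readRDS(f)
      assign(protein_id, stack, envir = store$mem)
      return(stack)
    }
  }
  stop(sprintf("no cached embedding for '%s'", protein_id))
}

#' @rdname cache_embedding
#' @export
evict_embedding <- function(protein_id, store) {
  if (exists(protein_id, envir = store$mem, inherits = FALSE)) {
    rm(list = protein_id, envir = store$mem)
  }
  if (!is.null(store$dir)) {
    unlink(file.path(store$dir, paste0(protein_id, ".rds")))
  }
  invisible(store)
}

# Embed with caching: at most one backend call per distinct sequence.
embed_cached <- function(sequence, layer_indices, backend, store) {
  key <- sequence_hash(sequence)
  if (exists(key, envir = store$mem, inherits = FALSE)) {
    return(get(key, envir = store$mem, inherits = FALSE))
  }
  if (!is.null(store$dir)) {
    f <- file.path(store$dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      stack <- readRDS(f)
      assign(key, stack, envir = store$mem)
      return(stack)
    }
  }
  stack <- embed_sequence(sequence, layer_indices, backend)
  cache_embedding(key, stack, store)
  stack
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id` (first word of the description line)
#'   and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  data.frame(id = ids, sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}
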