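# Dataset handling, decoy sampling, the masked multi-objective loss,
# the AdamW + cosine-decay optimization loop, and the homology-aware
# zero-shot training filter.
#
# Interaction records are rows of a data frame with columns
# protein_sequence, smiles, pKi, pKd, pIC50, pEC50 (NA = missing, -log10
# molar units), and is_decoy.

AFFINITY_HEADS <- c("pKi", "pKd", "pIC50", "pEC50")

#' Normalize an affinity from nM to the -log10 molar scale
#'
#' `p = -log10(x / 1e9)` where `x` is in nM, so 1 nM maps to 9.
#'
#' @param value_nM Positive affinity value(s) in nM.
#' @return Normalized value(s).
#' @export
normalize_affinity <- function(value_nM) {
  value_nM <- as.numeric(value_nM)
  if (any(!is.finite(value_nM)) || any(value_nM <= 0)) {
    stop("affinity values must be finite and positive (nM)")
  }
  -log10(value_nM / 1e9)
}

#' Read a BindingDB-style interaction table
#'
#' Tab-separated columns `protein_sequence`, `smiles`, `ki_nM`, `kd_nM`,
#' `ic50_nM`, `ec50_nM` (blank = missing).  Values carrying qualifiers
#' (`">"`, `"<"`) are treated as missing; exact values are normalized with
#' [normalize_affinity()].  Records with no usable label are dropped.
#'
#' @param path TSV file path.
#' @return Interaction records data frame.
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "", colClasses = "character")
  need <- c("protein_sequence", "smiles")
  if (!all(need %in% names(df))) {
    stop("interaction table needs protein_sequence and smiles columns")
  }
  parse_nm <- function(x) {
    x <- trimws(x)
    x[grepl("[<>]", x)] <- ""            # qualified measurements are dropped
    v <- suppressWarnings(as.numeric(x))
    v[!is.na(v) & v <= 0] <- NA
    ifelse(is.na(v), NA_real_, -log10(v / 1e9))
  }
  cols <- c(ki_nM = "pKi", kd_nM = "pKd", ic50_nM = "pIC50", ec50_nM = "pEC50")
  out <- data.frame(protein_sequence = df$protein_sequence, smiles = df$smiles,
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    out[[cols[[nm]]]] <- if (nm %in% names(df)) parse_nm(df[[nm]]) else NA_real_
  }
  out$is_decoy <- FALSE
  keep <- rowSums(!is.na(out[AFFINITY_HEADS])) > 0
  out[keep, , drop = FALSE]
}

#' Write interaction records back to the TSV format
#'
#' @param records Interaction records data frame.
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  df <- data.frame(protein_sequence = records$protein_sequence,
                   smiles = records$smiles, stringsAsFactors = FALSE)
  back <- c(pKi = "ki_nM", pKd = "kd_nM", pIC50 = "ic50_nM", pEC50 = "ec50_nM")
  for (h in AFFINITY_HEADS) {
    v <- records[[h]]
    df[[back[[h]]]] <- ifelse(is.na(v), "", format(10^(9 - v), digits = 8))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the protein-to-binders index
#'
#' @param records Interaction records (non-decoy rows are indexed).
#' @return Named list mapping each protein sequence to the character vector
#'   of SMILES recorded as its binders.
#' @export
build_binder_index <- function(records) {
  rec <- records[!records$is_decoy, , drop = FALSE]
  lapply(split(rec$smiles, rec$protein_sequence), unique)
}

#' Sample a decoy ligand for a record
#'
#' Draws uniformly from the ligand pool and rejection-resamples any ligand
#' that the dataset pairs with the record's protein, so returned SMILES are
#' never known binders of the target.
#'
#' @param record One interaction record (list or single data frame row with
#'   `protein_sequence`).
#' @param binder_index Index from [build_binder_index()].
#' @param ligand_pool Candidate SMILES (default: all ligands in the index).
#' @param max_retries Bounded retry budget before erroring (default 100).
#' @return A decoy SMILES string.  Uses the R random number generator.
#' @export
sample_decoy <- function(record, binder_index, ligand_pool = NULL,
                         max_retries = 100L) {
  if (is.null(ligand_pool)) {
    ligand_pool <- unique(unlist(binder_index, use.names = FALSE))
  }
  bound <- binder_index[[record$protein_sequence]]
  for (i in seq_len(max_retries)) {
    cand <- ligand_pool[[sample.int(length(ligand_pool), 1L)]]
    if (!(cand %in% bound)) return(cand)
  }
  stop(sprintf("no decoy found in %d retries: every sampled ligand binds the target",
               max_retries))
}

#' Masked multi-objective loss for one prediction
#'
#' Sum of Huber losses over the affinity targets that are present (and not
#' zeroized by the decoy rule) plus binary cross-entropy of the classifier
#' probability against `1 - is_decoy`.  Absent targets, and all four
#' regression targets of decoy records, contribute exactly zero loss; the
#' reported `mean` averages only the non-zeroized terms.
#'
#' @param pred One-row prediction (from [bind_predict()]): `pKi`, `pKd`,
#'   `pIC50`, `pEC50`, `logit`.
#' @param record One interaction record with label columns and `is_decoy`.
#' @param delta Huber transition point (default 2).
#' @return List with `total`, `mean`, and the per-term breakdown `terms`.
#' @export
compute_loss <- function(pred, record, delta = 2) {
  if (!all(is.finite(unlist(pred[c(AFFINITY_HEADS, "logit")])))) {
    stop("predictions must be finite")
  }
  terms <- numeric(0)
  is_decoy <- isTRUE(record$is_decoy)
  for (h in AFFINITY_HEADS) {
    lab <- record[[h]]
    if (!is_decoy && !is.null(lab) && length(lab) == 1L && !is.na(lab)) {
      terms[[h]] <- huber_loss(pred[[h]] - lab, delta)
    }
  }
  z <- pred$logit
  target <- as.numeric(!is_decoy)
  terms[["bce"]] <- max(z, 0) - z * target + log1p(exp(-abs(z)))
  list(total = sum(terms), mean = mean(terms), terms = terms)
}

#' Huber loss of a residual
#' @param e Residual (prediction minus label).
#' @param delta Transition point between the quadratic and linear branches.
#' @return `0.5 e^2` for `|e| <= delta`, else `delta (|e| - delta / 2)`.
#' @export
huber_loss <- function(e, delta = 2) {
  ifelse(abs(e) <= delta, 0.5 * e^2, delta * (abs(e) - 0.5 * delta))
}

# Loss nodes on a tape.  Terms for absent labels (and all regression terms
# of decoys) are never built, so their heads receive exactly zero gradient.
.loss_nodes <- function(tape, fw, record, delta) {
  terms <- list()
  if (!isTRUE(record$is_decoy)) {
    for (h in AFFINITY_HEADS) {
      lab <- record[[h]]
      if (!is.null(lab) && length(lab) == 1L && !is.na(lab)) {
        terms[[h]] <- op_huber(tape, op_sum(tape, fw[[h]]), lab, delta)
      }
    }
  }
  terms[["bce"]] <- op_bce_logit(tape, op_sum(tape, fw$logit),
                                 as.numeric(!isTRUE(record$is_decoy)))
  total <- terms[[1L]]
  if (length(terms) > 1L) {
    for (k in 2:length(terms)) total <- op_add(tape, total, terms[[k]])
  }
  list(total = total, terms = terms)
}

#' Record-level train/validation/test split
#'
#' @param records Interaction records.
#' @param fractions Length-3 split fractions summing to 1
#'   (default `c(0.90, 0.02, 0.08)`).
#' @param seed Integer seed; the same seed reproduces the same membership.
#' @return List with `train`, `val`, `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(records, fractions = c(0.90, 0.02, 0.08), seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("cannot split an empty record set")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  ord <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  list(train = records[sort(ord[seq_len(n_train)]), , drop = FALSE],
       val = records[sort(ord[n_train + seq_len(n_val)]), , drop = FALSE],
       test = records[sort(ord[(n_train + n_val + 1L):n]), , drop = FALSE])
}

#' Global-alignment identity against a reference sequence
#'
#' Needleman-Wunsch with match = 1, mismatch = 0, and zero gap penalties
#' (so the score is the maximal number of aligned matches), divided by the
#' reference length.
#'
#' @param query,reference Amino-acid strings.
#' @return Identity fraction in `[0, 1]` (can exceed 1 only if the query is
#'   longer and fully contains the reference matches; by construction the
#'   match count is at most `min(nchar(query), nchar(reference))`).
#' @export
alignment_identity <- function(query, reference) {
  letters_all <- unique(c(AA_ALPHABET, strsplit(paste0(query, reference), "")[[1]]))
  sm <- diag(1, length(letters_all))
  dimnames(sm) <- list(letters_all, letters_all)
  score <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 0,
    scoreOnly = TRUE)
  score / nchar(reference)
}

#' Remove training records homologous to evaluation proteins
#'
#' For each training sequence, computes [alignment_identity()] against every
#' reference; records whose sequence exceeds `threshold` against any
#' reference are removed (zero-shot regime).
#'
#' @param train_records Interaction records.
#' @param reference_sequences Character vector of evaluation (reference)
#'   sequences.
#' @param threshold Identity threshold in `(0, 1]` (default 0.90; strictly
#'   greater identities are removed).
#' @return Filtered records.  An empty reference set returns the input
#'   unchanged with a warning.
#' @export
homology_filter <- function(train_records, reference_sequences, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  reference_sequences <- unique(reference_sequences[nzchar(reference_sequences)])
  if (length(reference_sequences) == 0L) {
    warning("no reference sequences: returning training records unchanged")
    return(train_records)
  }
  uniq <- unique(train_records$protein_sequence)
  drop <- vapply(uniq, function(q) {
    any(vapply(reference_sequences, function(r) {
      alignment_identity(q, r) > threshold
    }, TRUE))
  }, TRUE)
  train_records[!(train_records$protein_sequence %in% uniq[drop]), , drop = FALSE]
}

#' Training configuration
#'
#' @param lr AdamW learning rate (default 1e-4).
#' @param weight_decay Decoupled weight decay (default 1e-3).
#' @param huber_delta Huber transition point (default 2.0).
#' @param accumulation_steps Gradient accumulation micro-batches per
#'   optimizer step (default 256).
#' @param batch_size Records per micro-batch (default 1).
#' @param total_iterations Optimizer steps; the cosine schedule decays the
#'   learning rate to zero here.
#' @param decoy_fraction Per-step Bernoulli probability of replacing the
#'   ligand with a sampled decoy (default 0.5).
#' @param max_train_seq_len Sequences longer than this are excluded from
#'   training only (default 2048).
#' @param split_fractions Train/val/test fractions (default 0.90/0.02/0.08).
#' @param eval_every Validate every this many iterations (default: 10 times
#'   over the run).
#' @param seed Seed driving all training randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-3, huber_delta = 2.0,
                         accumulation_steps = 256L, batch_size = 1L,
                         total_iterations = 100L, decoy_fraction = 0.5,
                         max_train_seq_len = 2048L,
                         split_fractions = c(0.90, 0.02, 0.08),
                         eval_every = max(1L, total_iterations %/% 10L),
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (decoy_fraction < 0 || decoy_fraction > 1) stop("decoy_fraction must be in [0, 1]")
  structure(list(lr = lr, weight_decay = weight_decay, huber_delta = huber_delta,
                 accumulation_steps = as.integer(accumulation_steps),
                 batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 decoy_fraction = decoy_fraction,
                 max_train_seq_len = as.integer(max_train_seq_len),
                 split_fractions = split_fractions,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-decayed learning rate with no warm-up
#'
#' `lr(t) = lr0 * cos^2(pi t / (2 T))`, equal to `lr0 / 2` at `t = T / 2`
#' and 0 at `t = T`.
#'
#' @param iteration Current iteration `t` in `[0, total_iterations]`.
#' @param total_iterations Schedule horizon `T`.
#' @param lr Base learning rate `lr0`.
#' @return The decayed learning rate.
#' @export
cosine_lr <- function(iteration, total_iterations, lr) {
  lr * cos(pi * iteration / (2 * total_iterations))^2
}

# One AdamW update in place; `state` holds first/second moments and the step
# counter.
.adamw_step <- function(params, grads, state, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- array(0, dim(as.matrix(params[[nm]])))
    g <- array(as.numeric(g), dim = c(length(params[[nm]])))
    p <- as.numeric(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    pnew <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
    attributes(pnew) <- attributes(params[[nm]])
    params[[nm]] <- pnew
  }
  params
}

# Evaluate the mean (zeroized-term-disregarding) loss over records.
.mean_loss <- function(model, records, graphs, stacks, delta) {
  tot <- 0; nt <- 0L
  use_kernel <- .kernel_supported(model$config)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (use_kernel) {
      kg <- .kernel_graph(graphs[[rec$smiles]])
      krec <- .kernel_record(kg,
                             .stack_for_config(stacks[[rec$protein_sequence]],
                                               model$config),
                             rep(NA_real_, 4L), FALSE)
      pm <- .kernel_predict(model$params, list(krec), model$config)
      pred <- as.data.frame(pm)
    } else {
      pred <- bind_predict(model, graphs[[rec$smiles]],
                           stacks[[rec$protein_sequence]])
    }
    L <- compute_loss(pred, rec, delta)
    tot <- tot + sum(unlist(L$terms))
    nt <- nt + length(L$terms)
  }
  tot / nt
}

#' Train the model
#'
#' Per micro-step the ligand is replaced by a sampled decoy with probability
#' `decoy_fraction` (the record is then labelled a decoy and its regression
#' terms zeroized); gradients are accumulated over
#' `accumulation_steps * batch_size` records; AdamW updates follow a cosine
#' learning-rate decay with no warm-up.  Training sequences longer than
#' `max_train_seq_len` are excluded (training only).  The embedder is frozen
#' throughout — its weights are not in the parameter set.  The returned model
#' carries the parameters with the best validation loss.
#'
#' @param train_records,val_records Interaction records (validation may be
#'   `NULL`, in which case the final parameters are returned).
#' @param model_config A [bind_config()].
#' @param tc A [train_config()].
#' @param backend Protein embedder handle.
#' @return List with `model` (best validation loss), `final_model`,
#'   `history` (data frame: iteration, lr, train_loss), `val_history`, and
#'   `best_val_loss`.
#' @export
fit_bind <- function(train_records, val_records = NULL, model_config, tc,
                     backend = toy_embedder()) {
  stopifnot(inherits(model_config, "bind_config"), inherits(tc, "train_config"))
  keep <- nchar(train_records$protein_sequence) <= tc$max_train_seq_len
  train_records <- train_records[keep, , drop = FALSE]
  if (nrow(train_records) == 0L) stop("no training records after length filter")

  binder_index <- build_binder_index(train_records)
  ligand_pool <- unique(train_records$smiles)

  # Pre-parse graphs and pre-embed proteins once.
  all_smiles <- unique(c(train_records$smiles,
                         if (!is.null(val_records)) val_records$smiles))
  graphs <- new.env(parent = emptyenv())
  for (s in all_smiles) assign(s, smiles_to_graph(s), envir = graphs)
  graphs <- as.list(graphs)
  all_prot <- unique(c(train_records$protein_sequence,
                       if (!is.null(val_records)) val_records$protein_sequence))
  stacks <- list()
  for (sq in all_prot) {
    stacks[[sq]] <- embed_sequence(sq, model_config$encoder_layer_indices, backend)
  }

  model <- bind_model(model_config, d_latent = backend$d_embed)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(model$params, function(p) numeric(length(p)))
  state$v <- lapply(model$params, function(p) numeric(length(p)))

  # Deterministic half-decoy validation set so validation mirrors training.
  val_set <- NULL
  if (!is.null(val_records) && nrow(val_records) > 0L) {
    val_set <- val_records
    with_seed(tc$seed + 9999L, {
      flip <- stats::runif(nrow(val_set)) < tc$decoy_fraction
      for (i in which(flip)) {
        dec <- try(sample_decoy(val_set[i, ], binder_index, ligand_pool), silent = TRUE)
        if (!inherits(dec, "try-error")) {
          val_set$smiles[i] <- dec
          val_set$is_decoy[i] <- TRUE
          val_set[i, AFFINITY_HEADS] <- NA_real_
        }
      }
    })
    for (s in unique(val_set$smiles)) {
      if (is.null(graphs[[s]])) graphs[[s]] <- smiles_to_graph(s)
    }
  }

  best_val <- Inf
  best_params <- model$params
  history <- list()
  val_history <- list()
  n_train <- nrow(train_records)
  set.seed(tc$seed)
  order_idx <- sample.int(n_train)
  cursor <- 0L
  micro_n <- tc$accumulation_steps * tc$batch_size
  use_kernel <- .kernel_supported(model_config)
  kgraphs <- if (use_kernel) lapply(graphs, .kernel_graph) else NULL
  kstacks <- if (use_kernel) {
    lapply(stacks, .stack_for_config, config = model_config)
  } else NULL

  for (t in seq_len(tc$total_iterations)) {
    lr_t <- cosine_lr(t - 1L, tc$total_iterations, tc$lr)
    acc <- NULL
    loss_sum <- 0; term_count <- 0L; decoy_count <- 0L
    krecs <- if (use_kernel) vector("list", micro_n) else NULL
    for (ms in seq_len(micro_n)) {
      cursor <- cursor + 1L
      if (cursor > n_train) {
        order_idx <- sample.int(n_train)
        cursor <- 1L
      }
      rec <- train_records[order_idx[cursor], ]
      if (stats::runif(1) < tc$decoy_fraction) {
        dec <- try(sample_decoy(rec, binder_index, ligand_pool), silent = TRUE)
        if (!inherits(dec, "try-error")) {
          rec$smiles <- dec
          rec$is_decoy <- TRUE
          rec[AFFINITY_HEADS] <- NA_real_
          decoy_count <- decoy_count + 1L
        }
      }
      if (use_kernel) {
        krecs[[ms]] <- .kernel_record(kgraphs[[rec$smiles]],
                                      kstacks[[rec$protein_sequence]],
                                      unlist(rec[AFFINITY_HEADS]),
                                      rec$is_decoy)
        next
      }
      tape <- ad_tape()
      Pn <- list()
      for (nm in names(model$params)) {
        Pn[[nm]] <- ad_param(tape, model$params[[nm]], nm)
      }
      batch <- batch_graphs(list(graphs[[rec$smiles]]))
      layers <- .stack_for_config(stacks[[rec$protein_sequence]], model$config)
      fw <- .bind_forward(tape, Pn, model$config, batch, layers, training = TRUE)
      ln <- .loss_nodes(tape, fw, rec, tc$huber_delta)
      grads <- ad_param_grads(tape, ad_backward(tape, ln$total))
      loss_sum <- loss_sum + sum(unlist(lapply(ln$terms, ad_value)))
      term_count <- term_count + length(ln$terms)
      if (is.null(acc)) {
        acc <- grads
      } else {
        for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
      }
    }
    if (use_kernel) {
      kb <- .kernel_grad_batch(model$params, krecs, model_config,
                               tc$huber_delta, training = TRUE)
      acc <- lapply(model$params, function(p) 0)
      for (nm in names(kb$grads)) {
        g <- kb$grads[[nm]]
        if (is.null(dim(model$params[[nm]]))) g <- as.numeric(g)
        acc[[nm]] <- g
      }
      loss_sum <- kb$loss_sum
      term_count <- kb$term_count
    }
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / micro_n
    model$params <- .adamw_step(model$params, acc, state, lr_t, tc$weight_decay)
    history[[t]] <- data.frame(iteration = t, lr = lr_t,
                               train_loss = loss_sum / term_count,
                               decoy_fraction = decoy_count / micro_n)
    if (!is.null(val_set) &&
        (t %% tc$eval_every == 0L || t == tc$total_iterations)) {
      vl <- .mean_loss(model, val_set, graphs, stacks, tc$huber_delta)
      val_history[[length(val_history) + 1L]] <-
        data.frame(iteration = t, val_loss = vl)
      if (vl < best_val) {
        best_val <- vl
        best_params <- model$params
      }
    }
  }
  final_model <- model
  best_model <- model
  best_model$params <- if (is.finite(best_val)) best_params else model$params
  list(model = best_model, final_model = final_model,
       history = do.call(rbind, history),
       val_history = if (length(val_history)) do.call(rbind, val_history) else NULL,
       best_val_loss = if (is.finite(best_val)) best_val else NA_real_)
}
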