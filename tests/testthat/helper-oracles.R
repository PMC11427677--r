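# Independent oracles the implementation is checked against.

# Brute-force per-node multi-head softmax attention: explicit loops, no
# shared code with the tape implementation.
oracle_attention <- function(H, E, mask, p, n_heads) {
  n <- nrow(H); d <- ncol(H); L <- nrow(E)
  dk <- d / n_heads
  if (is.null(mask)) mask <- rep(TRUE, L)
  out_heads <- matrix(0, n, d)
  Q <- H %*% p$Wq
  K <- E %*% p$Wk
  V <- E %*% p$Wv
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    for (i in seq_len(n)) {
      scores <- numeric(L)
      for (j in seq_len(L)) {
        scores[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
      }
      w <- numeric(L)
      sub <- scores[mask]
      esub <- exp(sub - max(sub))
      w[mask] <- esub / sum(esub)
      acc <- numeric(length(cols))
      for (j in seq_len(L)) acc <- acc + w[j] * V[j, cols]
      out_heads[i, cols] <- acc
    }
  }
  sweep(out_heads %*% p$Wo, 2, p$bo, "+")
}

# Direct-summation RIE/BEDROC evaluation (explicit sums, no geometric
# closed form).
oracle_bedroc <- function(active_ranks, n_total, alpha) {
  n_act <- length(active_ranks)
  s <- 0
  for (r in active_ranks) s <- s + exp(-alpha * r / n_total)
  s_best <- 0
  for (i in seq_len(n_act)) s_best <- s_best + exp(-alpha * i / n_total)
  s_worst <- 0
  for (i in (n_total - n_act + 1):n_total) s_worst <- s_worst + exp(-alpha * i / n_total)
  (s - s_worst) / (s_best - s_worst)
}

# Exhaustive active/inactive pair enumeration for AUROC (ties 1/2).
oracle_auroc <- function(scores, labels) {
  act <- scores[labels]; inact <- scores[!labels]
  tot <- 0
  for (a in act) {
    for (b in inact) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(act) * length(inact))
}

# Dynamic-programming global alignment with match = 1, mismatch = 0, gap = 0
# (the maximal number of aligned matches).
oracle_match_count <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- max(D[i, j] + (x[i] == y[j]), D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# Random valence-valid SMILES (alkyl/ether chains with optional terminal
# groups), for property checks over many molecules.
random_smiles <- function() {
  len <- sample(2:6, 1)
  atoms <- c("C", rep("", len - 1))
  for (i in seq_len(len)[-1]) {
    atoms[i] <- if (atoms[i - 1] == "O") "C" else sample(c("C", "C", "O"), 1)
  }
  if (atoms[len] == "O") atoms[len] <- "C"
  paste0(paste0(atoms, collapse = ""),
         sample(c("", "N", "S", "C#N", "C(=O)O"), 1))
}

# Apply a node permutation to a molgraph (features and edge indices).
permute_molgraph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  if (nrow(g$edge_index) > 0) {
    g2$edge_index <- matrix(inv[g$edge_index], ncol = 2)
  }
  g2
}

# Random parameter set for the exposed cross-attention block.
random_attention_params <- function(d, with_ln = TRUE) {
  p <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
            Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
            bo = rnorm(d))
  if (with_ln) { p$ln_g <- runif(d, 0.5, 1.5); p$ln_b <- rnorm(d) }
  p
}
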