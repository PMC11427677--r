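# SMILES -> featurized molecular graph.
#
# Atoms are read in SMILES token order; hydrogens stay implicit and enter the
# node features as a count.  Aromaticity is taken exactly as written
# (lowercase atoms / ':' bonds stay aromatic; nothing is kekulized or
# re-perceived), so the graph reflects the input string, not a normalized
# perception of it.

MOLGRAPH_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

# Default valences used to infer implicit hydrogen counts on organic-subset
# atoms (lists allow hypervalent N/P/S).  Aromatic bonds count 1.5.
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Names of the per-atom feature columns
#'
#' Feature layout of [smiles_to_graph()] node matrices: a one-hot element
#' block over C, N, O, S, P, F, Cl, Br, I and a catch-all "other" bucket,
#' followed by an aromaticity flag, the formal charge, the implicit hydrogen
#' count, and the heavy-atom degree.
#'
#' @return Character vector of column names, in order.
#' @export
node_feature_names <- function() {
  c(paste0("elem_", MOLGRAPH_ELEMENTS), "aromatic", "charge", "n_hydrogens", "degree")
}

#' Names of the per-bond feature columns
#'
#' One-hot bond order: single, double, triple, aromatic.
#'
#' @return Character vector of column names, in order.
#' @export
edge_feature_names <- function() {
  c("bond_single", "bond_double", "bond_triple", "bond_aromatic")
}

# Tokenize a SMILES string into atom/bond/structure tokens.
.smiles_tokenize <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, text) toks[[length(toks) + 1L]] <<- list(type = type, text = text)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(sprintf("unparseable SMILES '%s': unclosed bracket atom", smiles))
      push("bracket", paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      push("atom", ch)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push("aromatic_atom", ch)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      push("bond", ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop(sprintf("unparseable SMILES '%s': bad %% ring closure", smiles))
      }
      push("ring", paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch)
      i <- i + 1L
    } else if (ch == "(") {
      push("open", ch); i <- i + 1L
    } else if (ch == ")") {
      push("close", ch); i <- i + 1L
    } else if (ch == ".") {
      push("dot", ch); i <- i + 1L
    } else {
      stop(sprintf("unparseable SMILES '%s': unexpected character '%s' at position %d",
                   smiles, ch, i))
    }
  }
  toks
}

# Parse a bracket atom body "[...]" into element/aromatic/charge/H-count.
.parse_bracket <- function(body, smiles) {
  inner <- substr(body, 2L, nchar(body) - 1L)
  # isotope prefix
  inner <- sub("^[0-9]+", "", inner)
  m <- regmatches(inner, regexpr("^([A-Z][a-z]?|[bcnops])", inner))
  if (length(m) == 0L) {
    stop(sprintf("unparseable SMILES '%s': bad bracket atom %s", smiles, body))
  }
  elem_raw <- m
  rest <- substr(inner, nchar(elem_raw) + 1L, nchar(inner))
  aromatic <- elem_raw %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (aromatic) toupper(elem_raw) else elem_raw
  rest <- gsub("@", "", rest, fixed = TRUE)   # stereo parsed, not featurized
  hcount <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1L && nzchar(hm)) {
    hcount <- if (hm == "H") 1L else as.integer(substr(hm, 2L, nchar(hm)))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*[+-]*", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    if (grepl("^[+-][0-9]+$", cm)) {
      charge <- as.integer(paste0(substr(cm, 1L, 1L), substr(cm, 2L, nchar(cm))))
    } else {
      signs <- strsplit(cm, "")[[1]]
      charge <- sum(ifelse(signs == "+", 1L, -1L))
    }
    rest <- sub("[+-][0-9]*[+-]*", "", rest)
  }
  rest <- sub(":[0-9]+$", "", rest)  # atom-map number
  list(element = elem, aromatic = aromatic, charge = charge,
       hcount = hcount, explicit_h = TRUE)
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Heavy atoms become nodes in SMILES token order; every bond contributes two
#' directed edges (i to j and j to i) with identical features.  Aromaticity
#' is kept exactly as written: lowercase atoms are flagged aromatic and bonds
#' between two aromatic atoms default to aromatic order, with no kekulization
#' or aromaticity re-perception.  Hydrogens are implicit and appear only as a
#' per-node count inferred from default valences (or taken verbatim from
#' bracket atoms).  Stereo markers are accepted and ignored.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molgraph`: a list with `node_features`
#'   (`n_nodes` x `length(node_feature_names())` matrix), `edge_index`
#'   (2-column integer matrix of directed source/target indices),
#'   `edge_features` (`n_edges` x 4 one-hot bond order matrix), and `smiles`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' nrow(g$node_features)  # 6
#' nrow(g$edge_index)     # 12 directed edges
#' @export
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("cannot parse empty or non-string SMILES")
  }
  toks <- .smiles_tokenize(smiles)
  atoms <- list()     # element, aromatic, charge, hcount, explicit_h
  bonds <- list()     # i, j, order ("single","double","triple","aromatic")
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NULL
  ring_open <- list()

  bond_symbol_order <- function(sym) {
    switch(sym, "-" = "single", "/" = "single", "\\" = "single",
           "=" = "double", "#" = "triple", ":" = "aromatic",
           stop(sprintf("unparseable SMILES '%s': bond '%s'", smiles, sym)))
  }
  add_atom <- function(at) {
    atoms[[length(atoms) + 1L]] <<- at
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- if (!is.null(pending_bond)) {
        bond_symbol_order(pending_bond)
      } else if (atoms[[prev]]$aromatic && at$aromatic) "aromatic" else "single"
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = ord)
    }
    pending_bond <<- NULL
    prev <<- idx
  }

  for (tk in toks) {
    switch(tk$type,
      atom = add_atom(list(element = tk$text, aromatic = FALSE, charge = 0L,
                           hcount = NA_integer_, explicit_h = FALSE)),
      aromatic_atom = add_atom(list(element = toupper(tk$text), aromatic = TRUE,
                                    charge = 0L, hcount = NA_integer_,
                                    explicit_h = FALSE)),
      bracket = add_atom(.parse_bracket(tk$text, smiles)),
      bond = { pending_bond <- tk$text },
      ring = {
        if (is.na(prev)) stop(sprintf("unparseable SMILES '%s': ring digit before atom", smiles))
        key <- tk$text
        if (is.null(ring_open[[key]])) {
          ring_open[[key]] <- list(atom = prev, bond = pending_bond)
          pending_bond <- NULL
        } else {
          opener <- ring_open[[key]]
          ring_open[[key]] <- NULL
          sym <- if (!is.null(pending_bond)) pending_bond else opener$bond
          ord <- if (!is.null(sym)) {
            bond_symbol_order(sym)
          } else if (atoms[[opener$atom]]$aromatic && atoms[[prev]]$aromatic) {
            "aromatic"
          } else "single"
          bonds[[length(bonds) + 1L]] <- list(i = opener$atom, j = prev, order = ord)
          pending_bond <- NULL
        }
      },
      open = { stack <- c(stack, prev) },
      close = {
        if (length(stack) == 0L) stop(sprintf("unparseable SMILES '%s': unbalanced ')'", smiles))
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
      },
      dot = { prev <- NA_integer_; pending_bond <- NULL }
    )
  }
  if (length(ring_open) > 0L) {
    stop(sprintf("unparseable SMILES '%s': unclosed ring bond", smiles))
  }
  if (length(stack) > 0L) {
    stop(sprintf("unparseable SMILES '%s': unbalanced '('", smiles))
  }
  if (length(atoms) == 0L) stop(sprintf("unparseable SMILES '%s': no atoms", smiles))

  n <- length(atoms)
  bond_order_value <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bond_sum <- numeric(n)
  degree <- integer(n)
  for (b in bonds) {
    bond_sum[b$i] <- bond_sum[b$i] + bond_order_value[[b$order]]
    bond_sum[b$j] <- bond_sum[b$j] + bond_order_value[[b$order]]
    degree[b$i] <- degree[b$i] + 1L
    degree[b$j] <- degree[b$j] + 1L
  }

  node_features <- matrix(0, n, length(node_feature_names()),
                          dimnames = list(NULL, node_feature_names()))
  for (k in seq_len(n)) {
    at <- atoms[[k]]
    slot <- if (at$element %in% MOLGRAPH_ELEMENTS) at$element else "other"
    node_features[k, paste0("elem_", slot)] <- 1
    node_features[k, "aromatic"] <- as.numeric(at$aromatic)
    node_features[k, "charge"] <- at$charge
    h <- at$hcount
    if (!isTRUE(at$explicit_h)) {
      vals <- .default_valences[[at$element]]
      need <- ceiling(bond_sum[k])
      h <- 0L
      if (!is.null(vals)) {
        ok <- vals[vals >= need]
        if (length(ok) > 0L) h <- as.integer(min(ok) - need)
      }
    }
    node_features[k, "n_hydrogens"] <- h
    node_features[k, "degree"] <- degree[k]
  }

  n_bonds <- length(bonds)
  edge_index <- matrix(0L, 2L * n_bonds, 2L)
  edge_features <- matrix(0, 2L * n_bonds, length(edge_feature_names()),
                          dimnames = list(NULL, edge_feature_names()))
  if (n_bonds > 0L) {
    for (k in seq_len(n_bonds)) {
      b <- bonds[[k]]
      feat <- numeric(4L)
      feat[match(paste0("bond_", b$order), edge_feature_names())] <- 1
      edge_index[2L * k - 1L, ] <- c(b$i, b$j)
      edge_index[2L * k, ] <- c(b$j, b$i)
      edge_features[2L * k - 1L, ] <- feat
      edge_features[2L * k, ] <- feat
    }
  }
  structure(list(node_features = node_features, edge_index = edge_index,
                 edge_features = edge_features, smiles = smiles),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d atoms, %d directed edges\n",
              x$smiles, nrow(x$node_features), nrow(x$edge_index)))
  invisible(x)
}

#' Batch molecular graphs into a disjoint union
#'
#' Stacks node and edge matrices with shifted indices and records a
#' node-to-graph membership vector, so per-graph quantities can be pooled
#' back out.  [unbatch_graphs()] inverts the operation exactly.
#'
#' @param graphs Non-empty list of `molgraph` objects.
#' @return A `batched_molgraph`: node/edge matrices of the union, integer
#'   `membership` (1-based graph index per node), `n_graphs`, and the source
#'   SMILES vector.
#' @export
batch_graphs <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L) {
    stop("batch_graphs: need a non-empty list of graphs")
  }
  stopifnot(all(vapply(graphs, inherits, TRUE, "molgraph")))
  nn <- vapply(graphs, function(g) nrow(g$node_features), 0L)
  offs <- cumsum(c(0L, nn[-length(nn)]))
  node_features <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edge_index <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    ei <- graphs[[k]]$edge_index
    if (nrow(ei) == 0L) ei else ei + offs[k]
  }))
  edge_features <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  structure(list(
    node_features = node_features,
    edge_index = edge_index,
    edge_features = edge_features,
    membership = rep(seq_along(graphs), nn),
    n_graphs = length(graphs),
    smiles = vapply(graphs, `[[`, "", "smiles")
  ), class = "batched_molgraph")
}

#' Recover the individual graphs from a batch
#'
#' @param batch A `batched_molgraph` from [batch_graphs()].
#' @return List of `molgraph` objects identical to the batched inputs.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "batched_molgraph"))
  lapply(seq_len(batch$n_graphs), function(k) {
    rows <- which(batch$membership == k)
    off <- min(rows) - 1L
    esel <- batch$edge_index[, 1L] %in% rows
    ei <- batch$edge_index[esel, , drop = FALSE]
    if (nrow(ei) > 0L) ei <- ei - off
    structure(list(
      node_features = batch$node_features[rows, , drop = FALSE],
      edge_index = ei,
      edge_features = batch$edge_features[esel, , drop = FALSE],
      smiles = batch$smiles[k]
    ), class = "molgraph")
  })
}

#' Read SMILES from a plain text file (one per line)
#'
#' Blank lines are dropped; anything after whitespace on a line is treated
#' as an identifier.
#'
#' @param path File path.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\\s+")
  data.frame(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("mol_%d", i)
    }, ""),
    smiles = vapply(parts, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )
}

#' Read SMILES from a named column of a CSV/TSV file
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#' @param column Name of the column holding SMILES.
#' @return Data frame as read, with the SMILES column checked present.
#' @export
read_smiles_table <- function(path, column = "smiles") {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!column %in% names(df)) {
    stop(sprintf("column '%s' not found in %s", column, path))
  }
  df
}
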