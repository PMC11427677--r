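# Synthetic BindingDB-like data with a planted, recoverable binding rule:
# each protein carries exactly one sequence motif, each true binder carries
# the matching pharmacophore appended to a valence-safe scaffold, and
# affinities are the motif's base level plus Gaussian noise with
# BindingDB-like per-label missingness.

#' Define a planted binding rule
#'
#' @param motifs K amino-acid motifs (length 5-8, pairwise non-overlapping
#'   as substrings); each protein carries exactly one.
#' @param pharmacophores K SMILES fragments appended to scaffolds; fragment
#'   k marks the true binders of motif-k proteins.
#' @param base_affinity K base affinities in pK units (-log10 molar).
#' @param noise_sd Gaussian noise added to each label (pK units).
#' @param missing_rates Per-label missingness fractions, named pKi, pKd,
#'   pIC50, pEC50 (IC50 most often measured, mirroring public interaction
#'   tables).
#' @return A `planted_rule` list.
#' @export
planted_rule <- function(motifs = c("WWHKEC", "MYRFDQ", "CPNGTV", "HLIASD"),
                         pharmacophores = c("C(=O)O", "N", "C#N", "S"),
                         base_affinity = c(8.0, 7.0, 9.0, 6.5),
                         noise_sd = 0.4,
                         missing_rates = c(pKi = 0.4, pKd = 0.6,
                                           pIC50 = 0.2, pEC50 = 0.7)) {
  K <- length(motifs)
  if (K < 2L) stop("need at least 2 motifs")
  if (length(pharmacophores) != K || length(base_affinity) != K) {
    stop("motifs, pharmacophores and base_affinity must have equal length")
  }
  if (any(nchar(motifs) < 5L | nchar(motifs) > 8L)) {
    stop("motifs must be 5-8 residues long")
  }
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j && grepl(motifs[i], motifs[j], fixed = TRUE)) {
        stop("motifs must be pairwise non-overlapping as substrings")
      }
    }
  }
  if (!all(names(missing_rates) == AFFINITY_HEADS)) {
    stop("missing_rates must be named pKi, pKd, pIC50, pEC50")
  }
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missing_rates must be in [0, 1)")
  }
  structure(list(motifs = motifs, pharmacophores = pharmacophores,
                 base_affinity = base_affinity, noise_sd = noise_sd,
                 missing_rates = missing_rates, K = K),
            class = "planted_rule")
}

# Fixed scaffold library: short alkyl/ether chains whose terminal carbon
# accepts any appended pharmacophore fragment valence-safely.  A finite
# library keeps ligands shared across proteins, so pair identity carries no
# information and only the motif-pharmacophore rule predicts binding.
SCAFFOLD_LIBRARY <- c("CCC", "CCCC", "CCCCC", "CCCCCC",
                      "CCOCC", "CCOC", "COCCC", "CCCOCC")

.random_scaffold <- function() {
  sample(SCAFFOLD_LIBRARY, 1L)
}

#' Generate synthetic proteins carrying planted motifs
#'
#' Uniform-background sequences over the 20 standard residues; the assigned
#' motif replaces a window at a random position (replacement, not insertion,
#' keeps lengths fixed).
#'
#' @param rule A [planted_rule()].
#' @param n Number of proteins.
#' @param seq_len_range Length range `c(min, max)`.
#' @param seed Seed (deterministic output).
#' @param motif_assignment Optional integer vector of motif indices per
#'   protein (default round-robin over the K motifs).
#' @return Data frame with `id`, `sequence`, `motif_index`.
#' @export
generate_proteins <- function(rule, n, seq_len_range = c(60L, 100L), seed = 1L,
                              motif_assignment = NULL) {
  if (is.null(motif_assignment)) {
    motif_assignment <- rep(seq_len(rule$K), length.out = n)
  }
  aa20 <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      L <- sample(seq_len_range[1L]:seq_len_range[2L], 1L)
      s <- sample(aa20, L, replace = TRUE)
      motif <- strsplit(rule$motifs[motif_assignment[i]], "")[[1]]
      pos <- sample.int(L - length(motif) + 1L, 1L)
      s[pos:(pos + length(motif) - 1L)] <- motif
      paste0(s, collapse = "")
    }, "")
    data.frame(id = sprintf("prot_%03d", seq_len(n)), sequence = seqs,
               motif_index = motif_assignment, stringsAsFactors = FALSE)
  })
}

#' Generate a BindingDB-like interaction dataset with a planted rule
#'
#' Each protein carries one motif; each true binder is a random scaffold
#' carrying the matching pharmacophore; each label is the motif's base
#' affinity plus `Normal(0, noise_sd)`, then masked missing independently at
#' its configured rate (records with all four labels missing are dropped).
#' Deterministic under `seed`.
#'
#' @param rule A [planted_rule()].
#' @param n_proteins Number of proteins (`>= K`).
#' @param ligands_per_protein Binders generated per protein.
#' @param seq_len_range Protein length range.
#' @param seed Seed.
#' @return List with `records` (interaction data frame), `proteins`,
#'   `binder_index`, and `rule`.
#' @export
generate_dataset <- function(rule, n_proteins = 40L, ligands_per_protein = 50L,
                             seq_len_range = c(60L, 100L), seed = 1L) {
  stopifnot(inherits(rule, "planted_rule"))
  if (n_proteins < rule$K) stop("need at least one protein per motif")
  proteins <- generate_proteins(rule, n_proteins, seq_len_range, seed)
  with_seed(seed + 1L, {
    rows <- list()
    for (i in seq_len(n_proteins)) {
      k <- proteins$motif_index[i]
      for (j in seq_len(ligands_per_protein)) {
        smi <- paste0(.random_scaffold(), rule$pharmacophores[k])
        labs <- rule$base_affinity[k] + stats::rnorm(4L, 0, rule$noise_sd)
        miss <- stats::runif(4L) < rule$missing_rates
        labs[miss] <- NA_real_
        if (all(is.na(labs))) next
        rows[[length(rows) + 1L]] <- data.frame(
          protein_sequence = proteins$sequence[i], smiles = smi,
          pKi = labs[1L], pKd = labs[2L], pIC50 = labs[3L], pEC50 = labs[4L],
          is_decoy = FALSE, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    list(records = records, proteins = proteins,
         binder_index = build_binder_index(records), rule = rule)
  })
}

#' Generate a labelled actives/decoys screening library
#'
#' Actives carry the pharmacophore matching the given motif; decoys carry a
#' mismatched pharmacophore or a plain scaffold.  Deterministic under
#' `seed`.
#'
#' @param rule A [planted_rule()].
#' @param motif_index Which motif class the target protein carries.
#' @param n_actives,n_decoys Library composition (each `>= 1`).
#' @param seed Seed.
#' @return Data frame with `smiles` and `is_active`.
#' @export
generate_screen <- function(rule, motif_index, n_actives, n_decoys, seed = 1L) {
  stopifnot(inherits(rule, "planted_rule"))
  if (motif_index < 1L || motif_index > rule$K) stop("motif_index out of range")
  if (n_actives < 1L || n_decoys < 1L) stop("need at least one active and one decoy")
  with_seed(seed, {
    actives <- vapply(seq_len(n_actives), function(i) {
      paste0(.random_scaffold(), rule$pharmacophores[motif_index])
    }, "")
    wrong <- c(rule$pharmacophores[-motif_index], "")
    decoys <- vapply(seq_len(n_decoys), function(i) {
      paste0(.random_scaffold(), sample(wrong, 1L))
    }, "")
    data.frame(smiles = c(actives, decoys),
               is_active = rep(c(TRUE, FALSE), c(n_actives, n_decoys)),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the training TSV, a FASTA of the proteins, and a JSON manifest
#' recording the rule, seed, and counts.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "interactions.tsv")
  write_interactions(dataset$records, tsv)
  fasta <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", dataset$proteins$id, " motif_", dataset$proteins$motif_index,
                    "\n", dataset$proteins$sequence), fasta)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    rule = unclass(dataset$rule),
    seed = seed,
    n_proteins = nrow(dataset$proteins),
    n_records = nrow(dataset$records)
  ), manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(interactions = tsv, proteins = fasta, manifest = manifest))
}
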