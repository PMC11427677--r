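test_that("planted rules validate their structure", {
  expect_s3_class(planted_rule(), "planted_rule")
  expect_error(planted_rule(motifs = "AAAAA", pharmacophores = "N",
                            base_affinity = 7), "at least 2")
  expect_error(planted_rule(motifs = c("AAAA", "CCCCC"),
                            pharmacophores = c("N", "S"),
                            base_affinity = c(7, 8)), "5-8")
  expect_error(planted_rule(motifs = c("ACDEF", "ACDEFGH"),
                            pharmacophores = c("N", "S"),
                            base_affinity = c(7, 8)), "non-overlapping")
  expect_error(planted_rule(missing_rates = c(pKi = 1, pKd = 0, pIC50 = 0,
                                              pEC50 = 0)), "missing_rates")
})

test_that("dataset generation is deterministic with the expected composition", {
  rule <- planted_rule(noise_sd = 0)
  ds1 <- generate_dataset(rule, n_proteins = 8L, ligands_per_protein = 5L,
                          seq_len_range = c(40L, 60L), seed = 9L)
  ds2 <- generate_dataset(rule, n_proteins = 8L, ligands_per_protein = 5L,
                          seq_len_range = c(40L, 60L), seed = 9L)
  expect_identical(ds1, ds2)
  expect_lte(nrow(ds1$records), 40L)   # records with all labels missing drop
  expect_equal(nrow(ds1$proteins), 8L)

  # every protein carries exactly its assigned motif
  for (i in seq_len(8)) {
    expect_true(grepl(rule$motifs[ds1$proteins$motif_index[i]],
                      ds1$proteins$sequence[i], fixed = TRUE))
    others <- rule$motifs[-ds1$proteins$motif_index[i]]
    expect_false(any(vapply(others, grepl, TRUE,
                            x = ds1$proteins$sequence[i], fixed = TRUE)))
  }
  # with zero noise, present labels equal the motif's base affinity exactly
  for (r in seq_len(nrow(ds1$records))) {
    k <- ds1$proteins$motif_index[
      match(ds1$records$protein_sequence[r], ds1$proteins$sequence)]
    labs <- unlist(ds1$records[r, c("pKi", "pKd", "pIC50", "pEC50")])
    expect_true(all(labs[!is.na(labs)] == rule$base_affinity[k]))
  }
  # binders carry the matching pharmacophore fragment
  for (r in sample(nrow(ds1$records), 10)) {
    k <- ds1$proteins$motif_index[
      match(ds1$records$protein_sequence[r], ds1$proteins$sequence)]
    expect_true(grepl(rule$pharmacophores[k], ds1$records$smiles[r],
                      fixed = TRUE))
  }
})

test_that("all generated SMILES parse through the graph builder", {
  rule <- planted_rule()
  ds <- generate_dataset(rule, n_proteins = 8L, ligands_per_protein = 10L,
                         seed = 10L)
  for (s in unique(ds$records$smiles)) {
    expect_s3_class(smiles_to_graph(s), "molgraph")
  }
  lib <- generate_screen(rule, 2L, n_actives = 5L, n_decoys = 20L, seed = 11L)
  for (s in lib$smiles) expect_s3_class(smiles_to_graph(s), "molgraph")
})

test_that("label missingness matches the configured rates within binomial bounds", {
  rates <- c(pKi = 0.4, pKd = 0.6, pIC50 = 0.2, pEC50 = 0.7)
  rule <- planted_rule(missing_rates = rates)
  ds <- generate_dataset(rule, n_proteins = 40L, ligands_per_protein = 50L,
                         seed = 12L)
  n_gen <- 40L * 50L   # pre-drop draws are per generated record
  for (h in names(rates)) {
    n_missing_kept <- sum(is.na(ds$records[[h]]))
    n_dropped <- n_gen - nrow(ds$records)
    # records dropped had all four labels missing; add them back for the
    # per-label missingness count
    p_hat <- (n_missing_kept + n_dropped) / n_gen
    bound <- 2.58 * sqrt(rates[[h]] * (1 - rates[[h]]) / n_gen)
    expect_lt(abs(p_hat - rates[[h]]), bound + 0.01,
              label = sprintf("missing rate of %s", h))
  }
})

test_that("screening libraries separate actives from decoys by construction", {
  rule <- planted_rule()
  lib <- generate_screen(rule, 1L, n_actives = 5L, n_decoys = 95L, seed = 13L)
  expect_equal(nrow(lib), 100L)
  expect_equal(sum(lib$is_active), 5L)
  ph <- rule$pharmacophores[1]
  for (s in lib$smiles[lib$is_active]) {
    expect_true(grepl(ph, s, fixed = TRUE))
  }
  # decoys never end with the matching pharmacophore (it can only appear as
  # the appended suffix by construction)
  for (s in lib$smiles[!lib$is_active]) {
    expect_false(endsWith(s, ph))
  }
  lib2 <- generate_screen(rule, 1L, n_actives = 5L, n_decoys = 95L, seed = 13L)
  expect_identical(lib, lib2)
  expect_error(generate_screen(rule, 9L, 5L, 5L), "out of range")
})

test_that("a linear probe recovers the planted motif class from toy latents", {
  skip_if_not_installed("nnet")
  # The probe reads the latent of the motif's central residue: the planted
  # signal must be linearly separable at the residues that carry it, which
  # is what ligand-conditioned attention over residues can exploit.
  rule <- planted_rule()
  prot <- generate_proteins(rule, 120L, seq_len_range = c(60L, 80L), seed = 14L)
  be <- toy_embedder()
  X <- t(vapply(seq_len(nrow(prot)), function(i) {
    s <- prot$sequence[i]
    motif <- rule$motifs[prot$motif_index[i]]
    pos <- regexpr(motif, s, fixed = TRUE)[1]
    embed_sequence(s, 1L, be)$layers[[1]][pos + 3L, ]
  }, numeric(be$d_embed)))
  train <- seq_len(90L); test <- 91:120
  fit <- nnet::multinom(cls ~ ., data = data.frame(cls = factor(prot$motif_index[train]),
                                                   X[train, ]),
                        trace = FALSE, MaxNWts = 5000)
  pred <- predict(fit, newdata = data.frame(X[test, ]))
  acc <- mean(pred == factor(prot$motif_index[test]))
  expect_gt(acc, 0.95)
})

test_that("written datasets carry TSV, FASTA, and a valid manifest", {
  rule <- planted_rule()
  ds <- generate_dataset(rule, n_proteins = 4L, ligands_per_protein = 5L,
                         seed = 15L)
  dir <- tempfile()
  files <- write_dataset(ds, dir, seed = 15L)
  expect_true(all(file.exists(files)))
  rec <- read_interactions(files[["interactions"]])
  expect_equal(nrow(rec), nrow(ds$records))
  fa <- read_fasta(files[["proteins"]])
  expect_equal(fa$sequence, ds$proteins$sequence)
  man <- jsonlite::read_json(files[["manifest"]])
  expect_equal(man$seed, 15L)
  expect_equal(man$n_records, nrow(ds$records))
  expect_equal(unlist(man$rule$motifs), rule$motifs)
})
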