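test_that("affinity normalization follows -log10(x/1e9)", {
  expect_equal(normalize_affinity(1), 9)
  expect_equal(normalize_affinity(1e9), 0)
  expect_equal(normalize_affinity(0.1), 10)
  expect_error(normalize_affinity(0), "positive")
  expect_error(normalize_affinity(-3), "positive")
  expect_error(normalize_affinity(NA), "finite")
})

test_that("interaction TSV round-trips and drops qualified measurements", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(
    c("protein_sequence\tsmiles\tki_nM\tkd_nM\tic50_nM\tec50_nM",
      "ACDEF\tCCO\t1\t\t10\t",
      "ACDEF\tCCN\t>1000\t\t\t",      # only a qualified value: dropped
      "GHIKL\tCCS\t\t0.1\t\t100"),
    collapse = "\n"), tf)
  rec <- read_interactions(tf)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pKi[1], 9)
  expect_equal(rec$pIC50[1], 8)
  expect_true(is.na(rec$pKd[1]))
  expect_equal(rec$pKd[2], 10)
  expect_equal(rec$pEC50[2], 7)

  tf2 <- tempfile(fileext = ".tsv")
  write_interactions(rec, tf2)
  rec2 <- read_interactions(tf2)
  expect_equal(rec2$pKi, rec$pKi, tolerance = 1e-6)
  expect_equal(rec2$pEC50, rec$pEC50, tolerance = 1e-6)
})

test_that("decoy sampling never returns a known binder and errors on exhaustion", {
  idx <- list(P1 = c("L1", "L2"), P2 = "L3")
  set.seed(51)
  # only one valid choice for P1
  for (i in 1:20) {
    expect_equal(sample_decoy(list(protein_sequence = "P1"), idx), "L3")
  }
  draws <- replicate(50, sample_decoy(list(protein_sequence = "P2"), idx))
  expect_true(all(draws %in% c("L1", "L2")))
  expect_error(sample_decoy(list(protein_sequence = "P"), list(P = "L1"),
                            ligand_pool = "L1"),
               "retries")
})

test_that("the masked loss has the printed Huber values and zeroizes correctly", {
  pred <- data.frame(pKi = 9, pKd = 5, pIC50 = 7, pEC50 = 6, logit = 2)
  rec <- list(pKi = 8, pKd = NA, pIC50 = 3, pEC50 = NA, is_decoy = FALSE)
  L <- compute_loss(pred, rec, delta = 2)
  expect_equal(unname(L$terms["pKi"]), 0.5)        # residual 1 -> 0.5 e^2
  expect_equal(unname(L$terms["pIC50"]), 6.0)      # residual 4 -> delta(|e|-delta/2)
  expect_false("pKd" %in% names(L$terms))
  expect_false("pEC50" %in% names(L$terms))
  expect_equal(unname(L$terms["bce"]), log1p(exp(-2)))
  expect_equal(L$total, sum(L$terms))
  expect_equal(L$mean, mean(L$terms))

  # decoys: all four regression terms vanish even if a label sneaks in
  rec_d <- list(pKi = 8, pKd = 7, pIC50 = 3, pEC50 = 2, is_decoy = TRUE)
  Ld <- compute_loss(pred, rec_d, delta = 2)
  expect_equal(names(Ld$terms), "bce")
  expect_equal(unname(Ld$terms["bce"]), 2 + log1p(exp(-2)))
})

test_that("absent labels and decoys give exactly zero gradient to their heads", {
  bs <- asNamespace("bindscreen")
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  g <- batch_graphs(list(smiles_to_graph("CCOC(=O)N")))
  stk <- embed_sequence("ACDEFGHIKLMNP", c(0L, 1L), be)

  grad_for <- function(rec) {
    tape <- bs$ad_tape()
    Pn <- list()
    for (nm in names(m$params)) Pn[[nm]] <- bs$ad_param(tape, m$params[[nm]], nm)
    fw <- bs$.bind_forward(tape, Pn, cfg, g, stk$layers, training = FALSE)
    ln <- bs$.loss_nodes(tape, fw, rec, 2)
    bs$ad_param_grads(tape, bs$ad_backward(tape, ln$total))
  }
  gr <- grad_for(list(pKi = 8, pKd = NA, pIC50 = 7.5, pEC50 = NA, is_decoy = FALSE))
  for (nm in c("head_pKd.W1", "head_pKd.W2", "head_pKd.b1", "head_pKd.b2",
               "head_pEC50.W1", "head_pEC50.W2")) {
    expect_true(all(gr[[nm]] == 0), label = sprintf("zero grad into %s", nm))
  }
  expect_true(any(gr[["head_pKi.W1"]] != 0))
  expect_true(any(gr[["head_logit.W1"]] != 0))

  # decoy with corrupted labels present: regression heads get exact zero
  gr_d <- grad_for(list(pKi = 8, pKd = 7, pIC50 = 6, pEC50 = 5, is_decoy = TRUE))
  for (h in c("pKi", "pKd", "pIC50", "pEC50")) {
    expect_true(all(gr_d[[sprintf("head_%s.W1", h)]] == 0))
    expect_true(all(gr_d[[sprintf("head_%s.W2", h)]] == 0))
  }
  expect_true(any(gr_d[["head_logit.W1"]] != 0))
})

test_that("splits are exact, disjoint, exhaustive, and seed-reproducible", {
  rec <- data.frame(protein_sequence = sprintf("P%03d", 1:100),
                    smiles = sprintf("C%d", 1:100),
                    pKi = 7, pKd = NA, pIC50 = NA, pEC50 = NA,
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  sp <- split_dataset(rec, c(0.90, 0.02, 0.08), seed = 7L)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$val), 2L)
  expect_equal(nrow(sp$test), 8L)
  ids <- c(sp$train$protein_sequence, sp$val$protein_sequence,
           sp$test$protein_sequence)
  expect_setequal(ids, rec$protein_sequence)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- split_dataset(rec, c(0.90, 0.02, 0.08), seed = 7L)
  expect_identical(sp, sp2)
  expect_error(split_dataset(rec[0, ], c(0.9, 0.02, 0.08), 1L), "empty")
})

test_that("alignment identity agrees with the dynamic-programming oracle", {
  set.seed(52)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  for (rep in 1:25) {
    q <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
    r <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
    expect_equal(alignment_identity(q, r),
                 oracle_match_count(q, r) / nchar(r),
                 tolerance = 1e-12)
  }
  expect_equal(alignment_identity("ACDE", "ACDE"), 1)
})

test_that("homology filtering removes planted homologs and keeps the unrelated", {
  set.seed(53)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 100, TRUE), collapse = "")
  # 95 matching positions out of a 100-residue reference: identity 0.95
  hom <- strsplit(ref, "")[[1]]
  flip <- sample(100, 5)
  for (i in flip) hom[i] <- sample(setdiff(aa, hom[i]), 1)
  hom <- paste(hom, collapse = "")
  unrel <- paste(sample(aa, 80, TRUE), collapse = "")
  rec <- data.frame(protein_sequence = c(ref, hom, unrel),
                    smiles = c("C", "CC", "CCC"),
                    pKi = 7, pKd = NA, pIC50 = NA, pEC50 = NA,
                    is_decoy = FALSE, stringsAsFactors = FALSE)
  kept <- homology_filter(rec, ref, threshold = 0.90)
  expect_false(ref %in% kept$protein_sequence)    # identity 1.0
  expect_false(hom %in% kept$protein_sequence)    # identity 0.95 > 0.90
  expect_true(unrel %in% kept$protein_sequence)
  expect_warning(homology_filter(rec, character(0)), "unchanged")
  expect_error(homology_filter(rec, ref, threshold = 0), "threshold")
})

test_that("cosine decay matches its closed form with no warm-up", {
  lr0 <- 1e-4
  Tt <- 1000
  expect_equal(cosine_lr(0, Tt, lr0), lr0)
  expect_equal(cosine_lr(Tt, Tt, lr0), 0, tolerance = 1e-20)
  expect_equal(cosine_lr(Tt / 2, Tt, lr0), lr0 * cos(pi / 4)^2, tolerance = 1e-12)
  expect_equal(cosine_lr(Tt / 2, Tt, lr0), lr0 / 2, tolerance = 1e-12)
})

test_that("a short fit run reduces the loss and leaves the embedder frozen", {
  rule <- planted_rule(motifs = c("WWHKE", "MYRFD"),
                       pharmacophores = c("C(=O)O", "N"),
                       base_affinity = c(8, 6.5), noise_sd = 0.2,
                       missing_rates = c(pKi = 0.2, pKd = 0.5,
                                         pIC50 = 0.2, pEC50 = 0.5))
  ds <- generate_dataset(rule, n_proteins = 6L, ligands_per_protein = 10L,
                         seq_len_range = c(30L, 40L), seed = 5L)
  cfg <- small_config()
  be <- small_backend()
  checksum0 <- bindscreen:::embedder_checksum(be)
  tc <- train_config(lr = 3e-3, total_iterations = 30L,
                     accumulation_steps = 8L, seed = 2L, eval_every = 10L)
  sp <- split_dataset(ds$records, c(0.8, 0.1, 0.1), seed = 2L)
  fit <- fit_bind(sp$train, sp$val, cfg, tc, be)

  expect_equal(nrow(fit$history), 30L)
  expect_lt(mean(tail(fit$history$train_loss, 10)),
            mean(head(fit$history$train_loss, 10)))
  # learning rate column follows the cosine schedule exactly
  expect_equal(fit$history$lr,
               cosine_lr(0:29, 30L, 3e-3), tolerance = 1e-15)
  # the backend was never touched by training
  expect_identical(bindscreen:::embedder_checksum(be), checksum0)
  # checkpoint round-trip reproduces the validation loss bit-for-bit
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, tf)
  m2 <- load_checkpoint(tf)
  expect_identical(m2$params, fit$model$params)
})
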