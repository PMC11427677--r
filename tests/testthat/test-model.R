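test_that("single-key attention with identity projections returns the value row", {
  d <- 4L
  p <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d),
            bo = numeric(d))
  H <- matrix(c(1, 2, 3, 4), 1, d)
  E <- matrix(c(5, 6, 7, 8), 1, d)
  out <- cross_attention_graph_block(H, E, NULL, p, n_heads = 1L,
                                     residual = FALSE, norm = FALSE)
  # softmax over one key is 1, so the output is the value projection of E
  expect_equal(out, E %*% p$Wv, ignore_attr = TRUE)
})

test_that("cross-attention matches the brute-force per-node oracle", {
  set.seed(41)
  for (rep in 1:100) {
    n_heads <- sample(c(1L, 2L, 4L), 1)
    d <- n_heads * sample(2:4, 1)
    n <- sample(1:10, 1)
    L <- sample(2:20, 1)
    H <- matrix(rnorm(n * d), n)
    E <- matrix(rnorm(L * d), L)
    mask <- if (rep %% 3 == 0) {
      m <- runif(L) > 0.3
      if (!any(m)) m[1] <- TRUE
      m
    } else NULL
    p <- random_attention_params(d, with_ln = FALSE)
    got <- cross_attention_graph_block(H, E, mask, p, n_heads,
                                       residual = FALSE, norm = FALSE)
    want <- oracle_attention(H, E, mask, p, n_heads)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("masked residues receive exactly zero attention weight", {
  set.seed(42)
  d <- 4L
  H <- matrix(rnorm(3 * d), 3)
  E <- matrix(rnorm(8 * d), 8)
  mask <- rep(TRUE, 8); mask[c(3, 4)] <- FALSE
  p <- random_attention_params(d)
  res <- cross_attention_graph_block(H, E, mask, p, n_heads = 2L,
                                     return_attention = TRUE)
  for (A in res$attention) {
    expect_true(all(A[, c(3, 4)] == 0))
    expect_equal(rowSums(A), rep(1, 3))
  }
  expect_error(cross_attention_graph_block(H, E, rep(FALSE, 8), p, 2L),
               "masked")
  expect_error(cross_attention_graph_block(H, matrix(rnorm(16), 8, 2), NULL, p, 2L),
               "width mismatch")
})

test_that("graph convolution respects locality and symmetry", {
  set.seed(43)
  d <- 6L
  p <- list(W_src = matrix(rnorm(d * d), d), W_tgt = matrix(rnorm(d * d), d),
            W_edge = matrix(rnorm(4 * d), 4), a = matrix(rnorm(d), d, 1),
            b_out = rnorm(d))
  # single node, no edges: self-message only
  H1 <- matrix(rnorm(d), 1)
  out1 <- gatv2_conv(H1, matrix(0L, 0, 2), matrix(0, 0, 4), p)
  expect_equal(dim(out1), c(1L, d))
  expect_equal(out1, H1 %*% p$W_src + matrix(p$b_out, 1), ignore_attr = TRUE)

  # two isolated components: perturbing one leaves the other bitwise unchanged
  H <- matrix(rnorm(4 * d), 4)
  ei <- rbind(c(1L, 2L), c(2L, 1L), c(3L, 4L), c(4L, 3L))
  ef <- matrix(rnorm(4 * 4), 4)
  base <- gatv2_conv(H, ei, ef, p)
  H2 <- H; H2[3, ] <- rnorm(d)
  pert <- gatv2_conv(H2, ei, ef, p)
  expect_identical(base[1:2, ], pert[1:2, ])
  expect_false(isTRUE(all.equal(base[3:4, ], pert[3:4, ])))

  # uniform features on a triangle give identical rows
  Ht <- matrix(rep(rnorm(d), each = 3), 3)
  eit <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L), c(1L, 3L), c(3L, 1L))
  eft <- matrix(1, 6, 4)
  outt <- gatv2_conv(Ht, eit, eft, p)
  expect_equal(outt[1, ], outt[2, ])
  expect_equal(outt[2, ], outt[3, ])

  expect_error(gatv2_conv(H, rbind(c(1L, 9L)), matrix(0, 1, 4), p), "outside")
})

test_that("pooling modes reduce correctly and sum/mean are permutation invariant", {
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(pool_nodes(X, c(1L, 1L), "sum"), matrix(c(4, 6), 1),
               ignore_attr = TRUE)
  expect_equal(pool_nodes(matrix(c(7, 8), 1), 1L, "mean"), matrix(c(7, 8), 1),
               ignore_attr = TRUE)
  expect_error(pool_nodes(X, c(1L, 3L), "sum"), "zero nodes")

  set.seed(44)
  Y <- matrix(rnorm(6 * 3), 6)
  memb <- c(1L, 1L, 1L, 1L, 2L, 2L)
  base <- pool_nodes(Y, memb, "sum")
  for (rep in 1:100) {
    perm <- sample(6)
    expect_equal(pool_nodes(Y[perm, ], memb[perm], "sum"), base,
                 tolerance = 1e-12)
  }
  # lcm reduces with a learned commutative operator: swapping the two
  # children of any pair leaves the result unchanged
  d <- 4L
  lp <- list(W1 = matrix(rnorm(2 * d * d), 2 * d), b1 = rnorm(d),
             W2 = matrix(rnorm(d * d), d), b2 = rnorm(d))
  Z <- matrix(rnorm(2 * d), 2)
  expect_equal(pool_nodes(Z, c(1L, 1L), "lcm", lp),
               pool_nodes(Z[2:1, ], c(1L, 1L), "lcm", lp), tolerance = 1e-12)
})

test_that("logit scaling applies exp(tau) then clips symmetrically", {
  expect_equal(scale_logit(1.0, 0.07, 100), exp(0.07))
  expect_equal(scale_logit(200, 0, 100), 100)
  expect_equal(scale_logit(-500, 0, 100), -100)
  expect_error(scale_logit(NaN, 0), "finite")
  expect_error(scale_logit(Inf, 0), "finite")
  # adversarial magnitudes stay inside the clip even when the product
  # overflows to Inf
  expect_equal(abs(scale_logit(1e300, 700, 100)), 100)
  expect_equal(scale_logit(-1e300, 700, 100), -100)
})

test_that("forward pass is deterministic, clipped, and layer-checked", {
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  g <- smiles_to_graph("CCOCC(=O)O")
  stk <- embed_sequence("ACDEFGHIKLMNPQ", c(0L, 1L), be)
  p1 <- bind_predict(m, g, stk)
  p2 <- bind_predict(m, g, stk)
  expect_identical(p1, p2)
  expect_true(abs(p1$logit) <= cfg$logit_clip)
  expect_equal(p1$probability, 1 / (1 + exp(-p1$logit)))
  bad <- embed_sequence("ACDEFGHIKLMNPQ", c(0L), be)
  expect_error(bind_predict(m, g, bad), "expects")
})

test_that("the trainable parameter census excludes the frozen embedder", {
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  # every trainable parameter belongs to a named network component
  expect_true(all(grepl("^(embed|conv|xatt|ffn|lcm|pool_ln|head_|tau)",
                        names(m$params))))
  # and the embedder weight count is not part of the census
  n_embedder <- length(be$proj) + sum(vapply(be$layers,
                                             function(l) length(l$A) + length(l$b), 0))
  expect_equal(n_parameters(m), sum(vapply(m$params, length, 0L)))
  expect_false(n_parameters(m) == n_parameters(m) + n_embedder)
})

test_that("full forward is permutation invariant under sum and mean pooling", {
  be <- small_backend()
  stk <- embed_sequence("ACDEFGHIKLMNPQRSTVWY", c(0L, 1L), be)
  g <- smiles_to_graph("CCOC(=O)CCN")
  set.seed(45)
  for (mode in c("sum", "mean")) {
    cfg <- small_config(pooling = mode)
    m <- bind_model(cfg, d_latent = 8L)
    base <- bind_predict(m, g, stk)
    for (rep in 1:5) {
      perm <- sample(nrow(g$node_features))
      gp <- permute_molgraph(g, perm)
      got <- bind_predict(m, gp, stk)
      expect_equal(got$logit, base$logit, tolerance = 1e-6)
      expect_equal(got$pKi, base$pKi, tolerance = 1e-6)
    }
  }
})

test_that("the logit responds to a single-residue change (non-degeneracy)", {
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  g <- smiles_to_graph("CCOCC")
  s1 <- "ACDEFGHIKLMNPQ"
  s2 <- "ACDEFGYIKLMNPQ"  # one substitution inside the attended region
  p1 <- bind_predict(m, g, embed_sequence(s1, c(0L, 1L), be))
  p2 <- bind_predict(m, g, embed_sequence(s2, c(0L, 1L), be))
  expect_false(p1$logit == p2$logit)
})

test_that("checkpoints round-trip and refuse mismatched versions", {
  cfg <- small_config()
  m <- bind_model(cfg, d_latent = 8L)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(m, tf)
  m2 <- load_checkpoint(tf)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  obj <- readRDS(tf)
  obj$format_version <- 999L
  saveRDS(obj, tf)
  expect_error(load_checkpoint(tf), "format version")
  expect_error(load_checkpoint(tempfile()), "not found")
})
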