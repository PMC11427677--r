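# Shared fixtures.  The trained desk-scale model is expensive, so it is
# built once per test run and reused by every test that needs it.

.fixture_env <- new.env(parent = emptyenv())

# Small model configuration used by mechanics tests (fast).
small_config <- function(pooling = "lcm", ...) {
  bind_config(d_hidden = 8L, n_attention_heads = 2L,
              encoder_layer_indices = c(0L, 1L), dropout = 0,
              pooling = pooling, seed = 3L, ...)
}

small_backend <- function() toy_embedder(d_embed = 8L, n_layers = 1L)

# Desk-scale study: the full planted-rule dataset and a trained model
# (d_hidden 64, toy embedder, seed 0).  Training hyperparameters are the
# package's desk-scale defaults (see the methods vignette).
desk_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  rule <- planted_rule()
  ds <- generate_dataset(rule, n_proteins = 100L, ligands_per_protein = 20L,
                         seed = 1L)
  cfg <- bind_config(seed = 0L)
  tc <- train_config(lr = 1e-3, total_iterations = 1500L,
                     accumulation_steps = 64L, seed = 0L, eval_every = 150L)
  sp <- split_dataset(ds$records, tc$split_fractions, seed = 0L)
  backend <- toy_embedder()
  fit <- fit_bind(sp$train, sp$val, cfg, tc, backend)
  .fixture_env$study <- list(rule = rule, dataset = ds, split = sp,
                             config = cfg, tc = tc, backend = backend,
                             fit = fit, model = fit$model)
  .fixture_env$study
}
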