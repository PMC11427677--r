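make_screen <- function(labels_in_rank_order) {
  n <- length(labels_in_rank_order)
  ranked_screen(seq_len(n), seq(n, 1), labels_in_rank_order)
}

test_that("ranked screens sort by score with stable, documented tie-breaking", {
  s <- ranked_screen(c("a", "b", "c", "d"), c(0.2, 0.9, 0.2, 0.5))
  expect_equal(s$id, c("b", "d", "a", "c"))  # ties keep input order
  expect_equal(s$rank, 1:4)
  expect_error(ranked_screen("a", NaN), "finite")
})

test_that("enrichment factor matches the concentration-ratio definition", {
  sc <- make_screen(rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(enrichment_factor(sc, 0.10), 10)    # perfect ranking: N/A
  # all-active screens have equal subset and dataset concentrations: EF = 1
  all_act <- make_screen(rep(TRUE, 50))
  expect_equal(enrichment_factor(all_act, 0.1), 1)
  # N = 200, 20 actives, 4 of them in the top 10 (5%)
  lab <- rep(FALSE, 200)
  lab[c(1, 4, 7, 9)] <- TRUE
  lab[101:116] <- TRUE
  sc2 <- make_screen(lab)
  expect_equal(enrichment_factor(sc2, 0.05), (4 / 10) / (20 / 200))
  expect_error(enrichment_factor(sc2, 0), "fraction")
  expect_error(enrichment_factor(sc2, 1.5), "fraction")
  expect_error(enrichment_factor(make_screen(rep(FALSE, 10)), 0.1), "no actives")
})

test_that("success rate is the subset active concentration", {
  sc <- make_screen(rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(success_rate(sc, 0.05), 1)          # subset smaller than actives
  lab <- rep(FALSE, 100); lab[c(2, 5, 8, 9)] <- TRUE; lab[50:60] <- TRUE
  expect_equal(success_rate(make_screen(lab), 0.10), 0.4)
  lab2 <- rep(FALSE, 100); lab2[90:95] <- TRUE
  expect_equal(success_rate(make_screen(lab2), 0.10), 0)
})

test_that("EF and success rate stay consistent on random instances", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(50:300, 1)
    lab <- runif(n) < 0.1
    if (!any(lab)) lab[1] <- TRUE
    if (all(lab)) lab[1] <- FALSE
    sc <- ranked_screen(seq_len(n), rnorm(n), lab)
    f <- runif(1, 0.01, 1)
    expect_equal(enrichment_factor(sc, f),
                 success_rate(sc, f) / (sum(lab) / n), tolerance = 1e-12)
  }
})

test_that("BEDROC hits its normalization bounds and matches direct summation", {
  best <- make_screen(rep(c(TRUE, FALSE), c(5, 45)))
  worst <- make_screen(rep(c(FALSE, TRUE), c(45, 5)))
  expect_equal(bedroc(best, 80.5), 1)
  expect_equal(bedroc(worst, 80.5), 0)
  expect_error(bedroc(best, -1), "alpha")

  # N = 20, actives at ranks 1, 5, 12
  lab <- rep(FALSE, 20); lab[c(1, 5, 12)] <- TRUE
  sc <- make_screen(lab)
  expect_equal(bedroc(sc, 80.5), oracle_bedroc(c(1, 5, 12), 20, 80.5),
               tolerance = 1e-10)

  set.seed(62)
  for (rep in 1:200) {
    n <- sample(10:200, 1)
    n_act <- sample(seq_len(n - 1), 1)
    ranks <- sort(sample(n, n_act))
    lab <- rep(FALSE, n); lab[ranks] <- TRUE
    alpha <- runif(1, 1, 120)
    expect_equal(bedroc(make_screen(lab), alpha),
                 oracle_bedroc(ranks, n, alpha), tolerance = 1e-10)
  }
})

test_that("BEDROC improves monotonically when an active moves up one rank", {
  # exhaustive over all label placements for N <= 12
  for (n in c(6, 9, 12)) {
    for (n_act in c(1, 2, 3)) {
      combs <- utils::combn(n, n_act)
      for (j in seq_len(ncol(combs))) {
        ranks <- combs[, j]
        movable <- ranks[ranks > 1 & !((ranks - 1) %in% ranks)]
        for (r in movable) {
          up <- sort(replace(ranks, ranks == r, r - 1))
          lab <- rep(FALSE, n); lab[ranks] <- TRUE
          lab_up <- rep(FALSE, n); lab_up[up] <- TRUE
          expect_gte(bedroc(make_screen(lab_up), 20),
                     bedroc(make_screen(lab), 20))
        }
      }
    }
  }
})

test_that("AUROC equals exhaustive pair enumeration, with ties at 1/2", {
  sc <- ranked_screen(1:4, c(0.9, 0.8, 0.7, 0.6),
                      c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auroc(sc), 0.75)
  expect_equal(auroc(make_screen(rep(c(TRUE, FALSE), c(5, 5)))), 1)
  expect_equal(auroc(make_screen(rep(c(FALSE, TRUE), c(5, 5)))), 0)
  expect_error(auroc(make_screen(rep(TRUE, 4))), "no inactives")

  set.seed(63)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    scores <- sample(seq_len(8), n, TRUE) / 8   # force ties
    lab <- runif(n) < 0.4
    if (!any(lab)) lab[1] <- TRUE
    if (all(lab)) lab[n] <- FALSE
    sc <- ranked_screen(seq_len(n), scores, lab)
    expect_equal(auroc(sc), oracle_auroc(scores, lab), tolerance = 1e-12)
  }
})

test_that("random rankings calibrate to EF ~ 1 and AUROC ~ 0.5", {
  set.seed(64)
  n <- 500
  lab <- rep(c(TRUE, FALSE), c(25, 475))
  efs <- numeric(1000); aucs <- numeric(1000)
  for (i in 1:1000) {
    sc <- ranked_screen(seq_len(n), rnorm(n), lab)
    efs[i] <- enrichment_factor(sc, 0.01)
    aucs[i] <- auroc(sc)
  }
  expect_gt(mean(efs), 0.8); expect_lt(mean(efs), 1.2)
  expect_gt(mean(aucs), 0.48); expect_lt(mean(aucs), 0.52)
})

test_that("forward screening ranks, deduplicates embedding work, and skips bad SMILES", {
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  res1 <- forward_screen(m, "ACDEFGHIKL", "CCO", backend = be)
  expect_equal(nrow(res1$screen), 1L)

  lig <- c("CCO", "not_a_smiles((", "CCN", "CCS")
  res <- forward_screen(m, "ACDEFGHIKL", lig, backend = be)
  expect_equal(res$skipped, "not_a_smiles((")
  expect_equal(nrow(res$screen), 3L)
  res_again <- forward_screen(m, "ACDEFGHIKL", lig, backend = be)
  expect_identical(res$screen, res_again$screen)

  # ranking by an affinity head uses that column
  resK <- forward_screen(m, "ACDEFGHIKL", lig, score = "pKi", backend = be)
  expect_equal(resK$screen$score,
               sort(resK$predictions$pKi, decreasing = TRUE))
  expect_error(forward_screen(m, "ACDEFGHIKL", character(0)), "empty")
})

test_that("reverse screening ranks proteins and is order invariant", {
  cfg <- small_config()
  be <- small_backend()
  m <- bind_model(cfg, d_latent = 8L)
  prots <- c(a = "ACDEFGHIKL", b = "MNPQRSTVWY", c = "ACDEFGHIKA")
  r1 <- reverse_screen(m, prots, "CCO", backend = be)
  expect_equal(nrow(r1$screen), 3L)
  r2 <- reverse_screen(m, prots[c(3, 1, 2)], "CCO", backend = be)
  expect_equal(sort(r1$screen$id), sort(r2$screen$id))
  expect_equal(r1$screen$id[r1$screen$rank], r2$screen$id[r2$screen$rank])
  single <- reverse_screen(m, c(x = "ACDEFGHIKL"), "CCO", backend = be)
  expect_equal(single$screen$rank, 1L)
})

test_that("reverse-screening rank summaries count correct pairs", {
  ranks <- c(a = 1, b = 3, c = 10)
  cc <- cumulative_correct_pairs(ranks, c(1, 5))
  expect_equal(unname(cc), c(1L, 2L))
  expect_equal(unname(cumulative_correct_pairs(ranks, 10)), 3L)
  expect_equal(unname(cumulative_correct_pairs(numeric(0), c(1, 5))), c(0L, 0L))
  ks <- c(1, 2, 5, 10, 20)
  expect_false(is.unsorted(cumulative_correct_pairs(ranks, ks)))

  expect_equal(topk_hit_rate(c(a = 1, b = 2), 1), 0.5)
  expect_equal(topk_hit_rate(c(a = 1, b = 2, c = 5), 5), 1)
  expect_equal(topk_hit_rate(c(a = 3, b = 2), 1), 0)
  expect_error(topk_hit_rate(numeric(0), 1), "no rankings")
})

test_that("benchmark aggregation is the unweighted mean, order invariant", {
  lab1 <- rep(c(TRUE, FALSE), c(10, 90))
  lab2 <- rep(FALSE, 100); lab2[c(3, 20, 40, 60, 80, 85, 90, 92, 95, 99)] <- TRUE
  m1 <- screen_metrics(make_screen(lab1))
  m2 <- screen_metrics(make_screen(lab2))
  expect_identical(aggregate_benchmark(list(m1)), m1)
  agg <- aggregate_benchmark(list(m1, m2))
  expect_equal(agg$auroc, (m1$auroc + m2$auroc) / 2)
  expect_equal(agg$ef, (m1$ef + m2$ef) / 2)
  agg_rev <- aggregate_benchmark(list(m2, m1))
  expect_equal(agg, agg_rev)
  m3 <- screen_metrics(make_screen(lab1), ef_fractions = 0.2)
  expect_error(aggregate_benchmark(list(m1, m3)), "inconsistent")
  expect_error(aggregate_benchmark(list()), "no per-target")
})

test_that("scores CSV round-trips through the evaluate interface", {
  n <- 40
  lab <- rep(c(TRUE, FALSE), c(4, 36))
  df <- data.frame(id = seq_len(n), logit = seq(n, 1), is_active = as.integer(lab))
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf, row.names = FALSE)
  m <- evaluate_scores_csv(tf)
  expect_equal(m$auroc, 1)
  expect_equal(unname(m$ef["0.05"]), n / 4)        # perfect ranking, subset <= A
  df$is_active <- NULL
  utils::write.csv(df, tf, row.names = FALSE)
  expect_error(evaluate_scores_csv(tf), "is_active")
})
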