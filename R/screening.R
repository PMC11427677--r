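# Forward and reverse screening drivers plus the early-recognition metrics
# (enrichment factor, success rate, BEDROC, AUROC) and reverse-screening
# rank summaries.

#' Construct a ranked screen
#'
#' Entries are sorted by score, best first (higher is better).  Ties are
#' broken deterministically by input order (stable sort); this matters for
#' enrichment at small cutoffs and is the declared tie policy throughout.
#'
#' @param ids Item identifiers.
#' @param scores Finite numeric scores, higher = better.
#' @param is_active Optional logical activity labels.
#' @return A `ranked_screen` data frame with columns `id`, `score`,
#'   `is_active` (NA when unlabelled), and `rank`.
#' @export
ranked_screen <- function(ids, scores, is_active = NULL) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(is_active)) is_active <- rep(NA, length(scores))
  ord <- order(-scores)  # stable: input order is the secondary key
  out <- data.frame(id = as.character(ids)[ord], score = scores[ord],
                    is_active = as.logical(is_active)[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("ranked_screen", "data.frame")
  out
}

.check_labels <- function(screen) {
  if (any(is.na(screen$is_active))) stop("all entries must carry activity labels")
  n_act <- sum(screen$is_active)
  if (n_act == 0L) stop("screen contains no actives")
  n_act
}

#' Enrichment factor at a fractional cutoff
#'
#' The top `ceil(fraction * N)` entries form the subset; the enrichment
#' factor is the concentration of actives in the subset divided by the
#' concentration of actives in the whole screen.
#'
#' @param screen A labelled [ranked_screen()].
#' @param fraction Subset fraction in `(0, 1]` (e.g. 0.01 for EF 1\%).
#' @return The enrichment factor (1 = no enrichment).
#' @export
enrichment_factor <- function(screen, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_act <- .check_labels(screen)
  n <- nrow(screen)
  k <- ceiling(fraction * n)
  (sum(screen$is_active[seq_len(k)]) / k) / (n_act / n)
}

#' Success rate at a fractional cutoff
#'
#' The concentration of actives in the top subset: `actives_subset /
#' size_subset` with the same `ceil(fraction * N)` subset convention as
#' [enrichment_factor()].
#'
#' @inheritParams enrichment_factor
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(screen, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  .check_labels(screen)
  k <- ceiling(fraction * nrow(screen))
  sum(screen$is_active[seq_len(k)]) / k
}

#' BEDROC early-recognition score
#'
#' Truchon-Bayly BEDROC: the exponentially weighted sum over active ranks,
#' min-max normalized so the best possible ranking scores exactly 1 and the
#' worst exactly 0.  Computed from ranks via the closed form (geometric
#' series for the extremes), with ties resolved by the screen's stable rank
#' policy.
#'
#' @param screen A labelled [ranked_screen()] with at least one active and
#'   one inactive.
#' @param alpha Early-recognition steepness (default 80.5, which focuses on
#'   roughly the top 2.5\% of the list).
#' @return BEDROC in `[0, 1]`.
#' @export
bedroc <- function(screen, alpha = 80.5) {
  if (alpha <= 0) stop("alpha must be positive")
  n_act <- .check_labels(screen)
  n <- nrow(screen)
  if (n_act == n) stop("screen contains no inactives")
  ranks <- screen$rank[screen$is_active]
  s <- sum(exp(-alpha * ranks / n))
  geo <- function(first, len) {
    # sum_{i=first}^{first+len-1} exp(-alpha i / n)
    r <- exp(-alpha / n)
    r^first * (1 - r^len) / (1 - r)
  }
  s_best <- geo(1, n_act)
  s_worst <- geo(n - n_act + 1, n_act)
  (s - s_worst) / (s_best - s_worst)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a randomly chosen active outscores a
#' randomly chosen inactive, with score ties counted 1/2.
#'
#' @param screen A labelled [ranked_screen()] with both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(screen) {
  n_act <- .check_labels(screen)
  n <- nrow(screen)
  if (n_act == n) stop("screen contains no inactives")
  r <- rank(screen$score, ties.method = "average")
  (sum(r[screen$is_active]) - n_act * (n_act + 1) / 2) / (n_act * (n - n_act))
}

#' All screening metrics for one target
#'
#' @param screen A labelled [ranked_screen()].
#' @param ef_fractions Cutoff fractions for enrichment factor and success
#'   rate (default 0.5\%, 1\%, 5\%).
#' @param bedroc_alpha BEDROC steepness values (default 80.5).
#' @return A `screen_metrics` list: `ef` and `success_rate` (named by
#'   fraction), `bedroc` (named by alpha), and `auroc`.
#' @export
screen_metrics <- function(screen, ef_fractions = c(0.005, 0.01, 0.05),
                           bedroc_alpha = 80.5) {
  ef <- vapply(ef_fractions, function(f) enrichment_factor(screen, f), 0)
  sr <- vapply(ef_fractions, function(f) success_rate(screen, f), 0)
  names(ef) <- names(sr) <- as.character(ef_fractions)
  bd <- vapply(bedroc_alpha, function(a) bedroc(screen, a), 0)
  names(bd) <- as.character(bedroc_alpha)
  structure(list(ef = ef, success_rate = sr, bedroc = bd,
                 auroc = auroc(screen)), class = "screen_metrics")
}

#' Average per-target metrics across a benchmark
#'
#' Unweighted arithmetic mean of each metric across targets, the convention
#' used to report benchmark-level screening power.
#'
#' @param per_target_metrics Non-empty list of [screen_metrics()] results
#'   with identical metric keys.
#' @return A `screen_metrics` object of means.
#' @export
aggregate_benchmark <- function(per_target_metrics) {
  if (length(per_target_metrics) == 0L) stop("no per-target metrics given")
  ref <- per_target_metrics[[1L]]
  for (m in per_target_metrics) {
    if (!identical(names(m$ef), names(ref$ef)) ||
        !identical(names(m$bedroc), names(ref$bedroc))) {
      stop("inconsistent metric keys across targets")
    }
  }
  mean_named <- function(field) {
    Reduce(`+`, lapply(per_target_metrics, `[[`, field)) / length(per_target_metrics)
  }
  structure(list(ef = mean_named("ef"), success_rate = mean_named("success_rate"),
                 bedroc = mean_named("bedroc"), auroc = mean_named("auroc")),
            class = "screen_metrics")
}

## ---- screening drivers ------------------------------------------------------

.score_column <- function(score) {
  match.arg(score, c("logit", "pKi", "pKd", "pIC50", "pEC50"))
}

#' Forward screen: rank a ligand library against one protein
#'
#' The protein is embedded once (cached); every parseable ligand gets a full
#' prediction set and the list is ranked by the chosen score, best first.
#' Unparseable SMILES are excluded from the ranking and reported in the
#' skip list.
#'
#' @param model A `bind_model`.
#' @param protein_sequence Target sequence.
#' @param ligand_smiles Character vector of SMILES.
#' @param score Ranking score: `"logit"` (default, the classifier) or one of
#'   the affinity heads.
#' @param is_active Optional activity labels aligned with `ligand_smiles`.
#' @param backend Embedder handle.
#' @param store Optional [embedding_store()] reused across screens.
#' @return List with `screen` (a [ranked_screen()] whose ids are indices
#'   into `ligand_smiles`), `predictions` (per-ligand prediction data frame
#'   with `id` and `smiles`), and `skipped` (failed SMILES).
#' @export
forward_screen <- function(model, protein_sequence, ligand_smiles,
                           score = "logit", is_active = NULL,
                           backend = toy_embedder(),
                           store = embedding_store()) {
  score <- .score_column(score)
  if (length(ligand_smiles) == 0L) stop("empty ligand list")
  stack <- embed_cached(protein_sequence, model$config$encoder_layer_indices,
                        backend, store)
  preds <- vector("list", length(ligand_smiles))
  ok <- logical(length(ligand_smiles))
  for (i in seq_along(ligand_smiles)) {
    g <- try(smiles_to_graph(ligand_smiles[i]), silent = TRUE)
    if (inherits(g, "try-error")) next
    preds[[i]] <- bind_predict(model, g, stack)
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no ligand could be parsed")
  ptab <- do.call(rbind, preds[ok])
  ptab <- cbind(data.frame(id = which(ok), smiles = ligand_smiles[ok],
                           stringsAsFactors = FALSE), ptab)
  labels <- if (is.null(is_active)) NULL else as.logical(is_active)[ok]
  screen <- ranked_screen(which(ok), ptab[[score]], labels)
  list(screen = screen, predictions = ptab, skipped = ligand_smiles[!ok])
}

#' Reverse screen: rank a protein panel against one ligand
#'
#' Scores the ligand against every protein (embeddings cached per protein)
#' and ranks the proteins by the chosen score, best first.
#'
#' @param model A `bind_model`.
#' @param protein_sequences Named character vector (or vector) of sequences.
#' @param ligand_smiles A single SMILES string.
#' @param score Ranking score, as in [forward_screen()].
#' @param backend Embedder handle.
#' @param store Optional shared [embedding_store()]; reusing one store
#'   across ligands gives exactly one embedding computation per protein per
#'   campaign.
#' @return List with `screen` (a [ranked_screen()] over protein names) and
#'   `predictions`.
#' @export
reverse_screen <- function(model, protein_sequences, ligand_smiles,
                           score = "logit", backend = toy_embedder(),
                           store = embedding_store()) {
  score <- .score_column(score)
  if (length(protein_sequences) == 0L) stop("empty protein list")
  nms <- names(protein_sequences)
  if (is.null(nms)) nms <- sprintf("protein_%d", seq_along(protein_sequences))
  g <- smiles_to_graph(ligand_smiles)
  preds <- vector("list", length(protein_sequences))
  for (i in seq_along(protein_sequences)) {
    stack <- embed_cached(protein_sequences[[i]],
                          model$config$encoder_layer_indices, backend, store)
    preds[[i]] <- bind_predict(model, g, stack)
  }
  ptab <- do.call(rbind, preds)
  ptab <- cbind(data.frame(id = nms, stringsAsFactors = FALSE), ptab)
  list(screen = ranked_screen(nms, ptab[[score]]), predictions = ptab)
}

#' Cumulative correct pairs by rank cutoff
#'
#' Given, for each ligand, the rank its true protein achieved in a reverse
#' screen, counts how many ligands have their true target at rank `<= k`.
#' Non-decreasing in `k`.
#'
#' @param rankings Named numeric vector: ligand -> rank of its true protein.
#' @param ks Rank cutoffs.
#' @return Named integer vector, one count per cutoff.
#' @export
cumulative_correct_pairs <- function(rankings, ks) {
  rankings <- as.numeric(rankings)
  if (any(!is.na(rankings) & rankings < 1)) stop("ranks must be >= 1")
  out <- vapply(ks, function(k) sum(rankings <= k, na.rm = TRUE), 0L)
  names(out) <- as.character(ks)
  out
}

#' Top-k hit rate of reverse screening
#'
#' Fraction of ligands whose true target ranks in the top `k`.
#'
#' @param rankings Named numeric vector: ligand -> rank of its true protein.
#' @param k Rank cutoff (`>= 1`).
#' @return Fraction in `[0, 1]`.
#' @export
topk_hit_rate <- function(rankings, k) {
  if (length(rankings) == 0L) stop("no rankings given")
  if (k < 1) stop("k must be >= 1")
  mean(rankings <= k)
}

## ---- CSV interfaces ---------------------------------------------------------

#' Write per-ligand screening scores to CSV
#'
#' @param predictions Prediction table from [forward_screen()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate screening metrics from a scores CSV
#'
#' The file must carry a score column and an `is_active` label column
#' (0/1 or logical).
#'
#' @param path CSV path.
#' @param score Name of the score column (default `"logit"`).
#' @param ef_fractions,bedroc_alpha Passed to [screen_metrics()].
#' @return A [screen_metrics()] object.
#' @export
evaluate_scores_csv <- function(path, score = "logit",
                                ef_fractions = c(0.005, 0.01, 0.05),
                                bedroc_alpha = 80.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"is_active" %in% names(df)) stop("scores CSV lacks an is_active column")
  if (!score %in% names(df)) stop(sprintf("scores CSV lacks a '%s' column", score))
  screen <- ranked_screen(seq_len(nrow(df)), df[[score]],
                          as.logical(df$is_active))
  screen_metrics(screen, ef_fractions, bedroc_alpha)
}

#' Flatten screen metrics to a one-row data frame
#' @param metrics A [screen_metrics()] object.
#' @return One-row data frame (EF/SR columns suffixed by percent cutoff).
#' @export
metrics_as_row <- function(metrics) {
  row <- c(
    stats::setNames(metrics$ef,
                    paste0("EF_", as.numeric(names(metrics$ef)) * 100, "pct")),
    stats::setNames(metrics$success_rate,
                    paste0("SR_", as.numeric(names(metrics$success_rate)) * 100, "pct")),
    stats::setNames(metrics$bedroc, paste0("BEDROC_", names(metrics$bedroc))),
    AUROC = metrics$auroc
  )
  as.data.frame(as.list(row), check.names = FALSE)
}
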