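#' Configuration for proximity-based AsymAD stratification
#'
#' @param perplexity t-SNE perplexity (default 30; automatically shrunk
#'   with a warning when the cohort is too small for it).
#' @param n_repeats Number of independent embedding repeats over which
#'   assignment probabilities are averaged (default 100; the embedding is
#'   sensitive to initialisation, so labels are aggregated over repeats).
#' @param k_neighbors Number of nearest reference neighbours (default 5;
#'   must be odd so the majority vote is well defined).
#' @param max_iter t-SNE gradient-descent iterations per repeat.
#' @param eta t-SNE learning rate.
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return Object of class `embedding_config`.
#' @export
embedding_config <- function(perplexity = 30, n_repeats = 100L,
                             k_neighbors = 5L, max_iter = 500L,
                             eta = 200, seed = 1L) {
  assert_that(k_neighbors >= 1 && k_neighbors %% 2 == 1,
              "k_neighbors must be odd so the majority is well defined")
  assert_that(n_repeats >= 1, "n_repeats must be >= 1")
  assert_that(perplexity > 0, "perplexity must be positive")
  structure(list(perplexity = perplexity, n_repeats = as.integer(n_repeats),
                 k_neighbors = as.integer(k_neighbors),
                 max_iter = as.integer(max_iter), eta = eta,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' t-SNE embedding to two dimensions
#'
#' Embeds a (standardised) panel matrix into 2-D with exact t-SNE.
#' Deterministic given `seed` (the random initial layout is drawn from R's
#' RNG). If the number of subjects is below `3 * perplexity + 1` the
#' perplexity is shrunk with a warning.
#'
#' @param x Numeric matrix (subjects x panel peptides), at least 2 columns.
#' @param perplexity Target perplexity.
#' @param seed Integer seed for this embedding.
#' @param max_iter,eta Gradient-descent schedule.
#' @return Numeric matrix (subjects x 2) with `x`'s row names.
#' @export
embed_2d <- function(x, perplexity = 30, seed = 1L, max_iter = 500L,
                     eta = 200) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 2, "embedding input needs at least 2 peptides")
  assert_that(nrow(x) >= 4, "embedding needs at least 4 subjects")
  # collapse exact duplicate rows: t-SNE has no special handling for
  # zero distances (the usual implementations refuse them), so copies are
  # embedded once and share the resulting coordinate
  key <- apply(x, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  xu <- x[first, , drop = FALSE]
  n <- nrow(xu)
  assert_that(n >= 4, "embedding needs at least 4 distinct subjects")
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %.1f too large for n=%d; shrunk to %.1f",
                    perplexity, n, max_perp), call. = FALSE)
    perplexity <- max_perp
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  y0 <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  yu <- tsne_embed_cpp(xu, y0, perplexity, as.integer(max_iter), eta,
                       12, min(100L, as.integer(max_iter) %/% 2L))
  y <- yu[match(key, key[first]), , drop = FALSE]
  rownames(y) <- rownames(x)
  y
}

#' k-nearest-neighbour proximity labels for AsymAD subjects
#'
#' Labels each AsymAD point in an embedding by majority vote of its `k`
#' nearest reference points (Euclidean distance); only Control and AD
#' points are eligible neighbours. A point is `ADLike` iff at least
#' `ceiling(k/2)` of its neighbours are AD. Distance ties are broken by
#' the lower reference row index.
#'
#' @param embedding Numeric matrix of 2-D coordinates for all subjects.
#' @param ref_labels Character vector aligned with `embedding` rows;
#'   entries `"Control"` or `"AD"` mark eligible neighbours, anything else
#'   is ignored as a neighbour.
#' @param query_idx Integer indices of the rows to label (the AsymAD
#'   subjects).
#' @param k Number of neighbours.
#' @return Character vector (`"ControlLike"`/`"ADLike"`) of
#'   `length(query_idx)`.
#' @export
knn_label <- function(embedding, ref_labels, query_idx, k = 5L) {
  embedding <- as.matrix(embedding)
  ref_idx <- which(ref_labels %in% c("Control", "AD"))
  assert_that(length(ref_idx) >= k,
              sprintf("need at least k=%d reference points", k))
  vapply(query_idx, function(i) {
    d <- sqrt(rowSums(sweep(embedding[ref_idx, , drop = FALSE], 2,
                            embedding[i, ])^2))
    nb <- ref_idx[order(d, ref_idx)][seq_len(k)]
    n_ad <- sum(ref_labels[nb] == "AD")
    if (n_ad >= ceiling(k / 2)) "ADLike" else "ControlLike"
  }, character(1))
}

#' Stability-aggregated AsymAD stratification
#'
#' Runs the embed-then-vote procedure `n_repeats` times with repeat seeds
#' derived from the master seed: each repeat embeds the standardised panel
#' values of all Control, AD and AsymAD subjects into 2-D and labels each
#' AsymAD subject by its `k` nearest Control/AD neighbours. The assignment
#' probability `p_adlike` is the exact fraction of repeats labelling the
#' subject `ADLike`; the consensus is the majority label, with the tie
#' `p_adlike == 0.5` resolved risk-conservatively to `ADLike` and flagged.
#'
#' @param table A `cohort_table` containing Control, AD and AsymAD rows.
#' @param panel Character vector of panel peptide names (>= 2).
#' @param config An [embedding_config()].
#' @param scaler Optional `panel_scaler` used to standardise the panel
#'   values (e.g. the training scaler from [select_panel()]); defaults to
#'   one fitted on the Control + AD rows of `table`.
#' @param log_transform Log-transform abundances first (default `TRUE`;
#'   must match the scale on which `scaler` was fitted).
#' @return Object of class `stratification_result` with
#'   `assignments` (data frame: `subject_id`, `consensus_label`,
#'   `p_adlike`, `tie`), `per_repeat` (repeats x subjects label matrix),
#'   `embedding` (canonical first-repeat coordinates for all subjects,
#'   with `group_label`), and `config`.
#' @export
stability_stratify <- function(table, panel, config = embedding_config(),
                               scaler = NULL, log_transform = TRUE) {
  assert_that(length(panel) >= 2, "panel must contain at least 2 peptides")
  keep <- table$group_label %in% c("Control", "AD", "AsymAD")
  tab <- table[keep, , drop = FALSE]
  asym_idx <- which(tab$group_label == "AsymAD")
  assert_that(length(asym_idx) > 0, "no AsymAD subjects to stratify")
  refs <- tab$group_label %in% c("Control", "AD")
  assert_that(sum(refs) >= config$k_neighbors,
              "too few Control/AD reference subjects")

  x_all <- panel_values(tab, log_transform = log_transform)
  scaler <- scaler %||% fit_scaler(x_all[refs, , drop = FALSE])
  xs <- apply_scaler(scaler, x_all)[, intersect(scaler$included, panel),
                                    drop = FALSE]

  seeds <- derive_seeds(config$seed, config$n_repeats)
  labels_mat <- matrix(NA_character_, config$n_repeats, length(asym_idx))
  canonical <- NULL
  suppress_shrink <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("perplexity", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  for (r in seq_len(config$n_repeats)) {
    y <- suppress_shrink(
      embed_2d(xs, config$perplexity, seed = seeds[r],
               max_iter = config$max_iter, eta = config$eta))
    if (r == 1) canonical <- y
    labels_mat[r, ] <- knn_label(y, tab$group_label, asym_idx,
                                 config$k_neighbors)
  }
  p_adlike <- colMeans(labels_mat == "ADLike")
  tie <- abs(p_adlike - 0.5) < 1e-12
  consensus <- ifelse(p_adlike >= 0.5, "ADLike", "ControlLike")
  if (any(tie)) {
    warning(sprintf("%d subject(s) tied at p_adlike = 0.5; labelled ADLike",
                    sum(tie)), call. = FALSE)
  }
  emb <- data.frame(subject_id = tab$subject_id,
                    group_label = tab$group_label,
                    dim1 = canonical[, 1], dim2 = canonical[, 2],
                    stringsAsFactors = FALSE)
  structure(list(
    assignments = data.frame(subject_id = tab$subject_id[asym_idx],
                             consensus_label = consensus,
                             p_adlike = p_adlike, tie = tie,
                             stringsAsFactors = FALSE),
    per_repeat = labels_mat, embedding = emb, scaler = scaler,
    config = config
  ), class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  tab <- table(x$assignments$consensus_label)
  cat(sprintf("<stratification_result> %d AsymAD subjects over %d repeats\n",
              nrow(x$assignments), nrow(x$per_repeat)))
  cat(sprintf("  consensus: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' APOE epsilon-4 enrichment between AsymAD subgroups
#'
#' Primary test: 2x2 Fisher's exact test on epsilon-4 allele counts (two
#' alleles per subject) by subgroup. A genotype-level 2x3 table (0/1/2
#' epsilon-4 copies) with a Pearson chi-square test is also reported.
#'
#' @param labels Character vector of subgroup labels
#'   (`ControlLike`/`ADLike`).
#' @param apoe Genotype strings such as `"e3/e4"`, aligned with `labels`.
#' @return List: `allele_table` (2x2), `p_value` (two-sided Fisher),
#'   `genotype_table` (2x3), `genotype_p`, `degenerate` (zero margin).
#' @export
apoe_enrichment <- function(labels, apoe) {
  assert_that(length(labels) == length(apoe),
              "labels and apoe must align")
  ok <- !is.na(labels) & !is.na(apoe)
  labels <- labels[ok]; apoe <- apoe[ok]
  assert_that(all(c("ControlLike", "ADLike") %in% labels),
              "both subgroups must be non-empty")
  e4 <- vapply(strsplit(apoe, "/"), function(a) sum(a == "e4"), integer(1))
  allele <- rbind(
    ControlLike = c(e4 = sum(e4[labels == "ControlLike"]),
                    other = 2 * sum(labels == "ControlLike") -
                      sum(e4[labels == "ControlLike"])),
    ADLike = c(e4 = sum(e4[labels == "ADLike"]),
               other = 2 * sum(labels == "ADLike") -
                 sum(e4[labels == "ADLike"]))
  )
  degenerate <- any(rowSums(allele) == 0) || any(colSums(allele) == 0)
  p <- if (degenerate) 1 else fisher.test(allele)$p.value
  geno <- table(factor(labels, c("ControlLike", "ADLike")),
                factor(e4, 0:2))
  genotype_p <- tryCatch(
    suppressWarnings(chisq.test(geno[, colSums(geno) > 0, drop = FALSE],
                                correct = FALSE)$p.value),
    error = function(e) NA_real_)
  list(allele_table = allele, p_value = p, genotype_table = geno,
       genotype_p = genotype_p, degenerate = degenerate)
}

#' Classifier evaluation of AsymAD subgroup labels
#'
#' Quantifies how well the panel separates the derived subgroups with a
#' logistic classifier, either on a single stratified held-out split or by
#' stratified k-fold cross-validation with out-of-fold predictions pooled
#' into one confusion matrix and one ROC-AUC (the usual choice for small
#' groups).
#'
#' @param table A `cohort_table` restricted to (or containing) the AsymAD
#'   subjects to classify.
#' @param panel Panel peptide names.
#' @param labels Named or aligned character vector of subgroup labels
#'   (`ControlLike`/`ADLike`) for the AsymAD rows of `table`.
#' @param mode `"kfold"` (default) or `"heldout"`.
#' @param k Number of folds (default 6).
#' @param train_fraction Training fraction for `"heldout"` mode.
#' @param seed Integer seed.
#' @param lambda L2 regularisation strength.
#' @param log_transform Log-transform abundances first (default `TRUE`).
#' @return List: `confusion` (2x2), `accuracy`, `sensitivity`,
#'   `specificity`, `roc_auc`, `predictions` (per subject, each exactly
#'   once), `mode`.
#' @export
subgroup_classifier_eval <- function(table, panel, labels,
                                     mode = c("kfold", "heldout"),
                                     k = 6L, train_fraction = 0.84,
                                     seed = 1L, lambda = 0.01,
                                     log_transform = TRUE) {
  mode <- match.arg(mode)
  asym <- table[table$group_label == "AsymAD", , drop = FALSE]
  assert_that(nrow(asym) == length(labels),
              "labels must align with the AsymAD rows of table")
  y <- as.integer(labels == "ADLike")
  assert_that(length(unique(y)) == 2, "both subgroup labels must be present")
  x <- panel_values(asym, panel, log_transform = log_transform)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  prob <- rep(NA_real_, nrow(asym))
  if (mode == "heldout") {
    test_idx <- integer(0)
    for (cls in 0:1) {
      idx <- which(y == cls)
      n_test <- max(1, round(length(idx) * (1 - train_fraction)))
      assert_that(length(idx) - n_test >= 1,
                  "subgroup too small for a held-out split")
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    train_idx <- setdiff(seq_len(nrow(asym)), test_idx)
    sc <- fit_scaler(x[train_idx, , drop = FALSE])
    fit <- fit_linear_classifier(apply_scaler(sc, x[train_idx, , drop = FALSE]),
                                 y[train_idx], "logistic", lambda)
    prob[test_idx] <- predict_linear(
      fit, apply_scaler(sc, x[test_idx, , drop = FALSE]))$prob
    eval_idx <- test_idx
  } else {
    assert_that(nrow(asym) >= k, "fewer subjects than folds")
    fold <- integer(nrow(asym))
    for (cls in 0:1) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(unique(y[tr])) < 2) {
        stop(sprintf("fold %d has a single-class training set", f),
             call. = FALSE)
      }
      sc <- fit_scaler(x[tr, , drop = FALSE])
      fit <- fit_linear_classifier(apply_scaler(sc, x[tr, , drop = FALSE]),
                                   y[tr], "logistic", lambda)
      prob[te] <- predict_linear(
        fit, apply_scaler(sc, x[te, , drop = FALSE]))$prob
    }
    eval_idx <- seq_len(nrow(asym))
  }
  pred <- as.integer(prob[eval_idx] > 0.5)
  cm <- confusion_metrics(pred, y[eval_idx])
  auc <- if (length(unique(y[eval_idx])) == 2) {
    roc_auc(prob[eval_idx], y[eval_idx])
  } else NA_real_
  list(confusion = matrix(c(cm$tn, cm$fp, cm$fn, cm$tp), 2, 2,
                          dimnames = list(predicted = c("ControlLike", "ADLike"),
                                          actual = c("ControlLike", "ADLike"))),
       accuracy = cm$accuracy, sensitivity = cm$sensitivity,
       specificity = cm$specificity, roc_auc = auc,
       predictions = data.frame(subject_id = asym$subject_id[eval_idx],
                                p_adlike = prob[eval_idx],
                                predicted = ifelse(pred == 1, "ADLike",
                                                   "ControlLike"),
                                actual = ifelse(y[eval_idx] == 1, "ADLike",
                                                "ControlLike"),
                                stringsAsFactors = FALSE),
       mode = mode)
}
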