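#' Configuration for peptide panel selection
#'
#' @param train_fraction Fraction of Control/AD subjects used for
#'   selection and training (default 0.80; the remaining 20% is the
#'   held-out validation set and never touches scaling, selection, or
#'   training).
#' @param rfe_stop_size Number of peptides at which recursive feature
#'   elimination stops, per classifier (default 14).
#' @param rfe_step Features eliminated per iteration (default 1, which
#'   yields the most faithful elimination order).
#' @param lambda Fixed L2 regularisation strength of both linear
#'   classifiers (default 0.01; determinism is preferred over tuning).
#' @param seed Integer seed controlling the train/held-out split.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(train_fraction = 0.80, rfe_stop_size = 14L,
                             rfe_step = 1L, lambda = 0.01, seed = 1L) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  assert_that(rfe_stop_size >= 1, "rfe_stop_size must be >= 1")
  assert_that(rfe_step >= 1, "rfe_step must be >= 1")
  structure(list(train_fraction = train_fraction,
                 rfe_stop_size = as.integer(rfe_stop_size),
                 rfe_step = as.integer(rfe_step), lambda = lambda,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Stratified train / held-out split
#'
#' Splits Control and AD subjects into a training set and a held-out set,
#' stratified by group label, deterministically for a given seed.
#'
#' @param table A `cohort_table` containing the two groups.
#' @param train_fraction Fraction per group assigned to training.
#' @param labels The two group labels to split (default Control/AD).
#' @param seed Integer seed.
#' @return List with character vectors `train_ids` and `heldout_ids`.
#' @export
split_train_test <- function(table, train_fraction = 0.8,
                             labels = c("Control", "AD"), seed = 1L) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  train_ids <- character(0); heldout_ids <- character(0)
  for (g in labels) {
    ids <- table$subject_id[table$group_label == g]
    n_train <- round(length(ids) * train_fraction)
    if (n_train < 1 || n_train >= length(ids)) {
      stop(sprintf("group %s too small to stratify at train_fraction %.2f",
                   g, train_fraction), call. = FALSE)
    }
    tr <- sample(ids, n_train)
    train_ids <- c(train_ids, tr)
    heldout_ids <- c(heldout_ids, setdiff(ids, tr))
  }
  list(train_ids = train_ids, heldout_ids = heldout_ids)
}

#' Standardisation scaler fitted on training rows
#'
#' Computes per-peptide mean and SD from the training rows only
#' (mean-centring and scaling to unit variance is the first step of the
#' selection pipeline). Zero-variance peptides are excluded from selection
#' and recorded.
#'
#' @param x Numeric matrix of training-row peptide abundances.
#' @return Object of class `panel_scaler`: `center`, `scale`, `included`,
#'   `excluded`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x, na.rm = TRUE)
  scale_ <- apply(x, 2, sd, na.rm = TRUE)
  excluded <- colnames(x)[!is.finite(scale_) | scale_ == 0]
  if (length(excluded) > 0) {
    message(sprintf("excluding %d zero-variance peptide(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  included <- setdiff(colnames(x), excluded)
  structure(list(center = center[included], scale = scale_[included],
                 included = included, excluded = excluded),
            class = "panel_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `panel_scaler`.
#' @param rows Numeric matrix to standardise with the training statistics.
#' @return `apply_scaler()` returns the standardised matrix restricted to
#'   the scaler's included columns.
#' @export
apply_scaler <- function(scaler, rows) {
  rows <- as.matrix(rows)[, scaler$included, drop = FALSE]
  sweep(sweep(rows, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Recursive feature elimination under a linear classifier
#'
#' Repeatedly fits an L2-regularised linear classifier (logistic
#' regression or squared-hinge linear SVM) on the standardised training
#' data and drops the `step` features with the smallest absolute weights
#' until `stop_size` features remain. Weight-magnitude ties are broken by
#' eliminating the lower column index first, for reproducibility.
#'
#' @param x Standardised training matrix (subjects x features).
#' @param y Binary labels (AD = positive).
#' @param classifier `"svm"` or `"logistic"`.
#' @param stop_size Number of features to retain.
#' @param step Features dropped per iteration (default 1).
#' @param lambda L2 regularisation strength.
#' @return List with `selected` (retained feature names, original column
#'   order) and `elimination_order` (feature names, first eliminated
#'   first).
#' @export
rfe_select <- function(x, y, classifier = c("svm", "logistic"),
                       stop_size, step = 1L, lambda = 0.01) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  assert_that(stop_size >= 1, "stop_size must be >= 1")
  assert_that(stop_size <= ncol(x), "stop_size exceeds feature count")
  all_features <- colnames(x)
  active <- all_features
  eliminated <- character(0)
  while (length(active) > stop_size) {
    fit <- fit_linear_classifier(x[, active, drop = FALSE], y,
                                 kind = classifier, lambda = lambda)
    aw <- abs(fit$weights)
    n_drop <- min(step, length(active) - stop_size)
    # order by |w| ascending, ties by original column index ascending
    ord <- order(aw, match(active, all_features))
    drop_now <- active[ord[seq_len(n_drop)]]
    eliminated <- c(eliminated, drop_now)
    active <- setdiff(active, drop_now)
  }
  list(selected = all_features[all_features %in% active],
       elimination_order = eliminated)
}

#' Intersect two per-classifier peptide selections
#'
#' The final panel is the set of peptides retained by both classifiers,
#' reported in stable peptide-index order. An empty intersection is an
#' error: the downstream embedding and staging stages need at least two
#' peptides.
#'
#' @param set_a,set_b Character vectors of peptide names.
#' @param universe Optional character vector fixing the stable order
#'   (defaults to `sort(union(set_a, set_b))`).
#' @return Character vector, the final panel.
#' @export
intersect_panels <- function(set_a, set_b, universe = NULL) {
  common <- intersect(set_a, set_b)
  if (length(common) == 0) {
    stop("empty panel: the two classifier selections do not intersect",
         call. = FALSE)
  }
  universe <- universe %||% sort(union(set_a, set_b))
  universe[universe %in% common]
}

#' Dual-classifier RFE panel selection
#'
#' End-to-end panel selection: stratified 80/20 split of Control and AD
#' subjects, standardisation fitted on the training rows, recursive
#' feature elimination run independently under a linear SVM and a logistic
#' regression (each stopping at `rfe_stop_size` peptides), intersection of
#' the two selections, and held-out evaluation of a logistic classifier
#' restricted to the final panel. The held-out rows play no role in
#' scaling, selection or training.
#'
#' @param table A `cohort_table` with Control and AD subjects.
#' @param config A [selection_config()].
#' @param log_transform Log-transform abundances before standardisation?
#'   Default `TRUE` (targeted mass-spectrometry intensities are
#'   right-skewed; all distance- and Gaussian-based downstream steps
#'   operate on the log scale).
#' @return Object of class `panel_result`: `svm_set`, `logistic_set` (each
#'   with elimination order), `final_panel`, `scaler`, `heldout_metrics`,
#'   `train_ids`, `heldout_ids`, `config`.
#' @export
select_panel <- function(table, config = selection_config(),
                         log_transform = TRUE) {
  split <- split_train_test(table, config$train_fraction, seed = config$seed)
  train <- table[table$subject_id %in% split$train_ids, , drop = FALSE]
  heldout <- table[table$subject_id %in% split$heldout_ids, , drop = FALSE]

  x_train <- panel_values(train, log_transform = log_transform)
  scaler <- fit_scaler(x_train)
  xs <- apply_scaler(scaler, x_train)
  y <- train$group_label == "AD"

  svm_sel <- rfe_select(xs, y, "svm", config$rfe_stop_size,
                        config$rfe_step, config$lambda)
  log_sel <- rfe_select(xs, y, "logistic", config$rfe_stop_size,
                        config$rfe_step, config$lambda)
  panel <- intersect_panels(svm_sel$selected, log_sel$selected,
                            universe = colnames(xs))
  metrics <- evaluate_panel(panel, train, heldout, scaler = scaler,
                            lambda = config$lambda,
                            log_transform = log_transform)
  structure(list(svm_set = svm_sel, logistic_set = log_sel,
                 final_panel = panel, scaler = scaler,
                 log_transform = log_transform,
                 heldout_metrics = metrics,
                 train_ids = split$train_ids,
                 heldout_ids = split$heldout_ids,
                 config = config),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result>\n")
  cat(sprintf("  SVM set (%d) & logistic set (%d) -> final panel of %d peptides\n",
              length(x$svm_set$selected), length(x$logistic_set$selected),
              length(x$final_panel)))
  cat("  panel:", paste(x$final_panel, collapse = ", "), "\n")
  m <- x$heldout_metrics
  cat(sprintf("  held-out: sens=%.3f spec=%.3f AUC=%.3f (n=%d)\n",
              m$sensitivity, m$specificity, m$roc_auc, m$n))
  invisible(x)
}

#' Held-out evaluation of a peptide panel
#'
#' Fits a logistic classifier on the training rows restricted to the panel
#' (standardised with the training scaler) and reports confusion counts,
#' sensitivity, specificity and ROC-AUC on the held-out rows. AD is the
#' positive class; predictions use a 0.5 probability threshold.
#'
#' @param panel Character vector of peptide names.
#' @param train,heldout `cohort_table` subsets with Control/AD labels.
#' @param scaler Optional `panel_scaler`; defaults to one fitted on the
#'   training rows.
#' @param lambda L2 regularisation strength.
#' @param log_transform Log-transform abundances first (default `TRUE`).
#' @return List of metrics: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `recall`, `roc_auc`, `n`.
#'   With a single-class held-out set, `roc_auc` is `NA` and
#'   `auc_undefined` is set.
#' @export
evaluate_panel <- function(panel, train, heldout, scaler = NULL,
                           lambda = 0.01, log_transform = TRUE) {
  assert_that(length(panel) >= 1, "panel must be non-empty")
  scaler <- scaler %||%
    fit_scaler(panel_values(train, log_transform = log_transform))
  panel <- intersect(scaler$included, panel)
  xtr <- apply_scaler(
    scaler, panel_values(train, log_transform = log_transform))[
      , panel, drop = FALSE]
  xte <- apply_scaler(
    scaler, panel_values(heldout, log_transform = log_transform))[
      , panel, drop = FALSE]
  ytr <- train$group_label == "AD"
  yte <- as.integer(heldout$group_label == "AD")
  fit <- fit_linear_classifier(xtr, ytr, "logistic", lambda = lambda)
  pr <- predict_linear(fit, xte)
  pred <- as.integer(pr$prob > 0.5)
  res <- confusion_metrics(pred, yte)
  if (length(unique(yte)) < 2) {
    res$roc_auc <- NA_real_
    res$auc_undefined <- TRUE
  } else {
    res$roc_auc <- roc_auc(pr$prob, yte)
    res$auc_undefined <- FALSE
  }
  res$n <- length(yte)
  res
}

#' Permutation null for a selected panel
#'
#' Draws `n_draws` uniform random peptide subsets of the panel's size from
#' the peptide universe, trains a logistic classifier on the training rows
#' for each draw, evaluates accuracy, precision, recall and ROC-AUC on the
#' held-out rows, and reports per-metric p-values as the plain fraction of
#' draws performing as well as or better than the observed panel. (With
#' `plus_one = TRUE` the (r+1)/(N+1) variant is reported instead.) By
#' default draws may coincide with the observed panel.
#'
#' @param panel Observed panel (character vector).
#' @param train,heldout `cohort_table` subsets with Control/AD labels.
#' @param n_draws Number of random subsets (default 1e5; fewer than 100
#'   triggers an instability warning).
#' @param seed Integer seed.
#' @param universe Peptide universe to draw from (default: all peptide
#'   columns of `train`).
#' @param exclude_observed Exclude draws identical to the observed panel?
#' @param plus_one Use the (r+1)/(N+1) p-value variant?
#' @param lambda L2 regularisation strength.
#' @param log_transform Log-transform abundances first (default `TRUE`).
#' @return Object of class `permutation_null`: `observed` metrics,
#'   `null` (data frame of per-draw metrics), `p_values`, `n_draws`,
#'   `seed`.
#' @export
permutation_test <- function(panel, train, heldout, n_draws = 100000L,
                             seed = 1L, universe = NULL,
                             exclude_observed = FALSE, plus_one = FALSE,
                             lambda = 0.01, log_transform = TRUE) {
  universe <- universe %||% grep("^pep_", names(train), value = TRUE)
  assert_that(length(universe) > length(panel),
              "universe must be larger than the panel")
  if (n_draws < 100) {
    warning("n_draws < 100: permutation p-values will be unstable",
            call. = FALSE)
  }
  scaler <- fit_scaler(panel_values(train, log_transform = log_transform))
  observed <- evaluate_panel(panel, train, heldout, scaler = scaler,
                             lambda = lambda, log_transform = log_transform)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  metrics <- c("accuracy", "precision", "recall", "roc_auc")
  null <- matrix(NA_real_, n_draws, length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_len(n_draws)) {
    repeat {
      draw <- sample(universe, length(panel))
      if (!exclude_observed || !setequal(draw, panel)) break
    }
    m <- evaluate_panel(draw, train, heldout, scaler = scaler,
                        lambda = lambda, log_transform = log_transform)
    null[i, ] <- c(m$accuracy, m$precision, m$recall, m$roc_auc)
  }
  obs <- c(accuracy = observed$accuracy, precision = observed$precision,
           recall = observed$recall, roc_auc = observed$roc_auc)
  p <- vapply(metrics, function(mm) {
    r <- sum(null[, mm] >= obs[[mm]], na.rm = TRUE)
    if (plus_one) (r + 1) / (n_draws + 1) else r / n_draws
  }, numeric(1))
  structure(list(observed = obs, null = as.data.frame(null), p_values = p,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 plus_one = plus_one),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d draws\n", x$n_draws))
  for (m in names(x$p_values)) {
    cat(sprintf("  %-9s observed=%.3f  p=%.4g\n", m, x$observed[[m]],
                x$p_values[[m]]))
  }
  invisible(x)
}

#' Kendall tau-b ranking of peptides against cognition
#'
#' Computes the tie-corrected Kendall tau-b correlation of every peptide
#' with the MoCA score across all subjects (the cognition score is an
#' integer in 0-30, so ties are heavy and tau-b is the appropriate
#' variant), sorts coefficients in decreasing order, and reports the rank
#' positions of the panel members. Discriminative peptides are expected to
#' occupy the extremes of the ranking.
#'
#' @param table A `cohort_table` with a `moca` column.
#' @param panel Optional character vector of panel peptides whose ranks to
#'   report.
#' @return Object of class `cognition_ranking`: `tau` (named, sorted
#'   decreasing), `panel_ranks`.
#' @export
kendall_moca_ranking <- function(table, panel = NULL) {
  assert_that("moca" %in% names(table), "table must contain a moca column")
  moca <- table$moca
  assert_that(length(unique(moca[!is.na(moca)])) > 1,
              "MoCA is constant: correlation undefined")
  x <- peptide_matrix(table)
  tau <- vapply(colnames(x), function(cl) {
    ok <- is.finite(x[, cl]) & !is.na(moca)
    suppressWarnings(cor(x[ok, cl], moca[ok], method = "kendall"))
  }, numeric(1))
  tau <- sort(tau, decreasing = TRUE)
  ranks <- if (is.null(panel)) integer(0) else
    setNames(match(panel, names(tau)), panel)
  structure(list(tau = tau, panel_ranks = ranks),
            class = "cognition_ranking")
}

#' Volcano statistics for a group contrast
#'
#' Per-peptide log2 fold change of linear-scale group means (second group
#' over first) and a two-sided Mann-Whitney U test p-value (exact where
#' feasible, normal-approximated otherwise).
#'
#' @param table A `cohort_table` subset (typically held-out rows).
#' @param groups Length-2 character vector; fold change is
#'   `log2(mean(groups[2]) / mean(groups[1]))`.
#' @return Data frame: `peptide`, `log2fc`, `p_value`, `flagged`
#'   (non-positive group mean).
#' @export
volcano_stats <- function(table, groups = c("Control", "AD")) {
  g1 <- table[table$group_label == groups[1], , drop = FALSE]
  g2 <- table[table$group_label == groups[2], , drop = FALSE]
  assert_that(nrow(g1) >= 3 && nrow(g2) >= 3,
              "both groups need at least 3 subjects")
  x1 <- peptide_matrix(g1); x2 <- peptide_matrix(g2)
  out <- lapply(colnames(x1), function(cl) {
    m1 <- mean(x1[, cl], na.rm = TRUE); m2 <- mean(x2[, cl], na.rm = TRUE)
    flagged <- !is.finite(m1) || !is.finite(m2) || m1 <= 0 || m2 <= 0
    fc <- if (flagged) NA_real_ else log2(m2 / m1)
    p <- suppressWarnings(
      wilcox.test(x2[, cl], x1[, cl], alternative = "two.sided")$p.value)
    data.frame(peptide = cl, log2fc = fc, p_value = p, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
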