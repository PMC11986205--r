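#' Rank-based ROC-AUC
#'
#' Computes the area under the ROC curve as the normalised Mann-Whitney U
#' statistic, using midranks for ties: the probability that a randomly
#' chosen positive scores above a randomly chosen negative (ties counted
#' half).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; the positive class is `TRUE` / `1` /
#'   the second factor level.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ok <- is.finite(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  assert_that(n1 > 0 && n0 > 0, "AUC undefined: both classes required")
  r <- rank(scores)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Confusion counts and derived rates; positive class = 1.
confusion_metrics <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Stratified k-fold cross-validated panel evaluation
#'
#' Splits subjects into `k` stratified folds (per-fold class ratios within
#' one subject of the global ratio), trains a logistic classifier on the
#' panel in each training fold (standardisation refitted per fold), and
#' reports per-fold ROC-AUCs, their mean and standard error, and pooled
#' out-of-fold metrics. Every subject is predicted exactly once.
#'
#' @param table A `cohort_table` with both groups present.
#' @param panel Panel peptide names.
#' @param labels Length-2 character vector; second entry is the positive
#'   class (default `c("Control", "AD")`).
#' @param k Number of folds (default 6).
#' @param seed Integer seed.
#' @param lambda L2 regularisation strength.
#' @param log_transform Log-transform abundances first (default `TRUE`).
#' @return Object of class `metrics_report`: `fold_auc`, `mean_auc`,
#'   `se_auc`, `pooled` (confusion metrics + AUC on pooled out-of-fold
#'   predictions), `fold` assignment per subject, `seed`.
#' @export
kfold_cv <- function(table, panel, labels = c("Control", "AD"), k = 6L,
                     seed = 1L, lambda = 0.01, log_transform = TRUE) {
  tab <- table[table$group_label %in% labels, , drop = FALSE]
  y <- as.integer(tab$group_label == labels[2])
  assert_that(length(unique(y)) == 2, "both groups must be present")
  n <- nrow(tab)
  if (n < k) stop("fewer subjects than folds", call. = FALSE)
  if (k >= min(table(y)) * 2 && k >= n / 2) {
    stop("fold size too small for a per-fold ROC; choose a smaller k",
         call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in 0:1) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  x <- panel_values(tab, panel, log_transform = log_transform)
  prob <- rep(NA_real_, n)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[te])) < 2) {
      stop(sprintf("fold %d held-out set has a single class; choose a smaller k", f),
           call. = FALSE)
    }
    sc <- fit_scaler(x[tr, , drop = FALSE])
    fit <- fit_linear_classifier(apply_scaler(sc, x[tr, , drop = FALSE]),
                                 y[tr], "logistic", lambda)
    prob[te] <- predict_linear(fit,
                               apply_scaler(sc, x[te, , drop = FALSE]))$prob
    fold_auc[f] <- roc_auc(prob[te], y[te])
  }
  pooled <- confusion_metrics(as.integer(prob > 0.5), y)
  pooled$roc_auc <- roc_auc(prob, y)
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 se_auc = sd(fold_auc) / sqrt(k), pooled = pooled,
                 fold = data.frame(subject_id = tab$subject_id,
                                   fold = fold, prob = prob,
                                   stringsAsFactors = FALSE),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d-fold CV: mean AUC %.3f (SE %.3f); pooled AUC %.3f\n",
              x$k, x$mean_auc, x$se_auc, x$pooled$roc_auc))
  invisible(x)
}

#' Percentage with half-up rounding to one decimal
#'
#' `100 * count / total`, rounded half-up to one decimal place — the
#' rounding convention of cohort characteristic tables (e.g. 227 of 787 is
#' reported as 28.8).
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
proportion_percent <- function(count, total) {
  assert_that(all(total > 0), "total must be positive")
  p <- 100 * count / total
  floor(p * 10 + 0.5 + 1e-9) / 10
}

#' Paired cohort comparison summary
#'
#' Compares paired groups (e.g. AsymAD vs matched Controls) variable by
#' variable: continuous variables are routed by a Shapiro normality screen
#' on the paired differences (alpha = 0.05) to a paired t-test or a
#' Wilcoxon signed-rank test; categorical variables use the
#' McNemar-Bowker symmetry test. Group proportions are reported with
#' half-up one-decimal percentages.
#'
#' @param table A `cohort_table`.
#' @param pairing Two-column data frame of paired subject IDs (first
#'   column = group 1, second = group 2), e.g. the `asymad_id` /
#'   `control_id` columns of [match_groups()] triplets.
#' @param continuous,categorical Variable names to compare.
#' @return Object of class `cohort_summary`: `tests` data frame
#'   (`variable`, `test`, `p_value`, `summary1`, `summary2`, `flagged`)
#'   and `proportions` (per categorical level: counts and percents per
#'   group).
#' @export
cohort_summary <- function(table, pairing,
                           continuous = c("age", "education", "moca",
                                          "abeta42", "ttau", "ptau"),
                           categorical = c("sex", "race")) {
  pairing <- as.data.frame(pairing)
  assert_that(ncol(pairing) >= 2, "pairing needs two ID columns")
  assert_that(all(unlist(pairing[, 1:2]) %in% table$subject_id),
              "pairing refers to unknown subject IDs")
  row1 <- table[match(pairing[[1]], table$subject_id), , drop = FALSE]
  row2 <- table[match(pairing[[2]], table$subject_id), , drop = FALSE]

  fmt_cont <- function(v, normal) {
    if (normal) {
      sprintf("%.1f +/- %.1f", mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
    } else {
      q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    }
  }

  tests <- list()
  for (v in intersect(continuous, names(table))) {
    d <- row1[[v]] - row2[[v]]
    d <- d[is.finite(d)]
    flagged <- FALSE
    if (length(d) < 3 || all(d == 0)) {
      test <- "wilcoxon_signed_rank"; p <- 1; normal <- FALSE
      flagged <- TRUE  # degenerate: no variation in paired differences
    } else {
      shap_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
      normal <- shap_p >= 0.05
      if (normal) {
        test <- "paired_t"
        p <- t.test(row1[[v]], row2[[v]], paired = TRUE)$p.value
      } else {
        test <- "wilcoxon_signed_rank"
        p <- suppressWarnings(
          wilcox.test(row1[[v]], row2[[v]], paired = TRUE)$p.value)
      }
    }
    tests[[length(tests) + 1]] <-
      data.frame(variable = v, test = test, p_value = p,
                 summary1 = fmt_cont(row1[[v]], normal),
                 summary2 = fmt_cont(row2[[v]], normal),
                 flagged = flagged, stringsAsFactors = FALSE)
  }

  props <- list()
  for (v in intersect(categorical, names(table))) {
    lev <- sort(unique(c(row1[[v]], row2[[v]])))
    f1 <- factor(row1[[v]], lev); f2 <- factor(row2[[v]], lev)
    p <- tryCatch(
      suppressWarnings(mcnemar.test(table(f1, f2), correct = FALSE)$p.value),
      error = function(e) NA_real_)
    tests[[length(tests) + 1]] <-
      data.frame(variable = v, test = "mcnemar_bowker", p_value = p,
                 summary1 = "", summary2 = "", flagged = is.na(p),
                 stringsAsFactors = FALSE)
    for (l in lev) {
      props[[length(props) + 1]] <- data.frame(
        variable = v, level = l,
        count1 = sum(f1 == l, na.rm = TRUE),
        percent1 = proportion_percent(sum(f1 == l, na.rm = TRUE),
                                      sum(!is.na(f1))),
        count2 = sum(f2 == l, na.rm = TRUE),
        percent2 = proportion_percent(sum(f2 == l, na.rm = TRUE),
                                      sum(!is.na(f2))),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(tests = do.call(rbind, tests),
                 proportions = if (length(props) > 0) do.call(rbind, props)
                 else NULL,
                 n_pairs = nrow(pairing)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d pairs\n", x$n_pairs))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis across groups with FDR-corrected follow-ups
#'
#' Three-or-more-group comparison for a continuous variable:
#' Kruskal-Wallis omnibus test, then pairwise two-sided Mann-Whitney tests
#' with Benjamini-Hochberg adjustment.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return List: `statistic` (H), `p_value`, `posthoc` data frame
#'   (`group1`, `group2`, `p_raw`, `p_adj`).
#' @export
kruskal_fdr <- function(values, groups) {
  groups <- as.character(groups)
  kw <- kruskal.test(values, factor(groups))
  gs <- sort(unique(groups))
  pairs <- utils::combn(gs, 2)
  post <- apply(pairs, 2, function(pr) {
    p <- suppressWarnings(
      wilcox.test(values[groups == pr[1]],
                  values[groups == pr[2]])$p.value)
    data.frame(group1 = pr[1], group2 = pr[2], p_raw = p,
               stringsAsFactors = FALSE)
  })
  post <- do.call(rbind, post)
  post$p_adj <- p.adjust(post$p_raw, method = "BH")
  list(statistic = unname(kw$statistic), p_value = kw$p.value,
       posthoc = post)
}
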