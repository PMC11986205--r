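test_that("train/held-out split is stratified and deterministic", {
  co <- generate_cohort(cohort_config(n_control = 100, n_asymad = 0,
                                      n_ad = 100, seed = 1))
  s1 <- split_train_test(co$table, 0.8, seed = 5)
  s2 <- split_train_test(co$table, 0.8, seed = 5)
  expect_identical(s1, s2)
  g <- co$table$group_label[match(s1$train_ids, co$table$subject_id)]
  expect_equal(unname(table(g)[c("Control", "AD")]), c(80L, 80L),
               ignore_attr = TRUE)
  expect_length(s1$heldout_ids, 40)
  expect_length(intersect(s1$train_ids, s1$heldout_ids), 0)
  expect_error(split_train_test(co$table, 1.0), "train_fraction")
  expect_error(split_train_test(co$table[1:3, ], 0.8), "too small")
})

test_that("scaler standardises training rows and is reused for held-out", {
  set.seed(2)
  xtr <- matrix(rnorm(200, 5, 2), 20, 10,
                dimnames = list(NULL, sprintf("pep_%04d", 1:10)))
  xte <- matrix(rnorm(100, 7, 2), 10, 10,
                dimnames = list(NULL, sprintf("pep_%04d", 1:10)))
  sc <- fit_scaler(xtr)
  zs <- apply_scaler(sc, xtr)
  expect_true(all(abs(colMeans(zs)) < 1e-9))
  expect_true(all(abs(apply(zs, 2, sd) - 1) < 1e-9))
  # held-out standardised with train statistics differs from self-scaling
  z_train_stats <- apply_scaler(sc, xte)
  z_self <- apply_scaler(fit_scaler(xte), xte)
  expect_gt(max(abs(z_train_stats - z_self)), 0.1)
  # constant column is excluded and recorded
  xtr[, 3] <- 1
  expect_message(sc2 <- fit_scaler(xtr), "pep_0003")
  expect_equal(sc2$excluded, "pep_0003")
  expect_false("pep_0003" %in% colnames(apply_scaler(sc2, xtr)))
})

test_that("RFE retains all features at stop_size = p and records order", {
  set.seed(3)
  x <- matrix(rnorm(300), 30, 10,
              dimnames = list(NULL, sprintf("pep_%04d", 1:10)))
  y <- rbinom(30, 1, 0.5)
  res <- rfe_select(x, y, "logistic", stop_size = 10)
  expect_equal(res$selected, colnames(x))
  expect_length(res$elimination_order, 0)
  res2 <- rfe_select(x, y, "svm", stop_size = 4)
  expect_length(res2$selected, 4)
  expect_length(res2$elimination_order, 6)
  expect_setequal(c(res2$selected, res2$elimination_order), colnames(x))
})

test_that("duplicated identical columns: lower index eliminated first", {
  set.seed(4)
  base <- matrix(rnorm(400), 40, 10,
                 dimnames = list(NULL, sprintf("pep_%04d", 1:10)))
  base[, 2] <- base[, 7]  # exact duplicates -> equal |w|
  y <- as.integer(base[, 1] + rnorm(40, sd = 0.5) > 0)
  res <- rfe_select(base, y, "logistic", stop_size = 1)
  # the L2 optimum gives the duplicated pair identical weights, so the
  # index tie-break must eliminate the lower index first
  expect_lt(match("pep_0002", res$elimination_order),
            match("pep_0007", res$elimination_order))
})

test_that("RFE recovers strongly planted features", {
  hits <- vapply(1:8, function(s) {
    co <- generate_cohort(cohort_config(
      n_control = 100, n_asymad = 0, n_ad = 100, n_peptides = 20,
      informative_peptides = data.frame(index = c(3, 9, 15),
                                        effect = c(2, -2, 2)),
      seed = s))
    split <- split_train_test(co$table, 0.8, seed = s)
    train <- co$table[co$table$subject_id %in% split$train_ids, ]
    xs <- apply_scaler(fit_scaler(panel_values(train)), panel_values(train))
    res <- rfe_select(xs, train$group_label == "AD", "svm", stop_size = 5)
    all(sprintf("pep_%04d", c(3, 9, 15)) %in% res$selected)
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("panel intersection is stable-ordered and rejects empty panels", {
  expect_error(intersect_panels(c("pep_0001"), c("pep_0002")), "empty panel")
  expect_equal(intersect_panels(c("pep_0003", "pep_0001"),
                                c("pep_0001", "pep_0003")),
               c("pep_0001", "pep_0003"))
  expect_equal(intersect_panels(c("b", "a", "c"), c("c", "b"),
                                universe = c("c", "b", "a")),
               c("c", "b"))
})

test_that("evaluate_panel: separation, chance level and AUC flagging", {
  co <- generate_cohort(cohort_config(n_control = 100, n_asymad = 0,
                                      n_ad = 100, seed = 6))
  split <- split_train_test(co$table, 0.8, seed = 6)
  train <- co$table[co$table$subject_id %in% split$train_ids, ]
  heldout <- co$table[co$table$subject_id %in% split$heldout_ids, ]
  m <- evaluate_panel(planted_panel(), train, heldout)
  expect_equal(m$roc_auc, 1.0, tolerance = 0.01)
  expect_equal(m$tp + m$fp + m$tn + m$fn, m$n)

  # label-permuted: chance level (Monte-Carlo, scaled from the spec's 50)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    perm <- co$table
    perm$group_label <- sample(perm$group_label)
    sp <- split_train_test(perm, 0.8, seed = s)
    evaluate_panel(planted_panel(),
                   perm[perm$subject_id %in% sp$train_ids, ],
                   perm[perm$subject_id %in% sp$heldout_ids, ])$roc_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)

  single <- heldout[heldout$group_label == "AD", ]
  flagged <- evaluate_panel(planted_panel(), train, single)
  expect_true(flagged$auc_undefined)
  expect_true(is.na(flagged$roc_auc))
})

test_that("permutation p-values match a brute-force rerun bit for bit", {
  co <- generate_cohort(cohort_config(n_control = 60, n_asymad = 0,
                                      n_ad = 60, seed = 7))
  split <- split_train_test(co$table, 0.8, seed = 7)
  train <- co$table[co$table$subject_id %in% split$train_ids, ]
  heldout <- co$table[co$table$subject_id %in% split$heldout_ids, ]
  panel <- planted_panel()
  perm <- permutation_test(panel, train, heldout, n_draws = 200, seed = 99)

  # oracle: replay the draw stream and recount from scratch
  universe <- grep("^pep_", names(train), value = TRUE)
  scaler <- fit_scaler(panel_values(train))
  obs <- evaluate_panel(panel, train, heldout, scaler = scaler)
  set.seed(99)
  null <- t(vapply(1:200, function(i) {
    draw <- sample(universe, length(panel))
    m <- evaluate_panel(draw, train, heldout, scaler = scaler)
    c(m$accuracy, m$precision, m$recall, m$roc_auc)
  }, numeric(4)))
  expected <- c(
    accuracy = sum(null[, 1] >= obs$accuracy, na.rm = TRUE) / 200,
    precision = sum(null[, 2] >= obs$precision, na.rm = TRUE) / 200,
    recall = sum(null[, 3] >= obs$recall, na.rm = TRUE) / 200,
    roc_auc = sum(null[, 4] >= obs$roc_auc, na.rm = TRUE) / 200)
  expect_identical(perm$p_values, expected)
  expect_equal(nrow(perm$null), 200)

  # strong panel, unreachable observed AUC -> plain-fraction p of exactly 0
  if (obs$roc_auc == 1 && max(null[, 4]) < 1) {
    expect_identical(unname(perm$p_values[["roc_auc"]]), 0)
  }
  expect_warning(permutation_test(panel, train, heldout, n_draws = 50,
                                  seed = 1), "unstable")
})

test_that("Kendall tau ranking is tie-corrected and flags extremes", {
  co <- small_cohort(seed = 8, n = 30)
  tab <- co$table
  tab$pep_0001 <- tab$moca  # perfect monotone association
  rk <- kendall_moca_ranking(tab, panel = "pep_0001")
  expect_equal(unname(rk$tau["pep_0001"]), 1)
  expect_equal(unname(rk$panel_ranks[["pep_0001"]]), 1)

  # hand example: tau = 2/3 by concordant/discordant counting
  expect_equal(cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "kendall"), 2 / 3)

  co2 <- generate_cohort(cohort_config(seed = 9))
  rk2 <- kendall_moca_ranking(co2$table, panel = planted_panel())
  n <- length(rk2$tau)
  extreme <- rk2$panel_ranks <= ceiling(n / 4) |
    rk2$panel_ranks > n - ceiling(n / 4)
  expect_true(all(extreme))

  const <- co$table
  const$moca <- 25
  expect_error(kendall_moca_ranking(const), "constant")
})

test_that("volcano statistics: null, doubled, and exact tiny-instance p", {
  co <- generate_cohort(cohort_config(
    n_control = 40, n_asymad = 0, n_ad = 40,
    informative_peptides = data.frame(index = integer(), effect = numeric()),
    seed = 10))
  tab <- co$table
  # doubled abundances in AD for one peptide -> log2FC ~ 1
  tab$pep_0002[tab$group_label == "AD"] <-
    2 * tab$pep_0002[tab$group_label == "AD"]
  vs <- volcano_stats(tab)
  expect_lt(abs(vs$log2fc[vs$peptide == "pep_0002"] - 1), 0.5)
  expect_lt(median(abs(vs$log2fc[vs$peptide != "pep_0002"])), 0.3)

  # 3 vs 3: exact Mann-Whitney p equals exhaustive label enumeration
  x1 <- c(1.1, 2.3, 3.1); x2 <- c(4.0, 5.2, 6.5)
  p_pkg <- wilcox.test(x2, x1)$p.value
  pool <- c(x1, x2)
  combs <- combn(6, 3)
  u_obs <- sum(outer(x2, x1, ">"))
  u_all <- apply(combs, 2, function(idx) {
    sum(outer(pool[setdiff(1:6, idx)], pool[idx], ">"))
  })
  p_oracle <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
})

test_that("select_panel reproduces itself and nests its intersection", {
  co <- generate_cohort(cohort_config(
    n_control = 80, n_asymad = 0, n_ad = 80, n_peptides = 30,
    informative_peptides = data.frame(index = c(3, 9, 15, 21, 27),
                                      effect = c(3, -3, 3, 3, -3)),
    seed = 11))
  cfg <- selection_config(rfe_stop_size = 8, seed = 11)
  r1 <- select_panel(co$table, cfg)
  r2 <- select_panel(co$table, cfg)
  expect_identical(r1$final_panel, r2$final_panel)
  expect_true(all(r1$final_panel %in% r1$svm_set$selected))
  expect_true(all(r1$final_panel %in% r1$logistic_set$selected))
  # scaler must be derived from training rows only
  expect_equal(unname(r1$scaler$center[1]),
               mean(panel_values(co$table[co$table$subject_id %in%
                                            r1$train_ids, ])[, 1]))
})
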