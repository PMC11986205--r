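test_that("t-SNE embedding is deterministic and preserves duplicates", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4)
  x[7, ] <- x[3, ]  # exact duplicate rows
  y1 <- embed_2d(x, perplexity = 10, seed = 5, max_iter = 250)
  y2 <- embed_2d(x, perplexity = 10, seed = 5, max_iter = 250)
  expect_identical(y1, y2)
  rng <- max(apply(y1, 2, function(v) diff(range(v))))
  expect_lt(sqrt(sum((y1[7, ] - y1[3, ])^2)), 0.01 * rng)
})

test_that("well-separated clusters stay separated in 2-D (silhouette)", {
  set.seed(2)
  x <- rbind(matrix(rnorm(200), 40, 5),
             matrix(rnorm(200, mean = 8), 40, 5))
  y <- embed_2d(x, perplexity = 12, seed = 3, max_iter = 400)
  d <- as.matrix(dist(y))
  sil <- vapply(1:80, function(i) {
    own <- if (i <= 40) 1:40 else 41:80
    oth <- setdiff(1:80, own)
    a <- mean(d[i, setdiff(own, i)])
    b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("perplexity is auto-shrunk for small cohorts", {
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4)
  expect_warning(embed_2d(x, perplexity = 30, seed = 1, max_iter = 50),
                 "shrunk")
})

test_that("k-NN labels agree with a brute-force distance-sort oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    emb <- matrix(rnorm(2 * n), n, 2)
    labels <- sample(c("Control", "AD", "AsymAD"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    labels[1:7] <- rep(c("Control", "AD"), length.out = 7)  # enough refs
    q <- which(labels == "AsymAD")
    if (length(q) == 0) next
    expect_identical(knn_label(emb, labels, q, k = 5),
                     unname(oracle_knn(emb, labels, q, k = 5)))
  }
})

test_that("k-NN trivial geometries behave as specified", {
  # query coincident with a Control point deep inside the Control cluster
  emb <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, mean = 10, sd = 0.1), 10, 2),
               c(0, 0))
  labels <- c(rep("Control", 10), rep("AD", 10), "AsymAD")
  expect_equal(knn_label(emb, labels, 21, k = 5), "ControlLike")
  # k = 1 with an AD nearest neighbour
  emb2 <- rbind(c(0, 0), c(5, 5), c(4.9, 5))
  expect_equal(knn_label(emb2, c("Control", "AD", "AsymAD"), 3, k = 1),
               "ADLike")
  expect_error(knn_label(emb2[1:2, ], c("Control", "AD"), 1, k = 5),
               "reference")
})

test_that("stability stratification: probabilities are exact fractions", {
  co <- small_cohort(seed = 4, n = 30)
  res <- quiet_stratify(co$table, planted_panel(),
                        embedding_config(n_repeats = 4, max_iter = 150,
                                         perplexity = 10, seed = 2))
  expect_equal(nrow(res$assignments), sum(co$table$group_label == "AsymAD"))
  manual <- colMeans(res$per_repeat == "ADLike")
  expect_identical(res$assignments$p_adlike, manual)
  expect_true(all(res$assignments$consensus_label %in%
                    c("ControlLike", "ADLike")))
  # consensus equals the majority (ties to ADLike)
  expect_identical(res$assignments$consensus_label,
                   ifelse(manual >= 0.5, "ADLike", "ControlLike"))

  one <- quiet_stratify(co$table, planted_panel(),
                        embedding_config(n_repeats = 1, max_iter = 150,
                                         perplexity = 10, seed = 2))
  expect_true(all(one$assignments$p_adlike %in% c(0, 1)))
})

test_that("AsymAD drawn from the Control band gets low p_adlike", {
  hits <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_config(
      n_control = 80, n_asymad = 30, n_ad = 80,
      asymad_severity_range = c(0.001, 0.2), seed = s))
    res <- quiet_stratify(co$table, planted_panel(),
                          embedding_config(n_repeats = 5, max_iter = 300,
                                           seed = s + 50))
    mean(res$assignments$p_adlike <= 0.1)
  }, numeric(1))
  expect_gte(median(hits), 0.9)
})

test_that("APOE enrichment: exact Fisher, null table, planted effect", {
  # [[10,0],[0,10]] allele table -> two-sided p = 2 / choose(20,10)
  labels <- c(rep("ControlLike", 5), rep("ADLike", 5))
  apoe <- c(rep("e4/e4", 5), rep("e3/e3", 5))
  res <- apoe_enrichment(labels, apoe)
  expect_equal(res$allele_table["ControlLike", "e4"], 10)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # equal allele frequencies -> p near 1
  set.seed(5)
  labels2 <- rep(c("ControlLike", "ADLike"), each = 200)
  geno <- replicate(400, paste(sort(ifelse(runif(2) < 0.3, "e4", "e3")),
                               collapse = "/"))
  expect_gt(apoe_enrichment(labels2, geno)$p_value, 0.2)

  # planted 0.40 vs 0.08 at n = 66/64 -> strong enrichment
  ps <- vapply(1:5, function(s) {
    set.seed(s)
    lab <- c(rep("ADLike", 66), rep("ControlLike", 64))
    gen <- c(replicate(66, paste(sort(ifelse(runif(2) < 0.40, "e4", "e3")),
                                 collapse = "/")),
             replicate(64, paste(sort(ifelse(runif(2) < 0.08, "e4", "e3")),
                                 collapse = "/")))
    apoe_enrichment(lab, gen)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.001), 0.8)
})

test_that("subgroup classifier pools k-fold predictions exactly once", {
  co <- generate_cohort(cohort_config(n_control = 10, n_asymad = 60,
                                      n_ad = 10, seed = 6))
  truth <- co$truth$true_asymad_subtype[co$truth$group_label == "AsymAD"]
  res <- subgroup_classifier_eval(co$table, planted_panel(), truth,
                                  mode = "kfold", k = 6, seed = 2)
  expect_equal(nrow(res$predictions),
               sum(co$table$group_label == "AsymAD"))
  expect_false(anyDuplicated(res$predictions$subject_id) > 0)
  expect_equal(sum(res$confusion), length(truth))

  # planted separation: pooled AUC is high (scaled from the spec's 25 seeds)
  aucs <- vapply(1:5, function(s) {
    cc <- generate_cohort(cohort_config(n_control = 10, n_asymad = 80,
                                        n_ad = 10, seed = s + 20))
    tr <- cc$truth$true_asymad_subtype[cc$truth$group_label == "AsymAD"]
    subgroup_classifier_eval(cc$table, planted_panel(), tr,
                             mode = "kfold", k = 6, seed = s)$roc_auc
  }, numeric(1))
  expect_gte(median(aucs), 0.85)
})

test_that("heldout mode evaluates only the held-out subjects", {
  co <- generate_cohort(cohort_config(n_control = 10, n_asymad = 60,
                                      n_ad = 10, seed = 7))
  truth <- co$truth$true_asymad_subtype[co$truth$group_label == "AsymAD"]
  res <- subgroup_classifier_eval(co$table, planted_panel(), truth,
                                  mode = "heldout", train_fraction = 0.8,
                                  seed = 3)
  expect_lt(nrow(res$predictions), length(truth))
  expect_equal(sum(res$confusion), nrow(res$predictions))
})

test_that("dropping two panel peptides leaves subgroup AUC stable", {
  # mirrors the robustness check that the panel does not hinge on the two
  # APOE-associated members: the remaining peptides carry signal
  full <- planted_panel()
  reduced <- full[-c(2, 6)]
  deltas <- vapply(1:3, function(s) {
    cc <- generate_cohort(cohort_config(n_control = 10, n_asymad = 90,
                                        n_ad = 10, seed = s + 40))
    tr <- cc$truth$true_asymad_subtype[cc$truth$group_label == "AsymAD"]
    a_full <- subgroup_classifier_eval(cc$table, full, tr,
                                       mode = "kfold", seed = s)$roc_auc
    a_red <- subgroup_classifier_eval(cc$table, reduced, tr,
                                      mode = "kfold", seed = s)$roc_auc
    abs(a_full - a_red)
  }, numeric(1))
  expect_lte(median(deltas), 0.05)
})
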