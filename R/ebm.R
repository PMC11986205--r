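#' Configuration for the scaled event-based model
#'
#' The scaled EBM groups the panel biomarkers into `n_clusters` clusters
#' of `cluster_size` biomarkers that become abnormal together, giving a
#' staging system with `n_clusters + 1` stages (stage 0 = no event has
#' occurred). Inference is Metropolis MCMC over the joint state (cluster
#' order plus balanced biomarker-to-cluster assignment), initialised by
#' greedy search from random starting points.
#'
#' Defaults follow the published schedule for an 8-peptide panel:
#' 4 clusters of size 2, 5e5 MCMC iterations with the first 3e5 discarded
#' as burn-in, greedy initialisation from 30 random starts of 800
#' iterations each, and implicit feature exclusion 0 (at which value it is
#' a no-op; other values are rejected as their semantics are undefined
#' here). `profile = "fast"` (5e4 iterations, 3e4 burn-in, 10 x 200
#' greedy) is provided for tests.
#'
#' @param n_clusters Number of event clusters (default 4).
#' @param cluster_size Biomarkers per cluster (default 2).
#' @param implicit_feature_exclusion Accepted for interface completeness;
#'   must be 0.
#' @param mcmc_iterations,burn_in Metropolis schedule
#'   (`burn_in < mcmc_iterations`).
#' @param greedy_starts,greedy_iterations Greedy initialisation schedule.
#' @param greedy_candidates Candidate moves sampled per greedy iteration.
#' @param profile `"full"` (default) or `"fast"`; `"fast"` overrides the
#'   MCMC and greedy schedules for quick runs.
#' @param seed Integer seed.
#' @return Object of class `ebm_config`.
#' @export
ebm_config <- function(n_clusters = 4L, cluster_size = 2L,
                       implicit_feature_exclusion = 0L,
                       mcmc_iterations = 500000L, burn_in = 300000L,
                       greedy_starts = 30L, greedy_iterations = 800L,
                       greedy_candidates = 8L,
                       profile = c("full", "fast"), seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "fast") {
    if (missing(mcmc_iterations)) mcmc_iterations <- 50000L
    if (missing(burn_in)) burn_in <- 30000L
    if (missing(greedy_starts)) greedy_starts <- 10L
    if (missing(greedy_iterations)) greedy_iterations <- 200L
  }
  assert_that(implicit_feature_exclusion == 0,
              "implicit feature exclusion is only supported at 0 (no-op)")
  assert_that(n_clusters >= 1 && cluster_size >= 1,
              "n_clusters and cluster_size must be >= 1")
  assert_that(burn_in < mcmc_iterations,
              "burn_in must be smaller than mcmc_iterations")
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 implicit_feature_exclusion = 0L,
                 mcmc_iterations = as.integer(mcmc_iterations),
                 burn_in = as.integer(burn_in),
                 greedy_starts = as.integer(greedy_starts),
                 greedy_iterations = as.integer(greedy_iterations),
                 greedy_candidates = as.integer(greedy_candidates),
                 profile = profile, seed = as.integer(seed)),
            class = "ebm_config")
}

#' Per-biomarker normal/abnormal Gaussian mixtures
#'
#' For each biomarker, fits a two-component Gaussian mixture by
#' constrained EM on the pooled Control + AD values: the normal component
#' is initialised from the Control rows, the abnormal component from the
#' AD rows, and the component means are kept ordered in the abnormality
#' direction (the sign of the initial AD-minus-Control mean difference).
#' SDs are floored at `1e-3` of the biomarker's data SD.
#'
#' @param x Numeric matrix (subjects x biomarkers).
#' @param labels Character/factor vector with `"Control"` and `"AD"`
#'   entries aligned with rows of `x`.
#' @param max_iter,tol EM schedule.
#' @return Object of class `biomarker_mixture`: a data frame with columns
#'   `biomarker`, `normal_mean`, `normal_sd`, `abnormal_mean`,
#'   `abnormal_sd`, `weight` (abnormal mixing weight), `direction`
#'   (sign of abnormal minus normal mean), `degenerate`.
#' @export
fit_mixtures <- function(x, labels, max_iter = 200L, tol = 1e-8) {
  x <- as.matrix(x)
  is_ctrl <- labels == "Control"; is_ad <- labels == "AD"
  assert_that(any(is_ctrl) && any(is_ad),
              "both Control and AD labels must be present")
  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[is_ctrl | is_ad, j]
    v <- v[is.finite(v)]
    vc <- x[is_ctrl, j]; va <- x[is_ad, j]
    mu_n <- mean(vc, na.rm = TRUE); mu_a <- mean(va, na.rm = TRUE)
    sd_floor <- 1e-3 * max(sd(v), 1e-12)
    sd_n <- max(sd(vc, na.rm = TRUE), sd_floor)
    sd_a <- max(sd(va, na.rm = TRUE), sd_floor)
    direction <- sign(mu_a - mu_n)
    if (direction == 0) direction <- 1
    w <- sum(is_ad) / sum(is_ctrl | is_ad)
    degenerate <- abs(mu_a - mu_n) < 1e-8 * max(abs(mu_n), 1)

    if (!degenerate) {
      for (it in seq_len(max_iter)) {
        dn <- (1 - w) * dnorm(v, mu_n, sd_n)
        da <- w * dnorm(v, mu_a, sd_a)
        tot <- dn + da
        tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
        ra <- da / tot
        na_ <- sum(ra); nn_ <- length(v) - na_
        if (na_ < 1e-8 || nn_ < 1e-8) break
        mu_n2 <- sum((1 - ra) * v) / nn_
        mu_a2 <- sum(ra * v) / na_
        # keep the components ordered in the abnormality direction
        if ((mu_a2 - mu_n2) * direction <= 0) break
        sd_n2 <- max(sqrt(sum((1 - ra) * (v - mu_n2)^2) / nn_), sd_floor)
        sd_a2 <- max(sqrt(sum(ra * (v - mu_a2)^2) / na_), sd_floor)
        w2 <- min(max(na_ / length(v), 1e-6), 1 - 1e-6)
        moved <- abs(mu_n2 - mu_n) + abs(mu_a2 - mu_a)
        mu_n <- mu_n2; mu_a <- mu_a2; sd_n <- sd_n2; sd_a <- sd_a2; w <- w2
        if (moved < tol) break
      }
    }
    data.frame(biomarker = colnames(x)[j] %||% sprintf("bm_%02d", j),
               normal_mean = mu_n, normal_sd = sd_n,
               abnormal_mean = mu_a, abnormal_sd = sd_a,
               weight = w, direction = direction, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("biomarker_mixture", "data.frame")
  out
}

# log densities under each component; missing values contribute 0 to both
# (the subject is staged over observed biomarkers only)
mixture_logdens <- function(mixtures, x) {
  x <- as.matrix(x)
  assert_that(ncol(x) == nrow(mixtures),
              "biomarker count mismatch between data and mixtures")
  logn <- loga <- matrix(0, nrow(x), ncol(x))
  any_missing <- rep(FALSE, nrow(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    miss <- !is.finite(v)
    ln <- dnorm(v, mixtures$normal_mean[j], mixtures$normal_sd[j],
                log = TRUE)
    la <- dnorm(v, mixtures$abnormal_mean[j], mixtures$abnormal_sd[j],
                log = TRUE)
    if (any(!miss & (!is.finite(ln) | !is.finite(la)))) {
      stop(sprintf("non-finite density for biomarker %s",
                   mixtures$biomarker[j]), call. = FALSE)
    }
    ln[miss] <- 0; la[miss] <- 0
    any_missing <- any_missing | miss
    logn[, j] <- ln; loga[, j] <- la
  }
  list(logN = logn, logA = loga, any_missing = any_missing)
}

#' Log-likelihood of an EBM state
#'
#' Computes the total log-likelihood of a joint state (cluster order +
#' biomarker-to-cluster assignment): the sum over subjects of the log of
#' the uniform-prior stage mixture, where a subject at stage `s` draws the
#' biomarkers in clusters at order positions `<= s` from their abnormal
#' component and the rest from their normal component.
#'
#' @param state List with `cluster_order` (permutation of cluster ids,
#'   position 1 first) and `cluster_assignment` (cluster id per
#'   biomarker).
#' @param x Numeric matrix (subjects x biomarkers).
#' @param mixtures A `biomarker_mixture`.
#' @return Scalar log-likelihood.
#' @export
state_log_likelihood <- function(state, x, mixtures) {
  ld <- mixture_logdens(mixtures, x)
  k <- length(state$cluster_order)
  assert_that(setequal(state$cluster_order, seq_len(k)),
              "cluster_order must be a permutation of 1..n_clusters")
  assert_that(all(state$cluster_assignment %in% seq_len(k)),
              "cluster_assignment refers to unknown clusters")
  ebm_loglik_cpp(ld$logN, ld$logA,
                 as.integer(state$cluster_assignment),
                 as.integer(state$cluster_order))
}

#' Greedy initial state for the EBM
#'
#' For each random start, draws a random balanced assignment and random
#' order, then repeatedly proposes a sampled set of candidate moves
#' (order swaps or cross-cluster biomarker swaps), taking the best
#' candidate only when it improves the likelihood. Returns the best state
#' over all starts. Deterministic given the config seed.
#'
#' @param x Numeric matrix (subjects x biomarkers).
#' @param mixtures A `biomarker_mixture`.
#' @param config An [ebm_config()].
#' @return List of class `ebm_state`: `cluster_order`,
#'   `cluster_assignment`, `log_likelihood`.
#' @export
greedy_init <- function(x, mixtures, config = ebm_config()) {
  check_ebm_dims(x, config)
  ld <- mixture_logdens(mixtures, x)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  res <- ebm_greedy_cpp(ld$logN, ld$logA, config$n_clusters,
                        config$cluster_size, config$greedy_starts,
                        config$greedy_iterations, config$greedy_candidates)
  structure(list(cluster_order = res$order,
                 cluster_assignment = res$assign,
                 log_likelihood = res$loglik),
            class = "ebm_state")
}

check_ebm_dims <- function(x, config) {
  assert_that(ncol(x) == config$n_clusters * config$cluster_size,
              sprintf("need %d biomarkers for %d clusters of size %d (got %d)",
                      config$n_clusters * config$cluster_size,
                      config$n_clusters, config$cluster_size, ncol(x)))
}

#' Metropolis MCMC over EBM states
#'
#' Samples the joint posterior over (cluster order, balanced assignment)
#' with symmetric proposals (uniformly: swap two order positions, or swap
#' two biomarkers between clusters) and Metropolis acceptance
#' `min(1, exp(delta logL))`. Post-burn-in samples are retained; the modal
#' state is the most frequently sampled state (ties broken by
#' likelihood). An acceptance rate outside \[0.01, 0.99\] triggers a
#' warning.
#'
#' @param init An `ebm_state` (e.g. from [greedy_init()]).
#' @param x Numeric matrix (subjects x biomarkers).
#' @param mixtures A `biomarker_mixture`.
#' @param config An [ebm_config()].
#' @return Object of class `ebm_fit`: `modal_state`, `samples`
#'   (`order`, `assign` matrices and `loglik`), `positional_variance`
#'   (clusters x positions, rows sum to 1),
#'   `biomarker_positional_variance`, `acceptance_rate`, `mixtures`,
#'   `biomarkers`, `config`.
#' @export
mcmc_sample <- function(init, x, mixtures, config = ebm_config()) {
  check_ebm_dims(x, config)
  ld <- mixture_logdens(mixtures, x)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed + 1L)
  res <- ebm_mcmc_cpp(ld$logN, ld$logA,
                      as.integer(init$cluster_assignment),
                      as.integer(init$cluster_order),
                      config$mcmc_iterations, config$burn_in)
  if (res$acceptance_rate < 0.01 || res$acceptance_rate > 0.99) {
    warning(sprintf("MCMC acceptance rate %.3f outside [0.01, 0.99]",
                    res$acceptance_rate), call. = FALSE)
  }
  n_keep <- config$mcmc_iterations - config$burn_in
  pv <- res$pos_counts / n_keep           # clusters x positions
  bpv <- res$biomarker_pos_counts / n_keep
  rownames(pv) <- sprintf("cluster_%d", seq_len(config$n_clusters))
  colnames(pv) <- sprintf("position_%d", seq_len(config$n_clusters))
  rownames(bpv) <- mixtures$biomarker
  colnames(bpv) <- colnames(pv)
  structure(list(
    modal_state = structure(list(cluster_order = res$modal_order,
                                 cluster_assignment = res$modal_assign,
                                 log_likelihood = res$modal_loglik),
                            class = "ebm_state"),
    samples = list(order = res$order_samples,
                   assign = res$assign_samples,
                   loglik = res$loglik_samples),
    positional_variance = pv,
    biomarker_positional_variance = bpv,
    acceptance_rate = res$acceptance_rate,
    mixtures = mixtures, biomarkers = mixtures$biomarker,
    config = config
  ), class = "ebm_fit")
}

#' Fit a scaled EBM to labelled panel data
#'
#' Convenience wrapper: fits per-biomarker mixtures on the Control/AD
#' rows, runs greedy initialisation, then MCMC.
#'
#' @param table A `cohort_table` containing Control and AD subjects.
#' @param panel Panel peptide names (length `n_clusters * cluster_size`).
#' @param config An [ebm_config()].
#' @param log_transform Model log-scale abundances? Default `TRUE` (peptide
#'   intensities are right-skewed; Gaussian components fit the log scale).
#' @return An `ebm_fit`.
#' @export
fit_ebm <- function(table, panel, config = ebm_config(),
                    log_transform = TRUE) {
  train <- table[table$group_label %in% c("Control", "AD"), , drop = FALSE]
  x <- peptide_matrix(train)[, panel, drop = FALSE]
  if (log_transform) x <- log(x)
  mixtures <- fit_mixtures(x, train$group_label)
  init <- greedy_init(x, mixtures, config)
  fit <- mcmc_sample(init, x, mixtures, config)
  fit$log_transform <- log_transform
  fit
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat("<ebm_fit>\n")
  cat("  modal cluster order:",
      paste(x$modal_state$cluster_order, collapse = " -> "), "\n")
  cat(sprintf("  modal log-likelihood: %.2f; acceptance rate %.3f; %d samples\n",
              x$modal_state$log_likelihood, x$acceptance_rate,
              length(x$samples$loglik)))
  invisible(x)
}

#' Probabilistic patient staging
#'
#' Computes, for each subject, the posterior over stages `0..K` under the
#' modal state with a uniform stage prior, and the maximum-likelihood
#' stage (ties resolved to the lower stage). Subjects with missing
#' biomarker values are staged over their observed biomarkers only and
#' flagged.
#'
#' @param fit An `ebm_fit`.
#' @param x Numeric matrix (subjects x biomarkers, matching the fit's
#'   biomarkers by column), or a `cohort_table` from which the fit's
#'   biomarker columns are extracted (log-transformed if the fit was).
#' @return Object of class `stage_posterior`: `probabilities` (subjects x
#'   stages, rows sum to 1), `ml_stage` (integer in `0..K`), `flagged`.
#' @export
stage_subjects <- function(fit, x) {
  if (inherits(x, "cohort_table") || is.data.frame(x)) {
    x <- peptide_matrix(x)[, fit$biomarkers, drop = FALSE]
    if (isTRUE(fit$log_transform)) x <- log(x)
  }
  x <- as.matrix(x)
  ld <- mixture_logdens(fit$mixtures, x)
  k <- length(fit$modal_state$cluster_order)
  delta <- matrix(0, nrow(x), k)
  for (j in seq_len(ncol(x))) {
    c_ <- fit$modal_state$cluster_assignment[j]
    delta[, c_] <- delta[, c_] + (ld$logA[, j] - ld$logN[, j])
  }
  stage_ll <- matrix(0, nrow(x), k + 1)
  stage_ll[, 1] <- rowSums(ld$logN)
  for (p in seq_len(k)) {
    stage_ll[, p + 1] <- stage_ll[, p] +
      delta[, fit$modal_state$cluster_order[p]]
  }
  probs <- t(apply(stage_ll, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  colnames(probs) <- sprintf("stage_%d", 0:k)
  ml <- apply(probs, 1, which.max) - 1L  # which.max takes the first tie
  structure(list(probabilities = probs, ml_stage = ml,
                 flagged = ld$any_missing),
            class = "stage_posterior")
}

#' Recalibrate mixtures on an external cohort
#'
#' Re-fits the per-biomarker mixture parameters on external data with the
#' event ordering and cluster assignment held fixed, to absorb
#' distributional shifts across cohorts. In labelled mode the components
#' are anchored by the external Control/AD labels exactly as in
#' [fit_mixtures()]; in unlabelled mode an unconstrained EM per biomarker
#' is initialised from the training parameters.
#'
#' @param fit An `ebm_fit`.
#' @param x External biomarker matrix or `cohort_table` (columns must
#'   match the fit's biomarkers by name).
#' @param labels Optional Control/AD labels (labelled mode); `NULL` for
#'   unlabelled EM.
#' @return A new `ebm_fit` with updated mixtures (ordering unchanged).
#' @export
recalibrate <- function(fit, x, labels = NULL) {
  if (inherits(x, "cohort_table") || is.data.frame(x)) {
    missing_cols <- setdiff(fit$biomarkers,
                            grep("^pep_", names(x), value = TRUE))
    if (length(missing_cols) > 0) {
      stop(sprintf("external data missing biomarker column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    x <- peptide_matrix(x)[, fit$biomarkers, drop = FALSE]
    if (isTRUE(fit$log_transform)) x <- log(x)
  }
  x <- as.matrix(x)
  assert_that(identical(colnames(x), fit$biomarkers),
              "external biomarkers must match the fit's biomarkers by name")
  if (!is.null(labels)) {
    mixtures <- fit_mixtures(x, labels)
  } else {
    mixtures <- fit$mixtures
    for (j in seq_len(ncol(x))) {
      v <- x[is.finite(x[, j]), j]
      em <- em_gauss2_init(v, mixtures$normal_mean[j], mixtures$normal_sd[j],
                           mixtures$abnormal_mean[j], mixtures$abnormal_sd[j],
                           mixtures$weight[j])
      mixtures$normal_mean[j] <- em$mu[1]
      mixtures$normal_sd[j] <- em$sigma[1]
      mixtures$abnormal_mean[j] <- em$mu[2]
      mixtures$abnormal_sd[j] <- em$sigma[2]
      mixtures$weight[j] <- em$w[2]
    }
  }
  out <- fit
  out$mixtures <- mixtures
  out
}

# unconstrained EM warm-started from given parameters; component 1 plays
# the "normal" role, component 2 the "abnormal" role
em_gauss2_init <- function(x, mu1, sd1, mu2, sd2, w2,
                           tol = 1e-8, max_iter = 200L) {
  mu <- c(mu1, mu2); sigma <- pmax(c(sd1, sd2), 1e-8)
  w <- c(1 - w2, w2)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    r2 <- d2 / tot
    n2 <- sum(r2); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu_new <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sigma <- pmax(sqrt(c(sum((1 - r2) * (x - mu_new[1])^2) / n1,
                         sum(r2 * (x - mu_new[2])^2) / n2)), 1e-8)
    moved <- sum(abs(mu_new - mu))
    mu <- mu_new
    w <- c(n1, n2) / length(x)
    if (moved < tol) break
  }
  list(mu = mu, sigma = sigma, w = w)
}

#' Kendall distance between an inferred and a planted event ordering
#'
#' Cluster ids are arbitrary labels, so inferred and planted orderings are
#' compared through the biomarkers: each planted cluster is placed at the
#' mean inferred position of its biomarkers, and the distance is the
#' number of planted cluster pairs whose relative order is inverted
#' (pairs tied at equal mean position count as half). A perfect recovery
#' (identical biomarker grouping and order) has distance 0.
#'
#' @param state An `ebm_state` (e.g. `fit$modal_state`).
#' @param planted_ordering Permutation of planted cluster ids, earliest
#'   first.
#' @param planted_assignment Planted cluster id per biomarker.
#' @return Non-negative Kendall distance.
#' @export
event_order_distance <- function(state, planted_ordering,
                                 planted_assignment) {
  k <- length(planted_ordering)
  pos_of_cluster <- match(seq_len(k), state$cluster_order)
  bm_pos <- pos_of_cluster[state$cluster_assignment]
  mean_pos <- vapply(planted_ordering, function(cl) {
    mean(bm_pos[planted_assignment == cl])
  }, numeric(1))  # planted earliest..latest
  d <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (mean_pos[i] > mean_pos[j]) d <- d + 1
      else if (mean_pos[i] == mean_pos[j]) d <- d + 0.5
    }
  }
  d
}

#' Chi-square comparison of stage distributions between groups
#'
#' Builds the group-by-stage contingency table (stages with all-zero
#' margins are pooled out) and applies Pearson's chi-square test without
#' continuity correction.
#'
#' @param stages Integer stage per subject.
#' @param groups Group label per subject (>= 2 groups).
#' @return List: `statistic`, `p_value`, `table`, `df`.
#' @export
stage_distribution_test <- function(stages, groups) {
  assert_that(length(stages) == length(groups),
              "stages and groups must align")
  assert_that(length(unique(groups)) >= 2, "need at least 2 groups")
  tab <- table(groups, stages)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       table = tab, df = unname(res$parameter))
}
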