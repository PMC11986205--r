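# Shared fixtures are built in code. Small cohorts keep the default suite
# fast; the acceptance tests use the spec-scale settings.

small_cohort <- function(seed = 1L, n = 40L, ...) {
  generate_cohort(cohort_config(n_control = n, n_asymad = n %/% 2,
                                n_ad = n, seed = seed, ...))
}

planted_panel <- function() {
  sprintf("pep_%04d", default_informative_peptides()$index)
}

# quiet wrappers: perplexity auto-shrink / consensus-tie warnings are
# expected on tiny fixtures
quiet_stratify <- function(...) {
  suppressWarnings(stability_stratify(...))
}

# independent EBM likelihood oracle: explicit loops over subjects, stages,
# biomarkers (no sharing with the package's computation path)
oracle_ebm_loglik <- function(x, mixtures, assign, ord) {
  k <- length(ord)
  total <- 0
  for (i in seq_len(nrow(x))) {
    stage_lik <- numeric(k + 1)
    for (s in 0:k) {
      abnormal_clusters <- if (s == 0) integer(0) else ord[seq_len(s)]
      lik <- 0
      for (j in seq_len(ncol(x))) {
        if (assign[j] %in% abnormal_clusters) {
          lik <- lik + dnorm(x[i, j], mixtures$abnormal_mean[j],
                             mixtures$abnormal_sd[j], log = TRUE)
        } else {
          lik <- lik + dnorm(x[i, j], mixtures$normal_mean[j],
                             mixtures$normal_sd[j], log = TRUE)
        }
      }
      stage_lik[s + 1] <- lik
    }
    m <- max(stage_lik)
    total <- total + m + log(sum(exp(stage_lik - m))) + log(1 / (k + 1))
  }
  total
}

# brute-force k-NN oracle: full distance sort, ties by lower index
oracle_knn <- function(embedding, ref_labels, query_idx, k) {
  ref_idx <- which(ref_labels %in% c("Control", "AD"))
  sapply(query_idx, function(i) {
    d <- apply(embedding[ref_idx, , drop = FALSE], 1, function(p) {
      sqrt(sum((p - embedding[i, ])^2))
    })
    ord <- ref_idx[order(d, ref_idx)]
    votes <- ref_labels[ord[seq_len(k)]]
    if (sum(votes == "AD") > k / 2) "ADLike" else "ControlLike"
  })
}

# brute-force AUC: concordant-pair enumeration with half-credit ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}
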