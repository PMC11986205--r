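#' Fit a two-component Gaussian mixture to a biomarker ratio
#'
#' Fits a univariate two-component Gaussian mixture by EM and derives a
#' positivity cut-off as the point between the component means where the
#' posterior responsibility of the upper (abnormal) component crosses 0.5.
#' This is the standard way of deriving a local positivity threshold for a
#' bimodal biomarker ratio such as CSF tTau:Abeta42 (where a threshold
#' around 0.24 has been reported for one large cohort).
#'
#' EM details: initialisation by quantile split (means at the 25th/75th
#' percentiles), convergence at 1e-6 relative change of the log-likelihood,
#' at most 500 iterations, best of 5 deterministic restarts with
#' progressively wider quantile pairs.
#'
#' @param values Positive finite ratio values (at least 20).
#' @param use_log Fit on the log scale? Default `FALSE`: the conventional
#'   ratio threshold is quoted on the raw scale.
#' @return Object of class `mixture_cutoff`: `component_means` (ascending),
#'   `component_sds`, `component_weights` (sum 1), `cutoff`,
#'   `log_scale_used`, `degenerate` flag and `log_likelihood`. When the fit
#'   is degenerate (component weight < 0.01, collapsed SD, or no posterior
#'   crossing between the means) `cutoff` is `NA` and `degenerate = TRUE`;
#'   no silent cut-off is produced.
#' @export
fit_ratio_mixture <- function(values, use_log = FALSE) {
  v <- values[is.finite(values)]
  assert_that(length(v) >= 20, "need at least 20 finite values")
  assert_that(all(v > 0), "ratio values must be positive")
  x <- if (use_log) log(v) else v
  assert_that(var(x) > 0, "values have zero variance")

  quantile_pairs <- list(c(0.25, 0.75), c(0.20, 0.80), c(0.30, 0.70),
                         c(0.15, 0.85), c(0.35, 0.65))
  best <- NULL
  for (qp in quantile_pairs) {
    fit <- em_gauss2(x, init_means = unname(quantile(x, qp)))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$mu)
  mu <- best$mu[ord]; sigma <- best$sigma[ord]; w <- best$w[ord]
  degenerate <- any(w < 0.01) || any(sigma < 1e-6 * sd(x)) ||
    !(mu[2] > mu[1])
  cutoff <- NA_real_
  if (!degenerate) {
    cutoff <- posterior_crossing(mu, sigma, w)
    if (is.na(cutoff)) degenerate <- TRUE
  }
  if (!is.na(cutoff) && use_log) cutoff <- exp(cutoff)
  structure(list(
    component_means = mu, component_sds = sigma, component_weights = w,
    cutoff = cutoff, log_scale_used = use_log,
    degenerate = degenerate, log_likelihood = best$loglik,
    n = length(x)
  ), class = "mixture_cutoff")
}

# Plain EM for a univariate 2-component Gaussian mixture.
em_gauss2 <- function(x, init_means, tol = 1e-6, max_iter = 500L) {
  mu <- init_means
  sigma <- rep(max(sd(x) / 2, 1e-8), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                    sum(r2 * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, 1e-8 * max(sd(x), 1e-12))
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old)
}

# Root of P(upper component | x) - 0.5 between the two component means.
posterior_crossing <- function(mu, sigma, w) {
  f <- function(x) {
    w[2] * dnorm(x, mu[2], sigma[2]) - w[1] * dnorm(x, mu[1], sigma[1])
  }
  lo <- mu[1]; hi <- mu[2]
  if (f(lo) >= 0 || f(hi) <= 0) {
    # no sign change at the means: scan a dense grid for a bracketing pair
    grid <- seq(lo, hi, length.out = 512)
    fg <- vapply(grid, f, numeric(1))
    i <- which(fg[-1] >= 0 & fg[-length(fg)] < 0)
    if (length(i) == 0) return(NA_real_)
    lo <- grid[i[1]]; hi <- grid[i[1] + 1]
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.mixture_cutoff <- function(x, ...) {
  cat("<mixture_cutoff>\n")
  cat(sprintf("  means: %.4g / %.4g  sds: %.3g / %.3g  weights: %.3f / %.3f\n",
              x$component_means[1], x$component_means[2],
              x$component_sds[1], x$component_sds[2],
              x$component_weights[1], x$component_weights[2]))
  if (x$degenerate) cat("  DEGENERATE fit: no cut-off derived\n")
  else cat(sprintf("  cutoff (posterior 0.5 crossing): %.4g%s\n", x$cutoff,
                   if (x$log_scale_used) " [fitted on log scale]" else ""))
  invisible(x)
}

#' Youden-index ROC cut-off
#'
#' Selects the threshold maximising Youden's J = sensitivity +
#' specificity - 1 over all midpoints between consecutive sorted unique
#' scores. Ties in J are broken in favour of higher sensitivity, then the
#' smaller threshold. This is the rule used to derive PET SUVR positivity
#' cut-offs (e.g. amyloid AV45 > 1.226, FDG < 1.191 in one public cohort).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or factor with two levels;
#'   the second level / `TRUE` / `1` is the positive class).
#' @param direction `"greater_is_positive"` (score above threshold calls
#'   positive) or `"less_is_positive"`.
#' @return Object of class `roc_cutoff` with `threshold`, `direction`,
#'   `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels,
                          direction = c("greater_is_positive",
                                        "less_is_positive")) {
  direction <- match.arg(direction)
  y <- as_binary_labels(labels)
  ok <- is.finite(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  assert_that(length(unique(y)) == 2, "both classes must be present")
  u <- sort(unique(scores))
  assert_that(length(u) >= 2, "need at least two distinct scores")
  thresholds <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(y == 1); nneg <- sum(y == 0)
  best <- NULL
  for (t in thresholds) {
    pred <- if (direction == "greater_is_positive") scores > t else scores < t
    sens <- sum(pred & y == 1) / npos
    spec <- sum(!pred & y == 0) / nneg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
           (sens > best$sens + 1e-12 ||
              (abs(sens - best$sens) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  structure(list(threshold = best$t, direction = direction,
                 youden_j = best$j, sensitivity = best$sens,
                 specificity = best$spec),
            class = "roc_cutoff")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (is.numeric(labels)) {
    u <- sort(unique(labels[!is.na(labels)]))
    assert_that(length(u) <= 2, "labels must be binary")
    return(as.integer(labels == max(u)))
  }
  if (is.character(labels)) {
    u <- sort(unique(labels[!is.na(labels)]))
    assert_that(length(u) <= 2, "labels must be binary")
    return(as.integer(labels == u[length(u)]))
  }
  stop("unsupported label type", call. = FALSE)
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("<roc_cutoff> threshold=%.4g (%s), J=%.3f (sens %.3f, spec %.3f)\n",
              x$threshold, x$direction, x$youden_j, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Assign diagnostic groups from biomarker positivity
#'
#' Applies the gating rule: cognitively normal (CN) and biomarker-negative
#' -> `Control`; CN and biomarker-positive -> `AsymAD`; symptomatic and
#' biomarker-positive -> `AD`; symptomatic and biomarker-negative ->
#' `excluded` (recorded with a reason, mirroring the exclusion of
#' symptomatic amyloid-negative subjects from such analyses). Positivity is
#' a strict inequality (ratio > cut-off; AV45 SUVR > cut-off).
#'
#' @param table A `cohort_table`.
#' @param cognitive_status Character vector aligned with `table` rows,
#'   values `"CN"` or `"symptomatic"`.
#' @param ratio_cutoff tTau:Abeta42 ratio positivity threshold (mode
#'   `"ratio"`), e.g. `fit_ratio_mixture(...)$cutoff`.
#' @param suvr_cutoffs Named list/vector with element `av45` (mode
#'   `"suvr"`); positivity is `av45_suvr > av45`.
#' @param mode `"ratio"` (CSF tTau:Abeta42) or `"suvr"` (amyloid PET).
#' @return The table with `group_label` replaced by one of `Control`,
#'   `AsymAD`, `AD`, `excluded`, `unassignable` (missing biomarker), plus
#'   an `assignment_reason` column.
#' @export
assign_groups <- function(table, cognitive_status, ratio_cutoff = NULL,
                          suvr_cutoffs = NULL,
                          mode = c("ratio", "suvr")) {
  mode <- match.arg(mode)
  assert_that(length(cognitive_status) == nrow(table),
              "cognitive_status must align with table rows")
  assert_that(all(cognitive_status %in% c("CN", "symptomatic"),
                  na.rm = TRUE),
              "cognitive_status values must be 'CN' or 'symptomatic'")
  if (mode == "ratio") {
    assert_that(is.numeric(ratio_cutoff) && length(ratio_cutoff) == 1 &&
                  is.finite(ratio_cutoff), "ratio_cutoff must be a number")
    marker <- table$ttau / table$abeta42
    positive <- marker > ratio_cutoff
  } else {
    av45 <- suvr_cutoffs[["av45"]]
    assert_that(is.numeric(av45) && is.finite(av45),
                "suvr_cutoffs must contain a finite 'av45' threshold")
    marker <- table$av45_suvr
    positive <- marker > av45
  }
  label <- character(nrow(table))
  reason <- rep(NA_character_, nrow(table))
  for (i in seq_len(nrow(table))) {
    if (is.na(marker[i]) || is.na(cognitive_status[i])) {
      label[i] <- "unassignable"
      reason[i] <- "missing biomarker or cognitive status"
    } else if (cognitive_status[i] == "CN") {
      label[i] <- if (positive[i]) "AsymAD" else "Control"
    } else {
      if (positive[i]) {
        label[i] <- "AD"
      } else {
        label[i] <- "excluded"
        reason[i] <- "symptomatic but biomarker-negative"
      }
    }
  }
  table$group_label <- label
  table$assignment_reason <- reason
  table
}

#' Demographically matched 1:1:1 group triplets
#'
#' Greedy nearest-age matching of one Control and one AD case to each
#' AsymAD subject within exact sex/race strata. The age caliper applies to
#' both pairs; the education caliper applies to the Control-AsymAD pair
#' only (symptomatic cases are typically matched on age/sex/race alone).
#' Greedy matching is simple and reproducible; the procedure processes
#' AsymAD subjects in increasing age order.
#'
#' @param table A `cohort_table` with assigned `group_label`.
#' @param age_caliper Maximum absolute age difference (years, default 5).
#' @param education_caliper Maximum absolute education difference (years,
#'   default 3) between AsymAD and Control.
#' @return Object of class `matched_cohort`: `triplets` data frame
#'   (`control_id`, `asymad_id`, `ad_id`), `matching_keys`, `calipers`,
#'   and `unmatched` (AsymAD IDs left unmatched).
#' @export
match_groups <- function(table, age_caliper = 5, education_caliper = 3) {
  for (g in c("Control", "AsymAD", "AD")) {
    if (!any(table$group_label == g)) {
      stop(sprintf("empty group: %s", g), call. = FALSE)
    }
  }
  tab <- as.data.frame(table)
  tab$.stratum <- paste(tab$sex, tab$race, sep = "|")
  asym <- tab[tab$group_label == "AsymAD", ]
  asym <- asym[order(asym$age), ]
  used_control <- character(0); used_ad <- character(0)
  triplets <- list(); unmatched <- character(0)

  for (i in seq_len(nrow(asym))) {
    a <- asym[i, ]
    cand_c <- tab[tab$group_label == "Control" & tab$.stratum == a$.stratum &
                    !(tab$subject_id %in% used_control) &
                    abs(tab$age - a$age) <= age_caliper &
                    abs(tab$education - a$education) <= education_caliper, ]
    cand_d <- tab[tab$group_label == "AD" & tab$.stratum == a$.stratum &
                    !(tab$subject_id %in% used_ad) &
                    abs(tab$age - a$age) <= age_caliper, ]
    if (nrow(cand_c) == 0 || nrow(cand_d) == 0) {
      unmatched <- c(unmatched, a$subject_id)
      next
    }
    cc <- cand_c[order(abs(cand_c$age - a$age), cand_c$subject_id), ][1, ]
    dd <- cand_d[order(abs(cand_d$age - a$age), cand_d$subject_id), ][1, ]
    used_control <- c(used_control, cc$subject_id)
    used_ad <- c(used_ad, dd$subject_id)
    triplets[[length(triplets) + 1]] <-
      data.frame(control_id = cc$subject_id, asymad_id = a$subject_id,
                 ad_id = dd$subject_id, stringsAsFactors = FALSE)
  }
  if (length(unmatched) > 0) {
    warning(sprintf("%d AsymAD subject(s) left unmatched", length(unmatched)),
            call. = FALSE)
  }
  trip <- if (length(triplets) > 0) do.call(rbind, triplets) else
    data.frame(control_id = character(), asymad_id = character(),
               ad_id = character(), stringsAsFactors = FALSE)
  structure(list(
    triplets = trip,
    matching_keys = c("age", "sex", "race", "education"),
    calipers = c(age = age_caliper, education = education_caliper),
    unmatched = unmatched
  ), class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d triplets, %d unmatched AsymAD\n",
              nrow(x$triplets), length(x$unmatched)))
  invisible(x)
}
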