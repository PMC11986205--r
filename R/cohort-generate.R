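peptide_colnames <- function(n) sprintf("pep_%04d", seq_len(n))

#' Generate a synthetic three-group CSF cohort
#'
#' Simulates a cohort table with the structure assumed by the panel
#' selection, stratification and staging stages, together with the ground
#' truth used for recovery testing. Each subject carries a latent disease
#' severity in \[0, 1\] (Control: Uniform(0, 0.2); AD: Uniform(0.8, 1);
#' AsymAD: spanning the configured range). Log-scale peptide abundances are
#' `base + effect * severity + noise` and exported on the linear scale
#' (targeted mass-spectrometry intensities are right-skewed). CSF analytes
#' are per-group log-normal draws, APOE alleles are binomial draws at the
#' per-group epsilon-4 frequency, and MoCA declines linearly with severity.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{table}{`cohort_table` data frame, one row per subject.}
#'     \item{truth}{Data frame: `subject_id`, `group_label`,
#'       `latent_severity`, `true_asymad_subtype` (`ADLike` iff severity
#'       > 0.5, defined only for AsymAD subjects).}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 20, n_asymad = 10,
#'                                         n_ad = 20, seed = 7))
#' table(cohort$table$group_label)
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must be a cohort_config object")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  groups <- c(rep("Control", config$n_control),
              rep("AsymAD", config$n_asymad),
              rep("AD", config$n_ad))
  n <- length(groups)
  if (n == 0) {
    tab <- empty_cohort_table(config$n_peptides)
    truth <- data.frame(subject_id = character(), group_label = character(),
                        latent_severity = numeric(),
                        true_asymad_subtype = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(table = tab, truth = truth),
                     class = "synthetic_cohort"))
  }

  sev <- numeric(n)
  sev[groups == "Control"] <- runif(sum(groups == "Control"), 0, 0.2)
  sev[groups == "AsymAD"] <- runif(sum(groups == "AsymAD"),
                                   config$asymad_severity_range[1],
                                   config$asymad_severity_range[2])
  sev[groups == "AD"] <- runif(sum(groups == "AD"), 0.8, 1)

  # fixed per-peptide baseline (log scale), deterministic under the seed
  base <- rnorm(config$n_peptides, mean = 5, sd = 1)
  eff <- numeric(config$n_peptides)
  if (nrow(config$informative_peptides) > 0) {
    eff[config$informative_peptides$index] <-
      config$informative_peptides$effect * config$noise_sd
  }
  logpep <- matrix(rnorm(n * config$n_peptides, sd = config$noise_sd),
                   nrow = n)
  logpep <- sweep(logpep, 2, base, `+`) + outer(sev, eff)
  pep <- exp(logpep)
  colnames(pep) <- peptide_colnames(config$n_peptides)
  if (config$mcar_rate > 0) {
    mask <- matrix(runif(length(pep)) < config$mcar_rate, nrow = n)
    pep[mask] <- NA_real_
  }

  analyte <- function(which) {
    out <- numeric(n)
    for (g in unique(groups)) {
      p <- config$analyte_params
      row <- p[p$group == g & p$analyte == which, ]
      assert_that(nrow(row) == 1,
                  sprintf("missing analyte parameters for %s/%s", g, which))
      idx <- groups == g
      out[idx] <- exp(rnorm(sum(idx), row$meanlog, row$sdlog))
    }
    out
  }
  abeta42 <- analyte("abeta42")
  ttau <- analyte("ttau")
  ptau <- analyte("ptau")

  apoe <- vapply(groups, function(g) {
    f <- config$apoe_e4_freq[[g]]
    alleles <- ifelse(runif(2) < f, "e4",
                      ifelse(runif(2) < 0.1, "e2", "e3"))
    paste(sort(alleles), collapse = "/")
  }, character(1), USE.NAMES = FALSE)

  moca <- round(config$moca_baseline - config$moca_slope * sev +
                  rnorm(n, sd = config$moca_noise_sd))
  moca <- pmin(30, pmax(0, moca))

  age <- round(rnorm(n, 66, 6), 1)
  sex <- ifelse(runif(n) < 0.746, "F", "M")
  race <- sample(c("Caucasian", "African-American", "Asian"), n,
                 replace = TRUE, prob = c(0.925, 0.067, 0.008))
  education <- pmax(8, round(rnorm(n, 16.7, 2.1)))

  tab <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group_label = groups,
    age = age, sex = sex, race = race, education = education,
    moca = moca, apoe = apoe,
    abeta42 = abeta42, ttau = ttau, ptau = ptau,
    stringsAsFactors = FALSE
  )
  if (config$include_suvr) {
    tab$av45_suvr <- round(1.05 + 0.45 * sev + rnorm(n, sd = 0.10), 4)
    tab$fdg_suvr <- round(1.35 - 0.30 * sev + rnorm(n, sd = 0.08), 4)
  } else {
    tab$av45_suvr <- NA_real_
    tab$fdg_suvr <- NA_real_
  }
  tab <- cbind(tab, as.data.frame(pep))
  class(tab) <- c("cohort_table", "data.frame")

  subtype <- rep(NA_character_, n)
  subtype[groups == "AsymAD"] <-
    ifelse(sev[groups == "AsymAD"] > 0.5, "ADLike", "ControlLike")
  truth <- data.frame(subject_id = tab$subject_id, group_label = groups,
                      latent_severity = sev, true_asymad_subtype = subtype,
                      stringsAsFactors = FALSE)
  structure(list(table = tab, truth = truth), class = "synthetic_cohort")
}

empty_cohort_table <- function(n_peptides) {
  tab <- data.frame(
    subject_id = character(), group_label = character(), age = numeric(),
    sex = character(), race = character(), education = numeric(),
    moca = numeric(), apoe = character(), abeta42 = numeric(),
    ttau = numeric(), ptau = numeric(), av45_suvr = numeric(),
    fdg_suvr = numeric(), stringsAsFactors = FALSE
  )
  for (nm in peptide_colnames(n_peptides)) tab[[nm]] <- numeric()
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Peptide abundance matrix of a cohort table
#'
#' @param table A `cohort_table` data frame.
#' @return Numeric matrix (subjects x peptides) with subject IDs as row
#'   names.
#' @export
peptide_matrix <- function(table) {
  cols <- grep("^pep_", names(table), value = TRUE)
  m <- as.matrix(table[, cols, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- table$subject_id
  m
}

# Peptide values as used by the analysis stages: optionally restricted to
# a panel and log-transformed (linear-scale SRM intensities are
# right-skewed; distances and Gaussian components assume the log scale).
panel_values <- function(table, panel = NULL, log_transform = TRUE) {
  x <- peptide_matrix(table)
  if (!is.null(panel)) x <- x[, panel, drop = FALSE]
  if (log_transform) {
    assert_that(all(x > 0, na.rm = TRUE),
                "log transform requires positive abundances")
    x <- log(x)
  }
  x
}

#' Default normal/abnormal mixtures for an event cascade
#'
#' One biomarker per row: standard-normal `normal` component and a shifted
#' `abnormal` component, grouped into `n_clusters` clusters of
#' `cluster_size` biomarkers that become abnormal together.
#'
#' @param n_clusters,cluster_size Cascade geometry (defaults 4 x 2 = 8
#'   biomarkers).
#' @param separation Abnormal-minus-normal mean shift in SD units
#'   (default 3, a well-separated cascade).
#' @return Data frame with columns `biomarker`, `cluster`, `normal_mean`,
#'   `normal_sd`, `abnormal_mean`, `abnormal_sd`.
#' @export
cascade_mixtures <- function(n_clusters = 4L, cluster_size = 2L,
                             separation = 3) {
  b <- n_clusters * cluster_size
  data.frame(
    biomarker = peptide_colnames(b),
    cluster = rep(seq_len(n_clusters), each = cluster_size),
    normal_mean = 0, normal_sd = 1,
    abnormal_mean = separation, abnormal_sd = 1,
    stringsAsFactors = FALSE
  )
}

#' Generate an event-cascade cohort with a planted event ordering
#'
#' Simulates the generative model assumed by the event-based disease
#' progression model: each subject has a true stage `s` in `0..K`; the
#' biomarkers belonging to clusters at ordering positions `<= s` are drawn
#' from their abnormal component, all others from their normal component.
#' Earlier-ordered clusters are therefore abnormal in a larger fraction of
#' the population.
#'
#' @param n_subjects Number of subjects.
#' @param ordering Permutation of the cluster ids giving the planted event
#'   order (position 1 = earliest).
#' @param mixtures Per-biomarker mixture table as from [cascade_mixtures()].
#' @param stage_dist Probability vector over stages `0..K` (K = number of
#'   clusters); must sum to 1.
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list; `truth` carries `true_stage` and the
#'   planted ordering as attribute `true_event_ordering`. Subjects at stage
#'   0 are labelled `Control`, at stage K `AD`, otherwise `Unlabelled`.
#' @export
generate_event_cascade <- function(n_subjects, ordering,
                                   mixtures = cascade_mixtures(),
                                   stage_dist = NULL, seed = 1L) {
  mixtures <- as.data.frame(mixtures)
  clusters <- sort(unique(mixtures$cluster))
  k <- length(clusters)
  assert_that(length(ordering) == k && setequal(ordering, clusters),
              "ordering must be a permutation of the cluster ids")
  if (is.null(stage_dist)) stage_dist <- rep(1 / (k + 1), k + 1)
  assert_that(length(stage_dist) == k + 1 &&
                abs(sum(stage_dist) - 1) < 1e-9 && all(stage_dist >= 0),
              "stage_dist must be a probability vector over 0..n_clusters")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  stages <- sample(0:k, n_subjects, replace = TRUE, prob = stage_dist)
  # position of each biomarker's cluster in the planted order
  pos_of_cluster <- match(clusters, ordering)
  b <- nrow(mixtures)
  x <- matrix(NA_real_, n_subjects, b)
  for (j in seq_len(b)) {
    p <- pos_of_cluster[match(mixtures$cluster[j], clusters)]
    abn <- stages >= p
    x[, j] <- ifelse(abn,
                     rnorm(n_subjects, mixtures$abnormal_mean[j],
                           mixtures$abnormal_sd[j]),
                     rnorm(n_subjects, mixtures$normal_mean[j],
                           mixtures$normal_sd[j]))
  }
  colnames(x) <- mixtures$biomarker

  labels <- rep("Unlabelled", n_subjects)
  labels[stages == 0] <- "Control"
  labels[stages == k] <- "AD"
  tab <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_subjects)),
    group_label = labels, age = NA_real_, sex = NA_character_,
    race = NA_character_, education = NA_real_, moca = NA_real_,
    apoe = NA_character_, abeta42 = NA_real_, ttau = NA_real_,
    ptau = NA_real_, av45_suvr = NA_real_, fdg_suvr = NA_real_,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(x))
  class(tab) <- c("cohort_table", "data.frame")
  truth <- data.frame(subject_id = tab$subject_id, group_label = labels,
                      true_stage = stages, stringsAsFactors = FALSE)
  attr(truth, "true_event_ordering") <- ordering
  structure(list(table = tab, truth = truth), class = "synthetic_cohort")
}
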