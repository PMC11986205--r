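#' Run the full stratification pipeline
#'
#' Orchestrates gate -> select -> permute -> stratify -> ebm-fit ->
#' ebm-stage -> report on a cohort table (read from CSV or simulated).
#' Clinical cognitive status is taken from the input labels (`AD` =
#' symptomatic); biomarker positivity is re-derived from a Gaussian
#' mixture on the tTau:Abeta42 ratio, so `Control` / `AsymAD` labels are
#' re-assigned by the gate. Each stage runs under a seed derived from the
#' master seed; the report records seeds, a configuration hash and all
#' headline quantities. Reruns with the same configuration produce an
#' identical report hash.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{input}{Path to a cohort CSV (alternative to `simulate`).}
#'     \item{simulate}{A [cohort_config()] (or argument list for one).}
#'     \item{seed}{Master seed (default 1).}
#'     \item{selection}{Argument list for [selection_config()].}
#'     \item{stratify}{Argument list for [embedding_config()].}
#'     \item{ebm}{Argument list for [ebm_config()] (default fast
#'       profile).}
#'     \item{n_permutation_draws}{Permutation-null draws (default 200 for
#'       pipeline runs; the standalone test defaults to 1e5).}
#'     \item{out_dir}{Optional directory for CSV/JSON artifacts.}
#'   }
#' @return Object of class `pipeline_report` (a nested list; see
#'   `$report` for the serialisable summary and `$report_hash`).
#' @export
run_pipeline <- function(config) {
  seed <- as.integer(config$seed %||% 1L)
  stage_seeds <- derive_seeds(seed, 6L)

  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$input)) {
      tab <- read_cohort(config$input)
    } else {
      sim <- config$simulate %||% list()
      if (!inherits(sim, "cohort_config")) {
        sim$seed <- sim$seed %||% stage_seeds[1]
        sim <- do.call(cohort_config, sim)
      }
      tab <- generate_cohort(sim)$table
    }

    stage <- "gate"
    ratio <- tab$ttau / tab$abeta42
    # log-scale fit: per-group ratios are log-normal, so the two-Gaussian
    # model is only faithful on the log scale (cut-off is back-transformed)
    mix <- fit_ratio_mixture(ratio[is.finite(ratio)], use_log = TRUE)
    if (mix$degenerate) stop("degenerate ratio mixture; no cut-off")
    cognitive <- ifelse(tab$group_label == "AD", "symptomatic", "CN")
    gated <- assign_groups(tab, cognitive, ratio_cutoff = mix$cutoff,
                           mode = "ratio")

    stage <- "select"
    sel_args <- config$selection %||% list()
    sel_args$seed <- sel_args$seed %||% stage_seeds[2]
    sel_cfg <- do.call(selection_config, sel_args)
    panel_res <- select_panel(gated, sel_cfg)

    stage <- "permute"
    train <- gated[gated$subject_id %in% panel_res$train_ids, , drop = FALSE]
    heldout <- gated[gated$subject_id %in% panel_res$heldout_ids, , drop = FALSE]
    perm <- permutation_test(panel_res$final_panel, train, heldout,
                             n_draws = config$n_permutation_draws %||% 200L,
                             seed = stage_seeds[3])

    stage <- "stratify"
    str_args <- config$stratify %||% list()
    str_args$seed <- str_args$seed %||% stage_seeds[4]
    str_cfg <- do.call(embedding_config, str_args)
    strat <- stability_stratify(gated, panel_res$final_panel, str_cfg,
                                scaler = panel_res$scaler)
    apoe <- apoe_enrichment(
      strat$assignments$consensus_label,
      gated$apoe[match(strat$assignments$subject_id, gated$subject_id)])

    stage <- "ebm-fit"
    ebm_args <- config$ebm %||% list(profile = "fast")
    ebm_args$seed <- ebm_args$seed %||% stage_seeds[5]
    ebm_cfg <- do.call(ebm_config, ebm_args)
    # the realised panel size must be a multiple of the cluster size; keep
    # the strongest members (training-classifier weight) and adapt the
    # cluster count
    ebm_panel <- panel_res$final_panel
    if (length(ebm_panel) < ebm_cfg$n_clusters * ebm_cfg$cluster_size ||
        length(ebm_panel) %% ebm_cfg$cluster_size != 0) {
      n_cl <- max(1L, length(ebm_panel) %/% ebm_cfg$cluster_size)
      n_keep <- n_cl * ebm_cfg$cluster_size
      xs <- apply_scaler(panel_res$scaler,
                         panel_values(train))[, ebm_panel, drop = FALSE]
      w <- abs(fit_linear_classifier(xs, train$group_label == "AD",
                                     "logistic")$weights)
      ebm_panel <- ebm_panel[ebm_panel %in%
                               ebm_panel[order(-w)][seq_len(n_keep)]]
      ebm_args$n_clusters <- n_cl
      ebm_cfg <- do.call(ebm_config, ebm_args)
      message(sprintf("EBM panel trimmed to %d peptides (%d clusters of %d)",
                      n_keep, n_cl, ebm_cfg$cluster_size))
    } else if (length(ebm_panel) > ebm_cfg$n_clusters * ebm_cfg$cluster_size) {
      ebm_args$n_clusters <- length(ebm_panel) %/% ebm_cfg$cluster_size
      ebm_cfg <- do.call(ebm_config, ebm_args)
    }
    fit <- fit_ebm(gated, ebm_panel, ebm_cfg)

    stage <- "ebm-stage"
    keep <- gated$group_label %in% c("Control", "AsymAD", "AD")
    staged_tab <- gated[keep, , drop = FALSE]
    post <- stage_subjects(fit, staged_tab)
    fine <- staged_tab$group_label
    sub <- strat$assignments$consensus_label[
      match(staged_tab$subject_id, strat$assignments$subject_id)]
    fine[!is.na(sub)] <- paste0("AsymAD_", sub[!is.na(sub)])
    stage_test <- stage_distribution_test(post$ml_stage, fine)
    stage_fractions <- prop.table(table(fine, post$ml_stage), margin = 1)

    stage <- "report"
    report <- list(
      seed = seed, stage_seeds = stage_seeds,
      n_subjects = nrow(tab),
      gate = list(cutoff = mix$cutoff,
                  component_means = mix$component_means,
                  group_counts = as.list(table(gated$group_label))),
      panel = list(final_panel = panel_res$final_panel,
                   heldout = panel_res$heldout_metrics[
                     c("sensitivity", "specificity", "roc_auc", "n")]),
      permutation = list(n_draws = perm$n_draws,
                         p_values = as.list(perm$p_values)),
      stratification = list(
        counts = as.list(table(strat$assignments$consensus_label)),
        apoe_p = apoe$p_value),
      ebm = list(modal_order = fit$modal_state$cluster_order,
                 acceptance_rate = fit$acceptance_rate,
                 stage_test = stage_test[c("statistic", "p_value")],
                 stage_fractions = apply(stage_fractions, 1, as.list)),
      config_hash = rlang::hash(list(config = config, seed = seed))
    )
    report_hash <- rlang::hash(report)

    out <- structure(list(
      table = gated, mixture = mix, panel = panel_res,
      permutation = perm, stratification = strat, apoe = apoe,
      ebm_fit = fit, stages = post, stage_test = stage_test,
      stage_fractions = stage_fractions,
      report = report, report_hash = report_hash
    ), class = "pipeline_report")

    if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

write_pipeline_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(x$table, file.path(out_dir, "labels.csv"))
  jsonlite::write_json(
    list(final_panel = x$panel$final_panel,
         svm_set = x$panel$svm_set$selected,
         logistic_set = x$panel$logistic_set$selected,
         scaler = list(center = as.list(x$panel$scaler$center),
                       scale = as.list(x$panel$scaler$scale)),
         heldout_metrics = x$panel$heldout_metrics),
    file.path(out_dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  write.csv(x$permutation$null, file.path(out_dir, "permutation_null.csv"),
            row.names = FALSE)
  write.csv(x$stratification$assignments, file.path(out_dir, "strat.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(x$ebm_fit$positional_variance),
            file.path(out_dir, "positional_variance.csv"))
  stages <- data.frame(subject_id = x$table$subject_id[
    x$table$group_label %in% c("Control", "AsymAD", "AD")],
    ml_stage = x$stages$ml_stage)
  write.csv(stages, file.path(out_dir, "stages.csv"), row.names = FALSE)
  jsonlite::write_json(x$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  gate cutoff %.3f; groups: %s\n", x$mixture$cutoff,
              paste(sprintf("%s=%d", names(table(x$table$group_label)),
                            table(x$table$group_label)), collapse = " ")))
  cat(sprintf("  panel: %d peptides, held-out AUC %.3f\n",
              length(x$panel$final_panel), x$panel$heldout_metrics$roc_auc))
  cat(sprintf("  stratification: %s; APOE p=%.2g\n",
              paste(sprintf("%s=%d",
                            names(table(x$stratification$assignments$consensus_label)),
                            table(x$stratification$assignments$consensus_label)),
                    collapse = " "), x$apoe$p_value))
  cat(sprintf("  EBM stage test: X2=%.1f p=%.3g\n",
              x$stage_test$statistic, x$stage_test$p_value))
  cat(sprintf("  report hash: %s\n", x$report_hash))
  invisible(x)
}
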