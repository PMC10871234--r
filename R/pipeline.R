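#' Run the full fragility pipeline
#'
#' Orchestrates every stage on one cohort: simulate (or ingest), FgI
#' scoring, PLL/95PLL labelling, lifespan summaries and group tests,
#' life-expectancy correlations, PLL trajectories with inflection
#' estimation, the TxW criterion and its PPV/NPV validation, the TxW and
#' TxW+FgI mixed models, the stacked ML ensemble with threshold metrics and
#' attributions, and the frailty-threshold healthspan comparison. All stage
#' outputs are written as CSV/JSON under `out_dir` together with a run
#' manifest (config hash, seed, row counts after each exclusion, file
#' hashes). Identical config and seed reproduce all outputs byte-for-byte.
#'
#' @param config A [cohort_config()] describing the synthetic cohort.
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-loaded cohort (as from [read_cohort()] or
#'   [simulate_cohort()]); when given, `config` supplies only the catalog.
#' @param seed Master seed for splitting/training stages (defaults to the
#'   config seed).
#' @param learners,recipes,grid_size,racing Ensemble training controls; the
#'   defaults are desk-scale (small sampled grids, no SVM) — enlarge for a
#'   production run.
#' @param healthspan_threshold Severe-deficit count ending healthspan.
#' @return The run manifest (list), invisibly; the heavyweight fitted
#'   objects are in its `objects` element.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         cohort = NULL, seed = config$seed,
                         learners = c("rlr", "rf", "xgb"),
                         recipes = recipe_ids(), grid_size = 5,
                         racing = TRUE, healthspan_threshold = 4,
                         explain_max_rows = 200) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_stage <- function(...) message(sprintf(...))
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  catalog <- config$catalog
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, na = "")
    files[[name]] <<- path
    df
  }

  # --- cohort ---------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- wrap("simulate", simulate_cohort(config))
    log_stage("simulate: %d mice, %d assessments", nrow(cohort$mice),
              nrow(cohort$assessments))
  }
  mice <- cohort$mice
  assessments <- cohort$assessments
  write_cohort(cohort, out_dir)
  files[["mice.csv"]] <- file.path(out_dir, "mice.csv")
  files[["assessments.csv"]] <- file.path(out_dir, "assessments.csv")

  # --- scoring and labels ---------------------------------------------
  fgi <- wrap("score", fgi_score(assessments, catalog))
  emit(fgi, "fgi_scores.csv")
  labels <- wrap("label", label_assessments(assessments, mice))
  emit(labels, "labels.csv")
  log_stage("score/label: %d assessments, %d at >95%% PLL",
            nrow(labels), sum(labels$is_95pll))

  # --- lifespan statistics --------------------------------------------
  lifespan <- wrap("lifespan", {
    do_mice <- dplyr::filter(mice, .data$strain == "DO")
    summaries <- dplyr::bind_rows(
      dplyr::mutate(summarize_lifespan(mice, "strain"), group = .data$strain),
      if (nrow(do_mice) > 0)
        dplyr::mutate(summarize_lifespan(do_mice, "diet"),
                      group = paste0("DO/", .data$diet))
    )
    emit(dplyr::select(summaries, "group", "n", "median", "q1", "q3", "p90"),
         "lifespan_summary.csv")
    list(
      summaries = summaries,
      quantile_p90 = if (nrow(do_mice) > 1)
        quantile_test(do_mice$lifespan_days, do_mice$diet, q = 0.9),
      variance = if (dplyr::n_distinct(mice$strain) > 1)
        median_deviation_variance_test(mice$lifespan_days, mice$strain)
    )
  })

  corr <- wrap("correlations",
               deficit_le_correlations(assessments, mice, catalog, fgi))
  emit(corr, "correlations.csv")

  traj <- wrap("trajectory", {
    d <- dplyr::inner_join(fgi, labels[c("mouse_id", "date", "pll")],
                           by = c("mouse_id", "date"))
    curve <- pll_trajectory(d, "fgi_score", "pll")
    emit(tibble::as_tibble(curve), "trajectories.csv")
    list(curve = curve, inflection = estimate_inflection(curve))
  })
  log_stage("trajectory: inflection at PLL %.3f",
            traj$inflection$pll_at_inflection)

  # --- TxW -------------------------------------------------------------
  statuses <- wrap("txw", evaluate_txw(assessments))
  emit(statuses, "txw_status.csv")
  txw_val <- wrap("txw", validate_txw(statuses, labels, mice,
                                      group_by = c("strain", "diet")))
  emit(txw_val, "txw_validation.csv")
  log_stage("txw: %d/%d rows with sufficient history",
            sum(statuses$flag != "insufficient"), nrow(statuses))

  # --- grouped split shared by GLMMs and ensemble ---------------------
  split <- split_grouped(mice, stratify = "diet", seed = seed)
  test_ids <- split$test_ids

  # --- mixed models per strain ----------------------------------------
  glmm <- wrap("glmm", {
    rows <- glmm_training_rows(assessments, mice, catalog) |>
      dplyr::inner_join(mice[c("mouse_id", "strain")], by = "mouse_id")
    per_strain <- lapply(split(rows, rows$strain), function(d) {
      tr <- dplyr::filter(d, !.data$mouse_id %in% test_ids)
      te <- dplyr::filter(d, .data$mouse_id %in% test_ids)
      te <- dplyr::inner_join(te, labels[c("mouse_id", "date", "is_95pll")],
                              by = c("mouse_id", "date"),
                              suffix = c("", ".lab"))
      fit_txw <- fit_95pll_glmm(tr, include_fgi = FALSE)
      fit_both <- fit_95pll_glmm(tr, include_fgi = TRUE)
      list(
        fit_txw = fit_txw, fit_both = fit_both,
        auc_txw = roc_auc(predict_fixed(fit_txw, te), te$is_95pll)$auc,
        auc_both = roc_auc(predict_fixed(fit_both, te), te$is_95pll)$auc,
        n_train = nrow(tr), n_test = nrow(te)
      )
    })
    per_strain
  })
  glmm_report <- purrr::imap(glmm, function(g, strain) {
    list(strain = strain,
         txw = c(as.list(g$fit_txw$coef),
                 random_intercept_sd = g$fit_txw$random_intercept_sd,
                 converged = g$fit_txw$converged, auc = g$auc_txw),
         txw_fgi = c(as.list(g$fit_both$coef),
                     random_intercept_sd = g$fit_both$random_intercept_sd,
                     converged = g$fit_both$converged, auc = g$auc_both))
  })
  jsonlite::write_json(glmm_report, file.path(out_dir, "glmm_fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files[["glmm_fit.json"]] <- file.path(out_dir, "glmm_fit.json")

  # --- ensemble --------------------------------------------------------
  ens <- wrap("ensemble", train_95pll_ensemble(
    assessments, mice, catalog, split = split, learners = learners,
    recipes = recipes, grid_size = grid_size, racing = racing, seed = seed
  ))
  preds <- predict(ens, assessments, mice) |>
    dplyr::inner_join(labels[c("mouse_id", "date", "is_95pll")],
                      by = c("mouse_id", "date"))
  test_preds <- dplyr::filter(preds, .data$mouse_id %in% test_ids)
  report <- wrap("ensemble",
                 evaluate_classifier(test_preds$prob, test_preds$is_95pll))
  emit(dplyr::mutate(report$metrics, auc_roc = report$auc_roc,
                     auc_pr = report$auc_pr), "metrics.csv")
  rocs <- roc_auc(test_preds$prob, test_preds$is_95pll)
  emit(rocs$curve, "roc_points.csv")
  shap <- wrap("ensemble", explain_top_member(
    ens, dplyr::filter(assessments, .data$mouse_id %in% test_ids),
    mice, max_rows = explain_max_rows, seed = seed))
  emit(dplyr::bind_cols(shap$keys, tibble::as_tibble(shap$attributions)),
       "attributions.csv")
  log_stage("ensemble: test ROC-AUC %.3f (PR-AUC %.3f)",
            report$auc_roc, report$auc_pr)

  # --- healthspan ------------------------------------------------------
  hs <- wrap("healthspan", {
    fgi_age <- dplyr::inner_join(
      fgi, assessments[c("mouse_id", "date", "age_days")],
      by = c("mouse_id", "date"))
    rec <- compute_healthspan(fgi_age, mice,
                              threshold = healthspan_threshold) |>
      dplyr::inner_join(mice[c("mouse_id", "strain", "sex", "diet")],
                        by = "mouse_id")
    emit(rec, "healthspan.csv")
    emit(km_curve(rec, group = "strain"), "km_points.csv")
    do_rec <- dplyr::filter(rec, .data$strain == "DO")
    list(records = rec,
         logrank_diet = if (dplyr::n_distinct(do_rec$diet) > 1)
           logrank_test(do_rec, "diet"),
         summary = healthspan_summary(rec, "strain"))
  })

  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "seed")]),
    seed = seed,
    package_version = as.character(utils::packageVersion("fragility")),
    n_mice = nrow(mice), n_assessments = nrow(assessments),
    files = vapply(files, function(f) unname(tools::md5sum(f)),
                   character(1)),
    objects = list(lifespan = lifespan, glmm = glmm, ensemble = ens,
                   healthspan = hs, trajectory = traj,
                   classifier_report = report, split = split)
  )
  jsonlite::write_json(
    manifest[c("config_hash", "seed", "package_version", "n_mice",
               "n_assessments", "files")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
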