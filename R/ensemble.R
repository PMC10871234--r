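#' Tune candidate 95PLL classifiers by grouped cross-validation
#'
#' For each learner-by-recipe combination, samples up to `grid_size`
#' hyperparameter configurations and evaluates them by v-fold grouped
#' cross-validation on ROC-AUC, with all rows of a mouse kept in one fold.
#' Preprocessing (zero-variance filter, PCA, standardization) is learned
#' inside each fold's training part; event rows are up-sampled inside each
#' fold's training part only. With `racing = TRUE`, configurations whose
#' running mean AUC after at least `racing_min_folds` folds trails the
#' current best by more than `racing_margin` are eliminated early; the
#' winner per combination always completes all folds, so its out-of-fold
#' predictions cover every training row exactly once.
#'
#' @param features An [build_features()] result.
#' @param labels Tibble with `mouse_id`, `date`, `is_95pll`.
#' @param split A [split_grouped()] plan; only training mice are used.
#' @param learners Subset of `c("rlr", "rf", "svm", "xgb")`.
#' @param recipes Subset of `c("M0", "M1", "M2", "M3")`.
#' @param grid_size Maximum hyperparameter configurations per combination.
#' @param racing Enable early elimination (full CV when FALSE).
#' @param racing_margin AUC margin for elimination.
#' @param racing_min_folds Folds required before any elimination.
#' @param n_pc Principal components retained per item block.
#' @param seed Master seed; expands deterministically into grid-sampling,
#'   up-sampling and learner seeds.
#' @return List of candidate objects (one per learner-recipe pair), each
#'   with `learner`, `recipe`, `params`, `cv_auc`, and out-of-fold
#'   predictions `oof` (tibble `row`, `pred`) indexed into the training
#'   rows.
#' @export
tune_candidates <- function(features, labels, split,
                            learners = learner_ids(),
                            recipes = recipe_ids(),
                            grid_size = 25, racing = TRUE,
                            racing_margin = 0.05, racing_min_folds = 3,
                            n_pc = 5, seed = 1L) {
  stopifnot(inherits(features, "fgi_features"), inherits(split, "split_plan"))
  stopifnot(all(learners %in% learner_ids()), all(recipes %in% recipe_ids()))
  tr <- training_rows(features, labels, split)
  v <- split$v

  # per-(recipe, fold) design matrices, shared across learners/configs
  designs <- list()
  for (rec in recipes) {
    designs[[rec]] <- lapply(seq_len(v), function(f) {
      idx_tr <- tr$idx[tr$fold != f]
      idx_va <- tr$idx[tr$fold == f]
      prep <- learn_prep(features, idx_tr, recipe = rec, n_pc = n_pc)
      x_tr <- apply_prep(prep, features, idx_tr)
      y_tr <- tr$y[tr$fold != f]
      up <- upsample_idx(y_tr, derive_seed(seed, sprintf("up-%s-%d", rec, f)))
      list(x_tr = x_tr[up, , drop = FALSE], y_tr = y_tr[up],
           x_va = apply_prep(prep, features, idx_va),
           y_va = tr$y[tr$fold == f],
           va_rows = which(tr$fold == f))
    })
  }

  out <- list()
  for (learner in learners) {
    for (rec in recipes) {
      grid <- learner_grid(learner, grid_size,
                           derive_seed(seed, paste0(learner, rec)))
      cand <- race_configs(grid, designs[[rec]], learner,
                           racing = racing, margin = racing_margin,
                           min_folds = racing_min_folds,
                           seed = derive_seed(seed,
                                              paste0("cv-", learner, rec)))
      cand$learner <- learner
      cand$recipe <- rec
      out[[paste(learner, rec, sep = "_")]] <- cand
    }
  }
  structure(out, n_train_rows = nrow(tr), class = "fgi_candidates")
}

# align feature rows of training mice with labels and fold assignments
training_rows <- function(features, labels, split) {
  check_columns(labels, c("mouse_id", "date", "is_95pll"), "labels")
  rows <- features$rows |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::inner_join(labels[c("mouse_id", "date", "is_95pll")],
                      by = c("mouse_id", "date")) |>
    dplyr::inner_join(split$folds, by = "mouse_id")
  if (length(unique(rows$is_95pll)) < 2) {
    abort("training outcome has a single class")
  }
  tibble::tibble(idx = rows$idx, y = rows$is_95pll, fold = rows$fold,
                 mouse_id = rows$mouse_id)
}

upsample_idx <- function(y, seed) {
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes must be present in a fold")
  if (n1 == n0) return(seq_along(y))
  minority <- which(y == (n1 < n0))
  withr::with_seed(seed, {
    c(seq_along(y), sample(minority, abs(n0 - n1), replace = TRUE))
  })
}

race_configs <- function(grid, folds, learner, racing, margin, min_folds,
                         seed) {
  n_cfg <- nrow(grid)
  active <- rep(TRUE, n_cfg)
  auc <- matrix(NA_real_, n_cfg, length(folds))
  oof <- vector("list", n_cfg)
  for (i in seq_len(n_cfg)) oof[[i]] <- list()

  for (f in seq_along(folds)) {
    d <- folds[[f]]
    one_class_va <- length(unique(d$y_va)) < 2
    if (one_class_va) {
      warn(sprintf("validation fold %d has one class; skipped for AUC", f))
    }
    for (i in which(active)) {
      fit <- fit_learner(learner, d$x_tr, d$y_tr, grid[i, ],
                         seed = derive_seed(seed, sprintf("f%d-c%d", f, i)))
      pred <- predict_learner(fit, d$x_va)
      oof[[i]][[f]] <- tibble::tibble(row = d$va_rows, pred = pred)
      if (!one_class_va) auc[i, f] <- roc_auc(pred, d$y_va)$auc
    }
    if (racing && f >= min_folds && sum(active) > 1) {
      means <- rowMeans(auc[, seq_len(f), drop = FALSE], na.rm = TRUE)
      means[!active] <- -Inf
      active <- active & (max(means, na.rm = TRUE) - means <= margin)
    }
  }
  means <- rowMeans(auc, na.rm = TRUE)
  means[!active] <- -Inf
  best <- which.max(means)
  list(params = grid[best, ], cv_auc = means[best],
       oof = dplyr::arrange(dplyr::bind_rows(oof[[best]]), .data$row),
       n_configs = n_cfg, n_survivors = sum(active))
}

#' Stack candidates into a single ensemble
#'
#' Pools each candidate's out-of-fold predictions into one table and fits an
#' L1-regularized logistic meta-model with non-negative coefficients
#' (penalty chosen by cross-validation on the pooled table, grouped by the
#' same folds). Candidates receiving non-zero weight are retained; the
#' ensemble probability is the meta-model applied to member probabilities.
#'
#' @param candidates A [tune_candidates()] result.
#' @param y Logical outcome for training rows (in feature-row order).
#' @param foldid Optional integer fold id per training row for the penalty
#'   cross-validation.
#' @param seed Integer seed.
#' @return An `ensemble_stack`: `weights` (named, > 0), `intercept`,
#'   `members` (names into `candidates`), `lambda`.
#' @export
stack_candidates <- function(candidates, y, foldid = NULL, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  oof_mat <- vapply(candidates, function(cand) {
    stopifnot(nrow(cand$oof) == length(y))
    cand$oof$pred
  }, numeric(length(y)))
  colnames(oof_mat) <- names(candidates)
  withr::with_seed(derive_seed(seed, "stack"), {
    cvfit <- if (ncol(oof_mat) == 1) {
      # glmnet needs >= 2 columns; duplicate and average the weights
      m2 <- cbind(oof_mat, oof_mat)
      colnames(m2) <- c(names(candidates), ".dup")
      glmnet::cv.glmnet(m2, factor(y), family = "binomial", alpha = 1,
                        lower.limits = 0, foldid = foldid)
    } else {
      glmnet::cv.glmnet(oof_mat, factor(y), family = "binomial", alpha = 1,
                        lower.limits = 0, foldid = foldid)
    }
  })
  cf <- as.numeric(coef(cvfit, s = "lambda.min"))
  names(cf) <- rownames(coef(cvfit, s = "lambda.min"))
  w <- cf[-1]
  if (ncol(oof_mat) == 1) {
    w <- setNames(sum(w), names(candidates))
  }
  w <- w[w > 0]
  if (length(w) == 0) {
    abort(paste("all stacking coefficients are zero;",
                "refit with a smaller penalty or stronger candidates"))
  }
  structure(list(weights = w, intercept = cf[1], members = names(w),
                 lambda = cvfit$lambda.min),
            class = "ensemble_stack")
}

predict_meta <- function(stack, member_probs) {
  m <- as.matrix(member_probs[, stack$members, drop = FALSE])
  plogis(stack$intercept + as.numeric(m %*% stack$weights))
}

#' Train the stacked 95PLL ensemble end-to-end
#'
#' Builds features, splits mice into held-out test and grouped CV folds,
#' tunes candidates, stacks them, and refits the retained members on all
#' training rows. The returned model carries everything needed to score new
#' assessments; test-mouse rows are never touched during training.
#'
#' @inheritParams tune_candidates
#' @param assessments,mice Cohort tables.
#' @param catalog Deficit catalog.
#' @param split Optional pre-computed [split_grouped()] plan.
#' @param test_fraction,stratify,v Split parameters when `split` is NULL.
#' @param seed Master seed governing split, grids, up-sampling and learner
#'   fits.
#' @return A `pll_ensemble` object.
#' @export
train_95pll_ensemble <- function(assessments, mice,
                                 catalog = deficit_catalog(),
                                 split = NULL,
                                 learners = learner_ids(),
                                 recipes = recipe_ids(),
                                 grid_size = 25, v = 5,
                                 test_fraction = 0.25, stratify = "diet",
                                 racing = TRUE, racing_margin = 0.05,
                                 racing_min_folds = 3, n_pc = 5,
                                 seed = 1L) {
  labels <- label_assessments(assessments, mice)
  features <- build_features(assessments, mice, catalog)
  mice_used <- mice[mice$mouse_id %in% unique(features$rows$mouse_id), ]
  if (is.null(split)) {
    split <- split_grouped(mice_used, test_fraction = test_fraction,
                           stratify = stratify, v = v, seed = seed)
  }
  candidates <- tune_candidates(features, labels, split,
                                learners = learners, recipes = recipes,
                                grid_size = grid_size, racing = racing,
                                racing_margin = racing_margin,
                                racing_min_folds = racing_min_folds,
                                n_pc = n_pc, seed = seed)
  tr <- training_rows(features, labels, split)
  stack <- stack_candidates(candidates, tr$y, foldid = tr$fold, seed = seed)

  # refit retained members on the full training data
  member_fits <- lapply(stack$members, function(nm) {
    cand <- candidates[[nm]]
    prep <- learn_prep(features, tr$idx, recipe = cand$recipe, n_pc = n_pc)
    x <- apply_prep(prep, features, tr$idx)
    up <- upsample_idx(tr$y, derive_seed(seed, paste0("up-final-", nm)))
    fit <- fit_learner(cand$learner, x[up, , drop = FALSE], tr$y[up],
                       cand$params,
                       seed = derive_seed(seed, paste0("final-", nm)))
    list(name = nm, learner = cand$learner, recipe = cand$recipe,
         params = cand$params, cv_auc = cand$cv_auc, prep = prep, fit = fit)
  })
  names(member_fits) <- stack$members

  structure(
    list(stack = stack, members = member_fits, split = split,
         catalog = catalog, n_pc = n_pc, seed = as.integer(seed),
         candidate_summary = tibble::tibble(
           member = names(candidates),
           learner = purrr::map_chr(candidates, "learner"),
           recipe = purrr::map_chr(candidates, "recipe"),
           cv_auc = purrr::map_dbl(candidates, "cv_auc"),
           weight = unname(stack$weights[names(candidates)])
         ) |> dplyr::mutate(weight = ifelse(is.na(.data$weight), 0,
                                            .data$weight))),
    class = "pll_ensemble"
  )
}

#' Predict 95PLL probabilities from a fitted ensemble
#'
#' @param object A `pll_ensemble`.
#' @param assessments,mice New (or original) cohort tables; features are
#'   rebuilt with the training-time catalog and the training-time preps are
#'   applied.
#' @param ... Unused.
#' @return Tibble with `mouse_id`, `date`, per-member probabilities, and the
#'   stacked `prob`.
#' @export
predict.pll_ensemble <- function(object, assessments, mice, ...) {
  features <- build_features(assessments, mice, object$catalog)
  member_probs <- purrr::map(object$members, function(m) {
    predict_learner(m$fit, apply_prep(m$prep, features))
  })
  mp <- tibble::as_tibble(member_probs)
  tibble::tibble(
    mouse_id = features$rows$mouse_id,
    date = features$rows$date
  ) |>
    dplyr::bind_cols(mp) |>
    dplyr::mutate(prob = predict_meta(object$stack, mp))
}

#' @export
print.pll_ensemble <- function(x, ...) {
  cat(sprintf("<pll_ensemble> %d retained member(s) of %d candidates\n",
              length(x$members), nrow(x$candidate_summary)))
  print(dplyr::arrange(x$candidate_summary, dplyr::desc(.data$weight)))
  invisible(x)
}

#' Threshold-sweep classification report
#'
#' Accuracy, PPV and NPV at each probability threshold (default 0.5 to 0.9
#' by 0.1) plus threshold-free ROC-AUC and PR-AUC.
#'
#' @param probabilities Predicted event probabilities.
#' @param labels Logical event indicator.
#' @param thresholds Probability cutoffs to sweep.
#' @return A `classifier_report`: list with `metrics` tibble (`threshold`,
#'   `accuracy`, `ppv`, `npv`), `auc_roc`, `auc_pr`, `n`, `prevalence`.
#' @export
evaluate_classifier <- function(probabilities, labels,
                                thresholds = seq(0.5, 0.9, by = 0.1)) {
  y <- as.logical(labels)
  ok <- !is.na(probabilities) & !is.na(y)
  p <- probabilities[ok]; y <- y[ok]
  if (length(unique(y)) < 2) abort("both classes must be present")
  metrics <- purrr::map_dfr(thresholds, function(t) {
    pos <- p >= t
    tibble::tibble(
      threshold = t,
      accuracy = mean(pos == y),
      ppv = if (sum(pos) > 0) mean(y[pos]) else NA_real_,
      npv = if (sum(!pos) > 0) mean(!y[!pos]) else NA_real_
    )
  })
  structure(list(metrics = metrics, auc_roc = roc_auc(p, y)$auc,
                 auc_pr = pr_auc(p, y), n = length(y),
                 prevalence = mean(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> n = %d, prevalence = %.3f\n",
              x$n, x$prevalence))
  cat(sprintf("ROC-AUC = %.3f, PR-AUC = %.3f\n", x$auc_roc, x$auc_pr))
  print(x$metrics)
  invisible(x)
}
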