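#' Shapley attributions for the top-weighted ensemble member
#'
#' Computes per-feature Shapley additive attributions for the member carrying
#' the largest stacking weight. For XGBoost members the exact tree algorithm
#' is used (attributions on the log-odds scale, additive to the margin
#' prediction minus the bias term). For other learners a permutation
#' estimator is used: marginal contributions averaged over random feature
#' orderings against a background sample, which is additive by construction
#' (per row, attributions sum exactly to the prediction minus the mean
#' background prediction) but averages over only `n_perm` orderings.
#'
#' @param model A fitted [train_95pll_ensemble()] ensemble.
#' @param assessments,mice Rows to explain (typically held-out test mice).
#' @param max_rows Cap on explained rows (head of the table).
#' @param n_perm Permutations for the sampling estimator.
#' @param background_n Background rows for the sampling estimator.
#' @param seed Integer seed for the sampling estimator.
#' @return List of class `shap_result`: `member` (name), `method`
#'   (`"tree"` or `"permutation"`), `keys` (mouse_id, date), `baseline`,
#'   `prediction` (per row, on the attribution scale), and `attributions`
#'   (matrix rows x features).
#' @export
explain_top_member <- function(model, assessments, mice, max_rows = 500,
                               n_perm = 6, background_n = 30, seed = 1L) {
  stopifnot(inherits(model, "pll_ensemble"))
  top <- model$members[[which.max(model$stack$weights[names(model$members)])]]
  features <- build_features(assessments, mice, model$catalog)
  x <- apply_prep(top$prep, features)
  take <- seq_len(min(nrow(x), max_rows))
  keys <- features$rows[take, c("mouse_id", "date")]
  x <- x[take, , drop = FALSE]

  if (top$learner == "xgb") {
    contrib <- predict(top$fit$fit, x, predcontrib = TRUE)
    # last column is the bias term (named BIAS when names survive)
    bias <- contrib[, ncol(contrib)]
    attr_mat <- contrib[, -ncol(contrib), drop = FALSE]
    colnames(attr_mat) <- colnames(x)
    res <- list(member = top$name, method = "tree", keys = keys,
                baseline = unname(bias[1]),
                prediction = unname(bias + rowSums(attr_mat)),
                attributions = attr_mat)
  } else {
    warn(sprintf(
      "no exact tree attribution for learner '%s'; using permutation sampling",
      top$learner))
    res <- withr::with_seed(derive_seed(seed, "shap"), {
      shap_permutation(function(m) predict_learner(top$fit, m), x,
                       n_perm = n_perm, background_n = background_n)
    })
    res$member <- top$name
    res$method <- "permutation"
    res$keys <- keys
  }
  structure(res, class = "shap_result")
}

# Permutation Shapley sampling. For each random feature ordering, features
# are switched one at a time from a background row's values to the explained
# row's values; the prediction increments are the marginal contributions.
# Per ordering and background row the increments telescope to
# f(x) - f(background), so the averaged attributions are exactly additive.
shap_permutation <- function(f, x, n_perm = 6, background_n = 30) {
  p <- ncol(x); n <- nrow(x)
  bg <- x[sample(nrow(x), min(background_n, nrow(x))), , drop = FALSE]
  b <- nrow(bg)
  attr_mat <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  baseline <- mean(f(bg))
  for (perm in seq_len(n_perm)) {
    ord <- sample(p)
    for (i in seq_len(n)) {
      # stack of b * (p + 1) rows: background, then cumulative replacement
      steps <- matrix(rep(t(bg), p + 1), ncol = p, byrow = TRUE)
      colnames(steps) <- colnames(x)
      for (k in seq_len(p)) {
        rows <- (k * b + 1):((p + 1) * b)
        steps[rows, ord[k]] <- x[i, ord[k]]
      }
      pr <- f(steps)
      step_means <- vapply(seq_len(p + 1), function(k) {
        mean(pr[((k - 1) * b + 1):(k * b)])
      }, numeric(1))
      attr_mat[i, ord] <- attr_mat[i, ord] + diff(step_means) / n_perm
    }
  }
  list(baseline = baseline, prediction = baseline + rowSums(attr_mat),
       attributions = attr_mat)
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("<shap_result> member %s (%s method), %d rows x %d features\n",
              x$member, x$method, nrow(x$attributions),
              ncol(x$attributions)))
  imp <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  print(round(head(imp, 10), 4))
  invisible(x)
}
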