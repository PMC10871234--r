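#' Grouped train/test split with stratification
#'
#' Allocates mice — never individual assessments — to a held-out test set
#' and assigns the remaining mice to v cross-validation folds, so all rows
#' of one animal share an assignment and within-animal correlation cannot
#' leak across resamples. The test allocation is stratified (default by
#' diet): each stratum contributes its own rounded share of test mice.
#' Strata with fewer than 4 mice fall back to a pooled global allocation
#' with a warning.
#'
#' @param mice Mouse table.
#' @param test_fraction Fraction of mouse IDs withheld for testing.
#' @param stratify Mouse-level column to stratify by (NULL for none).
#' @param v Number of CV folds for training mice.
#' @param seed Integer seed; identical inputs reproduce the plan exactly.
#' @return A `split_plan` list: `test_ids`, `folds` (tibble `mouse_id`,
#'   `fold`), `seed`.
#' @export
split_grouped <- function(mice, test_fraction = 0.25, stratify = "diet",
                          v = 5, seed = 1L) {
  check_columns(mice, c("mouse_id", stratify), "mice")
  if (nrow(mice) < 8) abort("need at least 8 mice to split")
  if (anyDuplicated(mice$mouse_id)) abort("duplicate mouse_id in mice")
  withr::with_seed(derive_seed(seed, "split"), {
    strata <- if (is.null(stratify)) {
      list(all = mice$mouse_id)
    } else {
      split(mice$mouse_id, mice[[stratify]])
    }
    small <- names(strata)[lengths(strata) < 4]
    if (length(small) > 0 && !is.null(stratify)) {
      warn(sprintf(
        "stratum/strata with <4 mice (%s); using pooled allocation for them",
        paste(small, collapse = ", ")))
      pooled <- unlist(strata[small], use.names = FALSE)
      strata <- strata[!names(strata) %in% small]
      if (length(pooled) > 0) strata$`.pooled` <- pooled
    }
    test_ids <- unlist(lapply(strata, function(ids) {
      n_test <- round(length(ids) * test_fraction)
      sample(ids, n_test)
    }), use.names = FALSE)
    train_ids <- sample(setdiff(mice$mouse_id, test_ids))
    folds <- tibble::tibble(
      mouse_id = train_ids,
      fold = rep_len(seq_len(v), length(train_ids))
    )
    structure(list(test_ids = sort(test_ids), folds = folds,
                   v = v, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d test mice, %d training mice in %d folds\n",
              length(x$test_ids), nrow(x$folds), x$v))
  invisible(x)
}

#' Up-sample the minority class
#'
#' Resamples minority-class rows with replacement until the classes are
#' equally frequent. Must be applied to training resamples only — never to
#' validation or test rows — so evaluation class frequencies stay those of
#' the data.
#'
#' @param rows Data frame.
#' @param outcome Name of the logical outcome column.
#' @param seed Integer seed.
#' @return Tibble with equal class counts (original rows plus resampled
#'   minority rows).
#' @export
upsample_events <- function(rows, outcome = "is_95pll", seed = 1L) {
  check_columns(rows, outcome, "rows")
  y <- as.logical(rows[[outcome]])
  if (length(unique(y)) < 2) abort("both classes must be present")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == n0) return(tibble::as_tibble(rows))
  minority <- which(y == (n1 < n0))
  n_extra <- abs(n0 - n1)
  withr::with_seed(derive_seed(seed, "upsample"), {
    extra <- sample(minority, n_extra, replace = TRUE)
  })
  tibble::as_tibble(rows[c(seq_len(nrow(rows)), extra), ])
}
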