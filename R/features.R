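#' Build feature tables for the 95PLL classifier
#'
#' Derives the model-ready predictor set from raw assessments under four
#' nested recipes:
#' \describe{
#'   \item{M0}{age at assay (days) and diet (one-hot), plus sex/strain
#'     indicators when the cohort mixes them.}
#'   \item{M1}{M0 + current body weight and temperature, raw and as 30-day
#'     rolling percent change (current value vs. the earliest observation in
#'     the preceding 30 days, rolled over the date index so windows stay
#'     equidistant under missed visits).}
#'   \item{M2}{M1 + the 30 ordinal deficit items rescaled to integer scores —
#'     \{0, 0.5, 1\} to \{1, 2, 3\} and \{0, 1\} to \{1, 3\} — so absent and
#'     severe sit an equal numeric distance apart for two- and three-level
#'     items; at training time these are zero-variance-filtered and reduced
#'     to 5 principal components.}
#'   \item{M3}{M2 + 30-day deficit deltas (current integer score minus the
#'     earliest in the preceding 30 days), reduced to a further 5
#'     components.}
#' }
#' All columns are built here; which are used, and the learned
#' transformations (zero-variance filter, PCA rotations, standardization),
#' are decided by [learn_prep()] on training rows only.
#'
#' Mice observed for fewer than `min_follow_days` days are excluded, as are
#' rows with no observation in the look-back window (delta features
#' undefined) and rows with any missing required input.
#'
#' @param assessments,mice Cohort tables.
#' @param catalog Deficit catalog.
#' @param delta_days Look-back window for rolling deltas (days).
#' @param min_follow_days Minimum per-mouse observation span.
#' @return An `fgi_features` list: `rows` (keys `mouse_id`, `date` plus all
#'   raw feature columns, complete cases only), `base_cols`, `quant_cols`,
#'   `item_cols`, `delta_cols`, `n_excluded` bookkeeping.
#' @export
build_features <- function(assessments, mice, catalog = deficit_catalog(),
                           delta_days = 30, min_follow_days = 30) {
  check_catalog(catalog)
  check_columns(assessments, c("mouse_id", "date", "age_days", "weight_g",
                               "temp_C", catalog$column), "assessments")
  check_columns(mice, c("mouse_id", "strain", "sex", "diet"), "mice")

  span <- assessments |>
    dplyr::summarise(span = as.numeric(max(.data$date) - min(.data$date)),
                     .by = "mouse_id")
  short_ids <- span$mouse_id[span$span < min_follow_days]

  d <- assessments |>
    dplyr::filter(!.data$mouse_id %in% short_ids) |>
    dplyr::inner_join(mice[c("mouse_id", "strain", "sex", "diet")],
                      by = "mouse_id") |>
    dplyr::arrange(.data$mouse_id, .data$date)

  # integer-rescaled items: {0,.5,1} -> {1,2,3}, {0,1} -> {1,3}
  int_cols <- paste0(catalog$column, "_int")
  for (j in seq_len(nrow(catalog))) {
    d[[int_cols[j]]] <- 1 + 2 * d[[catalog$column[j]]]
  }

  # per-mouse rolling deltas against the earliest observation in the
  # preceding `delta_days` (window half-open: [t - delta_days, t))
  delta_of <- function(day, v) {
    vapply(seq_along(day), function(i) {
      w <- which(day >= day[i] - delta_days & day < day[i] & !is.na(v))
      if (length(w) == 0) NA_real_ else v[w[1]]
    }, numeric(1))
  }
  d <- d |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::group_modify(function(g, key) {
      day <- as.numeric(g$date)
      g$weight_prev <- delta_of(day, g$weight_g)
      g$temp_prev <- delta_of(day, g$temp_C)
      for (ic in int_cols) {
        g[[paste0(ic, "_d30")]] <- g[[ic]] - delta_of(day, g[[ic]])
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      weight_pct30 = 100 * (.data$weight_g - .data$weight_prev) /
        .data$weight_prev,
      temp_pct30 = 100 * (.data$temp_C - .data$temp_prev) / .data$temp_prev
    )

  # one-hot encodings (full dummy set; constant columns drop at prep time)
  base_cols <- "age_days"
  for (v in c("strain", "sex", "diet")) {
    for (lev in sort(unique(d[[v]]))) {
      col <- paste0(v, "_", lev)
      d[[col]] <- as.numeric(d[[v]] == lev)
      base_cols <- c(base_cols, col)
    }
  }

  quant_cols <- c("weight_g", "temp_C", "weight_pct30", "temp_pct30")
  delta_cols <- paste0(int_cols, "_d30")
  all_cols <- c(base_cols, quant_cols, int_cols, delta_cols)
  keep <- complete.cases(d[all_cols])
  rows <- d[keep, c("mouse_id", "date", all_cols)]

  structure(
    list(rows = tibble::as_tibble(rows),
         base_cols = base_cols, quant_cols = quant_cols,
         item_cols = int_cols, delta_cols = delta_cols,
         n_excluded = c(short_follow_mice = length(short_ids),
                        incomplete_rows = sum(!keep))),
    class = "fgi_features"
  )
}

recipe_ids <- function() c("M0", "M1", "M2", "M3")

#' Learn preprocessing on training rows
#'
#' Fits, on training rows only, the transformations a recipe needs:
#' zero-variance filtering of raw columns, 5-component PCA of the integer
#' item scores (M2/M3) and of the 30-day item deltas (M3), and
#' standardization of every resulting column to mean 0, SD 1. PCA component
#' signs are pinned by making each loading vector's largest-magnitude element
#' positive. Apply with [apply_prep()]; validation and test rows must be
#' transformed with a prep learned on training rows to avoid leakage.
#'
#' @param features An `fgi_features` object.
#' @param train_idx Integer/logical index of training rows in
#'   `features$rows`.
#' @param recipe One of "M0", "M1", "M2", "M3".
#' @param n_pc Components retained per PCA block.
#' @return A `prep` list.
#' @export
learn_prep <- function(features, train_idx, recipe = "M3", n_pc = 5) {
  stopifnot(inherits(features, "fgi_features"),
            recipe %in% recipe_ids())
  tr <- features$rows[train_idx, ]
  raw_cols <- switch(recipe,
    M0 = features$base_cols,
    M1 = c(features$base_cols, features$quant_cols),
    M2 = c(features$base_cols, features$quant_cols, features$item_cols),
    M3 = c(features$base_cols, features$quant_cols, features$item_cols,
           features$delta_cols)
  )
  nzv <- function(cols) {
    cols[vapply(cols, function(cl) var(tr[[cl]]) > 0, logical(1))]
  }
  pca_block <- function(cols) {
    cols <- nzv(cols)
    if (length(cols) == 0) return(NULL)
    k <- min(n_pc, length(cols))
    p <- prcomp(as.matrix(tr[cols]), center = TRUE, scale. = FALSE,
                rank. = k)
    # pin component signs: largest-|loading| element positive
    for (j in seq_len(ncol(p$rotation))) {
      i_max <- which.max(abs(p$rotation[, j]))
      if (p$rotation[i_max, j] < 0) {
        p$rotation[, j] <- -p$rotation[, j]
        p$x[, j] <- -p$x[, j]
      }
    }
    list(cols = cols, center = p$center, rotation = p$rotation)
  }

  plain_cols <- nzv(intersect(raw_cols,
                              c(features$base_cols, features$quant_cols)))
  item_pca <- if (recipe %in% c("M2", "M3")) pca_block(features$item_cols)
  delta_pca <- if (recipe == "M3") pca_block(features$delta_cols)

  # standardization constants from the transformed training matrix
  m <- assemble_matrix(tr, plain_cols, item_pca, delta_pca)
  structure(
    list(recipe = recipe, plain_cols = plain_cols,
         item_pca = item_pca, delta_pca = delta_pca,
         center = colMeans(m), scale = apply(m, 2, sd)),
    class = "fgi_prep"
  )
}

assemble_matrix <- function(rows, plain_cols, item_pca, delta_pca) {
  parts <- list(as.matrix(rows[plain_cols]))
  if (!is.null(item_pca)) {
    x <- sweep(as.matrix(rows[item_pca$cols]), 2, item_pca$center)
    pc <- x %*% item_pca$rotation
    colnames(pc) <- paste0("item_pc", seq_len(ncol(pc)))
    parts <- c(parts, list(pc))
  }
  if (!is.null(delta_pca)) {
    x <- sweep(as.matrix(rows[delta_pca$cols]), 2, delta_pca$center)
    pc <- x %*% delta_pca$rotation
    colnames(pc) <- paste0("item_delta_pc", seq_len(ncol(pc)))
    parts <- c(parts, list(pc))
  }
  do.call(cbind, parts)
}

#' @rdname learn_prep
#' @param prep A prep returned by `learn_prep()`.
#' @param idx Rows of `features$rows` to transform (default all).
#' @export
apply_prep <- function(prep, features, idx = NULL) {
  stopifnot(inherits(prep, "fgi_prep"), inherits(features, "fgi_features"))
  rows <- if (is.null(idx)) features$rows else features$rows[idx, ]
  m <- assemble_matrix(rows, prep$plain_cols, prep$item_pca, prep$delta_pca)
  scale_ <- ifelse(prep$scale > 0, prep$scale, 1)
  sweep(sweep(m, 2, prep$center), 2, scale_, "/")
}
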