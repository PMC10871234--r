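#' The Fragility Index deficit catalog
#'
#' The Fragility Index (FgI) scores 30 ordinal health deficits alongside two
#' quantitative assays (body weight and rectal temperature). Most deficits are
#' scored on a three-level scale (0 absent, 0.5 mild, 1 severe); a subset are
#' two-level (0 absent, 1 severe). Which items are two-level is configurable;
#' the default marks five all-or-nothing clinical signs as two-level.
#'
#' @param two_level Character vector of item display names to score on a
#'   two-level \{0, 1\} scale. All other items are three-level \{0, 0.5, 1\}.
#' @return A tibble with one row per item: `item` (display name), `column`
#'   (the snake_case column name used in assessment tables), and `n_levels`
#'   (2 or 3).
#' @examples
#' cat30 <- deficit_catalog()
#' nrow(cat30)        # 30
#' table(cat30$n_levels)
#' @export
deficit_catalog <- function(two_level = c("Paralysis", "Rectal Prolapse",
                                          "Malocclusions", "Nasal Discharge",
                                          "Vaginal/Uterine Prolapse")) {
  items <- c(
    "Breathing Rate/Depth", "Tumors", "Head Piloerection", "Tail Stiffening",
    "Tremor", "Coat Condition", "Pallor/Cyanosis", "Body Condition",
    "Distended Abdomen", "Dehydration, Skin Turgor", "Dermatitis", "Urine",
    "Thoracic Mass", "Gait Disorders", "Paralysis", "Rectal Prolapse",
    "Eye Discharge/Eyelid Inflammation", "Kyphosis", "Hunched",
    "Changes to Eye Globe", "Response to Analgesic",
    "Peri-retro-orbital Swelling", "Activity", "Malocclusions",
    "Piloerection", "Diarrhea", "Response to External Stimuli",
    "Vestibular Disturbance", "Nasal Discharge", "Vaginal/Uterine Prolapse"
  )
  bad <- setdiff(two_level, items)
  if (length(bad) > 0) {
    abort(sprintf("Unknown two-level item(s): %s", paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    item = items,
    column = item_to_column(items),
    n_levels = ifelse(items %in% two_level, 2L, 3L)
  )
}

# display name -> assessment-table column name
item_to_column <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

# valid score set for an item given its number of levels
valid_scores <- function(n_levels) {
  if (n_levels == 2L) c(0, 1) else c(0, 0.5, 1)
}

check_catalog <- function(catalog) {
  check_columns(catalog, c("item", "column", "n_levels"), "catalog")
  if (nrow(catalog) != 30L) {
    abort(sprintf("catalog must have exactly 30 items, got %d", nrow(catalog)))
  }
  if (anyDuplicated(catalog$item) || anyDuplicated(catalog$column)) {
    abort("catalog item names must be unique")
  }
  if (!all(catalog$n_levels %in% c(2L, 3L))) {
    abort("catalog n_levels must be 2 or 3")
  }
  invisible(catalog)
}

#' Collapse the four-level dermatitis score to the three-level scale
#'
#' Dermatitis is assessed on a four-level scale (0 none, 1 mild, 2 moderate,
#' 3 severe) and is collapsed to the common \{0, 0.5, 1\} scale before FgI
#' scoring. The collapse maps both intermediate levels to "mild" (0.5); any
#' monotone surjection onto the three-level scale preserves the FgI's meaning,
#' and this choice is pinned for reproducibility.
#'
#' @param score4 Numeric vector with values in \{0, 1, 2, 3\} (NA passed
#'   through).
#' @return Numeric vector with values in \{0, 0.5, 1\}.
#' @examples
#' simplify_dermatitis(c(0, 1, 2, 3))
#' @export
simplify_dermatitis <- function(score4) {
  ok <- is.na(score4) | score4 %in% c(0, 1, 2, 3)
  if (!all(ok)) {
    abort(sprintf("dermatitis scores must be in {0,1,2,3}; got %s",
                  paste(unique(score4[!ok]), collapse = ", ")))
  }
  out <- rep(NA_real_, length(score4))
  out[!is.na(score4)] <- c(0, 0.5, 0.5, 1)[score4[!is.na(score4)] + 1]
  out
}
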