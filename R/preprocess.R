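# Score sheets -> normalized feature matrix with missing-indicator
# columns, encoded labels, and a stratified train/test split.
#
# All features live on the instrument's native 0-3 severity scale:
# ordinal codes stay as coded, each item gets a paired binary
# "<item>_missing" indicator in {0, 3}, gender is coded {0, 3}
# (male = 0, female = 3), and age is min-max rescaled onto [0, 3].

#' Encode score sheets as a numeric feature matrix
#'
#' For each of the `n` items this produces a base column (codes 0-3;
#' missing positions filled with 0, the least-severity neutral point)
#' and a companion `<item>_missing` indicator that is 3 exactly where
#' the raw code was 8, 9 or blank — missingness is encoded as a feature
#' rather than imputed, so the inability to answer an item can itself
#' carry diagnostic signal. Age and gender are appended, giving
#' `2n + 2` feature columns (58 for a 28-item instrument).
#'
#' @param sheets Cohort tibble ([simulate_cohort()] / [read_cohort()]).
#' @param age_range Optional length-2 numeric: the (min, max) age in
#'   months used for rescaling, e.g. from a training partition. Values
#'   outside the range are clamped. Default: the range of `sheets`.
#' @return A tibble of class `screen_features`: `subject_id`,
#'   `ordinal_label`, `binary_label`, then the feature columns. Raw ages
#'   are retained in the `age_months` attribute so [partition()] can
#'   re-derive leakage-free scaling from a training split.
#' @export
encode_features <- function(sheets, age_range = NULL) {
  if (nrow(sheets) < 2) {
    abort("need at least 2 subjects to encode", class = "screen_schema_error")
  }
  item_cols <- grep("^item_\\d+$", names(sheets), value = TRUE)
  n_items <- length(item_cols)
  if (n_items < 1) {
    abort("no item_* columns found", class = "screen_schema_error")
  }
  if (!setequal(item_cols, item_col_names(n_items))) {
    abort("item columns must be item_01..item_NN with no gaps",
          class = "screen_schema_error")
  }
  item_cols <- item_col_names(n_items)

  codes <- as.matrix(sheets[item_cols])
  ok <- is.na(codes) | codes %in% ITEM_CODES
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("invalid item code at row %d, column %s",
                  bad[1], item_cols[bad[2]]),
          class = "screen_parse_error")
  }
  miss <- is.na(codes) | codes == 8 | codes == 9
  base <- codes
  base[miss] <- 0
  indicator <- matrix(0, nrow(codes), ncol(codes))
  indicator[miss] <- 3

  raw_age <- as.numeric(sheets$age_months)
  age <- rescale_age(raw_age, age_range %||% range(raw_age))
  gender <- ifelse(sheets$gender == "female", 3, 0)

  labels <- encode_labels(sheets)

  feats <- cbind(base, indicator)
  colnames(feats) <- c(item_cols, paste0(item_cols, "_missing"))
  out <- dplyr::bind_cols(
    labels,
    tibble::as_tibble(as.data.frame(feats)),
    tibble::tibble(age = age, gender = gender)
  )
  new_screen_features(out, n_items = n_items, age_months = raw_age)
}

new_screen_features <- function(tbl, n_items, age_months) {
  structure(tbl,
            class = c("screen_features", class(tibble::tibble()))
            ) -> out
  attr(out, "n_items") <- n_items
  attr(out, "age_months") <- age_months
  out
}

rescale_age <- function(age, rng) {
  if (diff(rng) == 0) {
    warn("age has zero range; age column set to all 0")
    return(rep(0, length(age)))
  }
  pmin(3, pmax(0, (age - rng[1]) / diff(rng) * 3))
}

#' Feature names and numeric matrix of an encoded cohort
#'
#' @param features A `screen_features` tibble.
#' @return `feature_names()` returns the ordered feature-column names;
#'   `feature_matrix()` the subjects-by-features numeric matrix with
#'   `subject_id` rownames.
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("subject_id", "ordinal_label", "binary_label"))
}

#' @rdname feature_names
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[feature_names(features)])
  rownames(m) <- features$subject_id
  m
}

#' Encode diagnosis labels
#'
#' Ordinal labels capture increasing severity — non-ASD (0),
#' spectrum (1), autism (2) — and the binary label is 1 for ASD
#' (spectrum or autism) versus 0 for non-ASD.
#'
#' @param sheets Cohort tibble with `subject_id` and `diagnosis`.
#' @return Tibble: `subject_id`, `ordinal_label`, `binary_label`.
#' @export
encode_labels <- function(sheets) {
  ord <- match(sheets$diagnosis, DIAGNOSIS_LEVELS) - 1L
  if (anyNA(ord)) {
    bad <- sheets$diagnosis[which(is.na(ord))[1]]
    abort(sprintf("unknown diagnosis label '%s'", bad),
          class = "screen_label_error")
  }
  tibble::tibble(
    subject_id = sheets$subject_id,
    ordinal_label = ord,
    binary_label = as.integer(ord >= 1)
  )
}

#' Stratified train/test split
#'
#' Splits subjects into disjoint train and test sets preserving the
#' ASD : non-ASD ratio. Per-class test counts are `round(n_c *
#' test_fraction)` under half-up rounding, which keeps the global test
#' fraction within one subject of the target.
#'
#' @param features A `screen_features` tibble.
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return A list of class `screen_split`: `train_ids`, `test_ids`,
#'   `seed`, `test_fraction`.
#' @export
stratified_split <- function(features, test_fraction = 0.2, seed = 1L) {
  stop_if_not_prob(test_fraction, "test_fraction")
  y <- features$binary_label
  ids <- features$subject_id
  test_ids <- character()
  for (cl in sort(unique(y))) {
    members <- ids[y == cl]
    if (length(members) < 2) {
      abort(sprintf("class %s has fewer than 2 members; cannot stratify", cl),
            class = "screen_stratification_error")
    }
    n_test <- round_half_up(length(members) * test_fraction)
    set.seed(child_seed(seed, 17 + cl))
    test_ids <- c(test_ids, sort(sample(members, n_test)))
  }
  structure(
    list(train_ids = sort(setdiff(ids, test_ids)),
         test_ids = sort(test_ids),
         seed = as.integer(seed),
         test_fraction = test_fraction),
    class = "screen_split"
  )
}

#' Apply a split, rescaling age from the training partition only
#'
#' Subsets an encoded cohort into its train and test partitions and
#' recomputes the age column using the training partition's (min, max)
#' for both sides, so no information from the test partition leaks into
#' the feature scaling. Test ages outside the training range are clamped
#' to [0, 3].
#'
#' @param features A `screen_features` tibble.
#' @param split A `screen_split` from [stratified_split()].
#' @return List with `screen_features` elements `train` and `test`.
#' @export
partition <- function(features, split) {
  raw_age <- attr(features, "age_months")
  n_items <- attr(features, "n_items")
  tr <- features$subject_id %in% split$train_ids
  te <- features$subject_id %in% split$test_ids
  rng <- range(raw_age[tr])
  take <- function(keep) {
    out <- features[keep, , drop = FALSE]
    out$age <- rescale_age(raw_age[keep], rng)
    new_screen_features(out, n_items = n_items, age_months = raw_age[keep])
  }
  test <- if (any(te)) take(te) else {
    out <- features[te, , drop = FALSE]
    new_screen_features(out, n_items = n_items, age_months = numeric())
  }
  list(train = take(tr), test = test)
}

#' Restrict an encoded cohort to a subset of features
#'
#' @param features A `screen_features` tibble.
#' @param keep Character vector of feature names to retain (order kept).
#' @return A `screen_features` tibble with only those feature columns.
#' @export
select_features <- function(features, keep) {
  missing_f <- setdiff(keep, feature_names(features))
  if (length(missing_f)) {
    abort(sprintf("unknown feature(s): %s", paste(missing_f, collapse = ", ")),
          class = "screen_input_error")
  }
  out <- features[c("subject_id", "ordinal_label", "binary_label", keep)]
  new_screen_features(out, n_items = attr(features, "n_items"),
                      age_months = attr(features, "age_months"))
}

#' Write / read a split as JSON
#'
#' @param split A `screen_split`.
#' @param path File path.
#' @return `read_split()` returns the `screen_split` object.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(split)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(raw$train_ids),
                 test_ids = as.character(raw$test_ids),
                 seed = as.integer(raw$seed),
                 test_fraction = as.numeric(raw$test_fraction)),
            class = "screen_split")
}
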