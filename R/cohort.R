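# Synthetic score-sheet cohorts.
#
# Item codes follow the ADOS convention: ordinal severity codes 0-3,
# plus the missing-answer codes 8, 9 and a blank cell (NA). The
# generator plants informative items whose code distribution shifts
# monotonically with diagnostic class, so recovery of the planted
# signal by the selection pipeline is a testable property.

# Latent-scale cutpoints mapping a standard normal latent severity onto
# codes 0..3 (control class: ~60% code 0, ~4% code 3).
.code_cutpoints <- c(0.25, 1.0, 1.75)

DIAGNOSIS_LEVELS <- c("non-ASD", "spectrum", "autism")
GENDER_LEVELS <- c("male", "female")
ITEM_CODES <- c(0L, 1L, 2L, 3L, 8L, 9L)

#' Configure a synthetic score-sheet cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generative model is a latent Gaussian per subject and item: a shared
#' subject factor (loading `item_correlation`) plus idiosyncratic noise,
#' shifted by `effect_size * class` for the planted informative items,
#' then thresholded into the four ordinal codes. Missing answers are
#' drawn per item at `missing_rates` and coded 8, 9 or blank with equal
#' probability, mirroring instruments where several distinct codes all
#' mean "not answered". Optionally, missingness itself can carry class
#' signal for designated items.
#'
#' Demographic defaults emulate an ADOS module 3 style cohort: severe
#' class imbalance (5% controls), ages around 9-10 years with large
#' spread, and a strongly male-skewed case group.
#'
#' @param n_subjects Number of subjects to generate.
#' @param n_items Number of ordinal items per sheet (default 28).
#' @param class_proportions Probabilities for (non-ASD, spectrum,
#'   autism); must sum to 1. Class counts are apportioned exactly by
#'   largest-remainder rounding.
#' @param informative_items Indices of items whose code distribution
#'   depends on class.
#' @param effect_size Latent-scale shift per class level for informative
#'   items (0 = no signal).
#' @param missing_rates Per-item missingness probability; scalar or
#'   length-`n_items` vector.
#' @param missing_informative_items Items whose missingness rate rises
#'   with class severity.
#' @param missing_informative_rate Additional missingness probability at
#'   the autism class level for those items (spectrum gets half).
#' @param item_correlation Loading of the shared latent factor, in
#'   `[0, 1)`; induces item-item correlation.
#' @param age_mean_by_class,age_sd_by_class Age (months) normal
#'   parameters per class.
#' @param gender_male_prob_by_class Probability of male per class.
#' @param seed Integer seed; the same config reproduces byte-identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          n_items = 28,
                          class_proportions = c(0.05, 0.25, 0.70),
                          informative_items = 1:5,
                          effect_size = 0.8,
                          missing_rates = 0.01,
                          missing_informative_items = integer(),
                          missing_informative_rate = 0,
                          item_correlation = 0.3,
                          age_mean_by_class = c(109, 114, 116),
                          age_sd_by_class = c(35, 38, 38),
                          gender_male_prob_by_class = c(0.50, 0.84, 0.84),
                          seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    config_error("n_subjects", "must be a positive count")
  }
  if (!is.numeric(n_items) || length(n_items) != 1 || n_items < 1) {
    config_error("n_items", "must be a positive count (>= 1)")
  }
  n_items <- as.integer(n_items)
  if (length(class_proportions) != 3) {
    config_error("class_proportions", "must have length 3")
  }
  stop_if_not_prob(class_proportions, "class_proportions")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    config_error("class_proportions", "must sum to 1 (within 1e-9)")
  }
  informative_items <- as.integer(informative_items)
  if (length(informative_items) &&
      (anyNA(informative_items) || any(informative_items < 1) ||
       any(informative_items > n_items))) {
    config_error("informative_items", "must be a subset of 1..n_items")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 ||
      !is.finite(effect_size) || effect_size < 0) {
    config_error("effect_size", "must be a finite non-negative number")
  }
  if (!length(missing_rates) %in% c(1L, n_items)) {
    config_error("missing_rates", "must have length 1 or n_items")
  }
  stop_if_not_prob(missing_rates, "missing_rates")
  missing_informative_items <- as.integer(missing_informative_items)
  if (length(missing_informative_items) &&
      (anyNA(missing_informative_items) || any(missing_informative_items < 1) ||
       any(missing_informative_items > n_items))) {
    config_error("missing_informative_items", "must be a subset of 1..n_items")
  }
  stop_if_not_prob(missing_informative_rate, "missing_informative_rate")
  if (!is.numeric(item_correlation) || length(item_correlation) != 1 ||
      item_correlation < 0 || item_correlation >= 1) {
    config_error("item_correlation", "must be in [0, 1)")
  }
  for (f in c("age_mean_by_class", "age_sd_by_class",
              "gender_male_prob_by_class")) {
    v <- get(f)
    if (length(v) != 3 || anyNA(v)) config_error(f, "must have length 3")
  }
  if (any(age_mean_by_class <= 0) || any(age_sd_by_class < 0)) {
    config_error("age_mean_by_class", "ages must be positive")
  }
  stop_if_not_prob(gender_male_prob_by_class, "gender_male_prob_by_class")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_items = n_items,
      class_proportions = as.numeric(class_proportions),
      informative_items = informative_items,
      effect_size = effect_size,
      missing_rates = rep_len(as.numeric(missing_rates), n_items),
      missing_informative_items = missing_informative_items,
      missing_informative_rate = as.numeric(missing_informative_rate),
      item_correlation = as.numeric(item_correlation),
      age_mean_by_class = as.numeric(age_mean_by_class),
      age_sd_by_class = as.numeric(age_sd_by_class),
      gender_male_prob_by_class = as.numeric(gender_male_prob_by_class),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

item_col_names <- function(n_items) sprintf("item_%02d", seq_len(n_items))

#' Simulate a cohort of score sheets
#'
#' Draws `n_subjects` score sheets under the latent-factor ordinal model
#' described in [cohort_config()]. Class counts are exact (largest-
#' remainder apportionment), informative items shift monotonically with
#' class severity, and missing answers are split uniformly among code 8,
#' code 9 and a blank cell.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per subject: `subject_id`,
#'   `item_01`..`item_NN` (integer codes, `NA` = blank), `age_months`,
#'   `gender`, `diagnosis`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n <- config$n_subjects
  p <- config$n_items
  counts <- largest_remainder(n, config$class_proportions)
  cls <- rep(0:2, counts)

  set.seed(config$seed)
  shared <- rnorm(n)
  lam <- config$item_correlation
  latent <- lam * shared +
    sqrt(1 - lam^2) * matrix(rnorm(n * p), n, p)
  if (length(config$informative_items)) {
    latent[, config$informative_items] <-
      latent[, config$informative_items] + config$effect_size * cls
  }
  codes <- matrix(findInterval(latent, .code_cutpoints), n, p)
  storage.mode(codes) <- "integer"

  # class-dependent missingness for designated items
  rate <- matrix(rep(config$missing_rates, each = n), n, p)
  if (length(config$missing_informative_items) &&
      config$missing_informative_rate > 0) {
    bump <- config$missing_informative_rate * cls / 2
    rate[, config$missing_informative_items] <-
      pmin(1, rate[, config$missing_informative_items] + bump)
  }
  miss <- matrix(runif(n * p) < rate, n, p)
  n_miss <- sum(miss)
  if (n_miss > 0) {
    codes[miss] <- sample(c(8L, 9L, NA_integer_), n_miss, replace = TRUE)
  }

  age <- pmax(1, round_half_up(rnorm(
    n, config$age_mean_by_class[cls + 1], config$age_sd_by_class[cls + 1]
  )))
  gender <- ifelse(runif(n) < config$gender_male_prob_by_class[cls + 1],
                   "male", "female")

  out <- tibble::tibble(subject_id = sprintf("S%05d", seq_len(n)))
  item_df <- tibble::as_tibble(as.data.frame(codes))
  names(item_df) <- item_col_names(p)
  out <- dplyr::bind_cols(out, item_df)
  out$age_months <- as.numeric(age)
  out$gender <- gender
  out$diagnosis <- DIAGNOSIS_LEVELS[cls + 1]
  out
}

#' Write / read a cohort CSV
#'
#' RFC-4180 CSV with a header row; columns `subject_id`,
#' `item_01..item_NN`, `age_months`, `gender`, `diagnosis`. A blank item
#' cell means an omitted answer and round-trips as `NA`, distinct from
#' the explicit missing codes 8 and 9.
#'
#' @param sheets Cohort tibble as produced by [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `sheets` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(sheets, path) {
  readr::write_csv(sheets, path, na = "")
  invisible(sheets)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, na = "", col_types = readr::cols(
    subject_id = readr::col_character(),
    age_months = readr::col_double(),
    gender = readr::col_character(),
    diagnosis = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  required <- c("subject_id", "age_months", "gender", "diagnosis")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("cohort file lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "screen_schema_error")
  }
  item_cols <- grep("^item_\\d+$", names(raw), value = TRUE)
  if (!length(item_cols)) {
    abort("cohort file has no item_* columns", class = "screen_schema_error")
  }
  for (col in item_cols) {
    bad <- which(!is.na(raw[[col]]) & !raw[[col]] %in% ITEM_CODES)
    if (length(bad)) {
      abort(sprintf(
        "invalid item code '%s' at row %d, column %s (allowed: 0-3, 8, 9, blank)",
        raw[[col]][bad[1]], bad[1], col
      ), class = "screen_parse_error")
    }
  }
  bad_diag <- which(!raw$diagnosis %in% DIAGNOSIS_LEVELS)
  if (length(bad_diag)) {
    abort(sprintf("unknown diagnosis '%s' at row %d",
                  raw$diagnosis[bad_diag[1]], bad_diag[1]),
          class = "screen_parse_error")
  }
  raw[c("subject_id", item_cols, "age_months", "gender", "diagnosis")]
}
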