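# Synthetic score-sheet generator: exact stratification, planted
# signal, missingness behaviour, determinism, and CSV round-trips.

test_that("class counts are exactly the largest-remainder targets", {
  co <- simulate_cohort(cohort_config(
    n_subjects = 100, class_proportions = c(0.05, 0.25, 0.70), seed = 1
  ))
  expect_equal(nrow(co), 100)
  tab <- table(co$diagnosis)
  expect_equal(unname(tab[["non-ASD"]]), 5)
  expect_equal(unname(tab[["spectrum"]]), 25)
  expect_equal(unname(tab[["autism"]]), 70)

  # exactness holds for awkward proportions too, not just in expectation
  for (n in c(7, 33, 101)) {
    co2 <- simulate_cohort(cohort_config(
      n_subjects = n, class_proportions = c(1 / 3, 1 / 3, 1 / 3), seed = 2
    ))
    expect_equal(nrow(co2), n)
    expect_lte(diff(range(table(co2$diagnosis))), 1)
  }
})

test_that("per-item missingness matches the configured rate", {
  rates <- rep(0.01, 28)
  rates[3] <- 0.786  # a heavily missing item, as real instruments show
  co <- simulate_cohort(cohort_config(
    n_subjects = 20000, missing_rates = rates, seed = 3
  ))
  frac <- mean(co$item_03 %in% c(8, 9) | is.na(co$item_03))
  expect_lt(abs(frac - 0.786), 0.01)
  # missing codes split across 8, 9 and blank
  expect_gt(sum(co$item_03 == 8, na.rm = TRUE), 0)
  expect_gt(sum(co$item_03 == 9, na.rm = TRUE), 0)
  expect_gt(sum(is.na(co$item_03)), 0)
})

test_that("the same config reproduces an identical cohort", {
  cfg <- cohort_config(n_subjects = 150, missing_rates = 0.1, seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("informative items shift monotonically with class; others do not", {
  co <- simulate_cohort(cohort_config(
    n_subjects = 6000, n_items = 8, informative_items = 1:2,
    effect_size = 1.0, missing_rates = 0, seed = 4,
    class_proportions = c(1 / 3, 1 / 3, 1 / 3)
  ))
  mean_by_class <- function(item) {
    tapply(co[[item]], co$diagnosis, mean)[c("non-ASD", "spectrum", "autism")]
  }
  for (item in c("item_01", "item_02")) {
    m <- mean_by_class(item)
    expect_true(all(diff(m) > 0), label = paste(item, "monotone"))
  }
  # a non-informative item shows no detectable class effect
  expect_gt(kruskal.test(co$item_05, factor(co$diagnosis))$p.value, 0.001)
})

test_that("with zero effect size items are exchangeable between classes", {
  # nominal 5% rejection rate of a rank test, checked against binomial
  # 99% bounds over 50 seeds
  rejections <- vapply(1:50, function(s) {
    co <- simulate_cohort(cohort_config(
      n_subjects = 240, n_items = 4, informative_items = 1:2,
      effect_size = 0, missing_rates = 0, seed = s,
      class_proportions = c(0.5, 0.25, 0.25)
    ))
    grp <- co$diagnosis == "non-ASD"
    suppressWarnings(
      wilcox.test(co$item_01[grp], co$item_01[!grp])$p.value
    ) < 0.05
  }, TRUE)
  bounds <- qbinom(c(0.005, 0.995), 50, 0.05)
  expect_gte(sum(rejections), bounds[1])
  expect_lte(sum(rejections), bounds[2])
})

test_that("missingness is class-independent unless made informative", {
  rejections <- vapply(1:50, function(s) {
    co <- simulate_cohort(cohort_config(
      n_subjects = 300, n_items = 4, informative_items = 1:2,
      effect_size = 1, missing_rates = 0.3, seed = s,
      class_proportions = c(0.5, 0.25, 0.25)
    ))
    miss <- co$item_02 %in% c(8, 9) | is.na(co$item_02)
    suppressWarnings(
      chisq.test(table(miss, co$diagnosis == "non-ASD"))$p.value
    ) < 0.05
  }, TRUE)
  bounds <- qbinom(c(0.005, 0.995), 50, 0.05)
  expect_gte(sum(rejections), bounds[1])
  expect_lte(sum(rejections), bounds[2])

  # and rises with class severity when informative missingness is on
  co <- simulate_cohort(cohort_config(
    n_subjects = 6000, n_items = 4, informative_items = 1:2,
    missing_rates = 0.05,
    missing_informative_items = 1, missing_informative_rate = 0.5,
    class_proportions = c(1 / 3, 1 / 3, 1 / 3), seed = 8
  ))
  miss_rate <- tapply(co$item_01 %in% c(8, 9) | is.na(co$item_01),
                      co$diagnosis, mean)
  expect_true(all(diff(miss_rate[c("non-ASD", "spectrum", "autism")]) > 0))
})

test_that("invalid configs are rejected naming the offending field", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(100, class_proportions = c(0.5, 0.5, 0.5)),
               "class_proportions")
  expect_error(cohort_config(100, n_items = 4, informative_items = 1:9),
               "informative_items")
  expect_error(cohort_config(100, missing_rates = 1.5), "missing_rates")
  expect_error(cohort_config(100, item_correlation = 1), "item_correlation")
  expect_error(cohort_config(100, effect_size = -1), "effect_size")
})

test_that("cohort CSV round-trips all fields including missing codes", {
  cfg <- cohort_config(n_subjects = 50, n_items = 6, missing_rates = 0.3,
                       seed = 21)
  co <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
  # the 8 / 9 / blank distinction survives the round trip
  expect_identical(is.na(back$item_01), is.na(co$item_01))
  expect_identical(back$item_01 == 8, co$item_01 == 8)
})

test_that("blank cells are preserved as NA in the file, not as 0", {
  co <- hand_sheets()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  raw <- readLines(path)
  cells <- strsplit(raw[4], ",")[[1]]  # subject C: item_03 blank
  expect_identical(cells[4], "")
  expect_true(is.na(read_cohort(path)$item_03[3]))
})

test_that("malformed cohort files fail with located errors", {
  co <- hand_sheets()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  raw <- readLines(path)
  raw[2] <- sub("^A,0", "A,5", raw[2])  # out-of-alphabet code
  writeLines(raw, path)
  expect_error(read_cohort(path), "row 1.*item_01", class = "screen_parse_error")

  write_cohort(co[setdiff(names(co), "diagnosis")], path)
  suppressWarnings(
    expect_error(read_cohort(path), "diagnosis", class = "screen_schema_error")
  )
})
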