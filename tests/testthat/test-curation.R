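test_that("missingness pruning drops variables below the populated threshold", {
  set.seed(1)
  n <- 200
  fracs <- seq(0.5, 0.95, by = 0.05)
  X <- sapply(fracs, function(f) {
    x <- rnorm(n)
    x[sample(n, round((1 - f) * n))] <- NA
    x
  })
  tab <- toy_table(X)
  out <- prune_missingness(tab, 0.80)
  # counting oracle: observed fraction per column
  observed <- colMeans(!is.na(X))
  expect_setequal(out$table$meta$name, tab$meta$name[observed >= 0.80])
  expect_setequal(out$report$dropped_missingness$variable,
                  tab$meta$name[observed < 0.80])
  expect_equal(sort(out$report$dropped_missingness$populated_fraction),
               sort(unname(observed[observed < 0.80])))
})

test_that("a 79%-populated variable is dropped at the 80% threshold", {
  X <- cbind(a = c(rnorm(79), rep(NA, 21)), b = rnorm(100))
  out <- prune_missingness(toy_table(X), 0.80)
  expect_equal(out$table$meta$name, "b")
})

test_that("near-constant filter drops dominant-value and constant columns", {
  X <- cbind(
    nearly = c(rep(0, 995), rep(1, 5)),    # 99.5% > 99%
    balanced = rep(c(0, 1), 500),          # 50/50
    constant = rep(7, 1000),
    boundary = c(rep(0, 990), rep(1, 10))  # exactly 99%: retained
  )
  out <- drop_near_constant(toy_table(X), 0.99)
  expect_setequal(out$table$meta$name, c("balanced", "boundary"))
  expect_setequal(out$report$dropped_near_constant$variable,
                  c("nearly", "constant"))
  expect_equal(
    out$report$dropped_near_constant$top_value_fraction[
      out$report$dropped_near_constant$variable == "nearly"], 0.995)
})

test_that("discrete encoding produces one-hot indicators inheriting metadata", {
  x <- c(0, 1, 2, 3, 4, 0, 1, 2, NA, 4)
  tab <- toy_table(cbind(ethnicity = x), dtype = "discrete",
                   category = "Demographics")
  out <- encode_discrete(tab)
  expect_equal(ncol(out$table$values), 5)
  expect_equal(out$table$meta$name,
               sprintf("ethnicity=%d", 0:4))
  expect_true(all(out$table$meta$category == "Demographics"))
  expect_true(all(out$table$meta$dtype == "indicator"))
  complete <- which(!is.na(x))
  expect_true(all(rowSums(out$table$values[complete, ]) == 1))
  expect_true(all(is.na(out$table$values[9, ])))  # missing parent propagates
  # direct expansion oracle
  expect_equal(unname(out$table$values[complete, 3]),
               as.numeric(x[complete] == 2))
})

test_that("binary variables become two complementary indicators", {
  tab <- toy_table(cbind(flag = rep(c(0, 1), 10)), dtype = "discrete")
  out <- encode_discrete(tab)
  expect_equal(ncol(out$table$values), 2)
  expect_true(all(rowSums(out$table$values) == 1))
})

test_that("single-level discrete variables raise", {
  tab <- toy_table(cbind(stuck = rep(1, 10)), dtype = "discrete")
  expect_error(encode_discrete(tab), "single observed level")
})

test_that("winsorization replaces outliers with the max-magnitude in-range value", {
  # n must be large enough that a lone outlier can exceed 4 SD at all: the
  # sample z-score is bounded by (n-1)/sqrt(n), so n >= 18 is required
  x <- c(1:100, 1e6)
  tab <- toy_table(cbind(v = x))
  out <- robust_zscore_winsorize(tab, z_max = 4)
  # brute-force oracle
  m <- mean(x); s <- sd(x)
  in_range <- x[abs(x - m) / s <= 4]
  replacement <- in_range[which.max(abs(in_range))]
  replaced <- x; replaced[abs(x - m) / s > 4] <- replacement
  expect_equal(unname(out$table$values[, 1]),
               (replaced - mean(replaced)) / sd(replaced))
  expect_equal(unname(out$report$winsorized_counts["v"]), 1L)
  # replacement itself satisfies |z| <= 4 under pre-replacement statistics
  expect_lte(abs(replacement - m) / s, 4)
})

test_that("columns without outliers are only standardized", {
  set.seed(2)
  x <- rnorm(100)
  out <- robust_zscore_winsorize(toy_table(cbind(v = x)))
  expect_equal(unname(out$table$values[, 1]), (x - mean(x)) / sd(x))
  expect_equal(sum(out$report$winsorized_counts), 0L)
})

test_that("zero-variance columns make winsorization fail loudly", {
  expect_error(robust_zscore_winsorize(toy_table(cbind(v = rep(1, 10)))),
               "zero variance")
})

test_that("imputation fills medians and modes", {
  tab <- toy_table(cbind(v = c(1, 2, NA, 3)))
  expect_equal(impute_missing(tab)$values[3, 1], 2)
  ind <- toy_table(cbind(i = c(0, 0, 0, 1, NA)), dtype = "indicator")
  expect_equal(impute_missing(ind)$values[5, 1], 0)
  full <- toy_table(cbind(v = rnorm(5)))
  expect_identical(impute_missing(full)$values, full$values)
})

test_that("event retention keeps only well-covered events", {
  # three events with planted coverages 0.80, 0.96, 0.99
  n <- 500
  X <- matrix(rnorm(n * 6), n)
  coverage <- c(e1 = 0.80, e2 = 0.96, e3 = 0.99)
  event <- rep(names(coverage), each = 2)
  for (e in names(coverage)) {
    out_rows <- sample(n, round((1 - coverage[[e]]) * n))
    X[out_rows, event == e] <- NA
  }
  meta <- data.frame(name = sprintf("v%d", 1:6), category = "Behavior",
                     dtype = "continuous", event = event)
  tab <- phenome_table(X, meta)
  out <- retain_events(tab, 0.95)
  expect_setequal(out$report$retained_events, c("e2", "e3"))
  expect_setequal(unique(out$table$meta$event), c("e2", "e3"))
  expect_true(all(out$report$dropped_events$event == "e1"))
})

test_that("a 90%-covered event is dropped at the 95% rule", {
  n <- 200
  X <- matrix(rnorm(n * 4), n)
  X[1:20, 3:4] <- NA  # second event covers 90%
  meta <- data.frame(name = sprintf("v%d", 1:4), category = "Behavior",
                     dtype = "continuous",
                     event = rep(c("baseline", "late"), each = 2))
  out <- retain_events(phenome_table(X, meta), 0.95)
  expect_equal(out$report$retained_events, "baseline")
})

test_that("sentinel non-compliance codes are recoded to missing", {
  tab <- toy_table(cbind(v = c(1, 777, 2, 999, 3)))
  out <- recode_noncompliance(tab, codes = c(777, 999))
  expect_equal(sum(is.na(out$table$values)), 2)
  expect_equal(unname(out$report$recoded_counts["v"]), 2L)
})

test_that("full curation report accounts for planted violations", {
  cfg <- clean_config(n_participants = 800, n_variables = 100,
                      frac_discrete = 0.2, missing_rate = 0.05,
                      outlier_rate = 0.002, frac_near_constant = 0.05,
                      frac_high_missing = 0.05, seed = 13L)
  sim <- generate_phenome(cfg)
  out <- curate(sim$table)
  planted_nc <- sim$table$meta$name[sim$truth$planted$near_constant]
  planted_hm <- sim$table$meta$name[sim$truth$planted$high_missing]
  expect_setequal(out$report$dropped_near_constant$variable, planted_nc)
  expect_setequal(out$report$dropped_missingness$variable, planted_hm)
  # conservation: every input variable accounted for exactly once
  accounted <- c(out$report$dropped_events$variable,
                 out$report$dropped_missingness$variable,
                 out$report$dropped_near_constant$variable,
                 names(out$report$encoded),
                 intersect(sim$table$meta$name, out$table$meta$name))
  expect_setequal(accounted, sim$table$meta$name)
  expect_equal(anyDuplicated(accounted), 0)
})

test_that("curated tables are standardized, complete, and bounded", {
  fx <- small_trained_fixture()
  X <- fx$curated$values
  expect_false(anyNA(X))
  cont <- fx$curated$meta$dtype == "continuous"
  expect_lt(max(abs(colMeans(X[, cont]))), 1e-8)
  expect_lt(max(abs(apply(X[, cont], 2, sd) - 1)), 1e-8)
  expect_true(all(X[, !cont] %in% c(0, 1)))
  # no continuous entry beyond the winsorization bound under the
  # pre-standardization statistics (z-scored scale: 4 sd, small slack for
  # the post-replacement re-centering)
  expect_lt(max(abs(X[, cont])), 4.5)
})

test_that("curation is idempotent up to re-standardization", {
  fx <- small_trained_fixture()
  again <- curate(fx$curated)
  # structure is exactly stable: nothing dropped, nothing re-encoded
  expect_identical(again$table$meta$name, fx$curated$meta$name)
  expect_equal(nrow(again$report$dropped_missingness), 0)
  expect_equal(nrow(again$report$dropped_near_constant), 0)
  expect_length(again$report$encoded, 0)
  # values are stable up to re-standardization; entries that sat exactly at
  # the winsorization boundary may be clipped once more (and the max-magnitude
  # replacement rule is sign-agnostic), so at most a handful of entries move
  delta <- abs(again$table$values - fx$curated$values)
  expect_lt(mean(delta), 0.01)
  expect_lt(sum(delta > 0.1), 5)
  cont <- again$table$meta$dtype == "continuous"
  expect_lt(max(abs(colMeans(again$table$values[, cont]))), 1e-8)
  expect_lt(max(abs(apply(again$table$values[, cont], 2, sd) - 1)), 1e-8)
})
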