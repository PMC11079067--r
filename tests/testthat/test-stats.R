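test_that("a constant predictor is degenerate: OR 1, p 1", {
  y <- rep(c(0, 1), 20)
  got <- univariate_logistic(rep(2.5, 40), y, "flat")
  expect_equal(got$odds_ratio, 1)
  expect_equal(got$p_value, 1)
  expect_equal(got$status, "degenerate")
})

test_that("the logistic OR on a binary predictor equals the cross-product ratio", {
  # 2x2 table a=20, b=10, c=10, d=20 -> OR = (20*20)/(10*10) = 4
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  got <- univariate_logistic(x, y, "exposure")
  expect_equal(got$odds_ratio, 4, tolerance = 1e-6)
  expect_true(got$ci_low <= got$odds_ratio && got$odds_ratio <= got$ci_high)
})

test_that("complete separation is flagged, not reported as an estimate", {
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  got <- univariate_logistic(x, y, "sep")
  expect_equal(got$status, "separation")
})

test_that("a single-class outcome is a domain error", {
  expect_error(univariate_logistic(rnorm(10), rep(1, 10)), "single class")
})

test_that("missing predictor values are dropped and the analysed n reported", {
  set.seed(4)
  x <- c(rnorm(30), rep(NA, 10))
  y <- rep(c(0, 1), 20)
  expect_equal(univariate_logistic(x, y, "v")$n, 30)
})

test_that("a lone stepwise candidate equals its univariate refit", {
  set.seed(8)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(1.2 * x))
  uni <- univariate_logistic(x, y, "x")
  multi <- multivariate_stepwise(data.frame(x = x), y, "x")
  expect_equal(multi$odds_ratio, uni$odds_ratio, tolerance = 1e-9)
  expect_equal(multi$p_value, uni$p_value, tolerance = 1e-9)
  expect_equal(multi$analysis, "multivariate")
})

test_that("duplicated predictors are dropped as aliased without crashing", {
  set.seed(5)
  x <- rnorm(100)
  y <- rbinom(100, 1, plogis(1.5 * x))
  df <- data.frame(a = x, b = x)
  got <- multivariate_stepwise(df, y, c("a", "b"))
  expect_equal(nrow(got), 1L)
  expect_true("b" %in% attr(got, "dropped"))
})

test_that("stepwise keeps the informative index and sheds pure noise", {
  keep_signal <- 0L
  drop_noise <- 0L
  n_noise <- 2L
  for (r in 1:100) {
    set.seed(500 + r)
    n <- 200
    signal <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * signal))
    df <- data.frame(sti_am_v = signal, noise1 = rnorm(n), noise2 = rnorm(n))
    got <- multivariate_stepwise(df, y, names(df))
    if ("sti_am_v" %in% got$variable) keep_signal <- keep_signal + 1L
    drop_noise <- drop_noise +
      sum(!c("noise1", "noise2") %in% got$variable)
  }
  expect_gte(keep_signal, 90)
  expect_gte(drop_noise / (100 * n_noise), 0.90)
})

test_that("AUC follows the concordant-pair count with ties half-weighted", {
  got <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), "toy")
  expect_equal(got$auc, 0.75)  # 3 of 4 pairs concordant
  sep <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  ties <- roc_analysis(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(ties$auc, 0.5)
})

test_that("an anti-oriented predictor reports its AUC below one half as-is", {
  got <- roc_analysis(c(5, 4, 2, 1), c(0, 0, 1, 1))
  expect_equal(got$auc, 0)
  expect_equal(got$direction, "<=")
  expect_equal(got$sensitivity, 100)
  expect_equal(got$specificity, 100)
})

test_that("rank AUC equals exhaustive pair counting on random tied data", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    score <- round(rnorm(n), 1)  # coarse rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_analysis(score, y)$auc, brute_auc(score, y),
                 tolerance = 1e-12)
  }
})

test_that("the reported cutoff attains the brute-force Youden maximum", {
  set.seed(78)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    score <- round(rnorm(n), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- roc_analysis(score, y)
    oracle <- brute_youden(score, y, ge = got$direction == ">=")
    expect_equal(got$youden, oracle$youden, tolerance = 1e-12)
    expect_equal(got$cutoff, oracle$cutoff)
    # the reported sens/spec are attained at the reported cutoff
    call_pos <- if (got$direction == ">=") score >= got$cutoff else
      score <= got$cutoff
    expect_equal(got$sensitivity, 100 * mean(call_pos[y == 1]))
    expect_equal(got$specificity, 100 * mean(!call_pos[y == 0]))
  }
})

test_that("AUC and DeLong p agree with pROC on a reference dataset", {
  skip_if_not_installed("pROC")
  set.seed(99)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  a <- y + rnorm(n)
  b <- 0.3 * y + rnorm(n)
  ra <- roc_analysis(a, y)
  suppressMessages({
    pa <- pROC::roc(y, a, direction = "<", quiet = TRUE)
    pt <- pROC::roc.test(pa, pROC::roc(y, b, direction = "<", quiet = TRUE),
                         method = "delong", paired = TRUE)
  })
  expect_equal(ra$auc, as.numeric(pROC::auc(pa)), tolerance = 1e-12)
  got <- compare_aucs(a, b, y)
  expect_equal(got$p_value, pt$p.value, tolerance = 1e-9)
})

test_that("identical or rank-equivalent predictors compare with p = 1", {
  set.seed(55)
  y <- rbinom(60, 1, 0.5)
  x <- rnorm(60)
  expect_equal(compare_aucs(x, x, y)$p_value, 1)
  mono <- compare_aucs(x, exp(2 * x) - 3, y)
  expect_equal(mono$auc_diff, 0)
  expect_equal(mono$p_value, 1)
})

test_that("the paired AUC test detects an informative predictor over noise", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(900 + r)
    n <- 200
    y <- rbinom(n, 1, 0.5)
    informative <- y + rnorm(n)
    noise <- rnorm(n)
    if (compare_aucs(informative, noise, y)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 80)
})

test_that("degenerate group comparisons return null results, not errors", {
  h <- expand.grid(patient_id = sprintf("P%02d", 1:9),
                   side = c("affected", "healthy"),
                   stage = c("pre", "post"), stringsAsFactors = FALSE)
  # three postoperative AAO-HNS groups (A, B, D) with identical zero changes
  audio <- list(c(25, 80), c(40, 60), c(40, 30))[(as.integer(
    sub("P", "", h$patient_id)) - 1) %/% 3 + 1]
  h$pta_db <- vapply(audio, `[`, 0, 1)
  h$wrs_pct <- vapply(audio, `[`, 0, 2)
  got <- group_comparisons(h)
  expect_true(all(got$p_value == 1))
  expect_true(all(got$statistic == 0))
})

test_that("healthy-side change p-values are null-calibrated across seeds", {
  ps <- vapply(1:40, function(s) {
    hear <- cohort_hearing(simulate_cohort(sim_config(
      n_patients = 25, surgery_duration_min = 45, seed = 3000 + s)))
    gc <- group_comparisons(hear)
    gc$p_value[gc$comparison == "healthy pta_db pre vs post"]
  }, 0)
  expect_lte(mean(ps < 0.05), 0.15)   # near-nominal small-p rate
  expect_gt(mean(ps < 0.5), 0.25)     # and not piled at 1 either
  expect_lt(mean(ps < 0.5), 0.75)
})
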