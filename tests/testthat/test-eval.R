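test_that("brier_score matches its closed forms and a direct oracle", {
  expect_equal(brier_score(c(TRUE, FALSE), c(1, 0)), 0)
  expect_equal(brier_score(c(TRUE, FALSE), c(0.5, 0.5)), 0.25)
  set.seed(61)
  truth <- runif(50) > 0.5
  prob <- runif(50)
  expect_equal(brier_score(truth, prob),
               mean((as.numeric(truth) - prob)^2), tolerance = 1e-12)
  expect_error(brier_score(TRUE, c(0.5, 0.5)), class = "outlierboot_error_input")
  expect_error(brier_score(TRUE, 1.5), class = "outlierboot_error_input")
})

test_that("confusion_metrics reproduces a hand-computed contingency table", {
  # TP=3, FP=1, TN=4, FN=2
  truth <- c(rep("p", 5), rep("n", 5))
  pred <- c("p", "p", "p", "n", "n", "p", "n", "n", "n", "n")
  cm <- confusion_metrics(truth, pred, positive = "p")
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$npv, 2 / 3)
})

test_that("confusion_metrics covers the degenerate and error cases", {
  cm1 <- confusion_metrics(c("a", "b"), c("a", "b"), "a")
  expect_equal(unlist(cm1), c(accuracy = 1, sensitivity = 1, specificity = 1,
                              ppv = 1, npv = 1))
  cm2 <- confusion_metrics(c("a", "b"), c("b", "a"), "a")
  expect_equal(cm2$accuracy, 0)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 0)
  # all predictions positive: NPV undefined
  cm3 <- confusion_metrics(c("a", "b"), c("a", "a"), "a")
  expect_true(is.na(cm3$npv))
  expect_error(confusion_metrics(c("a", "b", "c"), c("a", "b", "c"), "a"),
               class = "outlierboot_error_input")
  expect_error(confusion_metrics(character(0), character(0), "a"),
               class = "outlierboot_error_input")
})

test_that("accuracy decomposes into sensitivity and specificity", {
  set.seed(62)
  for (i in 1:10) {
    truth <- sample(c("p", "n"), 40, replace = TRUE)
    pred <- sample(c("p", "n"), 40, replace = TRUE)
    cm <- confusion_metrics(truth, pred, "p")
    n_pos <- sum(truth == "p")
    n_neg <- sum(truth == "n")
    expect_equal(cm$accuracy,
                 (cm$sensitivity * n_pos + cm$specificity * n_neg) / 40)
  }
})

# deterministic, widely separated two-cluster dataset
separable_ds <- function(seed = 63, n_per = 10, d = 60) {
  set.seed(seed)
  expr <- matrix(rnorm(d * 2 * n_per), d, 2 * n_per,
                 dimnames = list(sprintf("t%03d", 1:d),
                                 sprintf("s%03d", 1:(2 * n_per))))
  expr[1:20, (n_per + 1):(2 * n_per)] <- expr[1:20, (n_per + 1):(2 * n_per)] + 8
  meta <- tibble::tibble(sample_id = colnames(expr),
                         group = rep(c("G1", "G2"), each = n_per))
  expression_dataset(expr, meta)
}

test_that("perfectly separable clusters give accuracy 1 for every classifier", {
  ds <- separable_ds()
  for (clf in c("svm", "rf", "lda")) {
    perf <- cv_evaluate(ds, clf, n_cv_runs = 5, gene_grid = c(5, 10),
                        rf_trees = 100, seed = 1)
    expect_true(all(perf$accuracy == 1), label = clf)
    expect_true(all(perf$brier < 0.25), label = clf)
  }
})

test_that("labels shuffled independently of the data give chance accuracy", {
  set.seed(64)
  expr <- matrix(rnorm(50 * 200), 50, 200,
                 dimnames = list(sprintf("t%02d", 1:50), sprintf("s%03d", 1:200)))
  meta <- tibble::tibble(sample_id = colnames(expr),
                         group = sample(rep(c("G1", "G2"), each = 100)))
  ds <- expression_dataset(expr, meta)
  perf <- cv_evaluate(ds, "lda", n_cv_runs = 25, gene_grid = 10, seed = 2)
  expect_gte(perf$accuracy, 0.4)
  expect_lte(perf$accuracy, 0.6)
})

test_that("cv_evaluate is reproducible and exposes per-run raw metrics", {
  ds <- separable_ds(seed = 65)
  p1 <- cv_evaluate(ds, "svm", n_cv_runs = 6, gene_grid = c(5, 10), seed = 3)
  p2 <- cv_evaluate(ds, "svm", n_cv_runs = 6, gene_grid = c(5, 10), seed = 3)
  expect_identical(tidy(p1), tidy(p2))
  runs <- attr(p1, "runs")
  expect_equal(nrow(runs), 6 * 2)
  expect_true(all(runs$accuracy >= 0 & runs$accuracy <= 1))
  expect_true(all(runs$brier >= 0 & runs$brier <= 1))
  # standard errors are across-run sd / sqrt(runs)
  a10 <- runs$accuracy[runs$n_genes == 10]
  expect_equal(p1$accuracy_se[p1$n_genes == 10],
               stats::sd(a10) / sqrt(length(a10)))
})

test_that("ranking on the full data is offered as an explicit variant", {
  ds <- separable_ds(seed = 66)
  perf <- cv_evaluate(ds, "lda", n_cv_runs = 4, gene_grid = 10,
                      select_on_full = TRUE, seed = 4)
  feats <- attr(perf, "top_features")
  # with full-data selection every run uses the same feature list
  expect_true(all(vapply(feats, identical, logical(1), y = feats[[1]])))
})

test_that("the regularized LDA fallback returns valid probabilities", {
  ds <- separable_ds(seed = 67, n_per = 8, d = 80)
  # 40 features vs ~11 training samples forces the shrinkage path
  perf <- cv_evaluate(ds, "lda", n_cv_runs = 4, gene_grid = 40, seed = 5)
  expect_true(all(perf$accuracy >= 0 & perf$accuracy <= 1))
  expect_true(all(perf$brier >= 0 & perf$brier <= 1))
})

test_that("four-group evaluation reports accuracy and multiclass Brier only", {
  cfg <- sim_config(n_transcripts = 80, groups = 4, samples_per_group = 8,
                    outliers_per_group = 0, n_de_transcripts = 25,
                    n_outlier_de_transcripts = 10)
  ds <- simulate_expression(cfg, seed = 68)
  perf <- cv_evaluate(ds, "rf", n_cv_runs = 3, gene_grid = c(10, 20),
                      rf_trees = 100, seed = 6)
  expect_true(all(!is.na(perf$accuracy)))
  expect_true(all(perf$brier >= 0 & perf$brier <= 2))
  expect_true(all(is.na(perf$sensitivity)))
  expect_true(all(is.na(perf$ppv)))
})

test_that("cv_evaluate validates its configuration", {
  ds <- separable_ds(seed = 69)
  expect_error(cv_evaluate(ds, "svm", train_fraction = 1),
               class = "outlierboot_error_input")
  expect_error(cv_evaluate(ds, "svm", gene_grid = c(0, 10)),
               class = "outlierboot_error_input")
  expect_error(cv_evaluate(ds, "svm", gene_grid = 10000),
               class = "outlierboot_error_input")
})

test_that("run_strategies evaluates A and B on the right sample subsets", {
  ds <- small_sim(seed = 70)
  res <- run_strategies(ds, c("A", "B"), classifier = "lda",
                        n_cv_runs = 3, gene_grid = c(10, 20), seed = 7)
  expect_s3_class(res, "performance_table")
  expect_setequal(unique(res$strategy), c("A", "B"))
  removed <- attr(res, "removed")
  expect_setequal(removed$B,
                  ds$samples$sample_id[ds$samples$is_true_outlier])
})

test_that("strategy B requires ground truth and cannot empty a group", {
  expr <- matrix(rnorm(40 * 12), 40, 12,
                 dimnames = list(sprintf("t%02d", 1:40), sprintf("s%02d", 1:12)))
  meta <- tibble::tibble(sample_id = colnames(expr),
                         group = rep(c("G1", "G2"), each = 6))
  ds_no_truth <- expression_dataset(expr, meta)
  expect_error(run_strategies(ds_no_truth, "B", classifier = "lda"),
               class = "outlierboot_error_input")
  meta$is_true_outlier <- c(rep(TRUE, 6), rep(FALSE, 6))
  ds_all_out <- expression_dataset(expr, meta)
  expect_error(run_strategies(ds_all_out, "B", classifier = "lda",
                              n_cv_runs = 2, gene_grid = 5),
               class = "outlierboot_error_input")
})

test_that("a strategy comparison against itself overlaps completely", {
  ds <- small_sim(seed = 71)
  ov <- de_overlap_report(ds, c("A", "A"), top_n = 25, n_cv_runs = 5, seed = 8)
  expect_equal(ov$pct_overlap, 100)
  expect_equal(ov$n_overlap, 25)
  fr <- ov$frequencies
  expect_true(all(fr$freq_1 >= 0 & fr$freq_1 <= 5))
  expect_true(all(fr$freq_2 >= 0 & fr$freq_2 <= 5))
  expect_error(de_overlap_report(ds, c("A", "B"), top_n = 10000),
               class = "outlierboot_error_input")
  expect_output(print(ov), "overlap_report")
})

test_that("autoplot methods return ggplot objects for every result type", {
  set.seed(72)
  bp <- detect_outliers_bagplot(matrix(rnorm(40), 20, 2))
  expect_s3_class(ggplot2::autoplot(bp), "ggplot")
  ds <- small_sim(seed = 72)
  tab <- bootstrap_outlier_probabilities(ds, n_runs = 8, seed = 9)
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
  perf <- run_strategies(ds, c("A", "B"), classifier = "lda",
                         n_cv_runs = 3, gene_grid = c(10, 20), seed = 10)
  expect_s3_class(ggplot2::autoplot(perf), "ggplot")
})

test_that("performance tables tidy and glance cleanly", {
  ds <- separable_ds(seed = 73)
  perf <- cv_evaluate(ds, "svm", n_cv_runs = 3, gene_grid = c(5, 10), seed = 11)
  td <- tidy(perf)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("classifier", "n_genes", "accuracy", "brier") %in% names(td)))
  gl <- glance(perf)
  expect_equal(gl$n_gene_settings, 2)
  expect_equal(gl$best_accuracy, max(perf$accuracy))
})
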