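#' Brier score
#'
#' Mean squared difference between the true class indicator and the
#' predicted probability of the positive class.
#'
#' @param truth Logical (or 0/1) vector: is the sample the positive class?
#' @param prob Predicted probability of the positive class, in \[0, 1\].
#'
#' @return A number in \[0, 1\] for two classes.
#' @export
#' @examples
#' brier_score(c(TRUE, FALSE), c(1, 0))    # 0
#' brier_score(c(TRUE, FALSE), c(0.5, 0.5))  # 0.25
brier_score <- function(truth, prob) {
  if (length(truth) != length(prob)) ob_abort("lengths differ", "input")
  if (any(prob < 0 | prob > 1)) ob_abort("probabilities must be in [0, 1]", "input")
  mean((as.numeric(truth) - prob)^2)
}

# multiclass Brier: mean over samples of the summed squared differences
# between the one-hot truth and the probability vector (range [0, 2])
brier_score_multiclass <- function(truth, prob) {
  truth <- factor(truth, levels = colnames(prob))
  onehot <- outer(as.integer(truth), seq_len(ncol(prob)), `==`) * 1
  mean(rowSums((onehot - prob)^2))
}

#' Binary confusion-matrix metrics
#'
#' Standard contingency ratios for a binary classification. Ratios with a
#' zero denominator are reported as `NA`.
#'
#' @param truth,pred Factors (or vectors) of true and predicted labels.
#' @param positive The positive class label.
#'
#' @return A tibble with one row: `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
#' @examples
#' confusion_metrics(rep(c("a", "b"), c(5, 5)),
#'                   c(rep("a", 3), rep("b", 2), rep("a", 1), rep("b", 4)), "a")
confusion_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) == 0) ob_abort("empty input", "input")
  if (length(truth) != length(pred)) ob_abort("lengths differ", "input")
  labs <- union(unique(truth), unique(pred))
  if (length(labs) > 2) ob_abort("inputs are not binary", "input")
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Cross-validated classifier evaluation with incremental feature selection
#'
#' Repeats, `n_cv_runs` times: draw a random training subset (fraction
#' `train_fraction`, without replacement, unstratified by default), rank the
#' transcripts by differential expression on the training split only, and
#' for each feature count in `gene_grid` fit the classifier on the top-ranked
#' transcripts and score the hold-out samples. Metrics are averaged over
#' runs; standard errors are across-run standard deviations divided by the
#' square root of the number of contributing runs.
#'
#' For two study groups the positive class is the first factor level and
#' accuracy, Brier score, sensitivity, specificity, PPV and NPV are
#' reported; with more groups only accuracy and the multiclass Brier score
#' are reported.
#'
#' @param ds An `expression_dataset`.
#' @param classifier `"svm"`, `"rf"` or `"lda"`.
#' @param n_cv_runs Number of cross-validation (bootstrap-validation) runs.
#' @param train_fraction Fraction of samples used for training.
#' @param gene_grid Integer vector of feature-set sizes.
#' @param svm_cost SVM cost of constraints violation (linear kernel).
#' @param rf_trees Number of random-forest trees.
#' @param select_on_full If `TRUE`, transcripts are ranked once on the full
#'   dataset instead of per training split (the optimistic variant).
#' @param stratified If `TRUE`, the training subset is drawn within groups.
#' @param seed Integer seed.
#' @param max_redraws Redraw limit for training splits missing a class.
#'
#' @return A tibble of class `performance_table`, one row per `n_genes`,
#'   with `<metric>` / `<metric>_se` columns. Attribute `runs` holds the
#'   per-run raw metrics; attribute `top_features` the per-run list of
#'   selected transcript ids at the largest grid value.
#' @export
cv_evaluate <- function(ds,
                        classifier = c("svm", "rf", "lda"),
                        n_cv_runs = 100,
                        train_fraction = 2 / 3,
                        gene_grid = seq(10, 200, by = 10),
                        svm_cost = 10,
                        rf_trees = 500,
                        select_on_full = FALSE,
                        stratified = FALSE,
                        seed = NULL,
                        max_redraws = 10) {
  stopifnot(inherits(ds, "expression_dataset"))
  classifier <- match.arg(classifier)
  if (train_fraction <= 0 || train_fraction >= 1) {
    ob_abort("train_fraction must be in (0, 1)", "input")
  }
  groups <- droplevels(ds$samples$group)
  if (nlevels(groups) < 2 || any(table(groups) < 3)) {
    ob_abort("need >= 2 groups with >= 3 samples each", "input")
  }
  gene_grid <- sort(unique(as.integer(gene_grid)))
  if (any(gene_grid < 1) || any(gene_grid > nrow(ds$expr))) {
    ob_abort("gene_grid values must lie in [1, n_transcripts]", "input")
  }
  n <- ncol(ds$expr)
  n_train <- round(train_fraction * n)
  binary <- nlevels(groups) == 2
  positive <- levels(groups)[1]
  if (!is.null(seed)) set.seed(seed)

  full_ranking <- if (select_on_full) rank_features(ds$expr, groups) else NULL

  draw_split <- function() {
    for (i in seq_len(max_redraws + 1)) {
      tr <- if (stratified) {
        unlist(lapply(split(seq_len(n), groups), function(ii) {
          sample(ii, round(train_fraction * length(ii)))
        }), use.names = FALSE)
      } else {
        sample.int(n, n_train)
      }
      if (nlevels(droplevels(groups[tr])) == nlevels(groups)) return(tr)
      message("training split lacked a class; redrawing")
    }
    ob_abort("could not draw a training split containing every class", "split")
  }

  run_rows <- vector("list", n_cv_runs)
  top_features <- vector("list", n_cv_runs)
  for (run in seq_len(n_cv_runs)) {
    tr <- draw_split()
    te <- setdiff(seq_len(n), tr)
    ranking <- if (select_on_full) full_ranking else {
      rank_features(ds$expr[, tr, drop = FALSE], groups[tr])
    }
    feats_all <- top_n_transcripts(ranking, max(gene_grid))
    top_features[[run]] <- feats_all
    y_tr <- droplevels(groups[tr])
    y_te <- groups[te]
    rows <- purrr::map(gene_grid, function(ng) {
      feats <- feats_all[seq_len(ng)]
      xt <- t(ds$expr[feats, tr, drop = FALSE])
      xe <- t(ds$expr[feats, te, drop = FALSE])
      pr <- fit_predict(classifier, xt, y_tr, xe,
                        svm_cost = svm_cost, rf_trees = rf_trees)
      if (binary) {
        cm <- confusion_metrics(y_te, pr$class, positive)
        cm$brier <- brier_score(y_te == positive, pr$prob[, positive])
      } else {
        cm <- tibble(accuracy = mean(as.character(pr$class) == as.character(y_te)),
                     sensitivity = NA_real_, specificity = NA_real_,
                     ppv = NA_real_, npv = NA_real_)
        cm$brier <- brier_score_multiclass(y_te, pr$prob)
      }
      cm$n_genes <- ng
      cm
    })
    run_rows[[run]] <- purrr::list_rbind(rows)
    run_rows[[run]]$run <- run
  }
  runs <- purrr::list_rbind(run_rows)

  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  }
  metrics <- c("accuracy", "brier", "sensitivity", "specificity", "ppv", "npv")
  perf <- runs |>
    dplyr::group_by(.data$n_genes) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE), se = ~se(.x)),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
  names(perf) <- sub("_mean$", "", names(perf))
  perf$classifier <- classifier
  perf <- dplyr::relocate(perf, "classifier")
  structure(perf, class = c("performance_table", class(perf)),
            runs = runs, top_features = top_features)
}

#' Evaluate outlier-handling strategies A, B and C
#'
#' Compares cross-validated classifier performance for up to three
#' sample-handling strategies: **A** keeps all samples, **B** removes the
#' known (simulated) outliers, and **C** removes the samples whose bootstrap
#' outlier probability is significantly above 0.5 (the outlier table is
#' computed once, on the full dataset). When no sample is significant,
#' strategy C runs on the same data as strategy A and reproduces its rows
#' exactly.
#'
#' @param ds An `expression_dataset`.
#' @param strategies Subset of `c("A", "B", "C")`.
#' @param detector,n_runs,factor,alpha,n_pcs,boot_seed Passed to
#'   [bootstrap_outlier_probabilities()] (strategy C only).
#' @param ... Passed to [cv_evaluate()] (classifier, grid, seed, ...).
#'
#' @return A `performance_table` with a leading `strategy` column; the
#'   outlier table (when computed) is in attribute `outlier_table`, the
#'   removed sample ids per strategy in attribute `removed`.
#' @export
run_strategies <- function(ds,
                           strategies = c("A", "B", "C"),
                           detector = "bagplot",
                           n_runs = 100,
                           factor = 2,
                           alpha = 0.05,
                           n_pcs = 2,
                           boot_seed = NULL,
                           ...) {
  stopifnot(inherits(ds, "expression_dataset"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (length(strategies) == 0) ob_abort("empty strategy list", "input")
  if ("B" %in% strategies && all(is.na(ds$samples$is_true_outlier))) {
    ob_abort("strategy B requires known true outliers", "input")
  }
  tab <- NULL
  removed <- list()
  out <- list()
  for (s in strategies) {
    sub <- switch(s,
      A = ds,
      B = {
        removed$B <- ds$samples$sample_id[ds$samples$is_true_outlier %in% TRUE]
        filter_samples(ds, !(ds$samples$sample_id %in% removed$B))
      },
      C = {
        if (is.null(tab)) {
          tab <- bootstrap_outlier_probabilities(
            ds, detector = detector, n_runs = n_runs, factor = factor,
            alpha = alpha, n_pcs = n_pcs, seed = boot_seed
          )
        }
        removed$C <- significant_outliers(tab, alpha = alpha)
        if (length(removed$C) == 0) ds
        else filter_samples(ds, !(ds$samples$sample_id %in% removed$C))
      }
    )
    if (nlevels(droplevels(sub$samples$group)) < nlevels(droplevels(ds$samples$group))) {
      ob_abort(sprintf("strategy %s removed an entire study group", s), "input")
    }
    perf <- cv_evaluate(sub, ...)
    perf$strategy <- s
    out[[s]] <- dplyr::relocate(as_tibble(as.data.frame(perf)), "strategy")
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("performance_table", class(res)),
            outlier_table = tab, removed = removed)
}

#' @rdname tidy-outlierboot
#' @method tidy performance_table
#' @export
tidy.performance_table <- function(x, ...) as_tibble(as.data.frame(x))

#' @rdname tidy-outlierboot
#' @method glance performance_table
#' @export
glance.performance_table <- function(x, ...) {
  tibble(
    n_rows = nrow(x),
    n_gene_settings = length(unique(x$n_genes)),
    best_accuracy = max(x$accuracy, na.rm = TRUE),
    best_n_genes = x$n_genes[which.max(x$accuracy)]
  )
}

#' Overlap of cross-validated top differentially expressed genes
#'
#' For each of two outlier-handling strategies, counts over `n_cv_runs`
#' cross-validation runs how often each transcript appears among the top
#' `top_n` differentially expressed transcripts of the training split, then
#' compares the two strategies' top-`top_n`-by-frequency lists: intersection
#' size and percentage, plus per-transcript frequency differences (the
#' rank-divergence view).
#'
#' @param ds An `expression_dataset`.
#' @param strategy_pair Two of `"A"`, `"B"`, `"C"`.
#' @param top_n Size of the per-run and final top lists.
#' @param n_cv_runs,train_fraction,seed As in [cv_evaluate()].
#' @param detector,n_runs,boot_seed Bootstrap settings for strategy C.
#'
#' @return An object of class `overlap_report`: list with `frequencies`
#'   (tibble: `transcript_id`, `freq_1`, `freq_2`, `freq_diff`), the two
#'   top-frequency id lists, `n_overlap` and `pct_overlap`.
#' @export
de_overlap_report <- function(ds,
                              strategy_pair = c("A", "C"),
                              top_n = 200,
                              n_cv_runs = 100,
                              train_fraction = 2 / 3,
                              seed = NULL,
                              detector = "bagplot",
                              n_runs = 100,
                              boot_seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), length(strategy_pair) == 2)
  if (top_n > nrow(ds$expr)) ob_abort("top_n exceeds transcript count", "input")
  tab <- NULL
  subset_for <- function(s) {
    switch(s,
      A = ds,
      B = filter_samples(ds, !(ds$samples$is_true_outlier %in% TRUE)),
      C = {
        if (is.null(tab)) {
          tab <<- bootstrap_outlier_probabilities(ds, detector = detector,
                                                  n_runs = n_runs,
                                                  seed = boot_seed)
        }
        sig <- significant_outliers(tab)
        if (length(sig) == 0) ds
        else filter_samples(ds, !(ds$samples$sample_id %in% sig))
      },
      ob_abort(sprintf("unknown strategy '%s'", s), "input")
    )
  }
  freq_for <- function(sub) {
    groups <- droplevels(sub$samples$group)
    n <- ncol(sub$expr)
    n_train <- round(train_fraction * n)
    counts <- setNames(integer(nrow(sub$expr)), rownames(sub$expr))
    for (run in seq_len(n_cv_runs)) {
      repeat {
        tr <- sample.int(n, n_train)
        if (nlevels(droplevels(groups[tr])) == nlevels(groups)) break
      }
      ranking <- rank_features(sub$expr[, tr, drop = FALSE], groups[tr])
      top <- top_n_transcripts(ranking, top_n)
      counts[top] <- counts[top] + 1L
    }
    counts
  }
  if (!is.null(seed)) set.seed(seed)
  sub1 <- subset_for(strategy_pair[1])
  sub2 <- subset_for(strategy_pair[2])
  # reset the stream per strategy so both use the same CV split sequence
  # (paired comparison; identical strategies then overlap completely)
  if (!is.null(seed)) set.seed(seed)
  f1 <- freq_for(sub1)
  if (!is.null(seed)) set.seed(seed)
  f2 <- freq_for(sub2)

  top_by_freq <- function(f) {
    names(f)[order(-f, names(f))][seq_len(top_n)]
  }
  t1 <- top_by_freq(f1)
  t2 <- top_by_freq(f2)
  inter <- intersect(t1, t2)
  structure(
    list(
      frequencies = tibble(
        transcript_id = names(f1),
        freq_1 = as.integer(f1),
        freq_2 = as.integer(f2),
        freq_diff = as.integer(f2) - as.integer(f1)
      ),
      strategies = strategy_pair,
      top_1 = t1, top_2 = t2,
      n_overlap = length(inter),
      pct_overlap = 100 * length(inter) / top_n,
      top_n = top_n, n_cv_runs = n_cv_runs
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> strategies %s vs %s: %d / %d top transcripts shared (%.1f%%)\n",
    x$strategies[1], x$strategies[2], x$n_overlap, x$top_n, x$pct_overlap))
  invisible(x)
}
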