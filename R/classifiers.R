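# Classifier backends used by cv_evaluate(). Each returns, for the test
# samples, the predicted class and a class-probability matrix whose columns
# follow levels(y_train).

fit_predict <- function(classifier, x_train, y_train, x_test,
                        svm_cost = 10, rf_trees = 500) {
  y_train <- droplevels(factor(y_train))
  switch(classifier,
    svm = fit_predict_svm(x_train, y_train, x_test, cost = svm_cost),
    rf = fit_predict_rf(x_train, y_train, x_test, ntree = rf_trees),
    lda = fit_predict_lda(x_train, y_train, x_test),
    ob_abort(sprintf("unknown classifier '%s'", classifier), "input")
  )
}

fit_predict_svm <- function(x_train, y_train, x_test, cost = 10) {
  # drop constant predictors: svm's internal scaling cannot handle them
  keep <- apply(x_train, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) keep[1] <- TRUE
  fit <- e1071::svm(x_train[, keep, drop = FALSE], y_train,
                    kernel = "linear", cost = cost, probability = TRUE)
  pr <- predict(fit, x_test[, keep, drop = FALSE], probability = TRUE)
  prob <- attr(pr, "probabilities")[, levels(y_train), drop = FALSE]
  list(class = factor(as.character(pr), levels = levels(y_train)), prob = prob)
}

fit_predict_rf <- function(x_train, y_train, x_test, ntree = 500) {
  fit <- randomForest::randomForest(
    x_train, y_train, ntree = ntree,
    mtry = max(1, floor(sqrt(ncol(x_train))))
  )
  prob <- predict(fit, x_test, type = "prob")[, levels(y_train), drop = FALSE]
  cls <- predict(fit, x_test, type = "response")
  list(class = cls, prob = prob)
}

fit_predict_lda <- function(x_train, y_train, x_test) {
  p <- ncol(x_train)
  n <- nrow(x_train)
  g <- nlevels(y_train)
  if (p < n - g) {
    fit <- tryCatch(MASS::lda(x_train, grouping = y_train),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      pr <- predict(fit, x_test)
      prob <- pr$posterior[, levels(y_train), drop = FALSE]
      return(list(class = pr$class, prob = prob))
    }
  }
  fit_predict_rlda(x_train, y_train, x_test)
}

# Regularized LDA for n <= p or a singular pooled covariance: the pooled
# covariance is shrunk toward a scaled identity with a Ledoit-Wolf-style
# intensity estimated from the within-class residuals.
fit_predict_rlda <- function(x_train, y_train, x_test) {
  lv <- levels(y_train)
  p <- ncol(x_train)
  n <- nrow(x_train)
  mu <- t(vapply(lv, function(cl) colMeans(x_train[y_train == cl, , drop = FALSE]),
                 numeric(p)))
  Z <- x_train - mu[as.integer(y_train), , drop = FALSE]
  S <- crossprod(Z) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  # dispersion of the per-sample outer products around S
  zz2 <- rowSums(Z^2)
  b2bar <- (sum(zz2^2) - 2 * sum((Z %*% S) * Z) + n * sum(S^2)) / n^2 / p
  b2 <- min(b2bar, d2)
  gamma <- if (d2 > 0) b2 / d2 else 1
  Sstar <- (1 - gamma) * S + gamma * diag(m, p)
  ch <- chol(Sstar + diag(1e-10 * max(m, 1), p))
  prior <- as.numeric(table(y_train)[lv]) / n
  disc <- vapply(seq_along(lv), function(i) {
    w <- backsolve(ch, forwardsolve(t(ch), t(x_test) - mu[i, ]))
    -0.5 * colSums(w^2) + log(prior[i])
  }, numeric(nrow(x_test)))
  disc <- matrix(disc, nrow = nrow(x_test))
  disc <- disc - apply(disc, 1, max)
  prob <- exp(disc) / rowSums(exp(disc))
  colnames(prob) <- lv
  cls <- factor(lv[max.col(prob, ties.method = "first")], levels = lv)
  list(class = cls, prob = prob)
}
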