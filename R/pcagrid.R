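#' Projection-pursuit search for a robust principal direction
#'
#' Finds the unit vector maximizing a robust scale (the median absolute
#' deviation, scaled for Gaussian consistency) of the projected data, by an
#' iterative grid search: starting from the coordinate axis of largest MAD,
#' each sweep scans a grid of angles in the plane spanned by the current best
#' direction and each coordinate axis, and successive sweeps halve the
#' angular search range. A final golden-section polish refines the last grid
#' step. The search is deterministic.
#'
#' @param data Numeric samples x features matrix, already centered (the
#'   caller typically subtracts the coordinate-wise median).
#' @param n_angles Grid points per sweep over the angular range.
#' @param n_refinements Number of range-halving sweeps.
#'
#' @return A unit-length numeric vector (length = `ncol(data)`).
#' @export
grid_direction <- function(data, n_angles = 90, n_refinements = 10) {
  X <- as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) ob_abort("need at least 3 samples", "input")
  axis_mads <- vapply(seq_len(p), function(j) mad(X[, j]), numeric(1))
  if (all(axis_mads == 0) && all(X == 0)) {
    ob_abort("zero-variance data: no direction is defined", "degenerate_direction")
  }
  a <- numeric(p)
  a[which.max(axis_mads)] <- 1
  best <- mad(as.numeric(X %*% a))

  obj <- function(gamma, xa, xb) mad(cos(gamma) * xa + sin(gamma) * xb)

  for (s in seq_len(n_refinements)) {
    w <- (pi / 2) / 2^(s - 1)
    gammas <- -w + (seq_len(n_angles) - 1) * (2 * w / n_angles)
    for (j in seq_len(p)) {
      b <- numeric(p)
      b[j] <- 1
      b <- b - sum(b * a) * a
      nb <- sqrt(sum(b^2))
      if (nb < 1e-12) next
      b <- b / nb
      xa <- as.numeric(X %*% a)
      xb <- as.numeric(X %*% b)
      vals <- vapply(gammas, obj, numeric(1), xa = xa, xb = xb)
      i <- which.max(vals)
      if (vals[i] > best) {
        g <- gammas[i]
        a <- cos(g) * a + sin(g) * b
        a <- a / sqrt(sum(a^2))
        best <- vals[i]
      }
    }
  }

  # polish: 1-D optimisation around the final direction in each axis plane
  step <- (pi / 2) / 2^(n_refinements - 1) / n_angles * 2
  for (j in seq_len(p)) {
    b <- numeric(p)
    b[j] <- 1
    b <- b - sum(b * a) * a
    nb <- sqrt(sum(b^2))
    if (nb < 1e-12) next
    b <- b / nb
    xa <- as.numeric(X %*% a)
    xb <- as.numeric(X %*% b)
    op <- optimize(obj, c(-step, step), xa = xa, xb = xb,
                   maximum = TRUE, tol = 1e-10)
    if (op$objective > best) {
      g <- op$maximum
      a <- cos(g) * a + sin(g) * b
      a <- a / sqrt(sum(a^2))
      best <- op$objective
    }
  }

  # deterministic sign: largest-magnitude coordinate is positive
  i <- which.max(abs(a))
  if (a[i] < 0) a <- -a
  a
}

#' Robust principal component analysis by grid search
#'
#' Computes `k` robust principal components sequentially: the data are
#' centered by the coordinate-wise median, the first loading maximizes the
#' MAD of the projections ([grid_direction()]), and each further loading is
#' found in the orthogonal complement of the previous ones. The robust scale
#' of each component is the MAD of its scores.
#'
#' @param data Numeric samples x features matrix (or data frame).
#' @param k Number of components.
#' @param n_angles,n_refinements Grid-search parameters, see
#'   [grid_direction()].
#'
#' @return An object of class `robust_pca`: list with `loadings`
#'   (features x k, orthonormal), `center`, `scales` (per component),
#'   `scores` (samples x k matrix), and the sample ids.
#' @export
robust_pca <- function(data, k = 2, n_angles = 90, n_refinements = 10) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (k > min(n - 1, p)) ob_abort("k exceeds min(samples - 1, features)", "input")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  center <- apply(X, 2, median)
  Xc <- sweep(X, 2, center)

  loadings <- matrix(0, nrow = p, ncol = k)
  for (c_i in seq_len(k)) {
    if (c_i == 1) {
      Q <- diag(p)
    } else {
      # orthonormal basis of the complement of the found loadings
      qr_prev <- qr(loadings[, seq_len(c_i - 1), drop = FALSE])
      Q <- qr.Q(qr_prev, complete = TRUE)[, c_i:p, drop = FALSE]
    }
    Y <- Xc %*% Q
    v <- grid_direction(Y, n_angles = n_angles, n_refinements = n_refinements)
    loadings[, c_i] <- Q %*% v
  }
  scores <- Xc %*% loadings
  colnames(scores) <- colnames(loadings) <- paste0("RPC", seq_len(k))
  rownames(scores) <- ids
  scales <- apply(scores, 2, mad)
  structure(list(loadings = loadings, center = center, scales = scales,
                 scores = scores, sample_ids = ids),
            class = "robust_pca")
}

#' PCA-Grid outlier detection
#'
#' Runs [robust_pca()] and flags samples whose robustly standardized score
#' distance exceeds a chi-square cutoff: the score distance of sample *i* is
#' \eqn{\sqrt{\sum_j (s_{ij}/\hat\sigma_j)^2}} with \eqn{\hat\sigma_j} the
#' MAD of component *j*, and the cutoff is
#' \eqn{\sqrt{\chi^2_{k;q}}} at quantile `quantile`.
#'
#' @inheritParams robust_pca
#' @param quantile Chi-square quantile used as the flagging cutoff.
#'
#' @return An object of class `robust_pca` with additional elements
#'   `distances`, `cutoff`, `quantile` and a logical `outlier` flag per
#'   sample.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 4), 100, 4)
#' x[1, ] <- x[1, ] + 20
#' res <- detect_outliers_pcagrid(x)
#' which(res$outlier)
detect_outliers_pcagrid <- function(data, k = 2, quantile = 0.975,
                                    n_angles = 90, n_refinements = 10) {
  fit <- robust_pca(data, k = k, n_angles = n_angles,
                    n_refinements = n_refinements)
  if (any(fit$scales <= 0)) {
    ob_abort("a component has zero robust scale (MAD)", "degenerate_scale")
  }
  z <- sweep(fit$scores, 2, fit$scales, "/")
  fit$distances <- sqrt(rowSums(z^2))
  fit$cutoff <- sqrt(qchisq(quantile, df = k))
  fit$quantile <- quantile
  fit$outlier <- fit$distances > fit$cutoff
  fit
}

#' @export
print.robust_pca <- function(x, ...) {
  cat(sprintf("<robust_pca> %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$outlier)) {
    cat(sprintf("  %d samples flagged beyond cutoff %.3f\n",
                sum(x$outlier), x$cutoff))
  }
  invisible(x)
}

#' Tidiers for outlierboot result objects
#'
#' `tidy()` returns a per-point / per-sample tibble; `glance()` a one-row
#' summary.
#'
#' @param x A result object (`bagplot_result`, `robust_pca`,
#'   `outlier_table`).
#' @param ... Unused.
#' @name tidy-outlierboot
#' @return A tibble.
#' @method tidy robust_pca
#' @export
tidy.robust_pca <- function(x, ...) {
  out <- tibble(id = x$sample_ids)
  out <- dplyr::bind_cols(out, as_tibble(x$scores))
  if (!is.null(x$distances)) {
    out$distance <- x$distances
    out$outlier <- x$outlier
  }
  out
}
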