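#' Configuration for simulated expression data
#'
#' Bundles the parameters of the expression simulator into a validated list.
#' The simulator draws log2-scale expression values from normal distributions:
#' every transcript gets a baseline mean, a subset of transcripts receives a
#' nonzero log2 fold change between study groups, and a small number of
#' outlier samples per group draw from means shifted on a second, independent
#' transcript subset.
#'
#' @param n_transcripts Number of transcripts (rows) to simulate.
#' @param groups Number of study groups (2 or 4).
#' @param samples_per_group Regular (non-outlier) samples per group.
#' @param outliers_per_group Planted outlier samples per group.
#' @param n_de_transcripts Number of transcripts with a nonzero between-group
#'   log2 fold change (per non-reference group).
#' @param n_outlier_de_transcripts Number of transcripts whose means are
#'   shifted for the outlier samples of a group.
#' @param baseline_mean_range Range of the uniform law for baseline means
#'   \eqn{\mu_t} (log2 scale).
#' @param lfc_range Magnitude range of the uniform law for nonzero log2 fold
#'   changes \eqn{\lambda_t}; the sign is random.
#' @param noise_sd Standard deviation of the Gaussian expression noise,
#'   shared across transcripts (log2 scale).
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_expression()]
#' @export
#' @examples
#' cfg <- sim_config(groups = 2)
#' cfg$samples_per_group
sim_config <- function(n_transcripts = 1000,
                       groups = 2,
                       samples_per_group = 50,
                       outliers_per_group = 5,
                       n_de_transcripts = 100,
                       n_outlier_de_transcripts = 50,
                       baseline_mean_range = c(4, 12),
                       lfc_range = c(0.8, 2.0),
                       noise_sd = 1) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    groups = as.integer(groups),
    samples_per_group = as.integer(samples_per_group),
    outliers_per_group = as.integer(outliers_per_group),
    n_de_transcripts = as.integer(n_de_transcripts),
    n_outlier_de_transcripts = as.integer(n_outlier_de_transcripts),
    baseline_mean_range = as.numeric(baseline_mean_range),
    lfc_range = as.numeric(lfc_range),
    noise_sd = as.numeric(noise_sd)
  )
  if (cfg$n_transcripts < 1 || cfg$samples_per_group < 1) {
    ob_abort("n_transcripts and samples_per_group must be positive", "config")
  }
  if (!cfg$groups %in% c(2L, 4L)) {
    ob_abort("groups must be 2 or 4", "config")
  }
  if (cfg$outliers_per_group < 0) {
    ob_abort("outliers_per_group must be non-negative", "config")
  }
  if (cfg$n_de_transcripts > cfg$n_transcripts ||
      cfg$n_outlier_de_transcripts > cfg$n_transcripts) {
    ob_abort("DE transcript counts cannot exceed n_transcripts", "config")
  }
  if (cfg$noise_sd < 0) ob_abort("noise_sd must be non-negative", "config")
  if (length(cfg$lfc_range) != 2 || any(cfg$lfc_range < 0) ||
      diff(cfg$lfc_range) < 0) {
    ob_abort("lfc_range must be an increasing non-negative pair", "config")
  }
  structure(cfg, class = "sim_config")
}

#' Shift a group mean by a log2 fold change
#'
#' @param mu1 Baseline (first-group) mean, strictly positive.
#' @param lfc Log2 fold change.
#'
#' @return `mu1 * 2^lfc`.
#' @export
#' @examples
#' shifted_mean(5, 1)  # 10
shifted_mean <- function(mu1, lfc) {
  if (any(!is.finite(mu1)) || any(mu1 <= 0)) {
    ob_abort("mu1 must be positive and finite", "invalid_parameter")
  }
  mu1 * 2^lfc
}

# draw nonzero log2 fold changes: magnitude uniform in range, random sign
draw_lfc <- function(n, lfc_range) {
  runif(n, lfc_range[1], lfc_range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate an expression dataset with planted outliers
#'
#' Generates a transcripts-by-samples matrix of log2-scale expression values
#' for `groups` study groups. Baseline means are uniform on
#' `baseline_mean_range`; for each non-reference group an independent subset
#' of `n_de_transcripts` transcripts gets group means
#' \eqn{\mu_{t2} = \mu_{t1} 2^{\lambda_t}}. Each group additionally contains
#' `outliers_per_group` outlier samples whose means are shifted, in the same
#' multiplicative way, on an independently chosen subset of
#' `n_outlier_de_transcripts` transcripts. Values are drawn from normal
#' distributions with standard deviation `noise_sd`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds reproduce the dataset exactly.
#'
#' @return A list of class `expression_dataset` with elements
#'   \describe{
#'     \item{expr}{numeric matrix, transcripts x samples, with dimnames.}
#'     \item{samples}{tibble with `sample_id`, `group`, `is_true_outlier`.}
#'     \item{group_means}{transcripts x groups matrix of the configured
#'       regular-sample means (simulation ground truth).}
#'     \item{de_transcripts, outlier_de_transcripts}{lists, per group, of the
#'       transcript ids carrying between-group and outlier mean shifts.}
#'   }
#' @export
#' @examples
#' ds <- simulate_expression(sim_config(n_transcripts = 50,
#'   samples_per_group = 10, outliers_per_group = 2,
#'   n_de_transcripts = 10, n_outlier_de_transcripts = 5), seed = 1)
#' dim(ds$expr)
simulate_expression <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$n_transcripts
  k <- config$groups
  n_reg <- config$samples_per_group
  n_out <- config$outliers_per_group

  transcript_ids <- sprintf("T%04d", seq_len(d))
  mu <- runif(d, config$baseline_mean_range[1], config$baseline_mean_range[2])

  group_means <- matrix(mu, nrow = d, ncol = k,
                        dimnames = list(transcript_ids, paste0("G", seq_len(k))))
  de_sets <- vector("list", k)
  names(de_sets) <- colnames(group_means)
  for (g in seq_len(k)[-1]) {
    idx <- sample.int(d, config$n_de_transcripts)
    lfc <- draw_lfc(config$n_de_transcripts, config$lfc_range)
    group_means[idx, g] <- shifted_mean(group_means[idx, g], lfc)
    de_sets[[g]] <- transcript_ids[sort(idx)]
  }
  de_sets[[1]] <- character(0)

  # outlier mean vectors: per group, shift an independent transcript subset
  outlier_means <- matrix(NA_real_, nrow = d, ncol = k)
  out_sets <- vector("list", k)
  names(out_sets) <- colnames(group_means)
  for (g in seq_len(k)) {
    out_sets[[g]] <- character(0)
    if (n_out > 0) {
      idx <- sample.int(d, config$n_outlier_de_transcripts)
      lfc <- draw_lfc(config$n_outlier_de_transcripts, config$lfc_range)
      om <- group_means[, g]
      om[idx] <- shifted_mean(om[idx], lfc)
      outlier_means[, g] <- om
      out_sets[[g]] <- transcript_ids[sort(idx)]
    }
  }

  n_per_group <- n_reg + n_out
  n_total <- k * n_per_group
  expr <- matrix(NA_real_, nrow = d, ncol = n_total)
  group <- character(n_total)
  is_out <- logical(n_total)
  col <- 0L
  for (g in seq_len(k)) {
    for (j in seq_len(n_per_group)) {
      col <- col + 1L
      outlier <- j > n_reg
      m <- if (outlier) outlier_means[, g] else group_means[, g]
      expr[, col] <- rnorm(d, mean = m, sd = config$noise_sd)
      group[col] <- colnames(group_means)[g]
      is_out[col] <- outlier
    }
  }
  sample_ids <- sprintf("S%03d", seq_len(n_total))
  dimnames(expr) <- list(transcript_ids, sample_ids)

  structure(
    list(
      expr = expr,
      samples = tibble(
        sample_id = sample_ids,
        group = factor(group),
        is_true_outlier = is_out
      ),
      group_means = group_means,
      de_transcripts = de_sets,
      outlier_de_transcripts = out_sets,
      config = config
    ),
    class = "expression_dataset"
  )
}

#' Construct an expression dataset from a matrix and sample table
#'
#' @param expr Numeric transcripts x samples matrix with dimnames.
#' @param samples Data frame with columns `sample_id`, `group` and optionally
#'   `is_true_outlier`; `sample_id` must match `colnames(expr)`.
#'
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(expr, samples) {
  expr <- as.matrix(expr)
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    ob_abort("samples must have columns sample_id and group", "input")
  }
  if (is.null(colnames(expr)) || !identical(colnames(expr), samples$sample_id)) {
    ob_abort("colnames(expr) must equal samples$sample_id (same order)", "input")
  }
  if (anyNA(expr)) ob_abort("expression matrix contains missing values", "input")
  if (!"is_true_outlier" %in% names(samples)) samples$is_true_outlier <- NA
  samples$group <- factor(samples$group)
  structure(list(expr = expr, samples = samples), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d transcripts x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  print(table(group = x$samples$group,
              outlier = x$samples$is_true_outlier, useNA = "ifany"))
  invisible(x)
}

#' Per-transcript mean expression of a group's regular samples
#'
#' Averages, for each transcript, over the non-outlier samples of one study
#' group (all samples of the group if outlier status is unknown).
#'
#' @param ds An `expression_dataset`.
#' @param group A group label present in `ds$samples$group`.
#'
#' @return A named numeric vector (one value per transcript).
#' @export
empirical_group_means <- function(ds, group) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!group %in% levels(ds$samples$group)) {
    ob_abort(sprintf("unknown group label '%s'", group), "input")
  }
  keep <- ds$samples$group == group &
    (is.na(ds$samples$is_true_outlier) | !ds$samples$is_true_outlier)
  if (!any(keep)) {
    ob_abort(sprintf("group '%s' has no regular samples", group), "input")
  }
  rowMeans(ds$expr[, keep, drop = FALSE])
}

#' Subset an expression dataset by sample
#'
#' @param ds An `expression_dataset`.
#' @param keep Logical vector or sample ids of the samples to keep.
#' @return An `expression_dataset` restricted to the kept samples.
#' @export
filter_samples <- function(ds, keep) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(keep)) keep <- ds$samples$sample_id %in% keep
  if (!any(keep)) ob_abort("no samples left after filtering", "input")
  out <- ds
  out$expr <- ds$expr[, keep, drop = FALSE]
  out$samples <- ds$samples[keep, ]
  out$samples$group <- droplevels(out$samples$group)
  out
}
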