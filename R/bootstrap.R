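#' Bootstrap estimation of per-sample outlier probabilities
#'
#' The core procedure: the dataset is resampled with replacement `n_runs`
#' times; in each run a classical PCA over all groups jointly reduces the
#' bootstrap dataset to `n_pcs` score dimensions, the configured detector
#' (bagplot or PCA-Grid) is applied separately to the point cloud of each
#' study group, and for every sample it is recorded whether it was present
#' in the run and whether it was flagged. The outlier probability of a
#' sample is its number of flagged runs divided by its number of occurrences;
#' an exact one-sided binomial test against probability 0.5 and a one-sided
#' Clopper-Pearson lower confidence bound quantify the evidence.
#'
#' A sample counts at most once per run for both occurrence and detection,
#' but duplicated bootstrap copies all enter the detector as (coincident)
#' points. Groups that are too small in a given run (fewer than
#' `min_group_size` distinct positions) are skipped for that run. Samples
#' never drawn in any run are reported with `occurrences = 0` and missing
#' probability, and are excluded from significance calls.
#'
#' @param ds An `expression_dataset`.
#' @param detector `"bagplot"` or `"pcagrid"`.
#' @param n_runs Number of bootstrap runs.
#' @param factor Bagplot fence inflation factor.
#' @param alpha Significance level of the binomial test.
#' @param n_pcs Number of principal components of the per-run PCA.
#' @param quantile Chi-square quantile of the PCA-Grid cutoff.
#' @param stratified If `TRUE`, resampling is done within each study group
#'   (preserving group sizes); the default resamples the whole dataset.
#' @param seed Integer seed; identical seeds reproduce the table exactly.
#' @param min_group_size Minimum per-group bootstrap size for the detector.
#'
#' @return A tibble of class `outlier_table`, one row per sample:
#'   `sample_id`, `group`, `occurrences`, `detections`, `probability`,
#'   `ci_lower`, `p_value`, `significant`. Attributes record the detector,
#'   `n_runs`, `alpha` and the number of skipped group-runs.
#' @export
#' @examples
#' ds <- simulate_expression(sim_config(n_transcripts = 100,
#'   samples_per_group = 12, outliers_per_group = 2,
#'   n_de_transcripts = 20, n_outlier_de_transcripts = 10), seed = 1)
#' tab <- bootstrap_outlier_probabilities(ds, n_runs = 20, seed = 1)
#' head(tab, 3)
bootstrap_outlier_probabilities <- function(ds,
                                            detector = c("bagplot", "pcagrid"),
                                            n_runs = 100,
                                            factor = 2,
                                            alpha = 0.05,
                                            n_pcs = 2,
                                            quantile = 0.975,
                                            stratified = FALSE,
                                            seed = NULL,
                                            min_group_size = 4) {
  stopifnot(inherits(ds, "expression_dataset"))
  detector <- match.arg(detector)
  if (n_runs < 1) ob_abort("n_runs must be at least 1", "input")
  if (alpha <= 0 || alpha >= 1) ob_abort("alpha must be in (0, 1)", "input")
  groups <- ds$samples$group
  if (nlevels(groups) < 2) ob_abort("need at least 2 study groups", "input")
  if (any(table(groups) < min_group_size)) {
    ob_abort("every group needs at least min_group_size samples", "input")
  }
  n <- ncol(ds$expr)
  ids <- ds$samples$sample_id
  if (!is.null(seed)) set.seed(seed)

  occurrences <- setNames(integer(n), ids)
  detections <- setNames(integer(n), ids)
  n_skipped <- 0L

  for (run in seq_len(n_runs)) {
    idx <- if (stratified) {
      unlist(lapply(split(seq_len(n), groups),
                    function(ii) sample(ii, length(ii), replace = TRUE)),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    ids_b <- ids[idx]
    grp_b <- groups[idx]
    present <- unique(ids_b)
    occurrences[present] <- occurrences[present] + 1L

    # classical PCA over both/all groups jointly
    scores <- prcomp(t(ds$expr[, idx, drop = FALSE]), center = TRUE,
                     scale. = FALSE, rank. = n_pcs)$x

    for (g in levels(groups)) {
      sel <- which(grp_b == g)
      if (length(sel) < min_group_size) {
        n_skipped <- n_skipped + 1L
        warn(sprintf("run %d: group %s has %d samples; skipped",
                     run, g, length(sel)))
        next
      }
      pts <- scores[sel, , drop = FALSE]
      flagged_local <- withCallingHandlers(
        if (detector == "bagplot") {
          res <- detect_outliers_bagplot(pts[, 1:2, drop = FALSE], factor = factor)
          res$points$outlier
        } else {
          res <- detect_outliers_pcagrid(pts, k = min(2L, ncol(pts)),
                                         quantile = quantile)
          res$outlier
        },
        warning = function(w) invokeRestart("muffleWarning")
      )
      hit <- unique(ids_b[sel][flagged_local])
      detections[hit] <- detections[hit] + 1L
    }
  }

  kk <- as.integer(detections)
  nn <- as.integer(occurrences)
  probability <- ifelse(nn > 0, kk / nn, NA_real_)
  ci_lower <- rep(NA_real_, n)
  p_value <- rep(NA_real_, n)
  pos <- nn > 0
  if (any(pos)) {
    ci_lower[pos] <- clopper_pearson_lower(kk[pos], nn[pos], alpha = alpha)
    p_value[pos] <- binom_pvalue_greater(kk[pos], nn[pos], p0 = 0.5)
  }
  out <- tibble(
    sample_id = ids,
    group = groups,
    occurrences = nn,
    detections = kk,
    probability = probability,
    ci_lower = ci_lower,
    p_value = p_value,
    significant = !is.na(p_value) & p_value < alpha
  )
  out <- out[order(-replace(out$probability, is.na(out$probability), -1),
                   -out$detections, out$sample_id), ]
  structure(out,
            class = c("outlier_table", class(out)),
            detector = detector, n_runs = n_runs, alpha = alpha,
            factor = factor, n_pcs = n_pcs, n_skipped = n_skipped)
}

#' @rdname tidy-outlierboot
#' @method tidy outlier_table
#' @export
tidy.outlier_table <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy-outlierboot
#' @method glance outlier_table
#' @export
glance.outlier_table <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_runs = attr(x, "n_runs"),
    detector = attr(x, "detector"),
    alpha = attr(x, "alpha"),
    n_detected_ever = sum(x$detections > 0),
    n_significant = sum(x$significant),
    n_never_drawn = sum(x$occurrences == 0)
  )
}

#' Write an outlier table as TSV
#'
#' Writes the per-sample bootstrap outlier results with the conventional
#' column set: sample id, occurrences in bootstrapping, detections as
#' outlier, outlier probability, one-sided 95% CI, and binomial p-value.
#'
#' @param table An `outlier_table`.
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_outlier_table <- function(table, path) {
  out <- tibble(
    sample_id = table$sample_id,
    occurrences_in_bootstrapping = table$occurrences,
    detected_as_outlier = table$detections,
    outlier_probability = round(table$probability, 2),
    ci_95 = ifelse(is.na(table$ci_lower), NA_character_,
                   sprintf("[%.2f, 1.00]", table$ci_lower)),
    p_value = table$p_value
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(table)
}
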