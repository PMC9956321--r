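#' Log-CPM transformation of a count matrix
#'
#' Converts raw read counts to log2 counts-per-million with a 0.5
#' pseudo-count: `log2((count + 0.5) / (library_size + 1) * 1e6)`.
#' Transcripts whose maximum counts-per-million across samples is below
#' `min_max_cpm` are dropped beforehand.
#'
#' @param counts Non-negative transcripts x samples count matrix.
#' @param min_max_cpm Filter threshold on the per-transcript maximum CPM.
#'
#' @return A numeric matrix of log2-CPM values (possibly fewer rows).
#' @export
#' @examples
#' m <- matrix(c(0, 999999), ncol = 1)
#' logcpm_transform(m, min_max_cpm = 0)[1, 1]  # about -1
logcpm_transform <- function(counts, min_max_cpm = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    ob_abort("counts must be finite and non-negative", "input")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) ob_abort("a sample column has library size 0", "input")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- apply(cpm, 1, max) >= min_max_cpm
  counts <- counts[keep, , drop = FALSE]
  log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
}

#' Two-group differential expression ranking by moderated t
#'
#' Ranks transcripts for a two-group comparison using the moderated
#' t-statistic: per-transcript residual variances are shrunk toward a common
#' prior by empirical Bayes (via the limma model fit), and transcripts are
#' ranked by ascending p-value with ties broken by descending absolute
#' statistic and then by transcript id. `method = "ordinary"` instead
#' computes the plain pooled two-sample t-statistic (no shrinkage), the
#' limiting case of zero prior degrees of freedom.
#'
#' @param expr Numeric transcripts x samples matrix of (continuous,
#'   normalized) expression values.
#' @param groups Factor or vector of two group labels, one per sample.
#' @param method `"moderated"` (default) or `"ordinary"`.
#'
#' @return A tibble of class `de_ranking` with columns `transcript_id`,
#'   `statistic`, `lfc` (mean difference, second level minus first),
#'   `p_value`, `rank`. Attributes `s2_resid`, `s2_prior`, `s2_post` and
#'   `df_prior` expose the variance-shrinkage components.
#' @export
moderated_t_rank <- function(expr, groups, method = c("moderated", "ordinary")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  groups <- factor(groups)
  if (nlevels(groups) != 2) ob_abort("groups must have exactly 2 levels", "input")
  if (any(table(groups) < 2)) {
    ob_abort("each group needs at least 2 samples", "input")
  }
  ids <- rownames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(expr)))

  design <- model.matrix(~groups)
  fit <- limma::lmFit(expr, design)
  if (method == "moderated") {
    fit <- limma::eBayes(fit)
    stat <- fit$t[, 2]
    p <- fit$p.value[, 2]
    s2_prior <- fit$s2.prior
    s2_post <- fit$s2.post
    df_prior <- fit$df.prior
  } else {
    n1 <- sum(groups == levels(groups)[1])
    n2 <- sum(groups == levels(groups)[2])
    se <- fit$sigma * fit$stdev.unscaled[, 2]
    stat <- fit$coefficients[, 2] / se
    p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
    s2_prior <- NA_real_
    s2_post <- fit$sigma^2
    df_prior <- 0
  }
  lfc <- fit$coefficients[, 2]
  ord <- order(p, -abs(stat), ids)
  rank <- integer(length(p))
  rank[ord] <- seq_along(ord)
  out <- tibble(
    transcript_id = ids,
    statistic = unname(stat),
    lfc = unname(lfc),
    p_value = unname(p),
    rank = rank
  )
  structure(out, class = c("de_ranking", class(out)),
            s2_resid = unname(fit$sigma^2), s2_prior = s2_prior,
            s2_post = unname(s2_post), df_prior = df_prior)
}

# multi-group ranking by moderated F (one-vs-rest style group effect)
moderated_f_rank <- function(expr, groups) {
  groups <- factor(groups)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(expr)))
  design <- model.matrix(~groups)
  fit <- limma::eBayes(limma::lmFit(as.matrix(expr), design))
  p <- fit$F.p.value
  stat <- fit$F
  ord <- order(p, -stat, ids)
  rank <- integer(length(p))
  rank[ord] <- seq_along(ord)
  structure(tibble(transcript_id = ids, statistic = unname(stat),
                   lfc = NA_real_, p_value = unname(p), rank = rank),
            class = c("de_ranking", "tbl_df", "tbl", "data.frame"))
}

# dispatch on the number of groups
rank_features <- function(expr, groups) {
  groups <- factor(groups)
  if (nlevels(groups) == 2) moderated_t_rank(expr, groups)
  else moderated_f_rank(expr, groups)
}

#' Top-ranked transcripts
#'
#' @param ranking A [moderated_t_rank()] result.
#' @param n Number of transcripts to return.
#'
#' @return Character vector of the `n` best-ranked transcript ids, in rank
#'   order (so `top_n_transcripts(r, 10)` is a prefix of
#'   `top_n_transcripts(r, 20)`).
#' @export
top_n_transcripts <- function(ranking, n) {
  stopifnot(is.data.frame(ranking), all(c("transcript_id", "rank") %in% names(ranking)))
  if (n < 1 || n > nrow(ranking)) {
    ob_abort("n must be between 1 and the number of transcripts", "input")
  }
  ranking$transcript_id[order(ranking$rank)][seq_len(n)]
}
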