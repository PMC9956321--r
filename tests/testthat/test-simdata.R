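test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(groups = 3), class = "outlierboot_error_config")
  expect_error(sim_config(n_transcripts = 0), class = "outlierboot_error_config")
  expect_error(sim_config(outliers_per_group = -1), class = "outlierboot_error_config")
  expect_error(sim_config(n_de_transcripts = 2000), class = "outlierboot_error_config")
  expect_error(sim_config(noise_sd = -1), class = "outlierboot_error_config")
  expect_error(sim_config(lfc_range = c(2, 1)), class = "outlierboot_error_config")
})

test_that("shifted_mean evaluates mu1 * 2^lfc and rejects bad means", {
  expect_equal(shifted_mean(5, 0), 5)
  expect_equal(shifted_mean(5, 1), 10)
  expect_equal(shifted_mean(3, -2), 0.75)
  expect_error(shifted_mean(0, 1), class = "outlierboot_error_invalid_parameter")
  expect_error(shifted_mean(-2, 1), class = "outlierboot_error_invalid_parameter")
})

test_that("default study designs have the expected sample counts", {
  ds2 <- simulate_expression(sim_config(n_transcripts = 150), seed = 1)
  expect_equal(ncol(ds2$expr), 110)
  expect_equal(sum(ds2$samples$is_true_outlier), 10)
  expect_equal(as.vector(table(ds2$samples$group)), c(55, 55))
  ds4 <- simulate_expression(sim_config(n_transcripts = 150, groups = 4), seed = 1)
  expect_equal(ncol(ds4$expr), 220)
  expect_equal(sum(ds4$samples$is_true_outlier), 20)
  expect_equal(nlevels(ds4$samples$group), 4)
})

test_that("identical seeds reproduce the dataset bit for bit", {
  cfg <- sim_config(n_transcripts = 80, samples_per_group = 10,
                    outliers_per_group = 2, n_de_transcripts = 20,
                    n_outlier_de_transcripts = 10)
  a <- simulate_expression(cfg, seed = 99)
  b <- simulate_expression(cfg, seed = 99)
  expect_identical(a$expr, b$expr)
  expect_identical(a$samples, b$samples)
  expect_identical(a$de_transcripts, b$de_transcripts)
  c <- simulate_expression(cfg, seed = 100)
  expect_false(identical(a$expr, c$expr))
})

test_that("zero noise without effects yields identical columns", {
  cfg <- sim_config(n_transcripts = 40, samples_per_group = 5,
                    outliers_per_group = 0, n_de_transcripts = 0,
                    n_outlier_de_transcripts = 0, noise_sd = 0)
  ds <- simulate_expression(cfg, seed = 3)
  base <- ds$group_means[, 1]
  for (j in seq_len(ncol(ds$expr))) {
    expect_equal(unname(ds$expr[, j]), unname(base))
  }
})

test_that("with zero noise exactly n_de_transcripts rows separate the groups", {
  cfg <- sim_config(n_transcripts = 60, samples_per_group = 4,
                    outliers_per_group = 0, n_de_transcripts = 15,
                    n_outlier_de_transcripts = 0, noise_sd = 0)
  ds <- simulate_expression(cfg, seed = 5)
  g1 <- ds$expr[, ds$samples$group == "G1"]
  g2 <- ds$expr[, ds$samples$group == "G2"]
  differs <- rowMeans(g1) != rowMeans(g2)
  expect_equal(sum(differs), 15)
  expect_setequal(rownames(ds$expr)[differs], ds$de_transcripts$G2)
})

test_that("empirical_group_means recovers configured means", {
  cfg <- sim_config(n_transcripts = 30, samples_per_group = 6,
                    outliers_per_group = 1, n_de_transcripts = 10,
                    n_outlier_de_transcripts = 5, noise_sd = 0)
  ds <- simulate_expression(cfg, seed = 2)
  expect_equal(empirical_group_means(ds, "G2"),
               setNames(ds$group_means[, "G2"], rownames(ds$expr)))
  expect_error(empirical_group_means(ds, "G9"), class = "outlierboot_error_input")
})

test_that("empirical_group_means concentrates by the law of large numbers", {
  cfg <- sim_config(n_transcripts = 25, samples_per_group = 2000,
                    outliers_per_group = 0, n_de_transcripts = 5,
                    n_outlier_de_transcripts = 0, noise_sd = 1)
  ds <- simulate_expression(cfg, seed = 8)
  for (g in c("G1", "G2")) {
    dev <- abs(empirical_group_means(ds, g) - ds$group_means[, g])
    expect_true(all(dev < 3 * 1 / sqrt(2000)))
  }
})

test_that("empirical_group_means errors when a group has no regular samples", {
  ds <- small_sim()
  keep <- ds$samples$group != "G1" | ds$samples$is_true_outlier
  sub <- filter_samples(ds, keep)
  expect_error(empirical_group_means(sub, "G1"), class = "outlierboot_error_input")
})

test_that("expression_dataset constructor validates input", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("t1", "t2"), c("a", "b", "c")))
  meta <- tibble::tibble(sample_id = c("a", "b", "c"), group = c("x", "x", "y"))
  ds <- expression_dataset(m, meta)
  expect_s3_class(ds, "expression_dataset")
  expect_true(all(is.na(ds$samples$is_true_outlier)))
  expect_error(expression_dataset(m, meta[c(2, 1, 3), ]),
               class = "outlierboot_error_input")
  m2 <- m; m2[1, 1] <- NA
  expect_error(expression_dataset(m2, meta), class = "outlierboot_error_input")
  expect_error(expression_dataset(m, meta["group"]), class = "outlierboot_error_input")
})

test_that("filter_samples subsets by logical or by id and drops empty levels", {
  ds <- small_sim()
  sub <- filter_samples(ds, ds$samples$group == "G1")
  expect_equal(nlevels(sub$samples$group), 1)
  expect_equal(ncol(sub$expr), sum(ds$samples$group == "G1"))
  ids <- ds$samples$sample_id[1:3]
  sub2 <- filter_samples(ds, ids)
  expect_equal(sub2$samples$sample_id, ids)
  expect_error(filter_samples(ds, rep(FALSE, ncol(ds$expr))),
               class = "outlierboot_error_input")
})

test_that("planted outliers sit farther from their group centroid in PC space", {
  # geometry check across seeds: mean PC-plane distance of planted outliers
  # to their group centroid exceeds that of regular samples
  cfg <- sim_config()
  hits <- vapply(1:20, function(s) {
    ds <- simulate_expression(cfg, seed = s)
    sc <- stats::prcomp(t(ds$expr), center = TRUE, rank. = 2)$x
    ok <- vapply(levels(ds$samples$group), function(g) {
      sel <- ds$samples$group == g
      pts <- sc[sel, , drop = FALSE]
      cen <- colMeans(pts)
      d <- sqrt(rowSums(sweep(pts, 2, cen)^2))
      out <- ds$samples$is_true_outlier[sel]
      mean(d[out]) > mean(d[!out])
    }, logical(1))
    all(ok)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("datasets round-trip through the TSV reader and writer", {
  ds <- small_sim()
  ep <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(ds, ep, mp)
  back <- read_expression_dataset(ep, mp)
  expect_equal(back$expr, ds$expr)
  expect_equal(back$samples$sample_id, ds$samples$sample_id)
  expect_equal(as.character(back$samples$group),
               as.character(ds$samples$group))
  expect_equal(back$samples$is_true_outlier, ds$samples$is_true_outlier)
})

test_that("reading counts applies the log-CPM transform", {
  counts <- matrix(c(100L, 0L, 50L, 200L, 10L, 40L), nrow = 3,
                   dimnames = list(paste0("t", 1:3), c("a", "b")))
  meta <- tibble::tibble(sample_id = c("a", "b"), group = c("x", "y"))
  ds <- expression_dataset(counts, meta)
  ep <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(ds, ep, mp)
  back <- read_expression_dataset(ep, mp, counts = TRUE)
  expect_equal(back$expr, logcpm_transform(counts))
})
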