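test_that("size factors respect symmetry and scaling", {
  cm <- counts_tbl(matrix(rep(c(5, 10, 20), 3), 3, 3))
  expect_equal(unname(estimate_size_factors(cm)), rep(1, 3))

  m <- matrix(rpois(300, 50) + 1, 100, 3)
  m[, 2] <- m[, 1] * 2
  sf <- estimate_size_factors(counts_tbl(m))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-8)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("size factors recover simulated library scalings", {
  sim <- simulate_dataset(sim_config(
    n_genes = 500, organs = "leaf", timepoints_h = 3, n_replicates = 3,
    frac_de_per_contrast = 0, frac_organ_specific = 0,
    n_tf_sets = 0, n_active_tf_sets = 0, n_term_sets = 0, n_active_term_sets = 0,
    seed = 13
  ))
  est <- estimate_size_factors(sim$counts)
  truth <- sim$size_factors / exp(mean(log(sim$size_factors)))
  expect_true(all(abs(est / truth - 1) < 0.1))
})

test_that("dispersion estimates are calibrated", {
  mk_design <- function(n) tibble::tibble(
    sample_id = sprintf("s%d", seq_len(2 * n)), organ = "leaf",
    treatment = rep(c("control", "cold"), each = n),
    duration_h = rep(c(0, 3), each = n), replicate = rep(seq_len(n), 2)
  )
  # Poisson counts: estimates collapse to the floor
  set.seed(31)
  cm <- counts_tbl(matrix(rpois(2000 * 6, 1000), 2000, 6),
                   samples = sprintf("s%d", 1:6))
  disp <- estimate_dispersion(cm, mk_design(3), "leaf", 3)
  expect_lt(median(disp$dispersion), 0.01)

  # constant replicates: exactly the floor
  cm_const <- counts_tbl(matrix(100, 5, 6), samples = sprintf("s%d", 1:6))
  disp_const <- estimate_dispersion(cm_const, mk_design(3), "leaf", 3)
  expect_equal(disp_const$dispersion, rep(1e-8, 5))

  # alpha = 0.2 at mean 500: median of MoM estimates in a broad band
  set.seed(32)
  cm_nb <- counts_tbl(matrix(rnbinom(2000 * 6, mu = 500, size = 5), 2000, 6),
                      samples = sprintf("s%d", 1:6))
  disp_nb <- estimate_dispersion(cm_nb, mk_design(3), "leaf", 3)
  expect_gt(median(disp_nb$dispersion), 0.1)
  expect_lt(median(disp_nb$dispersion), 0.4)
})

test_that("identical groups produce no calls", {
  set.seed(41)
  base <- matrix(rpois(300, 40), 100, 3)
  cm <- counts_tbl(cbind(base, base), samples = sprintf("s%d", 1:6))
  design <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6), organ = "leaf",
    treatment = rep(c("control", "cold"), each = 3),
    duration_h = rep(c(0, 3), each = 3), replicate = rep(1:3, 2)
  )
  de <- test_contrast(cm, design, "leaf", 3)
  expect_equal(de$log2fc, rep(0, 100))
  expect_true(all(de$status == "ns"))
})

test_that("status partitions genes and responds monotonically to thresholds", {
  sim <- small_sim(organs = "leaf", n_genes = 600, seed = 17)
  de1 <- test_contrast(sim$counts, sim$design, "leaf", 3)
  expect_true(all(de1$status %in% c("up", "down", "ns")))

  de_strict_fdr <- test_contrast(sim$counts, sim$design, "leaf", 3, fdr_max = 0.01)
  de_strict_fc <- test_contrast(sim$counts, sim$design, "leaf", 3, min_fold_change = 4)
  hits <- function(x) x$gene_id[x$status != "ns"]
  expect_true(all(hits(de_strict_fdr) %in% hits(de1)))
  expect_true(all(hits(de_strict_fc) %in% hits(de1)))
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(51)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("untested all-zero genes are excluded from the BH family", {
  set.seed(61)
  m <- matrix(rpois(50 * 6, 30), 50, 6)
  m[1:5, ] <- 0
  cm <- counts_tbl(m, samples = sprintf("s%d", 1:6))
  design <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6), organ = "leaf",
    treatment = rep(c("control", "cold"), each = 3),
    duration_h = rep(c(0, 3), each = 3), replicate = rep(1:3, 2)
  )
  de <- test_contrast(cm, design, "leaf", 3)
  expect_true(all(is.na(de$pvalue[1:5])))
  expect_true(all(de$status[1:5] == "ns"))
  expect_equal(attr(de, "n_tested"), 45L)
  expect_equal(de$qvalue[!is.na(de$pvalue)],
               bh_oracle(de$pvalue[!is.na(de$pvalue)]))
})

test_that("fold changes agree with an established NB GLM fit", {
  suppressPackageStartupMessages(requireNamespace("DESeq2", quietly = TRUE))
  sim <- simulate_dataset(sim_config(
    n_genes = 300, organs = "leaf", timepoints_h = 3, n_replicates = 3,
    n_tf_sets = 0, n_active_tf_sets = 0, n_term_sets = 0, n_active_term_sets = 0,
    seed = 23
  ))
  de <- test_contrast(sim$counts, sim$design, "leaf", 3)

  m <- as.matrix(sim$counts[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- sim$counts$gene_id
  col <- data.frame(condition = factor(
    ifelse(sim$design$treatment == "control", "A", "B"), levels = c("A", "B")
  ))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, col, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))

  both <- !is.na(de$pvalue) & !is.na(ref$log2FoldChange) & de$base_mean > 20
  expect_gt(cor(de$log2fc[both], ref$log2FoldChange[both]), 0.95)
  strong <- both & abs(ref$log2FoldChange) > 1 & ref$padj < 0.05 & !is.na(ref$padj)
  expect_gt(mean(sign(de$log2fc[strong]) == sign(ref$log2FoldChange[strong])), 0.99)
})
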