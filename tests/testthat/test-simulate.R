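test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 120, organs = c("leaf", "seeds"), seed = 7,
                    n_tf_sets = 4, n_active_tf_sets = 1,
                    n_term_sets = 4, n_active_term_sets = 1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$size_factors, s2$size_factors)
})

test_that("zero DE fraction yields a null experiment", {
  sim <- small_sim(frac_de_per_contrast = 0, frac_sign_flip = 0, n_genes = 100)
  lfc_cols <- grep("^lfc_", names(sim$truth), value = TRUE)
  expect_true(all(sim$truth[lfc_cols] == 0))
  de_cols <- grep("^de_", names(sim$truth), value = TRUE)
  expect_false(any(as.matrix(sim$truth[de_cols])))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(frac_de_per_contrast = 1.2), "frac_de_per_contrast")
  expect_error(sim_config(effect_log2fc_range = c(0.5, 2)), "effect_log2fc_range")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_active_tf_sets = 10, n_tf_sets = 5), "n_active_tf_sets")
})

test_that("replicate counts follow the NB mean-variance relation", {
  # Var = mu + alpha mu^2, checked by pooling genes into mean bins
  alpha <- 0.05
  sim <- simulate_dataset(sim_config(
    n_genes = 5000, organs = "leaf", timepoints_h = 3, n_replicates = 3,
    frac_de_per_contrast = 0, frac_sign_flip = 0, frac_organ_specific = 0,
    dispersion = alpha, size_factor_range = c(1, 1),
    n_tf_sets = 0, n_active_tf_sets = 0, n_term_sets = 0, n_active_term_sets = 0,
    seed = 5
  ))
  ctrl <- sim$design$sample_id[sim$design$treatment == "control"]
  m <- as.matrix(sim$counts[ctrl])
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  bins <- cut(mu, breaks = c(50, 100, 200, 400, 800, 3200))
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (sum(sel) < 50) next
    expected <- mean(mu[sel] + alpha * mu[sel]^2)
    expect_gt(mean(v[sel]) / expected, 0.75)
    expect_lt(mean(v[sel]) / expected, 1.3)
  }
})

test_that("planted effects are realised in group means", {
  sim <- simulate_dataset(sim_config(
    n_genes = 3000, organs = "leaf", timepoints_h = 3, n_replicates = 3,
    frac_sign_flip = 0, frac_organ_specific = 0, size_factor_range = c(1, 1),
    n_tf_sets = 0, n_active_tf_sets = 0, n_term_sets = 0, n_active_term_sets = 0,
    seed = 9
  ))
  ctrl <- sim$design$sample_id[sim$design$treatment == "control"]
  cold <- sim$design$sample_id[sim$design$treatment == "cold"]
  mA <- rowMeans(as.matrix(sim$counts[ctrl]))
  mB <- rowMeans(as.matrix(sim$counts[cold]))
  tr <- sim$truth
  sel <- tr$de_leaf_3h & tr$mean_leaf >= 100
  expect_gt(sum(sel), 50)
  emp <- log2(mB[sel] / mA[sel])
  expect_gte(mean(abs(emp - tr$lfc_leaf_3h[sel]) <= 0.5), 0.9)
})

test_that("active regulons are enriched among true-DE genes", {
  enr_factor <- 4
  sim <- small_sim(n_genes = 2000, seed = 21, n_tf_sets = 12,
                   n_active_tf_sets = 4, tf_target_de_enrichment = enr_factor)
  de_cols <- grep("^de_", names(sim$truth), value = TRUE)
  de_any <- rowSums(as.matrix(sim$truth[de_cols])) > 0
  de_genes <- sim$truth$gene_id[de_any]
  tf <- sim$sets[sim$sets$kind == "tf_target", ]
  ann <- sim$annotations[sim$annotations$kind == "tf_target", ]
  ratios <- vapply(tf$set_id, function(id) {
    targets <- ann$gene_id[ann$term_id == id]
    p_de <- mean(de_genes %in% targets)
    p_non <- mean(setdiff(sim$truth$gene_id, de_genes) %in% targets)
    p_de / p_non
  }, numeric(1))
  expect_true(all(ratios[tf$active] > enr_factor / 2))
  expect_true(all(ratios[!tf$active] > 0.5 & ratios[!tf$active] < 2))
  expect_gt(min(ratios[tf$active]), max(ratios[!tf$active]))
})

test_that("organ-specific genes are silent outside their organ", {
  sim <- small_sim(n_genes = 300, frac_organ_specific = 0.2)
  os <- grepl("^organ_specific:", sim$truth$pattern)
  expect_gt(sum(os), 0)
  mean_cols <- grep("^mean_", names(sim$truth), value = TRUE)
  home <- sub("^organ_specific:", "mean_", sim$truth$pattern[os])
  mm <- as.matrix(sim$truth[os, mean_cols])
  for (i in seq_len(nrow(mm))) {
    expect_true(all(mm[i, colnames(mm) != home[i]] == 0))
    expect_gt(mm[i, home[i]], 0)
  }
})

test_that("truth tables round-trip through TSV", {
  sim <- small_sim(n_genes = 50)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, tmp)
  back <- read_truth(tmp)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))
  expect_equal(nrow(back), 50L)

  empty <- sim$truth[0, ]
  write_truth(empty, tmp)
  expect_equal(nrow(read_truth(tmp)), 0L)
})
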