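test_that("contrast summaries compute totals and half-up ratios", {
  s <- summarize_contrast(tibble::tibble(n_down = 5, n_up = 4))
  expect_equal(s$n_total, 9)
  expect_equal(s$down_up_ratio, 1.25)
  expect_false(s$ratio_undefined)

  empty <- summarize_contrast(tibble::tibble(n_down = 0, n_up = 0))
  expect_equal(empty$n_total, 0)
  expect_true(is.na(empty$down_up_ratio))
  expect_true(empty$ratio_undefined)

  # half-up, not banker's rounding: 0.125 -> 0.13
  s2 <- summarize_contrast(tibble::tibble(n_down = 1, n_up = 8))
  expect_equal(s2$down_up_ratio, 0.13)
})

test_that("genes classify into Down, Up and Mix by cross-contrast direction", {
  genes <- c("g1", "g2", "g3", "g4")
  res <- list(
    c1 = status_frame(genes, c("up", "down", "ns", "ns")),
    c2 = status_frame(genes, c("up", "ns", "down", "ns")),
    c3 = status_frame(genes, c("ns", "up", "ns", "ns"))
  )
  cls <- classify_response(res)
  expect_equal(nrow(cls), 3)  # g4 ns everywhere, excluded
  expect_equal(cls$category[cls$gene_id == "g1"], "Up")
  expect_equal(cls$category[cls$gene_id == "g2"], "Mix")
  expect_equal(cls$category[cls$gene_id == "g3"], "Down")
})

test_that("classification is invariant to contrast order and checks universes", {
  res <- random_results(80, 4)
  cls <- classify_response(res)
  cls_rev <- classify_response(rev(res))
  expect_equal(
    dplyr::arrange(tibble::tibble(gene_id = cls$gene_id, category = cls$category), gene_id),
    dplyr::arrange(tibble::tibble(gene_id = cls_rev$gene_id, category = cls_rev$category), gene_id)
  )

  res$c4 <- res$c4[-1, ]
  expect_error(classify_response(res), "different gene universe")
})

test_that("commonality counts match a brute-force recount", {
  set.seed(71)
  for (rep in 1:20) {
    res <- random_results(60, sample(2:6, 1))
    cls <- classify_response(res)
    smat <- sapply(res, function(f) f$status)
    rownames(smat) <- res[[1]]$gene_id
    smat <- smat[cls$gene_id, , drop = FALSE]
    for (dir in c("down", "up", "mixed")) {
      ct <- commonality(cls, dir)
      cat_name <- c(down = "Down", up = "Up", mixed = "Mix")[[dir]]
      in_cat <- cls$category == cat_name
      k_brute <- if (dir == "mixed") {
        rowSums(smat[in_cat, , drop = FALSE] != "ns")
      } else {
        rowSums(smat[in_cat, , drop = FALSE] == dir)
      }
      expect_equal(ct$n_genes, as.integer(tabulate(k_brute, nbins = length(res))))
      expect_equal(sum(ct$n_genes), sum(in_cat))  # conservation
    }
  }
})

test_that("single-organ extremes land in the right commonality stratum", {
  genes <- c("a", "b", "c", "d")
  res <- list(
    o1 = status_frame(genes, c("up", "ns", "ns", "up")),
    o2 = status_frame(genes, c("ns", "up", "ns", "up")),
    o3 = status_frame(genes, c("ns", "ns", "up", "up"))
  )
  cls <- classify_response(res)
  ct <- commonality(cls, "up")
  expect_equal(ct$n_genes, c(3L, 0L, 1L))
})

test_that("unique genes are the k = 1 stratum of their contrast", {
  set.seed(73)
  res <- random_results(100, 4)
  cls <- classify_response(res)
  smat <- sapply(res, function(f) f$status)
  rownames(smat) <- res[[1]]$gene_id
  for (ct in names(res)) {
    for (dir in c("down", "up")) {
      got <- unique_genes(cls, ct, dir)
      brute <- rownames(smat)[smat[, ct] == dir &
                                rowSums(smat[, colnames(smat) != ct, drop = FALSE] != "ns") == 0]
      expect_setequal(got, brute)
    }
  }
  expect_error(unique_genes(cls, "nope", "up"), "unknown contrast")
})

test_that("direction concordance compares signs of DE reference genes", {
  genes <- sprintf("g%d", 1:10)
  result <- status_frame(genes, c(rep("up", 4), rep("down", 2), rep("ns", 4)))
  all_up <- tibble::tibble(gene_id = genes[1:4], direction = "up")
  cc <- direction_concordance(result, all_up)
  expect_equal(cc$pct_match, 100)

  half <- tibble::tibble(gene_id = genes[1:4],
                         direction = c("up", "up", "down", "down"))
  cc2 <- direction_concordance(result, half)
  expect_equal(cc2$n_compared, 4)
  expect_equal(cc2$pct_match, 50)

  none <- tibble::tibble(gene_id = genes[7:10], direction = "up")
  cc3 <- direction_concordance(result, none)
  expect_equal(cc3$n_compared, 0)
  expect_true(is.na(cc3$pct_match))

  bad <- tibble::tibble(gene_id = c("g1", "g1"), direction = c("up", "down"))
  expect_error(direction_concordance(result, bad), "both directions")
})

test_that("planted regulon direction is recovered through the DE caller", {
  sim <- small_sim(organs = c("leaf", "seeds"), n_genes = 800, seed = 29,
                   frac_sign_flip = 0)
  de <- test_contrast(sim$counts, sim$design, "leaf", 3)
  tr <- sim$truth
  ref <- tibble::tibble(
    gene_id = tr$gene_id[tr$de_leaf_3h],
    direction = ifelse(tr$lfc_leaf_3h[tr$de_leaf_3h] > 0, "up", "down")
  )
  cc <- direction_concordance(de, ref)
  expect_gt(cc$n_compared, 20)
  expect_gte(cc$pct_match, 95)
})
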