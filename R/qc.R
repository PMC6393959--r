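#' Replicate-correlation quality control
#'
#' Pairwise Pearson r-squared between samples on `log2(expression + 1)`,
#' with the mean taken over within-group (replicate) pairs only.  A pair
#' involving a constant expression vector has undefined correlation and
#' is reported as `NA` and flagged.
#'
#' @param expression Expression tibble (`gene_id` + one numeric column
#'   per sample), typically RPKM from [compute_rpkm()].
#' @param design Design tibble covering the expression samples; replicate
#'   groups are taken from a `group` column when present, otherwise from
#'   organ/treatment/duration_h.
#' @param log_transform Apply `log2(x + 1)` before correlating.
#' @return A list of class `cold_qc`: `r2` (symmetric matrix with unit
#'   diagonal), `pairs` (tibble `sample_1`, `sample_2`, `r2`,
#'   `within_group`, `undefined`) and `mean_replicate_r2`.
#' @export
replicate_correlation <- function(expression, design, log_transform = TRUE) {
  m <- counts_matrix(expression)
  miss <- setdiff(design$sample_id, colnames(m))
  if (length(miss) > 0) {
    abort(sprintf("design sample(s) absent from expression: %s",
                  paste(miss, collapse = ", ")))
  }
  m <- m[, design$sample_id, drop = FALSE]
  if (log_transform) m <- log2(m + 1)
  const <- apply(m, 2, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  r <- suppressWarnings(cor(m))
  r2 <- r^2
  diag(r2) <- 1
  r2[const, ] <- NA_real_
  r2[, const] <- NA_real_
  diag(r2) <- ifelse(const, NA_real_, 1)
  grp <- design_groups(design)
  ids <- design$sample_id
  pairs <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids))
  pairs <- pairs[pairs$i < pairs$j, ]
  pair_tbl <- tibble::tibble(
    sample_1 = ids[pairs$i],
    sample_2 = ids[pairs$j],
    r2 = r2[cbind(pairs$i, pairs$j)],
    within_group = grp[pairs$i] == grp[pairs$j]
  )
  pair_tbl$undefined <- is.na(pair_tbl$r2)
  if (any(pair_tbl$undefined)) {
    warn("some sample pairs have undefined correlation (constant expression vector)")
  }
  within <- pair_tbl$r2[pair_tbl$within_group]
  structure(list(
    r2 = r2,
    pairs = pair_tbl,
    mean_replicate_r2 = mean(within, na.rm = TRUE)
  ), class = "cold_qc")
}

#' @export
print.cold_qc <- function(x, ...) {
  cat(sprintf("<cold_qc> %d samples; mean within-replicate r^2 = %.3f\n",
              ncol(x$r2), x$mean_replicate_r2))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerates samples on correlation distance `1 - Pearson r` of
#' `log2(expression + 1)` profiles, average linkage by default (the
#' distance and linkage are explicit parameters since different choices
#' are defensible).
#'
#' @inheritParams replicate_correlation
#' @param method Linkage passed to [stats::hclust()].
#' @return An [stats::hclust()] tree over the samples.
#' @seealso [sample_tree_newick()]
#' @export
cluster_samples <- function(expression, log_transform = TRUE, method = "average") {
  m <- counts_matrix(expression)
  if (ncol(m) < 2) abort("clustering needs at least 2 samples")
  if (log_transform) m <- log2(m + 1)
  d <- as.dist(1 - suppressWarnings(cor(m)))
  if (any(!is.finite(d))) {
    abort("correlation distance undefined for a constant sample; remove it first")
  }
  hclust(d, method = method)
}

#' Newick serialisation of a sample tree
#'
#' @param tree An [stats::hclust()] object, e.g. from [cluster_samples()].
#' @return A single Newick string (with branch lengths).
#' @export
sample_tree_newick <- function(tree) {
  if (!inherits(tree, "hclust")) abort("`tree` must be an hclust object")
  ape::write.tree(ape::as.phylo(tree))
}
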