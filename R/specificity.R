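#' Shannon entropy of an expression profile
#'
#' Expression-pattern width in bits: `H = -sum(p_i * log2(p_i))` with
#' `p_i = x_i / sum(x)`.  A gene expressed uniformly over `N` groups has
#' `H = log2(N)`; a gene confined to one group has `H = 0`.  `H` is
#' undefined (`NA`) when the profile is all zero, and invariant to
#' rescaling by a positive constant.
#'
#' @param x Non-negative expression values, one per sample group.
#' @return Entropy in bits, or `NA` for an all-zero profile.
#' @examples
#' shannon_entropy(rep(1, 8))        # 3 bits
#' shannon_entropy(c(0, 5, 0))       # 0 bits
#' shannon_entropy(c(2, 1, 1))       # 1.5 bits
#' @export
shannon_entropy <- function(x) {
  if (!is.numeric(x)) abort("expression values must be numeric")
  if (any(x < 0, na.rm = TRUE)) abort("expression values must be non-negative")
  s <- sum(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Number of unordered sample pairs
#'
#' The maximum attainable DE Score of a transcriptome map with `n`
#' sample groups: `n * (n - 1) / 2` pairwise comparisons.
#'
#' @param n Number of sample groups (>= 0).
#' @return Integer pair count.
#' @examples
#' pair_count(79)  # 3081
#' @export
pair_count <- function(n) {
  if (!is.numeric(n) || any(n < 0) || any(n != floor(n))) {
    abort("`n` must be a non-negative integer")
  }
  as.integer(n * (n - 1) / 2)
}

map_groups <- function(design) {
  grp <- design_groups(design)
  split(design$sample_id, factor(grp, levels = unique(grp)))
}

#' Pairwise DE Score over a transcriptome map
#'
#' Runs the moderated negative-binomial contrast test of
#' [test_contrast()] between every unordered pair of sample groups and
#' counts, per gene, the comparisons in which it is differentially
#' expressed (same thresholds as the stress analysis).  The score ranges
#' from 0 to [pair_count()] of the number of groups, and grows with both
#' expression-pattern width and between-group expression differences.
#'
#' @inheritParams test_contrast
#' @param design Design tibble; groups are taken from a `group` column
#'   when present, otherwise from organ/treatment/duration_h.
#' @return Tibble with `gene_id` and integer `de_score`.
#' @export
de_score <- function(counts, design, fdr_max = 0.05, min_fold_change = 2,
                     pseudocount = 0.5, prior_df = 6) {
  validate_counts(counts)
  validate_thresholds(fdr_max, min_fold_change)
  if (nrow(counts) == 0) {
    return(tibble::tibble(gene_id = character(), de_score = integer()))
  }
  groups <- map_groups(design)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small) > 0) {
    abort(sprintf("design error: group '%s' has < 2 replicates", small[1]))
  }
  m <- counts_matrix(counts)
  miss <- setdiff(unlist(groups), colnames(m))
  if (length(miss) > 0) {
    abort(sprintf("design sample(s) absent from counts: %s", paste(miss, collapse = ", ")))
  }
  sf <- estimate_size_factors(counts)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  score <- integer(nrow(m))
  gn <- names(groups)
  for (i in seq_along(gn)[-length(gn)]) {
    for (j in seq((i + 1), length(gn))) {
      cols <- c(groups[[i]], groups[[j]])
      fit <- nb_pair_test(norm[, cols, drop = FALSE],
                          idxA = seq_along(groups[[i]]),
                          idxB = length(groups[[i]]) + seq_along(groups[[j]]),
                          pseudocount = pseudocount, prior_df = prior_df)
      q <- rep(NA_real_, nrow(m))
      q[fit$tested] <- bh_adjust(fit$pvalue[fit$tested])
      st <- de_status(fit$log2fc, q, fdr_max, min_fold_change)
      score <- score + (st != "ns")
    }
  }
  tibble::tibble(gene_id = rownames(m), de_score = as.integer(score))
}

#' Entropy and DE Score specificity profile
#'
#' Computes, per gene, the Shannon entropy of its replicate-averaged
#' RPKM profile across sample groups and its pairwise DE Score, the two
#' atlas-level specificity statistics.
#'
#' @inheritParams de_score
#' @param lengths Gene-length tibble for RPKM normalisation.
#' @return Tibble of class `cold_specificity` with `gene_id`, `H`
#'   (bits; `NA` for unexpressed genes) and `de_score`; the number of
#'   groups is stored in attribute `n_groups`.
#' @export
specificity_table <- function(counts, design, lengths,
                              fdr_max = 0.05, min_fold_change = 2,
                              pseudocount = 0.5, prior_df = 6) {
  if (nrow(counts) == 0) {
    out <- tibble::tibble(gene_id = character(), H = numeric(), de_score = integer())
    return(structure(out, class = c("cold_specificity", class(out)),
                     n_groups = length(map_groups(design))))
  }
  rpkm <- compute_rpkm(counts, lengths)
  groups <- map_groups(design)
  rm <- counts_matrix(rpkm)
  group_mean <- vapply(groups, function(s) rowMeans(rm[, s, drop = FALSE]),
                       numeric(nrow(rm)))
  if (is.null(dim(group_mean))) group_mean <- matrix(group_mean, nrow = nrow(rm))
  H <- apply(group_mean, 1, shannon_entropy)
  sc <- de_score(counts, design, fdr_max = fdr_max,
                 min_fold_change = min_fold_change,
                 pseudocount = pseudocount, prior_df = prior_df)
  out <- tibble::tibble(gene_id = rownames(rm), H = H,
                        de_score = sc$de_score[match(rownames(rm), sc$gene_id)])
  structure(out, class = c("cold_specificity", class(out)),
            n_groups = length(groups))
}

#' Histogram of an entropy distribution
#'
#' Bins entropies into fixed-width strata; the default width 0.3 makes
#' the first bin the narrow-pattern `[0, 0.3)` stratum.
#'
#' @param profile A [specificity_table()] result, or numeric entropies.
#' @param binwidth Bin width in bits.
#' @return Tibble with `bin_lo`, `bin_hi` and `n`.
#' @export
entropy_histogram <- function(profile, binwidth = 0.3) {
  h <- if (is.data.frame(profile)) profile$H else profile
  h <- h[!is.na(h)]
  stopifnot_scalar_number(binwidth, "binwidth", lo = 1e-9)
  if (length(h) == 0) {
    return(tibble::tibble(bin_lo = numeric(), bin_hi = numeric(), n = integer()))
  }
  nbin <- max(1L, ceiling((max(h) + 1e-12) / binwidth))
  idx <- pmin(pmax(floor(h / binwidth), 0) + 1L, nbin)
  tibble::tibble(
    bin_lo = (seq_len(nbin) - 1L) * binwidth,
    bin_hi = seq_len(nbin) * binwidth,
    n = vapply(seq_len(nbin), function(b) sum(idx == b), integer(1))
  )
}
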