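#' Median-of-ratios size factors
#'
#' Estimates per-sample library-size factors as the median, over genes
#' with nonzero counts in every sample, of the ratio between a sample's
#' count and the gene's geometric mean across samples.  Factors are
#' rescaled to geometric mean 1.
#'
#' @inheritParams compute_rpkm
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  eligible <- rowSums(m > 0) == ncol(m)
  if (!any(eligible)) {
    abort(paste("no gene has nonzero counts in every sample;",
                "filter samples or genes before size-factor estimation"))
  }
  lg <- rowMeans(log(m[eligible, , drop = FALSE]))
  s <- apply(m[eligible, , drop = FALSE], 2, function(x) median(exp(log(x) - lg)))
  s <- s / exp(mean(log(s)))
  s
}

# sample ids of the two groups of an organ x duration stress contrast
contrast_samples <- function(design, organ, duration_h) {
  validate_design(design)
  a <- design$sample_id[design$organ == organ & design$treatment == "control"]
  b <- design$sample_id[design$organ == organ & design$treatment == "cold" &
                          design$duration_h == duration_h]
  if (length(a) == 0 || length(b) == 0) {
    abort(sprintf("no samples for contrast %s %gh (control n=%d, cold n=%d)",
                  organ, duration_h, length(a), length(b)))
  }
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf("design error: contrast %s %gh needs >= 2 replicates per group (control n=%d, cold n=%d)",
                  organ, duration_h, length(a), length(b)))
  }
  list(A = a, B = b)
}

# raw method-of-moments NB dispersion on normalised counts, group means removed
mom_dispersion <- function(norm, idxA, idxB, alpha_min = 1e-8) {
  A <- norm[, idxA, drop = FALSE]
  B <- norm[, idxB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  df <- nA + nB - 2L
  pooled_var <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / df
  pooled_mean <- rowMeans(cbind(A, B))
  alpha <- (pooled_var - pooled_mean) / pooled_mean^2
  alpha[!is.finite(alpha)] <- alpha_min
  pmax(alpha, alpha_min)
}

#' Gene-wise negative-binomial dispersion
#'
#' Method-of-moments estimator on size-factor-normalised counts of one
#' stress contrast: group means are removed, the pooled residual variance
#' `v` and pooled mean `m` give `alpha = max((v - m) / m^2, 1e-8)`.
#' Degenerate genes (zero variance or zero mean) get the floor `1e-8`.
#'
#' @inheritParams compute_rpkm
#' @param design Sample design tibble (see [read_design()]).
#' @param organ,duration_h The contrast: `organ` cold-treated for
#'   `duration_h` hours versus its controls.
#' @param size_factors Optional precomputed [estimate_size_factors()]
#'   result.
#' @return Tibble with `gene_id` and `dispersion`.
#' @export
estimate_dispersion <- function(counts, design, organ, duration_h,
                                size_factors = NULL) {
  validate_counts(counts)
  grp <- contrast_samples(design, organ, duration_h)
  sf <- size_factors %||% estimate_size_factors(counts)
  m <- counts_matrix(counts)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  tibble::tibble(
    gene_id = rownames(m),
    dispersion = unname(mom_dispersion(norm, grp$A, grp$B))
  )
}

# moderated two-group NB Wald test on normalised counts.
# Gene-wise MoM dispersions are shrunk toward the mean-variance trend
# v(m) = m + alpha_trend * m^2 with prior_df pseudo-observations, and the
# Wald statistic is referred to a t distribution with residual + prior df.
nb_pair_test <- function(norm, idxA, idxB, pseudocount = 0.5, prior_df = 6) {
  A <- norm[, idxA, drop = FALSE]
  B <- norm[, idxB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  df <- nA + nB - 2L
  pooled_var <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / df
  pooled_mean <- rowMeans(cbind(A, B))
  tested <- pooled_mean > 0

  alpha_raw <- mom_dispersion(norm, idxA, idxB)
  trend_pool <- alpha_raw[tested & pooled_mean >= 10]
  alpha_trend <- if (length(trend_pool) > 0) median(trend_pool) else 0.01
  var_mod <- (df * pooled_var + prior_df * (pooled_mean + alpha_trend * pooled_mean^2)) /
    (df + prior_df)
  alpha <- pmax((var_mod - pooled_mean) / pooled_mean^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8

  lfc <- log2((mB + pseudocount) / (mA + pseudocount))
  ln2sq <- log(2)^2
  vA <- (mA + alpha * mA^2) / (nA * (mA + pseudocount)^2 * ln2sq)
  vB <- (mB + alpha * mB^2) / (nB * (mB + pseudocount)^2 * ln2sq)
  se <- sqrt(vA + vB)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(z), df = df + prior_df)
  p[!tested] <- NA_real_
  list(base_mean = unname(pooled_mean), log2fc = unname(lfc),
       pvalue = unname(p), tested = unname(tested))
}

de_status <- function(log2fc, qvalue, fdr_max, min_fold_change) {
  lfc_min <- log2(min_fold_change)
  sig <- !is.na(qvalue) & qvalue <= fdr_max
  dplyr::case_when(
    sig & log2fc >= lfc_min ~ "up",
    sig & log2fc <= -lfc_min ~ "down",
    TRUE ~ "ns"
  )
}

#' Test one stress-versus-control contrast
#'
#' Calls differential expression for one organ at one cold duration with
#' a moderated negative-binomial Wald test: median-of-ratios size factors,
#' gene-wise method-of-moments dispersion shrunk toward a mean-variance
#' trend (`prior_df` pseudo-observations), a delta-method standard error
#' for the log2 fold change of group means (pseudocount `pseudocount`),
#' a two-sided t reference distribution, and Benjamini-Hochberg adjusted
#' q-values over all tested genes.  A gene is `up` when
#' `q <= fdr_max` and `log2fc >= log2(min_fold_change)`; `down`
#' symmetrically; otherwise `ns`.  Genes with zero counts in every sample
#' of the contrast are excluded from testing (and from the BH family) and
#' reported with `NA` p- and q-values.
#'
#' @inheritParams estimate_dispersion
#' @param fdr_max Significance threshold on the BH-adjusted q-value.
#' @param min_fold_change Minimum fold change; `2` means `|log2FC| >= 1`.
#' @param pseudocount Added to both normalised group means in the fold
#'   change so genes absent from one group stay finite.
#' @param prior_df Pseudo-observations of the dispersion trend blended
#'   into each gene-wise estimate; also augments the t degrees of freedom.
#' @return A tibble of class `cold_de` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `pvalue`, `qvalue`, `status`, and attributes
#'   `organ`, `duration_h`, `fdr_max`, `min_fold_change`, `n_tested`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 200, organs = c("leaf", "seeds"),
#'                                    n_tf_sets = 5, n_active_tf_sets = 1,
#'                                    n_term_sets = 5, n_active_term_sets = 1))
#' de <- test_contrast(sim$counts, sim$design, "leaf", 3)
#' table(de$status)
#' @export
test_contrast <- function(counts, design, organ, duration_h,
                          fdr_max = 0.05, min_fold_change = 2,
                          pseudocount = 0.5, prior_df = 6,
                          size_factors = NULL) {
  validate_counts(counts)
  validate_thresholds(fdr_max, min_fold_change)
  grp <- contrast_samples(design, organ, duration_h)
  sf <- size_factors %||% estimate_size_factors(counts)
  m <- counts_matrix(counts)
  norm <- sweep(m, 2, sf[colnames(m)], "/")
  fit <- nb_pair_test(norm[, c(grp$A, grp$B), drop = FALSE],
                      idxA = seq_along(grp$A),
                      idxB = length(grp$A) + seq_along(grp$B),
                      pseudocount = pseudocount, prior_df = prior_df)
  q <- rep(NA_real_, nrow(m))
  q[fit$tested] <- bh_adjust(fit$pvalue[fit$tested])
  out <- tibble::tibble(
    gene_id = rownames(m),
    base_mean = fit$base_mean,
    log2fc = fit$log2fc,
    pvalue = fit$pvalue,
    qvalue = q,
    status = de_status(fit$log2fc, q, fdr_max, min_fold_change)
  )
  structure(out,
            class = c("cold_de", class(out)),
            organ = organ, duration_h = duration_h,
            fdr_max = fdr_max, min_fold_change = min_fold_change,
            n_tested = sum(fit$tested))
}

validate_thresholds <- function(fdr_max, min_fold_change) {
  if (!is.numeric(fdr_max) || length(fdr_max) != 1 || fdr_max <= 0 || fdr_max >= 1) {
    abort("`fdr_max` must be a single number in (0, 1)")
  }
  if (!is.numeric(min_fold_change) || length(min_fold_change) != 1 || min_fold_change < 1) {
    abort("`min_fold_change` must be a single number >= 1")
  }
  invisible(NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("p-values must be numeric")
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Enumerate and test every stress contrast of a design
#'
#' @inheritParams test_contrast
#' @param ... Passed to [test_contrast()].
#' @return Named list of `cold_de` results, one per organ-by-duration
#'   contrast, named `"<organ>_<duration>h"`.
#' @export
test_all_contrasts <- function(counts, design, ...) {
  validate_design(design, counts)
  cold <- dplyr::distinct(design[design$treatment == "cold", c("organ", "duration_h")])
  cold <- dplyr::arrange(cold, match(.data$organ, unique(design$organ)), .data$duration_h)
  sf <- estimate_size_factors(counts)
  res <- purrr::pmap(cold, function(organ, duration_h) {
    test_contrast(counts, design, organ, duration_h, size_factors = sf, ...)
  })
  names(res) <- paste0(cold$organ, "_", cold$duration_h, "h")
  res
}

#' @export
print.cold_de <- function(x, ...) {
  cat(sprintf("<cold_de> %s %gh vs control: %d genes (%d tested), %d up / %d down at FDR <= %g, fold >= %g\n",
              attr(x, "organ"), attr(x, "duration_h"), nrow(x), attr(x, "n_tested"),
              sum(x$status == "up"), sum(x$status == "down"),
              attr(x, "fdr_max"), attr(x, "min_fold_change")))
  NextMethod()
}
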