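#' Right-tailed Fisher exact p-value for a 2x2 table
#'
#' Probability, under the hypergeometric null with the table's margins,
#' of an overlap at least as large as the observed `a`:
#' `a` = DE and target, `b` = DE and non-target, `c` = non-DE and
#' target, `d` = non-DE and non-target.  Vectorised over tables.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Right-tail p-value(s) in `(0, 1]`.
#' @export
fisher_right_tail <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("contingency counts must be non-negative integers")
  }
  # X ~ Hypergeometric(N, targets = a + c, draws = a + b); P(X >= a)
  phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Log2 target-percentage enrichment score
#'
#' `log2( %target(DE) / %target(non-DE) )` =
#' `log2( (a / (a + b)) / (c / (c + d)) )`.  The score is infinite when
#' one stratum has no targets; those cases are flagged.
#'
#' @inheritParams fisher_right_tail
#' @return Tibble with `enrichment` and logical `infinite` flag.
#' @export
enrichment_score <- function(a, b, c, d) {
  if (any(a + b == 0) || any(c + d == 0)) {
    abort("enrichment score undefined: empty DE or non-DE stratum")
  }
  score <- log2((a / (a + b)) / (c / (c + d)))
  tibble::tibble(enrichment = score, infinite = !is.finite(score))
}

#' Fisher-exact enrichment of gene sets in a gene list
#'
#' Builds the 2x2 table of each set against a gene list within a
#' universe, and reports the log2 target-percentage enrichment, the fold
#' enrichment `(a / (a + b)) / ((a + c) / N)`, the right-tailed Fisher
#' p-value and Benjamini-Hochberg q-values over exactly the tested sets.
#' Sets with fewer than `min_set_size` genes in the universe are skipped
#' (and excluded from the BH family).
#'
#' @param genes Character vector, the gene list (e.g. DE genes); must be
#'   a subset of `universe`.
#' @param universe Character vector of all eligible genes (typically all
#'   genes tested for differential expression).
#' @param sets Gene sets: a tibble with `term_id`/`gene_id` columns (see
#'   [read_annotation()]) or a named list of gene-id vectors.
#' @param fdr_max Significance threshold on q.
#' @param min_set_size Minimum in-universe set size to test.
#' @return Tibble of class `cold_enrichment` with columns `term_id`,
#'   `a`, `b`, `c`, `d`, `enrichment`, `infinite`, `fold_enrichment`,
#'   `pvalue`, `qvalue`, `significant`.
#' @export
set_enrichment <- function(genes, universe, sets, fdr_max = 0.05,
                           min_set_size = 2) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    abort(sprintf("gene list not contained in universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  set_list <- as_gene_sets(sets)
  set_list <- lapply(set_list, intersect, universe)
  sizes <- vapply(set_list, length, integer(1))
  drop <- sizes < min_set_size
  if (any(drop)) {
    warn(sprintf("skipping %d set(s) with fewer than %d genes in the universe",
                 sum(drop), min_set_size))
    set_list <- set_list[!drop]
  }
  n_de <- length(genes)
  N <- length(universe)
  if (length(set_list) == 0) {
    out <- tibble::tibble(term_id = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), enrichment = numeric(),
                          infinite = logical(), fold_enrichment = numeric(),
                          pvalue = numeric(), qvalue = numeric(),
                          significant = logical())
    return(structure(out, class = c("cold_enrichment", class(out)),
                     n_tested = 0L, universe_size = N, n_genes = n_de))
  }
  a <- vapply(set_list, function(s) length(intersect(s, genes)), integer(1))
  k <- vapply(set_list, length, integer(1))
  b <- n_de - a
  cc <- k - a
  d <- (N - n_de) - cc
  p <- fisher_right_tail(a, b, cc, d)
  q <- bh_adjust(p)
  score <- if (n_de > 0 && N > n_de) {
    log2((a / (a + b)) / (cc / (cc + d)))
  } else {
    rep(NA_real_, length(a))
  }
  fold <- if (n_de > 0) (a / n_de) / (k / N) else rep(NA_real_, length(a))
  out <- tibble::tibble(
    term_id = names(set_list),
    a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
    enrichment = unname(score), infinite = unname(!is.finite(score)),
    fold_enrichment = unname(fold),
    pvalue = unname(p), qvalue = unname(q),
    significant = unname(q <= fdr_max)
  )
  structure(out, class = c("cold_enrichment", class(out)),
            n_tested = length(set_list), universe_size = N, n_genes = n_de)
}

#' Transcription-factor regulon enrichment among DE genes
#'
#' Tests every transcription-factor target set for overrepresentation
#' among differentially expressed genes; the BH family is exactly the
#' tested regulons.
#'
#' @param de_genes Character vector of DE genes.
#' @inheritParams set_enrichment
#' @param tf_sets Target sets, as in `sets` of [set_enrichment()].
#' @return A `cold_enrichment` tibble, one row per tested regulon.
#' @export
tf_enrichment <- function(de_genes, universe, tf_sets, fdr_max = 0.05) {
  set_enrichment(de_genes, universe, tf_sets, fdr_max = fdr_max,
                 min_set_size = 1)
}

#' Functional term enrichment of a gene list
#'
#' Fisher-exact term overrepresentation with the usual double threshold:
#' a term is reported when its BH q-value is at most `fdr_max` and its
#' fold enrichment at least `min_fold`, sorted by q then by descending
#' fold.
#'
#' @param gene_list Character vector of genes of interest.
#' @inheritParams set_enrichment
#' @param term_sets Term sets, as in `sets` of [set_enrichment()].
#' @param min_fold Minimum fold enrichment of reported terms.
#' @return A `cold_enrichment` tibble of the enriched terms only.
#' @export
term_enrichment <- function(gene_list, universe, term_sets,
                            fdr_max = 0.05, min_fold = 2) {
  res <- set_enrichment(gene_list, universe, term_sets, fdr_max = fdr_max,
                        min_set_size = 2)
  keep <- res$significant & !is.na(res$fold_enrichment) &
    res$fold_enrichment >= min_fold
  out <- res[keep, ]
  out <- out[order(out$qvalue, -out$fold_enrichment), ]
  structure(out, class = class(res), n_tested = attr(res, "n_tested"),
            universe_size = attr(res, "universe_size"),
            n_genes = attr(res, "n_genes"))
}
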