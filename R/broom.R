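#' Tidy and one-row summaries of analysis results
#'
#' Broom-style accessors: `tidy()` returns the per-gene (or per-set,
#' per-pair) table as a plain tibble; `glance()` returns a one-row
#' summary of the fit.
#'
#' @param x An analysis result (`cold_de`, `cold_classification`,
#'   `cold_specificity`, `cold_enrichment` or `cold_qc`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name coldatlas-tidiers
NULL

strip_tbl <- function(x) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname coldatlas-tidiers
#' @method tidy cold_de
#' @export
tidy.cold_de <- function(x, ...) strip_tbl(x)

#' @rdname coldatlas-tidiers
#' @method glance cold_de
#' @export
glance.cold_de <- function(x, ...) {
  dplyr::mutate(
    summarize_contrast(x),
    n_tested = attr(x, "n_tested"),
    fdr_max = attr(x, "fdr_max"),
    min_fold_change = attr(x, "min_fold_change")
  )
}

#' @rdname coldatlas-tidiers
#' @method tidy cold_classification
#' @export
tidy.cold_classification <- function(x, ...) strip_tbl(x)

#' @rdname coldatlas-tidiers
#' @method glance cold_classification
#' @export
glance.cold_classification <- function(x, ...) {
  tibble::tibble(
    n_de_genes = nrow(x),
    n_down = sum(x$category == "Down"),
    n_up = sum(x$category == "Up"),
    n_mix = sum(x$category == "Mix"),
    n_contrasts = length(attr(x, "scope"))
  )
}

#' @rdname coldatlas-tidiers
#' @method tidy cold_specificity
#' @export
tidy.cold_specificity <- function(x, ...) strip_tbl(x)

#' @rdname coldatlas-tidiers
#' @method glance cold_specificity
#' @export
glance.cold_specificity <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_groups = attr(x, "n_groups"),
    max_de_score = pair_count(attr(x, "n_groups")),
    mean_H = mean(x$H, na.rm = TRUE),
    median_de_score = median(x$de_score, na.rm = TRUE)
  )
}

#' @rdname coldatlas-tidiers
#' @method tidy cold_enrichment
#' @export
tidy.cold_enrichment <- function(x, ...) strip_tbl(x)

#' @rdname coldatlas-tidiers
#' @method glance cold_enrichment
#' @export
glance.cold_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tested = attr(x, "n_tested"),
    n_significant = sum(x$significant),
    universe_size = attr(x, "universe_size"),
    n_genes = attr(x, "n_genes")
  )
}

#' @rdname coldatlas-tidiers
#' @method tidy cold_qc
#' @export
tidy.cold_qc <- function(x, ...) x$pairs

#' @rdname coldatlas-tidiers
#' @method glance cold_qc
#' @export
glance.cold_qc <- function(x, ...) {
  tibble::tibble(
    n_samples = ncol(x$r2),
    n_replicate_pairs = sum(x$pairs$within_group),
    mean_replicate_r2 = x$mean_replicate_r2
  )
}
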