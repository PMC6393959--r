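#' Summarise a contrast's up/down counts and ratio
#'
#' Returns the per-contrast headline numbers: the number of down- and
#' upregulated genes, their total, and the down/up ratio (reported
#' rounded half-up to 2 decimals and, for display, 1 decimal).  The ratio
#' is undefined when no gene is upregulated.
#'
#' `x` may be a [test_contrast()] result or a data frame of precomputed
#' counts with columns `n_down` and `n_up` (one row per contrast, other
#' columns carried through), so published count tables can be summarised
#' directly.
#'
#' @param x A `cold_de` result or a tibble with `n_down` and `n_up`.
#' @return A tibble with `n_down`, `n_up`, `n_total`, `down_up_ratio`
#'   (2 dp), `down_up_ratio_1dp` and `ratio_undefined`.
#' @export
summarize_contrast <- function(x) {
  UseMethod("summarize_contrast")
}

#' @export
summarize_contrast.cold_de <- function(x) {
  out <- summarize_de_counts(tibble::tibble(
    organ = attr(x, "organ"), duration_h = attr(x, "duration_h"),
    n_down = sum(x$status == "down"), n_up = sum(x$status == "up")
  ))
  out
}

#' @export
summarize_contrast.data.frame <- function(x) {
  if (!all(c("n_down", "n_up") %in% names(x))) {
    abort("count summaries need columns `n_down` and `n_up`")
  }
  summarize_de_counts(x)
}

summarize_de_counts <- function(tbl) {
  ratio <- ifelse(tbl$n_up > 0, tbl$n_down / tbl$n_up, NA_real_)
  dplyr::mutate(tibble::as_tibble(tbl),
                n_total = .data$n_down + .data$n_up,
                down_up_ratio = round_half_up(ratio, 2),
                down_up_ratio_1dp = round_half_up(ratio, 1),
                ratio_undefined = .data$n_up == 0)
}

# accept either cold_de objects or bare tibbles with gene_id + status
de_status_frame <- function(result, name) {
  if (!is.data.frame(result) || !all(c("gene_id", "status") %in% names(result))) {
    abort(sprintf("contrast '%s' must be a data frame with gene_id and status columns", name))
  }
  tibble::tibble(gene_id = as.character(result$gene_id),
                 status = as.character(result$status))
}

#' Classify genes by their cross-contrast response direction
#'
#' Combines per-contrast DE calls over a scope of contrasts into the
#' three response categories: `Down` (downregulated in at least one
#' contrast, upregulated in none), `Up` (the mirror image) and `Mix`
#' (both directions somewhere in the scope).  Genes not significant in
#' any scope contrast are excluded.
#'
#' @param results Named list of [test_contrast()] results (or tibbles
#'   with `gene_id` and `status`), all over the same gene universe.
#' @param scope Character vector of contrast names to consider; defaults
#'   to all of `results`.
#' @return A tibble of class `cold_classification` with `gene_id`,
#'   `category` and one `status_<contrast>` column per scope contrast.
#' @export
classify_response <- function(results, scope = names(results)) {
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a named list of contrasts")
  }
  missing_scope <- setdiff(scope, names(results))
  if (length(missing_scope) > 0) {
    abort(sprintf("unknown contrast(s) in scope: %s", paste(missing_scope, collapse = ", ")))
  }
  frames <- purrr::imap(results[scope], de_status_frame)
  universe <- sort(frames[[1]]$gene_id)
  for (nm in names(frames)) {
    if (!identical(sort(frames[[nm]]$gene_id), universe)) {
      abort(sprintf("contrast '%s' has a different gene universe", nm))
    }
  }
  status <- purrr::map(frames, function(f) setNames(f$status, f$gene_id)[universe])
  smat <- do.call(cbind, status)
  n_up <- rowSums(smat == "up")
  n_down <- rowSums(smat == "down")
  keep <- n_up + n_down > 0
  category <- dplyr::case_when(
    n_up > 0 & n_down > 0 ~ "Mix",
    n_up > 0 ~ "Up",
    n_down > 0 ~ "Down",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(gene_id = universe[keep], category = category[keep])
  for (nm in colnames(smat)) {
    out[[paste0("status_", nm)]] <- unname(smat[keep, nm])
  }
  structure(out, class = c("cold_classification", class(out)), scope = scope)
}

classification_status <- function(classification) {
  cols <- grep("^status_", names(classification), value = TRUE)
  if (length(cols) == 0) abort("classification has no status_ columns")
  m <- as.matrix(classification[cols])
  colnames(m) <- sub("^status_", "", cols)
  rownames(m) <- classification$gene_id
  m
}

#' Count genes shared by exactly k contrasts
#'
#' For one direction class, counts how many genes are differentially
#' expressed in exactly `k = 1, ..., n` contrasts of the scope: `down`
#' counts downregulation among `Down`-category genes, `up` upregulation
#' among `Up` genes, and `mixed` any significant call among `Mix` genes.
#'
#' @param classification A [classify_response()] result.
#' @param direction `"down"`, `"up"` or `"mixed"`.
#' @return A tibble of class `cold_commonality` with `k` and `n_genes`;
#'   the counts sum to the size of the direction's category.
#' @export
commonality <- function(classification, direction = c("down", "up", "mixed")) {
  direction <- match.arg(direction)
  smat <- classification_status(classification)
  cat_name <- c(down = "Down", up = "Up", mixed = "Mix")[[direction]]
  rows <- classification$category == cat_name
  k_of <- if (direction == "mixed") {
    rowSums(smat[rows, , drop = FALSE] != "ns")
  } else {
    rowSums(smat[rows, , drop = FALSE] == direction)
  }
  ks <- seq_len(ncol(smat))
  out <- tibble::tibble(k = ks,
                        n_genes = vapply(ks, function(k) sum(k_of == k), integer(1)))
  structure(out, class = c("cold_commonality", class(out)),
            direction = direction, n_category = sum(rows))
}

#' Genes responding in exactly one contrast
#'
#' @inheritParams commonality
#' @param contrast Name of the contrast (as in the classification's
#'   `status_` columns).
#' @param direction `"down"` or `"up"`.
#' @return Character vector of genes with that direction in `contrast`
#'   and no significant call in any other scope contrast.
#' @export
unique_genes <- function(classification, contrast, direction = c("down", "up")) {
  direction <- match.arg(direction)
  smat <- classification_status(classification)
  if (!contrast %in% colnames(smat)) {
    abort(sprintf("unknown contrast '%s' (scope: %s)", contrast,
                  paste(colnames(smat), collapse = ", ")))
  }
  others <- smat[, colnames(smat) != contrast, drop = FALSE]
  hit <- smat[, contrast] == direction & rowSums(others != "ns") == 0
  rownames(smat)[hit]
}

#' Direction concordance with a signed reference list
#'
#' Compares the sign of DE calls with a reference list of expected
#' directions (for example a regulon observed under constitutive
#' overexpression of its transcription factor).  Only reference genes
#' that are differentially expressed in `result` are compared.
#'
#' @param result A [test_contrast()] result.
#' @param reference Tibble with `gene_id` and `direction`
#'   (`"up"`/`"down"`); no gene may carry both directions.
#' @return One-row tibble with `n_matched`, `n_compared` and `pct_match`
#'   (whole percent, half-up; `NA` when nothing is compared).
#' @export
direction_concordance <- function(result, reference) {
  if (!all(c("gene_id", "direction") %in% names(reference)) || nrow(reference) == 0) {
    abort("`reference` must be a non-empty tibble with gene_id and direction")
  }
  if (!all(reference$direction %in% c("up", "down"))) {
    abort("reference directions must be 'up' or 'down'")
  }
  if (anyDuplicated(reference$gene_id)) {
    dup <- unique(reference$gene_id[duplicated(reference$gene_id)])
    both <- dup[vapply(dup, function(g)
      length(unique(reference$direction[reference$gene_id == g])) > 1, logical(1))]
    if (length(both) > 0) {
      abort(sprintf("gene listed with both directions in reference: %s", both[1]))
    }
    reference <- dplyr::distinct(reference, .data$gene_id, .data$direction)
  }
  calls <- de_status_frame(result, "result")
  merged <- dplyr::inner_join(reference, calls, by = "gene_id")
  merged <- merged[merged$status != "ns", ]
  n_compared <- nrow(merged)
  n_matched <- sum(merged$status == merged$direction)
  tibble::tibble(
    n_matched = n_matched,
    n_compared = n_compared,
    pct_match = if (n_compared > 0) round_half_up(100 * n_matched / n_compared, 0) else NA_real_
  )
}
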