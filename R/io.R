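#' Read a gene-by-sample count matrix
#'
#' Counts are stored as tab-separated text with a header row of sample
#' identifiers and gene identifiers in the first column.  Every entry must
#' be a non-negative integer; malformed files are rejected with the row and
#' column of the first offending cell rather than silently coerced.
#'
#' @param path Path to a tab-separated counts file.
#' @return A tibble whose first column is `gene_id` and whose remaining
#'   columns are integer-valued counts, one per sample.
#' @seealso [write_counts()], [compute_rpkm()]
#' @export
read_counts <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort(sprintf("counts file '%s' needs a gene_id column and at least one sample column", path))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("counts file '%s' is ragged: first problem at row %d, column %d",
                  path, prob$row[1], prob$col[1]))
  }
  names(raw)[1] <- "gene_id"
  counts <- raw
  for (j in 2:ncol(counts)) {
    x <- suppressWarnings(as.numeric(counts[[j]]))
    bad <- which(is.na(x) & !is.na(counts[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric count at row %d, column '%s'", bad[1], names(counts)[j]))
    }
    counts[[j]] <- x
  }
  validate_counts(counts)
  counts
}

#' Write a count matrix to tab-separated text
#'
#' @param counts A counts tibble as returned by [read_counts()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Validate a counts tibble
#'
#' Checks the count-matrix contract: unique gene and sample identifiers,
#' and non-negative integral entries.  Called by all readers and writers;
#' exported so user-assembled tibbles can be checked too.
#'
#' @inheritParams write_counts
#' @return `counts`, invisibly, if valid; otherwise an error naming the
#'   offending cell or identifier.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("counts must be a data frame with a gene_id column and >= 1 sample column")
  }
  gid <- as.character(counts[[1]])
  dup <- gid[duplicated(gid)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id: %s", dup[1]))
  }
  sid <- names(counts)[-1]
  if (anyDuplicated(sid)) {
    abort(sprintf("duplicate sample id: %s", sid[duplicated(sid)][1]))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    abort("count entries must be numeric")
  }
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("invalid count (negative, non-integer or missing) at gene '%s', sample '%s'",
                  gid[bad[1, 1]], sid[bad[1, 2]]))
  }
  invisible(counts)
}

#' Read a sample design table
#'
#' The design maps each sequencing sample to its organ, treatment
#' (`control` or `cold`), stress duration in hours and replicate index.
#'
#' @param path Path to a tab-separated design file with columns
#'   `sample_id`, `organ`, `treatment`, `duration_h`, `replicate`.
#' @param counts Optional counts tibble; when supplied the design is
#'   checked to cover exactly the samples of the count matrix.
#' @return A tibble with one row per sample.
#' @export
read_design <- function(path, counts = NULL) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    organ = readr::col_character(),
    treatment = readr::col_character(),
    duration_h = readr::col_double(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  validate_design(design, counts)
  design
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
validate_design <- function(design, counts = NULL) {
  need <- c("sample_id", "organ", "treatment", "duration_h", "replicate")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    abort(sprintf("design is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort(sprintf("duplicate sample_id in design: %s",
                  design$sample_id[duplicated(design$sample_id)][1]))
  }
  bad_trt <- setdiff(unique(design$treatment), c("control", "cold"))
  if (length(bad_trt) > 0) {
    abort(sprintf("unknown treatment label '%s' (expected control or cold)", bad_trt[1]))
  }
  if (any(design$treatment == "control" & design$duration_h != 0)) {
    abort("control samples must have duration_h = 0")
  }
  if (any(design$replicate < 1 | design$replicate != floor(design$replicate))) {
    abort("replicate must be a positive integer")
  }
  if (!is.null(counts)) {
    csamp <- names(counts)[-1]
    miss <- setdiff(csamp, design$sample_id)
    if (length(miss) > 0) {
      abort(sprintf("design is missing counts sample(s): %s", paste(miss, collapse = ", ")))
    }
    extra <- setdiff(design$sample_id, csamp)
    if (length(extra) > 0) {
      abort(sprintf("design sample(s) absent from counts: %s", paste(extra, collapse = ", ")))
    }
  }
  invisible(design)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read exonic gene lengths
#'
#' @param path Tab-separated file with columns `gene_id` and `length_bp`.
#' @return A tibble with `gene_id` and positive integer `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  len <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    length_bp = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(len$gene_id)) {
    abort(sprintf("duplicate gene_id in lengths: %s", len$gene_id[duplicated(len$gene_id)][1]))
  }
  if (any(!is.finite(len$length_bp) | len$length_bp <= 0 | len$length_bp != floor(len$length_bp))) {
    bad <- which(!is.finite(len$length_bp) | len$length_bp <= 0 |
                   len$length_bp != floor(len$length_bp))[1]
    abort(sprintf("gene length must be a positive integer (gene '%s')", len$gene_id[bad]))
  }
  len
}

#' @rdname read_gene_lengths
#' @param lengths A gene-length tibble.
#' @export
write_gene_lengths <- function(lengths, path) {
  readr::write_tsv(lengths, path, progress = FALSE)
  invisible(path)
}

#' Read a flat gene-set annotation file
#'
#' Annotation files carry one `(term_id, gene_id)` pair per line, e.g.
#' transcription-factor target sets or functional category terms.
#'
#' @param path Tab-separated two-column file `term_id<TAB>gene_id`.
#' @param kind Optional label (`"tf_target"` or `"category_term"`) stored
#'   as an attribute.
#' @return A tibble with columns `term_id` and `gene_id`.
#' @export
read_annotation <- function(path, kind = NULL) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    term_id = readr::col_character(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  if (nrow(ann) > 0 && anyDuplicated(ann[c("term_id", "gene_id")])) {
    ann <- dplyr::distinct(ann)
  }
  if (!is.null(kind)) attr(ann, "kind") <- kind
  ann
}

#' @rdname read_annotation
#' @param annotation An annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[c("term_id", "gene_id")], path, progress = FALSE)
  invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' Normalises raw counts for gene length and sequencing depth:
#' `rpkm = count * 1e9 / (length_bp * total_counts_of_sample)`.  The
#' per-million denominator is each sample's total assigned gene reads.
#'
#' @inheritParams write_counts
#' @param lengths Gene-length tibble covering every gene in `counts`.
#' @return A tibble of the same shape as `counts` with RPKM values.
#' @export
compute_rpkm <- function(counts, lengths) {
  validate_counts(counts)
  len <- setNames(lengths$length_bp, lengths$gene_id)
  miss <- setdiff(counts$gene_id, names(len))
  if (length(miss) > 0) {
    abort(sprintf("missing gene length(s): %s", paste(head(miss, 5), collapse = ", ")))
  }
  m <- counts_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("sample '%s' has zero total counts", colnames(m)[which(totals == 0)[1]]))
  }
  r <- m * 1e9 / outer(unname(len[rownames(m)]), totals)
  out <- matrix_to_counts(r)
  names(out)[1] <- names(counts)[1]
  out
}
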