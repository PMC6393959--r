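# shared helpers; internal only

# round-half-up (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# counts tibble -> numeric matrix with gene_id rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts[[1]]
  m
}

matrix_to_counts <- function(m, id_col = "gene_id") {
  out <- tibble::as_tibble(m, rownames = id_col)
  out
}

# canonical group label for a design row set
design_groups <- function(design) {
  if ("group" %in% names(design)) {
    return(as.character(design$group))
  }
  cols <- intersect(c("organ", "treatment", "duration_h"), names(design))
  if (length(cols) == 0) {
    abort("design must contain a `group` column or organ/treatment/duration_h columns")
  }
  do.call(paste, c(unname(as.list(design[cols])), sep = "_"))
}

# named list of character vectors from a (term_id, gene_id) tibble or list
as_gene_sets <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("gene-set list must have unique names")
    }
    return(lapply(sets, function(x) unique(as.character(x))))
  }
  if (!is.data.frame(sets) || !all(c("term_id", "gene_id") %in% names(sets))) {
    abort("gene sets must be a named list or a data frame with columns term_id and gene_id")
  }
  split(as.character(sets$gene_id), factor(sets$term_id, levels = unique(sets$term_id)))
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
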