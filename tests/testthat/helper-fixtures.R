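# shared fixtures, built in code

# a small simulated experiment; defaults keep tests fast
small_sim <- function(seed = 11, n_genes = 400,
                      organs = c("cotyledons", "leaf", "seeds"),
                      n_tf_sets = 8, n_active_tf_sets = 2,
                      n_term_sets = 8, n_active_term_sets = 2, ...) {
  simulate_dataset(sim_config(
    n_genes = n_genes, organs = organs,
    n_tf_sets = n_tf_sets, n_active_tf_sets = n_active_tf_sets,
    n_term_sets = n_term_sets, n_active_term_sets = n_active_term_sets,
    seed = seed, ...
  ))
}

# bare per-contrast status frame, enough for classification functions
status_frame <- function(gene_id, status) {
  tibble::tibble(gene_id = gene_id, status = status)
}

# random per-contrast status lists over a fixed gene universe
random_results <- function(n_genes, n_contrasts,
                           probs = c(down = 0.1, ns = 0.8, up = 0.1)) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  res <- lapply(seq_len(n_contrasts), function(i) {
    status_frame(genes, sample(names(probs), n_genes, TRUE, prob = probs))
  })
  names(res) <- sprintf("c%d", seq_len(n_contrasts))
  res
}

# a counts tibble from a plain matrix
counts_tbl <- function(m, genes = sprintf("g%03d", seq_len(nrow(m))),
                       samples = sprintf("s%d", seq_len(ncol(m)))) {
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = genes), out)
}

# independent BH step-up oracle: q_(i) = min over j >= i of min(1, m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive right-tail Fisher oracle by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  K <- a + c   # targets
  n <- a + b   # draws (DE genes)
  N <- a + b + c + d
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}
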