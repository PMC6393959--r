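#' Configure the synthetic cold-stress experiment
#'
#' Builds a validated configuration for [simulate_dataset()].  Defaults
#' mirror a six-organ cold-stress design: aerial organs sampled under
#' control conditions and after 3 h and 27 h at +4 degrees C, with
#' negative-binomial counts, a spectrum of expression-pattern widths from
#' ubiquitous to single-organ genes, organ-dependent stress effects
#' including sign flips, and transcription-factor regulons enriched among
#' stress-responsive genes.
#'
#' @param n_genes Number of genes.
#' @param organs Organ labels; the first three (when present among
#'   `"cotyledons"`, `"hypocotyl"`, `"leaf"`) share a photosynthetic
#'   baseline block so sample clustering has realistic structure.
#' @param timepoints_h Cold-stress durations in hours.
#' @param n_replicates Replicates per (organ, condition) group; >= 2.
#' @param frac_de_per_contrast Fraction of (expressed) genes with a true
#'   stress effect in each organ-by-timepoint contrast.
#' @param effect_log2fc_range Interval of |true log2 fold change| for
#'   genes with a stress effect; the lower bound must be >= 1 so every
#'   true effect clears a 2-fold threshold.
#' @param frac_sign_flip Fraction of stress-responsive genes given
#'   opposite-direction effects in two organs (the future "Mix" class).
#' @param frac_organ_specific Fraction of genes expressed in exactly one
#'   organ under control conditions.
#' @param baseline_log_mean,baseline_log_sd Natural-log-normal parameters
#'   of the control expression mean.
#' @param dispersion Negative-binomial dispersion alpha
#'   (`Var = mu + alpha * mu^2`); a single value or one per gene.
#' @param n_tf_sets,n_active_tf_sets Number of simulated transcription
#'   factor regulons and how many of them are "active" (target sets
#'   enriched among stress-responsive genes).
#' @param tf_target_de_enrichment Multiplicative enrichment of
#'   stress-responsive genes among targets of active regulons.
#' @param n_term_sets,n_active_term_sets Number of functional category
#'   terms and how many are enriched among stress-responsive genes.
#' @param size_factor_range Per-sample library-size factors are drawn
#'   log-uniformly from this interval.
#' @param seed Integer seed; all draws flow from this single seed.
#' @return A `cold_sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       organs = c("cotyledons", "hypocotyl", "leaf",
                                  "flower", "young_flower", "seeds"),
                       timepoints_h = c(3, 27),
                       n_replicates = 3,
                       frac_de_per_contrast = 0.1,
                       effect_log2fc_range = c(1.5, 4),
                       frac_sign_flip = 0.05,
                       frac_organ_specific = 0.1,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.5,
                       dispersion = 0.05,
                       n_tf_sets = 219,
                       n_active_tf_sets = 10,
                       tf_target_de_enrichment = 4,
                       n_term_sets = 40,
                       n_active_term_sets = 5,
                       size_factor_range = c(0.5, 2),
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, organs = organs, timepoints_h = timepoints_h,
    n_replicates = n_replicates, frac_de_per_contrast = frac_de_per_contrast,
    effect_log2fc_range = effect_log2fc_range, frac_sign_flip = frac_sign_flip,
    frac_organ_specific = frac_organ_specific,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion, n_tf_sets = n_tf_sets,
    n_active_tf_sets = n_active_tf_sets,
    tf_target_de_enrichment = tf_target_de_enrichment,
    n_term_sets = n_term_sets, n_active_term_sets = n_active_term_sets,
    size_factor_range = size_factor_range, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cold_sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_genes) || length(cfg$n_genes) != 1 || cfg$n_genes < 1) {
    abort("invalid config field `n_genes`: must be a positive integer")
  }
  if (length(cfg$organs) < 1 || anyDuplicated(cfg$organs)) {
    abort("invalid config field `organs`: must be a non-empty set of unique labels")
  }
  if (length(cfg$timepoints_h) < 1 || any(cfg$timepoints_h <= 0)) {
    abort("invalid config field `timepoints_h`: durations must be positive")
  }
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 2) {
    abort("invalid config field `n_replicates`: must be >= 2")
  }
  for (f in c("frac_de_per_contrast", "frac_sign_flip", "frac_organ_specific")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("invalid config field `%s`: must be a fraction in [0, 1]", f))
    }
  }
  r <- cfg$effect_log2fc_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
    abort("invalid config field `effect_log2fc_range`: lower bound must be >= 1 and <= upper")
  }
  d <- cfg$dispersion
  if (!is.numeric(d) || !(length(d) == 1 || length(d) == cfg$n_genes) || any(d < 0)) {
    abort("invalid config field `dispersion`: scalar or length n_genes, all >= 0")
  }
  if (cfg$n_active_tf_sets > cfg$n_tf_sets) {
    abort("invalid config field `n_active_tf_sets`: cannot exceed n_tf_sets")
  }
  if (cfg$n_active_term_sets > cfg$n_term_sets) {
    abort("invalid config field `n_active_term_sets`: cannot exceed n_term_sets")
  }
  sfr <- cfg$size_factor_range
  if (length(sfr) != 2 || any(sfr <= 0) || sfr[1] > sfr[2]) {
    abort("invalid config field `size_factor_range`: need 0 < lo <= hi")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("invalid config field `seed`: must be a single integer")
  }
  invisible(cfg)
}

nb_draw <- function(n, mu, alpha) {
  # alpha = 0 degenerates to Poisson
  pois <- alpha < 1e-12
  out <- numeric(n)
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
  }
  out
}

#' Simulate a cold-stress count dataset with known truth
#'
#' Generates a gene-by-sample count matrix, its sample design, gene
#' lengths, gene-set annotations (transcription-factor regulons and
#' functional terms) and a per-gene ground-truth table.  Counts are drawn
#' from a negative binomial with `Var = mu + alpha * mu^2`; stress-group
#' means equal the control mean times `2^(true log2 fold change)`;
#' per-sample library-size factors perturb every mean.  Output is
#' deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cold_sim` with elements `counts`, `design`,
#'   `lengths`, `annotations` (tibble `term_id`, `gene_id`, `kind`),
#'   `sets` (per-set truth: `set_id`, `kind`, `active`), `truth` (per-gene
#'   truth), `size_factors`, and `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  withr::with_seed(as.integer(config$seed), simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- as.integer(cfg$n_genes)
  organs <- cfg$organs
  tps <- cfg$timepoints_h
  gene_id <- sprintf("AT%dG%05d", (seq_len(n) - 1L) %% 5L + 1L, seq_len(n))
  alpha <- if (length(cfg$dispersion) == 1) rep(cfg$dispersion, n) else cfg$dispersion

  # control baselines: shared gene level x block deviation x organ deviation
  lam <- rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  photo <- intersect(organs, c("cotyledons", "hypocotyl", "leaf"))
  blocks <- if (length(photo) >= 2) ifelse(organs %in% photo, "photosynthetic", organs) else organs
  block_names <- unique(blocks)
  block_dev <- matrix(rnorm(n * length(block_names), 0, 0.8), nrow = n,
                      dimnames = list(NULL, block_names))
  organ_dev <- matrix(rnorm(n * length(organs), 0, 0.15), nrow = n,
                      dimnames = list(NULL, organs))
  mean_organ <- matrix(0, n, length(organs), dimnames = list(NULL, organs))
  for (i in seq_along(organs)) {
    mean_organ[, i] <- lam * exp(block_dev[, blocks[i]] + organ_dev[, i])
  }

  # organ-specific genes: expressed in exactly one organ under control
  pattern <- rep("ubiquitous", n)
  n_os <- round(cfg$frac_organ_specific * n)
  if (n_os > 0) {
    os_idx <- sample.int(n, n_os)
    os_organ <- sample(organs, n_os, replace = TRUE)
    pattern[os_idx] <- paste0("organ_specific:", os_organ)
    for (k in seq_len(n_os)) {
      mean_organ[os_idx[k], organs != os_organ[k]] <- 0
    }
  }

  # true stress effects per organ x timepoint contrast
  lfc <- array(0, dim = c(n, length(organs), length(tps)),
               dimnames = list(gene_id, organs, paste0(tps, "h")))
  lo <- cfg$effect_log2fc_range[1]; hi <- cfg$effect_log2fc_range[2]
  for (oi in seq_along(organs)) {
    eligible <- which(mean_organ[, oi] > 0)
    for (ti in seq_along(tps)) {
      n_de <- round(cfg$frac_de_per_contrast * length(eligible))
      if (n_de > 0) {
        idx <- sample(eligible, n_de)
        lfc[idx, oi, ti] <- sample(c(-1, 1), n_de, replace = TRUE) * runif(n_de, lo, hi)
      }
    }
  }

  # explicit sign-flip genes: opposite directions in two organs (Mix class)
  de_any <- which(apply(lfc != 0, 1, any))
  n_flip <- if (length(organs) >= 2) round(cfg$frac_sign_flip * length(de_any)) else 0
  if (n_flip > 0) {
    ubi <- which(pattern == "ubiquitous")
    cand <- intersect(de_any, ubi)
    if (length(cand) < n_flip) cand <- ubi
    flip <- sample(cand, min(n_flip, length(cand)))
    for (g in flip) {
      oo <- sample.int(length(organs), 2)
      for (ti in seq_along(tps)) {
        e <- runif(1, lo, hi)
        lfc[g, oo[1], ti] <- e
        lfc[g, oo[2], ti] <- -e
      }
    }
  }

  # sample sheet: organ x (control + each timepoint) x replicate
  cond <- rbind(data.frame(treatment = "control", duration_h = 0),
                data.frame(treatment = "cold", duration_h = tps))
  design <- tidyr::expand_grid(
    organ = organs,
    cond,
    replicate = seq_len(cfg$n_replicates)
  )
  design$sample_id <- with(design, paste0(
    organ, "_", ifelse(treatment == "control", "control", paste0("cold", duration_h)),
    "_r", replicate
  ))
  design <- tibble::as_tibble(design[c("sample_id", "organ", "treatment",
                                       "duration_h", "replicate")])

  sf <- exp(runif(nrow(design), log(cfg$size_factor_range[1]),
                  log(cfg$size_factor_range[2])))
  names(sf) <- design$sample_id

  counts <- matrix(0, n, nrow(design), dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    oi <- match(design$organ[j], organs)
    mu <- mean_organ[, oi]
    if (design$treatment[j] == "cold") {
      ti <- match(design$duration_h[j], tps)
      mu <- mu * 2^lfc[, oi, ti]
    }
    counts[, j] <- nb_draw(n, mu * sf[j], alpha)
  }

  lengths <- tibble::tibble(gene_id = gene_id,
                            length_bp = sample(300:5000, n, replace = TRUE))

  de_any_flag <- apply(lfc != 0, 1, any)
  tf <- simulate_sets(gene_id, de_any_flag, cfg$n_tf_sets, cfg$n_active_tf_sets,
                      cfg$tf_target_de_enrichment, "TF_%03d", "tf_target")
  terms <- simulate_sets(gene_id, de_any_flag, cfg$n_term_sets, cfg$n_active_term_sets,
                         cfg$tf_target_de_enrichment, "TERM_%03d", "category_term")

  truth <- tibble::tibble(gene_id = gene_id, pattern = pattern, dispersion = alpha)
  for (o in organs) truth[[paste0("mean_", o)]] <- mean_organ[, o]
  for (ti in seq_along(tps)) {
    for (oi in seq_along(organs)) {
      key <- paste0(organs[oi], "_", tps[ti], "h")
      truth[[paste0("lfc_", key)]] <- lfc[, oi, ti]
      truth[[paste0("de_", key)]] <- lfc[, oi, ti] != 0
    }
  }

  structure(list(
    counts = matrix_to_counts(counts),
    design = design,
    lengths = lengths,
    annotations = dplyr::bind_rows(tf$annotations, terms$annotations),
    sets = dplyr::bind_rows(tf$sets, terms$sets),
    truth = truth,
    size_factors = sf,
    config = cfg
  ), class = "cold_sim")
}

# sample gene sets; "active" sets oversample stress-responsive genes so that
# P(target | DE) / P(target | non-DE) ~= enrichment
simulate_sets <- function(gene_id, de_flag, n_sets, n_active, enrichment,
                          id_fmt, kind) {
  if (n_sets == 0) {
    empty <- tibble::tibble(term_id = character(), gene_id = character(),
                            kind = character())
    return(list(annotations = empty,
                sets = tibble::tibble(set_id = character(), kind = character(),
                                      active = logical())))
  }
  n <- length(gene_id)
  set_id <- sprintf(id_fmt, seq_len(n_sets))
  active <- rep(FALSE, n_sets)
  if (n_active > 0) active[sample.int(n_sets, n_active)] <- TRUE
  w_active <- ifelse(de_flag, enrichment, 1)
  ann <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    size <- sample(50:200, 1)
    size <- min(size, n)
    members <- if (active[i] && any(de_flag)) {
      sample(gene_id, size, prob = w_active)
    } else {
      sample(gene_id, size)
    }
    ann[[i]] <- tibble::tibble(term_id = set_id[i], gene_id = members, kind = kind)
  }
  list(annotations = dplyr::bind_rows(ann),
       sets = tibble::tibble(set_id = set_id, kind = kind, active = active))
}

#' Write or read a simulation ground-truth table
#'
#' The truth table is written as tab-separated text preceded by `#`
#' comment lines documenting the columns, one row per gene.
#'
#' @param truth The `truth` tibble of a [simulate_dataset()] result.
#' @param path Output path.
#' @return `path` invisibly (`write_truth`); a tibble (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  ok <- tryCatch({
    writeLines(c(
      "# simulation ground truth: one row per gene",
      "# pattern: ubiquitous | organ_specific:<organ>",
      "# dispersion: NB dispersion alpha (Var = mu + alpha mu^2)",
      "# mean_<organ>: control-condition expected count",
      "# lfc_<organ>_<t>h / de_<organ>_<t>h: true stress log2FC and DE flag"
    ), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write truth file '%s'", path))
  readr::write_tsv(truth, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols(gene_id = readr::col_character(),
                                          pattern = readr::col_character(),
                                          .default = readr::col_guess()))
}

#' Write every simulated artefact of a run to a directory
#'
#' @param sim A `cold_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    annotations = file.path(dir, "annotation_sets.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(sim$counts, paths["counts"])
  write_design(sim$design, paths["design"])
  write_gene_lengths(sim$lengths, paths["lengths"])
  readr::write_tsv(sim$annotations, paths["annotations"], progress = FALSE)
  write_truth(sim$truth, paths["truth"])
  invisible(paths)
}
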