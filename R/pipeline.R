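#' Run the full cold-stress analysis pipeline
#'
#' Orchestrates simulate (or load) -> qc -> differential expression ->
#' cross-organ classification -> specificity -> enrichment, writing every
#' stage's output under one run directory together with a JSON manifest
#' (package version, seed, parameters actually used, per-stage status and
#' an MD5 checksum per written file).  Reruns with the same configuration
#' and seed reproduce byte-identical tables.
#'
#' The configuration is a flat list (or a YAML/JSON file holding one)
#' with elements:
#' \describe{
#'   \item{seed}{integer seed for the simulation stage.}
#'   \item{simulate}{list of [sim_config()] arguments; when absent,
#'     `inputs` must name `counts`, `design`, `lengths` and optionally
#'     `annotations` files.}
#'   \item{fdr_max, min_fold_change}{DE thresholds (defaults 0.05 and 2).}
#'   \item{specificity, enrich}{logical stage switches (defaults `TRUE`).}
#' }
#'
#' @param config Configuration list, or path to a YAML/JSON file.
#' @param out_dir Run directory (created if needed).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a config file path")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  params <- list(
    seed = config$seed %||% 1L,
    fdr_max = config$fdr_max %||% 0.05,
    min_fold_change = config$min_fold_change %||% 2,
    specificity = config$specificity %||% TRUE,
    enrich = config$enrich %||% TRUE,
    simulate = config$simulate
  )
  manifest <- list(package = "coldatlas",
                   version = as.character(utils::packageVersion("coldatlas")),
                   parameters = params, stages = list(), files = list())
  files <- character()
  env <- new.env(parent = emptyenv())

  add_file <- function(path) files <<- c(files, path)
  fail <- function(stage, err) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(err)), marker)
    manifest$stages[[stage]] <<- "FAILED"
    manifest$files <<- unname_md5(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(err)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
    manifest$stages[[stage]] <<- "PASSED"
  }

  run_stage("simulate", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- params$seed
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      in_dir <- file.path(out_dir, "inputs")
      add_file(write_sim(sim, in_dir))
      env$counts <- sim$counts; env$design <- sim$design
      env$lengths <- sim$lengths; env$annotations <- sim$annotations
    } else {
      inp <- config$inputs
      if (is.null(inp$counts) || !file.exists(inp$counts)) {
        abort(sprintf("missing counts file: %s", inp$counts %||% "<unset>"))
      }
      env$counts <- read_counts(inp$counts)
      env$design <- read_design(inp$design, env$counts)
      env$lengths <- read_gene_lengths(inp$lengths)
      env$annotations <- if (!is.null(inp$annotations)) read_annotation(inp$annotations)
    }
  })

  run_stage("qc", {
    rpkm <- compute_rpkm(env$counts, env$lengths)
    qc <- replicate_correlation(rpkm, env$design)
    p <- file.path(out_dir, "qc_replicate_correlation.tsv")
    readr::write_tsv(qc$pairs, p, progress = FALSE); add_file(p)
    tree <- cluster_samples(rpkm)
    p <- file.path(out_dir, "qc_sample_tree.nwk")
    writeLines(sample_tree_newick(tree), p); add_file(p)
    env$qc <- qc
  })

  run_stage("de", {
    res <- test_all_contrasts(env$counts, env$design,
                              fdr_max = params$fdr_max,
                              min_fold_change = params$min_fold_change)
    for (nm in names(res)) {
      p <- file.path(out_dir, paste0("de_", nm, ".tsv"))
      readr::write_tsv(tidy(res[[nm]]), p, progress = FALSE); add_file(p)
    }
    summary <- dplyr::bind_rows(lapply(res, glance))
    p <- file.path(out_dir, "de_summary.tsv")
    readr::write_tsv(summary, p, progress = FALSE); add_file(p)
    env$de <- res
  })

  run_stage("classify", {
    cls <- classify_response(env$de)
    p <- file.path(out_dir, "classification.tsv")
    readr::write_tsv(tibble::as_tibble(cls), p, progress = FALSE); add_file(p)
    durations <- unique(env$design$duration_h[env$design$treatment == "cold"])
    common <- list()
    for (t in durations) {
      scope <- grep(paste0("_", t, "h$"), names(env$de), value = TRUE)
      if (length(scope) == 0) next
      cls_t <- classify_response(env$de, scope = scope)
      for (dir in c("down", "up", "mixed")) {
        ct <- commonality(cls_t, dir)
        common[[length(common) + 1]] <- dplyr::mutate(
          tibble::as_tibble(ct), duration_h = t, direction = dir, .before = 1)
      }
    }
    if (length(common) > 0) {
      p <- file.path(out_dir, "commonality.tsv")
      readr::write_tsv(dplyr::bind_rows(common), p, progress = FALSE); add_file(p)
    }
    env$classification <- cls
  })

  if (isTRUE(params$specificity)) {
    run_stage("specificity", {
      prof <- specificity_table(env$counts, env$design, env$lengths,
                                fdr_max = params$fdr_max,
                                min_fold_change = params$min_fold_change)
      p <- file.path(out_dir, "specificity.tsv")
      readr::write_tsv(tibble::as_tibble(prof), p, progress = FALSE); add_file(p)
      env$specificity <- prof
    })
  }

  if (isTRUE(params$enrich) && !is.null(env$annotations) && nrow(env$annotations) > 0) {
    run_stage("enrich", {
      de_any <- env$classification$gene_id
      universe <- env$counts$gene_id
      out <- list()
      for (kind in unique(env$annotations$kind %||% "set")) {
        ann <- env$annotations
        if (!is.null(ann$kind)) ann <- ann[ann$kind == kind, ]
        enr <- suppressWarnings(tf_enrichment(de_any, universe, ann,
                                              fdr_max = params$fdr_max))
        out[[kind]] <- dplyr::mutate(tibble::as_tibble(enr), kind = kind, .before = 1)
      }
      p <- file.path(out_dir, "enrichment.tsv")
      readr::write_tsv(dplyr::bind_rows(out), p, progress = FALSE); add_file(p)
    })
  }

  manifest$files <- as.list(unname_md5(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5sum keyed by path relative to the run dir parent would leak tempdirs
# into the manifest; key by basename instead (unique within one run)
unname_md5 <- function(x) {
  names(x) <- basename(names(x))
  as.list(x)
}
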