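#' Default run configuration
#'
#' Returns the full configuration list the pipeline consumes, with
#' documented defaults; any element can be overridden via `...`. Paths
#' (`ppi`, `gwas`, `annotations`, `gmt`, and optionally `tf_map`,
#' `targets`) must point to existing files; `out_dir` receives all reports.
#'
#' @param ... Named overrides of individual settings.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    ppi = NULL, gwas = NULL, annotations = NULL, tf_map = NULL,
    gmt = NULL, targets = NULL, out_dir = "gwasnet-out",
    p_column = "p", id_column = "snp",
    alpha = 0.05,          # nominal association threshold (strict <)
    n_samples = 10000L,    # Monte-Carlo background samples per size
    threshold = 3,         # combined-score significance cutoff
    max_size = 300L,       # module growth cap
    top_n = 5L,            # modules kept for reporting
    min_genes = 3L,        # term prefilter for enrichment
    kappa_threshold = 0.3, # term-grouping threshold
    seed = 1L)
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0)
      stop("configuration error: unknown setting '", bad[1L], "'")
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a run configuration from a JSON file
#'
#' @param path Path to a JSON object whose keys are [default_config()]
#'   settings.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains SNP scoring (filter, gene assignment, weighted p-value
#' aggregation, TF augmentation), active sub-network search (z transform,
#' Monte-Carlo calibration, greedy growth), enrichment of the top module
#' (hypergeometric test, Bonferroni, kappa grouping, annotation network),
#' and topology diagnostics, then writes all reports to `config$out_dir`.
#' Stage seeds are derived from `config$seed` by fixed offsets. All
#' log output goes to `stderr` via `message()`; data only to files.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @return Invisibly, a list with all intermediate and final objects plus
#'   the stage `counts`.
#' @export
run_pipeline <- function(config) {
  for (f in c("ppi", "gwas", "annotations", "gmt")) {
    if (is.null(config[[f]])) stop("configuration error: '", f, "' not set")
    if (!file.exists(config[[f]]))
      stop("fatal: input file for '", f, "' not found: ", config[[f]])
  }
  counts <- c()
  ## inputs
  network <- run_stage("read", read_ppi(config$ppi))
  snps <- run_stage("read", read_gwas_table(config$gwas, config$p_column,
                                            config$id_column))
  annotations <- run_stage("read", {
    a <- utils::read.table(config$annotations, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
    if ("ps" %in% names(a)) a$ps <- suppressWarnings(as.numeric(a$ps))
    a
  })
  collection <- run_stage("read", read_gmt(config$gmt))
  tf_map <- NULL
  if (!is.null(config$tf_map) && file.exists(config$tf_map))
    tf_map <- utils::read.table(config$tf_map, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, quote = "")
  counts["snps_read"] <- nrow(snps)

  ## step 1: scoring
  res <- run_stage("score", {
    kept <- filter_nominal(snps, config$alpha)
    assignments <- assign_snps_to_genes(kept, annotations)
    gene_scores <- aggregate_gene_pw(assignments, kept)
    spw <- snp_pw_table(assignments, kept)
    n_before <- nrow(gene_scores)
    if (!is.null(tf_map) && nrow(tf_map) > 0)
      gene_scores <- augment_tfbs(gene_scores, tf_map, spw)
    list(kept = kept, assignments = assignments,
         gene_scores = gene_scores, tfs_added = nrow(gene_scores) - n_before)
  })
  counts["snps_nominal"] <- nrow(res$kept)
  counts["genes_scored"] <- nrow(res$gene_scores)
  counts["tfs_added"] <- res$tfs_added

  ## step 2: active sub-network search
  search <- run_stage("search", {
    scores <- node_score_table(res$gene_scores, network)
    if (nrow(scores) < 2) stop("fewer than 2 scored genes on the network")
    max_size <- min(config$max_size, nrow(scores) - 1L)
    if (max_size < config$max_size)
      message(sprintf("search: max_size reduced to %d (scored genes - 1)",
                      max_size))
    bg <- calibrate_background(scores, sizes = seq_len(max_size),
                               n_samples = config$n_samples,
                               seed = config$seed + 101L)
    modules <- greedy_search(network, scores, bg,
                             threshold = config$threshold,
                             max_size = max_size)
    top <- select_top_modules(modules, config$top_n)
    list(scores = scores, bg = bg, modules = modules, top = top)
  })
  counts["modules_significant"] <- nrow(search$modules)

  ## step 3: enrichment of the top module
  enr <- run_stage("enrich", {
    if (nrow(search$top) == 0) {
      message("enrich: no significant module; skipping enrichment")
      list(results = NULL, groups = NULL, annotation = NULL)
    } else {
      module_genes <- search$top$genes[[1L]]
      results <- enrich_module(module_genes, collection, config$min_genes)
      if (nrow(results) > 0) {
        groups <- group_terms(results, config$kappa_threshold)
        annotation <- build_annotation_network(results, groups)
      } else {
        groups <- NULL
        annotation <- NULL
      }
      list(results = results, groups = groups, annotation = annotation)
    }
  })
  counts["terms_enriched"] <- if (is.null(enr$results)) 0L else nrow(enr$results)
  counts["term_groups"] <- if (is.null(enr$groups)) 0L else length(enr$groups$groups)

  ## topology diagnostics on the top module
  topo <- run_stage("topology", {
    if (nrow(search$top) == 0) return(NULL)
    sub <- igraph::induced_subgraph(
      network, igraph::V(network)$name %in% search$top$genes[[1L]])
    dd <- degree_distribution(sub)
    fit <- tryCatch(fit_power_law(dd), error = function(e) NULL)
    rand <- erdos_renyi_randomize(sub, seed = config$seed + 202L)
    list(dist = dd, fit = fit,
         poisson_random = poisson_check(degree_distribution(rand)))
  })

  ## drug-target comparison, if a target list is supplied
  overlap <- NULL
  if (!is.null(config$targets) && file.exists(config$targets)) {
    overlap <- run_stage("targets", {
      targets <- readLines(config$targets)
      targets <- targets[nzchar(targets)]
      pathway_union <- if (!is.null(enr$results) && nrow(enr$results) > 0)
        sort(unique(unlist(collection$genes[enr$results$term_id]))) else character(0)
      drug_target_overlap(res$gene_scores$gene, pathway_union, targets)
    })
  }

  ## reports
  enr_table <- NULL
  if (!is.null(enr$results)) {
    enr_table <- enr$results
    enr_table$genes_found <- lapply(enr_table$genes_found, identity)
  }
  files <- run_stage("report", write_reports(list(
    gene_scores = res$gene_scores,
    modules = search$modules,
    enrichment = enr_table,
    annotation = enr$annotation,
    config = config[!vapply(config, is.null, logical(1))],
    seed = config$seed,
    counts = counts), config$out_dir))
  message("run_pipeline: done; reports in ", config$out_dir)
  invisible(list(network = network, snps = snps,
                 gene_scores = res$gene_scores, scores = search$scores,
                 background = search$bg, modules = search$modules,
                 top = search$top, enrichment = enr$results,
                 groups = enr$groups, annotation = enr$annotation,
                 topology = topo, overlap = overlap,
                 counts = counts, files = files))
}
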