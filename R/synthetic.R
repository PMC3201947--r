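#' Generate a synthetic protein-protein interaction network
#'
#' Preferential attachment (default) emulates the heavy-tailed degree
#' distribution of curated human PPI maps; the Erdos-Renyi mode gives a
#' Poisson-degree control network. Vertex names are `G0001`, `G0002`, ...
#'
#' @param n_nodes Number of genes.
#' @param model `"preferential-attachment"` or `"erdos-renyi"`.
#' @param param Edges added per node (preferential attachment, default 3)
#'   or total edge count (Erdos-Renyi, default `3 * n_nodes`).
#' @param seed RNG seed (caller's RNG state restored).
#' @return An undirected simple igraph graph.
#' @export
generate_ppi <- function(n_nodes,
                         model = c("preferential-attachment", "erdos-renyi"),
                         param = NULL, seed = 1L) {
  model <- match.arg(model)
  g <- with_seed(seed, {
    if (model == "preferential-attachment") {
      igraph::sample_pa(n_nodes, power = 1, m = param %||% 3L,
                        directed = FALSE)
    } else {
      igraph::sample_gnm(n_nodes, param %||% (3L * n_nodes),
                         directed = FALSE)
    }
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  g
}

#' Plant a low-p-value module in a network
#'
#' Selects a connected `k_module`-gene subgraph by a seeded random walk and
#' assigns it small p-values on both attributes: member p-values are
#' Beta(`signal_strength`, 1) distributed (via `U^(1/alpha)`), coupled
#' across the two attributes through a shared latent Gaussian with mixing
#' weight `attr_correlation`; non-members draw independent Uniform(0, 1)
#' p-values per attribute. `signal_strength = 1` reduces members to the
#' uniform background (null case).
#'
#' @param network An igraph graph.
#' @param k_module Planted module size (default 25).
#' @param signal_strength Beta shape alpha in (0, 1]; smaller = stronger
#'   signal (default 0.1).
#' @param attr_correlation Latent mixing weight in \[0, 1\] coupling the two
#'   attributes for members (default 0.8: both attributes derive from the
#'   same underlying association signal and differ only in functional
#'   weighting, so they are strongly but not perfectly correlated).
#' @param seed RNG seed.
#' @return List with `scores` (`data.frame` `gene`, `spot_pw`, `fsnp_pw`)
#'   and `truth` (list with `module`, generator parameters, `seed`).
#' @export
plant_signal <- function(network, k_module = 25L, signal_strength = 0.1,
                         attr_correlation = 0.8, seed = 1L) {
  if (signal_strength <= 0 || signal_strength > 1)
    stop("signal_strength must lie in (0, 1]")
  genes <- igraph::V(network)$name
  n <- length(genes)
  if (k_module > n) stop("k_module exceeds the network size")
  with_seed(seed, {
    start <- sample.int(n, 1L)
    visited <- integer(0)
    steps <- 50L * k_module
    while (length(visited) < k_module) {
      walk <- as.integer(igraph::random_walk(network, start, steps))
      visited <- unique(c(visited, walk))
      start <- walk[length(walk)]
      steps <- 2L * steps
    }
    members <- sort(visited[seq_len(k_module)])
    is_mem <- seq_len(n) %in% members
    rho <- attr_correlation
    latent <- stats::rnorm(n)
    u1 <- stats::pnorm(sqrt(rho) * latent + sqrt(1 - rho) * stats::rnorm(n))
    u2 <- stats::pnorm(sqrt(rho) * latent + sqrt(1 - rho) * stats::rnorm(n))
    p1 <- ifelse(is_mem, u1^(1 / signal_strength), stats::runif(n))
    p2 <- ifelse(is_mem, u2^(1 / signal_strength), stats::runif(n))
    p1 <- pmax(p1, 1e-300)
    p2 <- pmax(p2, 1e-300)
    list(scores = data.frame(gene = genes, spot_pw = p1, fsnp_pw = p2,
                             stringsAsFactors = FALSE),
         truth = list(module = genes[members],
                      k_module = k_module,
                      signal_strength = signal_strength,
                      attr_correlation = attr_correlation,
                      seed = as.integer(seed)))
  })
}

#' Generate synthetic gene sets with one planted enriched term
#'
#' Random gene sets over the network genes, with exactly one designated
#' term containing at least `planted_term_overlap` of the planted module.
#'
#' @param genes All gene symbols (the sampling pool).
#' @param planted_module Genes of the planted module.
#' @param n_terms Number of terms (default 40).
#' @param size_range Term size range (default `c(10, 60)`).
#' @param planted_term_overlap Fraction of the planted module that the
#'   designated term must contain (default 0.8).
#' @param seed RNG seed.
#' @return List with `collection` (a `gene_set_collection`) and
#'   `planted_term` (the designated term id).
#' @export
generate_gene_sets <- function(genes, planted_module, n_terms = 40L,
                               size_range = c(10L, 60L),
                               planted_term_overlap = 0.8, seed = 1L) {
  if (n_terms < 1) stop("n_terms must be positive")
  with_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n_terms))
    planted_id <- ids[sample.int(n_terms, 1L)]
    nonmod <- setdiff(genes, planted_module)
    sets <- vector("list", n_terms)
    names(sets) <- ids
    for (i in seq_len(n_terms)) {
      s <- sample(seq(size_range[1L], size_range[2L]), 1L)
      if (ids[i] == planted_id) {
        n_pl <- min(ceiling(planted_term_overlap * length(planted_module)),
                    length(planted_module))
        core <- sample(planted_module, n_pl)
        fill <- sample(nonmod, max(s - n_pl, 0L))
        sets[[i]] <- sort(unique(c(core, fill)))
      } else {
        sets[[i]] <- sort(sample(nonmod, s))
      }
    }
    nm <- sprintf("synthetic pathway %d", seq_len(n_terms))
    names(nm) <- ids
    coll <- structure(list(term_id = ids, term_name = nm, genes = sets,
                           universe = sort(unique(unlist(sets)))),
                      class = "gene_set_collection")
    list(collection = coll, planted_term = planted_id)
  })
}

#' Generate a SNP layer that inverts the gene-level scoring
#'
#' Emits SNP association and annotation tables such that running the SNP
#' scoring stage on them reproduces the intended per-gene weighted p-values.
#' For each gene, one carrier SNP gets `p = max(spot, fsnp)` target and
#' per-track precomputed scores `log10(p / target)`, so `p / 10^PS` equals
#' the target exactly; the remaining SNPs carry strictly larger weighted
#' p-values (weight-zero `intergenic` annotation). Genes listed in
#' `tf_genes` receive no SNPs; instead the TF map links them to the carrier
#' SNP of a randomly chosen signal gene, from which they inherit both
#' weighted p-values during scoring.
#'
#' @param gene_pw `data.frame` with `gene`, `spot_pw`, `fsnp_pw` (the
#'   intended gene-level weighted p-values).
#' @param snps_per_gene SNPs emitted per gene (default 3).
#' @param seed RNG seed.
#' @param tf_genes Genes to expose only through the TF map.
#' @param decoy_fraction Fraction of carrier SNPs that also list a decoy
#'   candidate gene with a strictly lower score (default 0.2), exercising
#'   the highest-priority gene selection.
#' @return List with `gwas` (`rsid`, `p`), `annotations` (`rsid`, `gene`,
#'   `track`, `categories`, `ps`), and `tf_map` (`rsid`, `tf_gene`).
#' @export
generate_snp_layer <- function(gene_pw, snps_per_gene = 3L, seed = 1L,
                               tf_genes = character(0), decoy_fraction = 0.2) {
  if (snps_per_gene < 1) stop("snps_per_gene must be at least 1")
  scored <- gene_pw[!(gene_pw$gene %in% tf_genes), , drop = FALSE]
  with_seed(seed, {
    n <- nrow(scored)
    rs_id <- 0L
    gwas <- vector("list", n)
    ann <- vector("list", n)
    carrier <- character(n)
    for (i in seq_len(n)) {
      t1 <- scored$spot_pw[i]
      t2 <- scored$fsnp_pw[i]
      pc <- max(t1, t2)
      rsids <- sprintf("rs%06d", rs_id + seq_len(snps_per_gene))
      rs_id <- rs_id + snps_per_gene
      carrier[i] <- rsids[1L]
      p_others <- if (snps_per_gene > 1)
        pc + (1 - pc) * stats::runif(snps_per_gene - 1L) else numeric(0)
      gwas[[i]] <- data.frame(rsid = rsids, p = c(pc, p_others),
                              stringsAsFactors = FALSE)
      g <- scored$gene[i]
      rows <- data.frame(
        rsid = c(rsids[1L], rsids[1L], rep(rsids[-1L], each = 2L)),
        gene = g,
        track = c("spot", "fsnp", rep(c("spot", "fsnp"),
                                      times = snps_per_gene - 1L)),
        categories = c("", "", rep("intergenic", 2L * (snps_per_gene - 1L))),
        ps = c(log10(pc / t1), log10(pc / t2),
               rep(NA_real_, 2L * (snps_per_gene - 1L))),
        stringsAsFactors = FALSE)
      # decoy candidate gene with strictly lower priority
      if (stats::runif(1) < decoy_fraction &&
          min(rows$ps[1:2]) > 0.01 && n > 1) {
        decoy <- scored$gene[sample(setdiff(seq_len(n), i), 1L)]
        rows <- rbind(rows, data.frame(
          rsid = rsids[1L], gene = decoy, track = c("spot", "fsnp"),
          categories = "intergenic", ps = NA_real_,
          stringsAsFactors = FALSE))
      }
      ann[[i]] <- rows
    }
    gwas <- do.call(rbind, gwas)
    annotations <- do.call(rbind, ann)
    tf_map <- data.frame(rsid = character(0), tf_gene = character(0),
                         stringsAsFactors = FALSE)
    if (length(tf_genes) > 0) {
      sig <- which(pmax(scored$spot_pw, scored$fsnp_pw) < 0.05)
      pool <- if (length(sig) > 0) sig else
        order(pmax(scored$spot_pw, scored$fsnp_pw))[seq_len(min(5L, n))]
      src <- carrier[sample(pool, length(tf_genes), replace = TRUE)]
      tf_map <- data.frame(rsid = src, tf_gene = sort(tf_genes),
                           stringsAsFactors = FALSE)
    }
    rownames(gwas) <- rownames(annotations) <- NULL
    list(gwas = gwas, annotations = annotations, tf_map = tf_map)
  })
}

#' Generate a complete synthetic dataset
#'
#' Builds every input the pipeline consumes — PPI network, planted
#' gene-level signal, gene sets with a planted enriched term, and a SNP
#' layer inverting the gene scores — plus the ground truth. Stage seeds are
#' derived from `seed` by fixed offsets, so a single integer reproduces the
#' whole dataset.
#'
#' @param n_nodes Network size (default 500).
#' @param module_size Planted module size (default 25).
#' @param signal_strength Beta shape for member p-values (default 0.1).
#' @param n_terms Number of gene sets (default 40).
#' @param seed Master RNG seed.
#' @param out_dir If non-NULL, all input files plus a `truth.json` manifest
#'   are written there.
#' @param ppi_model Network model, see [generate_ppi()].
#' @param snps_per_gene SNPs per gene (default 3).
#' @param tf_fraction Fraction of non-member genes exposed only through the
#'   TF map (default 0.05).
#' @param attr_correlation See [plant_signal()].
#' @param term_size_range,planted_term_overlap See [generate_gene_sets()].
#' @return List with `network`, `scores`, `truth`, `collection`, `gwas`,
#'   `annotations`, `tf_map`, and (when written) `files`.
#' @export
simulate_dataset <- function(n_nodes = 500L, module_size = 25L,
                             signal_strength = 0.1, n_terms = 40L,
                             seed = 1L, out_dir = NULL,
                             ppi_model = "preferential-attachment",
                             snps_per_gene = 3L, tf_fraction = 0.05,
                             attr_correlation = 0.8,
                             term_size_range = c(10L, 60L),
                             planted_term_overlap = 0.8) {
  seed <- as.integer(seed)
  network <- generate_ppi(n_nodes, ppi_model, seed = seed)
  planted <- plant_signal(network, module_size, signal_strength,
                          attr_correlation, seed = seed + 1L)
  sets <- generate_gene_sets(igraph::V(network)$name, planted$truth$module,
                             n_terms, term_size_range, planted_term_overlap,
                             seed = seed + 2L)
  nonmembers <- setdiff(igraph::V(network)$name, planted$truth$module)
  tf_genes <- with_seed(seed + 3L,
                        sort(sample(nonmembers,
                                    round(tf_fraction * length(nonmembers)))))
  layer <- generate_snp_layer(planted$scores, snps_per_gene, seed = seed + 4L,
                              tf_genes = tf_genes)
  truth <- c(planted$truth,
             list(planted_term = sets$planted_term, tf_genes = tf_genes,
                  n_nodes = n_nodes, n_terms = n_terms,
                  snps_per_gene = snps_per_gene, master_seed = seed))
  out <- list(network = network, scores = planted$scores, truth = truth,
              collection = sets$collection, gwas = layer$gwas,
              annotations = layer$annotations, tf_map = layer$tf_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(ppi = file.path(out_dir, "ppi.txt"),
               gwas = file.path(out_dir, "gwas.tsv"),
               annotations = file.path(out_dir, "annotations.tsv"),
               tf_map = file.path(out_dir, "tf_map.tsv"),
               gmt = file.path(out_dir, "pathways.gmt"),
               truth = file.path(out_dir, "truth.json"))
    el <- igraph::as_edgelist(network)
    utils::write.table(el[order(el[, 1L], el[, 2L]), , drop = FALSE],
                       files["ppi"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_gwas_table(data.frame(rsid = layer$gwas$rsid, p = layer$gwas$p),
                     files["gwas"])
    ann <- layer$annotations
    ann$ps <- ifelse(is.na(ann$ps), "", sprintf("%.17g", ann$ps))
    utils::write.table(ann, files["annotations"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(layer$tf_map, files["tf_map"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(sets$collection, files["gmt"])
    jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$files <- files
  }
  out
}
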