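#' Two-sided hypergeometric test
#'
#' For a module of `n` genes drawn from a universe of `N`, of which `K`
#' belong to the term, the probability of observing at least (enrichment) or
#' at most (depletion) `k` term members is computed from the hypergeometric
#' distribution; the two-sided p-value doubles the smaller tail and caps
#' at 1.
#'
#' @param k Observed overlap (0 <= k <= min(n, K)). Vectorized together
#'   with `K`.
#' @param n Module size within the universe.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return Two-sided p-value(s).
#' @export
hypergeom_two_sided <- function(k, n, K, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0))
    stop("validation error: inconsistent hypergeometric counts")
  p_enrich <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, K, N - K, n)
  pmin(1, 2 * pmin(p_enrich, p_deplete))
}

#' Gene-set enrichment of a module
#'
#' Tests every term of the collection for over/under-representation of the
#' module genes with the two-sided hypergeometric test, Bonferroni-corrected
#' over the tested terms. Terms with fewer than `min_genes` module genes are
#' excluded *before* correction. The universe is the union of all term genes.
#'
#' @param module_genes Character vector of module gene symbols.
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param min_genes Minimum module genes a term must contain to be tested
#'   (default 3; use 0 to test every term, including pure depletion).
#' @return `data.frame` of class `enrichment_result`, sorted by corrected
#'   p-value: `term_id`, `term_name`, `k_found`, `K`, `n`, `N`, `percent`
#'   (100 k/K), `p_raw`, `p_corr`, and list column `genes_found`.
#' @export
enrich_module <- function(module_genes, collection, min_genes = 3L) {
  if (length(collection$term_id) == 0) stop("empty gene-set collection")
  u <- collection$universe
  N <- length(u)
  mod <- intersect(unique(module_genes), u)
  n <- length(mod)
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k_found = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), percent = numeric(0),
                      p_raw = numeric(0), p_corr = numeric(0),
                      stringsAsFactors = FALSE)
  empty$genes_found <- list()
  class(empty) <- c("enrichment_result", "data.frame")
  if (n == 0) {
    warning("enrich_module: module is disjoint from the gene-set universe")
    return(empty)
  }
  gf <- lapply(collection$genes, function(g) sort(intersect(g, mod)))
  k <- lengths(gf)
  K <- lengths(collection$genes)
  keep <- k >= min_genes
  if (!any(keep)) {
    message("enrich_module: no term passes the min_genes filter")
    return(empty)
  }
  ids <- collection$term_id[keep]
  k <- k[keep]; K <- K[keep]; gf <- gf[keep]
  p <- hypergeom_two_sided(k, n, K, N)
  m <- length(ids)
  res <- data.frame(term_id = ids,
                    term_name = unname(collection$term_name[ids]),
                    k_found = as.integer(k), K = as.integer(K),
                    n = n, N = N,
                    percent = 100 * k / K,
                    p_raw = p,
                    p_corr = pmin(1, p * m),
                    stringsAsFactors = FALSE)
  res$genes_found <- gf
  o <- order(res$p_corr, -res$k_found, res$term_id)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  message(sprintf("enrich_module: %d terms tested (n = %d, N = %d)", m, n, N))
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two binary membership vectors over a
#' common universe: `kappa = (p_o - p_e) / (1 - p_e)`. Identical sets give
#' exactly 1; the statistic is symmetric in its arguments.
#'
#' @param genes_a,genes_b Character vectors, both subsets of `universe`.
#' @param universe Non-empty character vector of all genes considered.
#' @return The kappa statistic (scalar).
#' @export
cohen_kappa <- function(genes_a, genes_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  a <- unique(genes_a); b <- unique(genes_b)
  if (length(setdiff(a, universe)) > 0 || length(setdiff(b, universe)) > 0)
    stop("validation error: gene sets must be subsets of the universe")
  ina <- universe %in% a
  inb <- universe %in% b
  if (identical(ina, inb)) return(1)
  po <- mean(ina == inb)
  pa <- mean(ina); pb <- mean(inb)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) stop("kappa undefined: chance agreement is 1 for distinct sets")
  (po - pe) / (1 - pe)
}

# Pairwise kappa matrix over the genes_found sets of an enrichment result.
kappa_matrix <- function(results, universe) {
  m <- nrow(results)
  km <- matrix(1, m, m, dimnames = list(results$term_id, results$term_id))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        km[i, j] <- km[j, i] <- cohen_kappa(results$genes_found[[i]],
                                            results$genes_found[[j]],
                                            universe)
      }
    }
  }
  km
}

#' Group enriched terms by kappa similarity
#'
#' Terms are linked whenever the kappa agreement of their module-associated
#' gene sets reaches the threshold; groups are the connected components of
#' that term graph (single linkage). Each group's leading term is the member
#' with the smallest corrected p-value (ties: larger overlap, then term id).
#'
#' @param results An `enrichment_result` (>= 1 row).
#' @param kappa_threshold Linking threshold (default 0.3).
#' @param universe Universe for the membership vectors; defaults to the
#'   union of all `genes_found` sets (the analyzed module genes).
#' @return Object of class `term_groups`: list with `groups` (list of
#'   lists `group_id`, `terms`, `leading`), the `kappa` matrix, and the
#'   `threshold`.
#' @export
group_terms <- function(results, kappa_threshold = 0.3, universe = NULL) {
  if (nrow(results) == 0) stop("no enrichment results to group")
  if (is.null(universe))
    universe <- sort(unique(unlist(results$genes_found, use.names = FALSE)))
  km <- kappa_matrix(results, universe)
  adjm <- km >= kappa_threshold
  diag(adjm) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable group ids: order groups by their lexicographically first term
  first_term <- tapply(results$term_id, comp, min)
  relabel <- match(names(sort(first_term)), names(first_term))
  groups <- lapply(seq_along(relabel), function(gi) {
    sel <- comp == as.integer(names(first_term))[relabel[gi]]
    sub <- results[sel, , drop = FALSE]
    o <- order(sub$p_corr, -sub$k_found, sub$term_id)
    list(group_id = gi, terms = sort(sub$term_id),
         leading = sub$term_id[o[1L]])
  })
  structure(list(groups = groups, kappa = km, threshold = kappa_threshold),
            class = "term_groups")
}

#' @export
print.term_groups <- function(x, ...) {
  cat(sprintf("term_groups: %d groups (kappa >= %g)\n",
              length(x$groups), x$threshold))
  for (g in x$groups)
    cat(sprintf("  group %d (%d terms), leading: %s\n",
                g$group_id, length(g$terms), g$leading))
  invisible(x)
}

#' Build the term-level annotation network
#'
#' Nodes are enriched terms (size attribute `-log10` corrected p, group id,
#' leading-term flag); edges link term pairs whose kappa reaches the
#' threshold, annotated with the kappa value and the shared-gene count.
#'
#' @param results An `enrichment_result`.
#' @param groups The matching `term_groups` from [group_terms()].
#' @param threshold Edge threshold; defaults to the grouping threshold.
#' @return List with `nodes` and `edges` data frames.
#' @export
build_annotation_network <- function(results, groups,
                                     threshold = groups$threshold) {
  gid <- integer(nrow(results)); names(gid) <- results$term_id
  leading <- character(0)
  for (g in groups$groups) {
    gid[g$terms] <- g$group_id
    leading <- c(leading, g$leading)
  }
  nodes <- data.frame(
    term_id = results$term_id,
    term_name = results$term_name,
    neg_log10_p = -log10(pmax(results$p_corr, 1e-300)),
    group = unname(gid[results$term_id]),
    leading = results$term_id %in% leading,
    stringsAsFactors = FALSE)
  km <- groups$kappa
  ids <- results$term_id
  ea <- character(0); eb <- character(0); ek <- numeric(0); es <- integer(0)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        if (km[ids[i], ids[j]] >= threshold) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
          ek <- c(ek, km[ids[i], ids[j]])
          es <- c(es, length(intersect(results$genes_found[[i]],
                                       results$genes_found[[j]])))
        }
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(term_a = ea, term_b = eb, kappa = ek,
                          shared = es, stringsAsFactors = FALSE))
}

#' Compare two enrichment result sets term by term
#'
#' For every term present in either result set, reports the proportion of
#' its associated genes contributed by set A: `k_A / (k_A + k_B)`. Equal
#' contributions give 0.5.
#'
#' @param results_a,results_b `enrichment_result` objects.
#' @return `data.frame` with `term_id`, `k_a`, `k_b`, `proportion_a`.
#' @export
compare_term_sets <- function(results_a, results_b) {
  ids <- sort(union(results_a$term_id, results_b$term_id))
  ka <- results_a$k_found[match(ids, results_a$term_id)]
  kb <- results_b$k_found[match(ids, results_b$term_id)]
  ka[is.na(ka)] <- 0L
  kb[is.na(kb)] <- 0L
  data.frame(term_id = ids, k_a = ka, k_b = kb,
             proportion_a = ifelse(ka + kb > 0, ka / (ka + kb), NA_real_),
             stringsAsFactors = FALSE)
}

#' Drug-target overlap report
#'
#' Compares a target list against (a) the genes implicated directly by the
#' association scan and (b) the union of genes of all significant pathway
#' terms, and lists the targets gained by taking the pathway context.
#'
#' @param gwas_genes Genes implicated directly from the SNP layer.
#' @param pathway_genes Union of genes of all significant terms.
#' @param targets The drug-target gene list.
#' @return List with `n_targets`, `n_gwas_hit`, `n_pathway_hit`, and
#'   `gained` (targets hit via pathways but not directly, sorted).
#' @export
drug_target_overlap <- function(gwas_genes, pathway_genes, targets) {
  targets <- unique(targets)
  if (length(targets) == 0) warning("drug_target_overlap: empty target list")
  hit_gwas <- intersect(targets, gwas_genes)
  hit_path <- intersect(targets, pathway_genes)
  list(n_targets = length(targets),
       n_gwas_hit = length(hit_gwas),
       n_pathway_hit = length(hit_path),
       gained = sort(setdiff(hit_path, hit_gwas)))
}
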