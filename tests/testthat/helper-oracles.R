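# Shared helpers: silencing, tiny fixture builders, and the independent
# oracles used by the DERIVED expectations (exhaustive search, brute-force
# recounts). Oracles deliberately avoid the code paths they check.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# minimal node-score table
score_table <- function(genes, z_spot, z_fsnp = z_spot) {
  data.frame(gene = genes, z_spot = z_spot, z_fsnp = z_fsnp,
             stringsAsFactors = FALSE)
}

# gene-score table (Pw scale) from two p-value vectors
pw_table <- function(genes, spot, fsnp = spot) {
  data.frame(gene = genes, spot_pw = spot, fsnp_pw = fsnp,
             spot_snp = NA_character_, fsnp_snp = NA_character_,
             origin = "gwas-gene", stringsAsFactors = FALSE)
}

graph_from_edges <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(data.frame(from = el[, 1], to = el[, 2]),
                                directed = FALSE)
}

# BFS connectivity of a vertex subset, independent of igraph
subset_connected <- function(adj, mem) {
  if (length(mem) <= 1) return(TRUE)
  seen <- mem[1L]
  queue <- mem[1L]
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    new <- setdiff(intersect(adj[[v]], mem), seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == length(mem)
}

# Exhaustive optimum over all connected subsets (n <= ~12): the oracle for
# the greedy search. Uses the package's scoring primitives but enumerates
# candidates independently.
exhaustive_best_module <- function(g, scores, bg, max_size) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  stopifnot(n <= 15)
  idx <- match(vn, scores$gene)
  z1 <- scores$z_spot[idx]
  z2 <- scores$z_fsnp[idx]
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  best <- -Inf
  bestset <- NULL
  bits <- 2^(0:(n - 1))
  for (mask in seq_len(2^n - 1)) {
    mem <- which(bitwAnd(mask, bits) > 0)
    k <- length(mem)
    if (k > max_size) next
    if (!subset_connected(adj, mem)) next
    c1 <- corrected_score(sum(z1[mem]) / sqrt(k), k, bg, "spot")
    c2 <- corrected_score(sum(z2[mem]) / sqrt(k), k, bg, "fsnp")
    sc <- combine_attributes(c(c1, c2))
    if (sc > best) {
      best <- sc
      bestset <- sort(vn[mem])
    }
  }
  list(score = best, genes = bestset)
}

random_connected_graph <- function(n, p, seed) {
  gwasnet:::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    g
  })
}

# hypergeometric tail by explicit pmf summation (oracle)
hyper_tails_enum <- function(k, n, K, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  i <- lo:hi
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  c(enrich = sum(pmf[i >= k]), deplete = sum(pmf[i <= k]))
}
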