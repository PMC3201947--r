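# Expected maximum of j iid standard normal variables, j = 1..5.
# Closed forms: 0, 1/sqrt(pi), 3/(2 sqrt(pi)); j = 4, 5 are the classical
# numerically integrated order-statistic means. Used as the rank-adjustment
# penalty when combining calibrated scores across attributes.
.EXPECTED_MAX_NORMAL <- c(0,
                          0.56418958354775628,
                          0.84628437532163443,
                          1.02937537300645358,
                          1.16296447438592882)

#' Convert a weighted p-value to a z-score
#'
#' Uses the upper-tail convention `z = qnorm(1 - pw)`: a small p-value maps
#' to a large positive score, so a module score three standard deviations
#' above the randomized mean corresponds to the significance threshold 3.
#' Input is clamped to `[1e-15, 1 - 1e-15]` before the transform to keep the
#' result finite.
#'
#' @param pw Weighted p-value(s) in (0, 1].
#' @return Standard-normal-scale score(s).
#' @export
pvalue_to_z <- function(pw) {
  if (any(is.na(pw)) || any(pw <= 0))
    stop("validation error: p-values must be strictly positive")
  if (any(pw > 1)) stop("validation error: p-values must not exceed 1")
  stats::qnorm(1 - pmin(pmax(pw, 1e-15), 1 - 1e-15))
}

#' Raw score of a sub-network
#'
#' The aggregate score of a k-gene sub-network is the sum of its gene
#' z-scores divided by `sqrt(k)`; under independent standard-normal node
#' scores this keeps mean and variance independent of size.
#'
#' @param zs Numeric vector of member z-scores (length >= 1).
#' @return The raw score `sum(zs) / sqrt(length(zs))`.
#' @export
score_subnetwork <- function(zs) {
  if (length(zs) == 0) stop("validation error: empty sub-network")
  sum(zs) / sqrt(length(zs))
}

#' Build the node-score table for a network
#'
#' Transforms the per-gene weighted p-values to z-scores and restricts to
#' genes present in the network.
#'
#' @param gene_scores Gene-score table (see [aggregate_gene_pw()]).
#' @param network An igraph PPI network.
#' @return `data.frame` with columns `gene`, `z_spot`, `z_fsnp`, sorted by
#'   gene.
#' @export
node_score_table <- function(gene_scores, network) {
  keep <- gene_scores$gene %in% igraph::V(network)$name
  message(sprintf("node_score_table: %d of %d scored genes found in the network",
                  sum(keep), nrow(gene_scores)))
  gs <- gene_scores[keep, , drop = FALSE]
  out <- data.frame(gene = gs$gene,
                    z_spot = pvalue_to_z(gs$spot_pw),
                    z_fsnp = pvalue_to_z(gs$fsnp_pw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo background for module scores
#'
#' For each module size k the raw scores of `n_samples` random size-k gene
#' sets, drawn without replacement from the empirical node-score table, are
#' summarized by their mean and standard deviation. Each attribute is
#' calibrated independently. Sampling draws score values, not uniform
#' p-values, and sets are not required to be connected.
#'
#' @param scores Node-score table (see [node_score_table()]); every column
#'   other than `gene` is treated as one attribute, with the `z_` prefix
#'   stripped for the attribute name.
#' @param sizes Module sizes to cover; defaults to `1:min(300, n - 1)`
#'   where n is the number of scored genes. Internally all sizes up to the
#'   maximum are tabulated (cumulative sampling makes this free).
#' @param n_samples Random sets per size (default 10000, minimum 100).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return Object of class `score_background`: list with `sizes`, `attrs`
#'   (per attribute, vectors `mean` and `sd` indexed by size), `n_samples`,
#'   `seed`.
#' @export
calibrate_background <- function(scores, sizes = NULL, n_samples = 10000L,
                                 seed = 1L) {
  zcols <- setdiff(names(scores), "gene")
  if (length(zcols) == 0) stop("no score columns in the node-score table")
  n <- nrow(scores)
  if (n == 0) stop("empty node-score table")
  if (is.null(sizes)) sizes <- seq_len(min(300L, n - 1L))
  if (length(sizes) == 0) stop("sizes must be non-empty")
  if (n_samples < 100) stop("n_samples must be at least 100")
  maxk <- max(sizes)
  if (maxk > n)
    stop("validation error: requested module size ", maxk,
         " exceeds the ", n, " scored genes")
  attrs <- list()
  with_seed(seed, {
    for (a in zcols) {
      z <- scores[[a]]
      if (!all(is.finite(z)))
        stop("validation error: non-finite score in column ", a)
      sums <- vapply(seq_len(n_samples),
                     function(i) cumsum(sample(z, maxk)),
                     numeric(maxk))
      S <- sums / sqrt(seq_len(maxk))
      m <- rowMeans(S)
      sdv <- sqrt(rowSums((S - m)^2) / (n_samples - 1))
      if (any(sdv <= 0))
        stop("degenerate background: zero score variance at size ",
             which(sdv <= 0)[1L], " (are all node scores identical?)")
      attrs[[sub("^z_", "", a)]] <- list(mean = m, sd = sdv)
    }
  })
  structure(list(sizes = seq_len(maxk), attrs = attrs,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "score_background")
}

#' @export
print.score_background <- function(x, ...) {
  cat(sprintf("score_background: sizes 1..%d, %d samples/size, attributes: %s\n",
              max(x$sizes), x$n_samples, paste(names(x$attrs), collapse = ", ")))
  invisible(x)
}

#' Size-calibrated module score
#'
#' Standardizes a raw score against the Monte-Carlo background for its size:
#' `(S - mean_k) / sd_k`.
#'
#' @param S Raw score(s).
#' @param k Module size(s), each covered by the background table.
#' @param bg A `score_background`.
#' @param attribute Which attribute's background to use (default `"spot"`).
#' @return Calibrated score(s).
#' @export
corrected_score <- function(S, k, bg, attribute = "spot") {
  if (!attribute %in% names(bg$attrs))
    stop("unknown attribute '", attribute, "' in background table")
  if (any(!(k %in% bg$sizes)))
    stop("module size ", setdiff(k, bg$sizes)[1L],
         " missing from background table; recalibrate with a larger size range")
  (S - bg$attrs[[attribute]]$mean[k]) / bg$attrs[[attribute]]$sd[k]
}

#' Combine calibrated scores across attributes
#'
#' Scores are sorted in decreasing order; for every prefix of j attributes
#' the prefix sum rescaled by `sqrt(j)` is penalized by the expected maximum
#' of j independent standard normals (a shipped constant table), and the
#' combined score is the maximum over prefixes. With a single attribute this
#' reduces to the calibrated score itself; the penalty removes the selection
#' advantage of picking the best-scoring attributes after the fact.
#'
#' @param cal_scores Numeric vector of per-attribute calibrated scores
#'   (1 to 5 attributes).
#' @return The combined score (scalar).
#' @export
combine_attributes <- function(cal_scores) {
  m <- length(cal_scores)
  if (m < 1) stop("at least one attribute score required")
  if (m > length(.EXPECTED_MAX_NORMAL))
    stop("rank-adjustment constants are shipped for up to ",
         length(.EXPECTED_MAX_NORMAL), " attributes")
  s <- sort(cal_scores, decreasing = TRUE)
  j <- seq_len(m)
  max(cumsum(s) / sqrt(j) - .EXPECTED_MAX_NORMAL[j])
}

# Vectorized two-attribute combination (internal greedy kernel).
combine2 <- function(c1, c2) {
  pmax(pmax(c1, c2), (c1 + c2) / sqrt(2) - .EXPECTED_MAX_NORMAL[2L])
}

#' Greedy search for active sub-networks
#'
#' From every scored node as a seed, the module repeatedly absorbs the
#' frontier neighbor that maximizes the combined calibrated score, stopping
#' as soon as no addition strictly increases the score or the size cap is
#' reached (strict hill climbing, no plateau toleration). Ties are broken by
#' the larger node z-score (maximum over attributes), then by gene symbol.
#' Modules whose combined score exceeds the threshold are kept; duplicate
#' gene sets are merged and results sorted by decreasing score. The search
#' runs on the subgraph induced by scored genes only.
#'
#' @param network An igraph PPI network.
#' @param scores Node-score table with `z_spot` and `z_fsnp`.
#' @param bg A `score_background` covering sizes up to `max_size`.
#' @param threshold Significance cutoff on the combined score (default 3).
#' @param max_size Maximum module size (default 300).
#' @return A `data.frame` of class `module_set` with columns `module_id`,
#'   `seed_gene`, `k`, `s_spot`, `s_fsnp`, `s_spot_cal`, `s_fsnp_cal`,
#'   `score`, and a list column `genes` (sorted gene symbols).
#' @export
greedy_search <- function(network, scores, bg, threshold = 3, max_size = 300L) {
  if (nrow(scores) == 0) stop("empty node-score table")
  for (a in c("spot", "fsnp"))
    if (!a %in% names(bg$attrs)) stop("background table lacks attribute ", a)
  vids <- which(igraph::V(network)$name %in% scores$gene)
  g <- igraph::induced_subgraph(network, vids)
  vnames <- igraph::V(g)$name
  nv <- length(vnames)
  if (nv == 0) stop("no scored gene is present in the network")
  max_size <- min(max_size, max(bg$sizes))
  idx <- match(vnames, scores$gene)
  z1 <- scores$z_spot[idx]
  z2 <- scores$z_fsnp[idx]
  zmax <- pmax(z1, z2)
  m1 <- bg$attrs$spot$mean; s1v <- bg$attrs$spot$sd
  m2 <- bg$attrs$fsnp$mean; s2v <- bg$attrs$fsnp$sd
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  found <- list()
  for (seed in order(vnames)) {
    mem <- logical(nv)
    mem[seed] <- TRUE
    k <- 1L
    sum1 <- z1[seed]; sum2 <- z2[seed]
    cur <- combine2((sum1 - m1[1L]) / s1v[1L], (sum2 - m2[1L]) / s2v[1L])
    frontier <- adj[[seed]]
    frontier <- frontier[!mem[frontier]]
    while (k < max_size && length(frontier) > 0) {
      k2 <- k + 1L
      c1 <- ((sum1 + z1[frontier]) / sqrt(k2) - m1[k2]) / s1v[k2]
      c2 <- ((sum2 + z2[frontier]) / sqrt(k2) - m2[k2]) / s2v[k2]
      comb <- combine2(c1, c2)
      best <- order(-comb, -zmax[frontier], vnames[frontier])[1L]
      if (comb[best] <= cur) break
      v <- frontier[best]
      mem[v] <- TRUE
      k <- k2
      sum1 <- sum1 + z1[v]; sum2 <- sum2 + z2[v]
      cur <- comb[best]
      nb <- adj[[v]]
      frontier <- c(frontier[frontier != v], nb[!mem[nb] & !(nb %in% frontier)])
    }
    if (cur > threshold) {
      members <- which(mem)
      found[[length(found) + 1L]] <- list(
        seed_gene = vnames[seed], k = k,
        s_spot = sum1 / sqrt(k), s_fsnp = sum2 / sqrt(k),
        s_spot_cal = (sum1 / sqrt(k) - m1[k]) / s1v[k],
        s_fsnp_cal = (sum2 / sqrt(k) - m2[k]) / s2v[k],
        score = cur, genes = sort(vnames[members]))
    }
  }
  if (length(found) == 0) {
    message("greedy_search: no module exceeds the threshold")
    out <- data.frame(module_id = character(0), seed_gene = character(0),
                      k = integer(0), s_spot = numeric(0), s_fsnp = numeric(0),
                      s_spot_cal = numeric(0), s_fsnp_cal = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    out$genes <- list()
    class(out) <- c("module_set", "data.frame")
    return(out)
  }
  key <- vapply(found, function(f) paste(f$genes, collapse = ";"), character(1))
  found <- found[!duplicated(key)]
  key <- key[!duplicated(key)]
  score <- vapply(found, `[[`, numeric(1), "score")
  o <- order(-score, key)
  found <- found[o]
  out <- data.frame(
    module_id = sprintf("M%03d", seq_along(found)),
    seed_gene = vapply(found, `[[`, character(1), "seed_gene"),
    k = vapply(found, `[[`, integer(1), "k"),
    s_spot = vapply(found, `[[`, numeric(1), "s_spot"),
    s_fsnp = vapply(found, `[[`, numeric(1), "s_fsnp"),
    s_spot_cal = vapply(found, `[[`, numeric(1), "s_spot_cal"),
    s_fsnp_cal = vapply(found, `[[`, numeric(1), "s_fsnp_cal"),
    score = vapply(found, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  out$genes <- lapply(found, `[[`, "genes")
  rownames(out) <- NULL
  message(sprintf("greedy_search: %d significant modules (threshold %g)",
                  nrow(out), threshold))
  class(out) <- c("module_set", "data.frame")
  out
}

#' Select the top-scoring modules
#'
#' Keeps the n best modules by combined score and reports the pairwise
#' member overlap, measured as the intersection size divided by the smaller
#' module (greedy growth from different seeds often rediscovers largely the
#' same gene set).
#'
#' @param modules A `module_set` from [greedy_search()].
#' @param n Number of modules to keep (default 5).
#' @return The top-n `module_set`, with a numeric `overlap` matrix attached
#'   as an attribute.
#' @export
select_top_modules <- function(modules, n = 5L) {
  top <- utils::head(modules, n)
  m <- nrow(top)
  ov <- matrix(1, m, m, dimnames = list(top$module_id, top$module_id))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        a <- top$genes[[i]]; b <- top$genes[[j]]
        ov[i, j] <- ov[j, i] <-
          length(intersect(a, b)) / min(length(a), length(b))
      }
    }
  }
  attr(top, "overlap") <- ov
  top
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- utils::head(x, 10)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s k=%d score=%.3f seed=%s\n", show$module_id[i],
                  show$k[i], show$score[i], show$seed_gene[i]))
  }
  invisible(x)
}
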