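test_that("hypergeom_two_sided doubles the smaller exact tail", {
  # worked case: N=10, K=5, n=4, k=4; enrichment tail C(5,4)C(5,0)/C(10,4)
  one_sided <- 5 / 210
  expect_equal(hypergeom_two_sided(4, 4, 5, 10), 2 * one_sided)
  # k at the mode -> two-sided p caps at 1
  expect_equal(hypergeom_two_sided(2, 4, 5, 10), 1)
  # K = N: every draw is in the term
  expect_equal(hypergeom_two_sided(4, 4, 10, 10), 1)
  expect_error(hypergeom_two_sided(5, 4, 5, 10), "inconsistent")
  expect_error(hypergeom_two_sided(1, 4, 11, 10), "inconsistent")
})

test_that("enrich_module ranks a fully contained term first", {
  genes <- sprintf("G%03d", 1:100)
  sets <- split(genes, rep(1:10, each = 10))
  ids <- sprintf("T%02d", 1:10)
  names(sets) <- ids
  nm <- ids; names(nm) <- ids
  coll <- structure(list(term_id = ids, term_name = nm, genes = sets,
                         universe = genes), class = "gene_set_collection")
  module <- sets[["T03"]][1:8]
  res <- quiet(enrich_module(module, coll, min_genes = 0))
  expect_equal(res$term_id[1], "T03")
  expect_equal(res$k_found[1], 8)
  expect_equal(res$percent[1], 80)
  # oracle: direct enumeration over the 10 terms
  for (i in seq_len(nrow(res))) {
    tails <- hyper_tails_enum(res$k_found[i], 8, res$K[i], 100)
    expect_equal(res$p_raw[i], min(1, 2 * min(tails)))
  }
  # Bonferroni over the 10 tested terms, capped at 1
  expect_equal(res$p_corr, pmin(1, res$p_raw * 10))
  # min_genes = 0 keeps zero-overlap terms scored on the depletion side
  z <- res[res$k_found == 0, ]
  expect_true(all(z$p_raw > 0))
  # default prefilter removes them before correction
  res3 <- quiet(enrich_module(module, coll))
  expect_equal(nrow(res3), 1)
  expect_equal(res3$p_corr, res3$p_raw)  # m = 1
  # disjoint module
  expect_warning(empty <- suppressMessages(
    enrich_module("NOT_THERE", coll)), "disjoint")
  expect_equal(nrow(empty), 0)
})

test_that("adding a term gene to the module never weakens its enrichment", {
  # the enrichment tail is monotone everywhere; the two-sided p only on the
  # enrichment side (on the depletion side, gaining a term gene weakens the
  # depletion signal, which correctly raises the two-sided p)
  N <- 60
  K <- 15
  for (n0 in c(5, 10, 20)) {
    for (k0 in seq_len(min(n0, K) - 1)) {
      tail_before <- hyper_tails_enum(k0, n0, K, N)[["enrich"]]
      tail_after <- hyper_tails_enum(k0 + 1, n0 + 1, K, N)[["enrich"]]
      expect_lte(tail_after, tail_before + 1e-12)
      before <- hyper_tails_enum(k0, n0, K, N)
      after <- hyper_tails_enum(k0 + 1, n0 + 1, K, N)
      if (before[["enrich"]] <= before[["deplete"]] &&
          after[["enrich"]] <= after[["deplete"]]) {
        expect_lte(hypergeom_two_sided(k0 + 1, n0 + 1, K, N),
                   hypergeom_two_sided(k0, n0, K, N) + 1e-12)
      }
    }
  }
})

test_that("cohen_kappa matches the 2x2 hand computation and its symmetries", {
  u <- sprintf("G%03d", 1:100)
  expect_equal(cohen_kappa(u[1:5], u[1:5], u), 1.0)
  # disjoint 5-gene sets: p_o = .90, p_e = .905
  expect_equal(cohen_kappa(u[1:5], u[6:10], u),
               (0.90 - 0.905) / (1 - 0.905))
  gwasnet:::with_seed(81, {
    for (i in 1:5) {
      a <- sample(u, 20)
      b <- sample(u, 35)
      expect_equal(cohen_kappa(a, b, u), cohen_kappa(b, a, u))
      # invariance under relabeling of the universe
      perm <- setNames(sample(u), u)
      expect_equal(cohen_kappa(unname(perm[a]), unname(perm[b]), unname(perm[u])),
                   cohen_kappa(a, b, u))
    }
  })
  expect_error(cohen_kappa("X", u[1], u), "subsets")
  # both sets equal to the universe are identical, hence kappa = 1 by the
  # identity rule (the p_e = 1 error branch is unreachable for valid input)
  expect_equal(cohen_kappa(u, u, u), 1)
  expect_true(is.finite(cohen_kappa(u, u[1:99], u)))
})

make_enrichment <- function(sets, universe, p_corr = NULL) {
  m <- length(sets)
  res <- data.frame(term_id = names(sets), term_name = names(sets),
                    k_found = lengths(sets), K = lengths(sets),
                    n = length(universe), N = length(universe),
                    percent = 100, p_raw = seq(0.001, 0.01, length.out = m),
                    p_corr = p_corr %||% seq(0.01, 0.1, length.out = m),
                    stringsAsFactors = FALSE)
  res$genes_found <- unname(sets)
  class(res) <- c("enrichment_result", "data.frame")
  res
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group_terms forms kappa components with correct leading terms", {
  u <- sprintf("G%03d", 1:100)
  # all pairwise kappa below threshold -> singleton groups
  sets <- list(T01 = u[1:5], T02 = u[20:24], T03 = u[40:44])
  gr <- group_terms(make_enrichment(sets, u), 0.3, universe = u)
  expect_length(gr$groups, 3)
  # identical gene sets -> one group, leading = smaller p_corr
  sets2 <- list(T01 = u[1:5], T02 = u[1:5])
  gr2 <- group_terms(make_enrichment(sets2, u, p_corr = c(0.05, 0.01)),
                     0.3, universe = u)
  expect_length(gr2$groups, 1)
  expect_equal(gr2$groups[[1]]$leading, "T02")
})

test_that("grouping matches brute-force components and ignores term order", {
  u <- sprintf("G%03d", 1:120)
  # 12 terms in 3 blocks of heavy sharing
  blocks <- list(1:30, 41:70, 81:110)
  sets <- list()
  gwasnet:::with_seed(83, {
    for (b in 1:3) for (j in 1:4) {
      sets[[sprintf("T%02d", (b - 1) * 4 + j)]] <-
        u[sample(blocks[[b]], 22)]
    }
  })
  res <- make_enrichment(sets, u)
  gr <- group_terms(res, 0.3, universe = u)
  # oracle: independent component search on the kappa graph
  m <- length(sets)
  adj <- matrix(FALSE, m, m)
  for (i in 1:m) for (j in 1:m) {
    if (i != j)
      adj[i, j] <- cohen_kappa(sets[[i]], sets[[j]], u) >= 0.3
  }
  comp <- integer(m)
  cid <- 0
  for (s in 1:m) {
    if (comp[s] > 0) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  expected <- sort(vapply(split(names(sets), comp),
                          function(x) paste(sort(x), collapse = ","),
                          character(1)))
  got <- sort(vapply(gr$groups, function(g) paste(g$terms, collapse = ","),
                     character(1)))
  expect_equal(unname(got), unname(expected))
  # order invariance
  perm <- gwasnet:::with_seed(84, sample(m))
  gr_p <- group_terms(res[perm, ], 0.3, universe = u)
  got_p <- sort(vapply(gr_p$groups, function(g) paste(g$terms, collapse = ","),
                       character(1)))
  expect_equal(got_p, got)
})

test_that("build_annotation_network emits correct nodes and edges", {
  u <- sprintf("G%03d", 1:50)
  one <- make_enrichment(list(T01 = u[1:6]), u)
  gr1 <- group_terms(one, 0.3, universe = u)
  net1 <- build_annotation_network(one, gr1)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
  expect_true(net1$nodes$leading)
  two <- make_enrichment(list(T01 = u[1:6], T02 = u[1:6]), u)
  gr2 <- group_terms(two, 0.3, universe = u)
  net2 <- build_annotation_network(two, gr2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$shared, 6)
  expect_equal(net2$edges$kappa, 1)
  expect_equal(net2$nodes$neg_log10_p, -log10(two$p_corr))
})

test_that("compare_term_sets reports set-A proportions", {
  u <- sprintf("G%02d", 1:40)
  a <- make_enrichment(list(T01 = u[1:4], T02 = u[5:10]), u)
  b <- make_enrichment(list(T02 = u[5:10], T03 = u[11:17]), u)
  cmp <- compare_term_sets(a, b)
  expect_equal(cmp$proportion_a[cmp$term_id == "T03"], 0)
  expect_equal(cmp$proportion_a[cmp$term_id == "T02"], 0.5)
  expect_equal(cmp$proportion_a[cmp$term_id == "T01"], 1)
  expect_equal(cmp$k_b[cmp$term_id == "T03"], 7)
})

test_that("drug_target_overlap counts direct and pathway-level hits", {
  gwas_genes <- sprintf("G%02d", 1:20)
  pathway <- sprintf("G%02d", 10:40)
  targets <- c(sprintf("G%02d", c(1, 2, 15)), sprintf("G%02d", 25:28),
               "X1", "X2", "X3")
  rep <- drug_target_overlap(gwas_genes, pathway, targets)
  expect_equal(rep$n_targets, 10)
  expect_equal(rep$n_gwas_hit, 3)
  expect_equal(rep$n_pathway_hit, 5)
  expect_equal(rep$gained, sprintf("G%02d", 25:28))
  # targets inside the gwas set gain nothing
  rep2 <- drug_target_overlap(gwas_genes, pathway, gwas_genes[1:5])
  expect_equal(rep2$gained, character(0))
  rep3 <- quiet(drug_target_overlap(gwas_genes, pathway, c("Z1", "Z2")))
  expect_equal(rep3$n_gwas_hit + rep3$n_pathway_hit, 0)
  expect_warning(drug_target_overlap(gwas_genes, pathway, character(0)),
                 "empty")
})
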