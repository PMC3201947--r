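test_that("filter_nominal keeps p strictly below alpha, in order", {
  snps <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                     p = c(0.04, 0.05, 0.049999), stringsAsFactors = FALSE)
  kept <- quiet(filter_nominal(snps, 0.05))
  expect_equal(kept$rsid, c("rs1", "rs3"))
  expect_equal(quiet(filter_nominal(snps, 1.0))$rsid, snps$rsid)

  big <- gwasnet:::with_seed(3, data.frame(
    rsid = sprintf("rs%04d", 1:1000), p = runif(1000)))
  kept2 <- quiet(filter_nominal(big, 0.05))
  expect_equal(nrow(kept2), sum(big$p < 0.05))
  expect_error(filter_nominal(big, 0), "alpha")
})

test_that("compute_ps combines category weights, caps, and overrides", {
  sch <- default_scheme()
  sch$weights <- c(missense = 1.0, conserved = 0.5)
  expect_equal(compute_ps(list(categories = c("missense", "conserved")), sch),
               1.5)
  expect_equal(compute_ps(list(categories = "missense,conserved"), sch), 1.5)
  sch$cap <- 1.0
  expect_equal(compute_ps(list(categories = c("missense", "conserved")), sch),
               1.0)
  expect_equal(compute_ps(list(categories = character(0), ps = 0)), 0)
  expect_equal(compute_ps(list(categories = "missense", ps = 2.25), sch), 2.25)
  expect_error(compute_ps(list(categories = "mystery"), default_scheme()),
               "unknown functional category 'mystery'")
  expect_error(compute_ps(list(categories = character(0))), "neither")
  expect_error(compute_ps(list(categories = "", ps = -1)), "non-negative")
})

test_that("weight_pvalue implements P/10^PS with its monotonicities", {
  expect_identical(weight_pvalue(0.04, 0), 0.04)
  expect_equal(weight_pvalue(0.04, 1), 0.004)
  expect_equal(weight_pvalue(1e-6, 3), 1e-9)
  expect_error(weight_pvalue(0.04, -1), "non-negative")
  expect_error(weight_pvalue(0, 1), "\\(0, 1\\]")
  # strictly decreasing in PS, strictly increasing in p
  ps <- seq(0, 5, by = 0.25)
  expect_true(all(diff(weight_pvalue(rep(0.3, length(ps)), ps)) < 0))
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(weight_pvalue(p, 1.7)) > 0))
  # never exceeds the raw p
  gwasnet:::with_seed(5, {
    pr <- runif(200)
    pw <- weight_pvalue(pr, runif(200, 0, 4))
    expect_true(all(pw <= pr))
  })
})

test_that("assign_snps_to_genes picks the highest-PS candidate per track", {
  snps <- data.frame(rsid = c("rs1", "rs2"), p = c(0.01, 0.02),
                     stringsAsFactors = FALSE)
  ann <- data.frame(
    rsid = c("rs1", "rs1", "rs2", "rs2"),
    gene = c("GENE_A", "GENE_B", "GENE_B", "GENE_A"),
    track = "spot",
    categories = c("", "", "missense", "missense"),
    ps = c(2.0, 0.5, NA, NA),
    stringsAsFactors = FALSE)
  res <- quiet(assign_snps_to_genes(snps, ann))
  expect_equal(res$gene[res$rsid == "rs1"], "GENE_A")     # highest priority
  expect_equal(res$gene[res$rsid == "rs2"], "GENE_A")     # tie -> lexicographic
  expect_equal(res$ps[res$rsid == "rs2"], 1.5)
})

test_that("assignment equals brute-force per-SNP argmax on 200 SNPs", {
  n <- 200
  gwasnet:::with_seed(7, {
    snps <- data.frame(rsid = sprintf("rs%03d", 1:n), p = runif(n, 0, 0.05))
    rows <- do.call(rbind, lapply(1:n, function(i) {
      k <- sample(1:4, 1)
      data.frame(rsid = snps$rsid[i],
                 gene = sprintf("G%03d", sample(60, k)),
                 track = sample(c("spot", "fsnp"), k, replace = TRUE),
                 categories = "", ps = round(runif(k, 0, 3), 2),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- quiet(assign_snps_to_genes(snps, rows))
  # oracle: exhaustive scan per (SNP, track)
  for (tr in c("spot", "fsnp")) {
    sub <- rows[rows$track == tr, ]
    for (rs in unique(sub$rsid)) {
      cand <- sub[sub$rsid == rs, ]
      best <- cand[cand$ps == max(cand$ps), "gene"]
      expect_equal(res$gene[res$rsid == rs & res$track == tr],
                   min(best))
    }
  }
})

test_that("aggregate_gene_pw takes the per-gene minimum Pw per track", {
  snps <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                     p = c(0.04, 0.01, 0.02, 0.03), stringsAsFactors = FALSE)
  asg <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs1", "rs4"),
    track = c("spot", "spot", "spot", "fsnp", "fsnp"),
    gene = c("A", "A", "A", "A", "B"),
    ps = c(1, 2, 0, 0, 0), stringsAsFactors = FALSE)
  gs <- quiet(aggregate_gene_pw(asg, snps))
  # A spot Pw candidates: .004, .0001, .02 -> min .0001 from rs2
  expect_equal(gs$spot_pw[gs$gene == "A"], 1e-4)
  expect_equal(gs$spot_snp[gs$gene == "A"], "rs2")
  expect_equal(gs$fsnp_pw[gs$gene == "A"], 0.04)
  # B has no spot rows: falls back to raw min p of its SNPs with PS = 0
  expect_equal(gs$spot_pw[gs$gene == "B"], 0.03)
  expect_equal(gs$fsnp_pw[gs$gene == "B"], 0.03)
})

test_that("aggregation equals a brute-force double loop on a 50-gene fixture", {
  gwasnet:::with_seed(9, {
    n <- 400
    snps <- data.frame(rsid = sprintf("rs%03d", 1:n), p = runif(n, 0, 0.05))
    asg <- data.frame(rsid = snps$rsid,
                      track = sample(c("spot", "fsnp"), n, replace = TRUE),
                      gene = sprintf("G%02d", sample(50, n, replace = TRUE)),
                      ps = round(runif(n, 0, 3), 3),
                      stringsAsFactors = FALSE)
  })
  gs <- quiet(aggregate_gene_pw(asg, snps))
  pw <- snps$p[match(asg$rsid, snps$rsid)] / 10^asg$ps
  for (g in unique(asg$gene)) {
    for (tr in c("spot", "fsnp")) {
      sel <- asg$gene == g & asg$track == tr
      expected <- if (any(sel)) min(pw[sel]) else
        min(snps$p[match(asg$rsid[asg$gene == g], snps$rsid)])
      expect_equal(gs[[paste0(tr, "_pw")]][gs$gene == g], expected)
    }
  }
  # conservation: every contributing SNP is a filtered SNP of that gene
  expect_true(all(gs$spot_snp %in% asg$rsid))
  expect_true(all(gs$fsnp_snp %in% asg$rsid))
})

test_that("with all PS = 0 the gene Pw equals the minimum raw p", {
  gwasnet:::with_seed(13, {
    snps <- data.frame(rsid = sprintf("rs%02d", 1:60), p = runif(60))
    asg <- data.frame(rsid = snps$rsid,
                      track = rep(c("spot", "fsnp"), 30),
                      gene = sprintf("G%01d", sample(8, 60, replace = TRUE)),
                      ps = 0, stringsAsFactors = FALSE)
  })
  gs <- quiet(aggregate_gene_pw(asg, snps))
  p <- snps$p[match(asg$rsid, snps$rsid)]
  for (g in gs$gene) {
    sel <- asg$gene == g
    for (tr in c("spot", "fsnp")) {
      selt <- sel & asg$track == tr
      expected <- if (any(selt)) min(p[selt]) else min(p[sel])
      expect_equal(gs[[paste0(tr, "_pw")]][gs$gene == g], expected)
    }
  }
})

test_that("augment_tfbs adds only unscored TFs, transferring SNP Pw pairs", {
  gs <- pw_table(c("A", "B", "C", "D"), c(0.01, 0.02, 0.03, 0.04))
  spw <- data.frame(rsid = sprintf("rs%02d", 1:10), p = 0.04,
                    spot_pw = seq(0.001, 0.01, by = 0.001),
                    fsnp_pw = seq(0.002, 0.02, by = 0.002),
                    stringsAsFactors = FALSE)
  # 10 pairs, 4 point at already-scored genes -> exactly 6 additions
  tf_map <- data.frame(rsid = spw$rsid,
                       tf_gene = c("A", "B", "C", "D", sprintf("TF%d", 1:6)),
                       stringsAsFactors = FALSE)
  out <- quiet(augment_tfbs(gs, tf_map, spw))
  expect_equal(nrow(out), 10)
  expect_equal(sum(out$origin == "tfbs-gene"), 6)
  expect_equal(out$spot_pw[out$gene == "TF1"], spw$spot_pw[5])
  expect_equal(out$fsnp_pw[out$gene == "TF1"], spw$fsnp_pw[5])
  # already-scored entries unchanged
  expect_equal(out$spot_pw[out$gene == "A"], 0.01)
  # unknown SNP rows are ignored with a warning
  bad <- data.frame(rsid = "rs99", tf_gene = "TF9")
  expect_warning(out2 <- suppressMessages(augment_tfbs(gs, bad, spw)),
                 "ignored")
  expect_identical(out2, gs)
})
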