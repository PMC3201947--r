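#' Controlled vocabulary of SNP functional categories
#'
#' Consequence and evidence classes a SNP annotation row may carry. These
#' stand in for the output of external SNP-annotation services: coding
#' consequences, splicing and regulatory evidence, conservation, and linkage
#' proxies.
#'
#' @return Character vector of category codes.
#' @export
functional_categories <- function() {
  c("nonsense", "frameshift", "missense", "utr5", "utr3", "splicing",
    "transcriptional", "posttranslational", "conserved", "intronic",
    "intergenic", "ld_proxy")
}

#' Default prioritization scheme
#'
#' Maps each functional category to a non-negative prioritization-score
#' increment. Coding-disruptive consequences weigh most, regulatory and
#' splicing evidence intermediately, and location-only evidence least.
#' The weights are configuration data, not a published scoring formula:
#' annotation rows may instead carry a precomputed score (`ps` column) that
#' bypasses category weighting entirely.
#'
#' @param combine How to combine the weights of a row's categories:
#'   `"sum"` (default, additive evidence) or `"max"`.
#' @param cap Optional upper bound applied to the combined score
#'   (default `Inf`).
#' @return A list with elements `weights`, `combine`, `cap`.
#' @export
default_scheme <- function(combine = c("sum", "max"), cap = Inf) {
  combine <- match.arg(combine)
  if (cap < 0) stop("cap must be non-negative")
  list(weights = c(nonsense = 2, frameshift = 2, missense = 1.5,
                   splicing = 1, transcriptional = 1,
                   utr5 = 0.5, utr3 = 0.5, posttranslational = 0.5,
                   conserved = 0.5, ld_proxy = 0.2, intronic = 0.1,
                   intergenic = 0),
       combine = combine, cap = cap)
}

#' Compute the prioritization score of one annotation row
#'
#' If the row carries a precomputed score (`ps_override`, or column `ps`),
#' that value is returned as-is. Otherwise the scheme's weights for the
#' row's categories are combined (`sum` or `max`) and capped.
#'
#' @param row A list or one-row `data.frame` with `categories` (character
#'   vector or comma-joined string) and optionally `ps_override`/`ps`.
#' @param scheme A prioritization scheme, see [default_scheme()].
#' @return A non-negative numeric scalar.
#' @export
compute_ps <- function(row, scheme = default_scheme()) {
  over <- row$ps_override %||% row$ps
  if (!is.null(over) && length(over) == 1L && !is.na(over)) {
    over <- as.numeric(over)
    if (over < 0) stop("validation error: precomputed PS must be non-negative")
    return(over)
  }
  cats <- row$categories
  if (is.list(cats)) cats <- cats[[1L]]
  if (is.character(cats) && length(cats) == 1L)
    cats <- strsplit(cats, ",", fixed = TRUE)[[1L]]
  cats <- trimws(cats)
  cats <- cats[nzchar(cats)]
  if (length(cats) == 0)
    stop("validation error: annotation row has neither categories nor a precomputed PS")
  unknown <- setdiff(cats, names(scheme$weights))
  if (length(unknown) > 0)
    stop("configuration error: unknown functional category '", unknown[1L], "'")
  w <- scheme$weights[cats]
  ps <- if (identical(scheme$combine, "max")) max(w) else sum(w)
  min(ps, scheme$cap %||% Inf)
}

#' Weight an association p-value by a prioritization score
#'
#' Computes the functionally weighted p-value `Pw = P / 10^PS`. Smaller
#' values indicate higher priority; with `PS = 0` the p-value is unchanged,
#' and the result never exceeds the raw p-value.
#'
#' @param p Association p-value(s) in (0, 1].
#' @param ps Non-negative prioritization score(s).
#' @return Weighted p-value(s), elementwise `p / 10^ps`.
#' @export
weight_pvalue <- function(p, ps) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("validation error: p-values must lie in (0, 1]")
  if (any(is.na(ps)) || any(ps < 0))
    stop("validation error: prioritization scores must be non-negative")
  p / 10^ps
}

#' Keep SNPs with nominal evidence of association
#'
#' Strict threshold: records with `p < alpha` are kept, in input order.
#'
#' @param snps SNP table as returned by [read_gwas_table()].
#' @param alpha Significance threshold in (0, 1]; default 0.05.
#' @return The filtered SNP table.
#' @export
filter_nominal <- function(snps, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  out <- snps[snps$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("filter_nominal: %d of %d SNPs with p < %g",
                  nrow(out), nrow(snps), alpha))
  if (nrow(out) == 0) warning("filter_nominal: no SNP survives the threshold")
  out
}

# Per-row PS for an annotation table (internal).
annotation_ps <- function(annotations, schemes) {
  n <- nrow(annotations)
  ps <- numeric(n)
  has_ps <- "ps" %in% names(annotations)
  for (i in seq_len(n)) {
    row <- list(categories = annotations$categories[i],
                ps = if (has_ps) annotations$ps[i] else NULL)
    sch <- schemes[[annotations$track[i]]]
    if (is.null(sch))
      stop("configuration error: no scheme for track '",
           annotations$track[i], "'")
    ps[i] <- compute_ps(row, sch)
  }
  ps
}

#' Assign each SNP to its highest-priority candidate gene, per track
#'
#' An annotation table may propose several candidate genes per SNP (one row
#' per SNP/gene/track). For every SNP and scoring track the candidate whose
#' row yields the highest prioritization score is chosen; ties are broken by
#' the lexicographically smallest gene symbol. SNPs without any annotation
#' row are dropped (count reported).
#'
#' @param snps Filtered SNP table (see [filter_nominal()]).
#' @param annotations `data.frame` with columns `rsid`, `gene`, `track`
#'   (values `"spot"`/`"fsnp"`), `categories`, and optionally `ps`.
#' @param schemes Named list of prioritization schemes, one per track.
#' @return `data.frame` with columns `rsid`, `track`, `gene`, `ps`: one row
#'   per (SNP, track) pair that has at least one candidate.
#' @export
assign_snps_to_genes <- function(snps, annotations,
                                 schemes = list(spot = default_scheme(),
                                                fsnp = default_scheme())) {
  ann <- annotations[annotations$rsid %in% snps$rsid, , drop = FALSE]
  n_dropped <- length(setdiff(snps$rsid, ann$rsid))
  if (n_dropped > 0)
    message(sprintf("assign_snps_to_genes: %d SNPs without annotation dropped",
                    n_dropped))
  if (nrow(ann) == 0) {
    return(data.frame(rsid = character(0), track = character(0),
                      gene = character(0), ps = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ann$ps_value <- annotation_ps(ann, schemes)
  o <- order(ann$track, ann$rsid, -ann$ps_value, ann$gene)
  ann <- ann[o, , drop = FALSE]
  key <- paste(ann$track, ann$rsid, sep = "\r")
  first <- !duplicated(key)
  ties <- tapply(ann$ps_value, key, function(v) sum(v == max(v)) > 1)
  if (any(ties))
    message(sprintf("assign_snps_to_genes: %d (SNP, track) ties broken lexicographically",
                    sum(ties)))
  out <- data.frame(rsid = ann$rsid[first], track = ann$track[first],
                    gene = ann$gene[first], ps = ann$ps_value[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-SNP weighted p-values on both tracks
#'
#' For every assigned SNP, the weighted p-value on each track: `p / 10^PS`
#' with the track's assigned PS, or the raw p-value (PS = 0) when the SNP
#' has no assignment on that track.
#'
#' @param assignments Output of [assign_snps_to_genes()].
#' @param snps Filtered SNP table supplying the raw p-values.
#' @return `data.frame` with columns `rsid`, `p`, `spot_pw`, `fsnp_pw`.
#' @export
snp_pw_table <- function(assignments, snps) {
  rsids <- sort(unique(assignments$rsid))
  p <- snps$p[match(rsids, snps$rsid)]
  if (any(is.na(p)))
    stop("validation error: assigned SNP missing from the SNP table")
  out <- data.frame(rsid = rsids, p = p, spot_pw = p, fsnp_pw = p,
                    stringsAsFactors = FALSE)
  for (tr in c("spot", "fsnp")) {
    rows <- assignments[assignments$track == tr, , drop = FALSE]
    i <- match(rows$rsid, rsids)
    out[[paste0(tr, "_pw")]][i] <- weight_pvalue(p[i], rows$ps)
  }
  out
}

#' Aggregate SNP-level weighted p-values to gene level
#'
#' Per gene and per track, the gene's weighted p-value is the minimum over
#' its assigned SNPs; the contributing SNP is recorded. A gene annotated on
#' only one track receives the other attribute from the raw minimum p of its
#' assigned SNPs (PS = 0); the number of such fallbacks is reported.
#'
#' @param assignments Output of [assign_snps_to_genes()].
#' @param snps Filtered SNP table supplying raw p-values.
#' @return Gene-score `data.frame`: `gene`, `spot_pw`, `fsnp_pw`,
#'   `spot_snp`, `fsnp_snp`, `origin` (here always `"gwas-gene"`), sorted
#'   by gene symbol.
#' @export
aggregate_gene_pw <- function(assignments, snps) {
  p <- snps$p[match(assignments$rsid, snps$rsid)]
  if (any(is.na(p)))
    stop("validation error: assigned SNP missing from the SNP table")
  pw <- weight_pvalue(p, assignments$ps)
  genes <- sort(unique(assignments$gene))
  res <- data.frame(gene = genes,
                    spot_pw = NA_real_, fsnp_pw = NA_real_,
                    spot_snp = NA_character_, fsnp_snp = NA_character_,
                    origin = "gwas-gene", stringsAsFactors = FALSE)
  n_fallback <- 0L
  for (tr in c("spot", "fsnp")) {
    sel <- assignments$track == tr
    sub <- assignments[sel, , drop = FALSE]
    sub$pw <- pw[sel]
    sub <- sub[order(sub$gene, sub$pw, sub$rsid), , drop = FALSE]
    first <- !duplicated(sub$gene)
    i <- match(sub$gene[first], genes)
    res[[paste0(tr, "_pw")]][i] <- sub$pw[first]
    res[[paste0(tr, "_snp")]][i] <- sub$rsid[first]
  }
  # fallback: gene absent from one track entirely -> raw min p, PS = 0
  for (tr in c("spot", "fsnp")) {
    col <- paste0(tr, "_pw")
    miss <- which(is.na(res[[col]]))
    if (length(miss) == 0) next
    n_fallback <- n_fallback + length(miss)
    for (i in miss) {
      sel <- assignments$gene == res$gene[i]
      praw <- p[sel]
      j <- order(praw, assignments$rsid[sel])[1L]
      res[[col]][i] <- praw[j]
      res[[paste0(tr, "_snp")]][i] <- assignments$rsid[sel][j]
    }
  }
  if (n_fallback > 0)
    message(sprintf(
      "aggregate_gene_pw: %d gene attributes filled from raw p (PS = 0) because the gene is absent from one track",
      n_fallback))
  message(sprintf("aggregate_gene_pw: %d genes scored", nrow(res)))
  rownames(res) <- NULL
  res
}

#' Add transcription factors inferred from binding-site overlap
#'
#' SNPs overlapping a known transcription-factor binding site transfer their
#' two weighted p-values to the bound transcription factor, unless that gene
#' is already scored. Map rows whose SNP is not among the scored SNPs are
#' ignored with a warning. Pairs are processed in input order; once a TF has
#' been added, later pairs naming it are skipped.
#'
#' @param gene_scores Gene-score table from [aggregate_gene_pw()].
#' @param tf_map `data.frame` with columns `rsid` and `tf_gene`.
#' @param snp_pw Per-SNP weighted p-values from [snp_pw_table()].
#' @return The extended gene-score table; added rows carry
#'   `origin = "tfbs-gene"`.
#' @export
augment_tfbs <- function(gene_scores, tf_map, snp_pw) {
  if (is.null(tf_map) || nrow(tf_map) == 0) return(gene_scores)
  unknown <- !(tf_map$rsid %in% snp_pw$rsid)
  if (any(unknown)) {
    warning(sprintf("augment_tfbs: %d TF-map rows ignored (SNP not scored)",
                    sum(unknown)))
    tf_map <- tf_map[!unknown, , drop = FALSE]
  }
  present <- gene_scores$gene
  added <- 0L
  for (i in seq_len(nrow(tf_map))) {
    tf <- tf_map$tf_gene[i]
    if (tf %in% present) next
    j <- match(tf_map$rsid[i], snp_pw$rsid)
    gene_scores <- rbind(gene_scores, data.frame(
      gene = tf, spot_pw = snp_pw$spot_pw[j], fsnp_pw = snp_pw$fsnp_pw[j],
      spot_snp = snp_pw$rsid[j], fsnp_snp = snp_pw$rsid[j],
      origin = "tfbs-gene", stringsAsFactors = FALSE))
    present <- c(present, tf)
    added <- added + 1L
  }
  message(sprintf("augment_tfbs: %d transcription factors added", added))
  gene_scores <- gene_scores[order(gene_scores$gene), , drop = FALSE]
  rownames(gene_scores) <- NULL
  gene_scores
}
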